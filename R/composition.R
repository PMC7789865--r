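#' Per-gene nucleotide and positional GC composition
#'
#' Computes, for each coding sequence, the base fractions of the coding
#' region, GC content at each codon position (GC1, GC2, GC3), their
#' derived summaries GC12 = (GC1 + GC2)/2 and GCall = (GC1 + GC2 + GC3)/3,
#' the synonymous third-position GC content GC3s (third positions of codons
#' whose amino acid has two or more synonymous codons; ATG, TGG and stops
#' excluded), and third-position base counts A3/U3/G3/C3 in the scope chosen
#' for parity-rule-2 analysis. The terminal stop codon is excluded from every
#' metric. All fractions are reported on `[0, 1]`; multiply by 100 only at
#' the reporting layer.
#'
#' @param cds Tibble of QC-passed CDS (`id`, `sequence`).
#' @param pr2_scope Codon scope for the A3/U3/G3/C3 counts:
#'   `"fourfold_only"` (default; third positions of the eight fourfold
#'   quartets, Sueoka's parity-rule convention) or `"all_synonymous"` (third
#'   positions of all 59 informative codons).
#' @return A tibble with one row per gene: `id`, `frac_a`, `frac_t`,
#'   `frac_g`, `frac_c`, `gc1`, `gc2`, `gc3`, `gc12`, `gc_all`, `gc3s`,
#'   `a3`, `u3`, `g3`, `c3`, `pr2_scope`. `gc3s` is `NA` when the gene has
#'   no synonymous codon; the counts are over DNA, so `u3` counts third-
#'   position T.
#' @examples
#' cds <- tibble::tibble(id = "g1", sequence = "ATGTTTTTCTGA")
#' codon_composition(cds)$gc3s  # TTT -> T, TTC -> C: 0.5
#' @export
codon_composition <- function(cds, pr2_scope = c("fourfold_only", "all_synonymous")) {
  pr2_scope <- match.arg(pr2_scope)
  stopifnot(is.data.frame(cds), all(c("id", "sequence") %in% names(cds)))
  counts <- count_codons(cds, include_stop = FALSE)
  m <- counts_matrix(counts)
  ct <- codon_table()
  stopifnot(identical(colnames(m), ct$codon))

  base_at <- function(pos) substr(ct$codon, pos, pos)
  gc_at <- function(pos) {
    w <- as.numeric(base_at(pos) %in% c("G", "C"))
    unname(as.vector(m %*% w) / rowSums(m))
  }
  frac_of <- function(base) {
    per_codon <- vapply(seq_len(64), function(i) {
      sum(strsplit(ct$codon[i], "")[[1]] == base)
    }, numeric(1))
    unname(as.vector(m %*% per_codon) / (3 * rowSums(m)))
  }

  gc1 <- gc_at(1); gc2 <- gc_at(2); gc3 <- gc_at(3)

  syn <- ct$informative
  syn_tot <- rowSums(m[, syn, drop = FALSE])
  syn_gc <- as.vector(m[, syn, drop = FALSE] %*%
                        as.numeric(ct$third[syn] %in% c("G", "C")))
  gc3s <- unname(ifelse(syn_tot > 0, syn_gc / syn_tot, NA_real_))

  tp <- third_position_counts(counts, scope = pr2_scope)

  tibble::tibble(
    id = counts$id,
    frac_a = frac_of("A"), frac_t = frac_of("T"),
    frac_g = frac_of("G"), frac_c = frac_of("C"),
    gc1 = gc1, gc2 = gc2, gc3 = gc3,
    gc12 = (gc1 + gc2) / 2,
    gc_all = (gc1 + gc2 + gc3) / 3,
    gc3s = gc3s,
    a3 = tp$a3, u3 = tp$u3, g3 = tp$g3, c3 = tp$c3,
    pr2_scope = pr2_scope
  )
}

#' Synonymous third-position GC content (GC3s)
#'
#' Convenience accessor for the `gc3s` column of [codon_composition()]:
#' the G+C fraction at third positions of codons whose amino acid has at
#' least two synonymous codons (ATG, TGG and termination codons excluded).
#'
#' @inheritParams codon_composition
#' @return A tibble `id`, `gc3s` (`NA` where no synonymous codon exists).
#' @export
gc3s_of <- function(cds) {
  codon_composition(cds)[, c("id", "gc3s")]
}

#' Third-position base counts per gene
#'
#' Counts A/T(U)/G/C at codon third positions over a selected codon scope,
#' as input to parity-rule-2 bias analysis.
#'
#' @param counts Wide per-gene codon count tibble from [count_codons()]
#'   (or a CDS tibble with `id`, `sequence`, which is counted first).
#' @param scope `"fourfold_only"`: third positions of the eight fourfold-
#'   degenerate quartets (CTN, GTN, TCN, CCN, ACN, GCN, CGN, GGN);
#'   `"all_synonymous"`: third positions of all 59 informative codons.
#' @return Tibble `id`, `a3`, `u3`, `g3`, `c3`, `scope`. Rows with an empty
#'   scope have all-zero counts; downstream PR2 analysis excludes them.
#' @examples
#' cds <- tibble::tibble(id = "g1", sequence = "ATGGTTGTAGTCGTGTGA")
#' third_position_counts(count_codons(cds), "fourfold_only")
#' @export
third_position_counts <- function(counts, scope = c("fourfold_only", "all_synonymous")) {
  scope <- match.arg(scope)
  if ("sequence" %in% names(counts) && !"AAA" %in% names(counts)) {
    counts <- count_codons(counts, include_stop = FALSE)
  }
  m <- counts_matrix(counts)
  ct <- codon_table()
  in_scope <- if (scope == "fourfold_only") {
    ct$codon %in% fourfold_codons()
  } else {
    ct$informative
  }
  count_base <- function(base) {
    w <- as.numeric(in_scope & ct$third == base)
    as.vector(m %*% w)
  }
  tibble::tibble(
    id = counts$id,
    a3 = count_base("A"), u3 = count_base("T"),
    g3 = count_base("G"), c3 = count_base("C"),
    scope = scope
  )
}

#' GC-content histogram table
#'
#' Bins per-gene overall GC content at a fixed width, the tabular analogue
#' of the usual GC-distribution histogram.
#'
#' @param composition Tibble from [codon_composition()].
#' @param width Bin width on the percentage scale (default 2.5).
#' @return Tibble `bin_low`, `bin_high` (percent), `n`.
#' @export
gc_histogram <- function(composition, width = 2.5) {
  pct <- composition$gc_all * 100
  lo <- floor(min(pct) / width) * width
  hi <- ceiling(max(pct) / width) * width
  if (hi <= lo) hi <- lo + width
  breaks <- seq(lo, hi, by = width)
  bin <- cut(pct, breaks = breaks, include.lowest = TRUE, right = FALSE)
  tibble::tibble(
    bin_low = breaks[-length(breaks)],
    bin_high = breaks[-1],
    n = as.integer(table(bin))
  )
}
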