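#' Relative synonymous codon usage (RSCU)
#'
#' RSCU of a codon is its observed count divided by the count expected if
#' all codons of the same amino-acid family were used equally:
#' `RSCU(c) = k * n_c / sum(family counts)` for a family of degeneracy `k`.
#' Values above 1 mark codons used more than expected. Leu, Ser and Arg are
#' single six-fold families; ATG and TGG have RSCU 1 by definition when
#' present. Counts from several genes are pooled before the ratio is taken.
#'
#' @param counts Wide per-gene count tibble from [count_codons()], or a
#'   named numeric vector of pooled codon counts.
#' @param include_stops Also report the three termination codons as a
#'   `k = 3` family (as pooled usage tables often print a `Ter` block)?
#' @return A tibble `amino_acid`, `codon`, `k`, `n`, `rscu`, sorted by
#'   (amino acid, codon). Families with zero total have `rscu = NA`, not 0.
#' @examples
#' rscu(c(TTT = 1118, TTC = 567))  # Phe family
#' @export
rscu <- function(counts, include_stops = FALSE) {
  n <- if (is.data.frame(counts)) pool_counts(counts) else counts
  assert_codons(names(n))
  ct <- codon_table()
  full <- stats::setNames(rep(0, 64), ct$codon)
  full[names(n)] <- n
  keep <- if (include_stops) rep(TRUE, 64) else ct$aa1 != "*"
  out <- tibble::tibble(
    amino_acid = ct$amino_acid[keep],
    codon = ct$codon[keep],
    k = ct$k[keep],
    n = unname(full[keep])
  )
  out <- dplyr::mutate(
    dplyr::group_by(out, .data$amino_acid),
    fam_total = sum(.data$n),
    rscu = dplyr::if_else(.data$fam_total > 0,
                          .data$k * .data$n / .data$fam_total, NA_real_)
  )
  out <- dplyr::ungroup(out)
  dplyr::arrange(dplyr::select(out, -"fam_total"), .data$amino_acid, .data$codon)
}

#' Per-gene RSCU matrix over the 59 informative codons
#'
#' One RSCU row per gene, the input expected by [coa_rscu()]. Families
#' absent from a gene yield `NA` entries (imputed downstream).
#'
#' @param counts Wide per-gene count tibble from [count_codons()].
#' @return Numeric matrix, genes x 59 informative codons, gene ids as
#'   rownames.
#' @export
rscu_matrix <- function(counts) {
  m <- counts_matrix(counts)
  ct <- codon_table()
  info <- which(ct$informative)
  fam <- ct$amino_acid[info]
  k <- ct$k[info]
  sub <- m[, info, drop = FALSE]
  fam_tot <- t(rowsum(t(sub), fam))          # genes x families
  denom <- fam_tot[, fam, drop = FALSE]      # expand to codon columns
  out <- sweep(sub, 2, k, `*`) / denom
  out[denom == 0] <- NA_real_
  dimnames(out) <- list(rownames(m), ct$codon[info])
  out
}

#' Effective number of codons (ENc), Wright's estimator
#'
#' Estimates, per gene, the effective number of codons actually in use:
#' 20 means one codon per amino acid (maximal bias), 61 means fully uniform
#' synonymous usage. For each amino-acid family with total count `n > 1`,
#' the codon homozygosity is `F = (n * sum(p^2) - 1) / (n - 1)` with `p`
#' the within-family codon frequencies; class means `F2, F3, F4, F6` over
#' families of degeneracy 2/3/4/6 give
#' `ENc = 2 + 9/F2 + 1/F3 + 5/F4 + 3/F6`, capped into `[20, 61]`.
#'
#' Families with `n <= 1` or `F = 0` are uninformative and excluded. When a
#' whole degeneracy class is missing: the 3-fold class (Ile only) is imputed
#' as `(F2 + F4)/2`; any other missing class simply drops out of the sum
#' (its numerator is rescaled to the number of families observed, i.e. 0).
#' A gene with no informative family at all returns `NA`.
#'
#' @param counts Wide per-gene count tibble from [count_codons()] (stop
#'   codons are ignored), or a named numeric vector for a single gene.
#' @return Tibble `id`, `enc`, `n_classes_missing` (of the four degeneracy
#'   classes). For vector input the `id` is `"gene"`.
#' @examples
#' cds <- tibble::tibble(id = "g1",
#'   sequence = paste0("ATG", strrep("TTTTTC", 60), "TGA"))
#' enc(count_codons(cds))
#' @export
enc <- function(counts) {
  if (!is.data.frame(counts)) {
    counts <- dplyr::bind_cols(tibble::tibble(id = "gene"),
                               tibble::as_tibble(as.list(counts)))
  }
  m <- counts_matrix(counts)
  if (nrow(m) == 0) {
    return(tibble::tibble(id = character(), enc = numeric(),
                          n_classes_missing = integer()))
  }
  res <- vapply(seq_len(nrow(m)), function(i) enc_one(m[i, ]), numeric(2))
  tibble::tibble(
    id = counts$id,
    enc = unname(res["enc", ]),
    n_classes_missing = as.integer(res["missing", ])
  )
}

# Wright's estimator for one gene (named codon-count vector over 64 codons).
enc_one <- function(n) {
  ct <- codon_table()
  sense <- ct$informative | ct$codon %in% c("ATG", "TGG")
  fam <- split(n[sense], ct$amino_acid[sense])
  f_hat <- vapply(fam, function(x) {
    tot <- sum(x)
    if (tot <= 1) return(NA_real_)
    f <- (tot * sum((x / tot)^2) - 1) / (tot - 1)
    if (f <= 0) NA_real_ else f
  }, numeric(1))
  k_of <- vapply(fam, length, integer(1))
  f_bar <- vapply(c(2, 3, 4, 6), function(k) {
    mean(f_hat[k_of == k], na.rm = TRUE)
  }, numeric(1))
  names(f_bar) <- c("F2", "F3", "F4", "F6")
  n_aa <- c(9, 1, 5, 3)  # family counts per degeneracy class
  missing <- is.nan(f_bar)
  if (missing[["F3"]] && !missing[["F2"]] && !missing[["F4"]]) {
    f_bar[["F3"]] <- (f_bar[["F2"]] + f_bar[["F4"]]) / 2
    missing[["F3"]] <- FALSE
  }
  if (all(missing)) return(c(enc = NA_real_, missing = 4))
  value <- 2 + sum(n_aa[!missing] / f_bar[!missing])
  c(enc = min(max(value, 20), 61), missing = sum(missing))
}

#' Expected ENc under pure compositional (mutational) bias
#'
#' The null curve for the ENc vs GC3s plot: the ENc a gene would show if
#' codon choice depended only on its third-position G+C content `s`,
#' `ENc_exp(s) = 2 + s + 29 / (s^2 + (1 - s)^2)`.
#'
#' @param gc3s Numeric vector of GC3s values in `[0, 1]`.
#' @return Numeric vector of expected ENc values.
#' @examples
#' expected_enc(c(0, 0.5))  # 31, 60.5
#' @export
expected_enc <- function(gc3s) {
  stopifnot(all(gc3s >= 0 & gc3s <= 1, na.rm = TRUE))
  2 + gc3s + 29 / (gc3s^2 + (1 - gc3s)^2)
}

#' Relative deviation of observed from expected ENc
#'
#' `(ENc_exp - ENc_obs) / ENc_exp`: positive values mean the gene uses fewer
#' effective codons than its composition alone predicts.
#'
#' @param enc_obs,enc_exp Numeric vectors.
#' @return Numeric vector of deviations.
#' @export
enc_deviation <- function(enc_obs, enc_exp) {
  stopifnot(all(enc_exp > 0, na.rm = TRUE))
  (enc_exp - enc_obs) / enc_exp
}

#' Relative-adaptiveness weights for CAI
#'
#' Pools the codon counts of a reference gene set (ideally highly expressed
#' genes) and scores each informative codon by its within-family relative
#' adaptiveness `w = n_c / max(family counts)`, so the most-used codon of
#' each family has `w = 1`. Codons unobserved in the reference are floored
#' at 0.5 occurrences before weighting, so no weight is exactly zero; a
#' family entirely absent from the reference gets uninformative weights of
#' 1 with a warning.
#'
#' @param reference Wide per-gene count tibble (one or more reference
#'   genes), or a named pooled count vector.
#' @return Tibble `amino_acid`, `codon`, `n`, `w` over the 59 informative
#'   codons.
#' @examples
#' cai_weights(c(AAA = 4, AAG = 2))  # w = 1, 0.5
#' @export
cai_weights <- function(reference) {
  n <- if (is.data.frame(reference)) pool_counts(reference) else reference
  assert_codons(names(n))
  ct <- codon_table()
  full <- stats::setNames(rep(0, 64), ct$codon)
  full[names(n)] <- n
  info <- ct$informative
  out <- tibble::tibble(
    amino_acid = ct$amino_acid[info],
    codon = ct$codon[info],
    n = unname(full[info])
  )
  out <- dplyr::group_by(out, .data$amino_acid)
  out <- dplyr::mutate(out, fam_absent = sum(.data$n) == 0,
                       n_floor = pmax(.data$n, 0.5),
                       w = dplyr::if_else(.data$fam_absent, 1,
                                          .data$n_floor / max(.data$n_floor)))
  out <- dplyr::ungroup(out)
  if (any(out$fam_absent)) {
    warning("reference has empty families (weights set to 1): ",
            paste(unique(out$amino_acid[out$fam_absent]), collapse = ", "),
            call. = FALSE)
  }
  dplyr::select(out, "amino_acid", "codon", "n", "w")
}

#' Codon adaptation index (CAI)
#'
#' The geometric mean of relative-adaptiveness weights over a gene's codons,
#' excluding ATG, TGG and stops. CAI is 1 when a gene uses only the
#' reference-preferred codon of every family. Computed as
#' `exp(mean(count-weighted log w))` for numerical stability.
#'
#' @param counts Wide per-gene count tibble from [count_codons()].
#' @param weights Weight tibble from [cai_weights()] (columns `codon`, `w`).
#' @return Tibble `id`, `cai` (`NA` for genes with no informative codon).
#' @export
cai <- function(counts, weights) {
  stopifnot(all(c("codon", "w") %in% names(weights)),
            all(weights$w > 0 & weights$w <= 1))
  m <- counts_matrix(counts)
  logw <- stats::setNames(rep(NA_real_, 64), all_codons())
  logw[weights$codon] <- log(weights$w)
  use <- !is.na(logw) & all_codons() %in% informative_codons()
  sub <- m[, use, drop = FALSE]
  tot <- rowSums(sub)
  score <- as.vector(sub %*% logw[use])
  tibble::tibble(id = counts$id,
                 cai = unname(ifelse(tot > 0, exp(score / tot), NA_real_)))
}

#' Per-gene composition and codon-usage index table
#'
#' One-stop computation of the per-gene record used by all downstream
#' diagnostics: composition ([codon_composition()]), ENc, GC3s-expected ENc
#' and its relative deviation, and CAI. The CAI reference defaults to the
#' pooled counts of the `reference_fraction` of genes with lowest ENc (the
#' most codon-biased genes, the usual stand-in for highly expressed genes
#' when no expression measure is available); pass `cai_reference` to use an
#' explicit reference instead.
#'
#' @param cds Tibble of QC-passed CDS (`id`, `sequence`).
#' @param cai_reference Optional weight tibble from [cai_weights()] or a
#'   reference count tibble/vector to derive weights from.
#' @param reference_fraction Fraction of lowest-ENc genes pooled for the
#'   default CAI reference (default 0.05).
#' @param pr2_scope Passed to [codon_composition()].
#' @return Tibble: `id`, `length_aa`, composition columns, `gc3s`, `enc`,
#'   `enc_exp`, `enc_dev`, `cai`.
#' @export
gene_metrics <- function(cds, cai_reference = NULL, reference_fraction = 0.05,
                         pr2_scope = "fourfold_only") {
  counts <- count_codons(cds, include_stop = FALSE)
  comp <- codon_composition(cds, pr2_scope = pr2_scope)
  enc_tab <- enc(counts)

  weights <- if (is.null(cai_reference)) {
    ranked <- dplyr::arrange(enc_tab, .data$enc, .data$id)
    n_ref <- max(1L, floor(reference_fraction * nrow(ranked) + 0.5))
    ref_ids <- ranked$id[seq_len(n_ref)]
    cai_weights(dplyr::filter(counts, .data$id %in% ref_ids))
  } else if (is.data.frame(cai_reference) && "w" %in% names(cai_reference)) {
    cai_reference
  } else {
    cai_weights(cai_reference)
  }
  cai_tab <- cai(counts, weights)

  out <- dplyr::left_join(comp, enc_tab[, c("id", "enc")], by = "id")
  out <- dplyr::left_join(out, cai_tab, by = "id")
  out$length_aa <- unname(rowSums(counts_matrix(counts)))
  out$enc_exp <- expected_enc(out$gc3s)
  out$enc_dev <- enc_deviation(out$enc, out$enc_exp)
  dplyr::relocate(out, "id", "length_aa")
}
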