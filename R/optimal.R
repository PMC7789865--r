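#' Partition genes into high- and low-expression sets by CAI
#'
#' Ranks genes by CAI (descending) and takes the top and bottom
#' `fraction` as the putative high- and low-expression sets used for
#' optimal-codon determination. Ties are broken by gene id
#' (lexicographic) so the partition is deterministic. Each set has
#' `max(1, round(fraction * n))` genes (half-up rounding).
#'
#' @param metrics Tibble with columns `id`, `cai` (e.g. [gene_metrics()]).
#' @param fraction Fraction per tail, in `(0, 0.5]` (default 0.05).
#' @return List of class `expression_partition`: `high_ids`, `low_ids`,
#'   `fraction`, `n_per_set`.
#' @export
partition_by_cai <- function(metrics, fraction = 0.05) {
  stopifnot(all(c("id", "cai") %in% names(metrics)),
            fraction > 0, fraction <= 0.5)
  d <- metrics[!is.na(metrics$cai), c("id", "cai")]
  n <- nrow(d)
  n_set <- max(1L, as.integer(floor(fraction * n + 0.5)))
  if (n < 2 * n_set || n < 2 / fraction) {
    stop("too few genes (", n, ") for disjoint ", fraction, " tails",
         call. = FALSE)
  }
  # one global ranking, so the two tails are disjoint even under ties
  ranked <- dplyr::arrange(d, dplyr::desc(.data$cai), .data$id)
  structure(
    list(high_ids = ranked$id[seq_len(n_set)],
         low_ids = rev(ranked$id[seq(n - n_set + 1, n)]),
         fraction = fraction, n_per_set = n_set),
    class = "expression_partition"
  )
}

#' @export
print.expression_partition <- function(x, ...) {
  cat("Expression partition by CAI:", x$n_per_set, "genes per tail (fraction",
      x$fraction, ")\n")
  invisible(x)
}

#' Pooled high/low RSCU table
#'
#' Sums codon counts within the high- and low-expression pools and computes
#' each pool's RSCU (stop codons included as a `Ter` family, as pooled
#' usage tables conventionally print them). Per-gene RSCU values are not
#' averaged: the pooled counts are what the chi-square test operates on.
#'
#' @param high,low Wide per-gene count tibbles ([count_codons()]) or named
#'   pooled count vectors for the two gene sets.
#' @return Tibble `amino_acid`, `codon`, `k`, `n_high`, `rscu_high`,
#'   `n_low`, `rscu_low`, sorted by (amino acid, codon).
#' @export
pooled_rscu_table <- function(high, low) {
  pool <- function(x) if (is.data.frame(x)) pool_counts(x) else x
  rh <- rscu(pool(high), include_stops = TRUE)
  rl <- rscu(pool(low), include_stops = TRUE)
  out <- dplyr::inner_join(
    dplyr::rename(rh, n_high = "n", rscu_high = "rscu"),
    dplyr::rename(rl[, c("codon", "n", "rscu")], n_low = "n", rscu_low = "rscu"),
    by = "codon"
  )
  dplyr::arrange(out, .data$amino_acid, .data$codon)
}

#' Chi-square test for optimal codons
#'
#' For every codon of a multi-codon family (ATG and TGG excluded), tests
#' the 2x2 contingency table (this codon vs rest of its family) x (high vs
#' low pool) with Pearson's chi-square without continuity correction, and
#' flags the codon optimal when `p < 0.01` and its usage is relatively
#' higher in the high pool (`rscu_high > rscu_low`). Stop codons are tested
#' but never flagged optimal. Families with a zero total in either pool are
#' skipped (no test, not optimal).
#'
#' @param table Tibble from [pooled_rscu_table()].
#' @param alpha Significance threshold (default 0.01).
#' @return The input tibble with `chi2`, `p` and `optimal` columns added.
#' @examples
#' high <- c(TTT = 1118, TTC = 567)
#' low <- c(TTT = 265, TTC = 986)
#' tab <- optimal_codon_test(pooled_rscu_table(high, low))
#' tab[tab$codon %in% c("TTT", "TTC"), ]
#' @export
optimal_codon_test <- function(table, alpha = 0.01) {
  stopifnot(all(c("amino_acid", "codon", "n_high", "n_low") %in% names(table)))
  out <- dplyr::group_by(table, .data$amino_acid)
  out <- dplyr::mutate(out,
                       fam_high = sum(.data$n_high),
                       fam_low = sum(.data$n_low))
  out <- dplyr::ungroup(out)
  ct <- codon_table()
  testable <- out$k > 1 &
    !out$codon %in% c("ATG", "TGG") &
    out$fam_high > 0 & out$fam_low > 0
  skipped <- out$k > 1 & !out$codon %in% c("ATG", "TGG") & !testable
  if (any(skipped)) {
    message("family total zero in a pool; test skipped for: ",
            paste(out$codon[skipped], collapse = ", "))
  }
  stats_for <- function(i) {
    m <- matrix(c(out$n_high[i], out$fam_high[i] - out$n_high[i],
                  out$n_low[i], out$fam_low[i] - out$n_low[i]), nrow = 2)
    if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
      return(c(NA_real_, NA_real_))
    }
    htest <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
    c(unname(htest$statistic), htest$p.value)
  }
  res <- vapply(seq_len(nrow(out)), function(i) {
    if (testable[i]) stats_for(i) else c(NA_real_, NA_real_)
  }, numeric(2))
  out$chi2 <- res[1, ]
  out$p <- res[2, ]
  is_stop <- out$codon %in% STOP_CODONS
  out$optimal <- !is.na(out$p) & out$p < alpha &
    !is.na(out$rscu_high) & !is.na(out$rscu_low) &
    out$rscu_high > out$rscu_low & !is_stop
  dplyr::select(out, -"fam_high", -"fam_low")
}

#' Full optimal-codon determination
#'
#' Runs the complete procedure: CAI-based partition, pooling of codon
#' counts within each tail, per-pool RSCU and the per-codon 2x2 chi-square
#' test.
#'
#' @param metrics Tibble with `id` and `cai` columns.
#' @param counts Wide per-gene count tibble for the same genes, counted
#'   with the terminal stop included so the `Ter` family can be reported
#'   (a stop-free count table works too; `Ter` rows are then `NA`).
#' @param fraction Tail fraction for [partition_by_cai()].
#' @param alpha Significance threshold.
#' @return List of class `optimal_codon_result`: `table` (tested tibble),
#'   `partition`, `n_optimal`.
#' @export
optimal_codons <- function(metrics, counts, fraction = 0.05, alpha = 0.01) {
  part <- partition_by_cai(metrics, fraction)
  high <- dplyr::filter(counts, .data$id %in% part$high_ids)
  low <- dplyr::filter(counts, .data$id %in% part$low_ids)
  tab <- optimal_codon_test(pooled_rscu_table(high, low), alpha = alpha)
  structure(
    list(table = tab, partition = part, n_optimal = sum(tab$optimal)),
    class = "optimal_codon_result"
  )
}

#' @export
print.optimal_codon_result <- function(x, ...) {
  cat("Optimal codons:", x$n_optimal, "flagged (p <",
      format(attr(x, "alpha") %||% 0.01), "and higher relative usage in the",
      "high-expression pool)\n")
  print(x$table[x$table$optimal, c("amino_acid", "codon", "rscu_high",
                                   "rscu_low", "chi2", "p")], n = Inf)
  invisible(x)
}

#' @rdname optimal_codons
#' @param x An `optimal_codon_result`.
#' @param ... Unused.
#' @method tidy optimal_codon_result
#' @export
tidy.optimal_codon_result <- function(x, ...) x$table

#' @rdname optimal_codons
#' @method glance optimal_codon_result
#' @export
glance.optimal_codon_result <- function(x, ...) {
  tibble::tibble(n_optimal = x$n_optimal,
                 n_tested = sum(!is.na(x$table$p)),
                 n_per_set = x$partition$n_per_set)
}

#' Read a pre-pooled high/low codon count table
#'
#' Reads a TSV with columns `codon`, `n_high`, `n_low` (codons in DNA or
#' RNA alphabet), the input mode that lets the optimal-codon procedure run
#' on published pooled counts without any sequence data. Extra columns are
#' ignored.
#'
#' @param path Path to the TSV.
#' @return List with named count vectors `high` and `low`.
#' @seealso The packaged example
#'   `system.file("extdata", "rpalmatum_highlow_counts.tsv", package = "codonbias")`
#' @export
read_codon_counts <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("codon", "n_high", "n_low")
  if (!all(need %in% names(d))) {
    stop("counts table needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  codon <- chartr("U", "T", toupper(d$codon))
  assert_codons(codon)
  if (anyDuplicated(codon)) stop("duplicate codon rows", call. = FALSE)
  list(high = stats::setNames(as.numeric(d$n_high), codon),
       low = stats::setNames(as.numeric(d$n_low), codon))
}
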