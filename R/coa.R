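#' Correspondence analysis of a gene x codon RSCU matrix
#'
#' Decomposes the major trends of codon-usage variation among genes by
#' correspondence analysis of their RSCU profiles over the 59 informative
#' codons. Rows are first normalized to profiles (each row divided by its
#' sum), so every gene carries equal mass and scaling a row by a positive
#' constant cannot change its coordinates; for genuine RSCU rows (which all
#' sum to 59 after imputation) this coincides with standard CA of the raw
#' matrix. The profile table is centred and standardized under row-column
#' independence, `S = (P - r c') / sqrt(r c')` elementwise with row masses
#' `r` and column masses `c`, and decomposed by SVD; gene and codon
#' principal coordinates are the mass-rescaled singular vectors scaled by
#' the singular values, and the inertia of axis `k` is `sigma_k^2`.
#'
#' Missing RSCU entries (families absent from a gene) are imputed with the
#' family-uniform value 1, which is direction-neutral. Axis signs: if `gc3`
#' is supplied, axis 1 is oriented so its correlation with GC3 is positive
#' (the conventional orientation of codon-usage CA plots); every other axis
#' (and axis 1 otherwise) is oriented so its largest-magnitude gene
#' coordinate is positive.
#'
#' @param rscu_mat Genes x codons numeric matrix from [rscu_matrix()] (any
#'   non-negative matrix with named rows works, e.g. a contingency table).
#' @param n_axes Number of axes to retain (default 4, capped at the rank).
#' @param gc3 Optional per-gene GC3 vector (same order as rows) used to
#'   orient axis 1.
#' @return Object of class `coa_result`: list with `gene_coords` (tibble
#'   `id`, `axis1`, ...), `codon_coords` (tibble `codon`, `axis1`, ...),
#'   `inertia` (tibble `axis`, `inertia`, `fraction`, `cumulative`),
#'   `total_inertia`, `n_axes`. `tidy()` returns gene coordinates,
#'   `glance()` the axis summary.
#' @examples
#' cds <- tibble::tibble(
#'   id = c("g1", "g2", "g3"),
#'   sequence = c("ATGAAAAAGTTTTGA", "ATGAAAAAATTCTGA", "ATGAAGAAGTTTTGA")
#' )
#' res <- coa_rscu(rscu_matrix(count_codons(cds)))
#' glance(res)
#' @export
coa_rscu <- function(rscu_mat, n_axes = 4, gc3 = NULL) {
  stopifnot(is.matrix(rscu_mat), nrow(rscu_mat) >= 2)
  x <- rscu_mat
  x[is.na(x)] <- 1
  if (any(x < 0)) stop("RSCU matrix must be non-negative", call. = FALSE)
  rs <- rowSums(x)
  if (any(rs == 0)) stop("all-zero row(s) in RSCU matrix", call. = FALSE)
  prof <- x / rs                       # row profiles, equal row mass
  keep_col <- colSums(prof) > 0
  prof <- prof[, keep_col, drop = FALSE]

  n <- prof / sum(prof)
  r <- rowSums(n)
  c_mass <- colSums(n)
  e <- outer(r, c_mass)
  s <- (n - e) / sqrt(e)
  sv <- svd(s)
  pos <- sv$d > max(sv$d, 0) * 1e-10
  d_full <- ifelse(pos, sv$d, 0)       # zero out numerically-null axes
  n_axes <- max(1L, min(n_axes, length(d_full)))
  ax <- seq_len(n_axes)
  gene_pc <- sweep(sv$u[, ax, drop = FALSE] / sqrt(r), 2, d_full[ax], `*`)
  codon_pc <- sweep(sv$v[, ax, drop = FALSE] / sqrt(c_mass), 2, d_full[ax], `*`)

  # sign stabilization
  for (k in ax) {
    flip <- if (k == 1 && !is.null(gc3) && stats::sd(gc3) > 0 &&
                stats::sd(gene_pc[, 1]) > 0) {
      stats::cor(gene_pc[, 1], gc3) < 0
    } else {
      gene_pc[which.max(abs(gene_pc[, k])), k] < 0
    }
    if (isTRUE(flip)) {
      gene_pc[, k] <- -gene_pc[, k]
      codon_pc[, k] <- -codon_pc[, k]
    }
  }

  inertia <- d_full^2
  total <- sum(inertia)
  frac <- if (total > 0) inertia / total else rep(0, length(inertia))
  axis_names <- paste0("axis", ax)
  gene_coords <- tibble::as_tibble(
    stats::setNames(as.data.frame(gene_pc), axis_names))
  gene_coords <- dplyr::bind_cols(
    tibble::tibble(id = rownames(rscu_mat) %||% as.character(seq_len(nrow(x)))),
    gene_coords)
  codon_coords <- dplyr::bind_cols(
    tibble::tibble(codon = colnames(prof)),
    tibble::as_tibble(stats::setNames(as.data.frame(codon_pc), axis_names)))

  structure(
    list(gene_coords = gene_coords,
         codon_coords = codon_coords,
         inertia = tibble::tibble(
           axis = ax,
           inertia = inertia[ax],
           fraction = frac[ax],
           cumulative = cumsum(frac)[ax]),
         all_inertia = inertia,
         total_inertia = total,
         n_axes = n_axes),
    class = "coa_result"
  )
}

#' @export
print.coa_result <- function(x, ...) {
  cat("Correspondence analysis:", nrow(x$gene_coords), "genes,",
      nrow(x$codon_coords), "codons; total inertia",
      signif(x$total_inertia, 4), "\n")
  print(x$inertia)
  invisible(x)
}

#' @rdname coa_rscu
#' @param x A `coa_result`.
#' @param ... Unused.
#' @method tidy coa_result
#' @export
tidy.coa_result <- function(x, ...) x$gene_coords

#' @rdname coa_rscu
#' @method glance coa_result
#' @export
glance.coa_result <- function(x, ...) x$inertia

#' First-axis gene scores
#'
#' @param result A `coa_result` from [coa_rscu()].
#' @return Tibble `id`, `axis1`.
#' @export
axis1_scores <- function(result) {
  stopifnot(inherits(result, "coa_result"), result$n_axes >= 1)
  result$gene_coords[, c("id", "axis1")]
}

#' GC-content class labels for CA plots
#'
#' The conventional three-way colour classes of codon-usage CA plots.
#'
#' @param gc_all Numeric vector of overall GC fractions in `[0, 1]`.
#' @return Factor with levels `"<45%"`, `"45-60%"`, `">60%"`.
#' @export
gc_class <- function(gc_all) {
  cut(gc_all, breaks = c(-Inf, 0.45, 0.60, Inf),
      labels = c("<45%", "45-60%", ">60%"), right = FALSE)
}
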