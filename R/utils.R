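#' Round half away from zero
#'
#' Report-table rounding: halves round up (`0.675 -> 0.68`), unlike base
#' [round()], which rounds half to even. A tiny guard absorbs binary
#' floating-point representation error in count-derived rationals.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Rounded numeric vector.
#' @examples
#' round_half_up(c(0.125, 0.675, 2.345), 2)
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

# Coerce a per-gene wide count tibble (id + codon columns) to a base matrix
# with gene ids as rownames and all 64 codons as columns (absent -> 0).
counts_matrix <- function(counts) {
  stopifnot(is.data.frame(counts), "id" %in% names(counts))
  codons <- intersect(names(counts), all_codons())
  m <- matrix(0L, nrow = nrow(counts), ncol = 64,
              dimnames = list(counts$id, all_codons()))
  m[, codons] <- as.matrix(counts[, codons])
  storage.mode(m) <- "double"
  m
}

#' Pool per-gene codon counts
#'
#' Sums codon counts over genes, e.g. to build the pooled tables used for
#' RSCU reporting, CAI reference weights and optimal-codon testing.
#'
#' @param counts Wide per-gene count tibble from [count_codons()].
#' @return A named numeric vector over the 64 codons.
#' @export
pool_counts <- function(counts) {
  colSums(counts_matrix(counts))
}

# Internal: validate a vector of codon strings.
assert_codons <- function(x) {
  bad <- setdiff(x, all_codons())
  if (length(bad) > 0) {
    stop("unknown codon(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  invisible(x)
}
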