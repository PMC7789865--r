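# Independent oracles and fixture builders shared across the test files.
# Every oracle here is written directly from the defining formulas, without
# calling the package functions it checks.

# --- sequence fixtures -------------------------------------------------

# A random in-frame CDS that passes QC: ATG start, stop end, no internal
# stop, no ambiguity, >= n_body non-stop codons.
random_cds <- function(n_body = 120, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sense <- setdiff(names(Biostrings::GENETIC_CODE),
                   c("TAA", "TAG", "TGA"))
  body <- sample(sense, n_body - 1, replace = TRUE)
  paste(c("ATG", body, sample(c("TAA", "TAG", "TGA"), 1)), collapse = "")
}

random_cds_set <- function(n = 10, n_body = 120, seed = 1) {
  set.seed(seed)
  tibble::tibble(
    id = sprintf("g%03d", seq_len(n)),
    sequence = vapply(seq_len(n), function(i) random_cds(n_body),
                      character(1))
  )
}

# Split a sequence into codons (re-implemented here for independence).
split_codons <- function(s) {
  substring(s, seq(1, nchar(s) - 2, 3), seq(3, nchar(s), 3))
}

# --- codon-table facts from the genetic code ---------------------------

GENCODE <- Biostrings::GENETIC_CODE
SENSE <- names(GENCODE)[GENCODE != "*"]
FAMILY_OF <- GENCODE  # one-letter amino acid per codon

# --- brute-force ENc oracle (Wright's estimator) -----------------------

# Counts: named vector over codons (stops ignored). Follows the package's
# documented estimator contract: F = (n*sum(p^2)-1)/(n-1) per family with
# n > 1 and F > 0; class means over degeneracy 2/3/4/6; missing 3-fold
# class imputed as (F2+F4)/2; other missing classes dropped; capped to
# [20, 61].
oracle_enc <- function(counts) {
  counts <- counts[names(counts) %in% SENSE]
  aa <- FAMILY_OF[names(counts)]
  degeneracy <- table(FAMILY_OF[SENSE])
  f_list <- list()
  for (a in unique(aa)) {
    x <- counts[aa == a]
    if (unname(degeneracy[a]) == 1) next  # Met, Trp carry no information
    n <- sum(x)
    if (n <= 1) next
    f <- (n * sum((x / n)^2) - 1) / (n - 1)
    if (f > 0) f_list[[a]] <- c(k = unname(degeneracy[a]), f = f)
  }
  if (length(f_list) == 0) return(NA_real_)
  tab <- do.call(rbind, f_list)
  fbar <- sapply(c(2, 3, 4, 6), function(k) mean(tab[tab[, "k"] == k, "f"]))
  n_fam <- c(9, 1, 5, 3)  # twofold, threefold, fourfold, sixfold families
  miss <- is.nan(fbar)
  if (miss[2] && !miss[1] && !miss[3]) {
    fbar[2] <- (fbar[1] + fbar[3]) / 2
    miss[2] <- FALSE
  }
  if (all(miss)) return(NA_real_)
  val <- 2 + sum(n_fam[!miss] / fbar[!miss])
  min(max(val, 20), 61)
}

# --- brute-force composition oracle ------------------------------------

oracle_gc <- function(sequence) {
  body <- sub("(TAA|TAG|TGA)$", "", sequence)
  chars <- strsplit(body, "")[[1]]
  mean(chars %in% c("G", "C"))
}

# --- RSCU oracle for a single family -----------------------------------

oracle_rscu_family <- function(counts) {
  k <- length(counts)
  k * counts / sum(counts)
}

# --- 2x2 Pearson chi-square (no continuity correction), closed form ----

oracle_chi2_2x2 <- function(a, b, c, d) {
  n <- a + b + c + d
  n * (a * d - b * c)^2 /
    ((a + b) * (c + d) * (a + c) * (b + d))
}

# --- dense CA oracle: eigendecomposition of the residual cross-product --

# Works on the same profile-normalized table the package decomposes.
oracle_ca_inertias <- function(x) {
  prof <- x / rowSums(x)
  n <- prof / sum(prof)
  r <- rowSums(n); cc <- colSums(n)
  s <- (n - outer(r, cc)) / sqrt(outer(r, cc))
  ev <- eigen(crossprod(s), symmetric = TRUE)$values
  sort(ev[ev > max(ev) * 1e-12], decreasing = TRUE)
}

oracle_ca_chisq_over_n <- function(x) {
  prof <- x / rowSums(x)
  e <- outer(rowSums(prof), colSums(prof)) / sum(prof)
  sum((prof - e)^2 / e) / sum(prof)
}
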