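#' Configuration for the synthetic CDS generator
#'
#' Bundles the knobs of the synthetic coding-sequence generator, which
#' emulates the statistical structure of an AT-leaning plant transcriptome
#' CDS set: a few hundred genes of at least 100 codons, a broad per-gene
#' GC3 spread around a mean slightly below 0.5, GC12 weakly tracking GC3,
#' and a latent expression gradient coupled to synonymous codon bias toward
#' a known set of preferred codons (the recoverable ground truth).
#'
#' Per-gene third-position GC targets are drawn as
#' `gc3_low + (gc3_high - gc3_low) * Beta(gc3_beta[1], gc3_beta[2])`; the
#' defaults give a mean near 0.47 with tails reaching both ends of the
#' range. The per-gene GC12 target is
#' `gc12_mean + gc12_slope * (gc3 - mean(gc3)) + Normal(0, gc12_sd)`, so
#' `gc12_slope` is the ground-truth neutrality-regression slope. Codon
#' choice within each synonymous family uses weights
#' `exp(bias * [codon == preferred]) * tilt(third base)`, a tilted
#' multinomial whose third-base tilt and amino-acid weights are calibrated
#' per gene (by root-finding) so the expected GC3 and GC12 hit their
#' targets. The per-gene bias is
#' `bias_strength * (expression_coupling * e + (1 - expression_coupling)/2)`
#' with latent expression `e ~ Uniform(0, 1)`: at coupling 1 bias follows
#' expression rank exactly, at coupling 0 all genes share the same
#' intermediate bias (a clean null for optimal-codon calibration).
#'
#' @param n_genes Number of genes (default 500).
#' @param min_aa,max_aa Gene length range in non-stop codons (default
#'   100-500).
#' @param length_shape Beta shape1 of the right-skewed length distribution
#'   (`shape2 = 2.5 * length_shape`).
#' @param gc3_range Per-gene GC3 target range (default `c(0.21, 0.89)`).
#' @param gc3_beta Beta shape pair for the GC3 target draw.
#' @param gc12_mean,gc12_slope,gc12_sd GC12 target model (defaults 0.46,
#'   0.17, 0.02).
#' @param bias_strength Log-scale preference for the preferred codon at
#'   full expression (default 2).
#' @param expression_coupling Correlation knob in `[0, 1]` between latent
#'   expression and bias (default 1).
#' @param preferred_codons Named character vector `amino_acid -> codon`
#'   (three-letter names) for the planted preferred codons; `NULL` samples
#'   one A/T-ending codon per multi-codon family from the seed (optimal
#'   codons of AT-leaning plant transcriptomes are overwhelmingly
#'   A/U-ending).
#' @param seed Integer seed; all randomness derives from it via per-gene
#'   substreams.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 500, min_aa = 100, max_aa = 500,
                       length_shape = 1.2,
                       gc3_range = c(0.21, 0.89), gc3_beta = c(0.8, 1.32),
                       gc12_mean = 0.46, gc12_slope = 0.17, gc12_sd = 0.02,
                       bias_strength = 2, expression_coupling = 1,
                       preferred_codons = NULL, seed = 1) {
  stopifnot(n_genes >= 1, min_aa >= 100, max_aa >= min_aa,
            length(gc3_range) == 2, all(gc3_range >= 0 & gc3_range <= 1),
            gc3_range[1] <= gc3_range[2],
            bias_strength >= 0,
            expression_coupling >= 0, expression_coupling <= 1)
  structure(
    list(n_genes = as.integer(n_genes), min_aa = as.integer(min_aa),
         max_aa = as.integer(max_aa), length_shape = length_shape,
         gc3_range = gc3_range, gc3_beta = gc3_beta,
         gc12_mean = gc12_mean, gc12_slope = gc12_slope, gc12_sd = gc12_sd,
         bias_strength = bias_strength,
         expression_coupling = expression_coupling,
         preferred_codons = preferred_codons, seed = as.integer(seed)),
    class = "sim_config"
  )
}

# Mean of the per-gene GC3 target distribution implied by a config.
gc3_target_mean <- function(config) {
  a <- config$gc3_beta[1]; b <- config$gc3_beta[2]
  config$gc3_range[1] + diff(config$gc3_range) * a / (a + b)
}

# Deterministic per-gene substream seed (kept below 2^31).
gene_seed <- function(seed, gene_index) {
  as.integer((as.numeric(seed) + as.numeric(gene_index) * 7919) %% 2147483629)
}

# Planted preferred codons: one per multi-codon sense family, drawn from
# the dataset seed (substream index 0) unless supplied. Defaults sample
# among each family's A/T-ending codons, the realistic choice for the
# AT-leaning transcriptomes this generator emulates (where observed
# optimal codons are overwhelmingly A/U-ending); it also means the planted
# preference is not systematically opposed by each gene's GC3 tilt.
sim_preferred <- function(config) {
  if (!is.null(config$preferred_codons)) {
    pref <- config$preferred_codons
    assert_codons(unname(pref))
    return(pref)
  }
  ct <- codon_table()
  fams <- split(ct$codon[ct$informative], ct$amino_acid[ct$informative])
  fams <- fams[vapply(fams, length, integer(1)) > 1]
  set.seed(gene_seed(config$seed, 0))
  vapply(fams, function(cs) {
    at <- cs[substr(cs, 3, 3) %in% c("A", "T")]
    at[sample.int(length(at), 1)]
  }, character(1))
}

# Per-family codon-choice weights for one gene.
# weights(c) = exp(bias * [c == preferred]) * (tau if third is G/C else 1 - tau)
codon_choice_probs <- function(bias, tau, preferred) {
  ct <- codon_table()
  sense <- ct$aa1 != "*"
  w <- exp(bias * (ct$codon %in% preferred)) *
    ifelse(ct$third %in% c("G", "C"), tau, 1 - tau)
  w <- w[sense]
  fam <- ct$amino_acid[sense]
  tot <- tapply(w, fam, sum)[fam]
  stats::setNames(w / tot, ct$codon[sense])
}

# GC content helpers per codon: third base, and first-two-base fraction.
.codon_gc3 <- function() {
  ct <- codon_table()
  stats::setNames(as.numeric(ct$third %in% c("G", "C")), ct$codon)
}
.codon_gc12 <- function() {
  ct <- codon_table()
  gc12 <- (substr(ct$codon, 1, 1) %in% c("G", "C")) +
    (substr(ct$codon, 2, 2) %in% c("G", "C"))
  stats::setNames(gc12 / 2, ct$codon)
}

# Calibrate the third-base tilt tau and amino-acid weights so the gene's
# expected GC3 and GC12 equal their targets, by alternating root-finds.
calibrate_gene <- function(bias, preferred, gc3_target, gc12_target) {
  ct <- codon_table()
  sense <- ct$aa1 != "*"
  aas <- sort(unique(ct$amino_acid[sense]))
  gc3_of <- .codon_gc3(); gc12_of <- .codon_gc12()

  aa_expect <- function(probs, value_of) {
    # expected per-amino-acid value under within-family codon probabilities
    v <- tapply(probs * value_of[names(probs)],
                ct$amino_acid[sense][match(names(probs), ct$codon[sense])], sum)
    v[aas]
  }
  aa_w <- stats::setNames(rep(1 / length(aas), length(aas)), aas)
  tau <- min(max(gc3_target, 0.02), 0.98)

  for (iter in 1:3) {
    probs <- codon_choice_probs(bias, tau, preferred)
    e_gc12 <- aa_expect(probs, gc12_of)
    # amino-acid tilt for the GC12 target
    f12 <- function(lambda) {
      w <- exp(lambda * e_gc12); w <- w / sum(w)
      sum(w * e_gc12) - gc12_target
    }
    lambda <- if (f12(0) == 0) 0 else
      tryCatch(stats::uniroot(f12, c(-40, 40))$root, error = function(e) 0)
    aa_w <- exp(lambda * e_gc12); aa_w <- aa_w / sum(aa_w)
    # third-base tilt for the GC3 target
    f3 <- function(t) {
      p <- codon_choice_probs(bias, t, preferred)
      sum(aa_w * aa_expect(p, gc3_of)) - gc3_target
    }
    tau <- tryCatch(stats::uniroot(f3, c(0.001, 0.999))$root,
                    error = function(e) tau)
  }
  list(tau = tau, aa_w = aa_w)
}

#' Generate one synthetic coding sequence
#'
#' Draws gene `gene_index` of the dataset defined by `config`, entirely
#' from its own deterministic substream, so single genes can be regenerated
#' without producing the whole set.
#'
#' @param config A [sim_config()].
#' @param gene_index Integer gene index (1-based).
#' @return List with `cds` (one-row tibble `id`, `sequence`) and `truth`
#'   (one-row tibble `id`, `length_aa`, `target_gc3`, `target_gc12`,
#'   `bias`, `expression`).
#' @export
generate_gene <- function(config, gene_index) {
  stopifnot(inherits(config, "sim_config"), gene_index >= 1)
  preferred <- sim_preferred(config)
  set.seed(gene_seed(config$seed, gene_index))

  e <- stats::runif(1)
  m <- config$expression_coupling * e + (1 - config$expression_coupling) / 2
  bias <- config$bias_strength * m
  theta <- config$gc3_range[1] + diff(config$gc3_range) *
    stats::rbeta(1, config$gc3_beta[1], config$gc3_beta[2])
  gc12_target <- config$gc12_mean +
    config$gc12_slope * (theta - gc3_target_mean(config)) +
    stats::rnorm(1, 0, config$gc12_sd)
  gc12_target <- min(max(gc12_target, 0.05), 0.95)
  len <- config$min_aa + floor(
    (config$max_aa - config$min_aa + 1) *
      stats::rbeta(1, config$length_shape, 2.5 * config$length_shape))
  len <- min(len, config$max_aa)

  cal <- calibrate_gene(bias, preferred, theta, gc12_target)
  probs <- codon_choice_probs(config$bias_strength * m, cal$tau, preferred)
  ct <- codon_table()
  sense <- ct$aa1 != "*"
  fam <- ct$amino_acid[sense]
  codons_of <- split(ct$codon[sense], fam)
  probs_of <- split(probs, fam)
  probs_of <- lapply(probs_of, function(p) p / sum(p))

  aa_seq <- c("Met", sample(names(cal$aa_w), len - 1, replace = TRUE,
                            prob = cal$aa_w))
  body <- vapply(aa_seq, function(a) {
    cs <- codons_of[[a]]
    if (length(cs) == 1) cs else sample(cs, 1, prob = probs_of[[a]])
  }, character(1), USE.NAMES = FALSE)
  body[1] <- "ATG"
  stop_codon <- sample(STOP_CODONS, 1)
  id <- sprintf("sim%05d", gene_index)
  list(
    cds = tibble::tibble(id = id,
                         sequence = paste(c(body, stop_codon), collapse = "")),
    truth = tibble::tibble(id = id, length_aa = as.integer(len),
                           target_gc3 = theta, target_gc12 = gc12_target,
                           bias = bias, expression = e)
  )
}

#' Generate a synthetic CDS dataset with ground truth
#'
#' Generates `config$n_genes` coding sequences (all of which pass
#' [qc_filter_cds()] by construction) together with the per-gene ground
#' truth and the planted preferred-codon set. Fully deterministic in
#' `config$seed`: rerunning yields byte-identical sequences.
#'
#' @param config A [sim_config()].
#' @param fasta_path,truth_path Optional output paths; when given, the
#'   sequences are written as FASTA and the ground truth as TSV.
#' @return List of class `codon_sim`: `cds` (tibble `id`, `sequence`),
#'   `truth` (per-gene tibble), `preferred` (tibble `amino_acid`, `codon`),
#'   `config`.
#' @examples
#' sim <- generate_dataset(sim_config(n_genes = 5, max_aa = 150, seed = 7))
#' sim$preferred
#' @export
generate_dataset <- function(config, fasta_path = NULL, truth_path = NULL) {
  stopifnot(inherits(config, "sim_config"))
  genes <- lapply(seq_len(config$n_genes), function(i) generate_gene(config, i))
  cds <- dplyr::bind_rows(lapply(genes, `[[`, "cds"))
  truth <- dplyr::bind_rows(lapply(genes, `[[`, "truth"))
  preferred <- sim_preferred(config)
  out <- structure(
    list(cds = cds, truth = truth,
         preferred = tibble::tibble(amino_acid = names(preferred),
                                    codon = unname(preferred)),
         config = config),
    class = "codon_sim"
  )
  if (!is.null(fasta_path)) write_cds_fasta(cds, fasta_path)
  if (!is.null(truth_path)) {
    utils::write.table(truth, truth_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  out
}

#' @export
print.codon_sim <- function(x, ...) {
  cat("Synthetic CDS dataset:", nrow(x$cds), "genes, seed",
      x$config$seed, "\n")
  cat("  mean target GC3:", round(mean(x$truth$target_gc3), 3),
      "; bias strength:", x$config$bias_strength,
      "; expression coupling:", x$config$expression_coupling, "\n")
  invisible(x)
}
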