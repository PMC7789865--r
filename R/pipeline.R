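#' Run the full codon-usage-bias analysis pipeline
#'
#' Orchestrates every stage over a CDS FASTA file (or, alternatively, a
#' pre-pooled high/low codon count table, in which case only the pooled
#' RSCU and optimal-codon stages run): QC filtering, per-gene metrics,
#' pooled RSCU, GC histogram, neutrality regression, ENc-GC3s table and
#' deviation bins, PR2 analysis, correspondence analysis, the parameter
#' correlation matrix and the optimal-codon table. All tables are written
#' as TSV into `out_dir` with fixed ordering and half-up 2-decimal rounding
#' of RSCU report columns, plus a JSON manifest of the configuration, so
#' reruns are byte-identical.
#'
#' @param input_fasta Path to a CDS FASTA file (exclusive with `counts_tsv`).
#' @param counts_tsv Path to a pre-pooled count TSV for
#'   [read_codon_counts()] (exclusive with `input_fasta`).
#' @param out_dir Output directory (created if needed).
#' @param min_aa QC length threshold in non-stop codons.
#' @param fraction CAI tail fraction for the optimal-codon partition.
#' @param pr2_scope Third-position scope, `"fourfold_only"` or
#'   `"all_synonymous"`.
#' @param cor_method `"pearson"` or `"spearman"`.
#' @param n_axes CA axes to retain.
#' @param cai_reference Optional explicit CAI reference (see
#'   [gene_metrics()]).
#' @return Invisibly, a list with every computed object (`qc`, `metrics`,
#'   `rscu_pooled`, `neutrality`, `enc_gc3s`, `pr2`, `coa`, `correlations`,
#'   `optimal`, or the subset available in counts mode).
#' @export
run_codon_pipeline <- function(input_fasta = NULL, counts_tsv = NULL,
                               out_dir, min_aa = 100, fraction = 0.05,
                               pr2_scope = "fourfold_only",
                               cor_method = "pearson", n_axes = 4,
                               cai_reference = NULL) {
  if (is.null(input_fasta) == is.null(counts_tsv)) {
    stop("give exactly one of input_fasta or counts_tsv", call. = FALSE)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  tsv <- function(d, name, round_cols = character(0)) {
    for (col in intersect(round_cols, names(d))) {
      d[[col]] <- round_half_up(d[[col]], 2)
    }
    num <- vapply(d, is.numeric, logical(1))
    for (col in names(d)[num]) d[[col]] <- format(d[[col]], trim = TRUE)
    utils::write.table(d, file.path(out_dir, name), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  stage <- function(name) message("[", name, "] ", appendLF = FALSE)
  results <- list()

  if (!is.null(counts_tsv)) {
    stage("optimal")
    pools <- read_codon_counts(counts_tsv)
    tab <- optimal_codon_test(pooled_rscu_table(pools$high, pools$low))
    message(sum(tab$optimal), " optimal codons")
    results$rscu_pooled <- pooled_rscu_table(pools$high, pools$low)
    results$optimal <- tab
    tsv(dplyr::arrange(tab, .data$amino_acid, .data$codon),
        "optimal_codons.tsv", c("rscu_high", "rscu_low"))
    write_manifest(out_dir, list(mode = "counts", counts_tsv = counts_tsv))
    return(invisible(results))
  }

  stage("qc")
  seqs <- read_cds_fasta(input_fasta)
  qc <- qc_filter_cds(seqs, min_aa = min_aa)
  message(qc$report$n_passed, "/", qc$report$n_input, " sequences passed")
  if (qc$report$n_passed == 0) {
    stop("pipeline aborted at stage qc: no sequence passed the filter",
         call. = FALSE)
  }
  results$qc <- qc
  write_qc_report(qc, file.path(out_dir, "qc_report.tsv"))
  cds <- qc$cds

  stage("indices")
  counts <- count_codons(cds, include_stop = FALSE)
  counts_with_stop <- count_codons(cds, include_stop = TRUE)
  metrics <- gene_metrics(cds, cai_reference = cai_reference,
                          pr2_scope = pr2_scope)
  message(nrow(metrics), " genes")
  results$metrics <- metrics
  results$rscu_pooled <- rscu(counts, include_stops = FALSE)
  tsv(results$rscu_pooled, "rscu_pooled.tsv", "rscu")
  tsv(gc_histogram(metrics), "gc_histogram.tsv")

  stage("diagnostics")
  results$neutrality <- neutrality_regression(metrics)
  results$enc_gc3s <- enc_gc3s_table(metrics)
  results$pr2 <- pr2_analysis(metrics)
  message(sprintf("neutrality slope %.3f", results$neutrality$slope))
  tsv(glance(results$neutrality), "neutrality.tsv")
  tsv(dplyr::arrange(results$enc_gc3s, .data$id), "enc_gc3s.tsv")
  tsv(enc_deviation_bins(results$enc_gc3s), "enc_deviation_bins.tsv")
  tsv(dplyr::arrange(tidy(results$pr2), .data$id), "pr2_points.tsv")
  tsv(results$pr2$quadrants, "pr2_quadrants.tsv")

  stage("coa")
  if (nrow(cds) < 3) stop("pipeline aborted at stage coa: fewer than 3 genes",
                          call. = FALSE)
  results$coa <- coa_rscu(rscu_matrix(counts), n_axes = n_axes,
                          gc3 = metrics$gc3)
  message(sprintf("axis 1 inertia %.1f%%",
                  100 * results$coa$inertia$fraction[1]))
  coords <- dplyr::left_join(tidy(results$coa),
                             tibble::tibble(id = metrics$id,
                                            gc_class = as.character(gc_class(metrics$gc_all))),
                             by = "id")
  tsv(dplyr::arrange(coords, .data$id), "coa_gene_coords.tsv")
  tsv(glance(results$coa), "coa_axes.tsv")

  metrics_ax <- dplyr::left_join(metrics, axis1_scores(results$coa), by = "id")
  results$correlations <- correlation_matrix(metrics_ax, method = cor_method)
  tsv(tidy(results$correlations), "correlations.tsv")

  stage("optimal")
  results$optimal <- optimal_codons(metrics, counts_with_stop,
                                    fraction = fraction)
  message(results$optimal$n_optimal, " optimal codons")
  tsv(dplyr::arrange(tidy(results$optimal), .data$amino_acid, .data$codon),
      "optimal_codons.tsv", c("rscu_high", "rscu_low"))

  tsv(dplyr::arrange(metrics[, !vapply(metrics, is.list, logical(1))],
                     .data$id), "gene_metrics.tsv")
  write_manifest(out_dir, list(
    mode = "fasta", input_fasta = input_fasta, min_aa = min_aa,
    fraction = fraction, pr2_scope = pr2_scope, cor_method = cor_method,
    n_axes = n_axes
  ))
  invisible(results)
}

write_manifest <- function(out_dir, config) {
  manifest <- list(
    package = "codonbias",
    version = as.character(utils::packageVersion("codonbias")),
    config = config
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(NULL)
}
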