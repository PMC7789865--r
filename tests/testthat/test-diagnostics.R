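test_that("neutrality regression recovers exact lines", {
  d <- tibble::tibble(gc3 = c(0.2, 0.4, 0.6, 0.8), gc12 = c(0.2, 0.4, 0.6, 0.8))
  fit <- neutrality_regression(d)
  expect_equal(fit$slope, 1)
  expect_equal(fit$r, 1)

  flat <- tibble::tibble(gc3 = c(0.2, 0.4, 0.6), gc12 = c(0.5, 0.5, 0.5))
  # constant GC12: slope 0 and an undefined correlation (warned by cor.test)
  expect_equal(suppressWarnings(neutrality_regression(flat))$slope, 0)

  expect_error(neutrality_regression(d[1:2, ]), "at least 3")
  expect_error(
    neutrality_regression(tibble::tibble(gc3 = rep(0.4, 5), gc12 = runif(5))),
    "zero variance")
})

test_that("neutrality regression matches the normal-equations solution", {
  d <- tibble::tibble(gc3 = c(0.21, 0.35, 0.48, 0.62, 0.80),
                      gc12 = c(0.40, 0.42, 0.47, 0.46, 0.52))
  fit <- neutrality_regression(d)
  # closed-form OLS
  sxx <- sum((d$gc3 - mean(d$gc3))^2)
  sxy <- sum((d$gc3 - mean(d$gc3)) * (d$gc12 - mean(d$gc12)))
  slope <- sxy / sxx
  expect_equal(fit$slope, slope)
  expect_equal(fit$intercept, mean(d$gc12) - slope * mean(d$gc3))
  # r^2 equals regression SS over total SS
  pred <- fit$intercept + fit$slope * d$gc3
  expect_equal(fit$r^2,
               sum((pred - mean(d$gc12))^2) / sum((d$gc12 - mean(d$gc12))^2),
               tolerance = 1e-9)
  # slope invariant under shifting gc12 by a constant
  fit2 <- neutrality_regression(dplyr::mutate(d, gc12 = gc12 + 0.123))
  expect_equal(fit2$slope, fit$slope)
})

test_that("ENc-GC3s table flags genes below the expected curve", {
  metrics <- tibble::tibble(
    id = c("a", "b"),
    gc3s = c(0.5, 0.5),
    enc = c(expected_enc(0.5), 50)
  )
  tab <- enc_gc3s_table(metrics)
  expect_equal(tab$deviation[1], 0)
  expect_false(tab$below_curve[1])
  expect_true(tab$below_curve[2])

  bins <- enc_deviation_bins(tab, width = 0.05)
  expect_equal(sum(bins$n), 2)
})

test_that("unbiased synthetic genes sit near the expected curve, selected genes below", {
  sim <- generate_dataset(sim_config(n_genes = 80, max_aa = 300,
                                     bias_strength = 0, seed = 6))
  m <- gene_metrics(sim$cds, cai_reference = count_codons(sim$cds))
  tab <- enc_gc3s_table(m)
  # at least half of the null deviations fall in the central +/-0.05 bin
  expect_gte(mean(abs(tab$deviation) <= 0.05), 0.5)

  biased <- generate_dataset(sim_config(n_genes = 40, max_aa = 300,
                                        bias_strength = 3,
                                        expression_coupling = 0, seed = 61))
  mb <- gene_metrics(biased$cds, cai_reference = count_codons(biased$cds))
  expect_gt(median(enc_gc3s_table(mb)$deviation), 0)
})

test_that("PR2 coordinates, quadrants and tie handling are correct", {
  tp <- tibble::tibble(id = c("bal", "q1"),
                       a3 = c(5, 8), u3 = c(5, 2), g3 = c(7, 6), c3 = c(7, 4))
  res <- pr2_analysis(tp)
  pts <- tidy(res)
  expect_equal(pts$x, c(0.5, 0.6))
  expect_equal(pts$y, c(0.5, 0.8))
  expect_equal(pts$quadrant, c(1L, 1L))  # centre tie -> lowest index
  expect_equal(res$n_boundary, 1)
  expect_equal(res$n_box, 2)

  # undefined ratios are excluded, not propagated
  bad <- tibble::tibble(id = "x", a3 = 0, u3 = 0, g3 = 3, c3 = 1)
  expect_message(res2 <- pr2_analysis(bad), "excluded")
  expect_equal(nrow(tidy(res2)), 0)
})

test_that("PR2 coordinates are scale-invariant in the counts", {
  tp <- tibble::tibble(id = "g", a3 = 8, u3 = 2, g3 = 6, c3 = 4)
  scaled <- dplyr::mutate(tp, a3 = a3 * 9, u3 = u3 * 9, g3 = g3 * 9, c3 = c3 * 9)
  expect_equal(tidy(pr2_analysis(tp))[, c("x", "y")],
               tidy(pr2_analysis(scaled))[, c("x", "y")])
})

test_that("strand-symmetric counts fill the quadrants uniformly", {
  set.seed(88)
  n <- 400
  # symmetric binomial third-position counts around 0.5
  tp <- tibble::tibble(
    id = as.character(seq_len(n)),
    a3 = rbinom(n, 60, 0.5), g3 = rbinom(n, 60, 0.5)
  )
  tp$u3 <- 60 - tp$a3
  tp$c3 <- 60 - tp$g3
  res <- pr2_analysis(tp)
  counts <- glance(res)[, c("n_q1", "n_q2", "n_q3", "n_q4")]
  gof <- stats::chisq.test(unlist(counts))
  expect_gt(gof$p.value, 0.001)
})

test_that("the correlation matrix matches a direct covariance computation", {
  set.seed(12)
  n <- 20
  metrics <- tibble::tibble(
    gc12 = runif(n, 0.3, 0.6), gc3 = runif(n, 0.2, 0.9)
  )
  metrics$gc_all <- (2 * metrics$gc12 + metrics$gc3) / 3
  metrics$enc <- runif(n, 30, 61)
  metrics$cai <- runif(n, 0.2, 0.9)
  metrics$axis1 <- -metrics$gc3  # exact negative
  cm <- correlation_matrix(metrics)
  expect_equal(unname(diag(cm$r)), rep(1, 6))
  expect_equal(cm$r, t(cm$r))
  expect_equal(cm$r["gc3", "axis1"], -1)
  # brute force r for one pair
  x <- metrics$gc12; y <- metrics$enc
  r_direct <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(cm$r["gc12", "enc"], r_direct, tolerance = 1e-9)
  # p-values agree with cor.test
  expect_equal(cm$p["gc12", "enc"],
               stats::cor.test(x, y)$p.value)

  # constant parameter -> NA with warning
  metrics$cai <- 0.5
  expect_warning(cm2 <- correlation_matrix(metrics), "constant")
  expect_true(all(is.na(cm2$r["cai", setdiff(colnames(cm2$r), "cai")])))

  # spearman option
  cm3 <- correlation_matrix(metrics[, c("gc12", "gc3", "gc_all")],
                            parameters = c("gc12", "gc3", "gc_all"),
                            method = "spearman")
  expect_equal(cm3$r["gc12", "gc3"],
               stats::cor(metrics$gc12, metrics$gc3, method = "spearman"))
})
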