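#' Neutrality regression (GC12 on GC3)
#'
#' Ordinary least-squares regression of GC12 on GC3 across genes, the
#' classic neutrality plot. A slope near 1 with strong correlation is read
#' as directional mutation pressure acting on all codon positions alike; a
#' slope near 0 as selective constraint on first/second positions.
#'
#' @param data Data frame with columns `gc3` and `gc12` (fractions), e.g.
#'   from [gene_metrics()].
#' @return Object of class `neutrality_fit` with elements `slope`,
#'   `intercept`, `r` (Pearson correlation), `p` (two-sided), `n`, and the
#'   underlying `lm` fit. `tidy()` gives the coefficient table, `glance()`
#'   the one-row summary.
#' @examples
#' d <- tibble::tibble(gc3 = c(.2, .4, .6, .8), gc12 = c(.3, .4, .5, .6))
#' glance(neutrality_regression(d))
#' @export
neutrality_regression <- function(data) {
  stopifnot(all(c("gc3", "gc12") %in% names(data)))
  d <- data[stats::complete.cases(data[, c("gc3", "gc12")]), ]
  if (nrow(d) < 3) stop("need at least 3 genes with GC3 and GC12", call. = FALSE)
  if (stats::sd(d$gc3) == 0) stop("GC3 has zero variance", call. = FALSE)
  fit <- stats::lm(gc12 ~ gc3, data = d)
  ct <- stats::cor.test(d$gc3, d$gc12)
  structure(
    list(slope = unname(stats::coef(fit)[2]),
         intercept = unname(stats::coef(fit)[1]),
         r = unname(ct$estimate), p = ct$p.value, n = nrow(d), fit = fit),
    class = "neutrality_fit"
  )
}

#' @export
print.neutrality_fit <- function(x, ...) {
  cat(sprintf("Neutrality regression (n = %d): GC12 = %.4f + %.4f * GC3, r = %.3f, p = %.3g\n",
              x$n, x$intercept, x$slope, x$r, x$p))
  invisible(x)
}

#' @rdname neutrality_regression
#' @param x A `neutrality_fit`.
#' @param ... Unused.
#' @method tidy neutrality_fit
#' @export
tidy.neutrality_fit <- function(x, ...) {
  s <- summary(x$fit)$coefficients
  tibble::tibble(term = c("intercept", "gc3"), estimate = s[, 1],
                 std_error = s[, 2], statistic = s[, 3], p_value = s[, 4])
}

#' @rdname neutrality_regression
#' @method glance neutrality_fit
#' @export
glance.neutrality_fit <- function(x, ...) {
  tibble::tibble(slope = x$slope, intercept = x$intercept, r = x$r,
                 r_squared = x$r^2, p = x$p, n = x$n)
}

#' ENc vs GC3s table with the expected-curve comparison
#'
#' Per-gene observed ENc, the composition-only expectation
#' [expected_enc()], their relative deviation and a below-curve flag: the
#' tabular form of the ENc-GC3s plot.
#'
#' @param metrics Tibble from [gene_metrics()] (columns `id`, `gc3s`,
#'   `enc`).
#' @return Tibble `id`, `gc3s`, `enc`, `enc_exp`, `deviation`,
#'   `below_curve`.
#' @export
enc_gc3s_table <- function(metrics) {
  stopifnot(all(c("id", "gc3s", "enc") %in% names(metrics)))
  exp_enc <- expected_enc(metrics$gc3s)
  tibble::tibble(
    id = metrics$id,
    gc3s = metrics$gc3s,
    enc = metrics$enc,
    enc_exp = exp_enc,
    deviation = enc_deviation(metrics$enc, exp_enc),
    below_curve = metrics$enc < exp_enc
  )
}

#' Binned frequency table of ENc deviations
#'
#' Frequency distribution of `(ENc_exp - ENc_obs)/ENc_exp` at a fixed bin
#' width, for the usual deviation histogram.
#'
#' @param deviation Numeric vector of deviations (or a table from
#'   [enc_gc3s_table()], whose `deviation` column is used).
#' @param width Bin width (default 0.05).
#' @return Tibble `bin_low`, `bin_high`, `n`, `frequency`.
#' @export
enc_deviation_bins <- function(deviation, width = 0.05) {
  if (is.data.frame(deviation)) deviation <- deviation$deviation
  d <- deviation[!is.na(deviation)]
  lo <- floor(min(d) / width) * width
  hi <- ceiling(max(d) / width) * width
  if (hi <= lo) hi <- lo + width
  breaks <- seq(lo, hi, by = width)
  bin <- cut(d, breaks = breaks, include.lowest = TRUE, right = FALSE)
  tibble::tibble(
    bin_low = breaks[-length(breaks)],
    bin_high = breaks[-1],
    n = as.integer(table(bin)),
    frequency = as.integer(table(bin)) / length(d)
  )
}

#' Parity-rule-2 bias analysis
#'
#' Places each gene at `x = G3/(G3 + C3)`, `y = A3/(A3 + U3)` computed over
#' the chosen third-position scope; under strand-symmetric mutation and no
#' selection both ratios are 0.5. Quadrants are numbered
#' counter-clockwise from the centre `(0.5, 0.5)`: 1 = (x > .5, y > .5),
#' 2 = (x < .5, y > .5), 3 = (x < .5, y < .5), 4 = (x > .5, y < .5).
#' Points falling exactly on a boundary are assigned the lowest consistent
#' quadrant number and counted separately in `n_boundary`.
#'
#' @param composition Tibble with per-gene third-position counts `a3`,
#'   `u3`, `g3`, `c3` ([codon_composition()] or
#'   [third_position_counts()] output).
#' @return Object of class `pr2_analysis`: list with `points` (tibble `id`,
#'   `x`, `y`, `quadrant`), `quadrants` (tibble `quadrant`, `n`), `n_box`
#'   (points inside the `[0.2, 0.8]^2` square), `n_boundary`, `excluded`
#'   (ids with an undefined ratio). `tidy()` returns the points,
#'   `glance()` the summary counts.
#' @examples
#' tp <- tibble::tibble(id = "g", a3 = 8, u3 = 2, g3 = 6, c3 = 4)
#' tidy(pr2_analysis(tp))  # x = 0.6, y = 0.8 -> quadrant 1
#' @export
pr2_analysis <- function(composition) {
  stopifnot(all(c("id", "a3", "u3", "g3", "c3") %in% names(composition)))
  at <- composition$a3 + composition$u3
  gc <- composition$g3 + composition$c3
  ok <- at > 0 & gc > 0
  excluded <- composition$id[!ok]
  if (length(excluded) > 0) {
    message(length(excluded), " gene(s) excluded from PR2 (empty axis)")
  }
  x <- composition$g3[ok] / gc[ok]
  y <- composition$a3[ok] / at[ok]
  quadrant_of <- function(x, y) {
    cand <- c(1L, 2L, 3L, 4L)[c(x >= 0.5 & y >= 0.5, x <= 0.5 & y >= 0.5,
                                x <= 0.5 & y <= 0.5, x >= 0.5 & y <= 0.5)]
    min(cand)
  }
  q <- mapply(quadrant_of, x, y)
  points <- tibble::tibble(id = composition$id[ok], x = x, y = y,
                           quadrant = as.integer(q))
  structure(
    list(points = points,
         quadrants = tibble::tibble(
           quadrant = 1:4,
           n = vapply(1:4, function(i) sum(points$quadrant == i), integer(1))),
         n_box = sum(x >= 0.2 & x <= 0.8 & y >= 0.2 & y <= 0.8),
         n_boundary = sum(x == 0.5 | y == 0.5),
         excluded = excluded),
    class = "pr2_analysis"
  )
}

#' @export
print.pr2_analysis <- function(x, ...) {
  cat("PR2 bias analysis:", nrow(x$points), "genes\n")
  print(x$quadrants)
  cat("within [0.2, 0.8]^2:", x$n_box, "; on a boundary:", x$n_boundary, "\n")
  invisible(x)
}

#' @rdname pr2_analysis
#' @param x A `pr2_analysis` object.
#' @param ... Unused.
#' @method tidy pr2_analysis
#' @export
tidy.pr2_analysis <- function(x, ...) x$points

#' @rdname pr2_analysis
#' @method glance pr2_analysis
#' @export
glance.pr2_analysis <- function(x, ...) {
  tibble::tibble(
    n = nrow(x$points),
    n_q1 = x$quadrants$n[1], n_q2 = x$quadrants$n[2],
    n_q3 = x$quadrants$n[3], n_q4 = x$quadrants$n[4],
    n_box = x$n_box, n_boundary = x$n_boundary,
    n_excluded = length(x$excluded)
  )
}

#' Pairwise correlation matrix of codon-usage parameters
#'
#' Correlations (with unadjusted two-sided p-values) among the per-gene
#' parameters conventionally examined together: GC12, GC3, overall GC, ENc,
#' CAI and the first correspondence-analysis axis.
#'
#' @param metrics Tibble from [gene_metrics()]; must also contain `axis1`
#'   (join it from [axis1_scores()]) unless `parameters` omits it.
#' @param parameters Character vector of metric columns to correlate.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return Object of class `cub_cor_matrix`: list with `r` and `p`
#'   (symmetric matrices), `n`, `method`. Constant parameters get `NA`
#'   with a warning. `tidy()` returns the lower triangle as a long tibble.
#' @export
correlation_matrix <- function(metrics,
                               parameters = c("gc12", "gc3", "gc_all",
                                              "enc", "cai", "axis1"),
                               method = c("pearson", "spearman")) {
  method <- match.arg(method)
  missing_cols <- setdiff(parameters, names(metrics))
  if (length(missing_cols) > 0) {
    stop("missing parameter column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  d <- metrics[, parameters]
  d <- d[stats::complete.cases(d), ]
  if (nrow(d) < 3) stop("need at least 3 complete genes", call. = FALSE)
  constant <- vapply(d, function(v) stats::sd(v) == 0, logical(1))
  if (any(constant)) {
    warning("constant parameter(s): ",
            paste(parameters[constant], collapse = ", "), call. = FALSE)
  }
  p <- length(parameters)
  r_mat <- p_mat <- matrix(NA_real_, p, p, dimnames = list(parameters, parameters))
  diag(r_mat) <- 1
  diag(p_mat) <- 0
  for (i in seq_len(p - 1)) {
    for (j in seq(i + 1, p)) {
      if (constant[i] || constant[j]) next
      ct <- suppressWarnings(
        stats::cor.test(d[[i]], d[[j]], method = method, exact = FALSE))
      r_mat[i, j] <- r_mat[j, i] <- unname(ct$estimate)
      p_mat[i, j] <- p_mat[j, i] <- ct$p.value
    }
  }
  structure(list(r = r_mat, p = p_mat, n = nrow(d), method = method),
            class = "cub_cor_matrix")
}

#' @export
print.cub_cor_matrix <- function(x, ...) {
  cat("Correlation matrix (", x$method, ", n = ", x$n, ")\n", sep = "")
  print(round(x$r, 3))
  invisible(x)
}

#' @rdname correlation_matrix
#' @param x A `cub_cor_matrix`.
#' @param ... Unused.
#' @method tidy cub_cor_matrix
#' @export
tidy.cub_cor_matrix <- function(x, ...) {
  params <- rownames(x$r)
  pairs <- which(lower.tri(x$r), arr.ind = TRUE)
  tibble::tibble(
    parameter1 = params[pairs[, 2]],
    parameter2 = params[pairs[, 1]],
    r = x$r[pairs],
    p = x$p[pairs]
  )
}
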