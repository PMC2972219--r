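# Population-genetic summaries: multiallelic LD (chi-square prime), Ne from
# LD decay (Sved's curve) and the df-weighted genomic-control lambda.

#' Standardized multiallelic LD coefficient (chi-square prime)
#'
#' For a two-locus haplotype frequency table `f` with marginals `p_i`
#' (locus A, k alleles) and `q_j` (locus B, l alleles) and disequilibria
#' `D_ij = f_ij - p_i q_j`,
#' `chi2' = sum_ij D_ij^2 / (p_i q_j) / min(k - 1, l - 1)`.
#' This normalization bounds the coefficient in `[0, 1]` and reduces it to
#' the familiar `r^2` for a pair of biallelic loci, which makes it the
#' natural LD measure for microsatellite panels.
#'
#' @param model A fitted [em_pair()] model, or a numeric haplotype
#'   frequency matrix summing to 1.
#' @return The chi-square prime value, or `NA` (with a warning) when either
#'   locus is monomorphic.
#' @export
chi2prime <- function(model) {
  f <- if (inherits(model, "em_pair")) model$f else as.matrix(model)
  if (abs(sum(f) - 1) > 1e-6) stop("haplotype frequencies must sum to 1")
  p <- rowSums(f); q <- colSums(f)
  f <- f[p > 0, q > 0, drop = FALSE]
  p <- p[p > 0]; q <- q[q > 0]
  k <- length(p); l <- length(q)
  if (k < 2L || l < 2L) {
    warning("monomorphic locus: chi-square prime undefined")
    return(NA_real_)
  }
  D <- f - outer(p, q)
  sum(D^2 / outer(p, q)) / min(k - 1L, l - 1L)
}

#' Pairwise LD records within a map window
#'
#' Computes chi-square prime for every within-chromosome marker pair whose
#' map distance is at most `window_cM`, from EM haplotype frequencies fitted
#' on the full supplied sample. Chromosomes named like the X (or Y/MT) are
#' excluded when `autosomes_only` is `TRUE`. Pairs where either marker is
#' monomorphic in the sample (or has no jointly genotyped individuals) are
#' skipped.
#'
#' @inheritParams scan_pairs
#' @param window_cM Maximum pair distance in cM (default 15).
#' @param autosomes_only Drop sex/mitochondrial chromosomes (default `TRUE`).
#' @return Data frame of LD records: `chromosome`, `marker1`, `marker2`,
#'   `dist_cM`, `c` (Morgans), `chi2prime`, `n_used`.
#' @seealso [fit_sved()]
#' @export
ld_window_pairs <- function(genotypes, map, window_cM = 15,
                            autosomes_only = TRUE) {
  unknown <- setdiff(genotypes$markers, map$marker)
  if (length(unknown))
    stop("marker(s) missing from the map: ", paste(unknown, collapse = ", "))
  map <- map[map$marker %in% genotypes$markers, , drop = FALSE]
  if (autosomes_only) {
    sex <- toupper(map$chromosome) %in% c("X", "Y", "MT", "CHRX", "CHRY")
    map <- map[!sex, , drop = FALSE]
  }
  # pre-screen: a pair is only informative if both markers are polymorphic
  # among the genotyped individuals, so monomorphic markers never enter pairs
  poly <- vapply(map$marker, function(mk) {
    g <- geno_pair(genotypes, mk)
    length(unique(g[!is.na(g)])) >= 2L
  }, logical(1))
  n_mono <- sum(!poly)
  map <- map[poly, , drop = FALSE]
  rows <- list()
  skipped <- 0L
  for (chr in unique(map$chromosome)) {
    mk <- map$marker[map$chromosome == chr]
    pos <- map$position_cM[map$chromosome == chr]
    if (length(mk) < 2L) next
    pairs <- which(upper.tri(diag(length(mk))), arr.ind = TRUE)
    for (pi in seq_len(nrow(pairs))) {
      i <- pairs[pi, 1]; j <- pairs[pi, 2]
      d <- abs(pos[j] - pos[i])
      if (d > window_cM) next
      gA <- geno_pair(genotypes, mk[i]); gB <- geno_pair(genotypes, mk[j])
      fit <- tryCatch(em_pair(gA, gB), error = function(e) NULL)
      x2 <- if (is.null(fit)) NA_real_ else
        suppressWarnings(chi2prime(fit))
      if (is.na(x2)) { skipped <- skipped + 1L; next }
      rows[[length(rows) + 1L]] <-
        data.frame(chromosome = chr, marker1 = mk[i], marker2 = mk[j],
                   dist_cM = d, c = d / 100, chi2prime = x2,
                   n_used = fit$n_used, stringsAsFactors = FALSE)
    }
  }
  if (n_mono > 0L || skipped > 0L)
    message(n_mono, " monomorphic marker(s) excluded; ", skipped,
            " further pair(s) skipped")
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(chromosome = character(0), marker1 = character(0),
                      marker2 = character(0), dist_cM = numeric(0),
                      c = numeric(0), chi2prime = numeric(0),
                      n_used = integer(0))
  out
}

#' Effective population size from LD decay (Sved's curve)
#'
#' Fits the drift-recombination equilibrium expectation
#' `E[chi2'] = 1 / (1 + 4 Ne c) + e` to pairwise LD records by non-linear
#' least squares, where `c` is the pair distance in Morgans and `e` a
#' residual error intercept. The optimizer is Levenberg-Marquardt
#' ([minpack.lm::nlsLM()]) restarted from a deterministic grid of starting
#' values (`Ne` in 1, 10, 100, 1000, 10000 crossed with `e` in 0, 0.05,
#' 0.1) with `Ne` constrained positive; the best local optimum by residual
#' sum of squares is reported.
#'
#' @param records Data frame with columns `c` (Morgans) and `chi2prime`,
#'   e.g. from [ld_window_pairs()].
#' @return Object of class `sved_fit`: `Ne`, `e`, `rss`, `n_pairs`,
#'   `converged`, and the underlying `nls` fit. `coef()`, `predict()`,
#'   `residuals()` and `plot()` methods are provided.
#' @examples
#' c <- seq(0.01, 0.15, by = 0.01)
#' fit <- fit_sved(data.frame(c = c, chi2prime = 1 / (1 + 4 * 30 * c) + 0.05))
#' coef(fit)   # recovers Ne = 30, e = 0.05
#' @export
fit_sved <- function(records) {
  if (!all(c("c", "chi2prime") %in% names(records)))
    stop("records need columns 'c' and 'chi2prime'")
  d <- records[is.finite(records$c) & is.finite(records$chi2prime), ]
  if (nrow(d) < 3L) stop("need at least 3 LD records")
  if (length(unique(d$c)) < 2L)
    stop("all pair distances are equal: Ne is unidentifiable")
  starts <- expand.grid(Ne = c(1, 10, 100, 1000, 10000),
                        e = c(0, 0.05, 0.1))
  best <- NULL
  for (s in seq_len(nrow(starts))) {
    fit <- tryCatch(suppressWarnings(
      minpack.lm::nlsLM(chi2prime ~ 1 / (1 + 4 * Ne * c) + e,
                        data = d,
                        start = list(Ne = starts$Ne[s], e = starts$e[s]),
                        lower = c(Ne = 1e-8, e = -1),
                        control = minpack.lm::nls.lm.control(maxiter = 200))),
      error = function(err) NULL)
    if (is.null(fit)) next
    rss <- sum(stats::residuals(fit)^2)
    if (is.null(best) || rss < best$rss - 1e-12)
      best <- list(fit = fit, rss = rss)
  }
  if (is.null(best)) stop("Sved regression failed from every start")
  cf <- stats::coef(best$fit)
  structure(list(Ne = unname(cf["Ne"]), e = unname(cf["e"]),
                 rss = best$rss, n_pairs = nrow(d),
                 converged = best$fit$convInfo$isConv,
                 fit = best$fit, data = d),
            class = "sved_fit")
}

#' @export
print.sved_fit <- function(x, ...) {
  cat(sprintf("Sved LD-decay fit on %d pairs: Ne = %.2f, e = %.4f (RSS %.4g)\n",
              x$n_pairs, x$Ne, x$e, x$rss))
  invisible(x)
}

#' @export
coef.sved_fit <- function(object, ...) c(Ne = object$Ne, e = object$e)

#' @export
predict.sved_fit <- function(object, newdata = NULL, ...) {
  c_new <- if (is.null(newdata)) object$data$c else newdata$c
  1 / (1 + 4 * object$Ne * c_new) + object$e
}

#' @export
residuals.sved_fit <- function(object, ...) {
  object$data$chi2prime - predict(object)
}

#' @export
plot.sved_fit <- function(x, ...) {
  graphics::plot(x$data$c, x$data$chi2prime, pch = 16,
                 col = grDevices::grey(0.4, 0.4),
                 xlab = "distance c (Morgans)",
                 ylab = expression(paste(chi^2, "'")), ...)
  cs <- seq(min(x$data$c), max(x$data$c), length.out = 200)
  graphics::lines(cs, 1 / (1 + 4 * x$Ne * cs) + x$e, col = "red", lwd = 2)
  invisible(x)
}

# median with a selectable convention for even counts: "lower" takes the
# lower of the two central order statistics, "mean" their average
.median_conv <- function(x, convention = c("lower", "mean")) {
  convention <- match.arg(convention)
  if (convention == "mean") return(stats::median(x))
  sort(x)[floor((length(x) + 1) / 2)]
}

#' Genomic-control inflation factor for mixed-df tests
#'
#' Computes the genomic-control lambda from a collection of chi-square
#' statistics with heterogeneous degrees of freedom: within each df class
#' `d`, `lambda_d` is the observed median divided by the null median
#' `qchisq(0.5, d)`, and the overall lambda is the mean of the `lambda_d`
#' weighted by the number of tests in each class. Lambda near 1 indicates
#' no inflation (e.g. no population stratification); because the inputs are
#' typically continuity-corrected statistics from sparse tables, values
#' slightly below 1 are common.
#'
#' @param chi2 Numeric vector of (Yates-corrected) chi-square values, or a
#'   data frame containing columns `chi2` and `df` (e.g. the `pairs` table
#'   of a [scan_pairs()] result).
#' @param df Integer degrees of freedom per test (recycled if length 1).
#' @param median_convention For even-sized classes, `"lower"` (default)
#'   takes the lower central order statistic, `"mean"` the usual midpoint.
#' @return Object of class `lambda_report`: `by_df` (df, n_tests, observed
#'   and expected medians, lambda) and `overall`.
#' @export
genomic_control_lambda <- function(chi2, df = NULL,
                                   median_convention = c("lower", "mean")) {
  median_convention <- match.arg(median_convention)
  if (is.data.frame(chi2)) {
    if (!all(c("chi2", "df") %in% names(chi2)))
      stop("data frame input needs columns 'chi2' and 'df'")
    df <- chi2$df; chi2 <- chi2$chi2
  }
  keep <- is.finite(chi2) & is.finite(df)
  chi2 <- chi2[keep]; df <- as.integer(df[keep])
  if (length(chi2) == 0L) stop("no usable test statistics")
  if (any(df < 1L)) stop("degrees of freedom must be >= 1")
  dfs <- sort(unique(df))
  by_df <- do.call(rbind, lapply(dfs, function(d) {
    x <- chi2[df == d]
    obs <- .median_conv(x, median_convention)
    expd <- stats::qchisq(0.5, d)
    data.frame(df = d, n_tests = length(x), observed_median = obs,
               expected_median = expd, lambda = obs / expd)
  }))
  overall <- sum(by_df$n_tests * by_df$lambda) / sum(by_df$n_tests)
  structure(list(by_df = by_df, overall = overall,
                 median_convention = median_convention),
            class = "lambda_report")
}

#' @export
print.lambda_report <- function(x, digits = 4, ...) {
  cat(sprintf("Genomic control: overall lambda = %.*f (%d tests, %d df classes)\n",
              digits, x$overall, sum(x$by_df$n_tests), nrow(x$by_df)))
  print(x$by_df, digits = digits, row.names = FALSE)
  invisible(x)
}
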