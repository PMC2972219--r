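# chi-square prime, LD windows, Sved Ne regression, genomic control

test_that("chi-square prime hits its analytic anchors", {
  # independence -> 0
  expect_equal(chi2prime(outer(c(0.3, 0.7), c(0.4, 0.6))), 0,
               tolerance = 1e-12)
  # complete biallelic LD -> 1
  expect_equal(chi2prime(matrix(c(0.5, 0, 0, 0.5), 2, 2)), 1,
               tolerance = 1e-12)
  # 3 x 2 fixture against direct formula evaluation
  f <- matrix(c(0.30, 0.10, 0.05, 0.05, 0.15, 0.35), 3, 2)
  p <- rowSums(f); q <- colSums(f)
  D <- f - outer(p, q)
  direct <- sum(D^2 / outer(p, q)) / min(2, 1)
  expect_equal(chi2prime(f), direct, tolerance = 1e-12)
  expect_warning(v <- chi2prime(matrix(c(0.6, 0.4), 1, 2)), "monomorphic")
  expect_true(is.na(v))
})

test_that("chi-square prime equals r^2 for biallelic pairs", {
  set.seed(12)
  for (i in 1:100) {
    f <- matrix(rgamma(4, 1), 2, 2); f <- f / sum(f)
    p <- rowSums(f); q <- colSums(f)
    D <- f[1, 1] - p[1] * q[1]
    r2 <- D^2 / (p[1] * p[2] * q[1] * q[2])
    expect_equal(chi2prime(f), r2, tolerance = 1e-12)
  }
})

test_that("chi-square prime is symmetric and relabeling-invariant", {
  set.seed(3)
  f <- matrix(rgamma(6, 1), 3, 2); f <- f / sum(f)
  expect_equal(chi2prime(t(f)), chi2prime(f), tolerance = 1e-12)
  expect_equal(chi2prime(f[c(3, 1, 2), ]), chi2prime(f), tolerance = 1e-12)
  expect_equal(chi2prime(f[, 2:1]), chi2prime(f), tolerance = 1e-12)
})

test_that("window pairing enumerates exactly the qualifying pairs", {
  st <- simulate_population(small_cfg(6, n_chr = 2, len = 10, n_mark = 3,
                                      n_ind = 150, gens = 5, effect = 0))
  rec <- suppressMessages(ld_window_pairs(st$genotypes, st$map,
                                          window_cM = 15))
  expect_equal(nrow(rec), 6)              # C(3,2) per chromosome, all within
  expect_true(all(rec$c == rec$dist_cM / 100))
  # brute-force enumeration oracle on a wider map with a binding window
  st2 <- simulate_population(small_cfg(8, n_chr = 1, len = 60, n_mark = 7,
                                       n_ind = 150, gens = 5, effect = 0))
  rec2 <- suppressMessages(ld_window_pairs(st2$genotypes, st2$map,
                                           window_cM = 15))
  pos <- st2$map$position_cM
  want <- sum(outer(pos, pos, function(a, b) b - a) > 0 &
                outer(pos, pos, function(a, b) b - a) <= 15)
  expect_equal(nrow(rec2), want)          # no monomorphic skips at 5 gens
  expect_true(all(rec2$dist_cM <= 15))
})

test_that("the X chromosome is excluded from autosomal LD windows", {
  map <- genetic_map(data.frame(marker = c("a1", "a2", "x1", "x2"),
                                chromosome = c("1", "1", "X", "X"),
                                position_cM = c(0, 5, 0, 5)))
  set.seed(9)
  a1 <- matrix(sample(1:3, 4 * 30, TRUE), 30, 4,
               dimnames = list(sprintf("i%02d", 1:30), map$marker))
  a2 <- matrix(sample(1:3, 4 * 30, TRUE), 30, 4, dimnames = dimnames(a1))
  g <- geno_matrix(pmin(a1, a2), pmax(a1, a2))
  expect_equal(unique(ld_window_pairs(g, map)$chromosome), "1")
  expect_true("X" %in% ld_window_pairs(g, map, autosomes_only = FALSE)$chromosome)
})

test_that("Sved regression recovers parameters from its own curve", {
  cs <- seq(0.01, 0.15, by = 0.01)
  fit <- fit_sved(data.frame(c = cs, chi2prime = 1 / (1 + 4 * 30 * cs) + 0.05))
  expect_equal(unname(coef(fit)), c(30, 0.05), tolerance = 1e-6)
  fit100 <- fit_sved(data.frame(c = cs, chi2prime = 1 / (1 + 4 * 100 * cs)))
  expect_equal(fit100$Ne, 100, tolerance = 1e-5)
  # monotonicity: higher LD level at every distance -> smaller Ne
  nes <- vapply(c(10, 30, 100, 300), function(ne)
    fit_sved(data.frame(c = cs, chi2prime = 1 / (1 + 4 * ne * cs)))$Ne,
    numeric(1))
  expect_true(all(diff(nes) > 0))
  expect_error(fit_sved(data.frame(c = rep(0.05, 10),
                                   chi2prime = runif(10))),
               "unidentifiable")
  expect_error(fit_sved(data.frame(c = 0.1, chi2prime = 0.5)), "at least 3")
})

test_that("Sved regression tolerates noise and is consistent in n", {
  set.seed(11)
  cs <- runif(5000, 0.001, 0.15)
  y <- 1 / (1 + 4 * 30 * cs) + 0.05 + rnorm(5000, 0, 0.05)
  fit <- fit_sved(data.frame(c = cs, chi2prime = y))
  expect_gte(fit$Ne, 24); expect_lte(fit$Ne, 36)
  err <- vapply(c(100, 1000, 10000), function(n) {
    set.seed(n)
    cc <- runif(n, 0.001, 0.15)
    yy <- 1 / (1 + 4 * 30 * cc) + rnorm(n, 0, 0.05)
    abs(fit_sved(data.frame(c = cc, chi2prime = yy))$Ne - 30)
  }, numeric(1))
  expect_lt(err[3], err[1])
})

test_that("genomic control lambda follows its definition and scaling", {
  lr <- genomic_control_lambda(rep(qchisq(0.5, 1), 1001), rep(1, 1001))
  expect_equal(lr$overall, 1, tolerance = 1e-12)
  set.seed(6)
  ch <- c(rchisq(501, 1), rchisq(200, 3))
  dfv <- c(rep(1, 501), rep(3, 200))
  l1 <- genomic_control_lambda(ch, dfv)
  l2 <- genomic_control_lambda(2 * ch, dfv)
  expect_equal(l2$overall, 2 * l1$overall, tolerance = 1e-12)
  expect_equal(l2$by_df$lambda, 2 * l1$by_df$lambda, tolerance = 1e-12)
  # weighted-mean identity
  expect_equal(l1$overall,
               sum(l1$by_df$n_tests * l1$by_df$lambda) / sum(l1$by_df$n_tests))
  expect_error(genomic_control_lambda(1.5, 0), "freedom")
})

test_that("lambda is near 1 on null chi-square draws with mixed df", {
  set.seed(5)
  ch <- c(rchisq(1000, 1), rchisq(122, 4))
  dfv <- c(rep(1, 1000), rep(4, 122))
  lr <- genomic_control_lambda(ch, dfv)
  expect_gte(lr$overall, 0.9)
  expect_lte(lr$overall, 1.1)
})

test_that("the even-count median convention is honoured and documented", {
  x <- c(1, 2, 3, 10)
  low <- genomic_control_lambda(x, rep(1, 4))
  mid <- genomic_control_lambda(x, rep(1, 4), median_convention = "mean")
  expect_equal(low$by_df$observed_median, 2)
  expect_equal(mid$by_df$observed_median, 2.5)
})
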