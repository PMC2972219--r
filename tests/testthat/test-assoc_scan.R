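# HWE tests, Fisher r x 2 exact test, Yates chi-square, pair tables, scan

test_that("HWE exact test matches closed-form biallelic enumeration", {
  expect_equal(hwe_test(c("1/1" = 10))$p.value, 1)   # monomorphic
  expect_equal(hwe_test(c("1/1" = 25, "1/2" = 50, "2/2" = 25))$p.value,
               oracle_hwe_biallelic(25, 50, 25), tolerance = 1e-10)
  set.seed(19)
  for (i in 1:10) {
    n11 <- sample(0:12, 1); n12 <- sample(0:12, 1); n22 <- sample(0:12, 1)
    if (n11 + n12 + n22 == 0) n11 <- 5
    cnt <- c("1/1" = n11, "1/2" = n12, "2/2" = n22)
    expect_equal(hwe_test(cnt[cnt > 0])$p.value,
                 oracle_hwe_biallelic(n11, n12, n22), tolerance = 1e-10)
  }
})

test_that("HWE Monte Carlo agrees with full enumeration", {
  cnt <- c("1/1" = 6, "1/2" = 9, "2/2" = 4, "1/3" = 3, "2/3" = 2, "3/3" = 2)
  exact <- hwe_test(cnt)
  expect_equal(exact$method, "exact-enumeration")
  mc <- hwe_test(cnt, max_tables = 1, mc_reps = 20000, seed = 7)
  expect_equal(mc$method, "monte-carlo")
  expect_lt(abs(mc$p.value - exact$p.value), 3 * mc$mc_se)
})

test_that("Fisher r x 2 reproduces analytic and enumeration-oracle p-values", {
  expect_equal(fisher_exact_rx2(rbind(c(5, 5), c(5, 5)))$p.value, 1)
  expect_equal(fisher_exact_rx2(rbind(c(5, 0), c(0, 5)))$p.value,
               2 / choose(10, 5), tolerance = 1e-12)
  t3 <- rbind(c(6, 1), c(3, 4), c(1, 5))
  expect_equal(fisher_exact_rx2(t3)$p.value, oracle_fisher_rx2(t3),
               tolerance = 1e-10)
  expect_error(fisher_exact_rx2(rbind(c(1, 0), c(2, 0))), "empty column")
})

test_that("r = 2 case reduces to the classical two-sided 2 x 2 Fisher test", {
  set.seed(23)
  for (i in 1:100) {
    tab <- matrix(rpois(4, 4), 2, 2)
    if (any(colSums(tab) == 0)) tab <- tab + 1
    expect_equal(fisher_exact_rx2(tab)$p.value,
                 stats::fisher.test(tab)$p.value, tolerance = 1e-7)
  }
})

test_that("zero-count haplotype rows do not change the Fisher p", {
  tab <- rbind(c(5, 2), c(3, 4))
  tab0 <- rbind(c(5, 2), c(0, 0), c(3, 4))
  expect_equal(fisher_exact_rx2(tab0)$p.value,
               fisher_exact_rx2(tab)$p.value, tolerance = 1e-12)
})

test_that("Monte Carlo Fisher agrees with enumeration within 3 MC-SE", {
  tab <- rbind(c(12, 3), c(5, 9), c(2, 8), c(7, 4))
  exact <- fisher_exact_rx2(tab)
  mc <- fisher_exact_rx2(tab, max_tables = 1, mc_reps = 20000, seed = 5)
  expect_lt(abs(mc$p.value - exact$p.value), 3 * mc$mc_se)
})

test_that("Yates-corrected chi-square follows the clamped per-cell formula", {
  expect_equal(yates_chi2(rbind(c(5, 5), c(5, 5)))$chi2, 0)
  y <- yates_chi2(rbind(c(10, 0), c(0, 10)))
  expect_equal(y$chi2, 4 * (4.5^2 / 5), tolerance = 1e-12)   # E = 5, |O-E| = 5
  expect_equal(y$df, 1L)
  # 3 x 2 hand computation: margins (8,8,8) x (10,14), E = (10/3, 14/3)
  tab <- rbind(c(6, 2), c(3, 5), c(1, 7))
  hand <- (6 - 10/3 - 0.5)^2 / (10/3) + (2 - 14/3 + 0.5)^2 / (14/3) +
    0 + 0 +                                   # row 2: |O-E| = 1/3 < 0.5
    (10/3 - 1 - 0.5)^2 / (10/3) + (7 - 14/3 - 0.5)^2 / (14/3)
  expect_equal(yates_chi2(tab)$chi2, hand, tolerance = 1e-12)
  expect_equal(yates_chi2(tab)$df, 2L)
  expect_error(yates_chi2(rbind(c(0, 0), c(1, 2))), "expected")
})

test_that("pair tables match hand counts and apply the frequency filter", {
  # phase-unambiguous construction: everyone homozygous at marker A
  a_allele <- c(rep(1, 10), rep(1, 4), rep(1, 6), rep(2, 4), rep(2, 1))
  b1 <- c(rep(1, 10), rep(1, 4), rep(2, 6), rep(1, 4), rep(1, 1))
  b2 <- c(rep(1, 10), rep(2, 4), rep(2, 6), rep(1, 4), rep(2, 1))
  gA <- cbind(a_allele, a_allele)
  gB <- cbind(b1, b2)
  groups <- rep(c("high", "low"), c(13, 12))
  model <- em_pair(gA, gB)
  # haplotype frequencies: 1:1 = 0.48, 1:2 = 0.32, 2:1 = 0.18, 2:2 = 0.02
  expect_equal(unname(coef(model)["2:2"]), 0.02, tolerance = 1e-9)
  pt <- build_pair_table(model, gA, gB, groups, min_freq = 0.05)
  expect_false(pt$untestable)
  expect_equal(rownames(pt$table), c("1:1", "1:2", "2:1"))
  expect_true("2:2" %in% pt$dropped)
  hand <- t(vapply(c("high", "low"), function(g) {
    idx <- groups == g
    hap <- paste0(c(gA[idx, 1], gA[idx, 2]), ":", c(gB[idx, 1], gB[idx, 2]))
    table(factor(hap, levels = c("1:1", "1:2", "2:1")))
  }, numeric(3)))
  expect_equal(unname(pt$table), unname(t(hand)))
  # fewer than two surviving haplotypes -> untestable
  gA1 <- cbind(rep(1, 20), rep(1, 20))
  gB1 <- cbind(rep(1, 20), c(rep(1, 19), 2))
  pt1 <- build_pair_table(em_pair(gA1, gB1), gA1, gB1,
                          rep(c("high", "low"), 10))
  expect_true(pt1$untestable)
})

test_that("scan p-values equal Fisher on the hand-built haplotype table", {
  ids <- sprintf("i%02d", 1:12)
  a1 <- c(rep(1, 6), rep(2, 3), rep(1, 3))
  b1 <- c(rep(1, 3), rep(1, 3), rep(2, 3), rep(2, 3))
  b2 <- c(rep(1, 3), rep(2, 3), rep(2, 3), rep(2, 3))
  A <- cbind(a1, a1); B <- cbind(b1, b2)
  g <- geno_matrix(matrix(c(pmin(A[, 1], A[, 2]), pmin(B[, 1], B[, 2])), 12, 2,
                          dimnames = list(ids, c("mA", "mB"))),
                   matrix(c(pmax(A[, 1], A[, 2]), pmax(B[, 1], B[, 2])), 12, 2,
                          dimnames = list(ids, c("mA", "mB"))))
  map <- genetic_map(data.frame(marker = c("mA", "mB"), chromosome = "1",
                                position_cM = c(0, 5)))
  groups <- stats::setNames(rep(c("high", "low"), each = 6), ids)
  sc <- suppressMessages(scan_pairs(g, map, groups, do_hwe = FALSE))
  hand_tab <- rbind("1:1" = c(9, 0), "1:2" = c(3, 6), "2:2" = c(0, 6))
  expect_equal(sc$pairs$p, fisher_exact_rx2(hand_tab)$p.value,
               tolerance = 1e-12)
  expect_equal(sc$pairs$df, 2L)
  expect_equal(sc$n_tests, 1L)
})

test_that("identical group counts give p = 1 and no significance", {
  ids <- sprintf("i%02d", 1:12)
  a1 <- rep(c(1, 2), 6)
  b1 <- rep(c(1, 2), 6)
  A <- cbind(a1, a1); B <- cbind(b1, b1)    # both groups identical
  dn <- list(ids, c("mA", "mB"))
  g <- geno_matrix(matrix(c(A[, 1], B[, 1]), 12, 2, dimnames = dn),
                   matrix(c(A[, 2], B[, 2]), 12, 2, dimnames = dn))
  map <- genetic_map(data.frame(marker = c("mA", "mB"), chromosome = "1",
                                position_cM = c(0, 5)))
  groups <- stats::setNames(rep(c("high", "high", "low", "low"), 3), ids)
  sc <- suppressMessages(scan_pairs(g, map, groups, do_hwe = FALSE))
  expect_equal(sc$pairs$p, 1)
  expect_false(any(sc$pairs$genome_significant))
})

test_that("scan output is invariant to marker renaming and individual order", {
  st <- simulate_population(small_cfg(17, n_ind = 80, n_mark = 5, n_chr = 2))
  sel <- select_tails(st$phenotypes, st$sires, n_high = 20, n_low = 20)
  sc1 <- suppressMessages(scan_pairs(st$genotypes, st$map, sel$groups,
                                     do_hwe = FALSE))
  # rename markers (same order) and permute individuals
  set.seed(2)
  perm <- sample(length(st$genotypes$ids))
  new_names <- sprintf("mk%02d", seq_along(st$genotypes$markers))
  a1 <- st$genotypes$a1[perm, ]; a2 <- st$genotypes$a2[perm, ]
  colnames(a1) <- colnames(a2) <- new_names
  g2 <- geno_matrix(a1, a2)
  map2 <- st$map
  map2$marker <- new_names
  map2 <- genetic_map(map2)
  sc2 <- suppressMessages(scan_pairs(g2, map2, sel$groups, do_hwe = FALSE))
  expect_equal(sc2$pairs$p, sc1$pairs$p, tolerance = 1e-12)
  expect_equal(sc2$pairs$chi2, sc1$pairs$chi2, tolerance = 1e-12)
})

test_that("HWE screen flags markers and single-marker chromosomes warn", {
  st <- simulate_population(small_cfg(21, n_ind = 60, n_mark = 3, n_chr = 1))
  sel <- select_tails(st$phenotypes, st$sires, n_high = 15, n_low = 15)
  sc <- suppressMessages(scan_pairs(st$genotypes, st$map, sel$groups,
                                    do_hwe = TRUE, hwe_mc_reps = 500,
                                    seed = 1))
  expect_true(all(c("marker", "group", "p", "fail") %in% names(sc$hwe)))
  expect_true(all(sc$hwe$p > 0 & sc$hwe$p <= 1))
  # a chromosome with a single marker is skipped with a warning
  map1 <- genetic_map(rbind(as.data.frame(st$map),
                            data.frame(marker = "solo", chromosome = "9",
                                       position_cM = 0)))
  a1 <- cbind(st$genotypes$a1, solo = 1L)
  a2 <- cbind(st$genotypes$a2, solo = 1L)
  g2 <- geno_matrix(a1, a2)
  expect_warning(suppressMessages(scan_pairs(g2, map1, sel$groups,
                                             do_hwe = FALSE)),
                 "skipped")
})

test_that("scan results serialize to the documented TSV layout", {
  st <- simulate_population(small_cfg(27, n_ind = 60, n_mark = 4, n_chr = 1))
  sel <- select_tails(st$phenotypes, st$sires, n_high = 15, n_low = 15)
  sc <- suppressMessages(scan_pairs(st$genotypes, st$map, sel$groups,
                                    do_hwe = TRUE, hwe_mc_reps = 200, seed = 3))
  dir <- withr::local_tempdir()
  write_scan(sc, dir)
  expect_true(all(file.exists(file.path(dir, c("pairs.tsv", "hwe.tsv",
                                               "thresholds.txt")))))
  back <- utils::read.delim(file.path(dir, "pairs.tsv"))
  expect_equal(nrow(back), nrow(sc$pairs))
  expect_equal(back$p, sc$pairs$p, tolerance = 1e-9)
})
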