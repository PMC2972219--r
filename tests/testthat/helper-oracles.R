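# Independent oracles used by the tests. These deliberately re-derive each
# quantity by a different route than the package implementation.

# --- Fisher r x 2: plain recursive enumeration of all tables with the
# observed margins, summing hypergeometric probabilities <= observed.
oracle_fisher_rx2 <- function(tab) {
  rs <- rowSums(tab); c1 <- sum(tab[, 1]); n <- sum(tab)
  lps <- c()
  rec <- function(i, rem, lp) {
    if (i == length(rs)) {
      if (rem <= rs[i]) lps <<- c(lps, lp + lchoose(rs[i], rem))
      return(invisible())
    }
    for (x in 0:min(rs[i], rem)) rec(i + 1L, rem - x, lp + lchoose(rs[i], x))
  }
  rec(1L, c1, 0)
  lp <- lps - lchoose(n, c1)
  obs <- sum(lchoose(rs, tab[, 1])) - lchoose(n, c1)
  sum(exp(lp)[lp <= obs + log1p(1e-12)])
}

# --- biallelic HWE: closed-form loop over heterozygote counts
oracle_hwe_biallelic <- function(n11, n12, n22) {
  n <- n11 + n12 + n22
  m1 <- 2 * n11 + n12
  m2 <- 2 * n22 + n12
  lp_of <- function(h) {
    hom1 <- (m1 - h) / 2; hom2 <- (m2 - h) / 2
    lfactorial(n) + lfactorial(m1) + lfactorial(m2) + h * log(2) -
      lfactorial(2 * n) - lfactorial(h) - lfactorial(hom1) - lfactorial(hom2)
  }
  hs <- seq(m1 %% 2, min(m1, m2), by = 2)
  lp <- vapply(hs, lp_of, numeric(1))
  obs <- lp_of(n12)
  sum(exp(lp)[lp <= obs + log1p(1e-12)])
}

# --- two-locus multinomial likelihood maximized directly (multi-start BFGS
# on a softmax parameterization); independent of the EM iteration.
# Indices of each individual's phase resolutions are precomputed once so the
# likelihood is a vectorized expression in the haplotype frequency vector.
oracle_em_mle <- function(gA, gB, n_starts = 25, seed = 1) {
  use <- stats::complete.cases(cbind(gA, gB))
  gA <- gA[use, , drop = FALSE]; gB <- gB[use, , drop = FALSE]
  A <- sort(unique(as.vector(gA))); B <- sort(unique(as.vector(gB)))
  hapnames <- as.vector(outer(A, B, function(a, b) paste0(a, ":", b)))
  nH <- length(hapnames)
  hidx <- function(a, b) match(paste0(a, ":", b), hapnames)
  a1 <- pmin(gA[, 1], gA[, 2]); a2 <- pmax(gA[, 1], gA[, 2])
  b1 <- pmin(gB[, 1], gB[, 2]); b2 <- pmax(gB[, 1], gB[, 2])
  i1 <- hidx(a1, b1); j1 <- hidx(a2, b2)   # resolution 1
  i2 <- hidx(a1, b2); j2 <- hidx(a2, b1)   # resolution 2 (double hets only)
  dh <- a1 != a2 & b1 != b2
  m1 <- ifelse(a1 == a2 & b1 == b2, 1, 2)
  loglik_of <- function(f) {
    li <- m1 * f[i1] * f[j1] + ifelse(dh, 2 * f[i2] * f[j2], 0)
    if (any(li <= 0)) return(-Inf)
    sum(log(li))
  }
  negll <- function(theta) {
    f <- exp(theta - max(theta)); f <- f / sum(f)
    -loglik_of(f)
  }
  set.seed(seed)
  best <- NULL
  starts <- c(list(rep(0, nH)),
              lapply(seq_len(n_starts - 1), function(i) rnorm(nH, 0, 1.5)))
  for (th0 in starts) {
    o <- tryCatch(stats::optim(th0, negll, method = "BFGS",
                               control = list(maxit = 2000, reltol = 1e-14)),
                  error = function(e) NULL)
    if (!is.null(o) && (is.null(best) || o$value < best$value)) best <- o
  }
  f <- exp(best$par - max(best$par)); f <- f / sum(f)
  list(f = stats::setNames(f, hapnames), loglik = -best$value)
}

# random small genotype instance drawn from a random haplotype distribution;
# guaranteed to contain phase-unambiguous individuals so the MLE is
# (generically) unique
rand_em_instance <- function(n = 8, kA = 3, kB = 3) {
  repeat {
    f <- rgamma(kA * kB, 1); f <- f / sum(f)
    hap <- matrix(sample(kA * kB, 2 * n, replace = TRUE, prob = f), n, 2)
    a <- (hap - 1) %% kA + 1
    b <- (hap - 1) %/% kA + 1
    gA <- cbind(a[, 1], a[, 2]); gB <- cbind(b[, 1], b[, 2])
    dh <- gA[, 1] != gA[, 2] & gB[, 1] != gB[, 2]
    if (sum(!dh) >= 2) return(list(gA = gA, gB = gB))
  }
}

# small simulation config on a compact genome
small_cfg <- function(seed, n_chr = 2, len = 60, n_mark = 8, n_ind = 120,
                      gens = 25, effect = -3, ne = 30, n_sires = 25, ...) {
  sim_config(ne = ne,
             chromosomes = data.frame(name = as.character(seq_len(n_chr)),
                                      length_cM = len, n_markers = n_mark),
             n_individuals = n_ind, n_generations = gens,
             causal = list(chromosome = "1", position_cM = len / 2,
                           maf = 0.3, effect = effect,
                           phenotype_mean = 16, phenotype_sd = 7),
             n_sires = n_sires, seed = seed, ...)
}
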