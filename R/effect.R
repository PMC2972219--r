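# Candidate-locus genotype-phenotype summary.

#' Genotype-class phenotype summary and additive effect at a candidate locus
#'
#' Summarizes a quantitative phenotype by candidate-locus genotype class
#' (0, 1 or 2 copies of the minor allele, i.e. major homozygote /
#' heterozygote / minor homozygote), runs pairwise two-sample Student
#' t-tests between classes, estimates the additive allele-substitution
#' effect as the least-squares slope of phenotype on minor-allele count,
#' and checks the genotype frequencies for Hardy-Weinberg equilibrium.
#' Effects should be estimated on the full (unselected) sample: estimates
#' from tail-selected samples are biased away from zero.
#'
#' @param allele_count Integer vector in 0:2, the per-individual number of
#'   minor-allele copies; `NA` allowed (excluded).
#' @param phenotypes Numeric vector aligned with `allele_count` (or named,
#'   with `allele_count` named identically).
#' @param welch Use Welch's unequal-variance t-test instead of the classical
#'   pooled-variance Student test (default `FALSE`).
#' @return Object of class `genotype_effect`: `classes` (per class: n,
#'   mean, sem), `t_tests` (pairwise t, df, p; classes with n < 2 are
#'   summarized but excluded from testing), `additive_effect` and
#'   `additive_se` (OLS slope on allele count), `hwe` (a [hwe_test()] on
#'   the genotype counts), `n`.
#' @examples
#' ac <- c(rep(0, 5), rep(1, 5), rep(2, 5))
#' ph <- 16 - 3 * ac + rnorm(15)
#' genotype_effect(ac, ph)
#' @export
genotype_effect <- function(allele_count, phenotypes, welch = FALSE) {
  if (!is.null(names(allele_count)) && !is.null(names(phenotypes)))
    phenotypes <- phenotypes[names(allele_count)]
  ok <- !is.na(allele_count) & is.finite(phenotypes)
  ac <- as.integer(allele_count[ok])
  ph <- as.numeric(phenotypes[ok])
  if (!all(ac %in% 0:2)) stop("allele counts must be 0, 1 or 2")
  cls <- factor(ac, levels = 0:2,
                labels = c("major/major", "major/minor", "minor/minor"))
  tab <- data.frame(class = levels(cls),
                    allele_count = 0:2,
                    n = as.integer(table(cls)),
                    mean = as.numeric(tapply(ph, cls, mean)),
                    sem = as.numeric(tapply(ph, cls, function(x)
                      stats::sd(x) / sqrt(length(x)))),
                    stringsAsFactors = FALSE)
  present <- tab$class[tab$n >= 2L]
  if (length(present) < 2L)
    stop("need at least two genotype classes with n >= 2")

  combos <- utils::combn(present, 2L)
  tt <- do.call(rbind, lapply(seq_len(ncol(combos)), function(i) {
    g1 <- combos[1, i]; g2 <- combos[2, i]
    x <- ph[cls == g1]; y <- ph[cls == g2]
    if (stats::var(x) + stats::var(y) == 0 && mean(x) == mean(y)) {
      # degenerate constant data: no evidence against equality
      return(data.frame(class1 = g1, class2 = g2, t = 0,
                        df = length(x) + length(y) - 2, p = 1,
                        stringsAsFactors = FALSE))
    }
    res <- stats::t.test(x, y, var.equal = !welch)
    data.frame(class1 = g1, class2 = g2,
               t = unname(res$statistic), df = unname(res$parameter),
               p = res$p.value, stringsAsFactors = FALSE)
  }))

  fit <- stats::lm(ph ~ ac)
  # suppressed warning: summary.lm complains about zero-residual (perfect)
  # fits, which arise for legitimate degenerate inputs such as constant
  # phenotypes
  sm <- suppressWarnings(summary(fit))$coefficients
  eff <- unname(sm["ac", "Estimate"])
  se <- unname(sm["ac", "Std. Error"])

  cnt <- c("1/1" = sum(ac == 0L), "1/2" = sum(ac == 1L),
           "2/2" = sum(ac == 2L))
  hwe <- hwe_test(cnt[cnt > 0])

  structure(list(classes = tab, t_tests = tt,
                 additive_effect = eff, additive_se = se,
                 hwe = hwe, n = length(ph), welch = welch),
            class = "genotype_effect")
}

#' @export
print.genotype_effect <- function(x, ...) {
  cat(sprintf("Candidate-locus effect summary (n = %d)\n", x$n))
  print(transform(x$classes, mean = round(mean, 3), sem = round(sem, 3)),
        row.names = FALSE)
  cat(sprintf("additive effect: %+.3f per minor-allele copy (SE %.3f)\n",
              x$additive_effect, x$additive_se))
  cat(sprintf("%s t-tests:\n", if (x$welch) "Welch" else "Student"))
  print(transform(x$t_tests, t = round(t, 3), p = signif(p, 3)),
        row.names = FALSE)
  cat(sprintf("HWE of genotype counts: p = %.4g (%s)\n",
              x$hwe$p.value, x$hwe$method))
  invisible(x)
}
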