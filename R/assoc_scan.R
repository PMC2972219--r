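# Association engine: HWE screening, haplotype count tables, exact tests,
# Bonferroni thresholds and the chromosome-by-chromosome scan.

.parse_geno_counts <- function(counts) {
  if (is.null(names(counts)) || any(names(counts) == ""))
    stop("genotype counts must be named 'i/j'")
  p <- strsplit(names(counts), "/", fixed = TRUE)
  if (any(lengths(p) != 2L)) stop("genotype names must be 'i/j'")
  a <- suppressWarnings(as.integer(vapply(p, `[`, "", 1L)))
  b <- suppressWarnings(as.integer(vapply(p, `[`, "", 2L)))
  if (anyNA(a) || anyNA(b)) stop("genotype names must be integer allele codes")
  lo <- pmin(a, b); hi <- pmax(a, b)
  counts <- as.integer(round(counts))
  if (any(counts < 0)) stop("negative genotype counts")
  keep <- counts > 0
  list(a = lo[keep], b = hi[keep], n = counts[keep])
}

# counts of one marker's genotypes from a geno_matrix column pair
.geno_counts <- function(pair) {
  ok <- !(is.na(pair[, 1]) | is.na(pair[, 2]))
  if (!any(ok)) return(stats::setNames(integer(0), character(0)))
  key <- paste0(pair[ok, 1], "/", pair[ok, 2])
  tab <- table(key)
  stats::setNames(as.integer(tab), names(tab))
}

# conditional log-probability of a genotype table given its allele counts:
# log[ n! prod(m_a!) 2^H / ((2n)! prod(n_ab!)) ]
.hwe_logprob <- function(n_total, m, het_total, cell_counts) {
  lfactorial(n_total) + sum(lfactorial(m)) + het_total * log(2) -
    lfactorial(2 * n_total) - sum(lfactorial(cell_counts))
}

#' Exact / Monte Carlo test for Hardy-Weinberg equilibrium
#'
#' Conditional exact test for HWE at one multiallelic marker: given the
#' observed allele counts, every genotype table is weighted by its
#' conditional probability under random union of gametes, and the p-value
#' is the total probability of tables no more probable than the observed
#' one. Tables are fully enumerated (over the heterozygote counts, which
#' determine the homozygote counts) when the enumeration bound is at most
#' `max_tables`; otherwise a Monte Carlo version of the same test is run by
#' repeatedly shuffling the 2n observed alleles into n random diploids, and
#' the Monte Carlo standard error is reported.
#'
#' @param counts Named integer vector of genotype counts, names `"i/j"`
#'   with integer allele codes (order within the pair is irrelevant).
#' @param mc_reps Monte Carlo replicates (default 10000).
#' @param max_tables Enumeration bound (default 1e6 candidate tables).
#' @param seed Optional integer; if given, the Monte Carlo draw is seeded
#'   locally so the result is reproducible without touching the caller's
#'   RNG stream.
#' @return Object of class `hwe_test`: `p.value`, `method`
#'   (`"exact-enumeration"` or `"monte-carlo"`), `mc_se` (`NA` for exact),
#'   `counts`, `n`, `k` (allele count).
#' @examples
#' hwe_test(c("1/1" = 25, "1/2" = 50, "2/2" = 25))$p.value
#' @export
hwe_test <- function(counts, mc_reps = 10000L, max_tables = 1e6,
                     seed = NULL) {
  pc <- .parse_geno_counts(counts)
  if (length(pc$n) == 0L) stop("no genotyped individuals")
  alleles <- sort(unique(c(pc$a, pc$b)))
  k <- length(alleles)
  n <- sum(pc$n)
  out <- function(p, method, se = NA_real_)
    structure(list(p.value = p, method = method, mc_se = se,
                   counts = counts, n = n, k = k),
              class = "hwe_test")
  if (k == 1L) return(out(1, "exact-enumeration"))

  ia <- match(pc$a, alleles); ib <- match(pc$b, alleles)
  m <- numeric(k)                       # allele counts
  for (i in seq_along(pc$n)) {
    m[ia[i]] <- m[ia[i]] + pc$n[i]
    m[ib[i]] <- m[ib[i]] + pc$n[i]
  }
  obs_lp <- .hwe_logprob(n, m, sum(pc$n[ia != ib]), pc$n)
  tol <- log1p(1e-12)

  pairs <- which(upper.tri(matrix(0, k, k)), arr.ind = TRUE)  # i < j
  caps <- pmin(m[pairs[, 1]], m[pairs[, 2]])
  bound <- prod(caps + 1)

  if (bound <= max_tables) {
    grid <- as.matrix(expand.grid(lapply(caps, function(cp) 0:cp)))
    het <- rowSums(grid)
    # per-allele heterozygote involvement
    S <- matrix(0, nrow(grid), k)
    for (p in seq_len(nrow(pairs))) {
      S[, pairs[p, 1]] <- S[, pairs[p, 1]] + grid[, p]
      S[, pairs[p, 2]] <- S[, pairs[p, 2]] + grid[, p]
    }
    rem <- -sweep(S, 2L, m)             # m_i - S_i
    valid <- rowSums(rem < 0 | rem %% 2 != 0) == 0L
    grid <- grid[valid, , drop = FALSE]
    hom <- rem[valid, , drop = FALSE] / 2
    het <- het[valid]
    lp <- lfactorial(n) + sum(lfactorial(m)) + het * log(2) -
      lfactorial(2 * n) -
      rowSums(lfactorial(grid)) - rowSums(lfactorial(hom))
    p <- sum(exp(lp)[lp <= obs_lp + tol])
    return(out(min(p, 1), "exact-enumeration"))
  }

  # Monte Carlo: random re-pairings of the observed 2n alleles
  run_mc <- function() {
    allele_vec <- rep.int(seq_len(k), m)
    K <- k + 1L
    hits <- 0L
    for (r in seq_len(mc_reps)) {
      perm <- allele_vec[sample.int(2L * n)]
      x <- perm[seq_len(n)]
      y <- perm[(n + 1L):(2L * n)]
      gid <- pmin(x, y) * K + pmax(x, y)
      cc <- tabulate(gid, nbins = K * K + K)
      cc <- cc[cc > 0L]
      lp <- lfactorial(n) + sum(lfactorial(m)) + sum(x != y) * log(2) -
        lfactorial(2 * n) - sum(lfactorial(cc))
      if (lp <= obs_lp + tol) hits <- hits + 1L
    }
    hits
  }
  hits <- if (is.null(seed)) run_mc() else {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    run_mc()
  }
  p <- (hits + 1) / (mc_reps + 1)
  out(p, "monte-carlo", sqrt(p * (1 - p) / mc_reps))
}

#' @export
print.hwe_test <- function(x, ...) {
  cat(sprintf("HWE %s test: %d alleles, n = %d, p = %.4g%s\n",
              x$method, x$k, x$n, x$p.value,
              if (is.na(x$mc_se)) "" else sprintf(" (MC SE %.2g)", x$mc_se)))
  invisible(x)
}

#' Fisher's exact test on an r x 2 count table
#'
#' Two-sided exact test of independence for an r x 2 contingency table with
#' fixed margins: under the multivariate hypergeometric null, the p-value is
#' the total probability of all tables whose probability does not exceed
#' that of the observed table (with a 1e-12 relative tolerance for ties).
#' The table space is fully enumerated when its size bound is at most
#' `max_tables`; larger problems use Monte Carlo sampling of tables with
#' the observed margins (via [stats::r2dtable()]) and report the Monte
#' Carlo standard error.
#'
#' @param tab Integer matrix with `r >= 2` rows and 2 columns; both column
#'   sums must be positive.
#' @param max_tables Enumeration bound (default 1e6).
#' @param mc_reps Monte Carlo table draws (default 10000).
#' @param seed Optional integer seed for the Monte Carlo branch (local,
#'   like in [hwe_test()]).
#' @return Object of class `fisher_rx2`: `p.value`, `method`, `mc_se`,
#'   `table`.
#' @examples
#' fisher_exact_rx2(rbind(c(5, 0), c(0, 5)))$p.value  # 2 / choose(10, 5)
#' @export
fisher_exact_rx2 <- function(tab, max_tables = 1e6, mc_reps = 10000L,
                             seed = NULL) {
  tab <- as.matrix(tab)
  if (ncol(tab) != 2L || nrow(tab) < 2L)
    stop("need an r x 2 table with r >= 2")
  if (any(tab < 0) || any(tab != round(tab)))
    stop("counts must be non-negative integers")
  cs <- colSums(tab)
  if (any(cs == 0)) stop("empty column in the count table")
  rs <- rowSums(tab)
  n <- sum(tab)
  c1 <- cs[1]
  r <- nrow(tab)
  obs_lp <- sum(lchoose(rs, tab[, 1])) - lchoose(n, c1)
  tol <- log1p(1e-12)
  out <- function(p, method, se = NA_real_)
    structure(list(p.value = p, method = method, mc_se = se, table = tab),
              class = "fisher_rx2")

  if (prod(pmin(rs, c1) + 1) <= max_tables) {
    S <- 0; LW <- 0
    ok <- TRUE
    for (i in seq_len(r)) {
      xi <- 0:min(rs[i], c1)
      lw <- lchoose(rs[i], xi)
      S2 <- rep(S, times = length(xi)) + rep(xi, each = length(S))
      LW2 <- rep(LW, times = length(xi)) + rep(lw, each = length(LW))
      tailcap <- if (i < r) sum(pmin(rs[(i + 1):r], c1)) else 0
      keep <- S2 <= c1 & c1 - S2 <= tailcap
      S <- S2[keep]; LW <- LW2[keep]
      if (length(S) > max_tables) { ok <- FALSE; break }
    }
    if (ok) {
      lp <- LW[S == c1] - lchoose(n, c1)
      p <- sum(exp(lp)[lp <= obs_lp + tol])
      return(out(min(p, 1), "exact-enumeration"))
    }
  }

  run_mc <- function() {
    hits <- 0L
    done <- 0L
    while (done < mc_reps) {
      b <- min(5000L, mc_reps - done)
      tabs <- stats::r2dtable(b, rs, cs)
      x1 <- vapply(tabs, function(t) t[, 1], numeric(r))
      if (r == 1L) x1 <- matrix(x1, nrow = 1L)
      lp <- colSums(lchoose(rs, x1)) - lchoose(n, c1)
      hits <- hits + sum(lp <= obs_lp + tol)
      done <- done + b
    }
    hits
  }
  hits <- if (is.null(seed)) run_mc() else {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    run_mc()
  }
  p <- (hits + 1) / (mc_reps + 1)
  out(p, "monte-carlo", sqrt(p * (1 - p) / mc_reps))
}

#' @export
print.fisher_rx2 <- function(x, ...) {
  cat(sprintf("Fisher exact test (%s): %d x 2 table, p = %.4g%s\n",
              x$method, nrow(x$table), x$p.value,
              if (is.na(x$mc_se)) "" else sprintf(" (MC SE %.2g)", x$mc_se)))
  invisible(x)
}

#' Yates-corrected chi-square for an r x 2 table
#'
#' The continuity-corrected Pearson statistic
#' `sum(max(|O - E| - 0.5, 0)^2 / E)` with expectations from the margins
#' and `r - 1` degrees of freedom. The per-cell clamp at zero extends the
#' classical 2 x 2 correction to r x 2 tables, where expected cell counts
#' in sparse haplotype tables are often below 5.
#'
#' @inheritParams fisher_exact_rx2
#' @return List with `chi2` and `df`.
#' @export
yates_chi2 <- function(tab) {
  tab <- as.matrix(tab)
  if (ncol(tab) != 2L || nrow(tab) < 2L)
    stop("need an r x 2 table with r >= 2")
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(E == 0))
    stop("zero expected cell; filter empty haplotype rows upstream")
  list(chi2 = sum(pmax(abs(tab - E) - 0.5, 0)^2 / E),
       df = nrow(tab) - 1L)
}

#' Haplotype count table for one marker pair
#'
#' Turns a combined-sample EM fit into the r x 2 (haplotype x group) count
#' table that Fisher's exact test consumes. Haplotypes whose combined-sample
#' EM frequency is below `min_freq` are removed. With
#' `method = "best_phase"` (default), every individual is assigned its most
#' likely phase under the combined fit and integer haplotype counts are
#' tallied per group; with `method = "em_expected"`, a separate EM is fitted
#' per group and its expected haplotype counts (frequency x 2n) are rounded
#' to the nearest integer.
#'
#' @inheritParams em_pair
#' @param model Combined-sample [em_pair()] fit for the marker pair.
#' @param groups Character vector aligned with the rows of `gA`/`gB`, with
#'   values `"high"` / `"low"` (anything else is ignored).
#' @param min_freq Minor-haplotype removal threshold on the combined EM
#'   frequency (default 0.05).
#' @param method Count-table construction, see above.
#' @return Object of class `pair_table`: `table` (r x 2 integer matrix,
#'   rows ordered by descending combined frequency, columns `high`, `low`),
#'   `haplotypes`, `combined_freq`, `dropped` (filtered haplotypes),
#'   `untestable` (`TRUE` when fewer than 2 haplotypes survive the filter).
#' @export
build_pair_table <- function(model, gA, gB, groups, min_freq = 0.05,
                             method = c("best_phase", "em_expected")) {
  method <- match.arg(method)
  f <- coef(model)
  keep <- names(f)[f >= min_freq]
  if (length(keep) < 2L) {
    return(structure(list(table = NULL, haplotypes = keep,
                          combined_freq = f[keep], dropped = setdiff(names(f[f > 0]), keep),
                          untestable = TRUE, method = method),
                     class = "pair_table"))
  }
  ord <- order(-f[keep], keep)
  keep <- keep[ord]
  gsel <- list(high = which(groups == "high"), low = which(groups == "low"))
  tabm <- matrix(0L, length(keep), 2L,
                 dimnames = list(keep, c("high", "low")))
  if (method == "best_phase") {
    ph <- assign_best_phase(model, gA, gB)
    for (g in c("high", "low")) {
      h <- c(ph[gsel[[g]], 1L], ph[gsel[[g]], 2L])
      h <- h[!is.na(h)]
      tb <- table(factor(h, levels = keep))
      tabm[, g] <- as.integer(tb)
    }
  } else {
    for (g in c("high", "low")) {
      idx <- gsel[[g]]
      fit <- em_pair(gA[idx, , drop = FALSE], gB[idx, , drop = FALSE])
      fg <- coef(fit)
      exp_cnt <- fg[keep] * 2 * fit$n_used
      exp_cnt[is.na(exp_cnt)] <- 0
      tabm[, g] <- as.integer(round(exp_cnt))
    }
  }
  structure(list(table = tabm, haplotypes = keep,
                 combined_freq = f[keep],
                 dropped = setdiff(names(f[f > 0]), keep),
                 untestable = FALSE, method = method),
            class = "pair_table")
}

#' @export
print.pair_table <- function(x, ...) {
  if (x$untestable) {
    cat("pair_table: untestable (<2 haplotypes at or above the frequency filter)\n")
  } else {
    cat(sprintf("pair_table (%s counts), %d haplotypes retained, %d dropped:\n",
                x$method, nrow(x$table), length(x$dropped)))
    print(x$table)
  }
  invisible(x)
}

#' Genome scan: haplotype association of consecutive marker pairs
#'
#' For every chromosome in map order, estimates two-locus haplotype
#' frequencies of each consecutive marker pair by EM on the pooled
#' high+low sample, filters minor haplotypes, and tests the haplotype x
#' group count table with Fisher's exact test. Per-marker Hardy-Weinberg
#' exact tests are run within each tail group as a quality screen; markers
#' failing at `hwe_alpha` are flagged (and by default retained with a
#' warning, since a failing marker indicates genotyping artefacts rather
#' than association). Bonferroni thresholds are `alpha / T` genome-wise and
#' `alpha / T_c` chromosome-wise, with `T` the number of testable pairs.
#'
#' @param genotypes A [geno_matrix()].
#' @param map A [genetic_map()] covering all markers to scan.
#' @param groups Named character vector: `"high"` / `"low"` per individual
#'   id; other values are ignored.
#' @param min_freq Minor-haplotype filter (default 0.05).
#' @param hwe_alpha HWE flagging level (default 0.002).
#' @param alpha Family-wise significance level (default 0.05).
#' @param count_method Passed to [build_pair_table()].
#' @param do_hwe Run the per-marker HWE screen (default `TRUE`).
#' @param drop_hwe_failures Exclude flagged markers from pairing (default
#'   `FALSE`).
#' @param hwe_mc_reps,fisher_max_tables,fisher_mc_reps Monte Carlo /
#'   enumeration controls for the underlying tests.
#' @param seed Optional seed fixing all Monte Carlo draws in the scan.
#' @return Object of class `marker_scan`: `pairs` (one row per consecutive
#'   pair: positions, n used, retained haplotype count, `df`, Fisher `p`,
#'   Yates `chi2`, significance flags), `hwe` (per marker and group),
#'   `thresholds` (genome-wise and per-chromosome), `n_tests`, `groups_n`.
#'   The `(chi2, df)` columns of `pairs` feed [genomic_control_lambda()].
#' @seealso [select_tails()], [fisher_exact_rx2()], [genomic_control_lambda()]
#' @export
scan_pairs <- function(genotypes, map, groups, min_freq = 0.05,
                       hwe_alpha = 0.002, alpha = 0.05,
                       count_method = c("best_phase", "em_expected"),
                       do_hwe = TRUE, drop_hwe_failures = FALSE,
                       hwe_mc_reps = 2000L, fisher_max_tables = 1e6,
                       fisher_mc_reps = 10000L, seed = NULL) {
  count_method <- match.arg(count_method)
  if (!is.null(seed)) set.seed(seed)
  sel_ids <- names(groups)[groups %in% c("high", "low")]
  sel_ids <- intersect(genotypes$ids, sel_ids)
  if (length(sel_ids) < 2L) stop("need grouped individuals to scan")
  g <- geno_subset(genotypes, ids = sel_ids)
  grp <- unname(groups[g$ids])
  unknown <- setdiff(g$markers, map$marker)
  if (length(unknown))
    stop("marker(s) missing from the map: ", paste(unknown, collapse = ", "))
  map <- map[map$marker %in% g$markers, , drop = FALSE]
  message(sprintf("scan: %d high + %d low individuals, %d mapped markers",
                  sum(grp == "high"), sum(grp == "low"), nrow(map)))

  # HWE screen per marker within each group
  hwe_df <- NULL
  flagged <- character(0)
  if (do_hwe) {
    rows <- list()
    for (mk in map$marker) {
      pair <- geno_pair(g, mk)
      for (side in c("high", "low")) {
        cnt <- .geno_counts(pair[grp == side, , drop = FALSE])
        if (length(cnt) == 0L) next
        ht <- hwe_test(cnt, mc_reps = hwe_mc_reps)
        rows[[length(rows) + 1L]] <-
          data.frame(marker = mk, group = side, p = ht$p.value,
                     method = ht$method, k = ht$k, n = ht$n,
                     fail = ht$p.value <= hwe_alpha,
                     stringsAsFactors = FALSE)
      }
    }
    hwe_df <- do.call(rbind, rows)
    flagged <- unique(hwe_df$marker[hwe_df$fail])
    if (length(flagged))
      warning(length(flagged), " marker(s) fail HWE at alpha = ", hwe_alpha,
              if (drop_hwe_failures) " and were dropped" else " (retained)")
  }
  scan_markers <- if (drop_hwe_failures) setdiff(map$marker, flagged) else map$marker
  map_s <- map[map$marker %in% scan_markers, , drop = FALSE]

  rows <- list()
  for (chr in unique(map_s$chromosome)) {
    mk <- map_s$marker[map_s$chromosome == chr]
    pos <- map_s$position_cM[map_s$chromosome == chr]
    if (length(mk) < 2L) {
      warning("chromosome ", chr, " has <2 markers; skipped")
      next
    }
    for (i in seq_len(length(mk) - 1L)) {
      gA <- geno_pair(g, mk[i]); gB <- geno_pair(g, mk[i + 1L])
      use <- !(is.na(gA[, 1]) | is.na(gB[, 1]))
      rec <- data.frame(chromosome = chr, marker1 = mk[i],
                        marker2 = mk[i + 1L], pos1_cM = pos[i],
                        pos2_cM = pos[i + 1L], n_used = sum(use),
                        n_haplotypes = NA_integer_, df = NA_integer_,
                        p = NA_real_, chi2 = NA_real_,
                        fisher_method = NA_character_,
                        untestable = TRUE, stringsAsFactors = FALSE)
      if (sum(use) >= 1L) {
        fit <- tryCatch(em_pair(gA, gB), error = function(e) NULL)
        if (!is.null(fit) && length(coef(fit)) >= 2L) {
          pt <- build_pair_table(fit, gA, gB, grp, min_freq = min_freq,
                                 method = count_method)
          if (!pt$untestable && all(colSums(pt$table) > 0)) {
            ft <- fisher_exact_rx2(pt$table, max_tables = fisher_max_tables,
                                   mc_reps = fisher_mc_reps)
            yc <- yates_chi2(pt$table)
            rec$n_haplotypes <- nrow(pt$table)
            rec$df <- yc$df
            rec$p <- ft$p.value
            rec$chi2 <- yc$chi2
            rec$fisher_method <- ft$method
            rec$untestable <- FALSE
          }
        }
      }
      rows[[length(rows) + 1L]] <- rec
    }
  }
  pairs <- do.call(rbind, rows)
  if (is.null(pairs)) stop("no testable chromosome in the map")
  testable <- !pairs$untestable
  n_tests <- sum(testable)
  tc <- tapply(testable, pairs$chromosome, sum)
  genome_thr <- if (n_tests > 0) alpha / n_tests else NA_real_
  chrom_thr <- alpha / pmax(tc, 1)
  pairs$chrom_significant <- !is.na(pairs$p) &
    pairs$p <= chrom_thr[pairs$chromosome]
  pairs$genome_significant <- !is.na(pairs$p) & pairs$p <= genome_thr
  message(sprintf("scan: %d of %d consecutive pairs testable", n_tests,
                  nrow(pairs)))
  structure(list(pairs = pairs, hwe = hwe_df,
                 thresholds = list(genome = genome_thr,
                                   chromosome = chrom_thr,
                                   alpha = alpha),
                 n_tests = n_tests,
                 groups_n = c(high = sum(grp == "high"),
                              low = sum(grp == "low")),
                 min_freq = min_freq, count_method = count_method),
            class = "marker_scan")
}

#' @export
print.marker_scan <- function(x, ...) {
  cat(sprintf("Haplotype-pair association scan: %d testable pairs (%d high / %d low)\n",
              x$n_tests, x$groups_n["high"], x$groups_n["low"]))
  cat(sprintf("  genome-wise threshold %.3g; %d genome-wise, %d chromosome-wise significant\n",
              x$thresholds$genome, sum(x$pairs$genome_significant),
              sum(x$pairs$chrom_significant)))
  top <- x$pairs[order(x$pairs$p), ][1, ]
  if (is.finite(top$p))
    cat(sprintf("  top pair: %s-%s (chr %s, %.1f-%.1f cM), p = %.3g, df = %d\n",
                top$marker1, top$marker2, top$chromosome, top$pos1_cM,
                top$pos2_cM, top$p, top$df))
  invisible(x)
}

#' @export
summary.marker_scan <- function(object, n_top = 10L, ...) {
  p <- object$pairs[!object$pairs$untestable, ]
  p <- p[order(p$p), ]
  list(top_pairs = utils::head(p, n_top),
       thresholds = object$thresholds,
       n_tests = object$n_tests,
       hwe_failures = if (is.null(object$hwe)) NULL else
         object$hwe[object$hwe$fail, , drop = FALSE])
}

#' @param x A `marker_scan`.
#' @param ... Passed to [graphics::plot()].
#' @describeIn scan_pairs Manhattan-style plot of -log10 Fisher p against
#'   cumulative map position, with the Bonferroni thresholds drawn.
#' @export
plot.marker_scan <- function(x, ...) {
  p <- x$pairs[!x$pairs$untestable, ]
  chrs <- unique(x$pairs$chromosome)
  offs <- c(0, cumsum(vapply(chrs, function(ch)
    max(x$pairs$pos2_cM[x$pairs$chromosome == ch]), numeric(1))))
  names(offs) <- c(chrs, "end")
  xx <- offs[p$chromosome] + (p$pos1_cM + p$pos2_cM) / 2
  graphics::plot(xx, -log10(p$p), pch = 16, col = (match(p$chromosome, chrs) %% 2) + 1,
                 xlab = "cumulative map position (cM)",
                 ylab = expression(-log[10](p)), ...)
  graphics::abline(h = -log10(x$thresholds$genome), col = "red", lty = 2)
  graphics::abline(h = -log10(mean(x$thresholds$chromosome)), col = "blue",
                   lty = 3)
  invisible(x)
}

#' Write scan results as tab-separated files
#'
#' Writes `pairs.tsv`, `hwe.tsv` (if the screen was run) and
#' `thresholds.txt` into `dir`.
#'
#' @param scan A `marker_scan` from [scan_pairs()].
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_scan <- function(scan, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.table(scan$pairs, file.path(dir, "pairs.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(scan$hwe))
    utils::write.table(scan$hwe, file.path(dir, "hwe.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  thr <- c(sprintf("alpha\t%g", scan$thresholds$alpha),
           sprintf("genome_wise\t%g", scan$thresholds$genome),
           sprintf("chromosome_wise_%s\t%g", names(scan$thresholds$chromosome),
                   scan$thresholds$chromosome))
  writeLines(thr, file.path(dir, "thresholds.txt"))
  invisible(dir)
}
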