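# Two-locus haplotype frequency estimation by EM.
#
# Each individual contributes an unordered allele pair at each of two
# markers. Phase is observable unless the individual is heterozygous at
# both loci, in which case the genotype is compatible with two complementary
# haplotype resolutions. The E-step splits each double heterozygote between
# its two resolutions in proportion to the products of the current haplotype
# frequencies; the M-step sets frequencies to expected haplotype counts over
# 2n chromosomes. The observed-data log-likelihood is multinomial and EM
# never decreases it (asserted every iteration).

# Collapse individuals into genotype classes. gA/gB: n x 2 allele matrices.
# Returns NULL if no individual has both markers observed.
.em_classes <- function(gA, gB) {
  gA <- as.matrix(gA); gB <- as.matrix(gB)
  use <- !(is.na(gA[, 1]) | is.na(gA[, 2]) | is.na(gB[, 1]) | is.na(gB[, 2]))
  if (!any(use)) return(NULL)
  a1 <- pmin(gA[use, 1], gA[use, 2]); a2 <- pmax(gA[use, 1], gA[use, 2])
  b1 <- pmin(gB[use, 1], gB[use, 2]); b2 <- pmax(gB[use, 1], gB[use, 2])
  alleles_A <- sort(unique(c(a1, a2)))
  alleles_B <- sort(unique(c(b1, b2)))
  ia1 <- match(a1, alleles_A); ia2 <- match(a2, alleles_A)
  ib1 <- match(b1, alleles_B); ib2 <- match(b2, alleles_B)
  key <- paste(ia1, ia2, ib1, ib2)
  first <- !duplicated(key)
  w <- as.vector(table(factor(key, levels = key[first])))
  list(alleles_A = alleles_A, alleles_B = alleles_B,
       kA = length(alleles_A), kB = length(alleles_B),
       ia1 = ia1[first], ia2 = ia2[first],
       ib1 = ib1[first], ib2 = ib2[first],
       w = w, n = sum(w), use = use)
}

#' Two-locus haplotype frequencies from unphased genotypes (EM)
#'
#' Maximum-likelihood estimation of the joint haplotype frequency table of
#' two multiallelic markers from unphased genotype data, by
#' expectation-maximization. Individuals missing either marker are excluded
#' pairwise. Initialization is the linkage-equilibrium product of observed
#' allele frequencies, perturbed by `+1e-6` on the lexicographically first
#' haplotype supported by a double heterozygote (this breaks the symmetric
#' saddle point that is otherwise an EM fixed point when all individuals are
#' doubly heterozygous). Convergence is declared when no frequency moves by
#' more than `tolerance`.
#'
#' @param gA,gB Per-individual unordered allele pairs at the two markers:
#'   n x 2 integer matrices (row order must agree); `NA` marks a missing
#'   allele.
#' @param tolerance Convergence threshold on `max |delta f|` (default 1e-8).
#' @param max_iter Iteration cap (default 1000).
#' @param restarts Number of additional EM runs from deterministic random
#'   (Dirichlet) starting tables, keeping the best final likelihood. The
#'   default (`NULL`) uses 9 restarts when the sample is small (`n <= 50`)
#'   and phase-ambiguous -- where the likelihood can be multimodal -- and
#'   none otherwise. Restarts never touch the caller's RNG stream, and the
#'   linkage-equilibrium start wins likelihood ties, so the documented
#'   tie-break behaviour is unchanged.
#' @return Object of class `em_pair`: `f` (kA x kB frequency matrix with
#'   allele codes as dimnames), `alleles_A`, `alleles_B`, `loglik`, `niter`,
#'   `converged`, `n_used`.
#' @examples
#' gA <- rbind(c(1, 1), c(1, 2))
#' gB <- rbind(c(1, 2), c(1, 1))
#' coef(em_pair(gA, gB))   # phase-unambiguous: equals direct gene counting
#' @export
em_pair <- function(gA, gB, tolerance = 1e-8, max_iter = 1000L,
                    restarts = NULL) {
  cl <- .em_classes(gA, gB)
  if (is.null(cl))
    stop("no individual has both markers genotyped")
  kA <- cl$kA; kB <- cl$kB
  # linear indices into f (column-major, kA rows) of the two resolutions
  li11 <- (cl$ib1 - 1L) * kA + cl$ia1   # (a1,b1)
  li22 <- (cl$ib2 - 1L) * kA + cl$ia2   # (a2,b2)
  li12 <- (cl$ib2 - 1L) * kA + cl$ia1   # (a1,b2)
  li21 <- (cl$ib1 - 1L) * kA + cl$ia2   # (a2,b1)
  dh <- cl$ia1 != cl$ia2 & cl$ib1 != cl$ib2
  hom <- cl$ia1 == cl$ia2 & cl$ib1 == cl$ib2
  m1 <- ifelse(hom, 1, 2)
  run <- list(cl = cl, li11 = li11, li22 = li22, li12 = li12, li21 = li21,
              dh = dh, m1 = m1, kA = kA, kB = kB)

  # primary start: product of observed allele frequencies, perturbed off the
  # symmetric saddle of the all-double-heterozygote case
  pA <- as.vector(rowsum(c(cl$w, cl$w), c(cl$ia1, cl$ia2))) / (2 * cl$n)
  pB <- as.vector(rowsum(c(cl$w, cl$w), c(cl$ib1, cl$ib2))) / (2 * cl$n)
  f0 <- as.vector(outer(pA, pB))
  if (any(dh)) {
    sup <- unique(c(li11[dh], li22[dh], li12[dh], li21[dh]))
    # lexicographic order of (allele A, allele B) = row-major order
    ai <- (sup - 1L) %% kA + 1L
    bi <- (sup - 1L) %/% kA + 1L
    f0[sup[order(ai, bi)][1]] <- f0[sup[order(ai, bi)][1]] + 1e-6
    f0 <- f0 / sum(f0)
  }

  # small samples with phase ambiguity have genuinely multimodal two-locus
  # likelihoods, so a few deterministic Dirichlet restarts are added there;
  # at study sample sizes the linkage-equilibrium start is reliable and the
  # restarts would only slow the scan down
  if (is.null(restarts))
    restarts <- if (any(dh) && cl$n <= 50L) 9L else 0L
  starts <- list(f0)
  if (restarts > 0L) {
    seed_state <- if (exists(".Random.seed", globalenv()))
      get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(seed_state))
      assign(".Random.seed", seed_state, globalenv())
      else if (exists(".Random.seed", globalenv()))
        rm(".Random.seed", envir = globalenv()))
    set.seed(971201L)
    for (i in seq_len(restarts)) {
      g <- stats::rgamma(kA * kB, shape = 0.5)
      starts[[i + 1L]] <- g / sum(g)
    }
  }

  best <- NULL
  for (si in seq_along(starts)) {
    res <- .em_run(run, starts[[si]], tolerance, max_iter)
    if (is.null(best) || res$loglik > best$loglik + 1e-10) best <- res
  }

  fmat <- matrix(best$f, kA, kB,
                 dimnames = list(as.character(cl$alleles_A),
                                 as.character(cl$alleles_B)))
  structure(list(f = fmat, alleles_A = cl$alleles_A,
                 alleles_B = cl$alleles_B,
                 loglik = best$loglik, niter = best$niter,
                 converged = best$converged, n_used = cl$n,
                 restarts = restarts),
            class = "em_pair")
}

# one EM run from a given start; asserts the monotone log-likelihood ascent
.em_run <- function(run, f, tolerance, max_iter) {
  cl <- run$cl
  w <- cl$w
  loglik <- -Inf
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    p1 <- run$m1 * f[run$li11] * f[run$li22]
    p2 <- ifelse(run$dh, 2 * f[run$li12] * f[run$li21], 0)
    lik <- p1 + p2
    if (any(lik <= 0)) {
      # a class lost all its mass under a degenerate start; split evenly
      z <- lik <= 0
      p1[z] <- 0.5; p2[z] <- ifelse(run$dh[z], 0.5, 0); lik[z] <- 1
      ll <- loglik
    } else ll <- sum(w * log(lik))
    if (is.finite(loglik) && ll < loglik - 1e-8)
      stop("internal error: EM log-likelihood decreased")
    w1 <- w * p1 / lik
    w2 <- w * p2 / lik
    idx <- c(run$li11, run$li22, run$li12, run$li21)
    wts <- c(w1, w1, w2, w2)
    cnt <- numeric(run$kA * run$kB)
    rs <- rowsum(wts, idx)
    cnt[as.integer(rownames(rs))] <- rs
    f_new <- cnt / (2 * cl$n)
    delta <- max(abs(f_new - f))
    f <- f_new
    loglik <- ll
    if (delta < tolerance) { converged <- TRUE; break }
  }
  if (any(!is.finite(f)))
    stop("internal error: non-finite haplotype frequencies")
  list(f = f, loglik = loglik, niter = it, converged = converged)
}

#' @export
print.em_pair <- function(x, digits = 4, ...) {
  cat(sprintf("Two-locus EM fit: %d x %d haplotypes, n = %d, logLik = %.4f (%d iterations%s)\n",
              nrow(x$f), ncol(x$f), x$n_used, x$loglik, x$niter,
              if (x$converged) "" else ", NOT converged"))
  print(round(x$f, digits))
  invisible(x)
}

#' @export
coef.em_pair <- function(object, ...) {
  f <- object$f
  stats::setNames(as.vector(f),
                  as.vector(outer(rownames(f), colnames(f), paste, sep = ":")))
}

#' @export
logLik.em_pair <- function(object, ...) {
  structure(object$loglik, df = length(object$f) - 1L, class = "logLik")
}

#' Assign each individual its most likely phase
#'
#' For a fitted [em_pair()] model, resolves every individual's two-locus
#' genotype into an ordered pair of haplotypes. Phase-unambiguous
#' individuals get their unique resolution; double heterozygotes get the
#' resolution with the larger product of estimated haplotype frequencies,
#' with an exact tie broken toward the lexicographically smaller haplotype
#' pair (ties are flagged). Individuals missing either marker get `NA`.
#'
#' @inheritParams em_pair
#' @param model A fitted `em_pair` (on a superset of these individuals).
#' @return n x 2 character matrix of haplotype labels `"a:b"` (columns
#'   `hap1`, `hap2`, sorted within individual), with a logical attribute
#'   `tie` marking tie-broken rows.
#' @export
assign_best_phase <- function(model, gA, gB) {
  gA <- as.matrix(gA); gB <- as.matrix(gB)
  n <- nrow(gA)
  out <- matrix(NA_character_, n, 2L,
                dimnames = list(rownames(gA), c("hap1", "hap2")))
  tie <- logical(n)
  use <- !(is.na(gA[, 1]) | is.na(gA[, 2]) | is.na(gB[, 1]) | is.na(gB[, 2]))
  if (!any(use)) return(structure(out, tie = tie))
  a1 <- pmin(gA[, 1], gA[, 2]); a2 <- pmax(gA[, 1], gA[, 2])
  b1 <- pmin(gB[, 1], gB[, 2]); b2 <- pmax(gB[, 1], gB[, 2])
  fget <- function(a, b) {
    i <- match(as.character(a), rownames(model$f))
    j <- match(as.character(b), colnames(model$f))
    v <- model$f[cbind(i, j)]
    v[is.na(v)] <- 0
    v
  }
  # a resolution is two (alleleA, alleleB) haplotypes, ordered numerically
  res_sorted <- function(ha, hb) {
    o <- order(ha, hb)
    rbind(c(ha[o[1]], hb[o[1]]), c(ha[o[2]], hb[o[2]]))
  }
  res_label <- function(r) paste0(r[, 1], ":", r[, 2])
  res_key <- function(r) sprintf("%09d%09d%09d%09d", r[1, 1], r[1, 2],
                                 r[2, 1], r[2, 2])
  for (i in which(use)) {
    if (a1[i] != a2[i] && b1[i] != b2[i]) {
      pr1 <- fget(a1[i], b1[i]) * fget(a2[i], b2[i])
      pr2 <- fget(a1[i], b2[i]) * fget(a2[i], b1[i])
      r1 <- res_sorted(c(a1[i], a2[i]), c(b1[i], b2[i]))
      r2 <- res_sorted(c(a1[i], a2[i]), c(b2[i], b1[i]))
      if (pr1 > pr2) out[i, ] <- res_label(r1)
      else if (pr2 > pr1) out[i, ] <- res_label(r2)
      else {
        out[i, ] <- res_label(if (res_key(r1) <= res_key(r2)) r1 else r2)
        tie[i] <- TRUE
      }
    } else {
      out[i, ] <- res_label(res_sorted(c(a1[i], a2[i]), c(b1[i], b2[i])))
    }
  }
  structure(out, tie = tie)
}
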