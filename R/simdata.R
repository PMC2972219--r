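#' Simulation configuration for a synthetic mapping study
#'
#' Builds and validates the configuration object consumed by
#' [simulate_population()]. The defaults emulate the data structure of a
#' half-sib cattle cohort genotyped on a genome-wide microsatellite panel:
#' a small closed nucleus population (effective size `ne`) drifts for
#' `n_generations` Wright-Fisher generations, generating linkage
#' disequilibrium on a genetic map of 29 autosomes plus X (~1154 markers),
#' and a study cohort of `n_individuals` half-sib offspring is then bred
#' from the final generation. A single biallelic causal locus with an
#' additive phenotype effect is carried along like a marker.
#'
#' @param ne Diploid effective population size of the drifting nucleus
#'   (default 30).
#' @param n_generations Number of Wright-Fisher generations of drift
#'   (default 50: enough for linkage disequilibrium to approach the
#'   drift-recombination quasi-equilibrium across a 15-cM window while
#'   retaining most founder marker diversity).
#' @param chromosomes Data frame with columns `name`, `length_cM`,
#'   `n_markers`; default is 29 autosomes of 100 cM with 39 markers each
#'   plus an X of 100 cM with 23 markers (1154 markers total). Markers are
#'   evenly spaced. The X is simulated autosomally.
#' @param n_individuals Size of the study cohort bred from the final
#'   generation (default 639).
#' @param alleles_per_marker Integer range (length-2 vector) of founder
#'   allele counts per marker; the count is drawn uniformly (default 3..8).
#' @param founder_allele_dirichlet Concentration of the symmetric Dirichlet
#'   from which founder allele frequencies are drawn (default 1).
#' @param causal List with elements `chromosome`, `position_cM`, `maf`
#'   (founder minor allele frequency, in (0, 0.5)), `effect` (additive
#'   phenotype change per minor-allele copy), `phenotype_mean`,
#'   `phenotype_sd` (residual noise SD). Defaults: chromosome "7" at 50 cM,
#'   maf 0.3, effect -3, mean 16, sd 7.
#' @param causal_min_maf Minimum minor allele frequency of the causal locus
#'   in the realized cohort; the simulation is redrawn until it is met
#'   (default 0.1 when `effect != 0`, ignored when `effect == 0`). This
#'   conditions on a segregating causal variant, as any mapped variant must
#'   be.
#' @param n_sires Number of final-generation males used as cohort sires
#'   (default 25; must be `<= ne`).
#' @param missing_rate Probability that a genotype call is missing
#'   (default 0).
#' @param seed Integer seed; the whole simulation is reproducible given it.
#'
#' @return An object of class `sim_config` (a validated list).
#' @seealso [simulate_population()], [select_tails()]
#' @export
sim_config <- function(ne = 30L,
                       n_generations = 50L,
                       chromosomes = default_chromosomes(),
                       n_individuals = 639L,
                       alleles_per_marker = c(3L, 8L),
                       founder_allele_dirichlet = 1,
                       causal = list(chromosome = "7", position_cM = 50,
                                     maf = 0.3, effect = -3,
                                     phenotype_mean = 16, phenotype_sd = 7),
                       causal_min_maf = 0.1,
                       n_sires = 25L,
                       missing_rate = 0,
                       seed = 1L) {
  stopifnot(is.numeric(ne), length(ne) == 1L, ne >= 2)
  stopifnot(is.numeric(n_generations), n_generations >= 0)
  chromosomes <- as.data.frame(chromosomes, stringsAsFactors = FALSE)
  if (!all(c("name", "length_cM", "n_markers") %in% names(chromosomes)))
    stop("'chromosomes' needs columns name, length_cM, n_markers")
  chromosomes$name <- as.character(chromosomes$name)
  if (anyDuplicated(chromosomes$name))
    stop("duplicated chromosome names")
  if (any(chromosomes$length_cM <= 0))
    stop("chromosome lengths must be positive")
  if (any(chromosomes$n_markers < 2))
    stop("each chromosome needs at least 2 markers")
  stopifnot(length(alleles_per_marker) == 2L,
            alleles_per_marker[1] >= 2L,
            alleles_per_marker[2] >= alleles_per_marker[1])
  stopifnot(founder_allele_dirichlet > 0)
  needed <- c("chromosome", "position_cM", "maf", "effect",
              "phenotype_mean", "phenotype_sd")
  if (!all(needed %in% names(causal)))
    stop("'causal' needs elements: ", paste(needed, collapse = ", "))
  if (!(causal$maf > 0 && causal$maf < 0.5))
    stop("causal minor allele frequency must lie in (0, 0.5)")
  if (causal$phenotype_sd <= 0)
    stop("phenotype_sd must be positive")
  ci <- match(as.character(causal$chromosome), chromosomes$name)
  if (is.na(ci))
    stop("causal chromosome '", causal$chromosome, "' is not in the map")
  if (causal$position_cM < 0 || causal$position_cM > chromosomes$length_cM[ci])
    stop("causal position ", causal$position_cM, " cM lies outside chromosome ",
         causal$chromosome, " (length ", chromosomes$length_cM[ci], " cM)")
  stopifnot(n_sires >= 1, n_sires <= ne)
  stopifnot(missing_rate >= 0, missing_rate < 1)
  stopifnot(n_individuals >= 1)
  cfg <- list(ne = as.integer(ne),
              n_generations = as.integer(n_generations),
              chromosomes = chromosomes,
              n_individuals = as.integer(n_individuals),
              alleles_per_marker = as.integer(alleles_per_marker),
              founder_allele_dirichlet = founder_allele_dirichlet,
              causal = causal,
              causal_min_maf = causal_min_maf,
              n_sires = as.integer(n_sires),
              missing_rate = missing_rate,
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  cfg
}

#' Default chromosome layout: 29 autosomes plus X, 1154 markers
#' @return Data frame with columns `name`, `length_cM`, `n_markers`.
#' @export
default_chromosomes <- function() {
  data.frame(name = c(as.character(1:29), "X"),
             length_cM = 100,
             n_markers = c(rep(39L, 29), 23L),
             stringsAsFactors = FALSE)
}

# Founder allele counts by largest-remainder rounding of target frequencies
# to n slots, so realized founder frequencies equal the drawn frequencies up
# to integer resolution.
.round_counts <- function(freq, n) {
  raw <- freq * n
  cnt <- floor(raw)
  short <- n - sum(cnt)
  if (short > 0) {
    idx <- order(raw - cnt, decreasing = TRUE)[seq_len(short)]
    cnt[idx] <- cnt[idx] + 1L
  }
  as.integer(cnt)
}

# One gamete per entry of parent_idx from haplotype pool H (2N x L).
# rvec: recombination fraction between adjacent loci (length L-1), 0.5 at
# chromosome boundaries. Fully vectorized over gametes.
.make_gametes <- function(H, parent_idx, rvec) {
  L <- ncol(H)
  ng <- length(parent_idx)
  h1 <- 2L * parent_idx - 1L
  h2 <- 2L * parent_idx
  if (L == 1L) {
    strandT <- matrix(stats::runif(ng) < 0.5, nrow = 1L)
  } else {
    sw <- matrix(stats::runif(ng * (L - 1L)) < rep(rvec, each = ng),
                 nrow = ng)                       # ng x (L-1) crossover flags
    cum <- apply(sw, 1L, cumsum)                  # (L-1) x ng
    if (L == 2L) cum <- matrix(cum, nrow = 1L)
    start <- as.integer(stats::runif(ng) < 0.5)
    strandT <- (rbind(0L, cum) + rep(start, each = L)) %% 2L   # L x ng
  }
  rowidxT <- matrix(h1, L, ng, byrow = TRUE) * (strandT == 0L) +
    matrix(h2, L, ng, byrow = TRUE) * (strandT == 1L)
  g <- H[cbind(as.vector(rowidxT), rep.int(seq_len(L), ng))]
  matrix(g, nrow = ng, ncol = L, byrow = TRUE)
}

.haldane_r <- function(d_cM) 0.5 * (1 - exp(-2 * d_cM / 100))

# Core of the simulator (one attempt; conditioning handled by the caller).
.simulate_once <- function(cfg) {
  chrs <- cfg$chromosomes
  ci <- match(as.character(cfg$causal$chromosome), chrs$name)

  # locus table: evenly spaced markers plus the causal locus at its position
  loci <- do.call(rbind, lapply(seq_len(nrow(chrs)), function(i) {
    pos <- seq(0, chrs$length_cM[i], length.out = chrs$n_markers[i])
    data.frame(chromosome = chrs$name[i],
               marker = sprintf("c%sm%02d", chrs$name[i],
                                seq_len(chrs$n_markers[i])),
               position_cM = pos, causal = FALSE,
               stringsAsFactors = FALSE)
  }))
  loci <- rbind(loci,
                data.frame(chromosome = chrs$name[ci], marker = ".causal",
                           position_cM = cfg$causal$position_cM, causal = TRUE,
                           stringsAsFactors = FALSE))
  loci <- loci[order(match(loci$chromosome, chrs$name), loci$position_cM,
                     loci$causal), , drop = FALSE]
  rownames(loci) <- NULL
  L <- nrow(loci)

  # recombination fractions between adjacent loci; free across chromosomes
  if (L > 1L) {
    d <- diff(loci$position_cM)
    rvec <- .haldane_r(pmax(d, 0))
    rvec[loci$chromosome[-1L] != loci$chromosome[-L]] <- 0.5
  } else rvec <- numeric(0)

  # founders: per-locus allele frequencies from a symmetric Dirichlet,
  # realized exactly (largest-remainder) in the 2*ne founder haplotypes
  nh <- 2L * cfg$ne
  H <- matrix(0L, nh, L)
  kr <- cfg$alleles_per_marker
  for (l in seq_len(L)) {
    if (loci$causal[l]) {
      n_minor <- max(1L, .round_counts(c(1 - cfg$causal$maf, cfg$causal$maf),
                                       nh)[2])
      al <- c(rep(1L, nh - n_minor), rep(2L, n_minor))
    } else {
      k <- if (kr[1] == kr[2]) kr[1] else sample(kr[1]:kr[2], 1L)
      g <- stats::rgamma(k, shape = cfg$founder_allele_dirichlet)
      cnt <- .round_counts(g / sum(g), nh)
      al <- rep.int(seq_len(k), cnt)
    }
    H[, l] <- al[sample.int(nh)]
  }
  founder_freq <- lapply(seq_len(L), function(l) table(H[, l]) / nh)
  names(founder_freq) <- loci$marker

  # Wright-Fisher drift at size ne with Haldane recombination
  for (g in seq_len(cfg$n_generations)) {
    mothers <- sample.int(cfg$ne, cfg$ne, replace = TRUE)
    fathers <- sample.int(cfg$ne, cfg$ne, replace = TRUE)
    gm <- .make_gametes(H, mothers, rvec)
    gp <- .make_gametes(H, fathers, rvec)
    H[seq(1L, nh, by = 2L), ] <- gm
    H[seq(2L, nh, by = 2L), ] <- gp
  }

  # study cohort: half-sib families from n_sires final-generation males
  n <- cfg$n_individuals
  sire_pool <- sample.int(cfg$ne, cfg$n_sires)
  sire_of <- sample.int(cfg$n_sires, n, replace = TRUE)
  fathers <- sire_pool[sire_of]
  mothers <- sample.int(cfg$ne, n, replace = TRUE)
  hap_pat <- .make_gametes(H, fathers, rvec)
  hap_mat <- .make_gametes(H, mothers, rvec)

  cc <- which(loci$causal)
  causal_count <- as.integer((hap_pat[, cc] == 2L) + (hap_mat[, cc] == 2L))

  ids <- sprintf("ind%04d", seq_len(n))
  phen <- cfg$causal$phenotype_mean + cfg$causal$effect * causal_count +
    stats::rnorm(n, 0, cfg$causal$phenotype_sd)
  names(phen) <- ids
  sires <- sprintf("sire%02d", sire_of)
  names(sires) <- ids

  keep <- !loci$causal
  markers <- loci$marker[keep]
  p1 <- hap_pat[, keep, drop = FALSE]
  p2 <- hap_mat[, keep, drop = FALSE]
  dimnames(p1) <- dimnames(p2) <- list(ids, markers)

  a1 <- pmin(p1, p2)
  a2 <- pmax(p1, p2)
  if (cfg$missing_rate > 0) {
    miss <- stats::runif(length(a1)) < cfg$missing_rate
    a1[miss] <- NA_integer_
    a2[miss] <- NA_integer_
  }
  geno <- geno_matrix(a1, a2)
  map <- genetic_map(loci[keep, c("marker", "chromosome", "position_cM")])

  truth <- list(causal_chromosome = loci$chromosome[cc],
                causal_position_cM = loci$position_cM[cc],
                causal_count = stats::setNames(causal_count, ids),
                phase_paternal = p1,
                phase_maternal = p2,
                founder_freq = founder_freq[keep])
  structure(list(map = map, genotypes = geno, phenotypes = phen,
                 sires = sires, truth = truth, config = cfg),
            class = "sim_study")
}

#' Simulate a synthetic half-sib mapping study
#'
#' Forward Wright-Fisher simulation on a genetic map. Founder haplotypes are
#' drawn in linkage equilibrium with per-marker allele frequencies from a
#' symmetric Dirichlet; `n_generations` of random-mating reproduction at
#' diploid size `ne` generate drift LD, with recombination between adjacent
#' loci at the Haldane fraction r = (1 - exp(-2d))/2 of their map distance d
#' (Morgans) and free recombination across chromosomes. A biallelic causal
#' locus travels with the markers; the study cohort is bred from the final
#' generation with `n_sires` paternal half-sib families, and phenotypes are
#' `mean + effect * (minor-allele copies) + N(0, sd)` noise.
#'
#' When the causal effect is nonzero the simulation is redrawn (advancing
#' the RNG deterministically) until the cohort minor allele frequency at the
#' causal locus is at least `causal_min_maf`, so the simulated study always
#' contains a segregating variant to map.
#'
#' @param config A [sim_config()] object.
#' @return An object of class `sim_study`: a list with elements `map`
#'   (a [genetic_map()]), `genotypes` (a [geno_matrix()], causal locus
#'   excluded), `phenotypes` (named numeric), `sires` (named character),
#'   `truth` (causal position, per-individual causal minor-allele counts and
#'   the two phased marker haplotypes) and `config`.
#' @examples
#' cfg <- sim_config(chromosomes = data.frame(name = "1", length_cM = 50,
#'                                            n_markers = 5),
#'                   causal = list(chromosome = "1", position_cM = 25,
#'                                 maf = 0.3, effect = -3,
#'                                 phenotype_mean = 16, phenotype_sd = 7),
#'                   n_individuals = 60, n_generations = 10, seed = 42)
#' st <- simulate_population(cfg)
#' st
#' @export
simulate_population <- function(config) {
  if (!inherits(config, "sim_config"))
    stop("'config' must be a sim_config object")
  set.seed(config$seed)
  condition <- config$causal$effect != 0 && config$causal_min_maf > 0
  for (attempt in seq_len(if (condition) 100L else 1L)) {
    st <- .simulate_once(config)
    if (!condition) return(st)
    p <- mean(st$truth$causal_count) / 2
    if (min(p, 1 - p) >= config$causal_min_maf) {
      st$attempts <- attempt
      return(st)
    }
  }
  stop("causal locus failed to segregate at MAF >= ", config$causal_min_maf,
       " in 100 attempts; reduce n_generations or causal_min_maf")
}

#' @export
print.sim_study <- function(x, ...) {
  cat("Simulated mapping study\n")
  cat(sprintf("  %d individuals, %d markers on %d chromosomes\n",
              length(x$phenotypes), length(x$genotypes$markers),
              length(unique(x$map$chromosome))))
  cat(sprintf("  causal locus: chr %s @ %.1f cM, cohort MAF %.3f, effect %+.2f\n",
              x$truth$causal_chromosome, x$truth$causal_position_cM,
              min(p <- mean(x$truth$causal_count) / 2, 1 - p),
              x$config$causal$effect))
  cat(sprintf("  phenotype: median %.1f, range %.1f-%.1f\n",
              stats::median(x$phenotypes), min(x$phenotypes),
              max(x$phenotypes)))
  invisible(x)
}

#' Select phenotypic tails under a per-sire cap
#'
#' Picks the `n_high` largest and `n_low` smallest phenotype individuals,
#' allowing at most `max_per_sire` members of the same paternal half-sib
#' family per group (the selective-genotyping design: genotype only the
#' extremes, capped per sire to limit family confounding). Ties are broken
#' deterministically by individual identifier; the two groups are disjoint.
#'
#' @param phenotypes Named numeric vector (names are individual ids).
#' @param sires Named character vector of sire labels for the same ids.
#' @param n_high,n_low Group sizes (defaults 42 and 42).
#' @param max_per_sire Cap per sire within each group (default 4).
#' @return Object of class `tail_selection`: list with `groups` (named
#'   character vector: "high", "low" or "unselected"), realized
#'   `high_threshold` and `low_threshold`, and the skipped-by-cap counts.
#' @export
select_tails <- function(phenotypes, sires, n_high = 42L, n_low = 42L,
                         max_per_sire = 4L) {
  ids <- names(phenotypes)
  if (is.null(ids) || anyDuplicated(ids))
    stop("phenotypes must be named with unique individual ids")
  if (!all(ids %in% names(sires)))
    stop("every phenotyped individual needs a sire label")
  sires <- sires[ids]
  if (n_high + n_low > length(phenotypes))
    stop("n_high + n_low exceeds the population size")

  pick <- function(ord, n, excluded) {
    chosen <- character(0)
    tally <- integer(0)
    skipped <- 0L
    for (id in ord) {
      if (id %in% excluded) next
      s <- sires[[id]]
      k <- if (s %in% names(tally)) tally[[s]] else 0L
      if (k >= max_per_sire) { skipped <- skipped + 1L; next }
      tally[s] <- k + 1L
      chosen <- c(chosen, id)
      if (length(chosen) == n) break
    }
    if (length(chosen) < n)
      stop("per-sire cap of ", max_per_sire,
           " makes a group of ", n, " unreachable")
    list(ids = chosen, skipped = skipped)
  }

  ord_high <- ids[order(-phenotypes, ids)]
  ord_low <- ids[order(phenotypes, ids)]
  hi <- pick(ord_high, n_high, character(0))
  lo <- pick(ord_low, n_low, hi$ids)

  groups <- stats::setNames(rep("unselected", length(ids)), ids)
  groups[hi$ids] <- "high"
  groups[lo$ids] <- "low"
  high_thr <- min(phenotypes[hi$ids])
  low_thr <- max(phenotypes[lo$ids])
  if (high_thr <= low_thr)
    warning("tail thresholds overlap (ties at the boundary); ",
            "groups were filled by identifier tie-break")
  structure(list(groups = groups, high_threshold = high_thr,
                 low_threshold = low_thr,
                 skipped_by_cap = c(high = hi$skipped, low = lo$skipped)),
            class = "tail_selection")
}

#' @export
print.tail_selection <- function(x, ...) {
  n <- table(factor(x$groups, c("high", "low", "unselected")))
  cat(sprintf("Tail selection: %d high (>= %.2f), %d low (<= %.2f), %d unselected\n",
              n[["high"]], x$high_threshold, n[["low"]], x$low_threshold,
              n[["unselected"]]))
  invisible(x)
}
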