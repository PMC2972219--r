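#' Genetic map container
#'
#' A validated data frame of marker positions: columns `marker`,
#' `chromosome`, `position_cM`. Marker names must be unique genome-wide and
#' positions non-decreasing within each chromosome (in row order, which
#' defines the "consecutive pairs" a scan tests).
#'
#' @param x Data frame with columns `marker`, `chromosome`, `position_cM`.
#' @return The same data frame with class `c("genetic_map", "data.frame")`.
#' @export
genetic_map <- function(x) {
  x <- as.data.frame(x, stringsAsFactors = FALSE)
  need <- c("marker", "chromosome", "position_cM")
  if (!all(need %in% names(x)))
    stop("genetic map needs columns: ", paste(need, collapse = ", "))
  x <- x[, need]
  x$marker <- as.character(x$marker)
  x$chromosome <- as.character(x$chromosome)
  x$position_cM <- as.numeric(x$position_cM)
  if (anyDuplicated(x$marker))
    stop("duplicated marker name(s): ",
         paste(unique(x$marker[duplicated(x$marker)]), collapse = ", "))
  if (any(!is.finite(x$position_cM)) || any(x$position_cM < 0))
    stop("map positions must be finite and non-negative")
  for (chr in unique(x$chromosome)) {
    p <- x$position_cM[x$chromosome == chr]
    bad <- which(diff(p) < 0)
    if (length(bad))
      stop("map positions decrease on chromosome ", chr, " at marker ",
           x$marker[x$chromosome == chr][bad[1] + 1L])
  }
  rownames(x) <- NULL
  class(x) <- c("genetic_map", "data.frame")
  x
}

#' Unphased multiallelic genotype matrix
#'
#' Stores one unordered allele pair per individual and marker as two integer
#' matrices in canonical order (`a1 <= a2`); a missing genotype is `NA` in
#' both. Allele codes are positive integers (for microsatellites, typically
#' repeat-length bins).
#'
#' @param a1,a2 Integer matrices (individuals x markers) with identical
#'   dimnames: rownames are individual ids, colnames marker names.
#' @return Object of class `geno_matrix`: list with `ids`, `markers`, `a1`,
#'   `a2`.
#' @export
geno_matrix <- function(a1, a2) {
  a1 <- as.matrix(a1); a2 <- as.matrix(a2)
  if (!identical(dim(a1), dim(a2)))
    stop("a1 and a2 must have identical dimensions")
  ids <- rownames(a1); markers <- colnames(a1)
  if (is.null(ids) || is.null(markers))
    stop("genotype matrices need rownames (ids) and colnames (markers)")
  if (anyDuplicated(ids)) stop("duplicated individual ids")
  if (anyDuplicated(markers)) stop("duplicated marker names")
  if (!identical(dimnames(a1), dimnames(a2)))
    stop("a1 and a2 dimnames differ")
  miss <- is.na(a1) | is.na(a2)
  if (any(miss != (is.na(a1) & is.na(a2)))) {
    # half-missing collapses to fully missing
    a1[miss] <- NA_integer_
    a2[miss] <- NA_integer_
  }
  lo <- pmin(a1, a2); hi <- pmax(a1, a2)
  storage.mode(lo) <- "integer"; storage.mode(hi) <- "integer"
  if (any(lo[!is.na(lo)] < 1L)) stop("allele codes must be positive integers")
  structure(list(ids = ids, markers = markers, a1 = lo, a2 = hi),
            class = "geno_matrix")
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat(sprintf("geno_matrix: %d individuals x %d markers (%.1f%% missing)\n",
              length(x$ids), length(x$markers),
              100 * mean(is.na(x$a1))))
  invisible(x)
}

# pull one marker's allele-pair matrix (n x 2)
geno_pair <- function(g, marker) {
  j <- match(marker, g$markers)
  if (is.na(j)) stop("unknown marker: ", marker)
  cbind(g$a1[, j], g$a2[, j])
}

# subset individuals (by id) and/or markers
geno_subset <- function(g, ids = NULL, markers = NULL) {
  i <- if (is.null(ids)) seq_along(g$ids) else match(ids, g$ids)
  j <- if (is.null(markers)) seq_along(g$markers) else match(markers, g$markers)
  if (anyNA(i)) stop("unknown individual id(s)")
  if (anyNA(j)) stop("unknown marker(s)")
  geno_matrix(g$a1[i, j, drop = FALSE], g$a2[i, j, drop = FALSE])
}

## ---------------------------------------------------------------- TSV IO

#' Read and write the tab-separated study formats
#'
#' All files are tab-separated with one header line. The map file has
#' columns `marker`, `chromosome`, `position_cM`. The genotype file has an
#' `id` column followed by one column per marker holding `a1/a2` (integer
#' allele codes) or `.` for missing; allele order is canonicalized on read.
#' Phenotype, sire and group files are two-column (`id` plus `value`,
#' `sire` or `group`). Readers are strict: malformed cells, duplicate ids
#' and markers absent from the map are errors, and writing then reading a
#' table returns it in canonical form unchanged.
#'
#' @param path File path.
#' @param map A [genetic_map()] used to validate genotype columns.
#' @return `read_map` a `genetic_map`; `read_genotypes` a `geno_matrix`;
#'   `read_phenotypes` a named numeric vector; `read_sires` / `read_groups`
#'   named character vectors.
#' @name study_io
NULL

#' @rdname study_io
#' @export
read_map <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE)
  genetic_map(x)
}

#' @rdname study_io
#' @param map_obj Genetic map to write.
#' @export
write_map <- function(map_obj, path) {
  utils::write.table(as.data.frame(map_obj), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname study_io
#' @export
read_genotypes <- function(path, map) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE,
                         colClasses = "character", check.names = FALSE)
  if (names(x)[1] != "id") stop("first genotype column must be 'id'")
  ids <- x$id
  if (anyDuplicated(ids)) stop("duplicated individual ids in ", path)
  markers <- names(x)[-1]
  unknown <- setdiff(markers, map$marker)
  if (length(unknown))
    stop("genotype column(s) not in the map: ",
         paste(unknown, collapse = ", "))
  n <- length(ids); m <- length(markers)
  a1 <- matrix(NA_integer_, n, m, dimnames = list(ids, markers))
  a2 <- a1
  for (j in seq_len(m)) {
    cell <- x[[j + 1L]]
    ok_missing <- cell == "."
    parts <- strsplit(cell, "/", fixed = TRUE)
    bad <- !ok_missing & lengths(parts) != 2L
    if (any(bad))
      stop("malformed genotype '", cell[which(bad)[1]], "' for marker ",
           markers[j])
    p1 <- suppressWarnings(as.integer(vapply(parts, `[`, "", 1L)))
    p2 <- suppressWarnings(as.integer(
      vapply(parts, function(p) if (length(p) >= 2L) p[2L] else NA_character_,
             "")))
    bad <- !ok_missing & (is.na(p1) | is.na(p2) | p1 < 1L | p2 < 1L)
    if (any(bad))
      stop("malformed genotype '", cell[which(bad)[1]], "' for marker ",
           markers[j])
    a1[!ok_missing, j] <- p1[!ok_missing]
    a2[!ok_missing, j] <- p2[!ok_missing]
  }
  geno_matrix(a1, a2)
}

#' @rdname study_io
#' @param genotypes A [geno_matrix()] to write.
#' @export
write_genotypes <- function(genotypes, path) {
  g <- genotypes
  cell <- matrix(".", length(g$ids), length(g$markers))
  ok <- !is.na(g$a1)
  cell[ok] <- paste0(g$a1[ok], "/", g$a2[ok])
  out <- data.frame(id = g$ids, cell, stringsAsFactors = FALSE,
                    check.names = FALSE)
  names(out) <- c("id", g$markers)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.read_two_col <- function(path, value_col, as_num = FALSE) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("id", value_col) %in% names(x)))
    stop(path, " needs columns 'id' and '", value_col, "'")
  if (anyDuplicated(x$id)) stop("duplicated ids in ", path)
  v <- x[[value_col]]
  if (as_num) {
    v <- as.numeric(v)
    if (any(!is.finite(v))) stop("non-finite values in ", path)
  } else v <- as.character(v)
  stats::setNames(v, x$id)
}

#' @rdname study_io
#' @export
read_phenotypes <- function(path) .read_two_col(path, "value", as_num = TRUE)

#' @rdname study_io
#' @param phenotypes Named numeric vector to write.
#' @export
write_phenotypes <- function(phenotypes, path) {
  utils::write.table(data.frame(id = names(phenotypes),
                                value = as.numeric(phenotypes)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname study_io
#' @export
read_sires <- function(path) .read_two_col(path, "sire")

#' @rdname study_io
#' @export
read_groups <- function(path) .read_two_col(path, "group")

#' Write all tables of a simulated study
#'
#' Writes `<prefix>.map.tsv`, `<prefix>.geno.tsv`, `<prefix>.pheno.tsv`,
#' `<prefix>.sires.tsv` and `<prefix>.truth.tsv` (id, causal minor-allele
#' count, then the phased marker haplotypes as `a|b`).
#'
#' @param study A `sim_study` from [simulate_population()].
#' @param prefix Output path prefix.
#' @return The five paths, invisibly.
#' @export
write_study <- function(study, prefix) {
  paths <- paste0(prefix, c(".map.tsv", ".geno.tsv", ".pheno.tsv",
                            ".sires.tsv", ".truth.tsv"))
  write_map(study$map, paths[1])
  write_genotypes(study$genotypes, paths[2])
  write_phenotypes(study$phenotypes, paths[3])
  utils::write.table(data.frame(id = names(study$sires),
                                sire = unname(study$sires)),
                     paths[4], sep = "\t", quote = FALSE, row.names = FALSE)
  tr <- study$truth
  phased <- matrix(paste0(tr$phase_paternal, "|", tr$phase_maternal),
                   nrow = nrow(tr$phase_paternal),
                   dimnames = dimnames(tr$phase_paternal))
  out <- data.frame(id = rownames(phased),
                    causal_count = unname(tr$causal_count[rownames(phased)]),
                    phased, stringsAsFactors = FALSE, check.names = FALSE)
  utils::write.table(out, paths[5], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}

## ------------------------------------------------------- ped/map import

#' Import PLINK-style .ped/.map files
#'
#' The `.map` file is whitespace-separated with columns chromosome, marker,
#' genetic position (cM) and optionally a physical position. The `.ped` file
#' has family, individual, father, mother, sex and phenotype columns
#' followed by two allele columns per marker; `0` codes a missing allele.
#' A half-missing genotype (one allele 0) collapses to fully missing, with
#' a message reporting how many genotypes were collapsed. Allele codes are
#' kept as integers.
#'
#' @param ped_path,map_path File paths.
#' @param keep_phenotype If `TRUE`, also return the ped phenotype column as
#'   a named numeric vector (default `FALSE`: ignored).
#' @return List with `map` (a [genetic_map()]), `genotypes` (a
#'   [geno_matrix()]), `sires` (named character, the ped father column) and
#'   optionally `phenotypes`.
#' @export
read_ped_map <- function(ped_path, map_path, keep_phenotype = FALSE) {
  mp <- utils::read.table(map_path, stringsAsFactors = FALSE)
  if (ncol(mp) < 3L) stop(".map needs >= 3 columns (chr, marker, cM)")
  map <- genetic_map(data.frame(marker = as.character(mp[[2]]),
                                chromosome = as.character(mp[[1]]),
                                position_cM = as.numeric(mp[[3]])))
  pd <- utils::read.table(ped_path, stringsAsFactors = FALSE)
  if (ncol(pd) < 8L) stop(".ped needs 6 leading columns plus allele pairs")
  nall <- ncol(pd) - 6L
  if (nall %% 2L != 0L)
    stop(".ped has an odd number of allele columns (", nall, ")")
  m <- nall %/% 2L
  if (m != nrow(map))
    stop(".ped carries ", m, " markers but the map lists ", nrow(map))
  ids <- as.character(pd[[2]])
  if (anyDuplicated(ids)) stop("duplicated individual ids in .ped")
  al <- as.matrix(pd[, -(1:6), drop = FALSE])
  storage.mode(al) <- "integer"
  a1 <- al[, seq(1L, nall, by = 2L), drop = FALSE]
  a2 <- al[, seq(2L, nall, by = 2L), drop = FALSE]
  half <- xor(a1 == 0L, a2 == 0L)
  if (any(half))
    message(sum(half), " half-missing genotype(s) collapsed to missing")
  a1[a1 == 0L | half] <- NA_integer_
  a2[a2 == 0L | half] <- NA_integer_
  dimnames(a1) <- dimnames(a2) <- list(ids, map$marker)
  out <- list(map = map, genotypes = geno_matrix(a1, a2),
              sires = stats::setNames(as.character(pd[[3]]), ids))
  if (keep_phenotype)
    out$phenotypes <- stats::setNames(as.numeric(pd[[6]]), ids)
  out
}
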