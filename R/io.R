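MISSING_CODE <- NA_integer_

#' Construct a SNP map
#'
#' @param snp_id unique SNP identifiers.
#' @param chromosome integer chromosome codes; 1--29 are autosomes, 30 is the
#'   X chromosome.
#' @param position_bp 1-based physical positions (bp).
#' @return data.frame of class \code{snp_map}, sorted by (chromosome,
#'   position); positions must be strictly increasing within a chromosome.
#' @export
snp_map <- function(snp_id, chromosome, position_bp) {
  snp_id <- as.character(snp_id)
  chromosome <- as.integer(chromosome)
  position_bp <- as.numeric(position_bp)
  if (anyDuplicated(snp_id)) stop("duplicate SNP id(s)")
  if (any(position_bp < 1)) stop("position_bp must be >= 1")
  map <- data.frame(snp_id = snp_id, chromosome = chromosome,
                    position_bp = position_bp, stringsAsFactors = FALSE)
  map <- map[order(map$chromosome, map$position_bp), , drop = FALSE]
  dup <- tapply(map$position_bp, map$chromosome,
                function(p) any(duplicated(p)))
  if (any(unlist(dup)))
    stop("duplicated position within a chromosome")
  rownames(map) <- NULL
  class(map) <- c("snp_map", "data.frame")
  map
}

#' Construct a genotype matrix
#'
#' Genotypes are coded per SNP as 0 = homozygote for the major allele,
#' 1 = heterozygote, 2 = homozygote for the minor allele, \code{NA} = missing.
#'
#' @param calls integer matrix, animals in rows, SNPs in columns.
#' @param animal_ids unique row ids.
#' @param map the matching [snp_map()]; column count must equal
#'   \code{nrow(map)}.
#' @return list of class \code{genotype_matrix} with elements \code{calls}
#'   (dimnames set) and \code{animal_ids}.
#' @export
genotype_matrix <- function(calls, animal_ids, map = NULL) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  animal_ids <- as.character(animal_ids)
  if (anyDuplicated(animal_ids)) stop("duplicate animal id(s)")
  if (nrow(calls) != length(animal_ids))
    stop("row count does not match animal_ids")
  if (!is.null(map) && ncol(calls) != nrow(map))
    stop("column count does not match SNP map")
  bad <- !(calls %in% c(0L, 1L, 2L, NA))
  if (any(bad)) stop("genotype codes must be 0, 1, 2 or NA")
  rownames(calls) <- animal_ids
  if (!is.null(map)) colnames(calls) <- map$snp_id
  structure(list(calls = calls, animal_ids = animal_ids),
            class = "genotype_matrix")
}

# recode so that 0 is the major-allele homozygote at every SNP
# (ties keep the current orientation)
.polarize_calls <- function(calls) {
  for (j in seq_len(ncol(calls))) {
    g <- calls[, j]
    n_ref <- sum(2L - g, na.rm = TRUE)  # count of allele coded 0
    n_alt <- sum(g, na.rm = TRUE)
    if (n_alt > n_ref) calls[, j] <- 2L - g
  }
  calls
}

#' Read PLINK genotype files
#'
#' Supports the text dialect (\code{.ped}/\code{.map}) and the binary v1.00
#' SNP-major dialect (\code{.bed}/\code{.bim}/\code{.fam}). Genotypes are
#' recoded so that 0 is the homozygote of the (observed) major allele at each
#' SNP, 2 the minor-allele homozygote, and \code{0 0} / \code{0} alleles are
#' missing. Columns are permuted to match the sorted map.
#'
#' @param prefix path prefix (without extension).
#' @param dialect \code{"ped_map"} or \code{"bed_bim_fam"}.
#' @return list with elements \code{genotypes} ([genotype_matrix()]) and
#'   \code{map} ([snp_map()]).
#' @export
read_plink <- function(prefix, dialect = c("ped_map", "bed_bim_fam")) {
  dialect <- match.arg(dialect)
  if (dialect == "ped_map") .read_ped_map(prefix) else .read_bed(prefix)
}

.read_ped_map <- function(prefix) {
  map_path <- paste0(prefix, ".map")
  ped_path <- paste0(prefix, ".ped")
  if (!file.exists(map_path) || !file.exists(ped_path))
    stop("missing .ped/.map for prefix ", prefix)
  m <- utils::read.table(map_path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(m) != 4) stop(".map must have 4 columns")
  map <- snp_map(m[[2]], m[[1]], m[[4]])
  p <- utils::read.table(ped_path, header = FALSE, stringsAsFactors = FALSE,
                         colClasses = "character")
  n_snp <- nrow(m)
  if (ncol(p) != 6 + 2 * n_snp)
    stop(".ped column count does not match .map (", ncol(p), " vs ",
         6 + 2 * n_snp, ")")
  ids <- p[[2]]
  if (anyDuplicated(ids)) stop("duplicate animal id(s) in .ped")
  a1 <- as.matrix(p[, 6 + 2 * seq_len(n_snp) - 1, drop = FALSE])
  a2 <- as.matrix(p[, 6 + 2 * seq_len(n_snp), drop = FALSE])
  calls <- matrix(NA_integer_, nrow(p), n_snp)
  for (j in seq_len(n_snp)) {
    x1 <- a1[, j]; x2 <- a2[, j]
    miss <- x1 == "0" | x2 == "0"
    alleles <- sort(unique(c(x1[!miss], x2[!miss])))
    if (length(alleles) > 2)
      stop("more than 2 alleles at SNP ", m[[2]][j], ": ",
           paste(alleles, collapse = "/"))
    if (length(alleles) == 0) next
    ref <- alleles[1]
    g <- (x1 != ref) + (x2 != ref)
    g[miss] <- NA_integer_
    calls[, j] <- g
  }
  calls <- .polarize_calls(calls)
  # permute columns into sorted-map order
  calls <- calls[, match(map$snp_id, m[[2]]), drop = FALSE]
  list(genotypes = genotype_matrix(calls, ids, map), map = map)
}

.read_bed <- function(prefix) {
  bim <- utils::read.table(paste0(prefix, ".bim"), header = FALSE,
                           stringsAsFactors = FALSE)
  if (ncol(bim) != 6) stop(".bim must have 6 columns")
  fam <- utils::read.table(paste0(prefix, ".fam"), header = FALSE,
                           stringsAsFactors = FALSE,
                           colClasses = "character")
  ids <- fam[[2]]
  if (anyDuplicated(ids)) stop("duplicate animal id(s) in .fam")
  n_ind <- length(ids)
  n_snp <- nrow(bim)
  map <- snp_map(bim[[2]], bim[[1]], bim[[4]])
  con <- file(paste0(prefix, ".bed"), "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 3)
  if (!identical(as.integer(magic), c(0x6cL, 0x1bL, 0x01L)))
    stop("not a SNP-major PLINK v1.00 .bed file")
  bytes_per_snp <- ceiling(n_ind / 4)
  raw <- readBin(con, "raw", bytes_per_snp * n_snp)
  if (length(raw) != bytes_per_snp * n_snp) stop("truncated .bed file")
  # 2-bit codes per individual: 00 hom A1, 01 missing, 10 het, 11 hom A2
  lut <- c(`0` = 2L, `1` = NA, `2` = 1L, `3` = 0L)
  ints <- as.integer(raw)
  two_bit <- cbind(ints %% 4L, (ints %/% 4L) %% 4L,
                   (ints %/% 16L) %% 4L, ints %/% 64L)
  calls <- matrix(NA_integer_, n_ind, n_snp)
  for (j in seq_len(n_snp)) {
    block <- two_bit[(j - 1L) * bytes_per_snp + seq_len(bytes_per_snp), ,
                     drop = FALSE]
    codes <- as.vector(t(block))[seq_len(n_ind)]
    calls[, j] <- lut[codes + 1L]
  }
  calls <- .polarize_calls(calls)
  calls <- calls[, match(map$snp_id, bim[[2]]), drop = FALSE]
  list(genotypes = genotype_matrix(calls, ids, map), map = map)
}

#' Write PLINK genotype files
#'
#' Writes either dialect. Codes are canonicalized first (2 = minor-allele
#' homozygote), so \code{read_plink(write_plink(x))} is the identity on
#' canonically coded input. Alleles are written as A (major) / G (minor).
#'
#' @param gm a [genotype_matrix()].
#' @param map the matching [snp_map()].
#' @param prefix output path prefix.
#' @param dialect \code{"ped_map"} or \code{"bed_bim_fam"}.
#' @param sexes optional named vector ("M"/"F") used for the sex column.
#' @return \code{prefix}, invisibly.
#' @export
write_plink <- function(gm, map, prefix,
                        dialect = c("ped_map", "bed_bim_fam"),
                        sexes = NULL) {
  dialect <- match.arg(dialect)
  calls <- .polarize_calls(gm$calls)
  ids <- gm$animal_ids
  sex_code <- rep(0L, length(ids))
  if (!is.null(sexes)) {
    sx <- sexes[ids]
    sex_code <- ifelse(is.na(sx), 0L, ifelse(sx == "M", 1L, 2L))
  }
  if (dialect == "ped_map") {
    a1 <- matrix("0", nrow(calls), ncol(calls))
    a2 <- a1
    a1[calls == 0L] <- "A"; a2[calls == 0L] <- "A"
    a1[calls == 1L] <- "A"; a2[calls == 1L] <- "G"
    a1[calls == 2L] <- "G"; a2[calls == 2L] <- "G"
    geno <- matrix("", nrow(calls), 2 * ncol(calls))
    geno[, 2 * seq_len(ncol(calls)) - 1] <- a1
    geno[, 2 * seq_len(ncol(calls))] <- a2
    ped <- cbind(ids, ids, "0", "0", sex_code, "-9", geno)
    utils::write.table(ped, paste0(prefix, ".ped"), quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    utils::write.table(
      data.frame(map$chromosome, map$snp_id, 0, map$position_bp),
      paste0(prefix, ".map"), quote = FALSE,
      row.names = FALSE, col.names = FALSE)
  } else {
    utils::write.table(
      data.frame(map$chromosome, map$snp_id, 0, map$position_bp, "G", "A"),
      paste0(prefix, ".bim"), quote = FALSE,
      row.names = FALSE, col.names = FALSE)
    utils::write.table(
      data.frame(ids, ids, 0, 0, sex_code, -9),
      paste0(prefix, ".fam"), quote = FALSE,
      row.names = FALSE, col.names = FALSE)
    n_ind <- nrow(calls)
    bytes_per_snp <- ceiling(n_ind / 4)
    # 2-bit codes: hom A1 (minor, our 2) = 00, missing = 01, het = 10,
    # hom A2 (major, our 0) = 11
    enc <- matrix(1L, bytes_per_snp * 4, ncol(calls))
    code_lut <- c(`0` = 3L, `1` = 2L, `2` = 0L)
    for (j in seq_len(ncol(calls))) {
      g <- calls[, j]
      v <- ifelse(is.na(g), 1L, code_lut[as.character(g)])
      enc[seq_len(n_ind), j] <- v
    }
    idx <- seq(1, bytes_per_snp * 4, by = 4)
    bytes <- enc[idx, , drop = FALSE] + 4L * enc[idx + 1, , drop = FALSE] +
      16L * enc[idx + 2, , drop = FALSE] + 64L * enc[idx + 3, , drop = FALSE]
    con <- file(paste0(prefix, ".bed"), "wb")
    on.exit(close(con))
    writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
    writeBin(as.raw(bytes), con)
  }
  invisible(prefix)
}

#' Read a pedigree CSV
#'
#' Expects a header \code{animal,sire,dam}; unknown parents coded 0 or empty.
#' Parents without their own row are appended as founders.
#'
#' @param path CSV file.
#' @return a [ped_table()].
#' @export
read_pedigree <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = "character")
  need <- c("animal", "sire", "dam")
  if (!all(need %in% names(d)))
    stop("pedigree file must have header animal,sire,dam")
  ped_table(d$animal, d$sire, d$dam)
}

#' Write a pedigree CSV
#' @param ped a [ped_table()].
#' @param path output file.
#' @export
write_pedigree <- function(ped, path) {
  out <- ped
  out$sire[is.na(out$sire)] <- "0"
  out$dam[is.na(out$dam)] <- "0"
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a phenotype CSV
#'
#' Expects header \code{animal,sex,year_of_birth,adg} (average daily gain in
#' kg/day). Sex must be M or F.
#'
#' @param path CSV file.
#' @return data.frame with columns \code{animal}, \code{sex},
#'   \code{year_of_birth}, \code{adg_raw}.
#' @export
read_phenotypes <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("animal", "sex", "year_of_birth", "adg")
  if (!all(need %in% names(d)))
    stop("phenotype file must have header animal,sex,year_of_birth,adg")
  if (!all(d$sex %in% c("M", "F"))) stop("sex must be M or F")
  data.frame(animal = as.character(d$animal), sex = d$sex,
             year_of_birth = as.integer(d$year_of_birth),
             adg_raw = as.numeric(d$adg), stringsAsFactors = FALSE)
}

#' Write a phenotype CSV
#' @param phenos data.frame as returned by [read_phenotypes()].
#' @param path output file.
#' @export
write_phenotypes <- function(phenos, path) {
  utils::write.csv(
    data.frame(animal = phenos$animal, sex = phenos$sex,
               year_of_birth = phenos$year_of_birth, adg = phenos$adg_raw),
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
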