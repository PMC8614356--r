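#' Chromosome lengths from a SNP map
#'
#' Default denominator convention for FROH: the SNP-covered length of each
#' chromosome, last SNP position minus first plus one. An assembly-length
#' table can be supplied instead wherever a \code{chromosome_lengths} result
#' is accepted (named numeric vector, names = chromosome codes).
#'
#' @param map a [snp_map()].
#' @return named numeric vector of bp lengths, one per chromosome in the map.
#' @export
chromosome_lengths <- function(map) {
  out <- c(tapply(map$position_bp, map$chromosome,
                  function(p) max(p) - min(p) + 1))
  out <- out[order(as.integer(names(out)))]
  if (any(out == 1))
    warning("chromosome(s) with a single SNP have length 1: ",
            paste(names(out)[out == 1], collapse = ", "))
  storage.mode(out) <- "double"
  out
}

#' Genome-wide and per-chromosome FROH
#'
#' FROH on chromosome c is the summed length of the animal's ROH segments on
#' c divided by the length of c; genome-wide FROH is the total ROH length
#' divided by the summed length of the included chromosomes (equivalently the
#' length-weighted mean of the per-chromosome values). For males the X
#' chromosome is treated as missing: its per-chromosome value is \code{NA}
#' and it is excluded from the male genome-wide numerator and denominator.
#' Animals without any segment get FROH = 0.
#'
#' @param segments ROH table from [detect_roh()].
#' @param lengths named length vector from [chromosome_lengths()].
#' @param sexes named character vector ("M"/"F") over all animals wanted in
#'   the output (animals without segments included).
#' @param fped optional data.frame from [compute_fped()]; merged in when
#'   given.
#' @param x_chromosome integer code of the X chromosome (default 30); use
#'   \code{NA} for an all-autosome map.
#' @param include_x_females keep X in the female genome-wide denominator
#'   (default TRUE).
#' @return data.frame with columns \code{animal}, \code{sex}, \code{f_ped}
#'   (if supplied), \code{f_roh}, and one \code{froh_chr<c>} column per
#'   chromosome.
#' @export
compute_froh <- function(segments, lengths, sexes, fped = NULL,
                         x_chromosome = 30L, include_x_females = TRUE) {
  animals <- names(sexes)
  if (is.null(animals)) stop("sexes must be a named vector")
  chroms <- as.integer(names(lengths))
  if (nrow(segments)) {
    if (!all(segments$chromosome %in% chroms))
      stop("segment on chromosome absent from lengths table")
    seg_len <- segments$end_bp - segments$start_bp + 1
    if (any(seg_len > lengths[as.character(segments$chromosome)]))
      stop("segment longer than its chromosome: corrupt input")
    tot <- tapply(seg_len,
                  list(factor(segments$animal, levels = animals),
                       factor(segments$chromosome, levels = chroms)),
                  sum)
    tot[is.na(tot)] <- 0
  } else {
    tot <- matrix(0, length(animals), length(chroms),
                  dimnames = list(animals, chroms))
  }
  fchr <- sweep(tot, 2, lengths[as.character(chroms)], "/")
  is_male <- sexes[animals] == "M"
  x_col <- which(chroms == x_chromosome)
  denom <- matrix(rep(lengths[as.character(chroms)], each = length(animals)),
                  length(animals), length(chroms))
  include <- matrix(TRUE, length(animals), length(chroms))
  if (length(x_col)) {
    fchr[is_male, x_col] <- NA
    include[is_male, x_col] <- FALSE
    if (!include_x_females) include[, x_col] <- FALSE
  }
  num <- rowSums(ifelse(include, tot, 0))
  den <- rowSums(ifelse(include, denom, 0))
  out <- data.frame(animal = animals, sex = unname(sexes[animals]),
                    f_roh = num / den, stringsAsFactors = FALSE)
  fchr_df <- as.data.frame(fchr)
  names(fchr_df) <- paste0("froh_chr", chroms)
  out <- cbind(out, fchr_df)
  if (!is.null(fped)) {
    out$f_ped <- fped$f_ped[match(out$animal, fped$animal)]
    out <- out[, c("animal", "sex", "f_ped", "f_roh",
                   paste0("froh_chr", chroms))]
  }
  rownames(out) <- NULL
  out
}

#' Drop animals with zero genome-wide FROH
#'
#' Applied genome-wide (not per chromosome); strictly positive values are
#' kept. The number removed is reported via \code{message()}.
#'
#' @param records data.frame from [compute_froh()].
#' @return the filtered data.frame.
#' @export
filter_positive_froh <- function(records) {
  drop <- records$f_roh == 0
  message(sum(drop), " animal(s) with FROH = 0 removed")
  out <- records[!drop, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Pearson correlation between pedigree and ROH inbreeding
#'
#' @param records data.frame carrying \code{f_ped} and \code{f_roh}.
#' @return a single correlation coefficient.
#' @export
correlate_inbreeding <- function(records) {
  ok <- stats::complete.cases(records$f_ped, records$f_roh)
  x <- records$f_ped[ok]
  y <- records$f_roh[ok]
  if (length(x) < 3) stop("need at least 3 animals with both coefficients")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance in an inbreeding coefficient: correlation undefined")
  stats::cor(x, y)
}

#' Write inbreeding records as CSV
#' @param records data.frame from [compute_froh()].
#' @param path output file.
#' @export
write_inbreeding <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}
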