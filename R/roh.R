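#' Parameters for run-of-homozygosity detection
#'
#' Defaults correspond to common sliding-window ROH scanning for medium
#' density cattle panels: runs must carry at least 30 SNPs, span at least
#' 1 Mb, average at least 1 SNP per 500 kb, and may contain at most two
#' heterozygous and two missing calls. The scanning window is 15 SNPs with a
#' per-SNP homozygosity-score threshold of 0.05, and runs are split at
#' inter-SNP gaps above 1 Mb.
#'
#' @param min_snp minimum SNPs per run.
#' @param min_length_bp minimum run length in bp (closed interval on SNPs).
#' @param min_density_bp_per_snp maximum average spacing: a run must have at
#'   least one SNP per this many bp.
#' @param max_het_in_run,max_miss_in_run allowed heterozygous / missing calls
#'   inside one run (and inside one scanning window).
#' @param window_size_snps sliding-window width in SNPs.
#' @param window_threshold minimum fraction of covering windows that must be
#'   homozygous for a SNP to be flagged.
#' @param max_gap_bp maximum bp gap between adjacent SNPs inside a run.
#' @return list of class \code{roh_params}.
#' @export
roh_params <- function(min_snp = 30, min_length_bp = 1e6,
                       min_density_bp_per_snp = 5e5,
                       max_het_in_run = 2, max_miss_in_run = 2,
                       window_size_snps = 15, window_threshold = 0.05,
                       max_gap_bp = 1e6) {
  stopifnot(min_snp >= 0, min_length_bp >= 0, min_density_bp_per_snp > 0,
            max_het_in_run >= 0, max_miss_in_run >= 0,
            window_size_snps >= 1,
            window_threshold > 0, window_threshold <= 1, max_gap_bp > 0)
  structure(list(min_snp = min_snp, min_length_bp = min_length_bp,
                 min_density_bp_per_snp = min_density_bp_per_snp,
                 max_het_in_run = max_het_in_run,
                 max_miss_in_run = max_miss_in_run,
                 window_size_snps = window_size_snps,
                 window_threshold = window_threshold,
                 max_gap_bp = max_gap_bp),
            class = "roh_params")
}

#' Per-SNP homozygosity flags from a sliding window
#'
#' Slides a window of \code{window_size_snps} SNPs one SNP at a time along one
#' animal's genotype vector for one chromosome. A window is homozygous when it
#' contains at most \code{max_het_in_run} heterozygotes and at most
#' \code{max_miss_in_run} missing calls. Each SNP's score is the fraction of
#' windows covering it that are homozygous; the SNP is flagged when the score
#' reaches \code{window_threshold}. When the chromosome carries fewer SNPs
#' than the window size, a single window spanning all SNPs is used.
#'
#' @param calls integer genotype vector (0/1/2/NA), aligned to the sorted map
#'   positions of one chromosome.
#' @param params a [roh_params()].
#' @return logical vector, one flag per SNP (empty input gives empty output).
#' @export
window_homozygosity_flags <- function(calls, params = roh_params()) {
  n <- length(calls)
  if (n == 0L) return(logical(0))
  w <- min(params$window_size_snps, n)
  het <- as.integer(!is.na(calls) & calls == 1L)
  mis <- as.integer(is.na(calls))
  ch <- c(0L, cumsum(het))
  cm <- c(0L, cumsum(mis))
  n_win <- n - w + 1L
  i <- seq_len(n_win)
  hom_win <- (ch[i + w] - ch[i]) <= params$max_het_in_run &
    (cm[i + w] - cm[i]) <= params$max_miss_in_run
  cw <- c(0L, cumsum(as.integer(hom_win)))
  j <- seq_len(n)
  lo <- pmax(1L, j - w + 1L)
  hi <- pmin(j, n_win)
  score <- (cw[hi + 1L] - cw[lo]) / (hi - lo + 1L)
  score >= params$window_threshold
}

# shared run filters; segs is a data.frame with start/end indices
.run_passes <- function(n_snps, len_bp, n_het, n_miss, params) {
  n_snps >= params$min_snp &
    len_bp >= params$min_length_bp &
    n_het <= params$max_het_in_run &
    n_miss <= params$max_miss_in_run &
    n_snps / len_bp >= 1 / params$min_density_bp_per_snp
}

#' Assemble ROH segments from per-SNP flags
#'
#' Maximal stretches of consecutively flagged SNPs become candidate runs.
#' Candidates are split wherever the bp gap between adjacent SNPs exceeds
#' \code{max_gap_bp}. Within a candidate, a heterozygous (missing) call that
#' would push the running count past \code{max_het_in_run}
#' (\code{max_miss_in_run}) truncates the run just before it; a fresh
#' candidate starts just after the violating SNP. Survivors are filtered by
#' SNP count, bp length and density. Run coordinates are the bp positions of
#' the first and last SNP (closed, 1-based); missing calls count toward
#' \code{n_snps} but are neither homozygous nor heterozygous.
#'
#' @param flags logical vector from [window_homozygosity_flags()].
#' @param calls the genotype vector the flags were computed from.
#' @param map_positions sorted bp positions, same length.
#' @param params a [roh_params()].
#' @return data.frame with columns \code{start_bp}, \code{end_bp},
#'   \code{n_snps}, \code{n_het}, \code{n_miss} (zero rows if none).
#' @export
flags_to_runs <- function(flags, calls, map_positions, params = roh_params()) {
  stopifnot(length(flags) == length(calls),
            length(calls) == length(map_positions))
  empty <- data.frame(start_bp = numeric(0), end_bp = numeric(0),
                      n_snps = integer(0), n_het = integer(0),
                      n_miss = integer(0))
  if (!length(flags) || !any(flags)) return(empty)
  r <- rle(flags)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cand <- cbind(starts[r$values], ends[r$values])
  # split candidates at large gaps
  pieces <- list()
  for (k in seq_len(nrow(cand))) {
    a <- cand[k, 1]; b <- cand[k, 2]
    if (a == b) { pieces[[length(pieces) + 1L]] <- c(a, b); next }
    gaps <- which(diff(map_positions[a:b]) > params$max_gap_bp)
    cuts <- c(a - 1L, a - 1L + gaps, b)
    for (q in seq_len(length(cuts) - 1L))
      pieces[[length(pieces) + 1L]] <- c(cuts[q] + 1L, cuts[q + 1L])
  }
  # truncate at het/missing overflow
  runs <- list()
  for (p in pieces) {
    a <- p[1]; b <- p[2]
    start <- a; hc <- 0L; mc <- 0L
    k <- a
    while (k <= b) {
      g <- calls[k]
      violate <- FALSE
      if (is.na(g)) {
        if (mc + 1L > params$max_miss_in_run) violate <- TRUE else mc <- mc + 1L
      } else if (g == 1L) {
        if (hc + 1L > params$max_het_in_run) violate <- TRUE else hc <- hc + 1L
      }
      if (violate) {
        if (k - 1L >= start) runs[[length(runs) + 1L]] <- c(start, k - 1L)
        start <- k + 1L; hc <- 0L; mc <- 0L
      }
      k <- k + 1L
    }
    if (b >= start) runs[[length(runs) + 1L]] <- c(start, b)
  }
  if (!length(runs)) return(empty)
  seg <- do.call(rbind, runs)
  n_het <- vapply(seq_len(nrow(seg)), function(k) {
    g <- calls[seg[k, 1]:seg[k, 2]]
    sum(!is.na(g) & g == 1L)
  }, integer(1))
  n_miss <- vapply(seq_len(nrow(seg)), function(k)
    sum(is.na(calls[seg[k, 1]:seg[k, 2]])), integer(1))
  out <- data.frame(start_bp = map_positions[seg[, 1]],
                    end_bp = map_positions[seg[, 2]],
                    n_snps = seg[, 2] - seg[, 1] + 1L,
                    n_het = n_het, n_miss = n_miss)
  len <- out$end_bp - out$start_bp + 1
  out <- out[.run_passes(out$n_snps, len, out$n_het, out$n_miss, params), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Detect runs of homozygosity
#'
#' Applies the sliding-window scan ([window_homozygosity_flags()] followed by
#' [flags_to_runs()]) to every animal on every chromosome. Output rows are
#' ordered by animal (genotype-matrix row order), chromosome, start position.
#'
#' @param gm a [genotype_matrix()].
#' @param map the matching [snp_map()].
#' @param params a [roh_params()].
#' @return data.frame with columns \code{animal}, \code{chromosome},
#'   \code{start_bp}, \code{end_bp}, \code{n_snps}, \code{n_het},
#'   \code{n_miss}.
#' @export
detect_roh <- function(gm, map, params = roh_params()) {
  if (ncol(gm$calls) != nrow(map))
    stop("genotype matrix and SNP map are misaligned")
  chroms <- unique(map$chromosome)
  col_idx <- split(seq_len(nrow(map)), map$chromosome)
  out <- list()
  for (a in seq_along(gm$animal_ids)) {
    for (cc in chroms) {
      idx <- col_idx[[as.character(cc)]]
      calls <- gm$calls[a, idx]
      pos <- map$position_bp[idx]
      flags <- window_homozygosity_flags(calls, params)
      seg <- flags_to_runs(flags, calls, pos, params)
      if (nrow(seg)) {
        seg <- cbind(data.frame(animal = gm$animal_ids[a], chromosome = cc,
                                stringsAsFactors = FALSE), seg)
        out[[length(out) + 1L]] <- seg
      }
    }
  }
  if (!length(out))
    return(data.frame(animal = character(0), chromosome = integer(0),
                      start_bp = numeric(0), end_bp = numeric(0),
                      n_snps = integer(0), n_het = integer(0),
                      n_miss = integer(0)))
  res <- do.call(rbind, out)
  res <- res[order(match(res$animal, gm$animal_ids), res$chromosome,
                   res$start_bp), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Naive reference ROH scan (test oracle)
#'
#' Applies exactly the same detection rules as [detect_roh()] through an
#' independent, deliberately naive code path: per-SNP window scores are
#' obtained by enumerating every window covering each SNP and counting its
#' heterozygous and missing calls with explicit loops, and runs are assembled
#' by a plain per-SNP state machine. Quadratic-ish and only suitable for
#' vectors of a few hundred SNPs.
#'
#' @param calls genotype vector for one animal on one chromosome.
#' @param map_positions sorted bp positions.
#' @param params a [roh_params()].
#' @return data.frame in the format of [flags_to_runs()].
#' @export
brute_force_roh <- function(calls, map_positions, params = roh_params()) {
  n <- length(calls)
  empty <- data.frame(start_bp = numeric(0), end_bp = numeric(0),
                      n_snps = integer(0), n_het = integer(0),
                      n_miss = integer(0))
  if (n == 0L) return(empty)
  w <- if (n < params$window_size_snps) n else params$window_size_snps
  hom_win <- logical(n - w + 1L)
  for (i in seq_along(hom_win)) {
    hets <- 0L; misses <- 0L
    for (k in i:(i + w - 1L)) {
      if (is.na(calls[k])) misses <- misses + 1L
      else if (calls[k] == 1L) hets <- hets + 1L
    }
    hom_win[i] <- hets <= params$max_het_in_run &&
      misses <= params$max_miss_in_run
  }
  flags <- logical(n)
  for (j in seq_len(n)) {
    n_cov <- 0L
    n_hom <- 0L
    for (i in seq_along(hom_win)) {
      if (i <= j && j <= i + w - 1L) {
        n_cov <- n_cov + 1L
        if (hom_win[i]) n_hom <- n_hom + 1L
      }
    }
    flags[j] <- (n_hom / n_cov) >= params$window_threshold
  }
  # state machine over SNPs: candidate boundaries are unflagged SNPs and
  # large gaps; het/miss overflow closes the run and restarts past it
  segs <- list()
  start <- NA_integer_; hc <- 0L; mc <- 0L
  close_run <- function(a, b) {
    if (is.na(a) || b < a) return(invisible(NULL))
    g <- calls[a:b]
    nh <- sum(!is.na(g) & g == 1L)
    nm <- sum(is.na(g))
    len <- map_positions[b] - map_positions[a] + 1
    ok <- (b - a + 1L) >= params$min_snp &&
      len >= params$min_length_bp &&
      nh <= params$max_het_in_run && nm <= params$max_miss_in_run &&
      (b - a + 1L) / len >= 1 / params$min_density_bp_per_snp
    if (ok) segs[[length(segs) + 1L]] <<- data.frame(
      start_bp = map_positions[a], end_bp = map_positions[b],
      n_snps = b - a + 1L, n_het = nh, n_miss = nm)
    invisible(NULL)
  }
  for (k in seq_len(n)) {
    if (!flags[k]) {
      close_run(start, k - 1L)
      start <- NA_integer_; hc <- 0L; mc <- 0L
      next
    }
    if (!is.na(start) &&
        map_positions[k] - map_positions[k - 1L] > params$max_gap_bp) {
      close_run(start, k - 1L)
      start <- NA_integer_; hc <- 0L; mc <- 0L
    }
    g <- calls[k]
    over <- (is.na(g) && mc + 1L > params$max_miss_in_run) ||
      (!is.na(g) && g == 1L && hc + 1L > params$max_het_in_run)
    if (over) {
      close_run(start, k - 1L)
      start <- NA_integer_; hc <- 0L; mc <- 0L
      next  # violating SNP excluded; next candidate starts after it
    }
    if (is.na(start)) start <- k
    if (is.na(g)) mc <- mc + 1L else if (g == 1L) hc <- hc + 1L
  }
  close_run(start, n)
  if (!length(segs)) return(empty)
  out <- do.call(rbind, segs)
  rownames(out) <- NULL
  out
}

#' Write ROH segments
#'
#' Tab-separated with a header. With \code{bed = TRUE} writes 3+ column BED
#' instead (0-based half-open: \code{start = start_bp - 1}, \code{end =
#' end_bp}).
#'
#' @param segments data.frame from [detect_roh()].
#' @param path output file.
#' @param bed write BED instead of the native table.
#' @export
write_roh <- function(segments, path, bed = FALSE) {
  if (bed) {
    out <- data.frame(chrom = segments$chromosome,
                      start = segments$start_bp - 1,
                      end = segments$end_bp,
                      name = segments$animal)
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  } else {
    utils::write.table(segments, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}
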