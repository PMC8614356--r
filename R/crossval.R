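#' Cross-validation configuration
#'
#' Repeated random-split validation: each round, \code{floor(train_fraction
#' * n)} animals train an OLS model whose predictions are correlated with the
#' observed values of the remaining animals. 500 rounds with an 80/20 split
#' is the default; convergence of the running mean accuracy is declared at
#' changes below \code{convergence_tol}.
#'
#' @param train_fraction fraction of animals in the training group.
#' @param n_rounds number of random splits.
#' @param seed integer seed controlling the split sequence.
#' @param convergence_tol tolerance on consecutive running means.
#' @return list of class \code{cv_config}.
#' @export
cv_config <- function(train_fraction = 0.8, n_rounds = 500, seed = 1,
                      convergence_tol = 1e-4) {
  stopifnot(train_fraction > 0, train_fraction < 1, n_rounds >= 1)
  structure(list(train_fraction = train_fraction,
                 n_rounds = as.integer(n_rounds),
                 seed = as.integer(seed),
                 convergence_tol = convergence_tol),
            class = "cv_config")
}

# split sequence shared across predictor sets: list of training index vectors
make_splits <- function(n, cfg) {
  n_train <- floor(cfg$train_fraction * n)
  stopifnot(n_train >= 1, n_train < n)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(cfg$seed)
  lapply(seq_len(cfg$n_rounds), function(i) sort(sample.int(n, n_train)))
}

#' Cross-validated prediction accuracy
#'
#' For each round an OLS model of \code{y} on the predictor columns is fit on
#' the training split and used to predict the validation animals; the round's
#' accuracy is the Pearson correlation between predicted and observed values.
#' Rounds where the predictions or observations have zero variance (or the
#' training design is rank deficient) record accuracy 0 and are flagged.
#' Identical configuration and seed give bit-identical accuracy vectors.
#'
#' @param y numeric response (corrected phenotype), no missing values.
#' @param X predictor matrix (or vector), rows aligned with \code{y}.
#' @param cfg a [cv_config()].
#' @param splits optional externally supplied split list (as produced
#'   internally from \code{cfg}); used to share split sequences across
#'   predictor sets.
#' @return list of class \code{cv_result}: \code{predictor_ids},
#'   \code{accuracies}, \code{mean}, \code{sd}, \code{running_means},
#'   \code{converged}, \code{rounds_to_convergence}, \code{flagged_rounds}.
#' @export
cv_accuracy <- function(y, X, cfg = cv_config(), splits = NULL) {
  X <- as.matrix(X)
  n <- length(y)
  stopifnot(n == nrow(X), n >= 10)
  if (anyNA(y) || anyNA(X)) stop("missing values; drop listwise first")
  if (any(apply(X, 2, stats::sd) == 0))
    stop("constant predictor column on the full data")
  if (is.null(splits)) splits <- make_splits(n, cfg)
  acc <- numeric(length(splits))
  flagged <- logical(length(splits))
  Xd <- cbind(1, X)
  for (i in seq_along(splits)) {
    tr <- splits[[i]]
    fit <- stats::lm.fit(Xd[tr, , drop = FALSE], y[tr])
    beta <- fit$coefficients
    if (anyNA(beta)) {
      beta[is.na(beta)] <- 0
      flagged[i] <- TRUE
    }
    pred <- Xd[-tr, , drop = FALSE] %*% beta
    obs <- y[-tr]
    if (stats::sd(pred) == 0 || stats::sd(obs) == 0) {
      acc[i] <- 0
      flagged[i] <- TRUE
    } else {
      acc[i] <- stats::cor(pred, obs)[1]
    }
  }
  conv <- check_convergence(acc, cfg$convergence_tol)
  structure(list(predictor_ids = colnames(X),
                 accuracies = acc,
                 mean = mean(acc),
                 sd = stats::sd(acc),
                 running_means = cumsum(acc) / seq_along(acc),
                 converged = conv$converged,
                 rounds_to_convergence = conv$rounds_to_convergence,
                 flagged_rounds = which(flagged)),
            class = "cv_result")
}

#' Convergence of the running mean accuracy
#'
#' Finds the smallest K such that every subsequent change of the running mean
#' \code{m_k = mean(acc[1:k])} is below \code{tol}; the sequence converged if
#' such K exists before the last round.
#'
#' @param accuracies numeric vector.
#' @param tol tolerance, default 1e-4.
#' @return list with \code{converged} (logical) and
#'   \code{rounds_to_convergence} (K, or \code{NA} when never stable).
#' @export
check_convergence <- function(accuracies, tol = 1e-4) {
  n <- length(accuracies)
  stopifnot(n >= 1)
  if (n == 1) return(list(converged = TRUE, rounds_to_convergence = 1L))
  m <- cumsum(accuracies) / seq_len(n)
  d <- abs(diff(m))  # d[j] = |m_{j+1} - m_j|
  viol <- which(d >= tol)
  K <- if (length(viol)) max(viol) + 1L else 1L
  converged <- K < n
  list(converged = converged,
       rounds_to_convergence = if (converged) K else NA_integer_)
}

#' Rank and select chromosomes
#'
#' Ranks chromosomes by full-data p-value (ascending), absolute slope
#' (descending) or mean cross-validated accuracy (descending) and returns the
#' top \code{k} (or all passing \code{threshold}). Ties break toward the
#' lower chromosome number. Chromosomes with absent fits are not eligible.
#'
#' @param fits named list from [per_chromosome_fits()] (names
#'   \code{froh_chr<c>}).
#' @param cv_results named list of [cv_accuracy()] results per chromosome
#'   (same names); required for \code{criterion = "accuracy"}.
#' @param criterion \code{"p_value"}, \code{"effect_size"} or
#'   \code{"accuracy"}.
#' @param k number of chromosomes to keep (exclusive with
#'   \code{threshold}).
#' @param threshold keep chromosomes with criterion value better than this
#'   (smaller p, larger |slope| or accuracy).
#' @return integer vector of selected chromosome numbers, in rank order.
#' @export
select_chromosomes <- function(fits, cv_results = NULL,
                               criterion = c("p_value", "effect_size",
                                             "accuracy"),
                               k = NULL, threshold = NULL) {
  criterion <- match.arg(criterion)
  if (is.null(k) == is.null(threshold))
    stop("supply exactly one of k or threshold")
  chr_of <- function(nm) as.integer(sub("^froh_chr", "", nm))
  if (criterion == "accuracy") {
    if (is.null(cv_results)) stop("cv_results required for accuracy criterion")
    keep <- !vapply(cv_results, is.null, logical(1))
    score <- vapply(cv_results[keep], function(r) r$mean, numeric(1))
    chrs <- chr_of(names(cv_results)[keep])
    better_than <- function(s, thr) s > thr
    ord <- order(-score, chrs)
  } else {
    keep <- !vapply(fits, is.null, logical(1))
    chrs <- chr_of(names(fits)[keep])
    if (criterion == "p_value") {
      score <- vapply(fits[keep], function(f) unname(f$p_values[1]), numeric(1))
      better_than <- function(s, thr) s < thr
      ord <- order(score, chrs)
    } else {
      score <- vapply(fits[keep], function(f) abs(unname(f$slopes[1])),
                      numeric(1))
      better_than <- function(s, thr) s > thr
      ord <- order(-score, chrs)
    }
  }
  sel <- chrs[ord]
  if (!is.null(k)) sel <- utils::head(sel, k)
  else sel <- sel[better_than(score[ord], threshold)]
  if (!length(sel))
    stop("no chromosome selected; loosen the threshold or increase k")
  sel
}

#' Compare predictor sets on shared cross-validation splits
#'
#' Runs [cv_accuracy()] for each predictor set using one common sequence of
#' training/validation splits (common random numbers), so per-round accuracy
#' differences are paired. Animals with a missing value in any set (e.g.,
#' male X) are dropped listwise for all sets. Mean accuracies are compared
#' with [tukey_compare()].
#'
#' @param y corrected phenotype vector.
#' @param sets named list of predictor matrices, rows aligned with \code{y}.
#' @param cfg a [cv_config()].
#' @return list with \code{results} (named list of \code{cv_result}),
#'   \code{summary} (data.frame set/mean/sd/converged), \code{tukey}
#'   (a \code{tukey_result}), \code{n} (animals used).
#' @export
compare_predictor_sets <- function(y, sets, cfg = cv_config()) {
  stopifnot(length(sets) >= 1)
  if (is.null(names(sets))) names(sets) <- paste0("set", seq_along(sets))
  sets <- lapply(sets, as.matrix)
  ok <- !is.na(y)
  for (s in sets) ok <- ok & stats::complete.cases(s)
  y2 <- y[ok]
  sets2 <- lapply(sets, function(s) s[ok, , drop = FALSE])
  splits <- make_splits(length(y2), cfg)
  results <- lapply(sets2, function(s) cv_accuracy(y2, s, cfg, splits = splits))
  summary <- data.frame(
    set = names(sets),
    mean = vapply(results, function(r) r$mean, numeric(1)),
    sd = vapply(results, function(r) r$sd, numeric(1)),
    converged = vapply(results, function(r) r$converged, logical(1)),
    row.names = NULL)
  tk <- if (length(sets) >= 2)
    tukey_compare(lapply(results, function(r) r$accuracies)) else NULL
  list(results = results, summary = summary, tukey = tk, n = sum(ok))
}
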