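#' Correct phenotypes for sex and year of birth
#'
#' Fits an ordinary least squares model of the raw phenotype on categorical
#' sex and categorical year of birth (with intercept) and returns the
#' residuals as \code{adg_corrected}. A factor with a single level present is
#' dropped with a warning; a level carried by a single animal is retained
#' (its residual is absorbed), also with a warning.
#'
#' @param phenos data.frame with \code{animal}, \code{sex},
#'   \code{year_of_birth}, \code{adg_raw}.
#' @return the input with an added \code{adg_corrected} column (residuals,
#'   mean zero).
#' @export
correct_phenotypes <- function(phenos) {
  d <- phenos
  d$sex_f <- factor(d$sex)
  d$year_f <- factor(d$year_of_birth)
  terms <- character(0)
  if (nlevels(d$sex_f) >= 2) terms <- c(terms, "sex_f")
  else warning("single sex present; sex effect dropped")
  if (nlevels(d$year_f) >= 2) terms <- c(terms, "year_f")
  else warning("single year of birth present; year effect dropped")
  singletons <- names(which(table(d$year_f) == 1))
  if (length(singletons) && "year_f" %in% terms)
    warning("year level(s) with a single observation retained: ",
            paste(singletons, collapse = ", "))
  fml <- if (length(terms))
    stats::reformulate(terms, response = "adg_raw") else adg_raw ~ 1
  fit <- stats::lm(fml, data = d)
  phenos$adg_corrected <- unname(stats::residuals(fit))
  phenos
}

#' Inbreeding-depression regression
#'
#' Ordinary least squares of a (corrected) phenotype on one or more
#' inbreeding predictors: \code{y = mu + F a + e}. Slopes are in kg/day per
#' unit of inbreeding coefficient; standard errors are the classical OLS
#' ones and p-values two-sided t-tests.
#'
#' @param y numeric response vector.
#' @param F numeric matrix (or vector) of inbreeding predictors, rows aligned
#'   with \code{y}; column names are the predictor ids.
#' @param predictor_ids optional character vector overriding column names.
#' @return list of class \code{depression_fit} with \code{predictor_ids},
#'   \code{intercept}, \code{slopes}, \code{se}, \code{p_values},
#'   \code{r_squared}, \code{n}.
#' @export
fit_depression <- function(y, F, predictor_ids = NULL) {
  F <- as.matrix(F)
  if (!is.null(predictor_ids)) {
    colnames(F) <- predictor_ids
  } else if (is.null(colnames(F))) {
    colnames(F) <- paste0("F", seq_len(ncol(F)))
  }
  if (length(y) != nrow(F)) stop("y and F are misaligned")
  if (anyNA(y) || anyNA(F)) stop("missing values in y or F; drop listwise first")
  sds <- apply(F, 2, stats::sd)
  if (any(sds == 0))
    stop("zero-variance predictor(s): ",
         paste(colnames(F)[sds == 0], collapse = ", "))
  X <- cbind(`(Intercept)` = 1, F)
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    aliased <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]]
    stop("collinear predictor(s): ", paste(aliased, collapse = ", "))
  }
  fit <- stats::lm.fit(X, y)
  n <- length(y)
  p <- ncol(X)
  rss <- sum(fit$residuals^2)
  tss <- sum((y - mean(y))^2)
  sigma2 <- rss / (n - p)
  xtxi <- chol2inv(chol(crossprod(X)))
  se <- sqrt(diag(xtxi) * sigma2)
  names(se) <- colnames(X)
  tval <- fit$coefficients / se
  pval <- 2 * stats::pt(abs(tval), df = n - p, lower.tail = FALSE)
  structure(list(predictor_ids = colnames(F),
                 intercept = unname(fit$coefficients[1]),
                 slopes = fit$coefficients[-1],
                 se = se[-1],
                 p_values = pval[-1],
                 intercept_se = unname(se[1]),
                 r_squared = if (tss > 0) 1 - rss / tss else NA_real_,
                 n = n),
            class = "depression_fit")
}

#' @export
print.depression_fit <- function(x, ...) {
  cat("Inbreeding-depression fit (n =", x$n, ")\n")
  cat(sprintf("  intercept: %.4f\n", x$intercept))
  for (i in seq_along(x$slopes))
    cat(sprintf("  %s: slope %.4f (SE %.4f, p %.3g)\n", x$predictor_ids[i],
                x$slopes[i], x$se[i], x$p_values[i]))
  cat(sprintf("  R-squared: %.4f\n", x$r_squared))
  invisible(x)
}

#' Single-chromosome depression fits
#'
#' One single-predictor regression of the corrected phenotype on FROH-CHR per
#' chromosome. For the X chromosome only females enter the model (male X is
#' missing by convention). A chromosome whose FROH-CHR has zero variance (or
#' too few informative animals) is skipped and recorded as \code{NULL}.
#'
#' @param y corrected phenotype vector aligned with \code{records} rows.
#' @param records data.frame from [compute_froh()].
#' @return named list, one [fit_depression()] result (or \code{NULL}) per
#'   \code{froh_chr*} column.
#' @export
per_chromosome_fits <- function(y, records) {
  cols <- grep("^froh_chr", names(records), value = TRUE)
  out <- vector("list", length(cols))
  names(out) <- cols
  for (cc in cols) {
    f <- records[[cc]]
    ok <- !is.na(f) & !is.na(y)
    if (sum(ok) < 3 || stats::sd(f[ok]) == 0) next  # stays NULL (absent)
    out[[cc]] <- fit_depression(y[ok], matrix(f[ok], ncol = 1,
                                              dimnames = list(NULL, cc)))
  }
  out
}

#' Tukey honest-significant-difference comparison with letter display
#'
#' Pairwise studentized-range tests between group means at family level
#' \code{alpha}, plus a compact letter display built by the greedy
#' insert-and-absorb algorithm with groups ordered by decreasing mean. Two
#' groups share no letter exactly when their pairwise adjusted p-value is
#' below \code{alpha}.
#'
#' @param samples named list of numeric vectors (e.g., per-model accuracy
#'   samples across cross-validation rounds).
#' @param alpha family-wise significance level, default 0.05.
#' @return list of class \code{tukey_result} with \code{group_ids},
#'   \code{group_means}, \code{group_sds}, \code{p_values} (symmetric
#'   matrix), \code{letters} (named character vector).
#' @export
tukey_compare <- function(samples, alpha = 0.05) {
  stopifnot(length(samples) >= 2, all(lengths(samples) >= 2))
  ids <- names(samples)
  if (is.null(ids)) ids <- paste0("group", seq_along(samples))
  d <- data.frame(value = unlist(samples, use.names = FALSE),
                  group = factor(rep(ids, lengths(samples)), levels = ids))
  fit <- stats::aov(value ~ group, data = d)
  tk <- stats::TukeyHSD(fit)$group
  pm <- matrix(1, length(ids), length(ids), dimnames = list(ids, ids))
  for (r in rownames(tk)) {
    pair <- strsplit(r, "-", fixed = TRUE)[[1]]
    pm[pair[1], pair[2]] <- pm[pair[2], pair[1]] <- tk[r, "p adj"]
  }
  pm[is.na(pm)] <- 1  # degenerate zero-variance comparisons: no evidence
  means <- vapply(samples, mean, numeric(1))
  sds <- vapply(samples, stats::sd, numeric(1))
  letters_out <- .letter_display(pm, means, alpha)
  structure(list(group_ids = ids, group_means = means, group_sds = sds,
                 p_values = pm, letters = letters_out, alpha = alpha),
            class = "tukey_result")
}

# compact letter display: insert-and-absorb (Piepho-style greedy), groups
# ordered by decreasing mean
.letter_display <- function(pmat, means, alpha) {
  ids <- names(means)[order(-means)]
  cols <- list(ids)  # start with one column containing every group
  pairs <- utils::combn(ids, 2, simplify = FALSE)
  for (pr in pairs) {
    if (pmat[pr[1], pr[2]] >= alpha) next
    for (k in seq_along(cols)) {
      col <- cols[[k]]
      if (all(pr %in% col)) {
        cols[[k]] <- setdiff(col, pr[1])
        cols[[length(cols) + 1L]] <- setdiff(col, pr[2])
      }
    }
    # absorb columns that are subsets of another
    keep <- rep(TRUE, length(cols))
    for (i in seq_along(cols)) for (j in seq_along(cols)) {
      if (i != j && keep[i] && keep[j] &&
          all(cols[[i]] %in% cols[[j]]) &&
          (length(cols[[i]]) < length(cols[[j]]) || i > j)) keep[i] <- FALSE
    }
    cols <- cols[keep]
  }
  # order columns by the best-ranked member so letters read along the means
  first_rank <- vapply(cols, function(col) min(match(col, ids)), numeric(1))
  cols <- cols[order(first_rank)]
  out <- stats::setNames(rep("", length(ids)), ids)
  for (k in seq_along(cols))
    for (g in cols[[k]]) out[g] <- paste0(out[g], letters[k])
  out[names(means)]
}

#' @export
print.tukey_result <- function(x, ...) {
  df <- data.frame(group = x$group_ids,
                   mean = round(x$group_means, 4),
                   sd = round(x$group_sds, 4),
                   letters = x$letters[x$group_ids])
  print(df, row.names = FALSE)
  invisible(x)
}

#' Write Tukey letters as CSV
#' @param tk a [tukey_compare()] result.
#' @param path output file.
#' @export
write_tukey <- function(tk, path) {
  utils::write.csv(
    data.frame(group = tk$group_ids, mean = tk$group_means,
               sd = tk$group_sds, letters = tk$letters[tk$group_ids]),
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Serialize depression fits as JSON
#' @param fits a [fit_depression()] result or a list of them.
#' @param path output file.
#' @export
write_fits <- function(fits, path) {
  strip <- function(f) {
    if (is.null(f)) return(NULL)
    lapply(unclass(f), function(v) if (is.numeric(v)) unname(v) else v)
  }
  obj <- if (inherits(fits, "depression_fit")) strip(fits) else lapply(fits, strip)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
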