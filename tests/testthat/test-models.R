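test_that("phenotype correction removes sex and year means", {
  # same sex, same year: residuals are centered raw values
  ph <- data.frame(animal = paste0("a", 1:6), sex = "M",
                   year_of_birth = 2000,
                   adg_raw = c(0.7, 0.8, 0.9, 1.0, 1.1, 1.2))
  expect_warning(expect_warning(out <- correct_phenotypes(ph),
                                "sex"), "year")
  expect_equal(out$adg_corrected, ph$adg_raw - mean(ph$adg_raw))

  # two sexes, deterministic effects: residuals all zero
  ph2 <- data.frame(animal = paste0("b", 1:8),
                    sex = rep(c("M", "F"), each = 4),
                    year_of_birth = 2000,
                    adg_raw = rep(c(1.0, 0.6), each = 4))
  expect_warning(out2 <- correct_phenotypes(ph2), "year")
  expect_equal(out2$adg_corrected, rep(0, 8), tolerance = 1e-12)

  # noisy sex/year effects: residuals orthogonal to the design
  set.seed(51)
  n <- 120
  ph3 <- data.frame(animal = paste0("c", 1:n),
                    sex = sample(c("M", "F"), n, TRUE),
                    year_of_birth = sample(2000:2004, n, TRUE))
  ph3$adg_raw <- 0.8 + 0.2 * (ph3$sex == "M") +
    0.05 * (ph3$year_of_birth - 2002) + stats::rnorm(n, 0, 0.1)
  out3 <- correct_phenotypes(ph3)
  expect_lt(abs(mean(out3$adg_corrected)), 1e-10)
  expect_lt(abs(stats::cor(out3$adg_corrected, ph3$sex == "M")), 1e-10)
  for (yr in 2000:2004)
    expect_lt(abs(stats::cor(out3$adg_corrected, ph3$year_of_birth == yr)),
              1e-10)
})

test_that("depression regression recovers planted coefficients", {
  set.seed(61)
  f <- stats::runif(50, 0, 0.5)
  fit <- fit_depression(-0.9 * f, f, predictor_ids = "FROH")
  expect_equal(unname(fit$slopes), -0.9, tolerance = 1e-10)
  expect_equal(fit$r_squared, 1, tolerance = 1e-10)
  expect_equal(fit$predictor_ids, "FROH")

  expect_error(fit_depression(f, rep(0.3, 50)), "zero-variance")
  expect_error(fit_depression(f, cbind(a = f, b = 2 * f)), "collinear")
})

test_that("OLS estimates match the normal-equations closed form", {
  set.seed(71)
  n <- 80
  F <- cbind(f1 = stats::runif(n), f2 = stats::runif(n))
  y <- 0.5 - 0.4 * F[, 1] + 0.2 * F[, 2] + stats::rnorm(n, 0, 0.1)
  fit <- fit_depression(y, F)
  X <- cbind(1, F)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  expect_equal(unname(c(fit$intercept, fit$slopes)), as.vector(beta),
               tolerance = 1e-10)
  # classical standard errors
  res <- y - X %*% beta
  s2 <- sum(res^2) / (n - 3)
  se <- sqrt(diag(solve(t(X) %*% X)) * s2)
  expect_equal(unname(fit$se), unname(se[-1]), tolerance = 1e-10)
  # p-values are two-sided t tests
  tv <- beta[2] / se[2]
  expect_equal(unname(fit$p_values[1]),
               unname(2 * stats::pt(abs(tv), n - 3, lower.tail = FALSE)),
               tolerance = 1e-12)
})

test_that("slope estimates fall within 3 SE of truth at the usual rate", {
  set.seed(81)
  n <- 500
  hits <- 0L
  for (r in 1:60) {
    f <- stats::runif(n, 0, 0.5)
    y <- 0.8 - 1.0 * f + stats::rnorm(n, 0, 0.3)
    fit <- fit_depression(y, f)
    if (abs(fit$slopes[1] - (-1.0)) <= 3 * fit$se[1]) hits <- hits + 1L
  }
  expect_gte(hits / 60, 0.95)
})

test_that("correction then regression matches the joint fit on balanced data", {
  # balanced sex x F design: Frisch-Waugh makes the two-step slope equal the
  # joint-model slope
  set.seed(91)
  n <- 100
  sex <- rep(c("M", "F"), each = n / 2)
  f <- rep(stats::runif(n / 2, 0, 0.5), 2)  # identical F within both sexes
  y <- 0.8 + 0.2 * (sex == "M") - 0.7 * f + stats::rnorm(n, 0, 0.05)
  ph <- data.frame(animal = paste0("a", 1:n), sex = sex,
                   year_of_birth = 2000, adg_raw = y)
  expect_warning(corr <- correct_phenotypes(ph), "year")
  two_step <- fit_depression(corr$adg_corrected, f)$slopes[1]
  joint <- stats::coef(stats::lm(y ~ sex + f))["f"]
  expect_equal(unname(two_step), unname(joint), tolerance = 1e-8)
})

test_that("per-chromosome fits skip flat chromosomes and use females for X", {
  set.seed(101)
  n <- 60
  rec <- data.frame(animal = paste0("a", 1:n),
                    sex = rep(c("M", "F"), n / 2),
                    froh_chr1 = stats::runif(n, 0, 0.4),
                    froh_chr2 = rep(0.2, n),            # zero variance
                    froh_chr30 = stats::runif(n, 0, 0.4))
  rec$froh_chr30[rec$sex == "M"] <- NA                  # male X missing
  y <- -0.5 * rec$froh_chr1 + stats::rnorm(n, 0, 0.05)
  fits <- per_chromosome_fits(y, rec)
  expect_length(fits, 3)
  expect_null(fits$froh_chr2)
  expect_equal(fits$froh_chr30$n, sum(rec$sex == "F"))
  expect_lt(abs(fits$froh_chr1$slopes[1] - (-0.5)), 0.2)
})

test_that("null per-chromosome p-values are close to uniform", {
  set.seed(111)
  pvals <- c()
  for (r in 1:40) {
    n <- 80
    rec <- as.data.frame(matrix(stats::runif(n * 8, 0, 0.4), n, 8))
    names(rec) <- paste0("froh_chr", 1:8)
    y <- stats::rnorm(n)
    fits <- per_chromosome_fits(y, rec)
    pvals <- c(pvals, vapply(fits, function(f) unname(f$p_values[1]),
                             numeric(1)))
  }
  ks <- stats::ks.test(pvals, "punif")
  expect_gt(ks$p.value, 1e-3)
})

test_that("Tukey comparison and letter display behave like the classics", {
  set.seed(121)
  # two samples with identical values: p = 1, shared letter
  s <- list(a = c(1, 2, 3, 4), b = c(1, 2, 3, 4))
  tk <- tukey_compare(s)
  expect_equal(tk$p_values["a", "b"], 1)
  expect_true(any(strsplit(tk$letters["a"], "")[[1]] %in%
                    strsplit(tk$letters["b"], "")[[1]]))

  # far-separated samples: tiny p, disjoint letters
  s2 <- list(lo = stats::rnorm(500, 0, 1), hi = stats::rnorm(500, 10, 1))
  tk2 <- tukey_compare(s2)
  expect_lt(tk2$p_values["lo", "hi"], 1e-6)
  expect_false(any(strsplit(tk2$letters["lo"], "")[[1]] %in%
                     strsplit(tk2$letters["hi"], "")[[1]]))

  # three-group fixture: p equals an independent studentized-range computation
  g <- list(g1 = stats::rnorm(30, 0, 1), g2 = stats::rnorm(30, 0.5, 1),
            g3 = stats::rnorm(30, 2, 1))
  tk3 <- tukey_compare(g)
  allv <- unlist(g)
  grp <- rep(names(g), lengths(g))
  mse <- sum(unlist(lapply(g, function(v) (v - mean(v))^2))) /
    (length(allv) - 3)
  for (pr in list(c("g1", "g2"), c("g1", "g3"), c("g2", "g3"))) {
    q <- abs(mean(g[[pr[1]]]) - mean(g[[pr[2]]])) / sqrt(mse / 30)
    p_ref <- stats::ptukey(q, nmeans = 3, df = length(allv) - 3,
                           lower.tail = FALSE)
    expect_equal(tk3$p_values[pr[1], pr[2]], p_ref, tolerance = 1e-10)
  }
})

test_that("letter display shares a letter iff the pair is not significant", {
  set.seed(131)
  for (r in 1:20) {
    k <- sample(3:7, 1)
    samples <- lapply(seq_len(k),
                      function(i) stats::rnorm(40, mean = sample(0:3, 1),
                                               sd = 1))
    names(samples) <- paste0("m", seq_len(k))
    tk <- tukey_compare(samples)
    for (i in 1:(k - 1)) for (j in (i + 1):k) {
      a <- names(samples)[i]; b <- names(samples)[j]
      share <- any(strsplit(tk$letters[a], "")[[1]] %in%
                     strsplit(tk$letters[b], "")[[1]])
      expect_equal(share, tk$p_values[a, b] >= 0.05)
    }
  }
})
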