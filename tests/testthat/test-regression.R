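test_that("standardize z-scores columns and rejects constants", {
  set.seed(40)
  df <- data.frame(x = rnorm(50, 10, 3), y = rnorm(50))
  out <- standardize(df, c("x", "y"))
  expect_equal(mean(out$x), 0, tolerance = 1e-12)
  expect_equal(sd(out$x), 1, tolerance = 1e-12)
  already <- standardize(out, "x")
  expect_equal(already$x, out$x, tolerance = 1e-12)
  # affine invariance: z(3x + 7) == z(x)
  df$z <- 3 * df$x + 7
  out <- standardize(df, c("x", "z"))
  expect_equal(out$z, out$x, tolerance = 1e-12)
  df$c <- 5
  expect_error(standardize(df, "c"), "'c' has zero variance")
})

test_that("OLS reports standardized betas matching the normal equations", {
  set.seed(41)
  n <- 200
  df <- data.frame(x1 = rnorm(n), x2 = rnorm(n))
  df$y <- 1.5 * df$x1 - 0.7 * df$x2 + rnorm(n, sd = 2)
  fit <- ols_fit(df, "y", c("x1", "x2"))
  # oracle: solve the normal equations on the z-scored design directly
  z <- scale(as.matrix(df))
  beta <- solve(crossprod(z[, 1:2]), crossprod(z[, 1:2], z[, 3]))
  expect_equal(unname(fit$beta_std), as.vector(beta), tolerance = 1e-10)
  expect_true(all(fit$p_values >= 0 & fit$p_values <= 1))
  expect_gte(fit$rss, 0)
})

test_that("noiseless responses give a perfect fit", {
  set.seed(42)
  df <- data.frame(x = rnorm(50))
  df$y <- 2 * df$x + 3
  fit <- ols_fit(df, "y", "x")
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)
  expect_lt(fit$rss, 1e-9)
  expect_equal(unname(fit$beta_std), 1, tolerance = 1e-9)
  # standardized response on itself: beta exactly 1
  df$y2 <- df$x
  expect_equal(unname(ols_fit(df, "y2", "x")$beta_std), 1, tolerance = 1e-12)
})

test_that("simulated effects are recovered within sampling error", {
  set.seed(43)
  n <- 500
  x1 <- rnorm(n)
  # noise SD chosen for a population R^2 of 0.25 with beta = 0.5
  y <- 0.5 * x1 + rnorm(n, sd = sqrt(0.75))
  df <- data.frame(y = y, x1 = x1)
  fit <- ols_fit(df, "y", "x1")
  expect_lt(abs(fit$beta_std[["x1"]] - 0.5), 0.1)
})

test_that("collinear designs are rejected with the offending column", {
  set.seed(44)
  df <- data.frame(x1 = rnorm(30))
  df$x2 <- 2 * df$x1
  df$y <- rnorm(30)
  expect_error(ols_fit(df, "y", c("x1", "x2")), "x2")
})

test_that("forward selection starts from the best single predictor", {
  set.seed(45)
  n <- 120
  df <- data.frame(a = rnorm(n), b = rnorm(n), c = rnorm(n), d = rnorm(n))
  df$y <- 0.6 * df$b - 0.4 * df$d + rnorm(n)
  pool <- c("a", "b", "c", "d")
  single_p <- vapply(pool, function(v)
    ols_fit(df, "y", v)$p_values[[v]], numeric(1))
  fit <- forward_select(df, "y", pool)
  expect_equal(fit$predictors[1], names(which.min(single_p)))
  expect_true(all(c("b", "d") %in% fit$predictors))
  expect_error(forward_select(df, "y", character(0)), "empty")
})

test_that("pure-noise pools mostly select nothing", {
  n <- 200
  outcomes <- integer(100)
  for (s in 1:100) {
    set.seed(1000 + s)
    df <- as.data.frame(matrix(rnorm(n * 5), n, 5))
    df$y <- rnorm(n)
    fit <- forward_select(df, "y", paste0("V", 1:5))
    outcomes[s] <- length(fit$predictors)
  }
  # intercept-only is the modal outcome and spurious runs stay short
  expect_equal(as.integer(names(which.max(table(outcomes)))), 0L)
  expect_gte(mean(outcomes == 0), 0.5)
})

test_that("a strong true effect is found almost always", {
  hits <- logical(100)
  for (s in 1:100) {
    set.seed(2000 + s)
    n <- 100
    df <- as.data.frame(matrix(rnorm(n * 4), n, 4))
    df$x <- rnorm(n)
    df$y <- 0.8 * df$x + rnorm(n, sd = sqrt(1 - 0.8^2))
    fit <- forward_select(df, "y", c("x", paste0("V", 1:4)))
    hits[s] <- length(fit$predictors) >= 1 && fit$predictors[1] == "x"
  }
  expect_gte(sum(hits), 95)
})

test_that("two-stage selection respects pools and nesting", {
  set.seed(46)
  gc <- gen_cohort(seed = 46)
  expect_error(two_stage_select(gc$table, "crst_t_change",
                                c("age", "sdr_sd"), c("sdr_sd")),
               "overlap")
  res <- two_stage_select(gc$table, "crst_t_change", gc$patient_pool,
                          gc$treatment_pool)
  expect_true(all(res$baseline$predictors %in% gc$patient_pool))
  expect_true(all(res$baseline$predictors %in% res$extended$predictors))
  expect_lte(res$extended$rss, res$baseline$rss + 1e-12)
  # empty treatment pool: flagged identical models
  res0 <- two_stage_select(gc$table, "crst_t_change", gc$patient_pool,
                           character(0))
  expect_true(res0$comparison$identical_models)
  expect_true(is.na(res0$comparison$f))
})

test_that("two-stage selection recovers one effect per stage", {
  wins <- 0L
  for (s in 1:100) {
    set.seed(3000 + s)
    n <- 100
    df <- data.frame(pat = rnorm(n), pat2 = rnorm(n),
                     trt = rnorm(n), trt2 = rnorm(n))
    df$y <- 0.6 * df$pat + 0.6 * df$trt + rnorm(n, sd = sqrt(1 - 0.72))
    res <- two_stage_select(df, "y", c("pat", "pat2"), c("trt", "trt2"))
    wins <- wins + ("pat" %in% res$baseline$predictors &&
                    "trt" %in% setdiff(res$extended$predictors,
                                       res$baseline$predictors))
  }
  expect_gte(wins, 90)
})

test_that("nested ANOVA matches R's anova() and flags misuse", {
  set.seed(47)
  n <- 60
  df <- data.frame(x1 = rnorm(n), x2 = rnorm(n))
  df$y <- 0.5 * df$x1 + rnorm(n)
  small <- ols_fit(df, "y", "x1")
  large <- ols_fit(df, "y", c("x1", "x2"))
  cmp <- anova_compare(small, large)
  # independent route: R's own nested-model ANOVA on the z-scored fits
  z <- as.data.frame(scale(df[c("y", "x1", "x2")]))
  ref <- anova(lm(y ~ x1, z), lm(y ~ x1 + x2, z))
  expect_equal(cmp$f, ref$F[2], tolerance = 1e-9)
  expect_equal(cmp$p, ref$`Pr(>F)`[2], tolerance = 1e-9)
  expect_error(anova_compare(small, small), "identical")
  other <- ols_fit(df, "y", "x2")
  expect_error(anova_compare(other, large), NA)  # x2 subset of {x1,x2}: nested
  expect_error(anova_compare(large, small), "not nested")
})

test_that("adding true signal yields decisive nested-model p-values", {
  hits <- 0L
  for (s in 1:100) {
    set.seed(4000 + s)
    n <- 80
    df <- data.frame(x1 = rnorm(n), x2 = rnorm(n))
    df$y <- 0.4 * df$x1 + 0.7 * df$x2 + rnorm(n, sd = 0.6)
    cmp <- anova_compare(ols_fit(df, "y", "x1"),
                         ols_fit(df, "y", c("x1", "x2")))
    hits <- hits + (cmp$p < 0.001)
  }
  expect_gte(hits, 95)
})

test_that("pearson matches its closed forms and the single-predictor R^2", {
  x <- c(1, 3, 4, 7, 9, 11)
  expect_equal(pearson(x, x)$r, 1)
  expect_equal(pearson(x, -x)$r, -1)
  set.seed(48)
  a <- rnorm(40); b <- 0.3 * a + rnorm(40)
  p <- pearson(a, b)
  fit <- ols_fit(data.frame(a = a, b = b), "b", "a")
  expect_equal(p$r_squared, fit$r_squared, tolerance = 1e-10)
  ct <- cor.test(a, b)
  expect_equal(p$p, ct$p.value)
  expect_error(pearson(a, rep(1, 40)), "zero-variance")
  expect_error(pearson(1:2, 1:2), "length >= 3")
})

test_that("large-sample correlation estimates hit the generative rho", {
  set.seed(49)
  n <- 10000
  rho <- 0.473
  x <- rnorm(n)
  y <- rho * x + sqrt(1 - rho^2) * rnorm(n)
  expect_lt(abs(pearson(x, y)$r - rho), 0.03)
})
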