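test_that("Gaussian random-intercept ML fit tracks the ANOVA estimator", {
  set.seed(71)
  n_g <- 400; k <- 5
  g <- rep(seq_len(n_g), each = k)
  y <- stats::rnorm(n_g)[g] + stats::rnorm(n_g * k)
  fit <- fit_lmm_random_intercept(y, group = g)
  # balanced one-way method-of-moments oracle
  gm <- tapply(y, g, mean)
  msb <- k * stats::var(gm)
  msw <- sum((y - gm[g])^2) / (n_g * k - n_g)
  vi_mom <- (msb - msw) / k
  # ML differs from the moment estimator by an O(1/n_groups) shrinkage
  expect_equal(fit$ranef_variances[["individual"]], vi_mom, tolerance = 5e-3)
  expect_equal(fit$ranef_variances[["residual"]], msw, tolerance = 5e-3)
})

test_that("variance components recover planted ratios and vanish under the null", {
  set.seed(72)
  g <- rep(1:500, each = 3)
  y0 <- stats::rnorm(1500)                      # no between-group signal
  f0 <- fit_lmm_random_intercept(y0, group = g)
  expect_lt(f0$ranef_variances[["individual"]], 0.05)
  y1 <- stats::rnorm(500)[g] + stats::rnorm(1500)  # 1:1 variance ratio
  f1 <- fit_lmm_random_intercept(y1, group = g)
  expect_equal(f1$ranef_variances[["individual"]], 1, tolerance = 0.15)
  expect_equal(f1$ranef_variances[["residual"]], 1, tolerance = 0.15)
})

test_that("repeatability is the variance ratio and ignores affine changes", {
  set.seed(73)
  g <- rep(1:60, each = 3)
  y <- stats::rnorm(60, sd = 1)[g] + stats::rnorm(180, sd = 1)
  fit <- fit_lmm_random_intercept(y, group = g)
  r <- repeatability(fit, n_boot = 50, seed = 1)
  vi <- fit$ranef_variances[["individual"]]; vr <- fit$ranef_variances[["residual"]]
  expect_equal(r$r, vi / (vi + vr))
  expect_gte(r$r, 0); expect_lte(r$r, 1)
  expect_true(r$ci[1] <= r$r && r$r <= r$ci[2])
  expect_gt(r$se, 0)
  fit2 <- fit_lmm_random_intercept(3 * y + 7, group = g)
  r2 <- repeatability(fit2, n_boot = 0)
  expect_equal(r2$r, r$r, tolerance = 1e-6)
})

test_that("logistic regression hits closed forms and flags separation", {
  y <- c(rep(1, 30), rep(0, 70))
  f <- fit_glm_binomial(y)
  expect_equal(unname(f$coefficients[1]), log(3 / 7), tolerance = 1e-9)
  # 2x2 table with odds ratio 4
  x <- rep(c(0, 1), each = 30)
  y2 <- c(rep(1, 10), rep(0, 20), rep(1, 20), rep(0, 10))
  f2 <- fit_glm_binomial(y2, data.frame(x = x))
  expect_equal(unname(f2$coefficients["x"]), log(4), tolerance = 1e-8)
  expect_error(fit_glm_binomial(rep(1, 40)), "separation")
  expect_error(fit_glm_binomial(c(0, 1, 0, 1, 0, 1, 0, 1),
                                data.frame(x = c(1, 2, 1, 2, 1, 2, 1, 2) +
                                             c(0, 10, 0, 10, 0, 10, 0, 10))),
               "separation")
})

test_that("binomial GLMM collapses to the GLM when group variance is zero", {
  set.seed(74)
  x <- stats::rnorm(600)
  y <- stats::rbinom(600, 1, stats::plogis(0.3 + 0.8 * x))
  g <- rep(1:40, each = 15)
  glmm <- suppressMessages(fit_glmm_binomial(y, data.frame(x = x), group = g))
  glm0 <- fit_glm_binomial(y, data.frame(x = x))
  expect_lt(glmm$ranef_variances[["group"]], 1e-6)
  expect_equal(unname(glmm$coefficients), unname(glm0$coefficients),
               tolerance = 1e-4)
  expect_equal(glmm$logLik, glm0$logLik, tolerance = 1e-6)
})

test_that("binomial GLMM recovers a planted random-intercept variance", {
  set.seed(75)
  ests <- replicate(10, {
    n_g <- 100; k <- 20
    g <- rep(seq_len(n_g), each = k)
    b <- stats::rnorm(n_g, sd = 1)
    x <- stats::rnorm(n_g * k)
    y <- stats::rbinom(n_g * k, 1, stats::plogis(0.2 + 0.5 * x + b[g]))
    fit <- suppressMessages(fit_glmm_binomial(y, data.frame(x = x), group = g))
    c(fit$ranef_variances[["group"]], unname(fit$coefficients["x"]))
  })
  expect_equal(mean(ests[1, ]), 1, tolerance = 0.3)
  expect_equal(mean(ests[2, ]), 0.5, tolerance = 0.15)
})

test_that("Gauss-Hermite rule integrates exactly on known cases", {
  gh <- boldtrack:::gauss_hermite(2)
  expect_equal(sort(gh$nodes), c(-1, 1) / sqrt(2), tolerance = 1e-12)
  expect_equal(gh$weights, rep(sqrt(pi) / 2, 2), tolerance = 1e-12)
  gh7 <- boldtrack:::gauss_hermite(7)
  expect_equal(sum(gh7$weights), sqrt(pi), tolerance = 1e-10)
  expect_equal(sum(gh7$weights * gh7$nodes^2), sqrt(pi) / 2, tolerance = 1e-10)
  expect_equal(sum(gh7$weights * gh7$nodes^4), 3 * sqrt(pi) / 4, tolerance = 1e-9)
})

test_that("ordinal fit reproduces closed-form thresholds and the binary case", {
  y <- factor(rep(c("shelf", "shelf_edge", "oceanic"), times = c(30, 50, 20)),
              levels = c("shelf", "shelf_edge", "oceanic"), ordered = TRUE)
  f <- fit_ordinal(y)
  expect_equal(unname(f$coefficients[c("theta1", "theta2")]),
               stats::qlogis(c(0.3, 0.8)), tolerance = 1e-4)
  set.seed(76)
  x <- stats::rnorm(200)
  yb <- stats::rbinom(200, 1, stats::plogis(-0.4 + 1.1 * x))
  fo <- fit_ordinal(factor(yb, ordered = TRUE), data.frame(x = x))
  fg <- fit_glm_binomial(yb, data.frame(x = x))
  expect_equal(fo$logLik, fg$logLik, tolerance = 1e-6)
  expect_equal(unname(fo$coefficients["x"]), unname(fg$coefficients["x"]),
               tolerance = 1e-4)
  expect_equal(unname(fo$coefficients["theta1"]),
               -unname(fg$coefficients["(Intercept)"]), tolerance = 1e-4)
})

test_that("ordinal ML matches the reference proportional-odds implementation", {
  skip_if_not_installed("MASS")
  set.seed(77)
  n <- 300
  x1 <- stats::rnorm(n); x2 <- stats::rnorm(n)
  eta <- 0.9 * x1 - 0.6 * x2
  u <- stats::runif(n)
  cum <- stats::plogis(outer(c(-0.8, 0.9), eta, "-"))
  yi <- 1L + colSums(u > cum)
  y <- factor(c("a", "b", "c")[yi], levels = c("a", "b", "c"), ordered = TRUE)
  mine <- fit_ordinal(y, data.frame(x1 = x1, x2 = x2))
  ref <- MASS::polr(y ~ x1 + x2, method = "logistic")
  expect_equal(mine$logLik, as.numeric(stats::logLik(ref)), tolerance = 1e-6)
  expect_equal(unname(mine$coefficients[c("x1", "x2")]),
               unname(stats::coef(ref)), tolerance = 1e-3)
  expect_equal(unname(mine$coefficients[c("theta1", "theta2")]),
               unname(ref$zeta), tolerance = 1e-3)
})

test_that("mixed ordinal models recover slope sign with near-nominal coverage", {
  set.seed(78)
  hits <- 0; covered <- 0; n_rep <- 25
  for (rep in seq_len(n_rep)) {
    n_g <- 30; k <- 6
    g <- rep(seq_len(n_g), each = k)
    x <- stats::rnorm(n_g * k)
    b <- stats::rnorm(n_g, sd = 0.7)
    eta <- 1.0 * x + b[g]
    u <- stats::runif(n_g * k)
    cum <- stats::plogis(outer(c(-0.7, 0.8), eta, "-"))
    y <- factor(1L + colSums(u > cum), levels = 1:3, ordered = TRUE)
    fit <- fit_ordinal(y, data.frame(x = x), group = g, n_nodes = 15)
    est <- unname(fit$coefficients["x"]); se <- unname(fit$se["x"])
    hits <- hits + (est > 0)
    if (is.finite(se)) covered <- covered + (abs(est - 1.0) <= 1.96 * se)
  }
  expect_equal(hits, n_rep)
  expect_gte(covered / n_rep, 0.8)
})

test_that("nested-pair ordinal Laplace stays close to the single-factor fit", {
  set.seed(79)
  n_g <- 25; k <- 8
  g <- rep(seq_len(n_g), each = k)
  g2 <- rep(seq_len(n_g * 2), each = k / 2)     # trips nested in birds
  x <- stats::rnorm(n_g * k)
  b <- stats::rnorm(n_g, sd = 0.8)
  eta <- 0.8 * x + b[g]
  u <- stats::runif(n_g * k)
  cum <- stats::plogis(outer(c(-0.7, 0.8), eta, "-"))
  y <- factor(1L + colSums(u > cum), levels = 1:3, ordered = TRUE)
  one <- fit_ordinal(y, data.frame(x = x), group = g, n_nodes = 25)
  two <- fit_ordinal(y, data.frame(x = x), group = g, group2 = g2)
  expect_equal(unname(two$coefficients["x"]), unname(one$coefficients["x"]),
               tolerance = 0.15)
  expect_gte(two$logLik, one$logLik - 2)   # extra variance can only help (approx.)
  expect_error(fit_ordinal(y, data.frame(x = x), group = g2, group2 = g),
               "nested")
})

test_that("likelihood-ratio tests compare nested ML fits", {
  set.seed(80)
  x <- stats::rnorm(200)
  y <- stats::rbinom(200, 1, stats::plogis(0.2))
  full <- fit_glm_binomial(y, data.frame(x = x))
  red <- fit_glm_binomial(y)
  out <- lrt(full, red)
  expect_equal(out$df, 1)
  expect_gte(out$chi2, 0)
  expect_equal(out$p, stats::pchisq(out$chi2, 1, lower.tail = FALSE))
  # equal likelihoods (an uninformative extra parameter): chi2 = 0, p = 1
  mk <- boldtrack:::new_model_fit
  a <- mk("binomial", c(b0 = 0, b1 = 0), numeric(0), -120.5, 200, 2)
  b <- mk("binomial", c(b0 = 0), numeric(0), -120.5, 200, 1)
  nothing <- lrt(a, b)
  expect_equal(nothing$chi2, 0)
  expect_equal(nothing$p, 1)
  # tiny numerically-negative statistics clamp to zero
  b2 <- mk("binomial", c(b0 = 0), numeric(0), -120.5 + 1e-9, 200, 1)
  expect_equal(lrt(a, b2)$chi2, 0)
  expect_error(lrt(red, full), "more parameters")
  expect_error(lrt(full, fit_glm_binomial(y[1:100])), "different numbers of rows")
})

test_that("SSTa banding follows the year-quality tercile bounds", {
  expect_equal(as.character(ssta_band(c(-0.5, -0.2, 0.0))),
               c("low", "medium", "high"))
  expect_equal(as.character(ssta_band(-0.36)), "low")
  expect_equal(as.character(ssta_band(-0.15)), "medium")
})

test_that("fitness analysis tests the 4-df interaction and checks inputs", {
  cfg <- sim_config(seed = 81, n_breeding_birds = 40L, years = 12L)
  scores <- data.frame(bird_id = sprintf("b%03d", 1:40),
                       score = stats::rnorm(40),
                       sex = rep(c("female", "male"), 20))
  br <- simulate_breeding(cfg, scores)
  fa <- fitness_analysis(br$breeding, scores, br$ssta)
  expect_equal(fa$interaction$df, 4)
  expect_gte(fa$interaction$chi2, 0)
  expect_equal(fa$full$n, 40 * 12)
  bad_ssta <- br$ssta[-1, ]
  expect_error(fitness_analysis(br$breeding, scores, bad_ssta), "missing SSTa")
  sy <- fitness_analysis(br$breeding[br$breeding$year == br$ssta$year[1], ],
                         scores, single_year = TRUE)
  expect_equal(sy$score_sex$df, 1)
  expect_true(all(c("score", "sex", "score_sex") %in% names(sy)))
  cur <- fitness_curves(fa)
  expect_true(all(cur$pred >= 0 & cur$pred <= 1))
  expect_setequal(unique(cur$sex), c("female", "male"))
})
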