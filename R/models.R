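#' @importFrom lme4 lmer glmer fixef VarCorr refit
NULL

new_model_fit <- function(family, coefficients, ranef_variances, logLik, n, npar,
                          fit = NULL, converged = TRUE, extra = list()) {
  structure(c(list(family = family, coefficients = coefficients,
                   ranef_variances = ranef_variances, logLik = logLik,
                   n = n, npar = npar, fit = fit, converged = converged), extra),
            class = "model_fit")
}

#' @export
print.model_fit <- function(x, ...) {
  cat("<model_fit>", x$family, "| logLik (ML):", format(x$logLik, digits = 8),
      "| n =", x$n, "| npar =", x$npar, "\n")
  cat("fixed:\n"); print(x$coefficients)
  if (length(x$ranef_variances)) {
    cat("random-intercept variances:\n"); print(x$ranef_variances)
  }
  invisible(x)
}

.build_df <- function(y, fixed, ...) {
  d <- data.frame(.y = y)
  if (!is.null(fixed)) {
    fixed <- as.data.frame(fixed)
    stopifnot(nrow(fixed) == length(y))
    d <- cbind(d, fixed)
  }
  groups <- list(...)
  for (nm in names(groups)) if (!is.null(groups[[nm]])) d[[nm]] <- factor(groups[[nm]])
  d
}

#' Gaussian random-intercept model by maximum likelihood
#'
#' One grouping factor; unbalanced designs allowed.  Fitted with lme4 by ML
#' (not REML) so that fits are comparable by likelihood ratio.
#'
#' @param y numeric response.
#' @param fixed optional data.frame of fixed covariates.
#' @param group grouping factor (e.g. bird identity).
#' @return a `model_fit` with `var_individual` (between-group) and
#'   `var_residual` components.
#' @export
fit_lmm_random_intercept <- function(y, fixed = NULL, group) {
  d <- .build_df(y, fixed, .g = group)
  if (nlevels(d$.g) < 2) stop("need >= 2 groups")
  covs <- setdiff(names(d), c(".y", ".g"))
  rhs <- paste(c("1", covs, "(1 | .g)"), collapse = " + ")
  fit <- lme4::lmer(stats::as.formula(paste(".y ~", rhs)), data = d, REML = FALSE)
  vc <- as.data.frame(lme4::VarCorr(fit))
  vi <- vc$vcov[vc$grp == ".g"]
  vr <- vc$vcov[vc$grp == "Residual"]
  new_model_fit("gaussian", lme4::fixef(fit),
                c(individual = vi, residual = vr),
                as.numeric(stats::logLik(fit)), nrow(d),
                npar = length(lme4::fixef(fit)) + 2L, fit = fit,
                extra = list(data = d))
}

#' Repeatability (intra-class correlation) with parametric bootstrap
#'
#' r = between-individual variance / total variance from a Gaussian
#' random-intercept model.  The standard error and percentile confidence
#' interval come from a parametric bootstrap (simulate from the fitted
#' model, refit, recompute r); the p-value is a likelihood-ratio test of
#' zero between-individual variance against the boundary reference
#' distribution 0.5*chi2(0) + 0.5*chi2(1).
#'
#' @param fit a `model_fit` from [fit_lmm_random_intercept()].
#' @param n_boot bootstrap replicates (default 1000).
#' @param seed optional integer seed for the bootstrap.
#' @return list `r`, `se`, `ci` (2.5/97.5 percentiles), `p`,
#'   `var_individual`, `var_residual`, `n_boot`.
#' @export
repeatability <- function(fit, n_boot = 1000, seed = NULL) {
  stopifnot(inherits(fit, "model_fit"), fit$family == "gaussian")
  if (!is.null(seed)) set.seed(seed)
  vi <- fit$ranef_variances[["individual"]]
  vr <- fit$ranef_variances[["residual"]]
  r <- vi / (vi + vr)
  d <- fit$data
  covs <- setdiff(names(d), c(".y", ".g"))
  rhs0 <- paste(c("1", covs), collapse = " + ")
  null_fit <- stats::lm(stats::as.formula(paste(".y ~", rhs0)), data = d)
  chi2 <- max(0, 2 * (fit$logLik - as.numeric(stats::logLik(null_fit))))
  p <- if (chi2 <= 0) 1 else 0.5 * stats::pchisq(chi2, 1, lower.tail = FALSE)
  boot_r <- rep(NA_real_, n_boot)
  if (n_boot > 0) {
    sims <- stats::simulate(fit$fit, nsim = n_boot)
    for (b in seq_len(n_boot)) {
      rb <- try(lme4::refit(fit$fit, newresp = sims[[b]]), silent = TRUE)
      if (inherits(rb, "try-error")) next
      vcb <- as.data.frame(lme4::VarCorr(rb))
      vib <- vcb$vcov[vcb$grp == ".g"]
      vrb <- vcb$vcov[vcb$grp == "Residual"]
      boot_r[b] <- vib / (vib + vrb)
    }
    boot_r <- boot_r[!is.na(boot_r)]
  }
  list(r = r, se = if (length(boot_r)) stats::sd(boot_r) else NA_real_,
       ci = if (length(boot_r)) unname(stats::quantile(boot_r, c(0.025, 0.975)))
            else c(NA_real_, NA_real_),
       p = p, var_individual = vi, var_residual = vr,
       n_boot = length(boot_r))
}

#' Fixed-effects logistic regression
#'
#' @param y binary response (0/1 or logical).
#' @param fixed optional data.frame of covariates.
#' @return a `model_fit`.  Complete separation (diverging coefficients) is
#'   an error.
#' @export
fit_glm_binomial <- function(y, fixed = NULL) {
  d <- .build_df(as.numeric(y), fixed)
  covs <- setdiff(names(d), ".y")
  rhs <- paste(c("1", covs), collapse = " + ")
  fit <- suppressWarnings(stats::glm(stats::as.formula(paste(".y ~", rhs)),
                                     data = d, family = stats::binomial()))
  if (any(abs(stats::coef(fit)) > 15) || !fit$converged)
    stop("complete (or quasi-complete) separation detected in logistic fit")
  new_model_fit("binomial", stats::coef(fit), numeric(0),
                as.numeric(stats::logLik(fit)), nrow(d),
                npar = length(stats::coef(fit)), fit = fit,
                extra = list(data = d))
}

#' Random-intercept logistic regression
#'
#' Single grouping factor: adaptive Gauss-Hermite quadrature (default 15
#' nodes).  Two grouping factors (e.g. trip nested in bird): Laplace
#' approximation, the standard choice when quadrature is unavailable for
#' crossed/nested layouts.  ML estimates throughout.
#'
#' @param y binary response.
#' @param fixed optional data.frame of covariates.
#' @param group grouping factor.
#' @param group2 optional second factor nested within `group`.
#' @param nagq quadrature nodes for the single-factor case (default 15).
#' @return a `model_fit`.
#' @export
fit_glmm_binomial <- function(y, fixed = NULL, group, group2 = NULL, nagq = 15) {
  d <- .build_df(as.numeric(y), fixed, .g = group, .g2 = group2)
  covs <- setdiff(names(d), c(".y", ".g", ".g2"))
  if (is.null(group2)) {
    rhs <- paste(c("1", covs, "(1 | .g)"), collapse = " + ")
    fit <- lme4::glmer(stats::as.formula(paste(".y ~", rhs)), data = d,
                       family = stats::binomial(), nAGQ = nagq)
    rv <- c(group = unname(as.data.frame(lme4::VarCorr(fit))$vcov[1]))
  } else {
    tab <- table(d$.g2, d$.g)
    if (any(rowSums(tab > 0) > 1)) stop("group2 levels must be nested within group")
    rhs <- paste(c("1", covs, "(1 | .g)", "(1 | .g2)"), collapse = " + ")
    fit <- lme4::glmer(stats::as.formula(paste(".y ~", rhs)), data = d,
                       family = stats::binomial(), nAGQ = 1)
    vc <- as.data.frame(lme4::VarCorr(fit))
    rv <- c(group = vc$vcov[vc$grp == ".g"], group2 = vc$vcov[vc$grp == ".g2"])
  }
  conv <- length(fit@optinfo$conv$lme4) == 0
  new_model_fit("binomial", lme4::fixef(fit), rv,
                as.numeric(stats::logLik(fit)), nrow(d),
                npar = length(lme4::fixef(fit)) + length(rv), fit = fit,
                converged = conv, extra = list(data = d))
}

# ---- proportional-odds (cumulative logit) models -------------------------

# Gauss-Hermite nodes/weights for integrals against exp(-x^2) (physicists'
# convention), via the Golub-Welsch eigendecomposition of the Jacobi matrix.
gauss_hermite <- function(n) {
  if (n == 1) return(list(nodes = 0, weights = sqrt(pi)))
  i <- seq_len(n - 1)
  off <- sqrt(i / 2)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1)] <- off
  J[cbind(i + 1, i)] <- off
  e <- eigen(J, symmetric = TRUE)
  ord <- order(e$values)
  list(nodes = e$values[ord], weights = sqrt(pi) * e$vectors[1, ord]^2)
}

# log-likelihood contributions and eta-derivatives for cumulative logit
# y: integer category 1..K; eta: linear predictor; theta: K-1 thresholds
.ordinal_ll_parts <- function(y, eta, theta, deriv = FALSE) {
  K <- length(theta) + 1L
  up <- ifelse(y < K, theta[pmin(y, K - 1L)] - eta, Inf)
  lo <- ifelse(y > 1, theta[pmax(y - 1L, 1L)] - eta, -Inf)
  gup <- stats::plogis(up)
  glo <- stats::plogis(lo)
  p <- pmax(gup - glo, 1e-300)
  out <- list(ll = log(p), p = p)
  if (deriv) {
    dup <- ifelse(is.finite(up), stats::dlogis(up), 0)
    dlo <- ifelse(is.finite(lo), stats::dlogis(lo), 0)
    # d ll / d eta (eta enters as theta - eta)
    out$s <- (dlo - dup) / p
    # second derivative wrt eta
    ddup <- ifelse(is.finite(up), dup * (1 - 2 * gup), 0)
    ddlo <- ifelse(is.finite(lo), dlo * (1 - 2 * glo), 0)
    out$w <- -((ddup - ddlo) / p - out$s^2)   # -d2ll/deta2 >= 0
    out$dup <- dup; out$dlo <- dlo
  }
  out
}

.theta_from_zeta <- function(zeta) cumsum(c(zeta[1], exp(zeta[-1])))

#' Proportional-odds (cumulative logit) regression by maximum likelihood
#'
#' Ordered response with K categories and K-1 increasing thresholds; the
#' logit link is used.  Optionally a single random intercept, integrated by
#' Gauss-Hermite quadrature, or a nested pair of random intercepts (e.g.
#' trip within bird), integrated by a joint Laplace approximation over the
#' concave penalised log-likelihood.
#'
#' @param y ordered factor (>= 2 observed categories; empty categories are
#'   collapsed with a warning).
#' @param fixed optional data.frame of covariates.
#' @param group optional grouping factor for a random intercept.
#' @param group2 optional second factor nested within `group`.
#' @param n_nodes quadrature nodes for the single-factor case (default 31).
#' @return a `model_fit`; coefficients hold the slopes followed by the
#'   thresholds (`theta1..`); `se` holds slope standard errors from the
#'   inverse observed information.
#' @export
fit_ordinal <- function(y, fixed = NULL, group = NULL, group2 = NULL, n_nodes = 31) {
  y0 <- as.factor(y)
  y <- droplevels(y0)
  if (nlevels(y) < nlevels(y0)) warning("empty response categories collapsed")
  if (nlevels(y) < 2) stop("need >= 2 observed categories")
  yi <- as.integer(y)
  K <- nlevels(y)
  X <- if (is.null(fixed)) matrix(0, length(yi), 0) else
    stats::model.matrix(~ ., data = as.data.frame(fixed))[, -1, drop = FALSE]
  p <- ncol(X)
  # starts: thresholds at logits of cumulative frequencies, slopes at 0
  cf <- cumsum(tabulate(yi, K))[seq_len(K - 1)] / length(yi)
  theta0 <- stats::qlogis(pmin(pmax(cf, 1e-3), 1 - 1e-3))
  theta0 <- cummax(theta0 + seq(0, 1e-3, length.out = K - 1))  # ensure increasing
  zeta0 <- c(theta0[1], if (K > 2) log(pmax(diff(theta0), 1e-3)))
  has_g <- !is.null(group)
  has_g2 <- !is.null(group2)
  if (has_g2 && !has_g) stop("group2 given without group")
  if (!has_g) {
    obj <- function(par) {
      beta <- par[seq_len(p)]
      theta <- .theta_from_zeta(par[p + seq_len(K - 1)])
      -sum(.ordinal_ll_parts(yi, if (p) drop(X %*% beta) else 0, theta)$ll)
    }
    grad <- function(par) {
      beta <- par[seq_len(p)]
      zeta <- par[p + seq_len(K - 1)]
      theta <- .theta_from_zeta(zeta)
      eta <- if (p) drop(X %*% beta) else rep(0, length(yi))
      parts <- .ordinal_ll_parts(yi, eta, theta, deriv = TRUE)
      gbeta <- if (p) -drop(crossprod(X, parts$s)) else numeric(0)
      # d ll / d theta_m: +dup/p when y == m, -dlo/p when y == m+1
      gtheta <- numeric(K - 1)
      for (m in seq_len(K - 1)) {
        gtheta[m] <- sum(parts$dup[yi == m] / parts$p[yi == m]) -
          sum(parts$dlo[yi == m + 1] / parts$p[yi == m + 1])
      }
      J <- matrix(0, K - 1, K - 1)   # dtheta/dzeta
      J[, 1] <- 1
      if (K > 2) for (j in 2:(K - 1)) J[j:(K - 1), j] <- exp(zeta[j])
      c(gbeta, -drop(crossprod(J, gtheta)))
    }
    opt <- stats::optim(c(rep(0, p), zeta0), obj, grad, method = "BFGS",
                        control = list(maxit = 500, reltol = 1e-14), hessian = TRUE)
    theta <- .theta_from_zeta(opt$par[p + seq_len(K - 1)])
    co <- c(if (p) stats::setNames(opt$par[seq_len(p)], colnames(X)),
            stats::setNames(theta, paste0("theta", seq_len(K - 1))))
    se <- tryCatch(sqrt(diag(solve(opt$hessian)))[seq_len(p)],
                   error = function(e) rep(NA_real_, p))
    return(new_model_fit("ordinal", co, numeric(0), -opt$value, length(yi),
                         npar = p + K - 1, converged = opt$convergence == 0,
                         extra = list(se = stats::setNames(se, colnames(X)))))
  }
  g <- factor(group)
  if (has_g2) {
    g2 <- factor(group2)
    if (any(rowSums(table(g2, g) > 0) > 1)) stop("group2 levels must be nested within group")
  }
  if (!has_g2) {
    gh <- gauss_hermite(n_nodes)
    gi <- split(seq_along(yi), g)
    obj <- function(par) {
      beta <- par[seq_len(p)]
      theta <- .theta_from_zeta(par[p + seq_len(K - 1)])
      sigma <- exp(par[p + K])
      eta0 <- if (p) drop(X %*% beta) else rep(0, length(yi))
      ll <- 0
      for (idx in gi) {
        lk <- vapply(seq_along(gh$nodes), function(k)
          sum(.ordinal_ll_parts(yi[idx], eta0[idx] + sqrt(2) * sigma * gh$nodes[k],
                                theta)$ll), numeric(1))
        lw <- log(gh$weights / sqrt(pi)) + lk
        m <- max(lw)
        ll <- ll + m + log(sum(exp(lw - m)))
      }
      if (!is.finite(ll)) return(1e10)
      -ll
    }
    opt <- stats::optim(c(rep(0, p), zeta0, log(0.5)), obj, method = "BFGS",
                        control = list(maxit = 500, reltol = 1e-12), hessian = TRUE)
    theta <- .theta_from_zeta(opt$par[p + seq_len(K - 1)])
    sigma2 <- exp(opt$par[p + K])^2
    co <- c(if (p) stats::setNames(opt$par[seq_len(p)], colnames(X)),
            stats::setNames(theta, paste0("theta", seq_len(K - 1))))
    se <- tryCatch(sqrt(diag(solve(opt$hessian)))[seq_len(p)],
                   error = function(e) rep(NA_real_, p))
    return(new_model_fit("ordinal", co, c(group = sigma2), -opt$value, length(yi),
                         npar = p + K - 1 + 1, converged = opt$convergence == 0,
                         extra = list(se = stats::setNames(se, colnames(X)))))
  }
  # nested pair: joint Laplace over (bird effects, trip effects)
  Zb <- stats::model.matrix(~ 0 + g)
  Zt <- stats::model.matrix(~ 0 + g2)
  qb <- ncol(Zb); qt <- ncol(Zt)
  laplace_ll <- function(beta, theta, sb2, st2, u0) {
    eta0 <- if (p) drop(X %*% beta) else rep(0, length(yi))
    dinv <- c(rep(1 / sb2, qb), rep(1 / st2, qt))
    u <- u0
    Z <- cbind(Zb, Zt)
    f_of <- function(u) {
      eta <- eta0 + drop(Z %*% u)
      v <- sum(.ordinal_ll_parts(yi, eta, theta)$ll) - 0.5 * sum(dinv * u^2)
      if (!is.finite(v)) -Inf else v
    }
    f_old <- f_of(u)
    if (!is.finite(f_old)) { u <- rep(0, length(u)); f_old <- f_of(u) }
    for (it in 1:50) {
      eta <- eta0 + drop(Z %*% u)
      parts <- .ordinal_ll_parts(yi, eta, theta, deriv = TRUE)
      gr <- drop(crossprod(Z, parts$s)) - dinv * u
      H <- crossprod(Z * sqrt(pmax(parts$w, 1e-10)))
      diag(H) <- diag(H) + dinv
      step <- tryCatch(solve(H, gr), error = function(e) NULL)
      if (is.null(step) || !all(is.finite(step))) break
      alpha <- 1
      repeat {
        unew <- u + alpha * step
        f_new <- f_of(unew)
        if (f_new >= f_old - 1e-12 || alpha < 1e-4) break
        alpha <- alpha / 2
      }
      if (!is.finite(f_new)) break
      moved <- abs(f_new - f_old)
      u <- unew; f_old <- f_new
      if (moved < 1e-10) break
    }
    if (!is.finite(f_old)) return(list(ll = -1e10, u = rep(0, length(u))))
    eta <- eta0 + drop(Z %*% u)
    parts <- .ordinal_ll_parts(yi, eta, theta, deriv = TRUE)
    H <- crossprod(Z * sqrt(pmax(parts$w, 1e-10)))
    diag(H) <- diag(H) + dinv
    ld <- determinant(H, logarithm = TRUE)$modulus
    list(ll = f_old - 0.5 * ld - 0.5 * (qb * log(sb2) + qt * log(st2)), u = u)
  }
  u_warm <- rep(0, qb + qt)
  obj <- function(par) {
    beta <- par[seq_len(p)]
    theta <- .theta_from_zeta(par[p + seq_len(K - 1)])
    # keep variances numerically away from 0/Inf so the Laplace stays defined
    sb2 <- min(max(exp(par[p + K])^2, 1e-8), 1e6)
    st2 <- min(max(exp(par[p + K + 1])^2, 1e-8), 1e6)
    res <- laplace_ll(beta, theta, sb2, st2, u_warm)
    u_warm <<- res$u
    if (!is.finite(res$ll)) 1e10 else -res$ll
  }
  opt <- stats::optim(c(rep(0, p), zeta0, log(0.5), log(0.5)), obj, method = "BFGS",
                      control = list(maxit = 300, reltol = 1e-10), hessian = TRUE)
  theta <- .theta_from_zeta(opt$par[p + seq_len(K - 1)])
  co <- c(if (p) stats::setNames(opt$par[seq_len(p)], colnames(X)),
          stats::setNames(theta, paste0("theta", seq_len(K - 1))))
  se <- tryCatch(sqrt(diag(solve(opt$hessian)))[seq_len(p)],
                 error = function(e) rep(NA_real_, p))
  new_model_fit("ordinal", co,
                c(group = exp(opt$par[p + K])^2, group2 = exp(opt$par[p + K + 1])^2),
                -opt$value, length(yi), npar = p + K - 1 + 2,
                converged = opt$convergence == 0,
                extra = list(se = stats::setNames(se, colnames(X))))
}

#' Likelihood-ratio test between nested ML fits
#'
#' chi2 = 2(llfull - llreduced) compared with the chi-square distribution on
#' the parameter-count difference.  Numerically negative statistics are
#' clamped at zero with a warning.
#'
#' @param full,reduced `model_fit` objects fitted to the same rows by ML.
#' @return list `chi2`, `df`, `p`.
#' @export
lrt <- function(full, reduced) {
  stopifnot(inherits(full, "model_fit"), inherits(reduced, "model_fit"))
  if (full$n != reduced$n) stop("models fitted to different numbers of rows")
  df <- full$npar - reduced$npar
  if (df < 1) stop("full model must have more parameters than reduced (nested designs only)")
  chi2 <- 2 * (full$logLik - reduced$logLik)
  if (chi2 < 0) {
    if (chi2 < -1e-6) warning("negative LRT statistic (", format(chi2),
                              ") clamped to 0; check convergence")
    chi2 <- 0
  }
  list(chi2 = chi2, df = df, p = stats::pchisq(chi2, df, lower.tail = FALSE))
}

#' Year-quality band from sea-surface temperature anomaly
#'
#' Terciles of the observed SSTa range: low (below -0.36), medium (-0.36 to
#' -0.15) and high (above -0.15) anomaly years.
#'
#' @param ssta numeric anomalies, degrees C.
#' @param bounds band boundaries (default c(-0.36, -0.15)).
#' @return factor low/medium/high.
#' @export
ssta_band <- function(ssta, bounds = c(-0.36, -0.15)) {
  cut(ssta, breaks = c(-Inf, bounds, Inf), labels = c("low", "medium", "high"))
}

#' Fitness analysis: fledging success against personality, sex and SSTa
#'
#' Multi-year model: fledging ~ score * sex * SSTa with random intercepts
#' for bird and year, by ML.  The "interaction with sex and year quality"
#' test drops the four interaction terms (score:sex, score:SSTa, sex:SSTa,
#' score:sex:SSTa) from the full model, a 4-df likelihood-ratio test.
#' Single-year mode (no SSTa or year term) tests score, sex and score:sex.
#'
#' @param breeding data.frame with `bird_id`, `year`, `sex`, `success`.
#' @param scores data.frame with `bird_id`, `score` (mean-centred).
#' @param ssta data.frame with `year`, `ssta`; required unless
#'   `single_year`.
#' @param single_year fit one season without year terms (default FALSE).
#' @return list with `full`, `reduced`, `interaction` (LRT), `data`, and in
#'   single-year mode the per-term LRTs `score`, `sex`, `score_sex`.
#' @export
fitness_analysis <- function(breeding, scores, ssta = NULL, single_year = FALSE) {
  d <- merge(breeding, scores[, c("bird_id", "score")], by = "bird_id")
  d$sex <- factor(d$sex, levels = c("female", "male"))
  if (single_year) {
    fixed_full <- data.frame(score = d$score, sex = d$sex,
                             score_sex = d$score * (d$sex == "male"))
    full <- fit_glm_binomial(d$success, fixed_full)
    red_int <- fit_glm_binomial(d$success, fixed_full[c("score", "sex")])
    red_score <- fit_glm_binomial(d$success, fixed_full[c("sex")])
    red_sex <- fit_glm_binomial(d$success, fixed_full[c("score")])
    base <- fit_glm_binomial(d$success, fixed_full[c("score", "sex")])
    return(list(full = full, reduced = red_int,
                score_sex = lrt(full, red_int),
                score = lrt(base, red_score),
                sex = lrt(base, red_sex),
                data = d))
  }
  if (is.null(ssta)) stop("ssta table required for the multi-year analysis")
  miss <- setdiff(unique(d$year), ssta$year)
  if (length(miss)) stop("missing SSTa for year(s): ", paste(sort(miss), collapse = ", "))
  d$ssta <- ssta$ssta[match(d$year, ssta$year)]
  d$ssta_c <- d$ssta - mean(ssta$ssta)
  m <- as.numeric(d$sex == "male")
  fx_full <- data.frame(score = d$score, sexM = m, ssta = d$ssta_c,
                        score_sex = d$score * m, score_ssta = d$score * d$ssta_c,
                        sex_ssta = m * d$ssta_c,
                        score_sex_ssta = d$score * m * d$ssta_c)
  fx_red <- fx_full[c("score", "sexM", "ssta")]
  # bird and year random intercepts are crossed, not nested: fitted directly
  full <- .glmm_two_crossed(d$success, fx_full, d$bird_id, d$year)
  reduced <- .glmm_two_crossed(d$success, fx_red, d$bird_id, d$year)
  list(full = full, reduced = reduced, interaction = lrt(full, reduced), data = d)
}

# binomial GLMM with two crossed random intercepts (bird, year), Laplace ML
.glmm_two_crossed <- function(y, fixed, bird, year) {
  d <- .build_df(as.numeric(y), fixed, .b = bird, .yr = year)
  covs <- setdiff(names(d), c(".y", ".b", ".yr"))
  rhs <- paste(c("1", covs, "(1 | .b)", "(1 | .yr)"), collapse = " + ")
  fit <- lme4::glmer(stats::as.formula(paste(".y ~", rhs)), data = d,
                     family = stats::binomial(), nAGQ = 1)
  vc <- as.data.frame(lme4::VarCorr(fit))
  rv <- c(bird = vc$vcov[vc$grp == ".b"], year = vc$vcov[vc$grp == ".yr"])
  new_model_fit("binomial", lme4::fixef(fit), rv,
                as.numeric(stats::logLik(fit)), nrow(d),
                npar = length(lme4::fixef(fit)) + 2L, fit = fit,
                converged = length(fit@optinfo$conv$lme4) == 0,
                extra = list(data = d))
}

#' Predicted fledging curves by sex and SSTa band
#'
#' Fixed-effects predictions from the multi-year fitness model over a score
#' grid, one curve per sex at the midpoint SSTa of each year-quality band.
#'
#' @param fa result of [fitness_analysis()] (multi-year).
#' @param score_grid score values (default 41 points over observed range).
#' @return data.frame `sex`, `band`, `score`, `pred` (probability).
#' @export
fitness_curves <- function(fa, score_grid = NULL) {
  d <- fa$data
  if (is.null(score_grid))
    score_grid <- seq(min(d$score), max(d$score), length.out = 41)
  mids <- tapply(d$ssta_c, ssta_band(d$ssta), mean)
  co <- fa$full$coefficients
  out <- expand.grid(sex = c("female", "male"), band = names(mids),
                     score = score_grid, KEEP.OUT.ATTRS = FALSE,
                     stringsAsFactors = FALSE)
  m <- as.numeric(out$sex == "male")
  s <- out$score
  a <- unname(mids[out$band])
  eta <- co["(Intercept)"] + co["score"] * s + co["sexM"] * m + co["ssta"] * a +
    co["score_sex"] * s * m + co["score_ssta"] * s * a + co["sex_ssta"] * m * a +
    co["score_sex_ssta"] * s * m * a
  out$pred <- stats::plogis(unname(eta))
  out
}
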