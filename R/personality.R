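#' Principal component analysis on the correlation matrix
#'
#' Behavioural counts, durations and trip metrics live on incommensurate
#' scales, so variables are standardised (correlation-matrix PCA) before the
#' eigendecomposition; eigenvalues then sum to the number of variables and
#' the proportion of variance for a component is eigenvalue / p.  The first
#' component's sign is oriented so that a named anchor variable (the
#' behavioural-intensity marker, e.g. pecking rate or foraging range) loads
#' positive.
#'
#' @param x numeric matrix or data.frame, observations x variables.
#' @param anchor variable name whose PC1 loading is forced positive
#'   (default: first column).
#' @return object of class `pca_result`: `loadings` (p x p, columns
#'   orthonormal), `eigenvalues` (descending), `proportion` (eigenvalue/p),
#'   `center`, `scale`, `n`.
#' @export
pca_correlation <- function(x, anchor = colnames(x)[1]) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("V", seq_len(ncol(x)))
  cc <- stats::complete.cases(x)
  if (sum(!cc)) message(sum(!cc), " incomplete row(s) dropped before PCA")
  x <- x[cc, , drop = FALSE]
  if (nrow(x) < 2) stop("need >= 2 complete rows for PCA")
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0))
    stop("constant column(s): ", paste(colnames(x)[sds == 0], collapse = ", "))
  pr <- stats::prcomp(x, center = TRUE, scale. = TRUE)
  load <- pr$rotation
  eig <- pr$sdev^2
  ai <- match(anchor, colnames(x))
  if (is.na(ai)) stop("anchor variable not found: ", anchor)
  # deterministic orientation: anchor loads positive on PC1; remaining
  # components oriented by their largest-magnitude loading
  if (load[ai, 1] < 0) load[, 1] <- -load[, 1]
  for (k in seq(2, ncol(load))) {
    im <- which.max(abs(load[, k]))
    if (load[im, k] < 0) load[, k] <- -load[, k]
  }
  structure(list(loadings = load, eigenvalues = eig,
                 proportion = eig / ncol(x),
                 center = pr$center, scale = pr$scale, n = nrow(x)),
            class = "pca_result")
}

#' Proportion of variance explained by a component of a correlation PCA
#'
#' For standardised (correlation-matrix) PCA the eigenvalues sum to the
#' number of variables, so a component's share of variance is its
#' eigenvalue divided by the variable count.
#'
#' @param eigenvalue the component's eigenvalue.
#' @param n_variables number of variables entering the PCA.
#' @return proportion in [0, 1].
#' @export
variance_explained <- function(eigenvalue, n_variables) {
  stopifnot(eigenvalue >= 0, n_variables >= 1)
  eigenvalue / n_variables
}

#' Project observations onto the first principal component
#'
#' @param result a `pca_result`.
#' @param x matrix/data.frame with the fitted variables.
#' @return numeric score per row (standardised rows times the PC1 loading
#'   vector).
#' @export
project_pc1 <- function(result, x) {
  x <- as.matrix(x)
  vars <- rownames(result$loadings)
  if (!all(vars %in% colnames(x)))
    stop("missing variable(s): ", paste(setdiff(vars, colnames(x)), collapse = ", "))
  xs <- sweep(sweep(x[, vars, drop = FALSE], 2, result$center), 2, result$scale, "/")
  drop(xs %*% result$loadings[, 1])
}

#' Per-individual boldness from observation-level scores
#'
#' A least-squares fit of score ~ observation number + date + bird, with
#' birds as sum-to-zero fixed effects so that the test-condition covariates
#' remain identifiable; the per-bird effects are then mean-centred across
#' birds.  Covariates without variation (e.g. a single test date) are
#' dropped with a warning.
#'
#' @param score observation-level PC1 scores.
#' @param bird_id bird identifier per observation.
#' @param obs_number 1 for a bird's first test, 2 for the retest.
#' @param date test date (Date or numeric day-of-season).
#' @return data.frame `bird_id`, `score` (centred), `n_obs`.
#' @export
individual_boldness <- function(score, bird_id, obs_number = NULL, date = NULL) {
  bird <- factor(bird_id)
  dat <- data.frame(score = score, bird = bird)
  terms <- character(0)
  if (!is.null(obs_number)) {
    if (length(unique(obs_number)) > 1) {
      dat$obs_number <- factor(obs_number)
      terms <- c(terms, "obs_number")
    } else warning("observation number has no variation; dropped")
  }
  if (!is.null(date)) {
    dnum <- as.numeric(date)
    if (length(unique(dnum)) > 1) {
      dat$date <- dnum
      terms <- c(terms, "date")
    } else warning("date has no variation; dropped")
  }
  rhs <- paste(c(terms, "bird"), collapse = " + ")
  fit <- stats::lm(stats::as.formula(paste("score ~", rhs)), data = dat,
                   contrasts = list(bird = "contr.sum"))
  co <- stats::coef(fit)
  bi <- grep("^bird", names(co))
  eff <- c(co[bi], -sum(co[bi]))            # sum-to-zero: last level implied
  names(eff) <- levels(bird)
  eff <- eff - mean(eff)
  data.frame(bird_id = names(eff), score = unname(eff),
             n_obs = as.integer(table(bird)[names(eff)]),
             stringsAsFactors = FALSE)
}

#' Per-individual foraging personality score from trip-level scores
#'
#' Fixed-effect fit of trip PC1 on bird identity; with no other covariates
#' this reduces to the per-bird mean, which is asserted, then mean-centred
#' across birds.
#'
#' @param score trip-level PC1 scores.
#' @param bird_id bird identifier per trip.
#' @return data.frame `bird_id`, `score` (centred), `n_trips`.
#' @export
individual_foraging_score <- function(score, bird_id) {
  bird <- factor(bird_id)
  fit <- stats::lm(score ~ bird, contrasts = list(bird = "contr.sum"))
  co <- stats::coef(fit)
  bi <- grep("^bird", names(co))
  eff <- c(co[bi], -sum(co[bi]))
  names(eff) <- levels(bird)
  eff <- eff - mean(eff)
  means <- tapply(score, bird, mean)
  stopifnot(max(abs(eff - (means - mean(means)))) < 1e-9)
  data.frame(bird_id = names(eff), score = unname(eff),
             n_trips = as.integer(table(bird)[names(eff)]),
             stringsAsFactors = FALSE)
}

#' Spearman rank correlation between two personality scores
#'
#' Average ranks for ties; p-value from the large-sample t approximation
#' t = rho * sqrt((n-2)/(1-rho^2)) on n-2 degrees of freedom.
#'
#' @param x,y paired scores (length >= 4).
#' @return list `rho`, `p`, `n`.
#' @export
score_correlation <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 4) stop("need >= 4 paired scores")
  rho <- stats::cor(rank(x), rank(y))
  if (abs(rho) >= 1) {
    p <- 0
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  }
  list(rho = rho, p = p, n = n)
}
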