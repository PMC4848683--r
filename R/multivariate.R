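# Latent-variable evaluation of the predictor panel, in the chemometrics
# style: NIPALS principal components on mean-centered, unit-variance
# scaled data with per-component R2X, row-wise cross-validated Q2, a
# two-sample Hotelling T-squared test on score space, and single-component
# PLS1 regression of tumor mass on the panel. The component extraction is
# implemented here directly (not delegated) so that scaling, deflation,
# sign conventions and the cross-validation scheme are fully specified.

# Center/scale a numeric matrix; errors name any zero-variance column.
#' @keywords internal
uv_scale <- function(X, center = TRUE, scale. = TRUE) {
  X <- as.matrix(X)
  if (!is.numeric(X)) stop("X must be numeric", call. = FALSE)
  mu <- if (center) colMeans(X) else rep(0, ncol(X))
  sdv <- if (scale.) apply(X, 2, stats::sd) else rep(1, ncol(X))
  if (scale. && any(sdv == 0)) {
    bad <- colnames(X)[sdv == 0]
    if (is.null(bad)) bad <- which(sdv == 0)
    stop(sprintf("zero-variance column under unit-variance scaling: %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  Xs <- sweep(sweep(X, 2, mu, "-"), 2, sdv, "/")
  list(X = Xs, center = mu, scale = sdv)
}

# One NIPALS component from a residual matrix E. Returns unit-norm
# loading p (sign fixed: largest-magnitude element positive) and score t.
#' @keywords internal
nipals_component <- function(E, tol = 1e-12, max_iter = 5000L) {
  j <- which.max(apply(E, 2, function(x) sum(x^2)))
  t <- E[, j]
  if (sum(t^2) == 0) t <- E[, which.max(colSums(E^2))]
  for (it in seq_len(max_iter)) {
    p <- drop(crossprod(E, t)) / sum(t^2)
    p <- p / sqrt(sum(p^2))
    t_new <- drop(E %*% p)
    if (sqrt(sum((t_new - t)^2)) < tol * max(sqrt(sum(t_new^2)), 1e-300)) {
      t <- t_new
      break
    }
    t <- t_new
  }
  jmax <- which.max(abs(p))
  if (p[jmax] < 0) {
    p <- -p
    t <- -t
  }
  list(p = p, t = t)
}

#' NIPALS principal components with per-component R2X
#'
#' Extracts `n_components` principal components from a mean-centered,
#' unit-variance scaled data matrix by nonlinear iterative partial least
#' squares (NIPALS) with deflation. R2X per component is the fraction of
#' total (scaled) sum of squares that component explains; the cumulative
#' R2X is non-decreasing. Loadings are unit-norm and mutually orthogonal,
#' scores are mutually orthogonal, and each loading's largest-magnitude
#' element is oriented positive so results are reproducible up to
#' convergence tolerance.
#'
#' @param X numeric matrix or data.frame, observations in rows (>= 3),
#'   variables in columns (>= 2).
#' @param n_components number of components, <= min(dim(X)).
#' @param center,scale. preprocessing flags (defaults: mean centering and
#'   unit-variance scaling).
#' @param tol relative score-change convergence tolerance; the tight
#'   default guards components whose eigenvalues are nearly tied, where
#'   the power-style iteration converges slowly.
#' @param max_iter iteration cap per component.
#' @return object of class `"pca_model"`: `loadings` (variables x
#'   components), `scores` (observations x components), `r2x`,
#'   `r2x_cumulative`, `center`, `scale`, `totss`.
#' @export
#' @examples
#' set.seed(1)
#' X <- matrix(rnorm(60), 20, 3)
#' pca_fit(X, 2)$r2x_cumulative
pca_fit <- function(X, n_components, center = TRUE, scale. = TRUE,
                    tol = 1e-12, max_iter = 5000L) {
  X <- as.matrix(X)
  if (nrow(X) < 3L) stop("need at least 3 observations", call. = FALSE)
  if (ncol(X) < 2L) stop("need at least 2 variables", call. = FALSE)
  if (n_components < 1L || n_components > min(dim(X)))
    stop("n_components must lie in [1, min(dim(X))]", call. = FALSE)
  sc <- uv_scale(X, center, scale.)
  E <- sc$X
  totss <- sum(E^2)
  P <- matrix(0, ncol(X), n_components,
              dimnames = list(colnames(X), paste0("PC", 1:n_components)))
  Tm <- matrix(0, nrow(X), n_components,
               dimnames = list(rownames(X), paste0("PC", 1:n_components)))
  r2 <- numeric(n_components)
  for (a in seq_len(n_components)) {
    cmp <- nipals_component(E, tol, max_iter)
    P[, a] <- cmp$p
    Tm[, a] <- cmp$t
    r2[a] <- sum(cmp$t^2) / totss
    E <- E - tcrossprod(cmp$t, cmp$p)
  }
  out <- list(loadings = P, scores = Tm, r2x = r2,
              r2x_cumulative = cumsum(r2), n_components = n_components,
              center = sc$center, scale = sc$scale, totss = totss,
              centered = center, scaled = scale.)
  class(out) <- "pca_model"
  out
}

#' @export
print.pca_model <- function(x, ...) {
  cat(sprintf("NIPALS PCA: %d components, R2X(cum) = %s\n",
              x$n_components,
              paste(sprintf("%.3f", x$r2x_cumulative), collapse = " ")))
  invisible(x)
}

#' Cross-validated Q2 for a principal component model
#'
#' Row-wise cross-validation: observations are split into contiguous
#' folds; for each fold a NIPALS component is extracted from the training
#' rows' residual matrix, and each held-out element is predicted from the
#' held-out row's OTHER variables: the row's score on the training
#' loading is computed leaving the target variable out, so no element
#' predicts itself. Q2 for component a is 1 - PRESS_a / SS_(a-1), where
#' SS_(a-1) is the residual sum of squares of the full-data model before
#' adding the component; cumulative Q2 is 1 - prod(PRESS_a / SS_(a-1)).
#' Scaling is done once on the full matrix before cross-validation.
#' Fully predictable structure gives Q2 near 1; pure noise gives Q2 near
#' or below 0.
#'
#' @param X numeric matrix, observations in rows (>= n_folds).
#' @param n_components components to evaluate.
#' @param n_folds number of contiguous row folds (default 7).
#' @param center,scale. preprocessing flags.
#' @return list: `q2` per component, `q2_cumulative`, `press`, `ss_prior`.
#' @export
q2_crossval <- function(X, n_components, n_folds = 7L, center = TRUE,
                        scale. = TRUE) {
  X <- as.matrix(X)
  if (n_folds < 2L) stop("need at least 2 folds", call. = FALSE)
  if (nrow(X) < n_folds)
    stop("each fold needs at least one observation", call. = FALSE)
  sc <- uv_scale(X, center, scale.)
  Xs <- sc$X
  fold <- rep(seq_len(n_folds), length.out = nrow(Xs))
  fold <- sort(fold)  # contiguous blocks
  # residual SS of the full-data model before each component
  ss_prior <- numeric(n_components)
  E <- Xs
  for (a in seq_len(n_components)) {
    ss_prior[a] <- sum(E^2)
    cmp <- nipals_component(E)
    E <- E - tcrossprod(cmp$t, cmp$p)
  }
  press <- numeric(n_components)
  for (f in seq_len(n_folds)) {
    test <- fold == f
    Etr <- Xs[!test, , drop = FALSE]
    Ete <- Xs[test, , drop = FALSE]
    for (a in seq_len(n_components)) {
      cmp <- nipals_component(Etr)
      p <- cmp$p
      # leave-one-variable-out prediction of each held-out element:
      # score for element j uses the row's other variables only
      full <- Ete %*% p                       # rows x 1
      denom <- pmax(1 - p^2, 1e-12)           # per variable j
      t_loo <- (matrix(full, nrow(Ete), length(p)) -
                  sweep(Ete, 2, p, "*")) / rep(denom, each = nrow(Ete))
      pred <- sweep(t_loo, 2, p, "*")
      press[a] <- press[a] + sum((Ete - pred)^2)
      # model-building deflation uses the ordinary projection
      Etr <- Etr - tcrossprod(cmp$t, p)
      Ete <- Ete - tcrossprod(drop(full), p)
    }
  }
  q2 <- 1 - press / ss_prior
  list(q2 = q2, q2_cumulative = 1 - cumprod(press / ss_prior),
       press = press, ss_prior = ss_prior, n_folds = n_folds)
}

#' Two-sample Hotelling T-squared test
#'
#' Compares multivariate group means (e.g. PCA scores of two strains)
#' with the pooled-covariance Hotelling T-squared statistic and its exact
#' F reference distribution. In one dimension the statistic equals the
#' squared pooled two-sample t statistic.
#'
#' @param scores numeric matrix (observations x dimensions) or vector.
#' @param labels group labels, exactly two groups; each group must have
#'   at least dimensions + 1 observations.
#' @return list: `t2`, `f_statistic`, `df1`, `df2`, `p_value`,
#'   `group_means`.
#' @export
#' @examples
#' set.seed(1)
#' x <- rbind(matrix(rnorm(40), 20), matrix(rnorm(40, 1), 20))
#' hotelling_two_group(x, rep(c("a", "b"), each = 20))
hotelling_two_group <- function(scores, labels) {
  X <- as.matrix(scores)
  labels <- as.factor(labels)
  if (nlevels(labels) != 2L)
    stop("exactly two groups required", call. = FALSE)
  p <- ncol(X)
  idx <- split(seq_len(nrow(X)), labels)
  n1 <- length(idx[[1]]); n2 <- length(idx[[2]])
  if (n1 < p + 1L || n2 < p + 1L)
    stop("each group needs at least dimensions + 1 observations",
         call. = FALSE)
  X1 <- X[idx[[1]], , drop = FALSE]; X2 <- X[idx[[2]], , drop = FALSE]
  d <- colMeans(X1) - colMeans(X2)
  S <- ((n1 - 1) * stats::cov(X1) + (n2 - 1) * stats::cov(X2)) /
    (n1 + n2 - 2)
  Sinv <- tryCatch(solve(S), error = function(e)
    stop("singular pooled covariance", call. = FALSE))
  t2 <- (n1 * n2 / (n1 + n2)) * drop(t(d) %*% Sinv %*% d)
  f <- (n1 + n2 - p - 1) / (p * (n1 + n2 - 2)) * t2
  df1 <- p; df2 <- n1 + n2 - p - 1
  list(t2 = t2, f_statistic = f, df1 = df1, df2 = df2,
       p_value = stats::pf(f, df1, df2, lower.tail = FALSE),
       group_means = rbind(colMeans(X1), colMeans(X2)))
}

#' Single-component PLS1 regression
#'
#' Regresses one response (tumor mass) on the predictor panel with one
#' partial-least-squares component via NIPALS on centered, unit-variance
#' scaled X and y. The weight vector is proportional to X'y on the scaled
#' data; regression coefficients are returned on the scaled scale, so
#' their magnitudes are comparable across predictors: large positive
#' coefficients mark variables that rise with the response, large
#' negative ones variables that fall.
#'
#' @param X numeric matrix or data.frame of predictors (observations x
#'   variables).
#' @param y numeric response, non-constant, length nrow(X).
#' @param center,scale. preprocessing flags, applied to X and y.
#' @return object of class `"pls1_model"`: `coefficients` (named, scaled
#'   scale), `weights`, `x_loadings`, `scores`, `y_loading`,
#'   `r2y` (fraction of scaled-y variance explained), `top_positive`,
#'   `top_negative`.
#' @export
pls1_fit <- function(X, y, center = TRUE, scale. = TRUE) {
  X <- as.matrix(X)
  if (nrow(X) < 3L) stop("need at least 3 observations", call. = FALSE)
  if (length(y) != nrow(X))
    stop("y must have one value per row of X", call. = FALSE)
  if (stats::sd(y) == 0) stop("constant response", call. = FALSE)
  scx <- uv_scale(X, center, scale.)
  Xs <- scx$X
  ys <- if (scale.) (y - mean(y)) / stats::sd(y)
  else if (center) y - mean(y) else y
  w <- drop(crossprod(Xs, ys))
  if (sqrt(sum(w^2)) == 0)
    stop("response is orthogonal to all predictors", call. = FALSE)
  w <- w / sqrt(sum(w^2))
  t <- drop(Xs %*% w)
  p <- drop(crossprod(Xs, t)) / sum(t^2)
  q <- sum(ys * t) / sum(t^2)
  b <- w * q / drop(crossprod(p, w))
  names(b) <- colnames(X)
  r2y <- 1 - sum((ys - t * q)^2) / sum(ys^2)
  ord <- order(b)
  out <- list(coefficients = b, weights = w, x_loadings = p, scores = t,
              y_loading = q, r2y = r2y,
              top_positive = names(b)[rev(ord)][1:min(3, length(b))],
              top_negative = names(b)[ord][1:min(3, length(b))])
  class(out) <- "pls1_model"
  out
}

#' @export
print.pls1_model <- function(x, ...) {
  cat(sprintf("PLS1 (1 component): R2Y = %.3f\n", x$r2y))
  cat("strongest positive:", paste(x$top_positive, collapse = ", "), "\n")
  cat("strongest negative:", paste(x$top_negative, collapse = ", "), "\n")
  invisible(x)
}
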