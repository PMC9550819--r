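#' L1-penalized logistic regression by coordinate descent
#'
#' Minimizes the penalized average negative log-likelihood
#' `mean(log(1 + exp(eta)) - y * eta) + lambda * sum(|w|)` with an
#' unpenalized intercept. Fitting alternates an outer quadratic (IRLS)
#' approximation with inner cyclic coordinate descent and soft-thresholding;
#' a step-halving safeguard keeps the penalized objective non-increasing
#' across outer sweeps. Convergence when no coefficient moves more than
#' `tol`.
#'
#' @param x samples x features numeric matrix (standardize beforehand for
#'   scale-equivariant penalization).
#' @param y binary 0/1 response with both classes present.
#' @param lambda penalty, >= 0. At `lambda >= lambda_max` (see
#'   [lasso_lambda_max()]) all weights are exactly zero.
#' @param tol convergence tolerance on coefficient changes.
#' @param max_iter outer iteration cap.
#' @param init optional warm start: list with `weights` and `intercept`
#'   (used by the cross-validation path).
#' @return list with `weights`, `intercept`, `lambda`, `objective`,
#'   `objective_path` (per outer sweep), `n_iter`.
#' @export
lasso_logistic <- function(x, y, lambda, tol = 1e-7, max_iter = 500,
                           init = NULL) {
  x <- as.matrix(x)
  if (any(!is.finite(x))) abort("non-finite values in x")
  if (!all(y %in% c(0, 1))) abort("y must be 0/1")
  if (length(unique(y)) < 2) abort("y has a single class; no contrast to fit")
  if (lambda < 0) abort("lambda must be >= 0")
  n <- nrow(x); p <- ncol(x)
  ybar <- mean(y)
  if (!is.null(init)) {
    w <- unname(init$weights)
    b <- init$intercept
  } else {
    w <- numeric(p)
    b <- log(ybar / (1 - ybar))
  }
  obj <- function(b, w) {
    eta <- b + drop(x %*% w)
    mean(log1p(exp(-abs(eta))) + pmax(eta, 0) - y * eta) + lambda * sum(abs(w))
  }
  path <- obj(b, w)
  soft <- function(z, g) sign(z) * pmax(abs(z) - g, 0)
  for (it in seq_len(max_iter)) {
    b0 <- b; w0 <- w
    eta <- b + drop(x %*% w)
    pr <- 1 / (1 + exp(-eta))
    wt <- pmax(pr * (1 - pr), 1e-6)
    z <- eta + (y - pr) / wt
    # inner cyclic coordinate descent on the weighted quadratic approximation
    r <- z - eta
    for (inner in seq_len(200)) {
      delta <- 0
      bn <- sum(wt * (r + b)) / sum(wt)
      r <- r + b - bn
      delta <- max(delta, abs(bn - b)); b <- bn
      for (j in seq_len(p)) {
        xj <- x[, j]
        zj <- sum(wt * xj * (r + xj * w[j])) / n
        vj <- sum(wt * xj^2) / n
        wj <- soft(zj, lambda) / vj
        if (wj != w[j]) {
          r <- r + xj * (w[j] - wj)
          delta <- max(delta, abs(wj - w[j]))
          w[j] <- wj
        }
      }
      if (delta < tol) break
    }
    # step-halving: the quadratic step must not increase the true objective
    f_new <- obj(b, w)
    step <- 1
    while (f_new > path[length(path)] + 1e-12 && step > 1e-10) {
      step <- step / 2
      b <- b0 + step * (b - b0)
      w <- w0 + step * (w - w0)
      f_new <- obj(b, w)
    }
    path <- c(path, f_new)
    if (max(abs(c(b - b0, w - w0))) < tol) break
  }
  # the soft threshold can leave O(eps) dust on the KKT boundary; snap it so
  # inactive features are exactly zero
  w[abs(w) < 1e-12] <- 0
  list(weights = setNames(w, colnames(x)), intercept = b, lambda = lambda,
       objective = path[length(path)], objective_path = path, n_iter = it)
}

#' Smallest penalty with an all-zero solution
#'
#' `lambda_max = max_j |x_j' (y - mean(y))| / n`: the KKT bound at the null
#' model (intercept only).
#'
#' @inheritParams lasso_logistic
#' @return numeric scalar.
#' @export
lasso_lambda_max <- function(x, y) {
  max(abs(crossprod(as.matrix(x), y - mean(y)))) / length(y)
}

#' KKT residuals of a fitted LASSO logistic model
#'
#' For active features the stationarity residual `|g_j + lambda * sign(w_j)|`
#' should be ~0; for inactive ones `|g_j|` must not exceed `lambda` (up to
#' tolerance). Used as a post-fit correctness assertion.
#'
#' @param fit result of [lasso_logistic()].
#' @param x,y the data the model was fit on.
#' @return tibble with `feature`, `weight`, `gradient`, `kkt_residual`.
#' @export
lasso_kkt <- function(fit, x, y) {
  x <- as.matrix(x)
  eta <- fit$intercept + drop(x %*% fit$weights)
  pr <- 1 / (1 + exp(-eta))
  g <- drop(crossprod(x, pr - y)) / nrow(x)
  resid <- ifelse(fit$weights == 0,
                  pmax(abs(g) - fit$lambda, 0),
                  abs(g + fit$lambda * sign(fit$weights)))
  tibble::tibble(feature = colnames(x) %||% paste0("x", seq_len(ncol(x))),
                 weight = unname(fit$weights), gradient = g,
                 kkt_residual = resid)
}

#' Cross-validated penalty selection (1-SE rule)
#'
#' Fits a 50-point log-spaced lambda grid from `lambda_max` down to
#' `0.001 * lambda_max` on stratified folds and returns the largest lambda
#' whose mean held-out binomial deviance is within one standard error of the
#' minimum.
#'
#' @inheritParams lasso_logistic
#' @param n_folds number of folds (>= 3); stratified by class.
#' @param seed integer seed for fold assignment.
#' @param n_lambda grid size.
#' @param lambda_min_ratio grid floor relative to `lambda_max`.
#' @return the selected lambda, with attribute `cv` (tibble of the CV curve).
#' @export
cv_select_lambda <- function(x, y, n_folds = 10, seed = 1, n_lambda = 50,
                             lambda_min_ratio = 0.001) {
  x <- as.matrix(x)
  if (n_folds < 3) abort("n_folds must be >= 3")
  n <- nrow(x)
  lam_max <- lasso_lambda_max(x, y)
  if (lam_max == 0) lam_max <- 1e-4
  grid <- exp(seq(log(lam_max), log(lam_max * lambda_min_ratio),
                  length.out = n_lambda))
  folds <- NULL
  for (attempt in seq_len(10)) {
    f <- with_substream(seed + attempt - 1, "folds", {
      fv <- integer(n)
      for (cl in unique(y)) {
        idx <- which(y == cl)
        fv[idx] <- sample(rep_len(seq_len(n_folds), length(idx)))
      }
      fv
    })
    ok <- all(vapply(seq_len(n_folds), function(k) {
      length(unique(y[f != k])) == 2
    }, logical(1)))
    if (ok) { folds <- f; break }
  }
  if (is.null(folds)) abort("could not build folds with both classes in training")
  dev <- matrix(NA_real_, n_folds, n_lambda)
  for (k in seq_len(n_folds)) {
    tr <- folds != k
    if (sum(!tr) == 0) next
    fit <- NULL
    for (li in seq_len(n_lambda)) {
      # held-out deviance is insensitive to the last digits of the fit, so
      # the path runs at a looser tolerance than the final model
      fit <- lasso_logistic(x[tr, , drop = FALSE], y[tr], grid[li],
                            tol = 1e-5, init = fit)
      eta <- fit$intercept + drop(x[!tr, , drop = FALSE] %*% fit$weights)
      pr <- pmin(pmax(1 / (1 + exp(-eta)), 1e-12), 1 - 1e-12)
      dev[k, li] <- -2 * mean(y[!tr] * log(pr) + (1 - y[!tr]) * log(1 - pr))
    }
  }
  mean_dev <- colMeans(dev, na.rm = TRUE)
  se_dev <- apply(dev, 2, function(v) sd(v, na.rm = TRUE) /
                    sqrt(sum(is.finite(v))))
  i_min <- which.min(mean_dev)
  ok_idx <- which(mean_dev <= mean_dev[i_min] + se_dev[i_min])
  chosen <- grid[min(ok_idx)]  # grid descends, so min index = largest lambda
  structure(chosen, cv = tibble::tibble(lambda = grid, mean_deviance = mean_dev,
                                        se_deviance = se_dev))
}
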