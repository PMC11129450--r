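#' Logistic regression by iteratively reweighted least squares
#'
#' Maximum-likelihood logistic regression fitted by IRLS, as used for the
#' crude metabolizer-status association models. Convergence is declared
#' when the largest absolute score component falls below `score_tol` or
#' the largest coefficient change falls below `coef_tol`. Perfect
#' separation (fitted probabilities collapsing to 0/1 with diverging
#' coefficients) is detected and raised as an error rather than returning
#' unstable estimates.
#'
#' @param y Binary outcome vector (0/1).
#' @param X Design matrix; an intercept column is *not* added implicitly.
#' @param weights Optional case weights (e.g. cell counts for grouped
#'   data).
#' @param max_iter Maximum IRLS iterations.
#' @param score_tol,coef_tol Convergence tolerances.
#' @param alpha Two-sided level for the Wald confidence intervals.
#' @return A list with `coefficients`, `se`, `odds_ratio` (exponentiated
#'   coefficients), `ci_low`, `ci_high`, `iterations`, `converged`,
#'   `log_lik`.
#' @examples
#' X <- cbind(1, c(rep(0, 4), rep(1, 4)))
#' y <- c(0, 0, 0, 1, 0, 0, 1, 1)
#' logistic_fit(y, X)$odds_ratio
#' @export
logistic_fit <- function(y, X, weights = NULL, max_iter = 50,
                         score_tol = 1e-8, coef_tol = 1e-10, alpha = 0.05) {
  y <- as.numeric(y)
  if (!all(y %in% c(0, 1))) stop("y must be binary 0/1", call. = FALSE)
  X <- as.matrix(X)
  if (nrow(X) != length(y)) stop("nrow(X) must equal length(y)", call. = FALSE)
  w <- if (is.null(weights)) rep(1, length(y)) else as.numeric(weights)
  if (sum(w * y) == 0 || sum(w * (1 - y)) == 0) {
    stop("degenerate outcome: all observations share the same outcome",
         call. = FALSE)
  }
  if (qr(X)$rank < ncol(X)) stop("design matrix is rank deficient", call. = FALSE)

  beta <- rep(0, ncol(X))
  converged <- FALSE
  iter <- 0
  repeat {
    iter <- iter + 1
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    score <- drop(crossprod(X, w * (y - mu)))
    v <- w * mu * (1 - mu)
    if (max(abs(eta)) > 15 && all(abs(score) < 1e-2)) {
      stop("perfect separation detected: coefficients diverge", call. = FALSE)
    }
    info <- crossprod(X, X * v)
    step <- solve(info, score)
    beta_new <- beta + step
    delta <- max(abs(beta_new - beta))
    beta <- beta_new
    if (max(abs(score)) < score_tol || delta < coef_tol) {
      converged <- TRUE
      break
    }
    if (iter >= max_iter) break
  }
  if (!converged) {
    stop("IRLS did not converge in ", max_iter, " iterations", call. = FALSE)
  }
  eta <- drop(X %*% beta)
  if (max(abs(eta)) > 15) {
    stop("perfect separation detected: coefficients diverge", call. = FALSE)
  }
  mu <- stats::plogis(eta)
  v <- w * mu * (1 - mu)
  cov_beta <- solve(crossprod(X, X * v))
  se <- sqrt(diag(cov_beta))
  z_crit <- stats::qnorm(1 - alpha / 2)
  list(
    coefficients = drop(beta),
    se = se,
    odds_ratio = exp(drop(beta)),
    ci_low = exp(drop(beta) - z_crit * se),
    ci_high = exp(drop(beta) + z_crit * se),
    iterations = iter,
    converged = converged,
    log_lik = sum(w * (y * log(mu) + (1 - y) * log(1 - mu)))
  )
}

#' Expand a 2x2 group-by-outcome table into grouped logistic data
#'
#' Returns the outcome vector, a single-dummy design (intercept plus
#' non-reference-group indicator) and cell-count weights, so that
#' [logistic_fit()] on the result estimates the table's log odds ratio.
#'
#' @param a,b,c,d Cell counts: event and reference outcome in the contrast
#'   group, then event and reference outcome in the reference group.
#' @return List with `y`, `X`, `weights`.
#' @export
expand_2x2 <- function(a, b, c, d) {
  list(
    y = c(1, 0, 1, 0),
    X = cbind(intercept = 1, group = c(1, 1, 0, 0)),
    weights = c(a, b, c, d)
  )
}
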