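#' Crude odds ratio with Wald confidence interval
#'
#' For a 2x2 table comparing one metabolizer group against the reference
#' (NM) on an event outcome (discontinued or switched) versus the reference
#' outcome (maintained): OR = (a d) / (b c) with a = events in the group,
#' b = reference outcome in the group, c = events in the reference group,
#' d = reference outcome in the reference group. The interval is symmetric
#' on the log scale, exp(ln OR +/- z * sqrt(1/a + 1/b + 1/c + 1/d)), with
#' no continuity correction.
#'
#' @param a,b,c,d Cell counts as above. Alternatively `a` may be a 2x2
#'   matrix with rows (group, reference group) and columns (event,
#'   reference outcome).
#' @param alpha Two-sided significance level for the interval.
#' @param haldane Add 0.5 to every cell (Haldane-Anscombe) instead of
#'   raising a zero-cell error. Off by default.
#' @return A list with `odds_ratio`, `ci_low`, `ci_high`, `log_or`,
#'   `log_se`, `z`, `p_value`, `alpha`.
#' @examples
#' odds_ratio_wald(22, 60, 88, 352) # OR 1.47 (0.85 - 2.52)
#' @export
odds_ratio_wald <- function(a, b = NULL, c = NULL, d = NULL,
                            alpha = 0.05, haldane = FALSE) {
  if (is.matrix(a)) {
    stopifnot(all(dim(a) == c(2, 2)))
    d <- a[2, 2]; c <- a[2, 1]; b <- a[1, 2]; a <- a[1, 1]
  }
  cells <- c(a = unname(a), b = unname(b), c = unname(c), d = unname(d))
  if (any(cells < 0)) stop("cell counts must be non-negative", call. = FALSE)
  if (any(cells == 0)) {
    if (!haldane) {
      stop("zero cell in 2x2 table; set haldane = TRUE to apply the ",
           "Haldane-Anscombe correction", call. = FALSE)
    }
    cells <- cells + 0.5
  }
  log_or <- log(cells["a"]) + log(cells["d"]) - log(cells["b"]) - log(cells["c"])
  log_se <- sqrt(sum(1 / cells))
  z_crit <- stats::qnorm(1 - alpha / 2)
  z <- log_or / log_se
  list(
    odds_ratio = unname(exp(log_or)),
    ci_low = unname(exp(log_or - z_crit * log_se)),
    ci_high = unname(exp(log_or + z_crit * log_se)),
    log_or = unname(log_or),
    log_se = unname(log_se),
    z = unname(z),
    p_value = unname(2 * stats::pnorm(-abs(z))),
    alpha = alpha
  )
}

#' Post-hoc power for the difference between two independent proportions
#'
#' The arcsine-transform z-test (the "difference between two independent
#' proportions" family of G*Power): Cohen's effect size
#' h = 2 asin(sqrt(p2)) - 2 asin(sqrt(p1)), test statistic
#' z = |h| / sqrt(1/n1 + 1/n2), and two-sided power
#' Phi(z - z_crit) + Phi(-z - z_crit) at critical value
#' z_crit = z_{1 - alpha/2}.
#'
#' @param p1,p2 Proportions strictly inside (0, 1).
#' @param n1,n2 Group sizes.
#' @param alpha Two-sided significance level.
#' @return A list with `power`, `h`, `z`.
#' @examples
#' power_two_proportions(223 / 575, 51 / 111, 575, 111)$power # about 0.29
#' @export
power_two_proportions <- function(p1, p2, n1, n2, alpha = 0.05) {
  if (any(c(p1, p2) <= 0) || any(c(p1, p2) >= 1)) {
    stop("proportions must lie strictly inside (0, 1)", call. = FALSE)
  }
  if (any(c(n1, n2) < 1)) stop("group sizes must be positive", call. = FALSE)
  h <- 2 * asin(sqrt(p2)) - 2 * asin(sqrt(p1))
  z <- abs(h) / sqrt(1 / n1 + 1 / n2)
  z_crit <- stats::qnorm(1 - alpha / 2)
  power <- stats::pnorm(z - z_crit) + stats::pnorm(-z - z_crit)
  list(power = power, h = h, z = z)
}
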