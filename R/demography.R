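#' Build an age-classified (Leslie) projection matrix
#'
#' Birth-pulse, pre-breeding bookkeeping: fertilities \eqn{m_x} occupy the
#' first row and survival probabilities \eqn{p_x} the subdiagonal, so the
#' entry in row 1, column x+1 is fertility at age x and the entry below the
#' diagonal in column x+1 is survival from age x to x+1. The survival of the
#' last age class is unused (the life table is closed there).
#'
#' @param px survival probabilities per age (length omega+1; the last entry
#'   is ignored).
#' @param mx fertility per age, same length.
#' @return An (omega+1) x (omega+1) matrix of class \code{"leslie_matrix"}.
#' @examples
#' A <- leslie_matrix(px = c(0.5, 0), mx = c(0, 2))
#' leslie_lambda(c(0.5, 0), c(0, 2))  # 1
#' @export
leslie_matrix <- function(px, mx) {
  if (length(px) != length(mx))
    abort_validation("leslie_matrix: px and mx must have the same length")
  check_range(px, "px", 0, 1)
  check_range(mx, "mx", 0, Inf)
  n <- length(px)
  A <- matrix(0, n, n)
  A[1, ] <- mx
  if (n > 1) A[cbind(2:n, 1:(n - 1))] <- px[1:(n - 1)]
  class(A) <- c("leslie_matrix", class(A))
  A
}

# Dominant eigenvalue of a Leslie matrix built from px, mx (real, >= 0).
leslie_lambda <- function(px, mx) {
  dominant_eigenvalue(leslie_matrix(px, mx))
}

dominant_eigenvalue <- function(A) {
  ev <- eigen(unclass(A), only.values = TRUE)$values
  lam <- ev[which.max(Mod(ev))]
  if (abs(Im(lam)) > 1e-8 * (1 + Mod(lam)))
    abort_numeric("dominant eigenvalue is not real (Im = ", signif(Im(lam), 3),
                  "); matrix may be reducible or degenerate")
  max(Re(lam), 0)
}

# Survivorship l_x = prod_{y<x} p_y, l_0 = 1.
survivorship <- function(px) {
  n <- length(px)
  c(1, cumprod(px[-n]))
}

# Stable age structure w_x (right eigenvector) from the closed form
# w_x = l_x lambda^-x, normalized to sum to 1. Exact for Leslie matrices.
stable_structure <- function(px, lambda) {
  lx <- survivorship(px)
  w <- lx * lambda^(-(seq_along(px) - 1L))
  w / sum(w)
}

# Reproductive values v_x (left eigenvector), v at the first age = 1, from the
# backward recursion lambda v_x = m_x v_1 + p_x v_{x+1}. Exact zeros at
# post-reproductive ages.
reproductive_value_vec <- function(px, mx, lambda) {
  n <- length(px)
  v <- numeric(n)
  v[n] <- mx[n] / lambda
  if (n > 1) for (j in (n - 1):1) v[j] <- (mx[j] + px[j] * v[j + 1]) / lambda
  v / v[1]
}

#' Reproductive value schedule
#'
#' Fisher's reproductive value \eqn{v_x}: the expected discounted future
#' reproduction of an individual of age x under the current vital rates,
#' scaled so the first age class has value 1. Ages past the last reproductive
#' age have value exactly 0.
#'
#' @param px,mx vital-rate schedules as in \code{\link{leslie_matrix}}.
#' @return Numeric vector of reproductive values per age.
#' @export
reproductive_value <- function(px, mx) {
  lam <- leslie_lambda(px, mx)
  if (lam <= 0) abort_numeric("reproductive_value: lambda is zero (no reproduction)")
  reproductive_value_vec(px, mx, lam)
}

#' Demographic summary of a life-history schedule
#'
#' @param px,mx vital-rate schedules (see \code{\link{leslie_matrix}}).
#' @return A list of class \code{"demographic_summary"}: \code{lambda}
#'   (dominant eigenvalue, per year), \code{r} (= log lambda), \code{lx}
#'   (survivorship, \code{lx[1] = 1}), \code{R0} (net reproductive rate
#'   \eqn{\sum l_x m_x}), \code{e0} (life expectancy at birth, the discrete
#'   sum \eqn{\sum l_x} with no half-interval correction), \code{TFR}
#'   (\eqn{\sum m_x}), \code{wx} (stable age distribution, sums to 1) and
#'   \code{vx} (reproductive values, first age = 1).
#' @export
demographic_summary <- function(px, mx) {
  lam <- leslie_lambda(px, mx)
  lx <- survivorship(px)
  out <- list(
    lambda = lam,
    r = if (lam > 0) log(lam) else -Inf,
    lx = lx,
    R0 = sum(lx * mx),
    e0 = sum(lx),
    TFR = sum(mx),
    wx = if (lam > 0) stable_structure(px, lam) else rep(NA_real_, length(px)),
    vx = if (lam > 0) reproductive_value_vec(px, mx, lam) else rep(NA_real_, length(px))
  )
  class(out) <- "demographic_summary"
  out
}

#' @export
print.demographic_summary <- function(x, ...) {
  cat(sprintf("lambda = %.6f   r = %.6f\n", x$lambda, x$r))
  cat(sprintf("R0 = %.4f   TFR = %.4f   e0 = %.2f\n", x$R0, x$TFR, x$e0))
  cat(sprintf("ages 0..%d; stable share over 50 = %.4f\n",
              length(x$lx) - 1L,
              if (length(x$lx) > 51L) sum(x$wx[-(1:51)]) else 0))
  invisible(x)
}

#' Sensitivities and elasticities of lambda to the vital rates
#'
#' For the dominant eigenvalue \eqn{\lambda} of the Leslie matrix,
#' \eqn{s_{ij} = \partial\lambda/\partial a_{ij} = v_i w_j / \langle v,w\rangle}
#' evaluated at the structurally nonzero entries: fertility sensitivities
#' \eqn{s_{1x}} and survival sensitivities \eqn{s_{x+1,x}}. Elasticities are
#' \eqn{e_{ij} = (a_{ij}/\lambda) s_{ij}} and sum to 1 over all vital rates.
#'
#' @param px,mx vital-rate schedules.
#' @return A list of class \code{"sensitivity_table"}: \code{lambda},
#'   \code{s_mx} (length omega+1), \code{s_px} (length omega, survival from x
#'   to x+1), \code{e_mx}, \code{e_px}.
#' @export
vital_sensitivities <- function(px, mx) {
  lam <- leslie_lambda(px, mx)
  if (lam <= 0) abort_numeric("vital_sensitivities: lambda is zero")
  n <- length(px)
  w <- stable_structure(px, lam)
  v <- reproductive_value_vec(px, mx, lam)
  denom <- sum(v * w)
  s_mx <- v[1] * w / denom
  s_px <- if (n > 1) v[2:n] * w[1:(n - 1)] / denom else numeric(0)
  out <- list(
    lambda = lam,
    s_mx = s_mx,
    s_px = s_px,
    e_mx = mx * s_mx / lam,
    e_px = px[1:(n - 1)] * s_px / lam
  )
  class(out) <- "sensitivity_table"
  out
}

#' Euler-Lotka residual
#'
#' Under the pre-breeding birth-pulse convention the characteristic equation
#' is \eqn{\sum_x \lambda^{-(x+1)} l_x m_x = 1}; this returns the left-hand
#' side minus 1 at the supplied (or computed) lambda. Used as a consistency
#' check on the eigensolve.
#'
#' @param px,mx vital-rate schedules.
#' @param lambda growth rate; computed from the matrix when missing.
#' @return The residual (should be ~0 at the true lambda).
#' @export
euler_lotka_residual <- function(px, mx, lambda = NULL) {
  if (is.null(lambda)) lambda <- leslie_lambda(px, mx)
  lx <- survivorship(px)
  x <- seq_along(px) - 1L
  sum(lambda^(-(x + 1)) * lx * mx) - 1
}
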