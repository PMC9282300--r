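#' Drop in net reproductive rate when one age's production is removed
#'
#' For each age y, the production column P_y is zeroed, the food ratio is
#' recomputed one-shot with the baseline survivorship (a local perturbation,
#' matching the fixed-\eqn{l_x/D_T} convention of the sensitivity chain), the
#' nutritional response is re-applied to the baseline vital rates, and the net
#' reproductive rate R0* is recomputed. \eqn{\Delta R_{Py} = R_0^{(0)} - R_0^*}
#' is nonnegative: removing production cannot raise R0. Set
#' \code{re_equilibrate = TRUE} to solve the survivorship feedback inside the
#' perturbation instead (sensitivity analysis).
#'
#' @param cal a \code{\link{calibrate_profiles}} result.
#' @param re_equilibrate logical (default FALSE).
#' @return Numeric vector \eqn{\Delta R_{Py}} per age.
#' @export
delta_R0 <- function(cal, re_equilibrate = FALSE) {
  n <- omega_of(cal$lh0) + 1L
  R0_base <- cal$summary$R0
  DT <- cal$DT
  vapply(seq_len(n), function(i) {
    P <- cal$Px
    if (P[i] == 0 && !re_equilibrate) return(0)
    P[i] <- 0
    sub_i <- subsistence(Px = P, Dx = cal$Dx)
    E <- if (re_equilibrate)
      food_ratio(sub_i, cal$lh0, cal$gamma, self_consistent = TRUE)
    else
      food_ratio(sub_i, cal$lh0, lx = cal$lx)
    lh <- suppressWarnings(apply_nutrition(cal$lh0, E, cal$gamma))
    R0_base - sum(survivorship(lh$px) * lh$mx)
  }, numeric(1))
}

#' Productive value
#'
#' The transfer analogue of Fisher's reproductive value: the expected residual
#' fitness value of the production transfers an individual of age x will make
#' over its remaining lifetime,
#' \deqn{PV_x = \tilde r_x k \frac{\lambda^{x-1}}{l_x} \sum_{y \ge x}
#'       \lambda^{-y} \Delta R_{Py},}
#' with the same direct-offspring relatedness benchmark
#' \eqn{\tilde r_x = r_x / 0.5} as the other transfer metrics. Replacing
#' \eqn{\Delta R_{Py}} by \eqn{l_y m_y} in the sum recovers the classic
#' discrete reproductive-value recursion, which is why the two metrics are
#' directly comparable age profiles. PV is zero past the last productive age.
#'
#' @param cal a \code{\link{calibrate_profiles}} result.
#' @param social a \code{\link{social_profile}}.
#' @param dR optional precomputed \code{\link{delta_R0}} vector.
#' @return A list with \code{PV} (raw), \code{PV_norm} (divided by its
#'   maximum; NA-safe) and \code{dR}.
#' @export
productive_value <- function(cal, social, dR = NULL) {
  check_social(cal, social)
  if (is.null(dR)) dR <- delta_R0(cal)
  lam <- cal$summary$lambda
  x <- cal$lh0$age
  disc <- lam^(-x) * dR
  tail_sum <- rev(cumsum(rev(disc)))          # sum_{y >= x} lambda^-y dR_y
  lx <- cal$lx
  pv <- rel_tilde(social) * social$k * lam^(x - 1) / lx * tail_sum
  pv[lx <= 0] <- NA_real_
  mx_pv <- suppressWarnings(max(pv, na.rm = TRUE))
  list(PV = pv,
       PV_norm = if (is.finite(mx_pv) && mx_pv > 0) pv / mx_pv else pv,
       dR = dR)
}
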