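# Serial production-sensitivity chain: production at age x raises the food
# ratio E (dE/dPx = lx/DT under need-based sharing), E moves every vital rate
# through Z, and each vital rate moves lambda through its eigenvalue
# sensitivity. The recipient sum
#   S = sum_y s_{y+1,y} dp_y/dE + sum_y s_{1y} dm_y/dE
# is common to all donor ages; the donor's age enters only through lx/DT and
# the social discount r~_x k.

recipient_sum <- function(cal) {
  dm <- dm_dE(cal$lh0$mx, cal$E0, cal$gamma)
  dp <- dp_dE(cal$lh0$qx, cal$E0, cal$gamma)
  n <- length(dm)
  sum(cal$sens$s_px * dp[1:(n - 1)]) + sum(cal$sens$s_mx * dm)
}

check_social <- function(cal, social) {
  if (omega_of(social) != omega_of(cal$lh0))
    abort_validation("social profile and calibration cover different age ranges")
  invisible(TRUE)
}

# Relatedness scaled to the direct-offspring benchmark r = 0.5, so r~ k = 1
# reproduces the undiscounted chain.
rel_tilde <- function(social) social$rx / 0.5

#' Sensitivity of lambda to age-specific production
#'
#' The marginal change in the sharing group's growth rate per extra kcal/day
#' produced by an age-x individual, discounted by the donor's mean relatedness
#' to the group (scaled to the direct-offspring benchmark 0.5) and by the
#' cooperation probability k:
#' \eqn{s_{Px} = (r_x/0.5)\, k\, S\, l_x / D_T}, where S sums the nutritional
#' effects over recipients of all ages. Derivatives are evaluated at the
#' calibrated baseline (E_0, baseline survivorship and demand total), with no
#' re-equilibration inside the derivative.
#'
#' @param cal a \code{\link{calibrate_profiles}} result.
#' @param social a \code{\link{social_profile}} on the same ages.
#' @return Numeric vector s_Px per age (per kcal/day).
#' @export
production_sensitivity <- function(cal, social) {
  check_social(cal, social)
  rel_tilde(social) * social$k * recipient_sum(cal) * cal$lx / cal$DT
}

#' Indirect fitness contribution of production transfers
#'
#' \eqn{\Delta\lambda_{Px} = P_x s_{Px}}: the first-order fitness the group
#' would lose if all age-x individuals stopped foraging.
#'
#' @param Px calibrated production schedule.
#' @param sPx production sensitivities (\code{\link{production_sensitivity}}).
#' @return Numeric vector per age.
#' @export
indirect_contribution <- function(Px, sPx) {
  if (length(Px) != length(sPx))
    abort_validation("indirect_contribution: length mismatch")
  Px * sPx
}

#' Fitness elasticity to production, raw and rescaled
#'
#' Raw elasticities \eqn{e_{Px} = s_{Px} P_x / \lambda} give the proportional
#' change in lambda per 1 percent change in age-x production. Because these do
#' not live on the unit-sum scale of the vital-rate elasticities, they are
#' rescaled so their age-sum equals the total fertility elasticity
#' \eqn{\sum_x e_{mx}}, which permits comparison of age profiles across
#' populations.
#'
#' @param sPx production sensitivities.
#' @param Px calibrated production.
#' @param lambda baseline growth rate.
#' @param e_mx fertility elasticities per age.
#' @return List with \code{raw} and \code{scaled} vectors.
#' @export
production_elasticity <- function(sPx, Px, lambda, e_mx) {
  if (lambda <= 0) abort_validation("production_elasticity: lambda must be positive")
  raw <- sPx * Px / lambda
  tot <- sum(raw)
  if (tot <= 0) {
    warning("production_elasticity: raw elasticities sum to zero; scaled set to 0")
    return(list(raw = raw, scaled = raw * 0))
  }
  list(raw = raw, scaled = raw * sum(e_mx) / tot)
}

#' Fertility equivalent of production transfers
#'
#' Solves \eqn{s_{mx} m_x^* = s_{Px} P_x} for the extra fertility at each age
#' that would contribute the same fitness as that age's production transfers.
#'
#' @param sPx production sensitivities.
#' @param Px calibrated production.
#' @param s_mx fertility sensitivities per age.
#' @return m_x* per age (NA where the fertility sensitivity is zero).
#' @export
fertility_equivalent <- function(sPx, Px, s_mx) {
  out <- ifelse(s_mx > 0, sPx * Px / s_mx, NA_real_)
  out
}

#' Late-life fertility-equivalent total (TFR_50)
#'
#' The expected number of future offspring of both sexes that a mother living
#' from age \code{from} to age \code{to} (50 to 80 by default, truncated at
#' the last age of the schedule) would bear under the fertility-equivalent
#' schedule: \eqn{2 \sum m_x^*} over those ages, unconditioned on survival.
#'
#' @param mstar fertility-equivalent schedule (\code{\link{fertility_equivalent}}).
#' @param from,to inclusive age bounds (defaults 50 and 80).
#' @return A single number.
#' @export
tfr50 <- function(mstar, from = 50, to = 80) {
  ages <- seq_along(mstar) - 1L
  keep <- ages >= from & ages <= to
  2 * sum(mstar[keep], na.rm = TRUE)
}

#' Mean ages of reproduction, production and demand
#'
#' \eqn{x_M = \sum_x x m_x / \sum_x m_x}, and analogously with production or
#' demand in place of fertility. The default follows this unweighted formula;
#' \code{weighting = "survivorship"} multiplies the schedule by \eqn{l_x} and
#' \code{"stable"} by the stable age structure, for sensitivity analysis.
#'
#' @param schedule a nonnegative age schedule (mx, Px or Dx).
#' @param weighting \code{"formula"}, \code{"survivorship"} or \code{"stable"}.
#' @param lx survivorship (required for \code{"survivorship"}).
#' @param wx stable structure (required for \code{"stable"}).
#' @return The weighted mean age.
#' @export
mean_age <- function(schedule, weighting = c("formula", "survivorship", "stable"),
                     lx = NULL, wx = NULL) {
  weighting <- match.arg(weighting)
  w <- switch(weighting,
              formula = schedule,
              survivorship = {
                if (is.null(lx)) abort_validation("mean_age: lx required")
                schedule * lx
              },
              stable = {
                if (is.null(wx)) abort_validation("mean_age: wx required")
                schedule * wx
              })
  tot <- sum(w)
  if (tot <= 0) abort_validation("mean_age: schedule sums to zero")
  x <- seq_along(schedule) - 1L
  sum(x * w) / tot
}

#' Cumulative share of an age schedule remaining after each cut age
#'
#' \eqn{share(a) = \sum_{x > a} v_x / \sum_x v_x}. Used with
#' \eqn{v_x = P_x l_x} (survivorship-weighted production, consistent with the
#' definition of total production \eqn{P_T}), with \eqn{v_x = \Delta\lambda_{Px}}
#' (indirect contributions) or with \eqn{v_x = m_x s_{1x}} (direct fertility
#' contributions).
#'
#' @param values nonnegative age schedule (age 0 first).
#' @param cut_ages ages after which the remaining share is reported.
#' @return Named numeric vector of shares, non-increasing in the cut age.
#' @export
cumulative_shares <- function(values, cut_ages = c(30, 40, 50)) {
  if (any(values < 0, na.rm = TRUE))
    abort_validation("cumulative_shares: negative values")
  tot <- sum(values, na.rm = TRUE)
  if (tot <= 0) abort_validation("cumulative_shares: schedule sums to zero")
  ages <- seq_along(values) - 1L
  out <- vapply(cut_ages, function(a) sum(values[ages > a], na.rm = TRUE) / tot,
                numeric(1))
  names(out) <- paste0("after", cut_ages)
  out
}

#' Full transfer-selection report
#'
#' Runs the whole pipeline at a calibrated baseline: production sensitivities,
#' indirect contributions, raw and rescaled production elasticities, fertility
#' equivalents and TFR_50, reproductive and productive value, mean ages and
#' cumulative shares.
#'
#' @param cal a \code{\link{calibrate_profiles}} result.
#' @param social a \code{\link{social_profile}}.
#' @param cut_ages cut ages for the share summaries (default 30, 40, 50).
#' @return An object of class \code{"selection_report"} with elements
#'   \code{table} (per-age data frame with columns \code{age, px, mx, Px, Dx,
#'   lx, s_mx, s_px, e_mx, e_px_scaled, dlambda_Px, m_star, RV, PV}),
#'   \code{summary} (named list: lambda, r, E0, Emin, mean ages, elasticity
#'   totals, share profiles, TFR_50, stable share over 50) and \code{social}
#'   (the parameters used).
#' @export
selection_report <- function(cal, social, cut_ages = c(30, 40, 50)) {
  check_social(cal, social)
  n <- omega_of(cal$lh0) + 1L
  sens <- cal$sens
  dem <- cal$summary

  sPx <- production_sensitivity(cal, social)
  dLam <- indirect_contribution(cal$Px, sPx)
  el <- production_elasticity(sPx, cal$Px, dem$lambda, sens$e_mx)
  mstar <- fertility_equivalent(sPx, cal$Px, sens$s_mx)
  pv <- productive_value(cal, social)

  tab <- data.frame(
    age = cal$lh0$age,
    px = cal$lh_base$px,
    mx = cal$lh_base$mx,
    Px = cal$Px,
    Dx = cal$Dx,
    lx = cal$lx,
    s_mx = sens$s_mx,
    s_px = c(sens$s_px, NA_real_),
    e_mx = sens$e_mx,
    e_px_scaled = el$scaled,
    dlambda_Px = dLam,
    m_star = mstar,
    RV = dem$vx,
    PV = pv$PV
  )

  fert_contrib <- cal$lh_base$mx * sens$s_mx
  summ <- list(
    lambda = dem$lambda, r = dem$r,
    E0 = cal$E0, Emin = cal$Emin, gamma = cal$gamma,
    R0 = dem$R0, e0 = dem$e0, TFR = dem$TFR,
    # survivorship weighting, consistent with the group totals P_T, D_T
    x_M = mean_age(cal$lh_base$mx, "survivorship", lx = cal$lx),
    x_P = mean_age(cal$Px, "survivorship", lx = cal$lx),
    x_D = mean_age(cal$Dx, "survivorship", lx = cal$lx),
    fertility_elasticity_total = sum(sens$e_mx),
    production_share = cumulative_shares(cal$Px * cal$lx, cut_ages),
    indirect_share = cumulative_shares(dLam, cut_ages),
    fertility_share = cumulative_shares(fert_contrib, cut_ages),
    TFR_50 = tfr50(mstar),
    stable_share_over50 = if (n > 51L) sum(dem$wx[cal$lh0$age > 50]) else 0
  )
  structure(list(table = tab, summary = summ,
                 social = list(rx = social$rx, k = social$k,
                               gamma = cal$gamma, E0 = cal$E0)),
            class = "selection_report")
}

#' @export
print.selection_report <- function(x, ...) {
  s <- x$summary
  cat("Transfer-selection report\n")
  cat(sprintf("  lambda = %.6f (r = %.4f)   E0 = %.4f   Emin = %.4f   gamma = %.3g\n",
              s$lambda, s$r, s$E0, s$Emin, s$gamma))
  cat(sprintf("  mean ages: reproduction %.1f, production %.1f, demand %.1f (x_P - x_D = %.1f)\n",
              s$x_M, s$x_P, s$x_D, s$x_P - s$x_D))
  cat(sprintf("  total fertility elasticity = %.4f of all vital-rate elasticities\n",
              s$fertility_elasticity_total))
  cat("  production share remaining: ",
      paste(sprintf("%s %.1f%%", names(s$production_share), 100 * s$production_share),
            collapse = ", "), "\n", sep = "")
  cat("  indirect-contribution share remaining: ",
      paste(sprintf("%s %.1f%%", names(s$indirect_share), 100 * s$indirect_share),
            collapse = ", "), "\n", sep = "")
  cat("  fertility-contribution share remaining: ",
      paste(sprintf("%s %.1f%%", names(s$fertility_share), 100 * s$fertility_share),
            collapse = ", "), "\n", sep = "")
  cat(sprintf("  TFR_50 = %.3f offspring (both sexes, ages 50-80)\n", s$TFR_50))
  cat(sprintf("  stable population share over age 50 = %.1f%%\n",
              100 * s$stable_share_over50))
  invisible(x)
}
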