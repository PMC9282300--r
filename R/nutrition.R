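#' Vital-rate scalar Z
#'
#' The concave nutritional response \eqn{Z = E(\gamma+1)/(E+\gamma)}:
#' fertility is multiplied by Z and mortality divided by Z when the food
#' ratio E falls below the replete level 1. Z(1, gamma) = 1 for every gamma;
#' large gamma makes the response nearly linear in E, small gamma makes it
#' saturate (little cost to mild deprivation).
#'
#' @param E food ratio, > 0 (the model is only used on (0, 1]).
#' @param gamma curvature parameter, > 0.
#' @return Z, same length as E.
#' @examples
#' vital_scalar(1, 0.3)          # 1
#' vital_scalar(0.5, 0.9)        # 0.5 * 1.9 / 1.4
#' @export
vital_scalar <- function(E, gamma) {
  if (any(!is.finite(E)) || any(E <= 0))
    abort_validation("vital_scalar: E must be positive")
  if (any(!is.finite(gamma)) || any(gamma <= 0))
    abort_validation("vital_scalar: gamma must be positive")
  E * (gamma + 1) / (E + gamma)
}

# dZ/dE = gamma (gamma+1) / (E+gamma)^2
dZ_dE <- function(E, gamma) gamma * (gamma + 1) / (E + gamma)^2

#' Derivatives of fertility and survival with respect to the food ratio
#'
#' With \eqn{m_x(E) = Z m_x^{(0)}} and \eqn{p_x(E) = 1 - q_x^{(0)}/Z},
#' the exact derivatives are
#' \eqn{dm_x/dE = m_x^{(0)} \gamma(\gamma+1)/(E+\gamma)^2} and
#' \eqn{dp_x/dE = q_x^{(0)} \gamma / ((\gamma+1) E^2)}. Both are nonnegative:
#' better nutrition raises fertility and survival.
#'
#' @param m0,q0 baseline (replete) fertility / mortality schedules.
#' @param E food ratio in (0, 1].
#' @param gamma curvature parameter.
#' @return Numeric vector of derivatives per age.
#' @name nutrition_derivatives
NULL

#' @rdname nutrition_derivatives
#' @export
dm_dE <- function(m0, E, gamma) m0 * dZ_dE(E, gamma)

#' @rdname nutrition_derivatives
#' @export
dp_dE <- function(q0, E, gamma) q0 * gamma / ((gamma + 1) * E^2)

#' Apply a nutritional state to baseline vital rates
#'
#' Fertility is multiplied by Z(E, gamma) and mortality divided by it
#' (clipped at 1 where the division would exceed certain death; a warning is
#' issued unless the baseline rate was already 1, as at the closing age).
#' E above 1 confers no benefit (no hypernutrition): Z is capped at 1.
#'
#' @param lh0 baseline (replete) \code{\link{life_history}}.
#' @param E food ratio.
#' @param gamma curvature parameter.
#' @return A \code{\link{life_history}} with nutrition-adjusted rates.
#' @export
apply_nutrition <- function(lh0, E, gamma) {
  Z <- vital_scalar(min(E, 1), gamma)
  m <- Z * lh0$mx
  q <- lh0$qx / Z
  clipped <- q > 1 & lh0$qx < 1
  if (any(clipped))
    warning("apply_nutrition: mortality clipped at 1 for ",
            sum(clipped), " age(s) (E = ", signif(E, 4), ")")
  q <- pmin(q, 1)
  life_history(qx = q, mx = m)
}

#' Food ratio of a sharing group
#'
#' \eqn{E = P_T / D_T} with \eqn{P_T = \sum_x P_x l_x} and
#' \eqn{D_T = \sum_x D_x l_x}: production and demand totalled over the
#' group's age structure via survivorship. Under need-based sharing every
#' individual receives the same fraction E of its demand. In one-shot mode
#' the supplied (or replete) survivorship is used directly; in
#' self-consistent mode E solves the fixed point \eqn{E = P_T(l(E))/D_T(l(E))}
#' in which survivorship itself responds to nutrition, by bracketed root
#' finding (tolerance 1e-10). E is capped at 1 (no hypernutrition).
#'
#' @param sub a \code{\link{subsistence}} (its \code{scale} multiplies Px).
#' @param lh0 baseline \code{\link{life_history}} (replete rates).
#' @param gamma curvature parameter (needed for self-consistent mode).
#' @param self_consistent logical; solve the survivorship feedback?
#' @param lx optional survivorship for one-shot mode (defaults to replete).
#' @return The food ratio E in (0, 1].
#' @export
food_ratio <- function(sub, lh0, gamma = NULL, self_consistent = FALSE, lx = NULL) {
  P <- sub$Px * sub$scale
  D <- sub$Dx
  if (!self_consistent) {
    if (is.null(lx)) lx <- survivorship(lh0$px)
    DT <- sum(D * lx)
    if (DT <= 0) abort_validation("food_ratio: total demand is zero")
    return(min(sum(P * lx) / DT, 1))
  }
  if (is.null(gamma)) abort_validation("food_ratio: gamma required for self-consistent mode")
  g <- function(E) {
    lx <- survivorship(suppressWarnings(apply_nutrition(lh0, E, gamma))$px)
    E - sum(P * lx) / sum(D * lx)
  }
  if (g(1) <= 0) return(1)  # production meets demand at replete rates
  # g is not monotone (survivorship collapses at starvation-level E), so
  # bracket the root nearest the replete state by scanning down from E = 1.
  grid <- seq(1, 0.02, by = -0.02)
  gv <- g(grid[1])
  for (i in 2:length(grid)) {
    gv_new <- g(grid[i])
    if (gv_new <= 0)
      return(stats::uniroot(g, c(grid[i], grid[i - 1]), tol = 1e-10)$root)
    gv <- gv_new
  }
  abort_numeric("food_ratio: no self-consistent root in (0, 1]; ",
                "production too low -- recalibrate the profiles")
}

# log growth rate at food ratio E, from baseline rates (no clip warnings:
# the calibration stays in the unclipped regime by construction).
growth_at_E <- function(lh0, E, gamma) {
  lh <- suppressWarnings(apply_nutrition(lh0, E, gamma))
  log(leslie_lambda(lh$px, lh$mx))
}

#' Calibrate a subsistence and life-history pair to a baseline growth rate
#'
#' Two-step calibration. First, production is scaled so that total production
#' meets total demand at replete vital rates (\eqn{P_T = D_T}, E = 1), where
#' the population grows at its maximum rate r_max. Second, production is
#' reduced proportionally at every age (multiplier rho) until the
#' self-consistent intrinsic growth rate falls to \code{r_target} (1 percent
#' per year by default, the contemporary hunter-gatherer average); the food
#' ratio there is the baseline E_0. The stationarity threshold E_min
#' (lambda = 1) is also recorded; below it the population crashes.
#'
#' @param lh0 baseline (replete) \code{\link{life_history}}. Input rates are
#'   treated as the replete rates; set \code{rescale_fertility = TRUE} to
#'   force the replete growth rate to \code{r_max} exactly.
#' @param sub a \code{\link{subsistence}}.
#' @param gamma curvature parameter of the nutritional response.
#' @param r_target baseline intrinsic growth rate (default 0.01).
#' @param r_max required replete growth when \code{rescale_fertility} is TRUE.
#' @param rescale_fertility logical (default FALSE).
#' @return An object of class \code{"calibration"}: the inputs plus
#'   \code{replete_scale}, \code{rho}, \code{E0}, \code{Emin}, \code{r_max}
#'   (realized replete growth), the baseline vital rates \code{lh_base},
#'   survivorship \code{lx}, calibrated production \code{Px} (= raw Px *
#'   replete_scale * rho), demand totals, \code{summary}
#'   (a \code{\link{demographic_summary}}) and \code{sens}
#'   (a \code{\link{vital_sensitivities}} table), all at E_0.
#' @export
calibrate_profiles <- function(lh0, sub, gamma, r_target = 0.01,
                               r_max = NULL, rescale_fertility = FALSE) {
  if (omega_of(lh0) != omega_of(sub))
    abort_validation("calibrate_profiles: profiles have different last ages")
  if (!is.finite(gamma) || gamma <= 0)
    abort_validation("calibrate_profiles: gamma must be positive")

  if (rescale_fertility) {
    if (is.null(r_max)) abort_validation("calibrate_profiles: r_max required to rescale fertility")
    fac <- replete_fertility_factor(lh0$qx, lh0$mx, r_max)
    lh0 <- life_history(qx = lh0$qx, mx = fac * lh0$mx)
  }

  lx_rep <- survivorship(lh0$px)
  P_raw <- sub$Px * sub$scale
  PT_raw <- sum(P_raw * lx_rep)
  if (PT_raw <= 0) abort_validation("calibrate_profiles: total production is zero")
  replete_scale <- sum(sub$Dx * lx_rep) / PT_raw

  r_rep <- log(leslie_lambda(lh0$px, lh0$mx))
  if (r_rep < r_target)
    abort_numeric("calibrate_profiles: replete growth (", signif(r_rep, 4),
                  ") is below r_target (", r_target, "); not bracketed. ",
                  "Consider rescale_fertility = TRUE.")

  # baseline food ratio: r(E0) = r_target, r strictly increasing in E
  f <- function(E) growth_at_E(lh0, E, gamma) - r_target
  E0 <- if (f(1) <= 1e-14) 1 else stats::uniroot(f, c(1e-6, 1), tol = 1e-12)$root

  # stationarity threshold: lambda(Emin) = 1
  g <- function(E) growth_at_E(lh0, E, gamma)
  Emin <- if (r_target <= 0) E0 else stats::uniroot(g, c(1e-6, E0), tol = 1e-12)$root

  # proportional production reduction consistent with E0 at its own survivorship
  lh_base <- suppressWarnings(apply_nutrition(lh0, E0, gamma))
  lx <- survivorship(lh_base$px)
  rho <- E0 * sum(sub$Dx * lx) / sum(P_raw * replete_scale * lx)
  rho <- min(rho, 1)

  Px_cal <- P_raw * replete_scale * rho
  out <- list(
    lh0 = lh0, sub = sub,
    sub_cal = subsistence(Px = sub$Px, Dx = sub$Dx,
                          scale = sub$scale * replete_scale * rho),
    gamma = gamma,
    r_target = r_target, r_max = r_rep,
    replete_scale = replete_scale, rho = rho,
    E0 = E0, Emin = Emin,
    lh_base = lh_base, lx = lx,
    Px = Px_cal, Dx = sub$Dx,
    PT = sum(Px_cal * lx), DT = sum(sub$Dx * lx),
    summary = demographic_summary(lh_base$px, lh_base$mx),
    sens = vital_sensitivities(lh_base$px, lh_base$mx)
  )
  class(out) <- "calibration"
  out
}

#' @export
print.calibration <- function(x, ...) {
  cat("Nutrition-dependent baseline calibration\n")
  cat(sprintf("  gamma = %.3g   replete r_max = %.4f   target r = %.4f\n",
              x$gamma, x$r_max, x$r_target))
  cat(sprintf("  replete production scale = %.4f   rho = %.4f\n",
              x$replete_scale, x$rho))
  cat(sprintf("  E0 = %.6f   Emin = %.6f\n", x$E0, x$Emin))
  cat(sprintf("  baseline lambda = %.6f (r = %.6f), R0 = %.3f, e0 = %.1f\n",
              x$summary$lambda, x$summary$r, x$summary$R0, x$summary$e0))
  invisible(x)
}
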