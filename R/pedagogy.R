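#' Preset parameter sets for the skill-based production model
#'
#' All constants of the two stylized foraging niches live here rather than in
#' code. \code{high_skill}: production depends strongly on slowly accumulating
#' skill (large skill weight, slow saturation), as in extractive hunting and
#' gathering. \code{low_skill}: production is mostly capacity-limited and
#' skill saturates within the first decade of foraging. Fields: \code{w}
#' (skill weight in [0,1]), \code{rho_s} (skill-acquisition rate per year of
#' experience), \code{cap_mid}, \code{cap_rise} (logistic rise of biomechanical
#' capacity), \code{cap_sen_start}, \code{cap_sen_width} (Gaussian senescent
#' decline) and \code{pmax} (kcal/day at full capacity and skill).
#'
#' @format A named list with elements \code{high_skill} and \code{low_skill}.
#' @export
pedagogy_presets <- list(
  high_skill = list(w = 0.8, rho_s = 0.045, cap_mid = 12, cap_rise = 4,
                    cap_sen_start = 45, cap_sen_width = 20, pmax = 3500),
  low_skill = list(w = 0.25, rho_s = 0.25, cap_mid = 10, cap_rise = 3,
                   cap_sen_start = 45, cap_sen_width = 20, pmax = 3500)
)

#' Skill-based production model
#'
#' Production at age x is capacity times skill,
#' \eqn{P_x = p_{max} M_x S_x^w}: a logistic-rise, senescing biomechanical
#' capacity curve \eqn{M_x} and a saturating-exponential skill curve
#' \eqn{S_x = 1 - e^{-\rho_s x}} accumulating with foraging experience. The
#' skill weight w blends skill- vs capacity-limited production.
#'
#' @param preset \code{"high-skill"} or \code{"low-skill"}
#'   (see \code{\link{pedagogy_presets}}).
#' @param omega last age (default 90).
#' @param params named list overriding preset entries.
#' @return An object of class \code{"skill_model"} with the parameter set and
#'   the baseline curves \code{Mx}, \code{Sx}, \code{Px}.
#' @export
skill_production_model <- function(preset = c("high-skill", "low-skill"),
                                   omega = 90L, params = list()) {
  preset <- match.arg(preset)
  p <- pedagogy_presets[[if (preset == "high-skill") "high_skill" else "low_skill"]]
  p <- utils::modifyList(p, params)
  x <- 0:omega
  Mx <- stats::plogis((x - p$cap_mid) / p$cap_rise) *
    exp(-0.5 * (pmax(x - p$cap_sen_start, 0) / p$cap_sen_width)^2)
  Sx <- 1 - exp(-p$rho_s * x)
  structure(c(p, list(preset = preset, omega = omega, age = x,
                      Mx = Mx, Sx = Sx, Px = p$pmax * Mx * Sx^p$w)),
            class = "skill_model")
}

#' Pedagogy regime
#'
#' @param phi fractional production cost to teachers while teaching, in [0, 1).
#' @param theta proportional boost to pupils' skill-acquisition rate
#'   (1 = twice as fast) before teacher-quality discounting.
#' @param a pupil age at onset of instruction (years).
#' @param b teacher age at onset of instruction (years), \code{b >= a}.
#' @param t duration of instruction (years).
#' @param omega last age of the schedules the regime will act on.
#' @return An object of class \code{"pedagogy_regime"}.
#' @export
pedagogy_regime <- function(phi, theta, a, b, t, omega) {
  if (!is.finite(phi) || phi < 0 || phi >= 1)
    abort_validation("pedagogy_regime: phi must lie in [0, 1)")
  if (!is.finite(theta) || theta < 0)
    abort_validation("pedagogy_regime: theta must be nonnegative")
  if (a + t > omega)
    abort_validation("pedagogy_regime: instruction window a + t exceeds omega")
  if (b < a)
    abort_validation("pedagogy_regime: teachers must be at least pupil age (b >= a)")
  if (b + t > omega + 1)
    abort_validation("pedagogy_regime: teaching window b + t exceeds the age range")
  structure(list(phi = phi, theta = theta, a = a, b = b, t = t, omega = omega),
            class = "pedagogy_regime")
}

# Effective boost to the pupils' acquisition rate. Teaching quality scales
# with the teachers' own (baseline) mean skill over their teaching window --
# knowledge is retained into old age even as capacity senesces -- and with
# demographic availability: the survivorship-weighted abundance of teachers
# relative to pupils caps instruction coverage at 1. This is what creates
# interior optimal teacher ages: young teachers are unskilled, very old
# teachers are scarce.
effective_theta <- function(model, regime, lx) {
  tw <- regime$b + seq_len(max(regime$t, 1)) - 1L   # teacher ages b .. b+t-1
  tw <- tw[tw <= model$omega]
  pw <- regime$a + seq_len(max(regime$t, 1)) - 1L   # pupil ages a .. a+t-1
  skill <- mean(model$Sx[tw + 1L])
  avail <- min(1, sum(lx[tw + 1L]) / sum(lx[pw + 1L]))
  regime$theta * skill * avail
}

#' Apply a pedagogy regime to a skill-production model
#'
#' Pupils' effective foraging experience accrues at rate (1 + theta_eff)
#' during the instruction window [a, a+t), where theta_eff is the nominal
#' boost discounted by teacher skill and teacher availability (see source);
#' their skill curve, and hence production at every later age, shifts
#' upward. Teachers' production is multiplied by (1 - phi) on [b, b+t).
#' The returned schedule is the steady-state population production profile:
#' every cohort passes through the pupil window, and ages in the teaching
#' window bear the cost.
#'
#' @param model a \code{\link{skill_production_model}}.
#' @param regime a \code{\link{pedagogy_regime}}.
#' @param lx baseline survivorship (for teacher availability).
#' @return List with \code{Px} (modified schedule), \code{Sx} (modified skill),
#'   \code{theta_eff} and the inputs.
#' @export
apply_pedagogy <- function(model, regime, lx) {
  if (length(lx) != model$omega + 1L)
    abort_validation("apply_pedagogy: lx length does not match the model's ages")
  th <- effective_theta(model, regime, lx)
  x <- model$age
  # extra effective experience accumulated by age x
  extra <- th * pmin(pmax(x - regime$a, 0), regime$t)
  Sx <- 1 - exp(-model$rho_s * (x + extra))
  cost <- ifelse(x >= regime$b & x < regime$b + regime$t, 1 - regime$phi, 1)
  list(Px = model$pmax * model$Mx * Sx^model$w * cost,
       Sx = Sx, theta_eff = th, model = model, regime = regime)
}

# Growth rate of the calibrated group when the raw production shape is
# replaced by `Px_raw` (same replete scale and rho as the calibration, so the
# null regime reproduces the baseline bit for bit).
pedagogy_growth <- function(cal, Px_raw) {
  sub <- subsistence(Px = Px_raw, Dx = cal$Dx, scale = cal$sub_cal$scale)
  E <- food_ratio(sub, cal$lh0, cal$gamma, self_consistent = TRUE)
  growth_at_E(cal$lh0, E, cal$gamma)
}

#' Fitness gain from a pedagogy regime
#'
#' Recomputes the self-consistent food ratio and intrinsic growth rate with
#' the pedagogy-modified production schedule and returns the change in growth
#' relative to the unmodified schedule, discounted by the teachers' scaled
#' relatedness \eqn{r_b/0.5} and the cooperation probability k. The
#' calibration must have been built on the model's baseline production
#' (\code{cal$sub$Px == model$Px}).
#'
#' @param cal a \code{\link{calibrate_profiles}} result on the model's
#'   baseline schedule.
#' @param model a \code{\link{skill_production_model}}.
#' @param social a \code{\link{social_profile}}.
#' @param regime a \code{\link{pedagogy_regime}}.
#' @return A list with \code{delta_r}, the raw (undiscounted) \code{delta_r_raw},
#'   \code{r_base}, \code{r_new} and \code{theta_eff}.
#' @export
pedagogy_fitness_gain <- function(cal, model, social, regime) {
  check_social(cal, social)
  if (!isTRUE(all.equal(cal$sub$Px, model$Px, tolerance = 1e-10)))
    abort_validation("pedagogy_fitness_gain: calibration was not built on the model's baseline production")
  mod <- apply_pedagogy(model, regime, cal$lx)
  r_base <- pedagogy_growth(cal, model$Px)
  r_new <- pedagogy_growth(cal, mod$Px)
  rb <- social$rx[regime$b + 1L] / 0.5
  list(delta_r = rb * social$k * (r_new - r_base),
       delta_r_raw = r_new - r_base,
       r_base = r_base, r_new = r_new, theta_eff = mod$theta_eff)
}

#' Optimal teacher age for a pedagogy regime
#'
#' Sweeps the teacher onset age b over a grid, returning the full fitness-gain
#' curve, the gain-maximizing age b*, and the break-even ages where the gain
#' crosses zero.
#'
#' @param cal,model,social as in \code{\link{pedagogy_fitness_gain}}.
#' @param phi,theta,a,t regime parameters held fixed across the sweep.
#' @param b_grid integer vector of candidate teacher onset ages
#'   (default: a to omega - t).
#' @return A list with \code{b_star}, \code{curve} (data frame
#'   \code{teacher_age, delta_r}) and \code{break_even} (grid ages where the
#'   gain changes sign).
#' @export
optimize_teacher_age <- function(cal, model, social, phi, theta, a, t,
                                 b_grid = NULL) {
  if (is.null(b_grid)) b_grid <- seq(a, model$omega - t)
  if (!length(b_grid)) abort_validation("optimize_teacher_age: empty teacher-age grid")
  gains <- vapply(b_grid, function(b) {
    reg <- pedagogy_regime(phi, theta, a, b, t, model$omega)
    pedagogy_fitness_gain(cal, model, social, reg)$delta_r
  }, numeric(1))
  sgn <- sign(gains)
  flips <- which(diff(sgn) != 0)
  list(b_star = b_grid[which.max(gains)],
       curve = data.frame(teacher_age = b_grid, delta_r = gains),
       break_even = b_grid[flips])
}
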