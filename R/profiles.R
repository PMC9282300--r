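#' Construct a life-history profile
#'
#' Bundles baseline ("replete") age-specific mortality and fertility into a
#' validated object. Ages are integer one-year classes starting at 0 and the
#' life table is closed: mortality at the last age \eqn{\omega} must be 1.
#'
#' @param qx numeric vector of annual mortality probabilities, one per age
#'   starting at age 0; \code{qx[length(qx)] == 1}.
#' @param mx numeric vector of fertility (daughters per female per year),
#'   same length as \code{qx}.
#' @return An object of class \code{"life_history"}: a list with elements
#'   \code{age}, \code{qx}, \code{px} (= 1 - qx) and \code{mx}.
#' @examples
#' lh <- life_history(qx = c(0.3, 0.1, 1), mx = c(0, 1.2, 0.4))
#' lh$px
#' @export
life_history <- function(qx, mx) {
  if (length(qx) != length(mx))
    abort_validation("life_history: qx and mx must have the same length")
  ages <- seq_along(qx) - 1L
  check_ages(ages, "life_history")
  check_range(qx, "qx", 0, 1)
  check_range(mx, "mx", 0, Inf)
  if (qx[length(qx)] != 1)
    abort_validation("qx: life table must be closed, q at the last age (",
                     length(qx) - 1L, ") is ", qx[length(qx)], ", not 1")
  structure(list(age = ages, qx = as.numeric(qx), px = 1 - as.numeric(qx),
                 mx = as.numeric(mx)),
            class = "life_history")
}

#' Construct a subsistence profile
#'
#' Age schedules of caloric production and caloric demand (kcal/day), plus a
#' positive multiplier \code{scale} applied to production by the replete
#' calibration (see \code{\link{calibrate_profiles}}).
#'
#' @param Px numeric vector, kcal/day produced per capita at each age.
#' @param Dx numeric vector, kcal/day demanded per capita at each age.
#' @param scale positive production multiplier (default 1; set by calibration).
#' @return An object of class \code{"subsistence"}.
#' @export
subsistence <- function(Px, Dx, scale = 1) {
  if (length(Px) != length(Dx))
    abort_validation("subsistence: Px and Dx must have the same length")
  ages <- seq_along(Px) - 1L
  check_ages(ages, "subsistence")
  check_range(Px, "Px", 0, Inf)
  check_range(Dx, "Dx", 0, Inf)
  if (all(Dx == 0))
    abort_validation("Dx: total demand must be positive")
  if (!is.finite(scale) || scale <= 0)
    abort_validation("subsistence: scale must be a positive number")
  structure(list(age = ages, Px = as.numeric(Px), Dx = as.numeric(Dx),
                 scale = as.numeric(scale)),
            class = "subsistence")
}

#' Construct a social profile (relatedness and cooperation)
#'
#' @param rx numeric vector of mean relatedness of an age-x donor to the focal
#'   sharing group, in [0, 0.5] (0.5 = relatedness to a direct offspring), or a
#'   single value recycled across ages.
#' @param k cooperation probability in [0, 1]: the chance a group member
#'   complies with the need-based sharing norm.
#' @param omega last age; required when \code{rx} is a scalar.
#' @return An object of class \code{"social_profile"}.
#' @export
social_profile <- function(rx, k, omega = NULL) {
  if (length(rx) == 1L) {
    if (is.null(omega))
      abort_validation("social_profile: omega required when rx is scalar")
    rx <- rep(rx, omega + 1L)
  }
  check_range(rx, "rx", 0, 0.5)
  if (!is.finite(k) || k < 0 || k > 1)
    abort_validation("k: cooperation probability must lie in [0, 1], got ", k)
  structure(list(age = seq_along(rx) - 1L, rx = as.numeric(rx), k = as.numeric(k)),
            class = "social_profile")
}

omega_of <- function(x) length(x$age) - 1L

#' Read life-history and subsistence profiles from CSV
#'
#' The canonical dialect is comma-separated, dot decimal, UTF-8, with header
#' \code{age,px,mx,Px,Dx} (a \code{qx} column is accepted in place of
#' \code{px}) and one row per age, contiguous from 0.
#'
#' @param path path to a CSV file.
#' @return A list with elements \code{lh} (\code{\link{life_history}}) and
#'   \code{sub} (\code{\link{subsistence}}).
#' @seealso \code{\link{write_profiles}}
#' @export
read_profiles <- function(path) {
  if (!file.exists(path))
    abort_validation("read_profiles: no such file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("age", "mx", "Px", "Dx")
  miss <- setdiff(need, names(df))
  if (length(miss))
    abort_validation("read_profiles: missing column(s): ", paste(miss, collapse = ", "))
  if (!("px" %in% names(df)) && !("qx" %in% names(df)))
    abort_validation("read_profiles: need a px or qx column")
  check_ages(as.integer(df$age), paste0("read_profiles(", basename(path), ")"))
  qx <- if ("qx" %in% names(df)) df$qx else 1 - df$px
  list(lh = life_history(qx = qx, mx = df$mx),
       sub = subsistence(Px = df$Px, Dx = df$Dx))
}

#' Write profiles to CSV in the canonical dialect
#'
#' @param lh a \code{\link{life_history}}.
#' @param sub a \code{\link{subsistence}} on the same ages.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_profiles <- function(lh, sub, path) {
  if (omega_of(lh) != omega_of(sub))
    abort_validation("write_profiles: profiles have different last ages")
  df <- data.frame(age = lh$age, px = lh$px, mx = lh$mx,
                   Px = sub$Px, Dx = sub$Dx)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Siler competing-hazards mortality: infant decline + constant + senescent rise.
siler_qx <- function(x, a1, b1, a2, a3, b3) {
  pmin(a1 * exp(-b1 * x) + a2 + a3 * exp(b3 * x), 1)
}

synth_param_defaults <- function(kind, omega) {
  if (kind == "chimp-like") {
    list(
      # mortality: high infant and adult hazard typical of wild chimpanzees
      mort = list(a1 = 0.35, b1 = 0.9, a2 = 0.028, a3 = 6e-4, b3 = 0.085),
      # fertility: first birth ~13, broad plateau, no mid-life cessation
      fert = list(alpha = 13, shape = 1.4, rate = 0.09),
      # demand rises to the adult level by early adolescence
      demand = list(adult = 1600, frac0 = 0.35, tau = 5),
      # production self-sufficient by ~5, peak before 20, no late surplus
      prod = list(pmax = 1750, rise = 3, peak = 18, fall = 0.0009),
      r_max = 0.03
    )
  } else {
    list(
      mort = list(a1 = 0.22, b1 = 1.1, a2 = 0.009, a3 = 1.6e-4, b3 = 0.085),
      # fertility confined to [15, 50): reproductive cessation near 50
      fert = list(alpha = 15, beta = 50, p = 1.2, q = 1.6),
      demand = list(adult = 2200, frac0 = 0.30, tau = 9, shape = 1.5),
      # production crosses demand near 20, peaks 30-45, surplus past 60
      prod = list(pmax = 3500, mid = 17, rise = 4, fall_center = 40, fall_width = 25),
      r_max = 0.03
    )
  }
}

#' Generate synthetic life-history and subsistence profiles
#'
#' Emulates two stylized subsistence regimes. \code{"chimp-like"}: foraging
#' self-sufficiency by about age 5, early production peak, small adult surplus
#' vanishing after age 40, high adult mortality, reproduction continuing into
#' old age. \code{"human-like"}: net caloric consumption for about two decades,
#' production peaking between ages 30 and 45 with surpluses persisting past 60,
#' lower adult mortality, and reproductive cessation near age 50. Mortality is
#' Siler-shaped and fertility unimodal in both regimes. Fertility is scaled so
#' the replete population grows at \code{r_max} (3 percent per year by
#' default), the growth-rate ceiling used downstream by
#' \code{\link{calibrate_profiles}}.
#'
#' @param kind \code{"chimp-like"} or \code{"human-like"}.
#' @param omega last age (default 60 for chimp-like, 90 for human-like);
#'   must be at least 10.
#' @param params named list overriding entries of the regime defaults
#'   (see source for the full parameter set).
#' @param seed integer seed; generation is deterministic given the seed.
#' @param noise_sd standard deviation of optional lognormal multiplicative
#'   noise on production (default 0 = smooth curves).
#' @return A list with elements \code{lh} and \code{sub}, as
#'   \code{\link{read_profiles}}.
#' @examples
#' p <- synth_profiles("human-like", seed = 1)
#' all(p$sub$Px[p$lh$age < 15] < p$sub$Dx[p$lh$age < 15])
#' @export
synth_profiles <- function(kind = c("human-like", "chimp-like"), omega = NULL,
                           params = list(), seed = 1L, noise_sd = 0) {
  kind <- match.arg(kind)
  if (is.null(omega)) omega <- if (kind == "chimp-like") 60L else 90L
  if (omega < 10L) abort_validation("synth_profiles: omega must be at least 10")
  def <- synth_param_defaults(kind, omega)
  for (nm in names(params)) def[[nm]] <- utils::modifyList(def[[nm]], params[[nm]])
  x <- 0:omega

  qx <- with(def$mort, siler_qx(x, a1, b1, a2, a3, b3))
  qx[omega + 1L] <- 1

  if (kind == "chimp-like") {
    f <- def$fert
    mx <- ifelse(x < f$alpha, 0,
                 (pmax(x - f$alpha, 0))^f$shape * exp(-f$rate * (x - f$alpha)))
    d <- def$demand
    Dx <- d$adult * (d$frac0 + (1 - d$frac0) * (1 - exp(-x / d$tau)))
    p <- def$prod
    Px <- p$pmax * (1 - exp(-(x / p$rise)^2)) * exp(-p$fall * pmax(x - p$peak, 0)^2)
  } else {
    f <- def$fert
    u <- (x - f$alpha) / (f$beta - f$alpha)
    mx <- ifelse(u > 0 & u < 1, u^f$p * (1 - u)^f$q, 0)
    d <- def$demand
    Dx <- d$adult * (d$frac0 + (1 - d$frac0) * (1 - exp(-(x / d$tau)^d$shape)))
    p <- def$prod
    Px <- p$pmax * stats::plogis((x - p$mid) / p$rise) *
      exp(-0.5 * (pmax(x - p$fall_center, 0) / p$fall_width)^2)
    Px[x < 3] <- 0  # infants do not forage
  }

  if (noise_sd > 0) {
    set.seed(as.integer(seed))
    Px <- Px * exp(stats::rnorm(length(Px), sd = noise_sd))
  }

  # scale fertility so the replete (baseline) growth rate equals r_max
  mx <- mx * replete_fertility_factor(qx, mx, def$r_max)

  list(lh = life_history(qx = qx, mx = mx), sub = subsistence(Px = Px, Dx = Dx))
}

# Solve for the scalar on mx giving log(lambda) = r_max at replete vital rates.
replete_fertility_factor <- function(qx, mx, r_max) {
  px <- 1 - qx
  f <- function(s) log(leslie_lambda(px, s * mx)) - r_max
  lo <- 1e-6; hi <- 1
  while (f(hi) < 0 && hi < 1e6) hi <- hi * 4
  if (f(hi) < 0) abort_numeric("synth_profiles: cannot reach r_max with this fertility shape")
  stats::uniroot(f, c(lo, hi), tol = 1e-12)$root
}

#' Permute life history and subsistence into a counterfactual composite
#'
#' Combines the vital rates of one population with the production/demand
#' profile of another (for example, chimpanzee life history with
#' hunter-gatherer subsistence). When the two are defined on different age
#' ranges the composite is truncated to the shared range, and the life table
#' is re-closed at the new last age.
#'
#' @param lh a \code{\link{life_history}}.
#' @param sub a \code{\link{subsistence}}.
#' @return A list with elements \code{lh} and \code{sub} on the common ages.
#' @export
permute_counterfactual <- function(lh, sub) {
  om <- min(omega_of(lh), omega_of(sub))
  if (om < 1L) abort_validation("permute_counterfactual: empty age intersection")
  idx <- 1:(om + 1L)
  qx <- lh$qx[idx]
  qx[om + 1L] <- 1
  list(lh = life_history(qx = qx, mx = lh$mx[idx]),
       sub = subsistence(Px = sub$Px[idx], Dx = sub$Dx[idx], scale = sub$scale))
}

#' Build an age profile of mean relatedness
#'
#' Constant profiles set \eqn{r_x} to \code{level} at every age. Increasing and
#' decreasing profiles are linear ramps symmetric about \code{level}, so the
#' age-mean equals \code{level}; the ramp half-range defaults to 0.15 and is
#' shrunk where needed to keep every value inside [0, 0.5].
#'
#' @param shape \code{"constant"}, \code{"increasing"} or \code{"decreasing"}.
#' @param level mean relatedness in [0, 0.5].
#' @param omega last age.
#' @param k cooperation probability attached to the returned profile.
#' @param half_range ramp half-range before clipping (default 0.15).
#' @return A \code{\link{social_profile}}.
#' @export
relatedness_profile <- function(shape = c("constant", "increasing", "decreasing"),
                                level, omega, k = 1, half_range = 0.15) {
  shape <- match.arg(shape)
  if (!is.finite(level) || level < 0 || level > 0.5)
    abort_validation("relatedness_profile: level must lie in [0, 0.5], got ", level)
  x <- 0:omega
  if (shape == "constant") {
    rx <- rep(level, omega + 1L)
  } else {
    d <- min(half_range, level, 0.5 - level)
    ramp <- d * (2 * x / omega - 1)  # zero mean on 0:omega, endpoints level -+ d
    rx <- level + if (shape == "increasing") ramp else -ramp
  }
  social_profile(rx = rx, k = k)
}
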