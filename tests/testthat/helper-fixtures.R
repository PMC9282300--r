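# Shared fixtures. Generation is deterministic, so these are computed once
# per test run.

toy_csv <- function() {
  path <- tempfile(fileext = ".csv")
  writeLines(c("age,px,mx,Px,Dx",
               "0,0.5,0,0,4",
               "1,0.5,1,5,4",
               "2,0,1,5,4"), path)
  path
}

hg_profiles <- local({
  val <- NULL
  function() {
    if (is.null(val)) val <<- synth_profiles("human-like", seed = 1)
    val
  }
})

chimp_profiles <- local({
  val <- NULL
  function() {
    if (is.null(val)) val <<- synth_profiles("chimp-like", seed = 1)
    val
  }
})

hg_calibration <- local({
  val <- NULL
  function() {
    if (is.null(val)) {
      p <- hg_profiles()
      val <<- calibrate_profiles(p$lh, p$sub, gamma = 0.3)
    }
    val
  }
})

chimp_calibration <- local({
  val <- NULL
  function() {
    if (is.null(val)) {
      p <- chimp_profiles()
      val <<- calibrate_profiles(p$lh, p$sub, gamma = 0.3)
    }
    val
  }
})

# A small random Leslie-compatible vital-rate pair with a simple dominant
# eigenvalue (positive fertility everywhere keeps the matrix primitive).
random_vitals <- function(n) {
  px <- c(stats::runif(n - 1, 0.3, 0.95), 0)
  mx <- stats::runif(n, 0.05, 2)
  list(px = px, mx = mx)
}

# Random small synthetic profile sets for property sweeps.
random_profile_set <- function(seed) {
  kind <- if (seed %% 2 == 0) "chimp-like" else "human-like"
  synth_profiles(kind, seed = seed, noise_sd = 0.05,
                 params = list(mort = list(a2 = 0.01 + 0.002 * (seed %% 5))))
}

# As random_vitals, but small and well-mixed so every structural sensitivity
# sits far above the finite-difference noise floor (~5e-10 at h = 1e-6).
random_vitals_dense <- function() {
  n <- sample(4:6, 1)
  list(px = c(stats::runif(n - 1, 0.5, 0.95), 0),
       mx = stats::runif(n, 0.3, 2))
}

# Central finite difference of lambda with respect to matrix entry (i, j).
fd_lambda_entry <- function(px, mx, i, j, h = 1e-6) {
  A <- leslie_matrix(px, mx)
  lam_of <- function(M) max(Re(eigen(unclass(M), only.values = TRUE)$values))
  Ap <- A; Ap[i, j] <- Ap[i, j] + h
  Am <- A; Am[i, j] <- Am[i, j] - h
  (lam_of(Ap) - lam_of(Am)) / (2 * h)
}

# One-shot pipeline: lambda as a function of the production vector, holding
# baseline survivorship fixed (the convention the analytic chain uses).
lambda_of_production <- function(cal, P) {
  E <- min(sum(P * cal$lx) / cal$DT, 1)
  lh <- suppressWarnings(apply_nutrition(cal$lh0, E, cal$gamma))
  demographic_summary(lh$px, lh$mx)$lambda
}

fd_production_sensitivity <- function(cal, i, rel_h = 1e-4) {
  h <- rel_h * max(cal$Px[i], 1)
  Pp <- cal$Px; Pp[i] <- Pp[i] + h
  Pm <- cal$Px; Pm[i] <- Pm[i] - h
  (lambda_of_production(cal, Pp) - lambda_of_production(cal, Pm)) / (2 * h)
}
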