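# Shared pedagogy fixtures: human-like backdrop with each skill preset.
ped_setup <- local({
  val <- NULL
  function() {
    if (is.null(val)) {
      base <- synth_profiles("human-like", omega = 90, seed = 1)
      soc <- social_profile(0.5, k = 1, omega = 90)
      out <- list(soc = soc)
      for (preset in c("high-skill", "low-skill")) {
        model <- skill_production_model(preset)
        cal <- calibrate_profiles(base$lh,
                                  subsistence(model$Px, base$sub$Dx),
                                  gamma = 0.3)
        out[[preset]] <- list(model = model, cal = cal)
      }
      val <<- out
    }
    val
  }
})

test_that("pedagogy regimes validate their invariants", {
  expect_error(pedagogy_regime(1, 1, 10, 30, 10, 90), "phi")
  expect_error(pedagogy_regime(0.1, -1, 10, 30, 10, 90), "theta")
  expect_error(pedagogy_regime(0.1, 1, 10, 5, 10, 90), "b >= a")
  expect_error(pedagogy_regime(0.1, 1, 85, 85, 10, 90), "omega")
})

test_that("the null regime is an exact fixed point of the pipeline", {
  st <- ped_setup()
  for (preset in c("high-skill", "low-skill")) {
    fx <- st[[preset]]
    reg <- pedagogy_regime(0, 0, 10, 30, 10, 90)
    mod <- apply_pedagogy(fx$model, reg, fx$cal$lx)
    expect_identical(mod$Px, fx$model$Px)
    g <- pedagogy_fitness_gain(fx$cal, fx$model, st$soc, reg)
    expect_identical(g$delta_r, 0)
    expect_equal(g$r_base, 0.01, tolerance = 1e-6)
  }
})

test_that("teaching boosts pupil skill and costless teaching never hurts", {
  st <- ped_setup()
  fx <- st[["high-skill"]]
  reg <- pedagogy_regime(0, 1, 10, 40, 10, 90)
  mod <- apply_pedagogy(fx$model, reg, fx$cal$lx)
  expect_true(all(mod$Sx >= fx$model$Sx))
  expect_gt(mod$Sx[31], fx$model$Sx[31])
  # pupils reach a given skill level at a younger age than baseline
  target <- 0.8 * max(fx$model$Sx)
  expect_lt(which(mod$Sx >= target)[1], which(fx$model$Sx >= target)[1])

  sw <- optimize_teacher_age(fx$cal, fx$model, st$soc, phi = 0, theta = 1,
                             a = 10, t = 10, b_grid = seq(10, 80, by = 10))
  expect_true(all(sw$curve$delta_r >= 0))
})

test_that("pure-cost teaching strictly lowers group production and growth", {
  st <- ped_setup()
  fx <- st[["high-skill"]]
  reg <- pedagogy_regime(0.2, 0, 10, 35, 10, 90)
  mod <- apply_pedagogy(fx$model, reg, fx$cal$lx)
  expect_lt(sum(mod$Px * fx$cal$lx), sum(fx$model$Px * fx$cal$lx))
  g <- pedagogy_fitness_gain(fx$cal, fx$model, st$soc, reg)
  expect_lt(g$delta_r, 0)
})

test_that("the fitness gain rises with the skill boost and falls with teacher cost", {
  st <- ped_setup()
  fx <- st[["high-skill"]]
  gain <- function(phi, theta)
    pedagogy_fitness_gain(fx$cal, fx$model, st$soc,
                          pedagogy_regime(phi, theta, 10, 40, 10, 90))$delta_r
  th_sweep <- vapply(c(0.25, 0.5, 1, 2), function(t) gain(0.05, t), numeric(1))
  expect_true(all(diff(th_sweep) > 0))
  phi_sweep <- vapply(c(0.01, 0.05, 0.15, 0.3), function(p) gain(p, 1), numeric(1))
  expect_true(all(diff(phi_sweep) < 0))
})

test_that("optimal teacher ages are older when teaching is costlier", {
  st <- ped_setup()
  fx <- st[["high-skill"]]
  cheap <- optimize_teacher_age(fx$cal, fx$model, st$soc, phi = 0.01, theta = 1,
                                a = 10, t = 10)
  dear <- optimize_teacher_age(fx$cal, fx$model, st$soc, phi = 0.3, theta = 1,
                               a = 10, t = 10)
  expect_gt(dear$b_star, cheap$b_star)
  # a singleton grid returns that age
  one <- optimize_teacher_age(fx$cal, fx$model, st$soc, phi = 0.05, theta = 1,
                              a = 10, t = 10, b_grid = 42)
  expect_equal(one$b_star, 42)
  expect_error(optimize_teacher_age(fx$cal, fx$model, st$soc, phi = 0.05,
                                    theta = 1, a = 10, t = 10,
                                    b_grid = integer(0)), "empty")
})

test_that("a skills-intensive niche profits more from pedagogy than a low-skill niche", {
  st <- ped_setup()
  best <- function(preset) {
    fx <- st[[preset]]
    max(optimize_teacher_age(fx$cal, fx$model, st$soc, phi = 0.01, theta = 1,
                             a = 10, t = 10,
                             b_grid = seq(10, 80, by = 5))$curve$delta_r)
  }
  expect_gt(best("high-skill"), best("low-skill"))
})

test_that("the gain responds continuously to phi and theta", {
  st <- ped_setup()
  fx <- st[["low-skill"]]
  gain <- function(phi, theta)
    pedagogy_fitness_gain(fx$cal, fx$model, st$soc,
                          pedagogy_regime(phi, theta, 10, 40, 10, 90))$delta_r
  eps <- 1e-4
  expect_lt(abs(gain(0.1 + eps, 1) - gain(0.1, 1)), 0.05 * eps + 1e-9)
  expect_lt(abs(gain(0.1, 1 + eps) - gain(0.1, 1)), 0.05 * eps + 1e-9)
})
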