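test_that("the vital-rate scalar Z obeys its identities and limits", {
  for (g in c(0.1, 0.3, 1, 5)) expect_equal(vital_scalar(1, g), 1)
  expect_equal(vital_scalar(0.5, 0.9), 0.5 * 1.9 / 1.4)
  # large gamma: Z -> E (linear response); small gamma: Z -> 1 (saturating)
  expect_equal(vital_scalar(0.4, 1e8), 0.4, tolerance = 1e-6)
  expect_equal(vital_scalar(0.4, 1e-8), 1, tolerance = 1e-6)
  # strictly increasing in E
  E <- seq(0.05, 1, by = 0.05)
  for (g in c(0.2, 1, 4)) expect_true(all(diff(vital_scalar(E, g)) > 0))
  # |Z - E| strictly decreasing in gamma at fixed E < 1
  gam <- c(0.1, 0.3, 1, 3, 10)
  dev <- abs(vital_scalar(0.6, gam) - 0.6)
  expect_true(all(diff(dev) < 0))
  expect_error(vital_scalar(0, 0.3), "positive")
  expect_error(vital_scalar(0.5, -1), "positive")
})

test_that("nutrition application scales fertility by Z and mortality by 1/Z", {
  lh0 <- life_history(qx = c(0.2, 0.1, 1), mx = c(0, 1, 0.5))
  same <- apply_nutrition(lh0, 1, 0.3)
  expect_equal(same$mx, lh0$mx)
  expect_equal(same$qx, lh0$qx)

  Z <- 0.5
  # pick E so that Z(E, 0.9) = 0.5: E = 0.5*0.9/(1.9-0.5)
  E <- Z * 0.9 / (1.9 - Z)
  adj <- apply_nutrition(lh0, E, 0.9)
  expect_equal(adj$qx[1], 0.4, tolerance = 1e-12)
  expect_equal(adj$mx[2], 0.5, tolerance = 1e-12)

  clip <- life_history(qx = c(0.8, 1), mx = c(0, 1))
  expect_warning(out <- apply_nutrition(clip, E, 0.9), "clipped")
  expect_equal(out$qx[1], 1)
})

test_that("analytic food-ratio derivatives of the vital rates match finite differences", {
  m0 <- c(0, 0.8, 1.2); q0 <- c(0.3, 0.15, 1)
  for (g in c(0.2, 0.9, 3)) {
    for (E in c(0.3, 0.7, 1)) {
      h <- 1e-6
      fd_m <- (vital_scalar(E + h, g) - vital_scalar(E - h, g)) / (2 * h) * m0
      expect_equal(dm_dE(m0, E, g), fd_m, tolerance = 1e-7)
      p_of <- function(e) 1 - q0 / vital_scalar(e, g)
      fd_p <- (p_of(E + h) - p_of(E - h)) / (2 * h)
      expect_equal(dp_dE(q0, E, g), fd_p, tolerance = 1e-7)
    }
    # closed form at replete: dm/dE = m0 gamma / (gamma + 1)
    expect_equal(dm_dE(m0, 1, g), m0 * g / (g + 1), tolerance = 1e-12)
  }
  # gamma -> 0: no nutritional response, both derivatives vanish
  expect_equal(dm_dE(m0, 0.5, 1e-10), m0 * 0, tolerance = 1e-9)
  expect_equal(dp_dE(q0, 0.5, 1e-10), q0 * 0, tolerance = 1e-9)
})

test_that("the food ratio is the survivorship-weighted production/demand ratio", {
  hg <- hg_profiles()
  equal <- subsistence(Px = hg$sub$Dx, Dx = hg$sub$Dx)
  expect_equal(food_ratio(equal, hg$lh), 1)
  expect_equal(food_ratio(equal, hg$lh, gamma = 0.3, self_consistent = TRUE), 1)

  lx <- cumprod(c(1, hg$lh$px))[seq_along(hg$lh$px)]
  sub <- subsistence(Px = 0.6 * hg$sub$Dx, Dx = hg$sub$Dx)
  E1 <- food_ratio(sub, hg$lh, lx = lx)
  expect_equal(E1, 0.6, tolerance = 1e-12)
  half <- subsistence(Px = 0.3 * hg$sub$Dx, Dx = hg$sub$Dx)
  expect_equal(food_ratio(half, hg$lh, lx = lx), E1 / 2, tolerance = 1e-12)

  # survivorship feedback lowers the self-consistent ratio below the
  # one-shot ratio computed with replete survivorship when E < 1
  Esc <- food_ratio(sub, hg$lh, gamma = 0.3, self_consistent = TRUE)
  expect_lte(Esc, E1 + 1e-12)
})

test_that("calibration meets its growth-rate contracts", {
  cal <- hg_calibration()
  expect_equal(cal$summary$r, 0.01, tolerance = 1e-8)
  expect_lt(abs(elderfit:::growth_at_E(cal$lh0, cal$Emin, cal$gamma)), 1e-8)
  expect_true(cal$rho > 0 && cal$rho <= 1)
  expect_true(cal$Emin <= cal$E0 && cal$E0 <= 1)
  expect_equal(cal$r_max, 0.03, tolerance = 1e-8)

  # fixed point: the calibrated production reproduces E0 under both modes
  expect_equal(food_ratio(cal$sub_cal, cal$lh0, lx = cal$lx), cal$E0,
               tolerance = 1e-9)
  expect_equal(food_ratio(cal$sub_cal, cal$lh0, gamma = cal$gamma,
                          self_consistent = TRUE), cal$E0, tolerance = 1e-8)

  # no reduction needed when the target equals the replete maximum
  hg <- hg_profiles()
  cal_max <- calibrate_profiles(hg$lh, hg$sub, gamma = 0.3, r_target = 0.03)
  expect_equal(cal_max$rho, 1, tolerance = 1e-7)
  expect_equal(cal_max$E0, 1, tolerance = 1e-7)
})

test_that("growth increases monotonically with the food ratio above Emin", {
  cal <- chimp_calibration()
  Es <- seq(cal$Emin, 1, length.out = 12)
  rs <- vapply(Es, function(E) elderfit:::growth_at_E(cal$lh0, E, cal$gamma),
               numeric(1))
  expect_true(all(diff(rs) > 0))
})

test_that("replete production scaling makes demand exactly met at E = 1", {
  hg <- hg_profiles()
  cal <- hg_calibration()
  lx_rep <- cumprod(c(1, hg$lh$px))[seq_along(hg$lh$px)]
  PT <- sum(hg$sub$Px * cal$replete_scale * lx_rep)
  DT <- sum(hg$sub$Dx * lx_rep)
  expect_equal(PT, DT, tolerance = 1e-10)
})
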