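test_that("production sensitivity matches the end-to-end numerical derivative", {
  cal <- hg_calibration()
  soc <- social_profile(0.5, k = 1, omega = 90)
  sPx <- production_sensitivity(cal, soc)
  for (i in c(1, 11, 31, 51, 71)) {
    fd <- fd_production_sensitivity(cal, i)
    expect_equal(sPx[i], fd, tolerance = 1e-3)
  }
})

test_that("full defection and the offspring benchmark bracket the discounting", {
  cal <- chimp_calibration()
  omega <- 60
  none <- production_sensitivity(cal, social_profile(0.2, k = 0, omega = omega))
  expect_true(all(none == 0))

  bench <- production_sensitivity(cal, social_profile(0.5, k = 1, omega = omega))
  S <- elderfit:::recipient_sum(cal)
  expect_equal(bench, S * cal$lx / cal$DT, tolerance = 1e-12)
  expect_true(all(bench >= 0))
})

test_that("all transfer metrics are linear in cooperation and scaled relatedness", {
  cal <- hg_calibration()
  s1 <- selection_report(cal, social_profile(0.1, k = 0.25, omega = 90))
  s2 <- selection_report(cal, social_profile(0.2, k = 0.25, omega = 90))
  s3 <- selection_report(cal, social_profile(0.1, k = 0.5, omega = 90))
  for (pair in list(list(s2, "r"), list(s3, "k"))) {
    sc <- pair[[1]]
    expect_equal(sc$table$dlambda_Px, 2 * s1$table$dlambda_Px, tolerance = 1e-12)
    expect_equal(sc$table$PV, 2 * s1$table$PV, tolerance = 1e-12)
    expect_equal(sc$table$m_star, 2 * s1$table$m_star, tolerance = 1e-12)
    expect_equal(sc$summary$TFR_50, 2 * s1$summary$TFR_50, tolerance = 1e-12)
  }
})

test_that("contributions factor into donor production, survivorship and relatedness", {
  cal <- hg_calibration()
  soc <- social_profile(0.3, k = 0.7, omega = 90)
  dLam <- indirect_contribution(cal$Px, production_sensitivity(cal, soc))
  base <- cal$Px * cal$lx * (soc$rx / 0.5)
  ratio <- dLam[base > 0] / base[base > 0]
  expect_lt(diff(range(ratio)), 1e-12 * max(abs(ratio)))
})

test_that("flat social profiles leave share profiles untouched while scaling magnitudes", {
  cal <- hg_calibration()
  a <- selection_report(cal, social_profile(0.5, k = 1, omega = 90))
  b <- selection_report(cal, social_profile(0.15, k = 0.4, omega = 90))
  expect_equal(a$summary$indirect_share, b$summary$indirect_share, tolerance = 1e-12)
  # with flat rx and k the post-50 indirect share equals the post-50 share
  # of survivorship-weighted production
  expect_equal(unname(a$summary$indirect_share["after50"]),
               unname(a$summary$production_share["after50"]), tolerance = 1e-12)
})

test_that("production elasticities rescale onto the fertility-elasticity total", {
  cal <- hg_calibration()
  soc <- social_profile(0.2, k = 0.5, omega = 90)
  sPx <- production_sensitivity(cal, soc)
  el <- production_elasticity(sPx, cal$Px, cal$summary$lambda, cal$sens$e_mx)
  expect_equal(sum(el$scaled), sum(cal$sens$e_mx), tolerance = 1e-10)
  expect_equal(which.max(el$scaled), which.max(el$raw))
  expect_warning(z <- production_elasticity(sPx * 0, cal$Px, 1, cal$sens$e_mx),
                 "zero")
  expect_true(all(z$scaled == 0))
})

test_that("fertility equivalents satisfy their defining identity", {
  cal <- hg_calibration()
  soc <- social_profile(0.2, k = 0.5, omega = 90)
  sPx <- production_sensitivity(cal, soc)
  mstar <- fertility_equivalent(sPx, cal$Px, cal$sens$s_mx)
  ok <- !is.na(mstar)
  expect_equal((cal$sens$s_mx * mstar)[ok], (sPx * cal$Px)[ok], tolerance = 1e-12)
  # late-life equivalents are small but positive daughters/year
  late <- mstar[cal$lh0$age > 50 & cal$lh0$age <= 70]
  expect_true(all(late > 0))
  expect_lt(max(late), 0.1)
  # TFR_50 truncates at the last age and is linear in k
  expect_equal(tfr50(mstar), 2 * sum(mstar[51:81], na.rm = TRUE))
})

test_that("mean ages follow the requested weighting", {
  point <- c(0, 0, 0, 1, 0)
  expect_equal(mean_age(point), 3)
  uniform <- rep(2, 11)
  expect_equal(mean_age(uniform), 5)
  lx <- c(1, rep(0.5, 10))
  expect_lt(mean_age(uniform, "survivorship", lx = lx), 5)
  expect_error(mean_age(rep(0, 5)), "zero")
})

test_that("cumulative shares are monotone with the correct endpoints", {
  vals <- c(1, 2, 3, 4)
  sh <- cumulative_shares(vals, cut_ages = c(-1, 0, 1, 2, 3))
  expect_equal(unname(sh[1]), 1)
  expect_equal(unname(sh[length(sh)]), 0)
  expect_true(all(diff(sh) <= 0))
  expect_error(cumulative_shares(c(0, 0)), "zero")
  expect_error(cumulative_shares(c(-1, 2)), "negative")
})

test_that("the report table carries the documented schema", {
  rep <- selection_report(hg_calibration(), social_profile(0.2, 0.5, omega = 90))
  expect_named(rep$table,
               c("age", "px", "mx", "Px", "Dx", "lx", "s_mx", "s_px", "e_mx",
                 "e_px_scaled", "dlambda_Px", "m_star", "RV", "PV"))
  expect_equal(nrow(rep$table), 91)
  expect_equal(rep$table$dlambda_Px, rep$table$Px *
                 production_sensitivity(hg_calibration(),
                                        social_profile(0.2, 0.5, omega = 90)),
               tolerance = 1e-14)
})
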