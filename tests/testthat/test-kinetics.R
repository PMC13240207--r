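test_that("velocity obeys the model identities", {
  mm <- list(Vmax = 80, Km = 25)
  expect_equal(velocity("michaelis_menten", 0, mm), 0)
  expect_equal(velocity("michaelis_menten", 25, mm), 40)  # half saturation
  si <- list(Vmax = 100, Km = 101.9, Ki = 500)
  expect_equal(velocity("substrate_inhibition", 0, si), 0)
  # maximum at S = sqrt(Km * Ki): derivative changes sign there
  s_star <- sqrt(si$Km * si$Ki)
  v <- velocity("substrate_inhibition", c(s_star - 1, s_star, s_star + 1), si)
  expect_true(v[2L] > v[1L] && v[2L] > v[3L])
  # rises then falls across the grid
  grid <- velocity("substrate_inhibition", seq(0, 2000, 50), si)
  expect_true(which.max(grid) > 1 && which.max(grid) < length(grid))
  expect_error(velocity("michaelis_menten", 1, list(Vmax = -1, Km = 2)),
               "positive")
  expect_error(velocity("substrate_inhibition", 1, list(Vmax = 1, Km = 2)),
               "Ki")
})

test_that("standard-curve conversion is exact on a line and matches OLS", {
  std <- data.frame(conc = c(0, 100), signal = c(0, 1000))
  expect_equal(as.numeric(rfu_to_concentration(500, std)), 50)
  expect_equal(as.numeric(rfu_to_concentration(1000, std)), 100)
  set.seed(601)
  std3 <- data.frame(conc = c(0, 50, 100),
                     signal = c(0, 50, 100) * 9.7 + 12 + rnorm(3))
  got <- rfu_to_concentration(c(300, 700), std3)
  beta <- oracle_ols_slope(std3$conc, std3$signal)
  expect_equal(attr(got, "slope"), unname(beta["slope"]), tolerance = 1e-10)
  expect_equal(attr(got, "intercept"), unname(beta["intercept"]),
               tolerance = 1e-10)
  expect_error(rfu_to_concentration(1, data.frame(conc = c(5, 5),
                                                  signal = c(1, 2))),
               "degenerate")
})

test_that("noiseless fits recover generating parameters exactly", {
  S <- seq(0, 250, length.out = 14)
  mm <- simulate_kinetic_dataset("michaelis_menten",
                                 list(Vmax = 60, Km = 30), S, seed = 1)
  fit <- global_fit(mm, "michaelis_menten", km_mode = "free")
  expect_equal(fit$fits$Vmax, 60, tolerance = 1e-4)
  expect_equal(fit$Km, 30, tolerance = 1e-4)
  expect_true(fit$converged)
  expect_true(fit$fits$ci_lo <= fit$fits$Vmax & fit$fits$Vmax <= fit$fits$ci_hi)
})

test_that("a fixed-Km fit equals the reduced one-parameter fit", {
  S <- seq(5, 250, length.out = 12)
  d <- simulate_kinetic_dataset("michaelis_menten", list(Vmax = 90, Km = 101.9),
                                S, noise_sd = 3, seed = 8)
  fit <- global_fit(d, "michaelis_menten", km_mode = "fixed",
                    km_value = 101.9)
  # reduced model: v = Vmax * g(S), one linear parameter, closed form OLS
  g <- S / (101.9 + S)
  vmax_hat <- sum(d$v * g) / sum(g^2)
  expect_equal(fit$fits$Vmax, vmax_hat, tolerance = 1e-6)
})

test_that("shared-Km fits nest inside free-Km fits", {
  S <- seq(0, 250, length.out = 10)
  d1 <- simulate_kinetic_dataset("michaelis_menten", list(Vmax = 100, Km = 80),
                                 S, noise_sd = 4, seed = 2, condition = "a")
  d2 <- simulate_kinetic_dataset("michaelis_menten", list(Vmax = 40, Km = 120),
                                 S, noise_sd = 4, seed = 3, condition = "b")
  dat <- rbind(d1, d2)
  shared <- global_fit(dat, "michaelis_menten", km_mode = "shared")
  free <- global_fit(dat, "michaelis_menten", km_mode = "free")
  expect_gte(shared$rss, free$rss - 1e-8)
})

test_that("substrate inhibition with huge Ki degenerates to Michaelis-Menten", {
  S <- seq(0, 250, length.out = 14)
  d <- simulate_kinetic_dataset("michaelis_menten", list(Vmax = 70, Km = 50),
                                S, noise_sd = 2, seed = 5)
  mm <- global_fit(d, "michaelis_menten", km_mode = "free")
  si <- global_fit(d, "substrate_inhibition", km_mode = "free")
  # the SI optimum cannot beat MM by more than numerical slack, and the
  # fitted curves agree over the observed range
  expect_lte(si$rss, mm$rss + 1e-6)
  v_mm <- velocity("michaelis_menten", S,
                   list(Vmax = mm$fits$Vmax, Km = mm$Km))
  v_si <- velocity("substrate_inhibition", S,
                   list(Vmax = si$fits$Vmax, Km = si$Km, Ki = si$Ki))
  expect_lt(max(abs(v_mm - v_si)), 0.05 * max(v_mm))
})

test_that("the extra-sum-of-squares F-test picks the generating model", {
  S <- seq(0, 250, length.out = 14)
  si_true <- list(Vmax = 100, Km = 101.9, Ki = 500)
  d_si <- simulate_kinetic_dataset("substrate_inhibition", si_true, S,
                                   noise_sd = 1, replicates = 3, seed = 6)
  expect_equal(select_model(d_si, km_mode = "free")$model,
               "substrate_inhibition")
})

test_that("global_fit validates its inputs", {
  bad <- data.frame(condition = "x", S = c(1, 1, 1), v = c(1, 2, 3))
  expect_error(global_fit(bad, "michaelis_menten"), "distinct concentrations")
  tiny <- data.frame(condition = "x", S = c(0, 5, 10), v = c(0, 1, 2))
  expect_error(global_fit(tiny, "substrate_inhibition", km_mode = "free"),
               "degrees of freedom")
  expect_error(global_fit(tiny, "michaelis_menten", km_mode = "fixed"),
               "km_value")
})

test_that("percent_change is the stated arithmetic", {
  expect_equal(percent_change(37, 100), 63)
  expect_equal(percent_change(5, 5), 0)
  expect_equal(percent_change(200, 100), -100)
})
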