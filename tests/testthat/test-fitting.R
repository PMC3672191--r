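test_that("noiseless one- and two-species curves are recovered exactly", {
  beam <- test_beam()
  lags <- lag_grid(1e-6, 1, 64)
  crv1 <- simulate_curve(fcs_model(84, occupancy = 5), beam, 0, lag_s = lags)
  f1 <- fit_correlation(crv1, 1, beam)
  expect_true(f1$converged)
  expect_equal(f1$model$species$D_um2_s, 84, tolerance = 1e-6)
  expect_equal(f1$model$occupancy, 5, tolerance = 1e-6)
  expect_lt(f1$chi2, 1e-12)

  m2 <- fcs_model(c(43, 14), fraction = c(0.8, 0.2), occupancy = 3)
  crv2 <- simulate_curve(m2, beam, 0, lag_s = lag_grid(1e-6, 1, 128))
  f2 <- fit_correlation(crv2, 2, beam)
  expect_equal(f2$model$species$D_um2_s, c(43, 14), tolerance = 1e-4)
  expect_equal(f2$model$species$fraction, c(0.8, 0.2), tolerance = 1e-4)
})

test_that("reduced chi-square is near 1 for correctly specified noise", {
  beam <- test_beam()
  crv <- simulate_curve(fcs_model(84, occupancy = 5), beam, noise_cv = 0.02,
                        lag_s = lag_grid(1e-6, 1, 128), seed = 1)
  f <- fit_correlation(crv, 1, beam)
  expect_gt(f$chi2_red, 0.7)
  expect_lt(f$chi2_red, 1.3)
})

test_that("estimates are invariant to point order and to sigma rescaling", {
  beam <- test_beam()
  crv <- simulate_curve(fcs_model(60, occupancy = 4), beam, 0.02,
                        lag_s = lag_grid(1e-6, 1, 64), seed = 5)
  f <- fit_correlation(crv, 1, beam)
  # permuted rows
  perm <- withr::with_seed(9, sample(nrow(crv)))
  f_perm <- fit_correlation(as.data.frame(crv)[perm, ], 1, beam)
  expect_equal(f_perm$model$species$D_um2_s, f$model$species$D_um2_s,
               tolerance = 1e-10)
  # uniform sigma rescaling: same estimates, chi2_red scales by 1/c^2
  crv3 <- crv
  crv3$sigma <- crv$sigma * 3
  f3 <- fit_correlation(crv3, 1, beam)
  expect_equal(f3$model$species$D_um2_s, f$model$species$D_um2_s,
               tolerance = 1e-8)
  expect_equal(f3$chi2_red * 9, f$chi2_red, tolerance = 1e-6)
})

test_that("a second species never increases the minimised chi-square", {
  beam <- test_beam()
  set.seed(21)
  for (i in 1:20) {
    D <- 10^runif(1, 0.7, 2.3)
    occ <- 10^runif(1, 0, 1)
    crv <- simulate_curve(fcs_model(D, occupancy = occ), beam, 0.03,
                          lag_s = lag_grid(1e-6, 1, 48),
                          seed = 100 + i)
    f1 <- fit_correlation(crv, 1, beam)
    f2 <- fit_correlation(crv, 2, beam)
    expect_lte(f2$chi2, f1$chi2 * (1 + 1e-8))
  }
})

test_that("species are reported sorted by descending D", {
  beam <- test_beam()
  m <- fcs_model(c(10, 200), fraction = c(0.5, 0.5), occupancy = 5)
  expect_equal(m$species$D_um2_s, c(200, 10))
  crv <- simulate_curve(m, beam, 0, lag_s = lag_grid(1e-6, 1, 96))
  f <- fit_correlation(crv, 2, beam)
  expect_true(f$model$species$D_um2_s[1] > f$model$species$D_um2_s[2])
})

test_that("fitting guards reject unusable curves", {
  beam <- test_beam()
  flat <- tibble::tibble(lag_s = lag_grid(1e-5, 1e-2, 20), g = rep(0.2, 20))
  expect_error(fit_correlation(flat, 1, beam), "Degenerate")
  short <- simulate_curve(fcs_model(84, occupancy = 5), beam, 0,
                          lag_s = lag_grid(1e-5, 1e-2, 6))
  expect_error(fit_correlation(short, 1, beam), "at least 8")
  ten <- simulate_curve(fcs_model(84, occupancy = 5), beam, 0,
                        lag_s = lag_grid(1e-5, 1e-2, 10))
  expect_error(fit_correlation(ten, 2, beam), "at least 12")
})

test_that("model comparison applies the parsimony rule", {
  beam <- test_beam()
  # identical chi2 -> one species
  crv <- simulate_curve(fcs_model(84, occupancy = 5), beam, 0.02,
                        lag_s = lag_grid(1e-6, 1, 96), seed = 3)
  f1 <- fit_correlation(crv, 1, beam)
  f2 <- fit_correlation(crv, 2, beam)
  fake2 <- f2
  fake2$chi2_red <- f1$chi2_red
  expect_equal(compare_models(f1, fake2)$selected, "one-species")
  # 0.8 -> 0.7 with a 3% minor fraction -> two species
  fake2$chi2_red <- 0.7
  fake1 <- f1
  fake1$chi2_red <- 0.8
  fake2$model <- fcs_model(c(43, 14), fraction = c(0.97, 0.03), occupancy = 5)
  expect_equal(compare_models(fake1, fake2)$selected, "two-species")
  # large improvement but negligible fraction -> one species
  fake2$chi2_red <- 0.8 * 0.8
  fake2$model <- fcs_model(c(43, 14), fraction = c(0.999, 0.001), occupancy = 5)
  expect_equal(compare_models(fake1, fake2)$selected, "one-species")
  # different curves are refused
  other <- fit_correlation(
    simulate_curve(fcs_model(30, occupancy = 2), beam, 0.02,
                   lag_s = lag_grid(1e-6, 1, 96), seed = 4), 2, beam)
  expect_error(compare_models(f1, other), "same curve")
})

test_that("bootstrap intervals are deterministic and collapse without noise", {
  beam <- test_beam()
  crv0 <- simulate_curve(fcs_model(84, occupancy = 5), beam, 0,
                         lag_s = lag_grid(1e-6, 1, 48))
  f0 <- fit_correlation(crv0, 1, beam)
  ci0 <- bootstrap_uncertainty(crv0, f0, n_boot = 100, seed = 1)
  expect_lt(max(ci0$upper - ci0$lower), 1e-6)

  crv <- simulate_curve(fcs_model(84, occupancy = 5), beam, 0.02,
                        lag_s = lag_grid(1e-6, 1, 48), seed = 8)
  f <- fit_correlation(crv, 1, beam)
  ci_a <- bootstrap_uncertainty(crv, f, n_boot = 120, seed = 77)
  ci_b <- bootstrap_uncertainty(crv, f, n_boot = 120, seed = 77)
  expect_identical(ci_a, ci_b)
  expect_true(all(ci_a$lower < ci_a$upper))
  expect_error(bootstrap_uncertainty(crv, f, n_boot = 50), "at least 100")
})

test_that("bootstrap intervals cover the generating truth", {
  beam <- test_beam()
  hits <- 0L
  n_rep <- 12L
  for (i in seq_len(n_rep)) {
    crv <- simulate_curve(fcs_model(84, occupancy = 5), beam, 0.02,
                          lag_s = lag_grid(1e-6, 1, 48), seed = 500 + i)
    f <- fit_correlation(crv, 1, beam)
    ci <- bootstrap_uncertainty(crv, f, n_boot = 100, seed = i)
    d <- ci[ci$term == "D1", ]
    if (d$lower <= 84 && 84 <= d$upper) hits <- hits + 1L
  }
  # 68% nominal interval: demand at least half the replicates cover
  expect_gte(hits, n_rep / 2)
})

test_that("tidy, glance and augment expose the fit consistently", {
  beam <- test_beam()
  crv <- simulate_curve(fcs_model(c(43, 14), fraction = c(0.9, 0.1),
                                  occupancy = 5), beam, 0.02,
                        lag_s = lag_grid(1e-6, 1, 128), seed = 6)
  f <- fit_correlation(crv, 2, beam)
  td <- tidy(f)
  expect_setequal(td$term, c("occupancy", "D1", "D2", "F1"))
  gl <- glance(f)
  expect_equal(gl$n_points, 128)
  expect_equal(gl$n_free, 4)
  au <- augment(f)
  expect_equal(au$.resid, au$g - au$.fitted, tolerance = 1e-14)
  expect_equal(f$chi2, sum((au$.resid / crv$sigma)^2), tolerance = 1e-10)
})
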