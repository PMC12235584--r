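# Area per lipid, bilayer thickness, compressibility, lateral diffusivity.

const_box_traj <- function(L = 14.5, n_per_leaflet = 500, n_steps = 10,
                           dt = 10, d_hh = 4, z_sigma = 0) {
  nh <- 2 * n_per_leaflet
  leaflet <- rep(c("upper", "lower"), each = n_per_leaflet)
  z <- matrix(rep(ifelse(leaflet == "upper", d_hh / 2, -d_hh / 2),
                  each = n_steps), n_steps, nh)
  if (z_sigma > 0) z <- z + matrix(rnorm(n_steps * nh, 0, z_sigma),
                                   n_steps, nh)
  structure(list(times = (seq_len(n_steps) - 1) * dt,
                 Lx = rep(L, n_steps), Ly = rep(L, n_steps),
                 x = matrix(runif(n_steps * nh, 0, L), n_steps, nh),
                 y = matrix(runif(n_steps * nh, 0, L), n_steps, nh),
                 z = z, leaflet = leaflet, n_per_leaflet = n_per_leaflet,
                 temperature = 310),
            class = "head_trajectory")
}

test_that("APL of the production-like box is the printed arithmetic value", {
  tr <- const_box_traj()
  ap <- apl_series(tr, interval_ns = 10)
  expect_equal(unique(ap$apl), 14.5 * 14.5 / 500)
  expect_equal(ap$mean, 0.4205)
  # doubling the leaflet occupancy halves the APL exactly
  tr2 <- const_box_traj(n_per_leaflet = 1000)
  expect_equal(apl_series(tr2)$mean, 0.4205 / 2)
  # missing box dimensions error out
  tr_nobox <- tr; tr_nobox$Lx <- NULL
  expect_error(apl_series(tr_nobox), "box")
})

test_that("APL sampling recovers a fluctuating generator mean", {
  tr <- fx_trajectory()
  ap <- apl_series(tr, interval_ns = 10)
  expect_equal(ap$mean, 0.42, tolerance = 2 * ap$stderr / 0.42)
  expect_equal(ap$sd, 0.004, tolerance = 0.1)
})

test_that("APL standard error shrinks as 1/sqrt(n_samples)", {
  ses <- vapply(c(500, 2000, 8000), function(n) {
    set.seed(SUITE_SEED)
    tr <- simulate_trajectory(n_heads = 4, D_true = 0.1, n_steps = n,
                              dt = 10, seed = SUITE_SEED)
    apl_series(tr, interval_ns = 10)$stderr
  }, 0)
  expect_equal(ses[1] / ses[2], 2, tolerance = 0.15)
  expect_equal(ses[2] / ses[3], 2, tolerance = 0.15)
})

test_that("bilayer thickness finds the head-group density peaks", {
  set.seed(SUITE_SEED)
  tr <- const_box_traj(n_steps = 40)
  expect_equal(bilayer_thickness(tr), 4.0, tolerance = 0.05 / 4)
  # translation invariance
  tr_shift <- tr; tr_shift$z <- tr$z + 1.7
  expect_equal(bilayer_thickness(tr_shift), bilayer_thickness(tr),
               tolerance = 1e-9)
  # Gaussian-smeared leaflets stay within 2%
  trs <- const_box_traj(n_steps = 40, z_sigma = 0.3)
  expect_equal(bilayer_thickness(trs), 4.0, tolerance = 0.02)
  # unimodal density is rejected
  tr_flat <- const_box_traj(n_steps = 40, d_hh = 1e-3, z_sigma = 0.3)
  expect_error(bilayer_thickness(tr_flat), "unresolved")
})

test_that("compressibility evaluates the printed relation literally", {
  kb <- 1.380649e-23
  apl <- c(0.594, 0.6, 0.606)  # mean 0.6, sd 0.006
  expect_equal(compressibility(apl, 310),
               kb * 310 * mean(apl) / sd(apl))
  expect_equal(compressibility(apl, 310), kb * 310 * 100, tolerance = 1e-6)
  # scale invariance: mean/sd ratio is unchanged by rescaling
  expect_equal(compressibility(2.7 * apl, 310), compressibility(apl, 310))
  # constant series diverges
  expect_error(compressibility(rep(0.6, 10), 310), "zero variance")
  # variance mode needs the leaflet occupancy and returns mN/m
  ka <- compressibility(apl, 310, mode = "variance", n_per_leaflet = 500)
  area <- apl * 500
  expect_equal(ka, kb * 310 * mean(area) / var(area) * 1e21)
  expect_error(compressibility(apl, 310, mode = "variance"), "n_per_leaflet")
})

test_that("MSD matches the brute-force double-loop oracle exactly", {
  set.seed(SUITE_SEED)
  tr <- simulate_trajectory(n_heads = 50, D_true = 3, n_steps = 100, dt = 2,
                            seed = SUITE_SEED)
  lags <- c(1, 2, 5, 10, 25, 50, 99)
  got <- msd_lateral(tr, lags = lags)
  ux <- unwrap_coords(tr$x, tr$Lx); uy <- unwrap_coords(tr$y, tr$Ly)
  want <- oracle_msd(ux, uy, lags)
  expect_equal(got$msd, want, tolerance = 1e-12)
})

test_that("diffusivity is invariant to box wrapping", {
  set.seed(SUITE_SEED)
  # unwrapped Brownian paths, then wrapped into a fixed box
  n <- 2000; nh <- 20; L <- 12
  dx <- matrix(rnorm(n * nh, 0, 0.1), n, nh)
  ux <- apply(dx, 2, cumsum); uy <- apply(matrix(rnorm(n * nh, 0, 0.1), n, nh),
                                          2, cumsum)
  base <- list(times = (seq_len(n) - 1) * 2, Lx = rep(L, n), Ly = rep(L, n),
               z = matrix(0, 1, 1), leaflet = rep(c("upper", "lower"), nh / 2),
               n_per_leaflet = nh / 2, temperature = 310)
  tr_u <- structure(c(base, list(x = ux, y = uy)), class = "head_trajectory")
  tr_w <- structure(c(base, list(x = ux %% L, y = uy %% L)),
                    class = "head_trajectory")
  mu <- msd_lateral(tr_u, lags = c(1, 10, 100, 500))
  mw <- msd_lateral(tr_w, lags = c(1, 10, 100, 500))
  expect_equal(mu$msd, mw$msd, tolerance = 1e-9)
})

test_that("Einstein-relation fit recovers the generator diffusivity", {
  tr <- fx_trajectory()
  fit <- lateral_diffusivity(tr)
  expect_equal(fit$D, 5, tolerance = 0.05)
  expect_false(fit$poor_fit)
  # default window mirrors the 1.6-14.5 us range of a 20 us run
  expect_equal(fit$fit_range_ns, c(0.08, 0.725) * max(tr$times))
})

test_that("degenerate motion regimes are flagged or measured as zero", {
  # immobile heads
  tr0 <- simulate_trajectory(n_heads = 20, D_true = 0, n_steps = 500, dt = 2,
                             seed = SUITE_SEED)
  fit0 <- lateral_diffusivity(tr0)
  expect_equal(fit0$D, 0, tolerance = 1e-9)
  # ballistic motion: MSD ~ tau^2 flags a poor linear fit
  n <- 1000; nh <- 10
  t_ns <- (seq_len(n) - 1) * 2
  x <- outer(t_ns, seq_len(nh) * 0.01)  # x = v t per head
  trb <- structure(list(times = t_ns, Lx = rep(1e6, n), Ly = rep(1e6, n),
                        x = x, y = x * 0, z = matrix(0, 1, 1),
                        leaflet = rep(c("upper", "lower"), nh / 2),
                        n_per_leaflet = nh / 2, temperature = 310),
                   class = "head_trajectory")
  fitb <- lateral_diffusivity(trb)
  expect_true(fitb$poor_fit)
  # window outside the span errors
  expect_error(lateral_diffusivity(tr0, fit_window_fraction = c(0.5, 1.5)),
               "window")
})

test_that("diffusivity ordering across formulations is preserved", {
  d_true <- c(6, 3, 4.5)  # formulation 1 > 3 > 2
  est <- vapply(seq_along(d_true), function(i) {
    tr <- simulate_trajectory(n_heads = 100, D_true = d_true[i],
                              n_steps = 4000, dt = 5, seed = SUITE_SEED + i)
    lateral_diffusivity(tr)$D
  }, 0)
  expect_true(est[1] > est[3] && est[3] > est[2])
})

test_that("the full metrics bundle reports consistent components", {
  tr <- fx_trajectory()
  m <- membrane_metrics(tr)
  expect_equal(m$apl$mean, 0.42, tolerance = 0.01)
  expect_equal(m$d_hh, 4.0, tolerance = 0.02)
  expect_equal(m$k_a_J,
               1.380649e-23 * 310 * m$apl$mean / m$apl$sd)
  expect_equal(m$diffusivity$D, 5, tolerance = 0.05)
  # JSON round trip
  path <- tempfile(fileext = ".json")
  write_membrane_metrics(m, path)
  back <- jsonlite::read_json(path)
  expect_equal(back$D_um2_s, m$diffusivity$D)
  expect_equal(back$apl_mean_nm2, m$apl$mean)
  unlink(path)
})

test_that("trajectory tables round-trip through long-format CSV", {
  tr <- simulate_trajectory(n_heads = 6, D_true = 2, n_steps = 20, dt = 10,
                            seed = SUITE_SEED)
  path <- tempfile(fileext = ".csv")
  write_trajectory(tr, path)
  back <- read_trajectory(path)
  expect_equal(back$x, tr$x, ignore_attr = TRUE)
  expect_equal(back$Lx, tr$Lx)
  expect_equal(back$n_per_leaflet, 3)
  unlink(path)
})
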