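# Phase segmentation of swelling trajectories (synthetic series and small
# simulated runs) and parameter sweeps.

fake_traj <- function(times, u, jw, jp = -0.1 * jw, jm = -0.05 * jw) {
  structure(list(times = times, u_top_mm = u, Jw_top = jw, Jp_top = jp,
                 Jm_top = jm), class = "swell_trajectory")
}

test_that("phase boundaries follow the flux/displacement thresholds", {
  t <- seq(1, 100)
  # water flux ramps up, peaks at t = 20, decays; displacement saturates
  jw <- ifelse(t <= 20, t / 20, exp(-(t - 20) / 10))
  u <- 1 - exp(-pmax(t - 5, 0) / 15)
  tr <- fake_traj(t, u, jw)
  rep <- detect_phases(tr)
  expect_equal(rep$n_phases, 5L)
  b <- rep$boundaries_s
  expect_equal(unname(b["I_end"]), 1)       # flux passes 5% threshold at t=2
  expect_equal(unname(b["II_end"]), 20)     # max water influx
  expect_equal(unname(b["III_end"]),
               t[which(u >= 0.99 * max(u))[1]])
  expect_true(all(diff(b) >= 0))
  expect_equal(rep$peak_u_mm, max(u))
  # shrink-delay metrics of a dipping trajectory
  ud <- c(seq(0, -0.4, length.out = 20), seq(-0.4, 1, length.out = 80))
  repd <- detect_phases(fake_traj(t, ud, jw))
  expect_equal(repd$min_u_mm, -0.4)
  expect_equal(repd$t_positive_s, t[which(ud > 1e-6)[1]])
})

test_that("degenerate inputs are handled", {
  expect_error(detect_phases(fake_traj(c(1, 3, 2), rep(0, 3), rep(0, 3))),
               "non-monotone")
  rep0 <- detect_phases(fake_traj(1:5, rep(0, 5), rep(0, 5)))
  expect_equal(rep0$n_phases, 1L)
  expect_equal(rep0$peak_u_mm, 0)
})

test_that("sweeps preserve FCD ordering and report failures", {
  base <- free_swelling_config("table2", mesh = list(nx = 1, ny = 1, nz = 8),
                               t_final = 400, profile_times = numeric(),
                               solver = fast_solver(t_final = 400, dt = 5))
  sp <- sweep_spec("c0F", c(200, 135, 110), base)
  res <- sweep_parameter(sp)
  expect_equal(nrow(res$metrics), 3L)
  expect_true(all(res$metrics$converged))
  # displacement ordering matches FCD ordering (steady state and peak)
  expect_true(all(diff(res$metrics$final_u_mm) < 0))
  expect_true(all(diff(res$metrics$peak_u_mm) < 0))
  # oracle ordering agrees
  expect_true(all(diff(res$metrics$u_top_oracle) < 0))
  # shrink-delay appears for the lower FCD members only
  expect_equal(res$metrics$min_u_mm[1], 0)
  expect_lt(res$metrics$min_u_mm[3], 0)
  expect_gt(res$metrics$t_positive_s[3], res$metrics$t_positive_s[1])
  expect_error(sweep_spec("Phi0w", c(0, 1.2)), "physical bounds")
})
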