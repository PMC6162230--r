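params14 <- game_params(T = 1.4, L = 0.4)

test_that("initialization modes place alpha mass as required", {
  w <- build_lattice(60)
  set.seed(1)
  w_pd <- init_population(w, "pd")
  expect_true(all(w_pd$alpha_idx == 0L))
  expect_lt(abs(mean(w_pd$s == 0L) - 0.5), 0.025) # 3 sigma at N = 3600

  w_opd <- init_population(w, "opd")
  expect_true(all(w_opd$alpha_idx %in% c(0L, 8L)))
  expect_lt(abs(mean(w_opd$alpha_idx == 8L) - 0.5), 0.025)

  w_pdpa <- init_population(w, "pdpa")
  occ <- tabulate(w_pdpa$alpha_idx + 1L, nbins = 9) / 3600
  expect_true(all(occ > 0))                  # all nine levels occupied
  expect_true(all(abs(occ - 1 / 9) < 0.026)) # 5 sigma binomial band
})

test_that("opd initialization at the published lattice size is balanced", {
  set.seed(3)
  w <- init_population(build_lattice(102), "opd")
  # binomial 3 sigma bound at N = 10404
  expect_lt(abs(mean(w$alpha_idx == 8L) - 0.5), 0.015)
})

test_that("synchronous accrual resolves each edge once with forced cases", {
  # all agents always abstain: every utility is kappa * L
  set.seed(2)
  u <- accrue_payoffs_sync(make_fixture("all_loners_5x5"), params14)
  expect_true(all(u == 4 * 0.4))

  # all cooperators who never abstain: every utility is kappa * R
  w <- world_from_matrices(matrix(0L, 4, 4), matrix(0L, 4, 4))
  u <- accrue_payoffs_sync(w, params14)
  expect_true(all(u == 4))

  # lone cooperator on the 3x3 torus: hand-enumerated utilities
  u <- accrue_payoffs_sync(make_fixture("single_c_3x3"), params14)
  expect_equal(u[2, 2], 0)               # centre C plays S = 0 four times
  nb <- rbind(c(1, 2), c(3, 2), c(2, 1), c(2, 3))
  expect_equal(u[nb], rep(1.4, 4))       # each D exploits the C once
  corners <- rbind(c(1, 1), c(1, 3), c(3, 1), c(3, 3))
  expect_equal(u[corners], rep(0, 4))    # mutual defection everywhere else
})

test_that("utilities are bounded sums of four interaction payoffs", {
  set.seed(4)
  for (i in 1:20) {
    w <- random_world(5)
    u <- accrue_payoffs_sync(w, params14)
    lo <- 4 * min(params14$P, params14$S)
    hi <- 4 * max(params14$T, params14$R, params14$L)
    expect_true(all(u >= lo & u <= hi))
  }
})

test_that("best-neighbour imitation adopts a unique strict maximum only", {
  w <- make_fixture("single_c_3x3")

  # homogeneous utilities: nothing changes
  w2 <- imitation_update_sync(w, matrix(1, 3, 3))
  expect_identical(w2$s, w$s)
  expect_identical(w2$alpha_idx, w$alpha_idx)

  # two-way tie at the neighbourhood maximum leaves the focal agent unchanged
  u <- matrix(0, 3, 3)
  u[1, 2] <- 1.4
  u[3, 2] <- 1.4
  w2 <- imitation_update_sync(w, u)
  expect_identical(w2$s[2, 2], w$s[2, 2])

  # a unique strict maximum is copied (strategy and alpha together)
  w$alpha_idx[1, 2] <- 3L
  u <- matrix(0, 3, 3)
  u[1, 2] <- 1.4
  w2 <- imitation_update_sync(w, u)
  expect_identical(w2$s[2, 2], w$s[1, 2])
  expect_identical(w2$alpha_idx[2, 2], 3L)
})

test_that("a lone cooperator on the 3x3 torus is frozen by the tie rule", {
  # the centre's four defector neighbours all earn T: a four-way tie, so the
  # centre keeps cooperating and the whole configuration is stationary
  w <- make_fixture("single_c_3x3")
  set.seed(9)
  w2 <- sync_step(w, params14)
  expect_identical(w2$s, w$s)
  expect_identical(w2$alpha_idx, w$alpha_idx)
})

test_that("a defector with a strict utility edge invades its neighbourhood", {
  s <- matrix(0L, 3, 3)
  s[1, 1] <- 1L # lone defector earns 4T, strictly above every cooperator
  w <- world_from_matrices(s, matrix(0L, 3, 3))
  set.seed(9)
  w2 <- sync_step(w, params14)
  expected <- matrix(0L, 3, 3)
  expected[1, 1] <- 1L
  expected[rbind(c(3, 1), c(2, 1), c(1, 3), c(1, 2))] <- 1L
  expect_identical(w2$s, expected)
})

test_that("all-defector populations are closed under both dynamics", {
  set.seed(10)
  a <- matrix(sample(0:8, 16, replace = TRUE), 4, 4)
  w <- world_from_matrices(matrix(1L, 4, 4), a)
  wd <- w
  for (i in 1:5) wd <- sync_step(wd, params14)
  expect_true(all(wd$s == 1L))
  wd <- w
  for (i in 1:5) wd <- async_step(wd, params14)
  expect_true(all(wd$s == 1L))
})

test_that("synchronous steps are bit-reproducible under a fixed seed", {
  set.seed(11)
  w <- random_world(6)
  set.seed(12)
  a <- sync_step(w, params14)
  set.seed(12)
  b <- sync_step(w, params14)
  expect_identical(a$s, b$s)
  expect_identical(a$alpha_idx, b$alpha_idx)
})

test_that("pd-mode trajectories match a PD-only reference engine", {
  set.seed(13)
  w <- init_population(build_lattice(8), "pd")
  w_pkg <- w
  w_ref <- w
  for (i in 1:10) {
    w_pkg <- sync_step(w_pkg, params14)
    w_ref <- oracle_pd_sync_step(w_ref, params14)
    expect_identical(w_pkg$s, w_ref$s)
  }
})

test_that("Fermi probability matches closed forms and is stable", {
  expect_equal(fermi_probability(1, 1), 0.5)
  expect_equal(fermi_probability(0.4 * log(3), 0, kappa = 4, K = 0.1), 0.25)
  # huge utility deficit: W -> 1 with no overflow
  expect_equal(fermi_probability(-100, 0), 1, tolerance = 1e-15)
  expect_equal(fermi_probability(100, 0), 0, tolerance = 1e-15)
})

test_that("Fermi probability is a proper monotone comparison kernel", {
  d <- seq(-6, 6, by = 0.25)
  w <- fermi_probability(d, 0)
  expect_true(all(w > 0 & w < 1))
  expect_true(all(diff(w) < 0)) # strictly decreasing in u_x - u_y
  for (i in seq_along(d)) {
    expect_equal(fermi_probability(d[i], 0) + fermi_probability(0, d[i]), 1)
  }
})

test_that("asynchronous moves cannot change homogeneous populations", {
  w <- world_from_matrices(matrix(0L, 4, 4), matrix(4L, 4, 4))
  set.seed(14)
  w2 <- async_step(w, params14)
  expect_identical(w2$s, w$s)
  expect_identical(w2$alpha_idx, w$alpha_idx)
})

test_that("an always-abstaining population is frozen under async updating", {
  # u_x = u_y = kappa * L for every pair, so u_y > u_x never holds
  w <- make_fixture("all_loners_5x5")
  set.seed(15)
  w2 <- async_step(w, params14)
  expect_identical(w2$s, w$s)
  expect_identical(w2$alpha_idx, w$alpha_idx)
  m <- measure_state(w2)
  expect_equal(m$mean_eps, 0)
  expect_equal(m$mean_alpha, 1)
})

test_that("asynchronous steps are bit-reproducible under a fixed seed", {
  set.seed(16)
  w <- random_world(6)
  set.seed(17)
  a <- async_step(w, params14)
  set.seed(17)
  b <- async_step(w, params14)
  expect_identical(a$s, b$s)
  expect_identical(a$alpha_idx, b$alpha_idx)
})

test_that("the elementary-move site hook mutates at most the focal site", {
  w <- make_fixture("single_c_3x3")
  set.seed(18)
  for (i in 1:20) {
    w2 <- async_elementary_move(w, params14, site = c(2, 2))
    changed <- which(w2$s != w$s | w2$alpha_idx != w$alpha_idx)
    expect_true(length(changed) <= 1)
    if (length(changed)) expect_equal(changed, 5L) # linear index of (2,2)
    expect_identical(attr(w2, "copied"), length(changed) == 1L)
  }
})

test_that("run_simulation validates its configuration up front", {
  expect_error(simulation_config(mc_steps = 0), "mc_steps")
  expect_error(simulation_config(record_every = 0), "record_every")
  expect_error(simulation_config(side = 1), "degenerate")
})

test_that("a one-step run records the initial and the one-step state", {
  cfg <- simulation_config(side = 6, mc_steps = 1, seed = 19)
  r <- run_simulation(cfg)
  expect_equal(r$time_series$step, c(0, 1))
})

test_that("pd-mode runs keep mean alpha at zero throughout", {
  for (scheme in c("synchronous", "asynchronous")) {
    cfg <- simulation_config(side = 10, mc_steps = 30, seed = 20,
                             update_scheme = scheme, init_mode = "pd",
                             record_every = 1)
    r <- run_simulation(cfg)
    expect_true(all(r$time_series$mean_alpha == 0))
  }
})

test_that("identical configurations give identical run results", {
  cfg <- simulation_config(side = 12, mc_steps = 40, seed = 21,
                           update_scheme = "asynchronous", record_every = 10)
  a <- run_simulation(cfg)
  b <- run_simulation(cfg)
  expect_identical(a$time_series, b$time_series)
  expect_identical(a$final_world$s, b$final_world$s)
  expect_identical(a$final_world$alpha_idx, b$final_world$alpha_idx)
})

test_that("the recorded step grid covers start, interval and final step", {
  cfg <- simulation_config(side = 6, mc_steps = 25, seed = 22,
                           record_every = 10)
  r <- run_simulation(cfg)
  expect_equal(r$time_series$step, c(0, 10, 20, 25))
})

test_that("absorbing-state early stop halts a homogeneous population", {
  # at T = 1.9 a small asynchronous pd population collapses to all-D within
  # a few steps, which is homogeneous in (s, alpha) and hence absorbing
  cfg <- simulation_config(params = game_params(T = 1.9, L = 0.4),
                           side = 6, mc_steps = 1000, seed = 23,
                           update_scheme = "asynchronous",
                           init_mode = "pd", record_every = 100,
                           stop_when_absorbing = TRUE)
  r <- run_simulation(cfg)
  expect_lt(r$steps_run, 1000)
  final <- r$final_world
  expect_length(unique(as.integer(final$s)), 1L)
  # without the flag the same configuration runs to full length
  cfg$stop_when_absorbing <- FALSE
  expect_equal(run_simulation(cfg)$steps_run, 1000)
})

test_that("the alpha support only ever shrinks (imitation closure)", {
  for (scheme in c("synchronous", "asynchronous")) {
    cfg <- simulation_config(side = 10, mc_steps = 40, seed = 24,
                             update_scheme = scheme, record_every = 1)
    r <- run_simulation(cfg)
    occ <- as.matrix(r$time_series[grep("^alpha_",
                                        names(r$time_series))]) > 0
    for (i in seq_len(nrow(occ) - 1)) {
      expect_true(all(occ[i, ] | !occ[i + 1, ])) # support(t+1) subset of (t)
    }
  }
})
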