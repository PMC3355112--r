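pc <- physical_constants()

test_that("gating protocol construction: episodes, labels, sample counts", {
  prot <- make_gating_protocol()
  expect_equal(n_episodes(prot), 19L)
  expect_equal(prot$episode_labels, seq(-140, 40, by = 10))
  expect_equal(prot$holding_potential, -100)
  # the 60 ms test step at 0.1 ms holds 601 samples (both endpoints)
  ep <- prot$episodes[[1L]]
  expect_equal(ep$voltage, c(-100, -140, -140))
  t <- kvgating:::episode_time_grid(prot, 1L)
  step_start <- sum(ep$duration[1:2])
  expect_equal(sum(t >= step_start - 1e-9), 601L)
  # degenerate range collapses to one episode
  expect_equal(n_episodes(make_gating_protocol(start = 0, stop = 0)), 1L)
  expect_error(make_gating_protocol(start = 10, stop = -10), "start")
  expect_error(make_gating_protocol(increment = -5), "increment")
})

test_that("protocol validation rejects bad sampling", {
  eps <- list(data.frame(duration = c(5, 1), voltage = c(-100, 0)))
  expect_error(voltage_protocol(eps, -100, sample_interval = 2),
               "shortest segment")
  eps2 <- list(data.frame(duration = c(5, 1.05), voltage = c(-100, 0)))
  expect_error(voltage_protocol(eps2, -100, sample_interval = 0.1),
               "integer multiples")
  eps3 <- list(data.frame(duration = c(-1, 5), voltage = c(-100, 0)))
  expect_error(voltage_protocol(eps3, -100), "> 0")
})

test_that("Cole-Moore protocol carries prepulse labels", {
  prot <- make_cole_moore_protocol(c(-140, -60), test_mV = 40)
  expect_equal(n_episodes(prot), 2L)
  expect_equal(prot$episode_labels, c(-140, -60))
  expect_equal(prot$episodes[[2L]]$voltage, c(-100, -60, 40))
  expect_equal(n_episodes(make_cole_moore_protocol(-140)), 1L)
})

test_that("occupancy is stationary under a constant protocol at holding", {
  asm <- preset_homotetramer(pc)
  prot <- voltage_protocol(
    list(data.frame(duration = 20, voltage = -100)),
    holding_potential = -100, sample_interval = 0.1)
  traj <- propagate_occupancy(asm, prot, 1L, pc)
  p0 <- traj$probabilities[1L, ]
  expect_lt(max(abs(sweep(traj$probabilities, 2, p0))), 1e-10)
})

test_that("long depolarization converges to the step equilibrium", {
  asm <- preset_heterotetramer(pc)
  prot <- make_gating_protocol(start = 40, stop = 40,
                               sample_interval_ms = 0.05)
  traj <- propagate_occupancy(asm, prot, 1L, pc)
  p_end <- traj$probabilities[nrow(traj$probabilities), ]
  p_eq <- equilibrium_distribution(asm, 40, pc)
  expect_lt(max(abs(p_end - p_eq)), 1e-6)
})

test_that("propagation preserves the probability simplex", {
  asm <- preset_heterotetramer(pc)
  prot <- make_gating_protocol(sample_interval_ms = 0.1)
  for (i in c(1L, 8L, 19L)) {
    traj <- propagate_occupancy(asm, prot, i, pc)
    expect_gt(min(traj$probabilities), -1e-12)
    expect_lt(max(abs(rowSums(traj$probabilities) - 1)), 1e-8)
  }
})

test_that("propagation agrees with an independent RK4 oracle", {
  asm <- preset_heterotetramer(pc)
  sp <- build_state_space(asm)
  prot <- voltage_protocol(
    list(data.frame(duration = c(2, 8), voltage = c(-140, -30))),
    holding_potential = -100, sample_interval = 0.05)
  traj <- propagate_occupancy(asm, prot, 1L, pc, sp)
  p0 <- equilibrium_distribution(asm, -100, pc, sp)
  Q1 <- generator_at_voltage(asm, -140, pc, sp)
  Q2 <- generator_at_voltage(asm, -30, pc, sp)
  p_mid <- rk4_propagate(Q1, p0, 2, 40000L)
  p_end <- rk4_propagate(Q2, p_mid, 8, 40000L)
  expect_lt(max(abs(traj$probabilities[nrow(traj$probabilities), ] - p_end)),
            1e-7)
})

test_that("halving the sampling step does not move the occupancies", {
  asm <- preset_homotetramer(pc)
  mk <- function(dt) {
    prot <- make_gating_protocol(start = -30, stop = -30,
                                 sample_interval_ms = dt)
    propagate_occupancy(asm, prot, 1L, pc)
  }
  a <- mk(0.1)
  b <- mk(0.05)
  sel <- match(round(a$time, 9), round(b$time, 9))
  expect_lt(max(abs(a$probabilities - b$probabilities[sel, ])), 1e-8)
})

test_that("gating current vanishes at equilibrium and conserves charge", {
  asm <- preset_heterotetramer(pc)
  sp <- build_state_space(asm)
  hold <- voltage_protocol(
    list(data.frame(duration = 10, voltage = -100)),
    holding_potential = -100, sample_interval = 0.1)
  tr0 <- gating_current_trace(propagate_occupancy(asm, hold, 1L, pc, sp),
                              sp, asm, pc)
  expect_lt(max(abs(tr0$current)), 1e-10)

  # saturating step: ON-charge integral over the test step equals the
  # occupancy-weighted charge difference (independent oracle), which is
  # itself the full (3 z_c + z_d) displacement minus the tiny charge
  # already moved at the -140 mV prepulse baseline
  prot <- make_gating_protocol(start = 40, stop = 40,
                               sample_interval_ms = 0.002)
  traj <- propagate_occupancy(asm, prot, 1L, pc, sp)
  tr <- gating_current_trace(traj, sp, asm, pc)
  w <- kvgating:::.step_window(tr)
  q_int <- integrate_on_charge(tr, w)
  i_start <- which(abs(traj$time - w[1L]) < 1e-9)
  dq_oracle <- expected_charge(sp, traj$probabilities[nrow(traj$probabilities), ]) -
    expected_charge(sp, traj$probabilities[i_start, ])
  expect_equal(q_int, dq_oracle, tolerance = 5e-3)
  z_total <- 3 * subunit_charge(asm$common) + subunit_charge(asm$distinct)
  expect_equal(q_int, z_total, tolerance = 5e-3)
})

test_that("population scaling converts per-channel flux to pA", {
  asm <- preset_homotetramer(pc, n_channels = 1e6)
  prot <- make_gating_protocol(start = 0, stop = 0, sample_interval_ms = 0.1)
  sp <- build_state_space(asm)
  traj <- propagate_occupancy(asm, prot, 1L, pc, sp)
  a <- gating_current_trace(traj, sp, asm, pc, scale = "e0_per_ms")
  b <- gating_current_trace(traj, sp, asm, pc, scale = "pA")
  expect_equal(b$current, a$current * 1e6 * 1.602176634e-4,
               tolerance = 1e-12)
  expect_equal(b$units, "pA")
})

test_that("integrated ON charge is nondecreasing in step voltage", {
  asm <- preset_heterotetramer(pc)
  traces <- simulate_protocol(asm, make_gating_protocol(
    sample_interval_ms = 0.02), "gating", pc)
  qv <- build_qv(traces)
  expect_true(all(diff(qv$raw_charge) > -1e-4 * max(qv$raw_charge)))
})

test_that("doubling time resolution changes integrated charge by < 0.1%", {
  asm <- preset_homotetramer(pc)
  q_at <- function(dt) {
    prot <- make_gating_protocol(start = -30, stop = -30,
                                 sample_interval_ms = dt)
    integrate_on_charge(simulate_protocol(asm, prot, "gating", pc)[[1L]])
  }
  q1 <- q_at(0.02)
  q2 <- q_at(0.01)
  expect_lt(abs(q2 - q1) / abs(q2), 1e-3)
})

test_that("ionic current obeys the ohmic driving force", {
  asm <- preset_heterotetramer(pc, n_channels = 100,
                               reversal_potential = -80)
  # step exactly to the reversal potential: zero current at any P_open
  prot <- make_gating_protocol(start = -80, stop = -80,
                               sample_interval_ms = 0.1)
  tr <- simulate_protocol(asm, prot, "ionic", pc)[[1L]]
  w <- tr$segments
  step_sel <- tr$time >= w$start[3L] - 1e-9
  expect_lt(max(abs(tr$current[step_sel])), 1e-12)
  # closed channel (deep hyperpolarization): P_open ~ 0 means no current
  prot2 <- make_gating_protocol(start = -140, stop = -140,
                                sample_interval_ms = 0.1)
  tr2 <- simulate_protocol(asm, prot2, "ionic", pc)[[1L]]
  expect_lt(max(abs(tr2$current)), 1e-6)
})

test_that("the heterotetramer activates with a shorter delay", {
  het <- preset_heterotetramer(pc, n_channels = 100)
  homo <- matched_homotetramer(het)
  prot <- make_gating_protocol(start = 0, stop = 0,
                               sample_interval_ms = 0.05)
  t_half <- function(asm) {
    tr <- simulate_protocol(asm, prot, "ionic", pc)[[1L]]
    sel <- tr$time >= tr$segments$start[3L] - 1e-9
    t <- tr$time[sel] - tr$segments$start[3L]
    y <- abs(tr$current[sel])
    t[which(y >= 0.5 * max(y))[1L]]
  }
  expect_lt(t_half(het), t_half(homo))
})

test_that("Gillespie simulation is reproducible and matches the master equation", {
  asm <- preset_homotetramer(pc)
  prot <- make_gating_protocol(start = -40, stop = -40,
                               sample_interval_ms = 0.5)
  g1 <- gillespie_simulate(asm, prot, 1L, n_channels = 50L, seed = 7L)
  g2 <- gillespie_simulate(asm, prot, 1L, n_channels = 50L, seed = 7L)
  expect_identical(g1$counts, g2$counts)
  g3 <- gillespie_simulate(asm, prot, 1L, n_channels = 50L, seed = 8L)
  expect_false(identical(g1$counts, g3$counts))

  n <- 2000L
  g <- gillespie_simulate(asm, prot, 1L, n_channels = n, seed = 11L)
  traj <- propagate_occupancy(asm, prot, 1L, pc)
  checkpoints <- round(seq(1L, length(g$time), length.out = 10L))
  for (k in checkpoints) {
    p <- pmin(pmax(traj$probabilities[k, ], 0), 1)
    se <- sqrt(p * (1 - p) / n)
    diff <- abs(g$counts[k, ] / n - p)
    expect_true(all(diff <= 3 * se + 2 / n))
  }
})

test_that("Gillespie with vanishing rates never leaves the initial state", {
  kin <- subunit_kinetics(1e-12, 1e-12, 1, 1)
  asm <- channel_assembly(kin, kin, opening_rate = 1e-12,
                          closing_rate = 1e-12)
  prot <- voltage_protocol(
    list(data.frame(duration = 10, voltage = 0)),
    holding_potential = -100, sample_interval = 0.5)
  g <- gillespie_simulate(asm, prot, 1L, n_channels = 1L, seed = 1L)
  occupied <- which(colSums(g$counts) > 0)
  expect_equal(length(occupied), 1L)
  expect_equal(unname(g$counts[, occupied]), rep(1L, length(g$time)))
})
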