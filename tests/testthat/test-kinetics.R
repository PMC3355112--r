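pc <- physical_constants()
vt <- pc$thermal_voltage

test_that("rate laws evaluate the exponential voltage dependence", {
  kin <- subunit_kinetics(1, 1, 1, 1)
  expect_equal(rate_alpha(kin, 0, pc), 1.0)
  expect_equal(rate_beta(kin, 0, pc), 1.0)
  expect_equal(rate_alpha(kin, vt, pc), exp(1))
  expect_equal(rate_beta(kin, vt, pc), exp(-1))
  kin2 <- subunit_kinetics(0.5, 0.5, 2, 2)
  expect_equal(rate_alpha(kin2, -vt, pc), 0.5 * exp(-2))
  # monotonicity
  v <- seq(-150, 50, by = 5)
  expect_true(all(diff(rate_alpha(kin, v, pc)) > 0))
  expect_true(all(diff(rate_beta(kin, v, pc)) < 0))
})

test_that("rate laws reject invalid input", {
  kin <- subunit_kinetics(1, 1, 1, 1)
  expect_error(rate_alpha(kin, NaN, pc), "finite")
  expect_error(rate_beta(kin, Inf, pc), "finite")
  expect_error(subunit_kinetics(-1, 1, 1, 1), "positive")
  expect_error(subunit_kinetics(1, 1, 0, 0), "positive sum")
})

test_that("alpha equals beta at the midpoint under a symmetric split", {
  kin <- calibrate_from_boltzmann(-26.5, 4.6, 16.5, -26.5, pc)
  vh <- subunit_vhalf(kin, pc)
  expect_equal(vh, -26.5, tolerance = 1e-10)
  expect_equal(rate_alpha(kin, vh, pc), rate_beta(kin, vh, pc),
               tolerance = 1e-12)
})

test_that("calibration reproduces charge, midpoint and tau constraints", {
  kin <- calibrate_from_boltzmann(-26.5, 4.6, 16.5, -26.5, pc)
  expect_equal(subunit_charge(kin), vt / 4.6, tolerance = 1e-12)
  expect_equal(subunit_charge(kin), 5.585, tolerance = 2e-4)
  # tau constraint at the reference voltage; alpha = beta there by symmetry
  expect_equal(1 / (rate_alpha(kin, -26.5, pc) + rate_beta(kin, -26.5, pc)),
               16.5, tolerance = 1e-10)
  expect_equal(rate_alpha(kin, -26.5, pc), 1 / (2 * 16.5), tolerance = 1e-10)
  # round trip: the subunit equilibrium IS the target Boltzmann
  v <- seq(-140, 40, by = 10)
  expect_equal(subunit_open_fraction(kin, v, pc), boltzmann(v, -26.5, 4.6),
               tolerance = 1e-10)
  # tau reference away from the midpoint is honoured too
  kin2 <- calibrate_from_boltzmann(-93.2, 9.4, 5.8, -70, pc)
  expect_equal(1 / (rate_alpha(kin2, -70, pc) + rate_beta(kin2, -70, pc)),
               5.8, tolerance = 1e-10)
  expect_equal(subunit_vhalf(kin2, pc), -93.2, tolerance = 1e-10)
  expect_error(calibrate_from_boltzmann(-26.5, -1, 16.5), "slope_k")
  expect_error(calibrate_from_boltzmann(-26.5, 4.6, 0), "tau_ref")
})

test_that("state space is the 9-state ladder with correct multiplicities", {
  asm <- preset_heterotetramer(pc)
  sp <- build_state_space(asm)
  expect_equal(nrow(sp$states), 9L)
  expect_equal(sum(sp$states$open), 1L)
  expect_equal(sp$states$label[9L], "O")
  # deterministic ordering: n ascending, C* before A*, open last
  expect_equal(sp$states$n_common_active[1:8], rep(0:3, each = 2))
  expect_equal(sp$states$distinct_active[1:8], rep(c(FALSE, TRUE), 4))
  # forward multiplicity 3 out of the resting corner
  e <- sp$transitions
  first <- e[e$from == 1L & e$to == 3L, ]
  expect_equal(first$mult_fwd, 3L)
  expect_equal(first$mult_rev, 1L)
  # single opening edge, only from (3 active, distinct active)
  open_edges <- e[e$type == "open", ]
  expect_equal(nrow(open_edges), 1L)
  expect_equal(open_edges$from, 8L)
  expect_equal(open_edges$to, 9L)
  # per-edge charges: common steps carry the common per-subunit charge
  expect_equal(unique(e$charge[e$type == "common"]),
               subunit_charge(asm$common))
  expect_equal(unique(e$charge[e$type == "distinct"]),
               subunit_charge(asm$distinct))
  expect_equal(e$charge[e$type == "open"], 0)
})

test_that("generator rows sum to zero and off-diagonals are nonnegative", {
  asm <- preset_heterotetramer(pc)
  for (v in c(-140, 0, 40)) {
    Q <- generator_at_voltage(asm, v, pc)
    expect_lt(max(abs(rowSums(Q))), 1e-12 * max(abs(Q)))
    off <- Q - diag(diag(Q))
    expect_true(all(off >= 0))
  }
  # resting at -140: deactivation dominates
  expect_gt(rate_beta(asm$common, -140, pc) /
              rate_alpha(asm$common, -140, pc), 1e3)
})

test_that("homotetramer limit: aggregated chain is the binomial(4) ladder", {
  # with distinct == common, total-active count follows a birth-death
  # chain with rates (4 - m) alpha, m beta; compare full dynamics
  kin <- calibrate_from_boltzmann(-26.5, 4.6, 16.5, -26.5, pc)
  asm <- channel_assembly(kin, kin, opening_rate = 1e-9, closing_rate = 1)
  sp <- build_state_space(asm)
  v_test <- -20
  Q9 <- generator_at_voltage(asm, v_test, pc)
  a <- rate_alpha(kin, v_test, pc)
  b <- rate_beta(kin, v_test, pc)
  # birth-death oracle on m = 0..4 activated subunits
  Q5 <- matrix(0, 5, 5)
  for (m in 0:3) Q5[m + 1, m + 2] <- (4 - m) * a
  for (m in 1:4) Q5[m + 1, m] <- m * b
  diag(Q5) <- -rowSums(Q5)
  p0_9 <- equilibrium_distribution(asm, -100, pc)
  m_of_state <- c(sp$states$n_common_active +
                    as.numeric(sp$states$distinct_active))
  p0_5 <- as.numeric(tapply(p0_9, m_of_state, sum))
  for (t in c(1, 5, 20)) {
    p9 <- expm_at(Q9, p0_9, t)
    agg <- as.numeric(tapply(p9, m_of_state, sum))
    p5 <- expm_at(Q5, p0_5, t)
    expect_lt(max(abs(agg - p5)), 1e-9)
  }
})

test_that("equilibrium distribution: simplex, detailed balance, null space", {
  asm <- preset_heterotetramer(pc)
  sp <- build_state_space(asm)
  for (v in c(-120, -60, -26.5, 0, 30)) {
    p <- equilibrium_distribution(asm, v, pc, sp)
    expect_equal(sum(p), 1, tolerance = 1e-10)
    expect_true(all(p >= 0))
    # detailed balance on every edge
    r <- kvgating:::.edge_rates(asm, sp, v, pc)
    flux_f <- p[sp$transitions$from] * r$fwd
    flux_r <- p[sp$transitions$to] * r$rev
    expect_lt(max(abs(flux_f - flux_r) / pmax(flux_f, 1e-300)), 1e-10)
    # algebraic oracle: null space of the generator transpose
    Q <- generator_at_voltage(asm, v, pc, sp)
    expect_lt(max(abs(p - nullspace_equilibrium(Q))), 1e-9)
  }
})

test_that("equilibrium limits and marginals", {
  asm <- preset_heterotetramer(pc)
  # deep hyperpolarization: everything in the fully resting state
  p <- equilibrium_distribution(asm, -500, pc)
  expect_gt(p[[1L]], 1 - 1e-10)
  # binomial product form for the common subunits (opening weight removed)
  kin <- asm$common
  asm0 <- channel_assembly(kin, asm$distinct,
                           opening_rate = 1e-12, closing_rate = 1)
  sp <- build_state_space(asm0)
  for (v in c(-60, -21.8, 0)) {
    p <- equilibrium_distribution(asm0, v, pc, sp)
    pa <- subunit_open_fraction(kin, v, pc)
    marg_n <- as.numeric(tapply(p, sp$states$n_common_active, sum))
    expect_lt(max(abs(marg_n - stats::dbinom(0:3, 3, pa))), 1e-10)
  }
  # distinct marginal is 1/2 at its own midpoint
  vh_d <- subunit_vhalf(asm0$distinct, pc)
  p <- equilibrium_distribution(asm0, vh_d, pc, sp)
  expect_equal(sum(p[sp$states$distinct_active]), 0.5, tolerance = 1e-9)
})

test_that("equilibrium activated charge is nondecreasing in voltage", {
  for (asm in list(preset_homotetramer(pc), preset_heterotetramer(pc))) {
    sp <- build_state_space(asm)
    qv <- vapply(seq(-140, 40, by = 5), function(v) {
      expected_charge(sp, equilibrium_distribution(asm, v, pc, sp))
    }, numeric(1L))
    expect_true(all(diff(qv) >= -1e-12))
  }
})

test_that("aggregated 9-state chain matches the explicit 17-state oracle", {
  asm <- preset_heterotetramer(pc)
  sp <- build_state_space(asm)
  for (v in c(-80, -30, 10)) {
    ex <- explicit_chain(asm, v, pc)
    Q9 <- generator_at_voltage(asm, v, pc, sp)
    p0_9 <- equilibrium_distribution(asm, -100, pc, sp)
    # explicit initial condition: product measure over identical subunits
    pa <- subunit_open_fraction(asm$common, -100, pc)
    pd <- subunit_open_fraction(asm$distinct, -100, pc)
    w_open <- asm$opening_rate / asm$closing_rate
    pr <- with(ex$conf,
               pa^(a1 + a2 + a3) * (1 - pa)^(3 - a1 - a2 - a3) *
                 pd^d * (1 - pd)^(1 - d))
    p0_17 <- c(pr, pr[nrow(ex$conf)] * w_open)
    p0_17 <- p0_17 / sum(p0_17)
    for (t in c(0.5, 3, 15)) {
      p9 <- expm_at(Q9, p0_9, t)
      p17 <- expm_at(ex$Q, p0_17, t)
      agg <- as.numeric(tapply(p17, ex$class_of, sum))
      expect_lt(max(abs(agg - p9)), 1e-9)
    }
  }
})

test_that("charge-voltage of one calibrated subunit round-trips", {
  kin <- calibrate_from_boltzmann(-26.5, 4.6, 16.5, -26.5, pc)
  v <- seq(-140, 40, by = 10)
  qv <- structure(list(voltages = v,
                       normalized_charge = subunit_open_fraction(kin, v, pc)),
                  class = "qv_curve")
  fit <- fit_boltzmann(qv)
  expect_equal(fit$Q_half, -26.5, tolerance = 1e-5)
  expect_equal(fit$slope_k, 4.6, tolerance = 1e-5)
})

test_that("opening equilibrium weight distorts the Q-V as documented", {
  # equilibrium charge at the protocol voltages, fitted with a Boltzmann:
  # a strong open-state stabilization (K = 2) steepens the apparent slope
  # far below the calibrated 4.6 mV, while the default K = 0.1 does not
  kin <- calibrate_from_boltzmann(-26.5, 4.6, 16.5, -20, pc)
  slope_at <- function(ko, kc) {
    asm <- channel_assembly(kin, kin, opening_rate = ko, closing_rate = kc)
    sp <- build_state_space(asm)
    v <- seq(-140, 40, by = 10)
    q <- vapply(v, function(vv) {
      expected_charge(sp, equilibrium_distribution(asm, vv, pc, sp))
    }, numeric(1L))
    q <- q - q[1L]
    fit_boltzmann(structure(list(voltages = v,
                                 normalized_charge = q / max(q)),
                            class = "qv_curve"))$slope_k
  }
  expect_lt(slope_at(1.0, 0.5), 3.8)
  expect_equal(slope_at(0.1, 1.0), 4.6, tolerance = 0.05)
})

test_that("assembly JSON serialization round-trips (schema 1)", {
  asm <- preset_heterotetramer(pc, n_channels = 1234)
  path <- tempfile(fileext = ".json")
  assembly_to_json(asm, path, pc)
  back <- assembly_from_json(path)
  expect_equal(back$assembly, asm)
  expect_equal(back$pc$temperature, pc$temperature)
  expect_match(readLines(path)[2L], "\"schema\": 1")
  bad <- sub("\"schema\": 1", "\"schema\": 99", readLines(path))
  writeLines(bad, path)
  expect_error(assembly_from_json(path), "schema")
})
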