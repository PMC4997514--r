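test_that("volatility coefficient scales with gamma and matches the room's vapor capacity", {
  w <- default_constituents()$water
  a <- volatility_coefficient(w, 298.15, 113)
  # a * M is the saturated vapor mass the room can hold: ~23 g/m^3 x 113 m^3
  expect_equal(a * w$molar_mass, 2600, tolerance = 0.02)
  w2 <- constituent(w$name, w$molar_mass, w$antoine, w$t_range,
                    gamma = 2, liquid_density = w$liquid_density)
  expect_equal(volatility_coefficient(w2, 298.15, 113), 2 * a)
  tiny <- synthetic_constituent("t", psat_298 = 1e-12)
  expect_lt(volatility_coefficient(tiny, 298.15, 113) * 100, 1e-6)
})

test_that("single-constituent system has the closed-form root", {
  nic <- default_constituents()$nicotine
  aM <- volatility_coefficient(nic, 296.15, 1) * nic$molar_mass * 1e6  # ug
  # m = 2 a M  ->  w = 1 - aM/m = 0.5
  pb <- partition_problem(2 * aM, list(nic), 296.15, 1)
  for (res in list(solve_partition(pb), brute_force_partition(pb))) {
    expect_true(res$converged)
    expect_equal(unname(res$liquid_fractions), 0.5, tolerance = 1e-9)
  }
  # m = 5 a M  ->  w = 0.8
  pb2 <- partition_problem(5 * aM, list(nic), 296.15, 1)
  expect_equal(unname(solve_partition(pb2)$liquid_fractions), 0.8,
               tolerance = 1e-9)
  # subsaturated room: everything fits in the vapor
  pb3 <- partition_problem(0.5 * aM, list(nic), 296.15, 1)
  expect_identical(unname(solve_partition(pb3)$liquid_fractions), 0)
  expect_identical(unname(brute_force_partition(pb3)$liquid_fractions), 0)
})

test_that("residuals vanish at w = 0 and at the oracle's solution", {
  set.seed(11)
  pb <- random_partition_problem(3)
  expect_equal(unname(partition_residual(rep(0, 3), pb)), rep(0, 3))
  # at the oracle's converged partition the algebraic system is satisfied
  pb2 <- partition_problem(c(5e4, 5e4, 1e6, 3e3), default_constituents(),
                           296.15, 0.1)
  w_o <- brute_force_partition(pb2)$liquid_fractions
  f <- partition_residual(w_o, pb2)
  expect_lt(max(abs(f) / (pb2$total_masses + 1)), 1e-8)
})

test_that("solver and brute-force oracle agree on randomized small systems", {
  set.seed(42)
  n_agree <- 0
  for (rep in 1:100) {
    k <- sample(2:4, 1)
    pb <- random_partition_problem(k)
    s <- solve_partition(pb)
    o <- brute_force_partition(pb)
    expect_true(s$converged)
    expect_true(o$converged)
    expect_lt(max(abs(s$liquid_fractions - o$liquid_fractions)), 1e-6)
    n_agree <- n_agree + 1
    # mass closure and box constraint, every call
    expect_equal(unname(s$liquid_masses + s$vapor_masses),
                 unname(pb$total_masses))
    expect_true(all(s$liquid_fractions >= 0 & s$liquid_fractions <= 1))
  }
  expect_identical(n_agree, 100)
})

test_that("oracle is invariant under relabeling of constituents", {
  set.seed(5)
  pb <- random_partition_problem(4)
  perm <- c(3, 1, 4, 2)
  pb_perm <- partition_problem(pb$total_masses[perm],
                               pb$constituents[perm],
                               pb$temperature, pb$volume)
  w1 <- brute_force_partition(pb)$liquid_fractions
  w2 <- brute_force_partition(pb_perm)$liquid_fractions
  expect_equal(unname(w2), unname(w1[perm]), tolerance = 1e-9)
})

test_that("physical limits: nonvolatile mass stays liquid, high dilution evaporates everything", {
  heavy <- synthetic_constituent("heavy", psat_298 = 1e-10,
                                 molar_mass = 92)
  light <- synthetic_constituent("light", psat_298 = 50, molar_mass = 76)
  pb <- partition_problem(c(1000, 1000), list(heavy, light), 298.15, 1)
  w <- solve_partition(pb)$liquid_fractions
  expect_gt(w[["heavy"]], 1 - 1e-6)          # P_sat -> 0  =>  w -> 1
  # same masses in a vast room: everything evaporates
  pb_big <- partition_problem(c(1000, 1000), list(heavy, light), 298.15,
                              1e12)
  expect_equal(unname(solve_partition(pb_big)$liquid_fractions), c(0, 0))
  # w decreases monotonically towards 0 as the room grows
  vols <- 10^seq(-2, 4, by = 1)
  w_light <- vapply(vols, function(v) {
    solve_partition(partition_problem(c(1000, 1000), list(heavy, light),
                                      298.15, v))$liquid_fractions[["light"]]
  }, 0)
  expect_true(all(diff(w_light) <= 1e-12))
})

test_that("increasing a constituent's mass never decreases its liquid fraction", {
  set.seed(9)
  pb <- random_partition_problem(3)
  masses <- pb$total_masses
  scale <- seq(0.5, 8, length.out = 8)
  w1 <- vapply(scale, function(s) {
    m <- masses; m[1] <- m[1] * s
    solve_partition(partition_problem(m, pb$constituents, pb$temperature,
                                      pb$volume))$liquid_fractions[[1]]
  }, 0)
  expect_true(all(diff(w1) >= -1e-9))
})

test_that("degenerate inputs are handled explicitly", {
  consts <- default_constituents()
  pb0 <- partition_problem(rep(0, 4), consts, 296.15, 1)
  r0 <- solve_partition(pb0)
  expect_true(r0$converged)
  expect_equal(unname(r0$liquid_fractions), rep(0, 4))
  # one zero-mass constituent among active ones
  pb1 <- partition_problem(c(0, 5e4, 1e6, 3e3), consts, 296.15, 0.1)
  r1 <- solve_partition(pb1)
  expect_identical(r1$liquid_fractions[[1]], 0)
  expect_true(r1$converged)
  expect_error(partition_problem(c(-1, 1), consts[1:2], 296.15, 1),
               "non-negative")
  expect_error(partition_residual(c(2, 0, 0, 0), pb1), "0, 1")
})

test_that("warm starts from a previous solution converge to the same root", {
  set.seed(13)
  pb <- random_partition_problem(4)
  cold <- solve_partition(pb)
  warm <- solve_partition(pb, w_init = pmin(1, cold$liquid_fractions + 0.1))
  expect_equal(warm$liquid_fractions, cold$liquid_fractions,
               tolerance = 1e-8)
})
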