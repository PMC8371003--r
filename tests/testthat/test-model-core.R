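test_that("parameter validation rejects out-of-range and unknown values", {
  expect_error(reef_params(delta_k = 5), "beta0")
  expect_error(reef_params(beta0 = 1), "delta_k")
  expect_error(reef_params(beta0 = 1, delta_k = 5, alpha = 1.5), "alpha")
  expect_error(reef_params(beta0 = 1, delta_k = 5, gamma = -0.1), "gamma")
  expect_error(reef_params(beta0 = 1, delta_k = 5, V = -1), "'V'")
  expect_error(reef_params(beta0 = 1, delta_k = 5, r = 0), "'r'")
  expect_error(reef_params(beta0 = 1, delta_k = 5, epsilon = 1.5), "epsilon")
  expect_error(reef_params(beta0 = 1, delta_k = 5,
                           attraction_form = "nope"), "attraction_form")
  p <- reef_params(beta0 = 1, delta_k = 5)
  expect_error(update_params(p, bogus = 1), "bogus")
  expect_error(validate_reef_params(c(unclass(p), list(extra = 1))), "extra")
})

test_that("update_params sets both catchabilities through q and survives
           partial-match-prone names", {
  p <- reef_params(beta0 = 1, delta_k = 5)
  p2 <- update_params(p, q = 0.5)
  expect_equal(p2$q1, 0.5)
  expect_equal(p2$q2, 0.5)
  # 'p' (price) and 'c' (cost) must reach the parameter list, not collide
  # with the function's own formals
  p3 <- update_params(p, p = 1.5, c = 2)
  expect_equal(p3$p, 1.5)
  expect_equal(p3$c, 2)
})

test_that("attraction vanishes without a reef and saturates with volume", {
  for (form in c("saturating", "absolute", "linear")) {
    p <- reef_params(beta0 = 1, delta_k = 5, attraction_form = form)
    expect_identical(attraction(0, p), 0)
  }
  p <- reef_params(beta0 = 1, delta_k = 5)
  # beta0 * (a / ((1 - alpha) K)) * (1 - exp(-sigma V)) at V = 120
  expect_equal(attraction(120, p), 0.025 * (1 - exp(-12)))
  expect_equal(signif(attraction(120, p), 3), 0.0250)
  # saturation limit approached from below
  limit <- p$beta0 * p$a / ((1 - p$alpha) * p$K)
  vals <- attraction(c(10, 50, 120, 250), p)
  expect_true(all(diff(vals) > 0))
  expect_true(all(vals < limit))
  expect_equal(attraction(5000, p), limit, tolerance = 1e-10)
  # the other registered closed forms
  pa <- update_params(p, attraction_form = "absolute")
  expect_equal(attraction(120, pa), 1 - exp(-12))
  pl <- update_params(p, attraction_form = "linear", beta0 = 0.1)
  expect_equal(attraction(120, pl), 0.1 * 0.1 * 120)
  expect_error(attraction(-5, p), "non-negative")
})

test_that("custom attraction forms can be registered and selected", {
  register_attraction("test_bump", function(V, params) {
    params$beta0 * params$sigma * V * exp(-params$sigma * V)
  })
  expect_true("test_bump" %in% attraction_forms())
  p <- reef_params(beta0 = 2, delta_k = 5, attraction_form = "test_bump")
  expect_equal(attraction(10, p), 2 * 0.1 * 10 * exp(-1))
})

test_that("zone capacities split the area and add reef production", {
  p0 <- reef_params(beta0 = 1, delta_k = 5, V = 0)
  expect_equal(zone_capacities(p0), list(K1 = 20, K2 = 80))
  p1 <- update_params(p0, V = 120)
  expect_equal(zone_capacities(p1), list(K1 = 620, K2 = 80))
  p2 <- update_params(p0, V = 120, delta_k = 0.1)
  expect_equal(zone_capacities(p2), list(K1 = 32, K2 = 80))
})

test_that("nu1_star matches the fast-subsystem steady state", {
  # no reef: ideal free distribution puts fish in proportion to capacity
  p0 <- reef_params(beta0 = 1, delta_k = 5, V = 0)
  expect_equal(nu1_star(p0), 0.2)
  # reef production without attraction: still the IFD limit K1/(K1+K2)
  p1 <- reef_params(beta0 = 0, delta_k = 5, V = 120)
  expect_equal(nu1_star(p1), 620 / 700, tolerance = 1e-12)
  expect_equal(nu1_star(p1), nu1_by_integration(p1), tolerance = 1e-8)
  # production and attraction together
  p2 <- reef_params(beta0 = 1, delta_k = 5, V = 120)
  expect_equal(signif(nu1_star(p2), 4), 0.9394)
  expect_equal(nu1_star(p2), nu1_by_integration(p2), tolerance = 1e-8)
})

test_that("nu1_star reduces to the IFD share whenever attraction is absent", {
  set.seed(101)
  for (i in 1:50) {
    p <- random_params(beta0 = 0)
    caps <- zone_capacities(p)
    expect_equal(nu1_star(p), caps$K1 / (caps$K1 + caps$K2),
                 tolerance = 1e-12)
  }
})

test_that("full system derivatives match hand arithmetic", {
  # extinction is an equilibrium
  p <- reef_params(beta0 = 1, delta_k = 5, V = 0, gamma = 0.2)
  expect_equal(unname(full_rhs(c(0, 0, 0, 0), p)), rep(0, 4))
  # hand-evaluated at n1 = n2 = 10, no effort, V = 0, epsilon = 0.1:
  # dn1 = (2/80)*10 - (2/20)*10 + 0.1*0.5*10*(1 - 10/20) = -0.5
  # dn2 = (2/20)*10 - (2/80)*10 + 0.1*0.5*10*(1 - 10/80) = +1.1875
  d <- full_rhs(c(10, 10, 0, 0), p)
  expect_equal(d[["n1"]], -0.5)
  expect_equal(d[["n2"]], 1.1875)
  expect_equal(d[["E1"]], 0)
  expect_equal(d[["E2"]], 0)
  expect_error(full_rhs(c(-1, 0, 0, 0), p), "non-negative")
})

test_that("states on the fast balance are equilibria of the movement part", {
  # with epsilon = 0 (pure movement) the balanced state is a fixed point
  set.seed(202)
  for (i in 1:25) {
    p <- random_params(epsilon = 0)
    caps <- zone_capacities(p)
    nu <- nu1_star(p)
    n_tot <- runif(1, 1, 100)
    E_tot <- runif(1, 0, 5)
    st <- c(nu * n_tot, (1 - nu) * n_tot,
            p$gamma * E_tot, (1 - p$gamma) * E_tot)
    expect_equal(unname(full_rhs(st, p)), rep(0, 4), tolerance = 1e-12)
  }
})

test_that("reduced system derivatives vanish at the closed-form equilibrium", {
  set.seed(303)
  for (i in 1:25) {
    p <- random_params()
    eq <- interior_equilibrium(p)
    d <- reduced_rhs(c(eq$n_star, eq$E_star), p)
    expect_equal(unname(d), c(0, 0), tolerance = 1e-12)
  }
})

test_that("reduced system boundary behavior: unfished capacity and effort
           decay without fish", {
  p <- reef_params(beta0 = 1, delta_k = 5, V = 120, gamma = 0.1)
  d <- reduced_rhs(c(k_eff(p), 0), p)
  expect_equal(d[["n"]], 0, tolerance = 1e-10)
  d0 <- reduced_rhs(c(0, 3), p)
  expect_equal(d0[["n"]], 0)
  expect_equal(d0[["E"]], -p$c * 3)
  expect_error(reduced_rhs(c(-1, 1), p), "non-negative")
})

test_that("without a reef the reduced system is two-patch Gordon-Schaefer", {
  set.seed(404)
  for (i in 1:25) {
    p <- random_params(V = 0, beta0 = 0)
    st <- c(runif(1, 0, 2 * p$K), runif(1, 0, 5))
    expect_equal(unname(reduced_rhs(st, p)),
                 gordon_schaefer_rhs(st, r = p$r, K = p$K, q = p$q1,
                                     p_price = p$p, cost = p$c,
                                     alpha = p$alpha, gamma = p$gamma),
                 tolerance = 1e-12)
  }
})

test_that("derivatives preserve non-negativity at the axes", {
  set.seed(505)
  for (i in 1:25) {
    p <- random_params()
    # each reduced component with value 0 has derivative >= 0
    dn <- reduced_rhs(c(0, runif(1, 0, 5)), p)
    expect_gte(dn[["n"]], 0)
    dE <- reduced_rhs(c(runif(1, 0, p$K), 0), p)
    expect_gte(dE[["E"]], 0)
    # full system: zero a single component at a time
    base <- c(runif(1, 1, 50), runif(1, 1, 50), runif(1, 0, 3),
              runif(1, 0, 3))
    for (j in 1:4) {
      st <- base
      st[j] <- 0
      expect_gte(full_rhs(st, p)[[j]], 0)
    }
  }
})

test_that("zone catches on the fast manifold sum to the aggregate catch", {
  set.seed(606)
  for (i in 1:25) {
    p <- random_params()
    nu <- nu1_star(p)
    n <- runif(1, 1, 100)
    E <- runif(1, 0, 5)
    zone_catch <- p$q1 * (nu * n) * (p$gamma * E) +
      p$q2 * ((1 - nu) * n) * ((1 - p$gamma) * E)
    W <- p$gamma * nu + (1 - p$gamma) * (1 - nu)
    expect_equal(zone_catch, p$q1 * W * n * E, tolerance = 1e-10)
  }
})

test_that("the reduced model refuses distinct zone catchabilities", {
  p <- reef_params(beta0 = 1, delta_k = 5, q1 = 1, q2 = 0.5)
  expect_error(reduced_rhs(c(10, 1), p), "q1 == q2")
  expect_error(interior_equilibrium(p), "q1 == q2")
})
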