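# shared fixtures: random valid parameter draws and independent oracles

# default figure scenario: production delta_k = 5, attraction beta0 = 1,
# overridable through ...
fig_params <- function(...) {
  args <- utils::modifyList(list(beta0 = 1, delta_k = 5), list(...))
  do.call(reef_params, args)
}

# random valid parameter draw; overrides applied after drawing
random_params <- function(...) {
  p <- reef_params(r = runif(1, 0.1, 1),
                   K = runif(1, 50, 200),
                   a = runif(1, 0.5, 4),
                   c = runif(1, 0.5, 2),
                   p = runif(1, 0.5, 2),
                   q = runif(1, 0.5, 2),
                   alpha = runif(1, 0.05, 0.95),
                   V = runif(1, 0, 600),
                   delta_k = runif(1, 0, 5),
                   beta0 = runif(1, 0, 1),
                   sigma = runif(1, 0.01, 0.2),
                   gamma = runif(1, 0, 1),
                   attraction_form = sample(c("saturating", "absolute",
                                              "linear"), 1))
  overrides <- list(...)
  if (length(overrides)) p <- do.call(update_params, c(list(p), overrides))
  p
}

# oracle: steady-state zone-1 biomass share from direct integration of the
# two-compartment fish-movement subsystem (independent of nu1_star)
nu1_by_integration <- function(params) {
  caps <- zone_capacities(params)
  in1 <- params$a / caps$K2 + attraction(params$V, params)
  out1 <- params$a / caps$K1
  move <- function(t, y, parms) {
    list(c(in1 * y[2] - out1 * y[1], out1 * y[1] - in1 * y[2]))
  }
  out <- deSolve::lsoda(y = c(0.5, 0.5), times = c(0, 5000), func = move,
                        parms = NULL, rtol = 1e-12, atol = 1e-14)
  final <- out[nrow(out), -1]
  unname(final[1] / sum(final))
}

# oracle: hand-coded aggregated two-patch open-access (Gordon-Schaefer)
# system without any reef terms; valid reference for V = 0, beta = 0
gordon_schaefer_rhs <- function(state, r, K, q, p_price, cost, alpha, gamma) {
  K1 <- alpha * K
  K2 <- (1 - alpha) * K
  nu <- K1 / (K1 + K2)        # ideal free distribution
  n <- state[1]
  E <- state[2]
  weight <- gamma * nu + (1 - gamma) * (1 - nu)
  c(r * n * (1 - nu^2 * n / K1 - (1 - nu)^2 * n / K2) - q * weight * n * E,
    (p_price * q * weight * n - cost) * E)
}

# dense-grid argmax of equilibrium total catch over volume
dense_argmax_volume <- function(params, V_lim = c(0, 600), n = 2001) {
  grid <- seq(V_lim[1], V_lim[2], length.out = n)
  vals <- vapply(grid, function(v) {
    interior_equilibrium(update_params(params, V = v))$catch_total
  }, numeric(1))
  list(V = grid[which.max(vals)], catch = max(vals), values = vals,
       grid = grid)
}
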