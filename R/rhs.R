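#' Right-hand side of the full two-patch fast-slow system
#'
#' Time derivatives, in fast time, of the zonal state
#' \code{(n1, n2, E1, E2)}: fish biomass and fishing effort in the no-take
#' zone (1) and the fishing area (2). Fast processes are fish movement --
#' immigration into the no-take zone at rate \code{a / K2 + beta(V)},
#' emigration at \code{a / K1} -- and effort redistribution at rates
#' \code{m1 = gamma * mu} (into zone 1) and \code{m2 = (1 - gamma) * mu}
#' (out of zone 1), so that at the fast equilibrium a fraction \code{gamma}
#' of the effort sits on the reef. Slow processes (logistic growth with the
#' zone's own capacity, harvest \code{q_i n_i E_i}, and profit-driven effort
#' growth \code{p q_i n_i E_i - c E_i}) are scaled by \code{epsilon}.
#'
#' @param state numeric vector \code{c(n1, n2, E1, E2)} (names optional),
#'   all components non-negative.
#' @param params a \code{reef_params} object.
#' @return named numeric vector of derivatives \code{(n1, n2, E1, E2)} with
#'   respect to fast time.
#' @seealso \code{\link{reduced_rhs}}, \code{\link{integrate_reef}}
#' @examples
#' p <- reef_params(beta0 = 1, delta_k = 5, V = 0, gamma = 0.2)
#' full_rhs(c(10, 10, 0.1, 0.4), p)
#' @export
full_rhs <- function(state, params) {
  state <- check_state(state, c("n1", "n2", "E1", "E2"))
  caps <- zone_capacities_raw(params)
  beta <- attraction(params$V, params)
  in1 <- params$a / caps$K2 + beta   # movement rate 2 -> 1
  out1 <- params$a / caps$K1         # movement rate 1 -> 2
  m1 <- params$gamma * params$mu
  m2 <- (1 - params$gamma) * params$mu
  n1 <- state[["n1"]]; n2 <- state[["n2"]]
  E1 <- state[["E1"]]; E2 <- state[["E2"]]
  eps <- params$epsilon
  c(n1 = in1 * n2 - out1 * n1 +
      eps * (params$r * n1 * (1 - n1 / caps$K1) - params$q1 * n1 * E1),
    n2 = out1 * n1 - in1 * n2 +
      eps * (params$r * n2 * (1 - n2 / caps$K2) - params$q2 * n2 * E2),
    E1 = m1 * E2 - m2 * E1 +
      eps * (params$p * params$q1 * n1 * E1 - params$c * E1),
    E2 = m2 * E1 - m1 * E2 +
      eps * (params$p * params$q2 * n2 * E2 - params$c * E2))
}

#' Right-hand side of the reduced (aggregated) system
#'
#' Slow-time dynamics of total fish biomass \code{n} and total fishing
#' effort \code{E} on the fast-equilibrium manifold, where a fraction
#' \code{nu1* = nu1_star(params)} of the biomass and a fraction \code{gamma}
#' of the effort sit in the no-take zone:
#' \deqn{dn/dt = r n (1 - \nu_1^{*2} n / K_1 - (1-\nu_1^*)^2 n / K_2)
#'   - q \gamma \nu_1^* n E - q (1-\gamma)(1-\nu_1^*) n E}
#' \deqn{dE/dt = (p q \gamma \nu_1^* n + p q (1-\gamma)(1-\nu_1^*) n - c) E}
#'
#' A single catchability \code{q = q1 = q2} is required.
#'
#' @param state numeric vector \code{c(n, E)}, non-negative.
#' @param params a \code{reef_params} object with \code{q1 == q2}.
#' @return named numeric vector of derivatives \code{(n, E)} with respect to
#'   slow time.
#' @seealso \code{\link{full_rhs}}, \code{\link{interior_equilibrium}}
#' @examples
#' p <- reef_params(beta0 = 1, delta_k = 5, V = 120, gamma = 0.05)
#' reduced_rhs(c(50, 0.5), p)
#' @export
reduced_rhs <- function(state, params) {
  state <- check_state(state, c("n", "E"))
  q <- single_q(params)
  caps <- zone_capacities_raw(params)
  nu1 <- nu1_star(params)
  n <- state[["n"]]; E <- state[["E"]]
  harvest_weight <- params$gamma * nu1 + (1 - params$gamma) * (1 - nu1)
  c(n = params$r * n * (1 - nu1^2 * n / caps$K1 - (1 - nu1)^2 * n / caps$K2) -
      q * harvest_weight * n * E,
    E = (params$p * q * harvest_weight * n - params$c) * E)
}

# internal: coerce and check a non-negative state vector
check_state <- function(state, fields) {
  state <- unlist(state, use.names = FALSE)
  if (length(state) != length(fields) || !is.numeric(state)) {
    stop("state must be a numeric vector of length ", length(fields),
         " (", paste(fields, collapse = ", "), ")", call. = FALSE)
  }
  if (any(!is.finite(state))) {
    stop("state components must be finite", call. = FALSE)
  }
  if (any(state < 0)) {
    stop("state components must be non-negative; got (",
         paste(signif(state, 6), collapse = ", "), ")", call. = FALSE)
  }
  names(state) <- fields
  state
}

# internal: the reduced model uses one catchability
single_q <- function(params) {
  if (params$q1 != params$q2) {
    stop("the reduced model requires q1 == q2; got q1 = ", params$q1,
         ", q2 = ", params$q2, call. = FALSE)
  }
  params$q1
}
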