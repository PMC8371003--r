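#' Integrate the full or reduced system
#'
#' Adaptive-step integration (via \code{deSolve::lsodar}) of either the
#' reduced aggregate system in slow time or the full two-patch system in
#' fast time. Integration stops early once the relative right-hand-side
#' norm \code{max(|dx_i| / (|x_i| + 1))} drops below \code{conv_tol},
#' i.e. once the trajectory has effectively reached an equilibrium
#' (including the boundary equilibrium where effort has collapsed).
#' Components are kept non-negative: values driven below zero by solver
#' error are clipped to zero (and counted) when their magnitude is below
#' solver tolerance.
#'
#' @param params a \code{reef_params} object.
#' @param model \code{"reduced"} (state \code{n}, \code{E}; slow time) or
#'   \code{"full"} (state \code{n1}, \code{n2}, \code{E1}, \code{E2};
#'   fast time).
#' @param init non-negative initial state, length 2 (reduced) or 4 (full).
#' @param t_end integration horizon, in the model's own time unit. The
#'   default 2000 slow-time units leaves room for the damped oscillations
#'   typical of open-access dynamics; for the full model pass a fast-time
#'   horizon (e.g. \code{t_end / epsilon}).
#' @param n_out number of output time points.
#' @param conv_tol relative RHS norm below which the run is declared
#'   converged. The norm is \code{max |dx_i| / (|x_i| + 1e-8)} over the
#'   components that have not collapsed to the boundary (below 1e-10);
#'   a collapsed effort component is treated as sitting at the boundary
#'   equilibrium. Scaling by the component's own magnitude prevents
#'   spurious convergence during the deep near-origin excursions of the
#'   damped open-access oscillations, where the state is tiny but the
#'   dynamics are still fast relative to it.
#' @param rtol,atol solver tolerances passed to \code{deSolve}.
#' @return an object of class \code{"reef_trajectory"}: list with
#'   \code{times}, \code{states} (matrix, one named column per component),
#'   \code{converged}, \code{final_state}, \code{model}, \code{clipped}
#'   (count of negative values zeroed).
#' @examples
#' p <- reef_params(beta0 = 1, delta_k = 5, V = 0, gamma = 0.2)
#' tr <- integrate_reef(p, "reduced", init = c(50, 0.5))
#' tr$final_state
#' @export
integrate_reef <- function(params, model = c("reduced", "full"), init,
                           t_end = 2000, n_out = 400, conv_tol = 1e-8,
                           rtol = 1e-10, atol = 1e-12) {
  model <- match.arg(model)
  params <- validate_reef_params(params)
  fields <- if (model == "reduced") c("n", "E") else c("n1", "n2", "E1", "E2")
  init <- check_state(init, fields)
  if (!is.numeric(t_end) || length(t_end) != 1L || t_end <= 0) {
    stop("'t_end' must be a positive scalar", call. = FALSE)
  }
  # constants hoisted out of the solver loop; algebra identical to
  # reduced_rhs() / full_rhs() (asserted in the test suite)
  rhs_fn <- if (model == "reduced") {
    q <- single_q(params)
    caps <- zone_capacities_raw(params)
    nu1 <- nu1_star(params)
    W <- params$gamma * nu1 + (1 - params$gamma) * (1 - nu1)
    L <- nu1^2 / caps$K1 + (1 - nu1)^2 / caps$K2
    r <- params$r; p <- params$p; cc <- params$c
    function(y) {
      n <- y[1]; E <- y[2]
      c(r * n * (1 - L * n) - q * W * n * E, (p * q * W * n - cc) * E)
    }
  } else {
    caps <- zone_capacities_raw(params)
    in1 <- params$a / caps$K2 + attraction(params$V, params)
    out1 <- params$a / caps$K1
    m1 <- params$gamma * params$mu
    m2 <- (1 - params$gamma) * params$mu
    eps <- params$epsilon
    r <- params$r; p <- params$p; cc <- params$c
    q1 <- params$q1; q2 <- params$q2
    K1 <- caps$K1; K2 <- caps$K2
    function(y) {
      n1 <- y[1]; n2 <- y[2]; E1 <- y[3]; E2 <- y[4]
      c(in1 * n2 - out1 * n1 + eps * (r * n1 * (1 - n1 / K1) - q1 * n1 * E1),
        out1 * n1 - in1 * n2 + eps * (r * n2 * (1 - n2 / K2) - q2 * n2 * E2),
        m1 * E2 - m2 * E1 + eps * (p * q1 * n1 * E1 - cc * E1),
        m2 * E1 - m1 * E2 + eps * (p * q2 * n2 * E2 - cc * E2))
    }
  }
  deriv <- function(t, y, parms) {
    list(rhs_fn(pmax(y, 0)))
  }
  rel_norm <- function(y) {
    d <- rhs_fn(y)
    active <- y >= 1e-10
    if (!any(active)) active <- rep(TRUE, length(y))
    max(abs(d[active]) / (abs(y[active]) + 1e-8))
  }
  rootfn <- function(t, y, parms) {
    rel_norm(pmax(y, 0)) - conv_tol
  }
  times <- seq(0, t_end, length.out = max(2L, n_out))
  out <- try(deSolve::lsodar(y = init, times = times, func = deriv,
                             parms = NULL, rootfunc = rootfn,
                             rtol = rtol, atol = atol), silent = TRUE)
  if (inherits(out, "try-error")) {
    stop("integration failed (", model, " model): ",
         attr(out, "condition")$message, call. = FALSE)
  }
  states <- as.matrix(out[, -1, drop = FALSE])
  colnames(states) <- fields
  clipped <- sum(states < 0)
  if (clipped > 0) {
    worst <- min(states)
    if (worst < -sqrt(atol)) {
      warning("integration produced negative components as low as ",
              signif(worst, 3), "; clipped to zero", call. = FALSE)
    }
    states[states < 0] <- 0
  }
  final <- states[nrow(states), ]
  structure(list(times = out[, 1], states = states,
                 converged = rel_norm(final) < conv_tol,
                 final_state = final, model = model, clipped = clipped),
            class = "reef_trajectory")
}

#' @export
print.reef_trajectory <- function(x, ...) {
  cat("Trajectory of the", x$model, "system:", length(x$times),
      "time points over [0, ", signif(max(x$times), 4), "]\n", sep = " ")
  cat("  converged:", x$converged, "\n  final state:\n")
  print(signif(x$final_state, 6))
  invisible(x)
}

#' @export
as.data.frame.reef_trajectory <- function(x, ...) {
  data.frame(t = x$times, x$states)
}

#' Fast-slow consistency of the aggregated model
#'
#' The reduced model is exact in the singular limit \code{epsilon -> 0} of
#' the full two-patch system. For each value of \code{epsilon} this
#' integrates the full system (fast time, horizon \code{t_end / epsilon}),
#' aggregates its long-time state (\code{n = n1 + n2}, \code{E = E1 + E2}),
#' and reports the relative distance to the reduced model's equilibrium.
#' Gaps should shrink (or at least not grow) as \code{epsilon} decreases.
#'
#' @param params a \code{reef_params} object.
#' @param epsilon_list values of the timescale-separation parameter, each in
#'   (0, 1].
#' @param init aggregate initial state \code{c(n, E)}; the full system is
#'   started on the fast manifold (\code{n1 = nu1* n}, \code{E1 = gamma E}).
#'   Default: 1.5 times the reduced equilibrium when the fishery is viable
#'   (a moderate displacement, so the gap measures the aggregation error
#'   rather than extreme transient excursions), else half the aggregate
#'   capacity with a small effort.
#' @param t_end slow-time horizon.
#' @return data.frame with one row per \code{epsilon}: the aggregated final
#'   state (\code{n_agg}, \code{E_agg}), the reduced equilibrium
#'   (\code{n_star}, \code{E_star}) and the relative gap.
#' @examples
#' p <- reef_params(beta0 = 1, delta_k = 5, V = 0, gamma = 0.2)
#' fast_slow_gap(p, c(0.1, 0.05))
#' @export
fast_slow_gap <- function(params, epsilon_list, init = NULL, t_end = 2000) {
  params <- validate_reef_params(params)
  if (any(epsilon_list <= 0 | epsilon_list > 1)) {
    stop("every epsilon must lie in (0, 1]", call. = FALSE)
  }
  eq <- interior_equilibrium(params)
  if (is.null(init)) {
    init <- if (eq$viable) {
      c(1.5 * eq$n_star, 1.5 * eq$E_star)
    } else {
      c(eq$K_eff / 2, 0.1)
    }
  }
  init <- check_state(init, c("n", "E"))
  nu1 <- nu1_star(params)
  rows <- lapply(epsilon_list, function(eps) {
    p_eps <- update_params(params, epsilon = eps)
    z0 <- c(nu1 * init[["n"]], (1 - nu1) * init[["n"]],
            params$gamma * init[["E"]], (1 - params$gamma) * init[["E"]])
    tr <- integrate_reef(p_eps, "full", init = z0, t_end = t_end / eps)
    n_agg <- tr$final_state[["n1"]] + tr$final_state[["n2"]]
    E_agg <- tr$final_state[["E1"]] + tr$final_state[["E2"]]
    scale_E <- max(eq$E_star, 1e-8)
    gap <- max(abs(n_agg - eq$n_star) / eq$n_star,
               abs(E_agg - eq$E_star) / scale_E)
    data.frame(epsilon = eps, n_agg = n_agg, E_agg = E_agg,
               n_star = eq$n_star, E_star = eq$E_star, gap = gap)
  })
  do.call(rbind, rows)
}
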