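# one equilibrium record per parameter combination; failures become NA rows
# (flagged via warning) so sweep grids stay complete
equilibrium_row <- function(params, overrides, scenario) {
  row <- tryCatch({
    p <- do.call(update_params, c(list(params), overrides))
    as.data.frame(interior_equilibrium(p))
  }, error = function(e) {
    warning("equilibrium failed for (",
            paste(names(overrides), unlist(overrides), sep = "=",
                  collapse = ", "), "): ", conditionMessage(e),
            call. = FALSE)
    out <- as.data.frame(as.list(stats::setNames(
      rep(NA_real_, length(.equilibrium_columns) - 1),
      setdiff(.equilibrium_columns, "viable"))))
    out$viable <- NA
    for (nm in intersect(names(overrides), names(out))) {
      out[[nm]] <- overrides[[nm]]
    }
    out
  })
  row$scenario <- scenario
  row
}

sweep_over <- function(params, grid, scenario) {
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    equilibrium_row(params, as.list(grid[i, , drop = FALSE]), scenario)
  })
  do.call(rbind, rows)
}

#' Equilibrium sweep over reef volume
#'
#' Computes the equilibrium record on the full Cartesian product of a reef
#' volume grid and a set of illegal-effort fractions: the catch-vs-volume
#' family of curves, one per illegal-fishing level.
#'
#' @param params baseline \code{reef_params}.
#' @param V_grid reef volumes, m^3. Default 0--600 in 2 m^3 steps.
#' @param gamma_list illegal-effort fractions; the default levels
#'   \code{0, 5, 10, 15, 25, 50, 75\%} are the standard panel.
#' @param scenario label attached to every row.
#' @return data.frame, one equilibrium record per (gamma, V) combination.
#' @examples
#' p <- reef_params(beta0 = 1, delta_k = 5)
#' tab <- sweep_volume(p, V_grid = c(0, 120, 500), gamma_list = c(0, 0.25))
#' @export
sweep_volume <- function(params, V_grid = seq(0, 600, by = 2),
                         gamma_list = c(0, 0.05, 0.10, 0.15, 0.25, 0.50,
                                        0.75),
                         scenario = "volume_sweep") {
  stopifnot(length(V_grid) > 0, length(gamma_list) > 0)
  grid <- expand.grid(V = V_grid, gamma = gamma_list,
                      KEEP.OUT.ATTRS = FALSE)
  grid <- grid[order(grid$gamma, grid$V), , drop = FALSE]
  sweep_over(validate_reef_params(params), grid, scenario)
}

#' Equilibrium sweep over the illegal-fishing fraction
#'
#' Catch decomposition (total, fishing area, reef) across a grid of
#' \code{gamma} at a fixed reef volume: the single-volume panel.
#'
#' @param params baseline \code{reef_params}.
#' @param gamma_grid illegal-effort fractions. Default 0--1 in steps of
#'   0.01, fine enough to resolve percent-level features.
#' @param V reef volume, m^3.
#' @param scenario label attached to every row.
#' @return data.frame of equilibrium records, one per \code{gamma}.
#' @examples
#' p <- reef_params(beta0 = 1, delta_k = 5)
#' tab <- sweep_gamma(p, gamma_grid = seq(0, 0.2, 0.05), V = 120)
#' @export
sweep_gamma <- function(params, gamma_grid = seq(0, 1, by = 0.01),
                        V = params$V, scenario = "gamma_sweep") {
  stopifnot(length(gamma_grid) > 0)
  grid <- expand.grid(V = V, gamma = gamma_grid, KEEP.OUT.ATTRS = FALSE)
  sweep_over(validate_reef_params(params), grid, scenario)
}

#' Attraction-by-production equilibrium grid
#'
#' Full factorial sweep over attraction strength \code{beta0}, production
#' \code{delta_k} and the illegal-effort fraction at a fixed reef volume:
#' the panel matrix separating the reef's attraction and production effects.
#'
#' @param params baseline \code{reef_params}.
#' @param beta0_list attraction strengths.
#' @param delta_k_list production levels (tons per m^3).
#' @param gamma_grid illegal-effort fractions.
#' @param V reef volume, m^3 (default 200).
#' @param scenario label attached to every row.
#' @return data.frame of equilibrium records over beta0 x delta_k x gamma.
#' @examples
#' p <- reef_params(beta0 = 1, delta_k = 5)
#' grid_attraction_production(p, beta0_list = c(0, 1),
#'                            delta_k_list = c(0.1, 5),
#'                            gamma_grid = c(0, 0.1))
#' @export
grid_attraction_production <- function(params,
                                       beta0_list = c(0, 0.1, 1),
                                       delta_k_list = c(0.1, 1, 5),
                                       gamma_grid = seq(0, 1, by = 0.01),
                                       V = 200,
                                       scenario = "attraction_production") {
  stopifnot(length(beta0_list) > 0, length(delta_k_list) > 0,
            length(gamma_grid) > 0)
  grid <- expand.grid(V = V, gamma = gamma_grid, beta0 = beta0_list,
                      delta_k = delta_k_list, KEEP.OUT.ATTRS = FALSE)
  grid <- grid[order(grid$delta_k, grid$beta0, grid$gamma), , drop = FALSE]
  sweep_over(validate_reef_params(params), grid, scenario)
}

#' Reef volume maximizing equilibrium catch
#'
#' Scans equilibrium total catch over a volume bracket at a fixed
#' illegal-effort fraction. If the catch is monotone across the bracket a
#' verdict is returned instead of an endpoint pretending to be an interior
#' optimum; otherwise the bracketing grid cell around the best point is
#' refined by golden-section search. Plateau ties break to the smallest
#' volume.
#'
#' @param params baseline \code{reef_params}.
#' @param gamma illegal-effort fraction.
#' @param V_bracket length-2 volume range, m^3.
#' @param n_grid coarse-scan resolution.
#' @param tol absolute volume tolerance of the refinement.
#' @return list with \code{verdict} (\code{"interior"},
#'   \code{"monotone increasing"}, \code{"monotone decreasing"},
#'   \code{"boundary"} or \code{"flat"}), \code{V_opt} and
#'   \code{catch_opt} (NA unless a maximum is identified).
#' @examples
#' p <- reef_params(beta0 = 1, delta_k = 5)
#' find_optimal_volume(p, gamma = 0, V_bracket = c(0, 600))
#' @export
find_optimal_volume <- function(params, gamma = params$gamma,
                                V_bracket = c(0, 600), n_grid = 121,
                                tol = 1e-4) {
  stopifnot(length(V_bracket) == 2, V_bracket[1] >= 0,
            V_bracket[2] > V_bracket[1], n_grid >= 5)
  params <- update_params(params, gamma = gamma)
  f <- function(V) {
    interior_equilibrium(update_params(params, V = V))$catch_total
  }
  grid <- seq(V_bracket[1], V_bracket[2], length.out = n_grid)
  vals <- vapply(grid, f, numeric(1))
  eps <- 1e-12 * max(abs(vals), 1)
  d <- diff(vals)
  if (all(abs(d) <= eps)) {
    return(list(verdict = "flat", V_opt = grid[1], catch_opt = vals[1]))
  }
  if (all(d >= -eps)) {
    return(list(verdict = "monotone increasing", V_opt = NA_real_,
                catch_opt = NA_real_))
  }
  if (all(d <= eps)) {
    return(list(verdict = "monotone decreasing", V_opt = NA_real_,
                catch_opt = NA_real_))
  }
  i <- which.max(vals)   # ties break to the smallest volume
  if (i == 1L || i == n_grid) {
    return(list(verdict = "boundary", V_opt = grid[i], catch_opt = vals[i]))
  }
  opt <- stats::optimize(f, interval = c(grid[i - 1L], grid[i + 1L]),
                         maximum = TRUE, tol = tol)
  list(verdict = "interior", V_opt = opt$maximum,
       catch_opt = opt$objective)
}

#' Viability boundary along a parameter axis
#'
#' The fishery is economically viable when the zero-profit stock
#' \code{n* = c / (p q Q)} lies below the aggregate capacity \code{K_eff}.
#' This locates, by bisection on the margin \code{K_eff - n*}, the value of
#' \code{V} or \code{gamma} at which viability flips within a bracket.
#'
#' @param params baseline \code{reef_params}.
#' @param axis \code{"V"} or \code{"gamma"}.
#' @param bracket length-2 search range on the chosen axis.
#' @param tol_rel relative tolerance on the boundary location.
#' @return list with \code{transition} (logical), \code{value} (the
#'   boundary, or NA), and \code{viable_lower}, \code{viable_upper} (the
#'   flags at the bracket ends).
#' @examples
#' p <- reef_params(beta0 = 1, delta_k = 5)
#' find_viability_threshold(p, axis = "V", bracket = c(0, 600))
#' @export
find_viability_threshold <- function(params, axis = c("V", "gamma"),
                                     bracket, tol_rel = 1e-6) {
  axis <- match.arg(axis)
  stopifnot(length(bracket) == 2, bracket[2] > bracket[1])
  params <- validate_reef_params(params)
  margin <- function(x) {
    overrides <- stats::setNames(list(x), axis)
    p <- do.call(update_params, c(list(params), overrides))
    q <- single_q(p)
    eq_nu <- nu1_star(p)
    Q <- p$gamma * eq_nu + (1 - p$gamma) * (1 - eq_nu)
    k_eff(p) - p$c / (p$p * q * Q)
  }
  lo <- margin(bracket[1]); hi <- margin(bracket[2])
  out <- list(transition = FALSE, value = NA_real_,
              viable_lower = lo > 0, viable_upper = hi > 0)
  if (sign(lo) == sign(hi)) return(out)
  root <- stats::uniroot(margin, interval = bracket,
                         tol = tol_rel * diff(bracket))
  out$transition <- TRUE
  out$value <- root$root
  out
}

#' One-at-a-time sensitivity sweeps
#'
#' Varies the demographic and economic parameters (\code{r}, \code{K},
#' \code{c}, \code{p}, \code{q}, \code{a}) one at a time from a base
#' scenario and records the equilibrium for each value.
#'
#' @param base baseline \code{reef_params}.
#' @param spec named list mapping parameter names (subset of r, K, c, p, q,
#'   a) to vectors of values.
#' @return data.frame of equilibrium records with extra columns
#'   \code{parameter} and \code{value}; empty spec gives an empty table.
#' @examples
#' p <- reef_params(beta0 = 1, delta_k = 5, V = 200, gamma = 0.05)
#' sensitivity_suite(p, list(c = c(1, 1.5), p = c(1, 1.5)))
#' @export
sensitivity_suite <- function(base, spec) {
  base <- validate_reef_params(base)
  allowed <- c("r", "K", "c", "p", "q", "a")
  empty <- {
    tmpl <- as.data.frame(interior_equilibrium(base))[0, , drop = FALSE]
    cbind(data.frame(parameter = character(0), value = numeric(0)), tmpl,
          scenario = character(0))
  }
  if (length(spec) == 0L) return(empty)
  bad <- setdiff(names(spec), allowed)
  if (length(bad)) {
    stop("sensitivity sweeps are restricted to ",
         paste(allowed, collapse = ", "), "; got: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  rows <- lapply(names(spec), function(nm) {
    do.call(rbind, lapply(spec[[nm]], function(val) {
      row <- equilibrium_row(base, stats::setNames(list(val), nm),
                             scenario = paste0("sensitivity:", nm))
      cbind(data.frame(parameter = nm, value = val), row)
    }))
  })
  do.call(rbind, rows)
}

#' Width of the fishing annulus around a circular no-take zone
#'
#' For a circular no-take zone of the given radius occupying a fraction
#' \code{alpha} of a larger concentric disc (no-take zone plus fishing
#' area), the fishing area is an annulus of width
#' \code{radius * (1 / sqrt(alpha) - 1)}.
#'
#' @param ntz_radius no-take-zone radius, metres (> 0).
#' @param alpha no-take fraction of the total disc, in (0, 1].
#' @return annulus width, metres.
#' @examples
#' annulus_width(500, 0.2)   # ~618 m
#' @export
annulus_width <- function(ntz_radius, alpha) {
  if (!is.numeric(ntz_radius) || any(ntz_radius <= 0)) {
    stop("'ntz_radius' must be strictly positive", call. = FALSE)
  }
  if (!is.numeric(alpha) || any(alpha <= 0) || any(alpha > 1)) {
    stop("'alpha' must lie in (0, 1]", call. = FALSE)
  }
  ntz_radius * (1 / sqrt(alpha) - 1)
}

#' Named scenario presets
#'
#' Bundles of parameters and grids for the standard panels: the
#' volume-by-illegal-effort family (\code{"fig2a"}), the single-volume
#' catch decompositions at 120, 200 and 500 m^3 (\code{"fig2b"},
#' \code{"fig2c"}, \code{"fig2d"}; production \code{delta_k = 5} and
#' attraction \code{beta0 = 1} throughout), and the attraction-by-production
#' grid at 200 m^3 (\code{"fig3"}).
#'
#' @param name preset identifier.
#' @return list with elements \code{name}, \code{params}, \code{sweep}
#'   (which sweep function the preset feeds) and the matching grids.
#' @examples
#' reef_preset("fig2b")$params$V
#' @export
reef_preset <- function(name) {
  presets <- list(
    fig2a = function() list(
      name = "fig2a", sweep = "volume",
      params = reef_params(beta0 = 1, delta_k = 5),
      V_grid = seq(0, 600, by = 2),
      gamma_list = c(0, 0.05, 0.10, 0.15, 0.25, 0.50, 0.75)),
    fig2b = function() list(
      name = "fig2b", sweep = "gamma",
      params = reef_params(beta0 = 1, delta_k = 5, V = 120),
      gamma_grid = seq(0, 1, by = 0.01)),
    fig2c = function() list(
      name = "fig2c", sweep = "gamma",
      params = reef_params(beta0 = 1, delta_k = 5, V = 200),
      gamma_grid = seq(0, 1, by = 0.01)),
    fig2d = function() list(
      name = "fig2d", sweep = "gamma",
      params = reef_params(beta0 = 1, delta_k = 5, V = 500),
      gamma_grid = seq(0, 1, by = 0.01)),
    fig3 = function() list(
      name = "fig3", sweep = "grid",
      params = reef_params(beta0 = 1, delta_k = 5, V = 200),
      beta0_list = c(0, 0.1, 1),
      delta_k_list = c(0.1, 1, 5),
      gamma_grid = seq(0, 1, by = 0.01))
  )
  if (!name %in% names(presets)) {
    stop("unknown preset '", name, "'; available: ",
         paste(names(presets), collapse = ", "), call. = FALSE)
  }
  presets[[name]]()
}

#' Run a preset scenario
#'
#' Executes the sweep a preset describes and returns its table.
#'
#' @param name preset identifier; see \code{\link{reef_preset}}.
#' @return data.frame of equilibrium records.
#' @examples
#' tab <- run_preset("fig2b")
#' @export
run_preset <- function(name) {
  ps <- reef_preset(name)
  switch(ps$sweep,
         volume = sweep_volume(ps$params, V_grid = ps$V_grid,
                               gamma_list = ps$gamma_list,
                               scenario = ps$name),
         gamma = sweep_gamma(ps$params, gamma_grid = ps$gamma_grid,
                             V = ps$params$V, scenario = ps$name),
         grid = grid_attraction_production(ps$params,
                                           beta0_list = ps$beta0_list,
                                           delta_k_list = ps$delta_k_list,
                                           gamma_grid = ps$gamma_grid,
                                           V = ps$params$V,
                                           scenario = ps$name))
}
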