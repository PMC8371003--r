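#' Artificial-reef fishery model
#'
#' Central constructor: binds a validated parameter set to its derived
#' quantities (zone capacities, attraction effect, fast-equilibrium fish
#' split) and the closed-form equilibrium of the reduced system. The
#' returned object supports \code{print}, \code{summary}, \code{coef},
#' \code{predict} (equilibria under parameter changes), \code{simulate}
#' (trajectories of either system) and \code{plot}.
#'
#' @param params a \code{reef_params} object; alternatively pass the
#'   parameter values directly through \code{...}.
#' @param ... arguments forwarded to \code{\link{reef_params}} when
#'   \code{params} is missing.
#' @return an object of class \code{"reef_model"}.
#' @examples
#' m <- reef_model(beta0 = 1, delta_k = 5, V = 120, gamma = 0.05)
#' summary(m)
#' coef(m)
#' @export
reef_model <- function(params, ...) {
  if (missing(params)) {
    params <- reef_params(...)
  } else {
    params <- validate_reef_params(params)
  }
  caps <- zone_capacities_raw(params)
  structure(list(params = params,
                 capacities = caps,
                 beta = attraction(params$V, params),
                 nu1_star = nu1_star(params),
                 equilibrium = interior_equilibrium(params)),
            class = "reef_model")
}

#' @export
print.reef_model <- function(x, digits = 4, ...) {
  p <- x$params
  cat("Artificial-reef fishery model\n")
  cat("  reef volume V =", p$V, "m^3,  illegal effort fraction gamma =",
      p$gamma, "\n")
  cat("  attraction:", p$attraction_form,
      "(beta0 =", p$beta0, ", sigma =", p$sigma,
      "), production delta_k =", p$delta_k, "\n")
  cat("  zone capacities: K1 =", signif(x$capacities$K1, digits),
      " K2 =", signif(x$capacities$K2, digits),
      " nu1* =", signif(x$nu1_star, digits), "\n")
  print(x$equilibrium, digits = digits)
  invisible(x)
}

#' @export
summary.reef_model <- function(object, ...) {
  eq <- object$equilibrium
  out <- list(params = object$params,
              capacities = object$capacities,
              beta = object$beta,
              nu1_star = object$nu1_star,
              equilibrium = eq,
              crossing_gamma = tryCatch(catch_crossing_gamma(object$params),
                                        error = function(e) NA_real_))
  class(out) <- "summary.reef_model"
  out
}

#' @export
print.summary.reef_model <- function(x, digits = 4, ...) {
  p <- x$params
  cat("Artificial-reef fishery model -- equilibrium summary\n\n")
  cat("Parameters:\n")
  num <- unlist(p[setdiff(names(p), "attraction_form")])
  print(signif(num, digits))
  cat("attraction_form:", p$attraction_form, "\n\n")
  cat("Derived quantities:\n")
  cat("  K1 =", signif(x$capacities$K1, digits),
      " K2 =", signif(x$capacities$K2, digits),
      " beta(V) =", signif(x$beta, digits),
      " nu1* =", signif(x$nu1_star, digits), "\n\n")
  print(x$equilibrium, digits = digits)
  if (is.finite(x$crossing_gamma)) {
    cat("Reef catch overtakes fishing-area catch at gamma =",
        signif(x$crossing_gamma, digits),
        sprintf("(%.0f%%)\n", 100 * x$crossing_gamma))
  }
  invisible(x)
}

#' @export
coef.reef_model <- function(object, ...) {
  p <- object$params
  unlist(p[setdiff(names(p), "attraction_form")])
}

#' Equilibria under modified parameters
#'
#' Recomputes the closed-form equilibrium for each row of \code{newdata},
#' a data frame whose columns name parameters to override (e.g. \code{V},
#' \code{gamma}, \code{beta0}). With \code{newdata = NULL} the model's own
#' equilibrium record is returned.
#'
#' @param object a \code{reef_model}.
#' @param newdata data.frame of parameter overrides, one scenario per row.
#' @param ... unused.
#' @return data.frame of equilibrium records (fixed column order), one row
#'   per scenario.
#' @examples
#' m <- reef_model(beta0 = 1, delta_k = 5)
#' predict(m, data.frame(V = c(0, 120, 500), gamma = 0.05))
#' @export
predict.reef_model <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) {
    return(as.data.frame(object$equilibrium))
  }
  stopifnot(is.data.frame(newdata), nrow(newdata) > 0)
  rows <- lapply(seq_len(nrow(newdata)), function(i) {
    overrides <- as.list(newdata[i, , drop = FALSE])
    p <- do.call(update_params, c(list(object$params), overrides))
    as.data.frame(interior_equilibrium(p))
  })
  do.call(rbind, rows)
}

#' Simulate trajectories of the model
#'
#' Deterministic integration of the reduced or full system from a given
#' initial state; a thin wrapper around \code{\link{integrate_reef}}.
#' The dynamics contain no stochastic terms, so \code{nsim} and \code{seed}
#' are accepted for generic compatibility and ignored.
#'
#' @param object a \code{reef_model}.
#' @param nsim,seed ignored (deterministic dynamics).
#' @param model \code{"reduced"} or \code{"full"}.
#' @param init initial state; default for the reduced model is half the
#'   aggregate capacity with unit effort, and for the full model that same
#'   aggregate placed on the fast manifold.
#' @param t_end integration horizon (model's own time unit).
#' @param ... passed to \code{\link{integrate_reef}}.
#' @return a \code{reef_trajectory}.
#' @examples
#' m <- reef_model(beta0 = 1, delta_k = 5, V = 0, gamma = 0.2)
#' tr <- simulate(m, init = c(50, 0.5))
#' tr$final_state
#' @export
simulate.reef_model <- function(object, nsim = 1, seed = NULL,
                                model = c("reduced", "full"), init = NULL,
                                t_end = 2000, ...) {
  model <- match.arg(model)
  if (is.null(init)) {
    n0 <- object$equilibrium$K_eff / 2
    init <- if (model == "reduced") {
      c(n0, 1)
    } else {
      c(object$nu1_star * n0, (1 - object$nu1_star) * n0,
        object$params$gamma, 1 - object$params$gamma)
    }
  }
  integrate_reef(object$params, model = model, init = init, t_end = t_end,
                 ...)
}

#' Plot equilibrium catch against the illegal-fishing fraction
#'
#' Draws the equilibrium catch decomposition (total, fishing area, reef)
#' as a function of \code{gamma} at the model's reef volume, the standard
#' single-volume panel of this model family.
#'
#' @param x a \code{reef_model}.
#' @param gamma_grid grid of illegal-effort fractions.
#' @param ... passed to \code{matplot}.
#' @return the sweep data.frame, invisibly.
#' @export
plot.reef_model <- function(x, gamma_grid = seq(0, 1, by = 0.01), ...) {
  tab <- sweep_gamma(x$params, gamma_grid = gamma_grid, V = x$params$V)
  graphics::matplot(tab$gamma,
                    cbind(tab$catch_total, tab$catch_fish, tab$catch_ar),
                    type = "l", lty = 1, lwd = 2,
                    col = c("steelblue", "firebrick", "goldenrod"),
                    xlab = "fraction of effort on the reef (gamma)",
                    ylab = "equilibrium catch (tons per unit time)",
                    main = sprintf("V = %g m^3", x$params$V), ...)
  graphics::legend("topright",
                   legend = c("total", "fishing area", "reef"),
                   col = c("steelblue", "firebrick", "goldenrod"),
                   lty = 1, lwd = 2, bty = "n")
  invisible(tab)
}
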