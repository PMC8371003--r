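# Registry of attraction-function variants.
#
# The attraction function beta(V) is the part of fish movement toward the
# reef that does not follow the ideal free distribution: an increment, per
# fast-time unit, to the immigration rate from the fishing area into the
# no-take zone. Every registered form must satisfy beta(0) = 0 and be
# non-negative and non-decreasing in V.
.attraction_registry <- new.env(parent = emptyenv())

.attraction_builtin <- function() {
  # multiplicative-saturating: a relative perturbation of the baseline
  # immigration rate a / ((1 - alpha) K), saturating over the volume
  # scale 1 / sigma
  assign("saturating", function(V, params) {
    params$beta0 * (params$a / ((1 - params$alpha) * params$K)) *
      (1 - exp(-params$sigma * V))
  }, envir = .attraction_registry)
  # absolute-saturating: same shape but an absolute rate in beta0 units
  assign("absolute", function(V, params) {
    params$beta0 * (1 - exp(-params$sigma * V))
  }, envir = .attraction_registry)
  # linear: unsaturated, proportional to reef volume
  assign("linear", function(V, params) {
    params$beta0 * params$sigma * V
  }, envir = .attraction_registry)
}

#' Registered attraction-function variants
#'
#' @return character vector of registered form names. The default form is
#'   \code{"saturating"}: \code{beta(V) = beta0 * (a / ((1 - alpha) * K)) *
#'   (1 - exp(-sigma * V))}, a saturating relative perturbation of the
#'   baseline immigration rate into the no-take zone. Also shipped:
#'   \code{"absolute"} (\code{beta0 * (1 - exp(-sigma * V))}) and
#'   \code{"linear"} (\code{beta0 * sigma * V}).
#' @seealso \code{\link{register_attraction}}
#' @export
attraction_forms <- function() {
  sort(ls(.attraction_registry))
}

#' Register a custom attraction function
#'
#' Adds (or replaces) a named attraction variant. The function receives the
#' reef volume and the full parameter list and must return a non-negative
#' migration-rate increment with \code{fn(0, params) == 0}.
#'
#' @param name form identifier.
#' @param fn \code{function(V, params)}.
#' @return \code{name}, invisibly.
#' @examples
#' # a hump-shaped variant useful for exercising optimum finders
#' register_attraction("gaussian_bump", function(V, params) {
#'   params$beta0 * V * exp(-params$sigma * V)
#' })
#' @export
register_attraction <- function(name, fn) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name),
            is.function(fn))
  assign(name, fn, envir = .attraction_registry)
  invisible(name)
}

#' Attraction effect of the reef on fish movement
#'
#' Evaluates the attraction function beta(V) selected by
#' \code{params$attraction_form}: the migration-rate increment (per
#' fast-time unit) from the fishing area into the no-take zone caused by
#' the reef, beyond the ideal-free-distribution movement.
#'
#' @param V reef volume, m^3 (may differ from \code{params$V}, e.g. in
#'   volume sweeps). Defaults to \code{params$V}.
#' @param params a \code{reef_params} object.
#' @return migration-rate increment, per fast-time unit.
#' @examples
#' p <- reef_params(beta0 = 1, delta_k = 5)
#' attraction(120, p)
#' @export
attraction <- function(V = params$V, params) {
  if (!is.numeric(V) || any(V < 0)) {
    stop("reef volume 'V' must be non-negative", call. = FALSE)
  }
  fn <- get0(params$attraction_form, envir = .attraction_registry)
  if (is.null(fn)) {
    stop("unknown attraction_form '", params$attraction_form,
         "'; registered forms: ", paste(attraction_forms(), collapse = ", "),
         call. = FALSE)
  }
  fn(V, params)
}

#' Fast-equilibrium fraction of fish biomass in the no-take zone
#'
#' The fast fish-movement subsystem balances immigration
#' \code{(a / K2 + beta(V)) * n2} against emigration \code{(a / K1) * n1},
#' giving a unique stable split of total biomass. With no attraction
#' (\code{beta = 0}) this reduces to the ideal free distribution
#' \code{K1 / (K1 + K2)}.
#'
#' @param params a \code{reef_params} object.
#' @return fraction of total fish biomass in the no-take zone, in (0, 1).
#' @examples
#' nu1_star(reef_params(beta0 = 1, delta_k = 5, V = 120))
#' @export
nu1_star <- function(params) {
  caps <- zone_capacities_raw(params)
  A <- params$a / caps$K1
  B <- params$a / caps$K2 + attraction(params$V, params)
  B / (A + B)
}
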