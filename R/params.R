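#' Model parameters for the artificial-reef fishery system
#'
#' Constructs and validates the full parameter set of the two-patch
#' bioeconomic model: a no-take zone containing an artificial reef (AR),
#' surrounded by an open-access fishing area. Fish follow an ideal free
#' distribution (IFD) perturbed by reef attraction; fishing effort follows
#' open-access (profit-driven) dynamics, with a fraction \code{gamma} of the
#' total effort deployed illegally inside the no-take zone.
#'
#' \code{beta0} and \code{delta_k} have no defaults: the reference parameter
#' table lists two candidate values for each (0.1 or 1 for \code{beta0},
#' 0.1 or 5 for \code{delta_k}), so every scenario must choose explicitly.
#'
#' @param r intrinsic fish population growth rate, per slow-time unit.
#' @param K carrying capacity of the whole study area, tons.
#' @param a fish mobility rate constant, per fast-time unit.
#' @param c fishing cost per unit effort.
#' @param p fish market price per ton.
#' @param q catchability; convenience setter for \code{q1} and \code{q2}.
#' @param q1,q2 zone-specific catchabilities (no-take zone, fishing area).
#'   Distinct values are only meaningful for the full two-patch system; the
#'   reduced model requires \code{q1 == q2}.
#' @param alpha fraction of the study area that is no-take zone, in [0, 1].
#' @param V artificial reef volume, m^3 (>= 0).
#' @param delta_k added carrying capacity per unit AR volume, tons per m^3.
#' @param beta0 attraction parameter 1 (dimensionless strength).
#' @param sigma attraction parameter 2, per m^3 (saturation scale).
#' @param gamma fraction of total fishing effort applied inside the no-take
#'   zone (the "illegal fishing rate"), in [0, 1].
#' @param epsilon timescale-separation parameter of the full system,
#'   dimensionless, in [0, 1]; \code{epsilon = 0} is the pure-movement
#'   (singular) limit, useful as a diagnostic. Reduced-model results do not
#'   depend on it.
#' @param mu overall effort redistribution speed (fast time); the fast
#'   transfer rates are \code{m1 = gamma * mu} and \code{m2 = (1 - gamma) * mu}.
#' @param attraction_form name of a registered attraction function variant;
#'   see \code{\link{attraction_forms}}.
#'
#' @return An object of class \code{"reef_params"}: a validated named list.
#' @seealso \code{\link{attraction}}, \code{\link{zone_capacities}},
#'   \code{\link{nu1_star}}, \code{\link{reef_model}}
#' @examples
#' p <- reef_params(beta0 = 1, delta_k = 5, V = 120, gamma = 0.05)
#' p
#' @export
reef_params <- function(r = 0.5, K = 100, a = 2, c = 1, p = 1,
                        q = 1, q1 = q, q2 = q,
                        alpha = 0.2, V = 0, delta_k, beta0, sigma = 0.1,
                        gamma = 0, epsilon = 0.1, mu = 1,
                        attraction_form = "saturating") {
  if (missing(beta0)) {
    stop("'beta0' must be given explicitly (candidate values: 0.1 or 1)",
         call. = FALSE)
  }
  if (missing(delta_k)) {
    stop("'delta_k' must be given explicitly (candidate values: 0.1 or 5)",
         call. = FALSE)
  }
  params <- list(r = r, K = K, a = a, c = c, p = p, q1 = q1, q2 = q2,
                 alpha = alpha, V = V, delta_k = delta_k, beta0 = beta0,
                 sigma = sigma, gamma = gamma, epsilon = epsilon, mu = mu,
                 attraction_form = attraction_form)
  validate_reef_params(params)
}

#' @rdname reef_params
#' @param params a list with the fields of \code{reef_params}.
#' @export
validate_reef_params <- function(params) {
  need <- c("r", "K", "a", "c", "p", "q1", "q2", "alpha", "V", "delta_k",
            "beta0", "sigma", "gamma", "epsilon", "mu", "attraction_form")
  missing_fields <- setdiff(need, names(params))
  if (length(missing_fields)) {
    stop("missing parameter fields: ", paste(missing_fields, collapse = ", "),
         call. = FALSE)
  }
  extra <- setdiff(names(params), need)
  if (length(extra)) {
    stop("unknown parameter fields: ", paste(extra, collapse = ", "),
         call. = FALSE)
  }
  num <- params[setdiff(need, "attraction_form")]
  bad <- names(num)[!vapply(num, function(x)
    is.numeric(x) && length(x) == 1L && is.finite(x), logical(1))]
  if (length(bad)) {
    stop("parameters must be finite numeric scalars: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  check_pos <- function(field) {
    if (params[[field]] <= 0) {
      stop("'", field, "' must be strictly positive (got ", params[[field]],
           ")", call. = FALSE)
    }
  }
  for (field in c("r", "K", "a", "c", "p", "q1", "q2", "mu")) check_pos(field)
  if (params$alpha < 0 || params$alpha > 1) {
    stop("'alpha' must lie in [0, 1] (got ", params$alpha, ")", call. = FALSE)
  }
  if (params$gamma < 0 || params$gamma > 1) {
    stop("'gamma' must lie in [0, 1] (got ", params$gamma, ")", call. = FALSE)
  }
  if (params$V < 0) {
    stop("'V' must be non-negative (got ", params$V, ")", call. = FALSE)
  }
  if (params$delta_k < 0) {
    stop("'delta_k' must be non-negative (got ", params$delta_k, ")",
         call. = FALSE)
  }
  if (params$beta0 < 0) {
    stop("'beta0' must be non-negative (got ", params$beta0, ")",
         call. = FALSE)
  }
  if (params$sigma < 0) {
    stop("'sigma' must be non-negative (got ", params$sigma, ")",
         call. = FALSE)
  }
  if (params$epsilon < 0 || params$epsilon > 1) {
    stop("'epsilon' must lie in [0, 1] (got ", params$epsilon, ")",
         call. = FALSE)
  }
  if (!is.character(params$attraction_form) ||
      length(params$attraction_form) != 1L) {
    stop("'attraction_form' must be a single string", call. = FALSE)
  }
  if (!params$attraction_form %in% attraction_forms()) {
    stop("unknown attraction_form '", params$attraction_form,
         "'; registered forms: ", paste(attraction_forms(), collapse = ", "),
         call. = FALSE)
  }
  # zone capacities must stay positive for the movement rates to be defined
  caps <- zone_capacities_raw(params)
  if (caps$K1 <= 0 || caps$K2 <= 0) {
    stop("zone carrying capacities must be strictly positive; got K1 = ",
         caps$K1, ", K2 = ", caps$K2,
         " (check alpha, K, V, delta_k)", call. = FALSE)
  }
  structure(params[need], class = "reef_params")
}

#' @export
print.reef_params <- function(x, ...) {
  cat("Artificial-reef fishery parameters\n")
  num <- unlist(x[setdiff(names(x), "attraction_form")])
  print(num)
  cat("attraction_form:", x$attraction_form, "\n")
  invisible(x)
}

#' Update a parameter set
#'
#' Returns a revalidated copy of the parameter set with the named fields
#' replaced. \code{q} may be used to set \code{q1} and \code{q2} together.
#' The first argument is named \code{object} (not \code{params}) so that
#' the parameter \code{p} (fish price) cannot partially match it.
#'
#' @param object a \code{reef_params} object.
#' @param ... named replacement values.
#' @return a validated \code{reef_params} object.
#' @examples
#' p <- reef_params(beta0 = 1, delta_k = 5)
#' update_params(p, V = 120, gamma = 0.05)
#' @export
update_params <- function(object, ...) {
  params <- object
  changes <- list(...)
  if (length(changes) == 0L) return(validate_reef_params(unclass(params)))
  if (is.null(names(changes)) || any(names(changes) == "")) {
    stop("all replacement values must be named", call. = FALSE)
  }
  if ("q" %in% names(changes)) {
    changes$q1 <- changes$q
    changes$q2 <- changes$q
    changes$q <- NULL
  }
  unknown <- setdiff(names(changes), names(params))
  if (length(unknown)) {
    stop("unknown parameter fields: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  out <- unclass(params)
  out[names(changes)] <- changes
  validate_reef_params(out)
}

# internal: capacities without class dispatch, used during validation
zone_capacities_raw <- function(params) {
  list(K1 = params$alpha * params$K + params$V * params$delta_k,
       K2 = (1 - params$alpha) * params$K)
}

#' Zone carrying capacities
#'
#' The no-take zone holds a fraction \code{alpha} of the baseline capacity
#' \code{K} plus the reef's production effect \code{V * delta_k}; the fishing
#' area holds the remaining \code{(1 - alpha) * K}.
#'
#' @param params a \code{reef_params} object.
#' @return a list with components \code{K1} (no-take zone incl. reef
#'   production, tons) and \code{K2} (fishing area, tons).
#' @examples
#' zone_capacities(reef_params(beta0 = 1, delta_k = 5, V = 120))
#' @export
zone_capacities <- function(params) {
  params <- validate_reef_params(params)
  zone_capacities_raw(params)
}
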