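#' Aggregate carrying capacity of the reduced model
#'
#' The logistic term of the reduced system has effective capacity
#' \code{K_eff = 1 / (nu1*^2 / K1 + (1 - nu1*)^2 / K2)}: the unfished
#' equilibrium of total biomass. When the attraction effect is absent
#' (\code{beta = 0}) this collapses to \code{K1 + K2} exactly.
#'
#' @param params a \code{reef_params} object.
#' @return aggregate carrying capacity, tons.
#' @examples
#' k_eff(reef_params(beta0 = 1, delta_k = 5, V = 120))
#' @export
k_eff <- function(params) {
  caps <- zone_capacities_raw(params)
  nu1 <- nu1_star(params)
  1 / (nu1^2 / caps$K1 + (1 - nu1)^2 / caps$K2)
}

# relative tolerance separating viable from boundary equilibria
.viability_tol <- 1e-12

#' Interior (bionomic) equilibrium of the reduced model
#'
#' Solves the reduced system at steady state in closed form. At a viable
#' equilibrium open-access effort adjusts until profit is zero, pinning the
#' stock at \code{n* = c / (p q Q)} where
#' \code{Q = gamma nu1* + (1 - gamma)(1 - nu1*)} is the effective harvest
#' weight; effort then follows from the biomass equation,
#' \code{E* = r (1 - n*/K_eff) / (q Q)}. If the zero-profit stock exceeds
#' the aggregate capacity the fishery is not economically viable: the model
#' settles on the boundary equilibrium \code{E = 0}, \code{n = K_eff} with
#' zero catches (reported as a complete record, not an error, so parameter
#' sweeps stay total).
#'
#' Equilibrium catch rates are decomposed by zone:
#' \code{catch_ar = q gamma nu1* n* E*} (taken illegally on the reef) and
#' \code{catch_fish = q (1 - gamma)(1 - nu1*) n* E*} (fishing area).
#'
#' @param params a \code{reef_params} object with \code{q1 == q2}.
#' @return an object of class \code{"reef_equilibrium"}: a list with fields
#'   \code{nu1_star}, \code{Q}, \code{K_eff}, \code{n_star}, \code{E_star},
#'   \code{catch_total}, \code{catch_ar}, \code{catch_fish}, \code{viable},
#'   and the generating \code{params}. Use \code{as.data.frame} for a flat
#'   record.
#' @examples
#' interior_equilibrium(reef_params(beta0 = 1, delta_k = 5, V = 120,
#'                                  gamma = 0.05))
#' @export
interior_equilibrium <- function(params) {
  params <- validate_reef_params(params)
  q <- single_q(params)
  nu1 <- nu1_star(params)
  Q <- params$gamma * nu1 + (1 - params$gamma) * (1 - nu1)
  if (Q <= 0) {
    stop("degenerate harvest policy: effective harvest weight Q = 0 ",
         "(gamma = ", params$gamma, ", nu1* = ", signif(nu1, 6),
         "); no zone receives both fish and effort", call. = FALSE)
  }
  Keff <- k_eff(params)
  n_star <- params$c / (params$p * q * Q)
  viable <- n_star < Keff * (1 - .viability_tol)
  if (viable) {
    E_star <- params$r * (1 - n_star / Keff) / (q * Q)
    catch_ar <- q * params$gamma * nu1 * n_star * E_star
    catch_fish <- q * (1 - params$gamma) * (1 - nu1) * n_star * E_star
  } else {
    n_star <- Keff
    E_star <- 0
    catch_ar <- 0
    catch_fish <- 0
  }
  structure(list(nu1_star = nu1, Q = Q, K_eff = Keff,
                 n_star = n_star, E_star = E_star,
                 catch_total = catch_ar + catch_fish,
                 catch_ar = catch_ar, catch_fish = catch_fish,
                 viable = viable, params = params),
            class = "reef_equilibrium")
}

#' @export
print.reef_equilibrium <- function(x, digits = 4, ...) {
  cat("Reduced-model equilibrium",
      if (x$viable) "(viable fishery)\n" else "(not economically viable)\n")
  cat("  nu1* =", signif(x$nu1_star, digits),
      " Q =", signif(x$Q, digits),
      " K_eff =", signif(x$K_eff, digits), "\n")
  cat("  n* =", signif(x$n_star, digits),
      " E* =", signif(x$E_star, digits), "\n")
  cat("  catch: total =", signif(x$catch_total, digits),
      " reef =", signif(x$catch_ar, digits),
      " fishing area =", signif(x$catch_fish, digits), "\n")
  invisible(x)
}

# fixed column order shared by every tabular writer
.equilibrium_columns <- c("V", "gamma", "beta0", "sigma", "delta_k",
                          "nu1_star", "Q", "K_eff", "n_star", "E_star",
                          "catch_total", "catch_ar", "catch_fish", "viable")

#' @export
as.data.frame.reef_equilibrium <- function(x, ...) {
  p <- x$params
  data.frame(V = p$V, gamma = p$gamma, beta0 = p$beta0, sigma = p$sigma,
             delta_k = p$delta_k, nu1_star = x$nu1_star, Q = x$Q,
             K_eff = x$K_eff, n_star = x$n_star, E_star = x$E_star,
             catch_total = x$catch_total, catch_ar = x$catch_ar,
             catch_fish = x$catch_fish, viable = x$viable)
}

#' Illegal-fishing fraction at which reef catch overtakes fishing-area catch
#'
#' At equilibrium the reef and fishing-area catches are
#' \code{q gamma nu1* n* E*} and \code{q (1 - gamma)(1 - nu1*) n* E*}, so
#' they are equal exactly when \code{gamma nu1* = (1 - gamma)(1 - nu1*)},
#' i.e. at \code{gamma = 1 - nu1*} -- independent of the equilibrium stock
#' and effort. Below this fraction most of the catch comes from the fishing
#' area; above it, from the reef.
#'
#' @param params a \code{reef_params} object.
#' @return the crossing value of \code{gamma}, in (0, 1).
#' @examples
#' # with a 120 m^3 reef under the default attraction form, the crossing
#' # sits just above 6% illegal effort
#' catch_crossing_gamma(reef_params(beta0 = 1, delta_k = 5, V = 120))
#' @export
catch_crossing_gamma <- function(params) {
  nu1 <- nu1_star(params)
  if (nu1 <= 0 || nu1 >= 1) {
    stop("degenerate fish distribution: nu1* = ", nu1,
         "; no crossing exists", call. = FALSE)
  }
  1 - nu1
}
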