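#' Sample power-law kinetic parameters for a network
#'
#' Every non-constant reaction rate is modelled as a product of power laws
#' of its controller concentrations, \eqn{v = k \prod_i x_i^{g_i}}
#' (Biochemical Systems Theory). Rate constants `k` are drawn uniformly
#' from \[0.1, 1\]; kinetic orders `g` uniformly from \[0.1, 1\] for
#' activating controllers and \[-1, -0.1\] for inhibiting ones. The value
#' of each constant flux is drawn from \[0.1, 1\] as well.
#'
#' @param net a [scour_network].
#' @param seed optional integer seed; when given, draws are reproducible.
#' @return An object of class `scour_bst_params`: per-reaction list with
#'   `k` (or `value` for constant reactions) and named exponent vector `g`.
#' @export
sample_bst_parameters <- function(net, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  params <- lapply(net$reactions, function(r) {
    if (r$constant) {
      list(constant = TRUE, value = stats::runif(1, 0.1, 1))
    } else {
      g <- ifelse(r$controllers > 0,
                  stats::runif(length(r$controllers), 0.1, 1),
                  -stats::runif(length(r$controllers), 0.1, 1))
      names(g) <- names(r$controllers)
      list(constant = FALSE, k = stats::runif(1, 0.1, 1), g = g)
    }
  })
  names(params) <- vapply(net$reactions, `[[`, character(1), "id")
  structure(params, class = "scour_bst_params")
}

#' Evaluate a power-law flux at one concentration state
#'
#' @param reaction a reaction specification from a [scour_network].
#' @param params the matching entry of [sample_bst_parameters] output (a
#'   list with `k` and `g`, or `value` for constant reactions).
#' @param x named vector of metabolite concentrations; controller entries
#'   must be strictly positive unless the corresponding exponent is a
#'   non-negative integer.
#' @return The flux value \eqn{k \prod x_i^{g_i}} (or the constant value).
#' @export
#' @examples
#' r <- list(id = "v", substrate = "a", products = "b", constant = FALSE,
#'           controllers = c(a = 1))
#' evaluate_flux(r, list(constant = FALSE, k = 0.5, g = c(a = 1)), c(a = 2))
evaluate_flux <- function(reaction, params, x) {
  if (isTRUE(params$constant)) return(params$value)
  g <- params$g
  xi <- x[names(g)]
  bad <- xi <= 0 & (g %% 1 != 0 | g < 0)
  if (any(bad)) {
    stop(sprintf("reaction %s: nonpositive concentration for %s with non-integer or negative exponent",
                 reaction$id, paste(names(g)[bad], collapse = ",")), call. = FALSE)
  }
  params$k * prod(xi^g)
}

## Stoichiometry matrix (metabolite x reaction): +1 product, -1 substrate.
stoichiometry <- function(net) {
  S <- matrix(0, length(net$metabolites), length(net$reactions),
              dimnames = list(net$metabolites,
                              vapply(net$reactions, `[[`, character(1), "id")))
  for (j in seq_along(net$reactions)) {
    r <- net$reactions[[j]]
    if (!is.na(r$substrate)) S[r$substrate, j] <- S[r$substrate, j] - 1
    for (p in r$products) S[p, j] <- S[p, j] + 1
  }
  S
}

## Vectorized flux evaluation: states is an n_time x m matrix (columns named
## by metabolite); returns n_time x n_reaction matrix.
flux_matrix <- function(net, params, states) {
  out <- matrix(NA_real_, nrow(states), length(net$reactions),
                dimnames = list(NULL, names(params)))
  for (j in seq_along(net$reactions)) {
    r <- net$reactions[[j]]
    p <- params[[r$id]]
    if (p$constant) {
      out[, j] <- p$value
    } else {
      lx <- log(states[, names(p$g), drop = FALSE])
      out[, j] <- p$k * exp(as.vector(lx %*% p$g))
    }
  }
  out
}

#' Simulate a power-law network time course
#'
#' Integrates \eqn{dx/dt = S v(x)} with `deSolve::lsoda` (relative
#' tolerance 1e-8, absolute 1e-10) and records concentrations and fluxes
#' on a uniform grid of `n_points` timepoints spanning \[0, `horizon`\].
#' Concentrations are clamped at a tiny floor inside the derivative so the
#' power laws stay defined; trajectories that actually hit the floor are
#' reported as failures (callers redraw initial conditions).
#'
#' @param net a [scour_network].
#' @param params parameters from [sample_bst_parameters].
#' @param x0 named strictly positive initial concentrations.
#' @param horizon total simulated time (default 10).
#' @param n_points number of stored timepoints (default 451).
#' @param positivity_floor concentrations below this value abort the
#'   simulation with an error.
#' @return A [scour_timecourse] with one replicate.
#' @export
simulate_timecourse <- function(net, params, x0, horizon = 10,
                                n_points = 451, positivity_floor = 1e-6) {
  stopifnot(horizon > 0, n_points >= 2)
  x0 <- x0[net$metabolites]
  if (anyNA(x0) || any(x0 <= 0)) {
    stop("x0 must be strictly positive for every metabolite", call. = FALSE)
  }
  S <- stoichiometry(net)
  times <- seq(0, horizon, length.out = n_points)
  deriv <- function(t, x, p) {
    xs <- matrix(pmax(x, 1e-12), nrow = 1,
                 dimnames = list(NULL, net$metabolites))
    v <- flux_matrix(net, params, xs)[1, ]
    list(as.vector(S %*% v))
  }
  # divert solver diagnostics (step-size failures are expected for
  # rejected parameter/initial-condition draws and handled by redraws)
  quiet <- file(nullfile(), open = "wt")
  sink(quiet, type = "message")
  sol <- tryCatch(
    suppressWarnings(
      deSolve::lsoda(y = x0, times = times, func = deriv, parms = NULL,
                     rtol = 1e-8, atol = 1e-10)),
    finally = {
      sink(type = "message")
      close(quiet)
    })
  if (attr(sol, "istate")[1] < 0 || nrow(sol) < n_points) {
    stop("integration failed for network ", net$name, call. = FALSE)
  }
  states <- sol[, net$metabolites, drop = FALSE]
  if (anyNA(states) || any(states < positivity_floor)) {
    worst <- net$metabolites[which.min(apply(states, 2, min))]
    stop(sprintf("concentration underflow (metabolite %s) during simulation",
                 worst), call. = FALSE)
  }
  v <- flux_matrix(net, params, states)
  scour_timecourse(times, t(states), t(v))
}
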