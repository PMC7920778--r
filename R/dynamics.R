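# Two-species ODE community model:
#   dN_X/dt = [E_X(N_X, N_Y) - v (N_X + b N_Y)] N_X   (and symmetrically for Y)
# Mating happens on a fast timescale (quasi-stationarity), so E is evaluated
# at the current densities at every instant.

# Smooth rate function used by the solver and the finite-difference Jacobian.
# Performs no validation and tolerates small negative probe densities (all
# terms are rational in N); returns (0, 0) at the exact origin, where species
# frequency is undefined.
.community_rate <- function(NX, NY, params) {
  wX <- params$aX * NX
  wY <- params$aY * NY
  s <- wX + wY
  if (s == 0) return(c(0, 0))
  fX <- wX / s
  fY <- wY / s
  p <- params$probs
  PX <- .rate_P(fX, fY, p$pXX, p$pXY, p$qXX)
  PY <- .rate_P(fY, fX, p$pYY, p$pYX, p$qYY)
  r <- params$r
  cc <- params$c
  EX <- ((1 - cc) + cc * PX) * r
  EY <- ((1 - cc) + cc * PY) * r
  v <- params$v
  b <- params$b
  c((EX - v * (NX + b * NY)) * NX,
    (EY - v * (NY + b * NX)) * NY)
}

# two-shot conspecific-mating probability on frequencies (no validation)
.rate_P <- function(f_own, f_other, p_con, p_het, q_con) {
  denom <- f_own * p_con + f_other * p_het
  if (denom == 0) return(0)
  (p_con + p_het * q_con * f_other) * f_own / denom
}

#' Instantaneous growth rates of the community model
#'
#' @param NX,NY non-negative population densities.
#' @param params a [community_params] object.
#' @return Named numeric vector `c(dNX = , dNY = )`. At the exact origin the
#'   rates are `(0, 0)` by convention (species frequency is undefined there).
#' @examples
#' pars <- community_params(example_mating_probs(), c = 0.9)
#' community_derivative(1, 1, pars) # dNX = 11.7
#' @export
community_derivative <- function(NX, NY, params) {
  stopifnot(inherits(params, "community_params"))
  if (NX < 0 || NY < 0) stop("densities must be non-negative", call. = FALSE)
  setNames(.community_rate(NX, NY, params), c("dNX", "dNY"))
}

#' Integrate the community dynamics
#'
#' Adaptive stiff-capable integration (lsodar) of the two-species model, with
#' early exit once the vector field norm drops below `steady_tol` and an
#' extinction floor: densities below `floor` are set to zero at every output
#' time so that vanishing populations cannot be rescued by numerical residue.
#'
#' @param params a [community_params] object.
#' @param NX0,NY0 non-negative initial densities.
#' @param horizon integration horizon in model time units (default 1000).
#' @param n_out number of stored output points (default 201).
#' @param rtol,atol solver relative/absolute tolerances (defaults `1e-9`,
#'   `1e-12`).
#' @param steady_tol terminate early when `max(|dN/dt|)` falls below this
#'   value (default `1e-10`).
#' @param floor extinction floor on stored densities (default `1e-9`).
#' @return An object of class `community_trajectory`: a data frame with
#'   columns `time`, `NX`, `NY`, with the parameters and the terminal state
#'   attached as attributes (`attr(x, "terminal")`).
#' @examples
#' pars <- community_params(example_mating_probs(), c = 0.9)
#' tr <- integrate_community(pars, 1, 0)
#' attr(tr, "terminal") # converges to the boundary equilibrium (r/v, 0)
#' @export
integrate_community <- function(params, NX0, NY0, horizon = 1000,
                                n_out = 201, rtol = 1e-9, atol = 1e-12,
                                steady_tol = 1e-10, floor = 1e-9) {
  stopifnot(inherits(params, "community_params"))
  if (NX0 < 0 || NY0 < 0) stop("initial densities must be non-negative", call. = FALSE)
  if (horizon <= 0) stop("'horizon' must be > 0", call. = FALSE)
  times <- seq(0, horizon, length.out = max(2L, n_out))
  rhs <- function(t, y, parms) {
    list(.community_rate(max(y[1L], 0), max(y[2L], 0), parms))
  }
  rootfun <- function(t, y, parms) {
    d <- .community_rate(max(y[1L], 0), max(y[2L], 0), parms)
    max(abs(d)) - steady_tol
  }
  eventfun <- function(t, y, parms) {
    y[y < floor] <- 0
    y
  }
  sol <- tryCatch(
    deSolve::lsodar(y = c(NX = NX0, NY = NY0), times = times, func = rhs,
                    parms = params, rtol = rtol, atol = atol,
                    rootfunc = rootfun,
                    events = list(func = eventfun, time = times[-1L])),
    error = function(e) stop("integration failed: ", conditionMessage(e),
                             call. = FALSE)
  )
  out <- as.data.frame(sol)
  names(out) <- c("time", "NX", "NY")
  out$NX[out$NX < floor] <- 0
  out$NY[out$NY < floor] <- 0
  terminal <- c(NX = out$NX[nrow(out)], NY = out$NY[nrow(out)])
  structure(out, class = c("community_trajectory", "data.frame"),
            params = params, terminal = terminal)
}

#' Per-capita growth rate of a rare invader at the resident's equilibrium
#'
#' At the resident's boundary equilibrium `(r/v, 0)` an infinitesimally rare
#' invader is always the minority in every encounter, so its conspecific
#' mating probability vanishes and its fecundity collapses to `(1 - c) r`;
#' its per-capita growth is therefore `(1 - c) r - b v (r/v) = r (1 - c - b)`.
#' Exclusion of the invader is locally stable exactly when this is negative,
#' i.e. when `b + c > 1`.
#'
#' @param params a [community_params] object.
#' @param invader `"X"` or `"Y"` (the resident is the other species).
#' @return The invader's per-capita growth rate (a single number).
#' @examples
#' invasion_fitness(community_params(example_mating_probs(), c = 0.9), "Y") # -5
#' @export
invasion_fitness <- function(params, invader = "Y") {
  stopifnot(inherits(params, "community_params"))
  .check_focal(invader)
  resident_density <- params$r / params$v
  state <- if (invader == "Y") c(resident_density, 0) else c(0, resident_density)
  E <- expected_fecundity(params, state[1L], state[2L])
  Einv <- if (invader == "Y") E[["EY"]] else E[["EX"]]
  Einv - params$v * params$b * resident_density
}
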