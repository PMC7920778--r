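# Equilibria and local stability of the community model.

# Numerical Jacobian of the vector field at a point. Strictly positive
# coordinates are differentiated by central differences with a step scaled to
# the density magnitude. For a coordinate that is exactly zero the product
# structure N_k * g_k(N) makes the corresponding Jacobian row exactly
# diag(g_k(N)) (the per-capita growth evaluated at the point), which is used
# analytically instead of probing negative densities. The exact origin is
# evaluated at an epsilon offset because species frequency is undefined there.
.community_jacobian <- function(NX, NY, params, eps_rel = 1e-5) {
  scale <- params$r / params$v
  if (NX == 0 && NY == 0) {
    eps <- 1e-8 * scale
    NX <- eps
    NY <- eps
  }
  x <- c(NX, NY)
  J <- matrix(0, 2L, 2L)
  for (k in 1:2) {
    h <- eps_rel * max(abs(x[k]), 0.01 * scale)
    up <- x; up[k] <- up[k] + h
    dn <- x; dn[k] <- dn[k] - h
    fu <- .community_rate(up[1L], up[2L], params)
    fd <- .community_rate(dn[1L], dn[2L], params)
    J[, k] <- (fu - fd) / (2 * h)
  }
  # rows for coordinates exactly at 0 are known analytically:
  # d(N_k g_k)/dN_j = g_k * delta_kj at N_k = 0
  zero <- which(x == 0)
  if (length(zero)) {
    g <- .percapita_rate(x[1L], x[2L], params)
    for (k in zero) {
      J[k, ] <- 0
      J[k, k] <- g[k]
    }
  }
  J
}

# per-capita growth g = (dN/dt)/N, defined off the axes by the rate formula
.percapita_rate <- function(NX, NY, params) {
  wX <- params$aX * NX
  wY <- params$aY * NY
  s <- wX + wY
  if (s == 0) stop("per-capita growth undefined at the origin", call. = FALSE)
  fX <- wX / s
  fY <- wY / s
  p <- params$probs
  PX <- .rate_P(fX, fY, p$pXX, p$pXY, p$qXX)
  PY <- .rate_P(fY, fX, p$pYY, p$pYX, p$qYY)
  r <- params$r
  cc <- params$c
  v <- params$v
  b <- params$b
  c(((1 - cc) + cc * PX) * r - v * (NX + b * NY),
    ((1 - cc) + cc * PY) * r - v * (NY + b * NX))
}

.classify_eigen <- function(ev, tol) {
  re <- Re(ev)
  if (all(re < -tol)) "stable"
  else if (all(re > tol)) "unstable"
  else if (any(re > tol) && any(re < -tol)) "saddle"
  else "marginal"
}

.equilibrium_kind <- function(NX, NY, zero_tol) {
  if (NX <= zero_tol && NY <= zero_tol) "origin"
  else if (NY <= zero_tol) "boundary_X"
  else if (NX <= zero_tol) "boundary_Y"
  else "interior"
}

#' Local stability of a community equilibrium
#'
#' Computes the Jacobian of the vector field at a point (central finite
#' differences, with the exact per-capita rate substituted along axes), its
#' eigenvalues, and a stability classification: `stable` if both real parts
#' are below `-tol`, `unstable` if both exceed `+tol`, `saddle` if they
#' differ in sign, otherwise `marginal`.
#'
#' @param NX,NY coordinates of the equilibrium.
#' @param params a [community_params] object.
#' @param tol tolerance on eigenvalue real parts for the classification
#'   (default `1e-8`).
#' @param resid_tol maximum allowed vector-field norm at the point for it to
#'   count as an equilibrium (default `1e-6`).
#' @return An object of class `equilibrium_report`: a list with elements
#'   `NX`, `NY`, `kind` (`origin`, `boundary_X`, `boundary_Y` or `interior`),
#'   `eigenvalues` (complex pair), `stability` and `residual`.
#' @examples
#' pars <- community_params(example_mating_probs(), c = 0.9)
#' stability_report(25, 0, pars) # eigenvalues -25 and -5: stable exclusion
#' @export
stability_report <- function(NX, NY, params, tol = 1e-8, resid_tol = 1e-6) {
  stopifnot(inherits(params, "community_params"))
  resid <- if (NX == 0 && NY == 0) 0 else max(abs(.community_rate(NX, NY, params)))
  if (resid > resid_tol) {
    stop(sprintf("point (%g, %g) is not an equilibrium: residual %.3g exceeds %.3g",
                 NX, NY, resid, resid_tol), call. = FALSE)
  }
  J <- .community_jacobian(NX, NY, params)
  ev <- eigen(J, only.values = TRUE)$values
  ev <- ev[order(-Re(ev))]
  if (!is.complex(ev)) ev <- as.complex(ev)
  structure(list(NX = NX, NY = NY,
                 kind = .equilibrium_kind(NX, NY, 1e-12 * params$r / params$v),
                 eigenvalues = ev,
                 stability = .classify_eigen(ev, tol),
                 residual = resid),
            class = "equilibrium_report")
}

#' @export
print.equilibrium_report <- function(x, ...) {
  cat(sprintf("%s equilibrium at (%.6g, %.6g): %s\n", x$kind, x$NX, x$NY,
              x$stability))
  cat(sprintf("  eigenvalues: %.6g%+.3gi, %.6g%+.3gi (residual %.2g)\n",
              Re(x$eigenvalues[1L]), Im(x$eigenvalues[1L]),
              Re(x$eigenvalues[2L]), Im(x$eigenvalues[2L]), x$residual))
  invisible(x)
}

# damped Newton on the per-capita growth system, numerical Jacobian
.newton_percapita <- function(start, params, max_iter = 60, ftol = 1e-12) {
  x <- start
  scale <- params$r / params$v
  g <- .percapita_rate(x[1L], x[2L], params)
  for (iter in seq_len(max_iter)) {
    if (max(abs(g)) < ftol) break
    h <- 1e-6 * pmax(abs(x), 0.01 * scale)
    Jg <- matrix(0, 2L, 2L)
    for (k in 1:2) {
      up <- x; up[k] <- up[k] + h[k]
      dn <- x; dn[k] <- dn[k] - h[k]
      Jg[, k] <- (.percapita_rate(up[1L], up[2L], params) -
                    .percapita_rate(dn[1L], dn[2L], params)) / (2 * h[k])
    }
    step <- tryCatch(solve(Jg, -g), error = function(e) NULL)
    if (is.null(step) || any(!is.finite(step))) return(NULL)
    lambda <- 1
    repeat {
      xn <- x + lambda * step
      if (all(xn > 0) && all(is.finite(xn))) {
        gn <- .percapita_rate(xn[1L], xn[2L], params)
        if (max(abs(gn)) < max(abs(g)) || lambda < 1e-4) break
      }
      lambda <- lambda / 2
      if (lambda < 1e-6) return(NULL)
    }
    x <- xn
    g <- gn
  }
  if (max(abs(g)) < ftol) x else NULL
}

#' Locate all equilibria of the community model
#'
#' The origin and the two boundary (species-exclusion) equilibria
#' `(r/v, 0)` and `(0, r/v)` are known analytically and always reported.
#' Interior equilibria are found by multi-start damped Newton iteration on the
#' per-capita growth system over a lattice of starting points, de-duplicated
#' within a merge radius and verified by the residual of the full system.
#' Each equilibrium is classified with [stability_report()].
#'
#' @param params a [community_params] object.
#' @param box search box `c(lo, hi)` for interior roots (default
#'   `c(0, 2 r / v)`).
#' @param resolution number of Newton starts per axis (default 20).
#' @param tol eigenvalue classification tolerance, passed to
#'   [stability_report()].
#' @return A list of `equilibrium_report` objects, of class
#'   `equilibrium_set`.
#' @examples
#' pars <- community_params(example_mating_probs(), c = 0.4)
#' find_equilibria(pars) # includes a stable interior (coexistence) point
#' @export
find_equilibria <- function(params, box = NULL, resolution = 20, tol = 1e-8) {
  stopifnot(inherits(params, "community_params"))
  scale <- params$r / params$v
  if (is.null(box)) box <- c(0, 2 * scale)
  merge_radius <- 1e-4 * scale
  roots <- list(c(0, 0), c(scale, 0), c(0, scale))
  starts <- seq(box[1L] + diff(box) / (2 * resolution), box[2L],
                length.out = resolution)
  for (sx in starts) {
    for (sy in starts) {
      root <- .newton_percapita(c(sx, sy), params)
      if (is.null(root)) next
      if (root[1L] <= merge_radius || root[2L] <= merge_radius) next
      if (max(abs(.community_rate(root[1L], root[2L], params))) > 1e-8) next
      dup <- vapply(roots, function(z) sqrt(sum((z - root)^2)) < merge_radius,
                    logical(1L))
      if (!any(dup)) roots <- c(roots, list(root))
    }
  }
  reports <- lapply(roots, function(z) {
    stability_report(z[1L], z[2L], params, tol = tol, resid_tol = 1e-6)
  })
  structure(reports, class = "equilibrium_set")
}

#' @export
print.equilibrium_set <- function(x, ...) {
  cat(length(x), "equilibria:\n")
  for (eq in x) print(eq)
  invisible(x)
}

#' Turn an equilibrium set into a data frame
#'
#' @param x an `equilibrium_set` from [find_equilibria()].
#' @param ... unused.
#' @return A data frame with one row per equilibrium.
#' @export
as.data.frame.equilibrium_set <- function(x, ...) {
  data.frame(
    NX = vapply(x, `[[`, numeric(1L), "NX"),
    NY = vapply(x, `[[`, numeric(1L), "NY"),
    kind = vapply(x, `[[`, character(1L), "kind"),
    eigen1_re = vapply(x, function(e) Re(e$eigenvalues[1L]), numeric(1L)),
    eigen1_im = vapply(x, function(e) Im(e$eigenvalues[1L]), numeric(1L)),
    eigen2_re = vapply(x, function(e) Re(e$eigenvalues[2L]), numeric(1L)),
    eigen2_im = vapply(x, function(e) Im(e$eigenvalues[2L]), numeric(1L)),
    stability = vapply(x, `[[`, character(1L), "stability")
  )
}

#' Critical niche overlap for stable species exclusion
#'
#' Bisects the niche overlap `c` for the sign change of the transverse
#' Jacobian eigenvalue at the boundary (exclusion) equilibrium `(r/v, 0)`:
#' below the critical overlap a rare invader grows back, above it exclusion is
#' locally stable. Analytically the threshold is `c* = 1 - b` (exclusion is
#' stable iff `b + c > 1`); this routine recovers it from the numerical
#' Jacobian alone.
#'
#' @param params a [community_params] object (its `c` is ignored).
#' @param b interspecific competition strength in `[0, 1]` (defaults to
#'   `params$b`).
#' @param tol bisection tolerance on `c` (default `1e-6`).
#' @return The critical niche overlap `c*` in `[0, 1]`.
#' @examples
#' exclusion_boundary(community_params(example_mating_probs(), c = 0.5)) # 0.7
#' @export
exclusion_boundary <- function(params, b = params$b, tol = 1e-6) {
  stopifnot(inherits(params, "community_params"))
  if (b < 0 || b > 1) stop("'b' must lie in [0, 1]", call. = FALSE)
  transverse <- function(cc) {
    pars <- params
    pars$c <- cc
    pars$b <- b
    J <- .community_jacobian(pars$r / pars$v, 0, pars)
    J[2L, 2L]
  }
  lo <- 0
  hi <- 1
  g_lo <- transverse(lo)
  g_hi <- transverse(hi)
  if (g_lo <= 0) return(0)  # exclusion stable already at zero overlap
  if (g_hi > 0) return(1)   # invader grows back even at complete overlap
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (transverse(mid) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}
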