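# Basins of attraction and phase-portrait export.

#' Basins of attraction on a density lattice
#'
#' Integrates the community dynamics forward from every point of a
#' rectangular lattice and assigns each point to the stable equilibrium its
#' trajectory ends nearest to (within an assignment radius); points that end
#' near no stable equilibrium are labelled `"unresolved"` and reported, never
#' dropped. Axes are invariant sets of the dynamics, so lattice points on an
#' axis always flow to an axis attractor.
#'
#' @param params a [community_params] object.
#' @param equilibria optional `equilibrium_set` from [find_equilibria()];
#'   computed if missing.
#' @param grid_n lattice dimensions `c(nx, ny)` (default `c(50, 50)`).
#' @param box lattice extent `c(x0, x1, y0, y1)` (default
#'   `c(0, 1.2 r/v, 0, 1.2 r/v)`).
#' @param horizon,rtol,atol,steady_tol solver contract, as in
#'   [integrate_community()].
#' @param assign_radius maximum distance between a terminal state and a
#'   stable equilibrium for assignment (default `0.01 r / v`).
#' @return An object of class `basin_map`: a data frame with columns `NX0`,
#'   `NY0`, `NX_end`, `NY_end`, `attractor` (a label such as `"boundary_X"`,
#'   `"interior_1"` or `"unresolved"`), with the stable attractors attached as
#'   `attr(x, "attractors")`.
#' @examples
#' \donttest{
#' pars <- community_params(example_mating_probs(), c = 0.9)
#' bm <- basins(pars, grid_n = c(10, 10), box = c(0, 30, 0, 30))
#' table(bm$attractor)
#' }
#' @export
basins <- function(params, equilibria = NULL, grid_n = c(50, 50), box = NULL,
                   horizon = 1000, rtol = 1e-9, atol = 1e-12,
                   steady_tol = 1e-10, assign_radius = NULL) {
  stopifnot(inherits(params, "community_params"))
  scale <- params$r / params$v
  if (is.null(box)) box <- c(0, 1.2 * scale, 0, 1.2 * scale)
  if (any(box < 0)) stop("lattice must lie in the non-negative quadrant", call. = FALSE)
  if (is.null(assign_radius)) assign_radius <- 0.01 * scale
  if (is.null(equilibria)) equilibria <- find_equilibria(params)
  stable <- Filter(function(e) e$stability == "stable", equilibria)
  if (!length(stable)) {
    stop("no stable equilibrium found: basins are undefined", call. = FALSE)
  }
  labels <- .attractor_labels(stable)
  ax <- vapply(stable, `[[`, numeric(1L), "NX")
  ay <- vapply(stable, `[[`, numeric(1L), "NY")

  xs <- seq(box[1L], box[2L], length.out = grid_n[1L])
  ys <- seq(box[3L], box[4L], length.out = grid_n[2L])
  grid <- expand.grid(NX0 = xs, NY0 = ys)
  n <- nrow(grid)
  end <- matrix(NA_real_, n, 2L)
  lab <- character(n)
  for (i in seq_len(n)) {
    tr <- integrate_community(params, grid$NX0[i], grid$NY0[i],
                              horizon = horizon, n_out = 2L,
                              rtol = rtol, atol = atol,
                              steady_tol = steady_tol)
    term <- attr(tr, "terminal")
    end[i, ] <- term
    d <- sqrt((ax - term[1L])^2 + (ay - term[2L])^2)
    k <- which.min(d)
    lab[i] <- if (d[k] <= assign_radius) labels[k] else "unresolved"
  }
  out <- data.frame(NX0 = grid$NX0, NY0 = grid$NY0,
                    NX_end = end[, 1L], NY_end = end[, 2L], attractor = lab)
  structure(out, class = c("basin_map", "data.frame"),
            attractors = setNames(stable, labels), params = params)
}

.attractor_labels <- function(stable) {
  kinds <- vapply(stable, `[[`, character(1L), "kind")
  labels <- kinds
  idx <- which(kinds == "interior")
  if (length(idx)) labels[idx] <- paste0("interior_", seq_along(idx))
  make.unique(labels, sep = "_")
}

#' Tabular phase-portrait data
#'
#' Collects everything needed to draw a phase portrait with any plotting tool:
#' the derivative field on a lattice, nullcline traces (zero contours of each
#' species' growth rate), the equilibria with their stability, and (optional)
#' basin labels.
#'
#' @param params a [community_params] object.
#' @param equilibria optional `equilibrium_set`; computed if missing.
#' @param basins optional `basin_map` from [basins()]; omitted from the output
#'   if `NULL`.
#' @param grid_n field lattice dimensions (default `c(21, 21)`).
#' @param box field extent `c(x0, x1, y0, y1)` (default `c(0, 1.2 r/v)` on
#'   both axes).
#' @return A list of data frames `field`, `nullclines`, `equilibria` and,
#'   when supplied, `basins`; of class `phase_portrait`.
#' @export
phase_portrait_data <- function(params, equilibria = NULL, basins = NULL,
                                grid_n = c(21, 21), box = NULL) {
  stopifnot(inherits(params, "community_params"))
  scale <- params$r / params$v
  if (is.null(box)) box <- c(0, 1.2 * scale, 0, 1.2 * scale)
  if (is.null(equilibria)) equilibria <- find_equilibria(params)
  xs <- seq(box[1L], box[2L], length.out = grid_n[1L])
  ys <- seq(box[3L], box[4L], length.out = grid_n[2L])
  grid <- expand.grid(NX = xs, NY = ys)
  rates <- t(mapply(function(x, y) .community_rate(x, y, params),
                    grid$NX, grid$NY))
  field <- data.frame(NX = grid$NX, NY = grid$NY,
                      dNX = rates[, 1L], dNY = rates[, 2L])

  # nullclines as zero contours of the two rate components
  zx <- matrix(rates[, 1L], nrow = length(xs))
  zy <- matrix(rates[, 2L], nrow = length(xs))
  trace_null <- function(z, which_species) {
    cl <- contourLines(x = xs, y = ys, z = z, levels = 0)
    if (!length(cl)) return(NULL)
    do.call(rbind, lapply(seq_along(cl), function(i) {
      data.frame(species = which_species, piece = i,
                 NX = cl[[i]]$x, NY = cl[[i]]$y)
    }))
  }
  nullclines <- rbind(trace_null(zx, "X"), trace_null(zy, "Y"))
  if (is.null(nullclines)) {
    nullclines <- data.frame(species = character(), piece = integer(),
                             NX = numeric(), NY = numeric())
  }

  out <- list(field = field,
              nullclines = nullclines,
              equilibria = as.data.frame(equilibria))
  if (!is.null(basins)) out$basins <- as.data.frame(basins)
  structure(out, class = "phase_portrait")
}

#' Write phase-portrait tables to CSV files
#'
#' @param portrait a `phase_portrait` from [phase_portrait_data()].
#' @param dir output directory (created if necessary).
#' @return Invisibly, the paths written (named by component).
#' @export
write_portrait <- function(portrait, dir) {
  stopifnot(inherits(portrait, "phase_portrait"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  for (nm in names(portrait)) {
    path <- file.path(dir, paste0("portrait_", nm, ".csv"))
    write.csv(portrait[[nm]], path, row.names = FALSE)
    paths[nm] <- path
  }
  invisible(paths)
}
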