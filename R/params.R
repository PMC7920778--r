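#' Acceptance probabilities of the mating decision-making tree
#'
#' A female's decision to accept a suitor depends on her mating status and on
#' the suitor's species. A virgin female of species `i` accepts a male of
#' species `j` with probability `p_ij`; a once-mated (non-virgin) female
#' accepts with probability `q_ij`. The heterospecific remating probabilities
#' `qXY` and `qYX` are fecundity-neutral under complete conspecific sperm
#' precedence (a heterospecific mating neither adds nor removes conspecific
#' sperm), so they influence only the stochastic simulator and the
#' multiple-mating state chain, never the two-shot closed form.
#'
#' @param pXX,pXY probability a virgin X-female accepts an X-male / a Y-male.
#' @param pYY,pYX probability a virgin Y-female accepts a Y-male / an X-male.
#' @param qXX,qYY probability a once-mated female accepts a conspecific male.
#' @param qXY,qYX probability a once-mated female accepts a heterospecific
#'   male (default 0).
#' @return An object of class `mating_probabilities` (a named list).
#' @examples
#' example_mating_probs()
#' @export
mating_probabilities <- function(pXX, pXY, pYX, pYY, qXX, qYY,
                                 qXY = 0, qYX = 0) {
  probs <- list(pXX = pXX, pXY = pXY, pYX = pYX, pYY = pYY,
                qXX = qXX, qYY = qYY, qXY = qXY, qYX = qYX)
  for (nm in names(probs)) {
    x <- probs[[nm]]
    if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
      stop("acceptance probability '", nm, "' must be a single value in [0, 1]",
           call. = FALSE)
    }
  }
  structure(probs, class = "mating_probabilities")
}

#' Published example acceptance probabilities
#'
#' The asymmetric parameter set used for the package's worked phase portraits:
#' species X is choosy towards heterospecifics only after mating
#' (`pXX = 0.4`, `pXY = 0.8`, `qXX = 0.4`) while species Y discriminates
#' already as a virgin (`pYY = 0.8`, `pYX = 0.4`, `qYY = 0.8`). This mirrors
#' the behavioural asymmetry measured between two *Harmonia* ladybird species.
#'
#' @return A [mating_probabilities] object.
#' @export
example_mating_probs <- function() {
  mating_probabilities(pXX = 0.4, pXY = 0.8, pYX = 0.4, pYY = 0.8,
                       qXX = 0.4, qYY = 0.8)
}

#' Community model parameters
#'
#' Bundles the demographic parameters of the two-species community model with
#' the mating-tree acceptance probabilities. Both species are ecologically
#' neutral: they share `r`, `v` and `b` and differ only through mating
#' behaviour (and optionally through encounter activity).
#'
#' @param probs a [mating_probabilities] object.
#' @param c niche overlap in `[0, 1]`: the probability that a female is
#'   subject to the interspecific mating decision-making tree at all.
#' @param r per-capita egg production (>= 1; default 25).
#' @param v density-dependence coefficient of resource competition (> 0;
#'   default 1).
#' @param b strength of interspecific resource competition in `[0, 1]`
#'   (default 0.3).
#' @param aX,aY male encounter-activity weights (> 0, default 1). Encounters
#'   are conspecific with probability `aX*NX / (aX*NX + aY*NY)` for an
#'   X-female, so unequal activities bias the effective encounter frequency.
#' @return An object of class `community_params`.
#' @examples
#' community_params(example_mating_probs(), c = 0.9)
#' @export
community_params <- function(probs, c, r = 25, v = 1, b = 0.3,
                             aX = 1, aY = 1) {
  if (!inherits(probs, "mating_probabilities")) {
    stop("'probs' must be a mating_probabilities object", call. = FALSE)
  }
  stopifnot(is.numeric(c), length(c) == 1L, is.numeric(r), is.numeric(v),
            is.numeric(b), is.numeric(aX), is.numeric(aY))
  if (r < 1) stop("'r' must be >= 1", call. = FALSE)
  if (v <= 0) stop("'v' must be > 0", call. = FALSE)
  if (b < 0 || b > 1) stop("'b' must lie in [0, 1]", call. = FALSE)
  if (c < 0 || c > 1) stop("'c' must lie in [0, 1]", call. = FALSE)
  if (aX <= 0 || aY <= 0) stop("activities 'aX', 'aY' must be > 0", call. = FALSE)
  structure(list(r = r, v = v, b = b, c = c, probs = probs,
                 aX = aX, aY = aY),
            class = "community_params")
}

#' @export
print.community_params <- function(x, ...) {
  cat("Two-species community parameters\n")
  cat(sprintf("  r = %g, v = %g, b = %g, c = %g, activities (aX, aY) = (%g, %g)\n",
              x$r, x$v, x$b, x$c, x$aX, x$aY))
  p <- x$probs
  cat(sprintf("  virgin acceptance     p: XX %.3g, XY %.3g, YX %.3g, YY %.3g\n",
              p$pXX, p$pXY, p$pYX, p$pYY))
  cat(sprintf("  once-mated acceptance q: XX %.3g, YY %.3g, XY %.3g, YX %.3g\n",
              p$qXX, p$qYY, p$qXY, p$qYX))
  invisible(x)
}

#' Read community parameters from a JSON or YAML config file
#'
#' The config is a flat mapping with any of the keys `r`, `v`, `b`, `c`,
#' `pXX`, `pXY`, `pYX`, `pYY`, `qXX`, `qYY`, `qXY`, `qYX`, `aX`, `aY`.
#' Demographic keys default to `r = 25`, `v = 1`, `b = 0.3`, activities to 1,
#' and heterospecific remating probabilities to 0; `c` and the remaining six
#' acceptance probabilities must be supplied.
#'
#' @param file path to a `.json`, `.yaml` or `.yml` file.
#' @return A [community_params] object.
#' @export
read_community_config <- function(file) {
  if (!file.exists(file)) stop("config file not found: ", file, call. = FALSE)
  cfg <- if (grepl("\\.json$", file, ignore.case = TRUE)) {
    jsonlite::fromJSON(file)
  } else {
    yaml::read_yaml(file)
  }
  if (!is.list(cfg)) stop("config must be a mapping of parameter names", call. = FALSE)
  known <- c("r", "v", "b", "c", "pXX", "pXY", "pYX", "pYY",
             "qXX", "qYY", "qXY", "qYX", "aX", "aY")
  extra <- setdiff(names(cfg), known)
  if (length(extra)) {
    stop("unknown config keys: ", paste(extra, collapse = ", "), call. = FALSE)
  }
  need <- c("c", "pXX", "pXY", "pYX", "pYY", "qXX", "qYY")
  missing <- setdiff(need, names(cfg))
  if (length(missing)) {
    stop("config is missing required keys: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  get <- function(key, default) if (!is.null(cfg[[key]])) cfg[[key]] else default
  probs <- mating_probabilities(
    pXX = cfg$pXX, pXY = cfg$pXY, pYX = cfg$pYX, pYY = cfg$pYY,
    qXX = cfg$qXX, qYY = cfg$qYY,
    qXY = get("qXY", 0), qYX = get("qYX", 0)
  )
  community_params(probs, c = cfg$c, r = get("r", 25), v = get("v", 1),
                   b = get("b", 0.3), aX = get("aX", 1), aY = get("aY", 1))
}
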