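# Mating decision-making tree: probability of securing conspecific sperm and
# the expected fecundity it implies.
#
# A female encounters suitors whose species is drawn by (activity-weighted)
# frequency. Her first mating always happens eventually: rejected suitors are
# simply redrawn (virgin acceptance probabilities p). She then has at most
# max_matings - 1 further mating opportunities; at each she assesses a single
# suitor and accepts with the once-mated probability q, a rejection wasting
# that opportunity. Under complete conspecific sperm precedence her fecundity
# is full whenever at least one accepted mate was conspecific.

.focal_probs <- function(probs, focal) {
  if (focal == "X") {
    list(p_con = probs$pXX, p_het = probs$pXY,
         q_con = probs$qXX, q_het = probs$qXY)
  } else {
    list(p_con = probs$pYY, p_het = probs$pYX,
         q_con = probs$qYY, q_het = probs$qYX)
  }
}

.check_focal <- function(focal) {
  if (!(is.character(focal) && length(focal) == 1L && focal %in% c("X", "Y"))) {
    stop("'focal' must be \"X\" or \"Y\"", call. = FALSE)
  }
  focal
}

.encounter_weights <- function(NX, NY, focal, activities) {
  wX <- activities[[1L]] * NX
  wY <- activities[[2L]] * NY
  if (wX + wY <= 0) {
    stop("both densities are zero: species frequency is undefined", call. = FALSE)
  }
  if (focal == "X") c(own = wX, other = wY) else c(own = wY, other = wX)
}

#' Probability that a female mates with a conspecific male at least once
#'
#' Evaluates the mating decision-making tree for a focal female: the
#' conditional probability (given she is subject to interspecific mate
#' encounters at all) that at least one of her at most `max_matings` matings
#' is conspecific, so that conspecific sperm precedence secures her full
#' fecundity. For `max_matings = 2` this is the closed form
#' \deqn{P_X = \frac{(p_{XX} + p_{XY} q_{XX} f_Y)\, f_X}{f_X p_{XX} + f_Y p_{XY}},}
#' with (activity-weighted) frequencies \eqn{f_X = a_X N_X / (a_X N_X + a_Y N_Y)};
#' for larger `max_matings` it is computed by exact dynamic programming over
#' mating-count states `(i, j)` (`i` conspecific, `j` heterospecific matings,
#' `i + j <= max_matings`).
#'
#' @param probs a [mating_probabilities] object.
#' @param NX,NY current population densities (non-negative, not both zero).
#' @param focal `"X"` or `"Y"`: the female's species.
#' @param max_matings maximum number of matings per female (>= 1; default 2).
#' @param activities length-2 vector of male encounter-activity weights
#'   `(aX, aY)` (default equal).
#' @return A probability in `[0, 1]`. If no male is acceptable to a virgin
#'   (`f_X p_con + f_Y p_het = 0`) the female never mates; the function warns
#'   and returns 0.
#' @examples
#' conspecific_mating_probability(example_mating_probs(), 1, 1, "X") # 0.4667
#' conspecific_mating_probability(example_mating_probs(), 1, 1, "Y") # 0.8
#' @export
conspecific_mating_probability <- function(probs, NX, NY, focal,
                                           max_matings = 2,
                                           activities = c(1, 1)) {
  if (!inherits(probs, "mating_probabilities")) {
    stop("'probs' must be a mating_probabilities object", call. = FALSE)
  }
  .check_focal(focal)
  if (!is.numeric(max_matings) || length(max_matings) != 1L || max_matings < 1 ||
      max_matings != round(max_matings)) {
    stop("'max_matings' must be a positive integer", call. = FALSE)
  }
  if (NX < 0 || NY < 0) stop("densities must be non-negative", call. = FALSE)
  if (any(activities <= 0)) stop("activities must be > 0", call. = FALSE)
  w <- .encounter_weights(NX, NY, focal, activities)
  f_own <- w[["own"]] / sum(w)
  fp <- .focal_probs(probs, focal)

  # probability the first accepted suitor is conspecific (rejections redraw)
  denom <- f_own * fp$p_con + (1 - f_own) * fp$p_het
  if (denom == 0) {
    warning("no male is acceptable to a virgin female; returning 0")
    return(0)
  }
  first_con <- f_own * fp$p_con / denom

  if (max_matings == 1) return(first_con)
  if (max_matings == 2) {
    # closed form: second opportunity is a single encounter under q
    return(first_con + (1 - first_con) * f_own * fp$q_con)
  }
  .mating_chain_prob(first_con, f_own, fp$q_con, fp$q_het, max_matings)
}

# Dynamic programme over mating-count states (i, j): occupancy after the
# first mating is (1,0) w.p. first_con, (0,1) otherwise; each of the
# max_matings - 1 remaining opportunities moves (i,j) -> (i+1,j) w.p.
# f_own*q_con, -> (i,j+1) w.p. (1-f_own)*q_het, else stays (rejection).
# Returns P(i >= 1) at the end.
.mating_chain_prob <- function(first_con, f_own, q_con, q_het, m) {
  acc_con <- f_own * q_con
  acc_het <- (1 - f_own) * q_het
  stay <- 1 - acc_con - acc_het
  occ <- matrix(0, nrow = m + 1L, ncol = m + 1L) # occ[i+1, j+1] = P(state (i,j))
  occ[2L, 1L] <- first_con
  occ[1L, 2L] <- 1 - first_con
  for (step in seq_len(m - 1L)) {
    nxt <- occ * stay
    nxt[-1L, ] <- nxt[-1L, ] + occ[-(m + 1L), ] * acc_con
    nxt[, -1L] <- nxt[, -1L] + occ[, -(m + 1L)] * acc_het
    occ <- nxt
  }
  sum(occ[-1L, ])
}

#' Expected per-capita fecundity of each species
#'
#' With probability `1 - c` a female reproduces free of interspecific
#' interference and realises the full egg production `r`; with probability `c`
#' she enters the mating decision-making tree and realises `r` only if she
#' secures at least one conspecific mating. Hence
#' \deqn{E_i = [(1 - c) + c\, P_i]\, r,}
#' bounded between `(1 - c) r` and `r`.
#'
#' @param params a [community_params] object.
#' @param NX,NY current population densities (not both zero).
#' @param max_matings maximum number of matings per female (default 2).
#' @return Named numeric vector `c(EX = , EY = )`.
#' @examples
#' pars <- community_params(example_mating_probs(), c = 0.9)
#' expected_fecundity(pars, 1, 1) # EX = 13, EY = 20.5
#' @export
expected_fecundity <- function(params, NX, NY, max_matings = 2) {
  stopifnot(inherits(params, "community_params"))
  acts <- c(params$aX, params$aY)
  PX <- conspecific_mating_probability(params$probs, NX, NY, "X",
                                       max_matings, acts)
  PY <- conspecific_mating_probability(params$probs, NX, NY, "Y",
                                       max_matings, acts)
  r <- params$r
  cc <- params$c
  c(EX = ((1 - cc) + cc * PX) * r, EY = ((1 - cc) + cc * PY) * r)
}
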