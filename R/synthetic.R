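# Seeded synthetic-data generators: an individual-based Monte-Carlo walk of
# the mating decision-making tree (the independent oracle for the closed-form
# probability) and a mating-trial session simulator with the statistical
# structure of paired one-female/one-male trials.

#' Monte-Carlo simulation of the mating decision-making tree
#'
#' Walks the tree individual by individual: each encounter is conspecific with
#' probability `w_focal / (w_X + w_Y)` (activity-weighted frequencies); the
#' first mating is found by redrawing rejected suitors (virgin acceptance
#' probabilities `p`), after which the female has `max_matings - 1` further
#' opportunities, each a single suitor accepted with the once-mated
#' probability `q` (a rejection wastes the opportunity). The estimate is the
#' fraction of replicate females with at least one conspecific mating.
#'
#' @inheritParams conspecific_mating_probability
#' @param n_rep number of replicate females (>= 1).
#' @param seed integer seed (required; the global RNG state is untouched).
#' @return A list with `estimate`, `se` (binomial standard error) and `n_rep`.
#' @examples
#' simulate_decision_tree(example_mating_probs(), 1, 1, "X",
#'                        n_rep = 1e4, seed = 1)
#' @export
simulate_decision_tree <- function(probs, NX, NY, focal, max_matings = 2,
                                   n_rep, seed, activities = c(1, 1)) {
  stopifnot(inherits(probs, "mating_probabilities"))
  .check_focal(focal)
  if (n_rep < 1) stop("'n_rep' must be >= 1", call. = FALSE)
  if (missing(seed)) stop("'seed' is required", call. = FALSE)
  w <- .encounter_weights(NX, NY, focal, activities)
  f_own <- w[["own"]] / sum(w)
  fp <- .focal_probs(probs, focal)
  if (f_own * fp$p_con + (1 - f_own) * fp$p_het == 0) {
    warning("no male is acceptable to a virgin female; estimate is 0")
    return(list(estimate = 0, se = 0, n_rep = n_rep))
  }
  got_con <- withr::with_seed(seed, {
    n <- as.integer(n_rep)
    first_con <- logical(n)
    unresolved <- seq_len(n)
    while (length(unresolved)) {
      enc_con <- runif(length(unresolved)) < f_own
      acc <- runif(length(unresolved)) <
        ifelse(enc_con, fp$p_con, fp$p_het)
      first_con[unresolved[acc & enc_con]] <- TRUE
      unresolved <- unresolved[!acc]
    }
    got <- first_con
    if (max_matings >= 2) {
      for (k in seq_len(max_matings - 1L)) {
        enc_con <- runif(n) < f_own
        acc <- runif(n) < ifelse(enc_con, fp$q_con, fp$q_het)
        got <- got | (enc_con & acc)
      }
    }
    got
  })
  est <- mean(got_con)
  list(estimate = est, se = sqrt(est * (1 - est) / n_rep), n_rep = n_rep)
}

#' Design table for synthetic mating-trial sessions
#'
#' Builds the per-combination design (female species x male species x year)
#' for [simulate_sessions()]. Probabilities marked `_con` apply when female
#' and male are conspecific, `_het` otherwise.
#'
#' @param species two species labels (default `c("A", "B")`).
#' @param years vector of year labels (default `2014`).
#' @param n_sessions sessions per combination and year.
#' @param attempt_con,attempt_het probability that a session contains at least
#'   one male mating attempt.
#' @param reject_con,reject_het probability that an individual attempt elicits
#'   female rejection.
#' @param coercion probability that a rejected attempt nevertheless ends in
#'   copulation (coercive mating).
#' @param copulation probability that an accepted (non-rejected) attempt ends
#'   in copulation.
#' @param mean_extra_attempts Poisson mean of additional attempts beyond the
#'   first in sessions where attempts occur (default 1).
#' @return A data frame with one row per combination, of class
#'   `session_design`.
#' @export
session_design <- function(species = c("A", "B"), years = 2014,
                           n_sessions = 50,
                           attempt_con = 0.6, attempt_het = 0.3,
                           reject_con = 0.2, reject_het = 0.6,
                           coercion = 0.1, copulation = 0.9,
                           mean_extra_attempts = 1) {
  if (length(species) != 2L) stop("'species' must name two species", call. = FALSE)
  probs <- c(attempt_con, attempt_het, reject_con, reject_het, coercion,
             copulation)
  if (any(probs < 0 | probs > 1)) {
    stop("all probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (n_sessions < 1) stop("'n_sessions' must be positive", call. = FALSE)
  grid <- expand.grid(female_species = species, male_species = species,
                      year = years, stringsAsFactors = FALSE)
  con <- grid$female_species == grid$male_species
  grid$n_sessions <- n_sessions
  grid$attempt_prob <- ifelse(con, attempt_con, attempt_het)
  grid$reject_prob <- ifelse(con, reject_con, reject_het)
  grid$coercion_prob <- coercion
  grid$copulation_prob <- copulation
  grid$mean_extra_attempts <- mean_extra_attempts
  structure(grid, class = c("session_design", "data.frame"))
}

#' Simulate mating-trial session records
#'
#' Each session holds one female and one male. Whether the session contains
#' any mating attempt is Bernoulli(`attempt_prob`); the number of attempts is
#' then 1 plus a Poisson(`mean_extra_attempts`) excess. Each attempt is
#' rejected with `reject_prob`; a non-rejected attempt ends in copulation with
#' `copulation_prob`, a rejected one with `coercion_prob` (coercive mating).
#'
#' @param design a [session_design] data frame.
#' @param seed integer seed (required; the global RNG state is untouched).
#' @return A data frame of session records with columns `female_species`,
#'   `male_species`, `year`, `n_attempts`, `n_rejections`, `copulated`.
#' @examples
#' sessions <- simulate_sessions(session_design(n_sessions = 20), seed = 1)
#' head(sessions)
#' @export
simulate_sessions <- function(design, seed) {
  stopifnot(inherits(design, "session_design") || is.data.frame(design))
  if (missing(seed)) stop("'seed' is required", call. = FALSE)
  need <- c("female_species", "male_species", "year", "n_sessions",
            "attempt_prob", "reject_prob", "coercion_prob", "copulation_prob",
            "mean_extra_attempts")
  missing_cols <- setdiff(need, names(design))
  if (length(missing_cols)) {
    stop("design is missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  withr::with_seed(seed, {
    rows <- lapply(seq_len(nrow(design)), function(i) {
      d <- design[i, ]
      n <- d$n_sessions
      occurs <- runif(n) < d$attempt_prob
      n_attempts <- ifelse(occurs, 1L + rpois(n, d$mean_extra_attempts), 0L)
      n_rejections <- rbinom(n, n_attempts, d$reject_prob)
      n_cop <- rbinom(n, n_attempts - n_rejections, d$copulation_prob) +
        rbinom(n, n_rejections, d$coercion_prob)
      data.frame(female_species = d$female_species,
                 male_species = d$male_species,
                 year = d$year,
                 n_attempts = n_attempts,
                 n_rejections = n_rejections,
                 copulated = as.integer(n_cop > 0))
    })
    do.call(rbind, rows)
  })
}
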