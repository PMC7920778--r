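# Shared test helpers: independent oracles and random-case generators.

# Independent closed-form oracle for the conspecific-mating probability:
# derived directly from the tree semantics (first mate by redraw, then m - 1
# single-encounter opportunities), bypassing the package's DP/Eq.-1 code path.
oracle_P <- function(probs, NX, NY, focal, m = 2, activities = c(1, 1)) {
  wX <- activities[1] * NX
  wY <- activities[2] * NY
  if (focal == "X") {
    f <- wX / (wX + wY); p_con <- probs$pXX; p_het <- probs$pXY; q_con <- probs$qXX
  } else {
    f <- wY / (wX + wY); p_con <- probs$pYY; p_het <- probs$pYX; q_con <- probs$qYY
  }
  denom <- f * p_con + (1 - f) * p_het
  if (denom == 0) return(0)
  A <- f * p_con / denom
  A + (1 - A) * (1 - (1 - f * q_con)^(m - 1))
}

random_probs <- function(lo = 0.1, hi = 1) {
  mating_probabilities(pXX = runif(1, lo, hi), pXY = runif(1, lo, hi),
                       pYX = runif(1, lo, hi), pYY = runif(1, lo, hi),
                       qXX = runif(1, 0, 1), qYY = runif(1, 0, 1),
                       qXY = runif(1, 0, 1), qYX = runif(1, 0, 1))
}

random_params <- function() {
  community_params(random_probs(), c = runif(1), r = runif(1, 1, 50),
                   v = runif(1, 0.5, 2), b = runif(1))
}

# midrank (Mann-Whitney) AUC, used by the bootstrap oracle
rank_auc <- function(cases, controls) {
  m <- length(cases)
  r <- rank(c(cases, controls))
  (sum(r[seq_len(m)]) - m * (m + 1) / 2) / (m * length(controls))
}

# Stratified-bootstrap oracle for the unpaired AUC comparison: resample each
# group's cases and controls, form the difference distribution, and convert
# the observed difference to a normal-reference two-sided p.
boot_delong_p <- function(a, b, B = 1e4) {
  ca <- a$scores[a$labels]; na <- a$scores[!a$labels]
  cb <- b$scores[b$labels]; nb <- b$scores[!b$labels]
  obs <- rank_auc(ca, na) - rank_auc(cb, nb)
  diffs <- replicate(B, {
    rank_auc(sample(ca, replace = TRUE), sample(na, replace = TRUE)) -
      rank_auc(sample(cb, replace = TRUE), sample(nb, replace = TRUE))
  })
  s <- stats::sd(diffs)
  if (s == 0) return(as.numeric(obs == 0))
  2 * stats::pnorm(-abs(obs) / s)
}

fig_portrait_params <- function(c) community_params(example_mating_probs(), c = c)
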