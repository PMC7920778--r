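# Unpaired DeLong comparison of two AUCs.
#
# AUC is estimated by the Mann-Whitney statistic with ties counted one half.
# Its sampling variance comes from the DeLong structural components: the
# placement of each signal score among the noise scores and vice versa.

#' Construct a score sample for ROC analysis
#'
#' @param labels logical or 0/1 vector: `TRUE`/1 marks a signal (case)
#'   observation, `FALSE`/0 a noise (control) observation.
#' @param scores numeric scores aligned with `labels` (higher = more
#'   signal-like).
#' @return An object of class `score_sample`.
#' @export
score_sample <- function(labels, scores) {
  labels <- as.logical(labels)
  if (length(labels) != length(scores)) {
    stop("'labels' and 'scores' must have the same length", call. = FALSE)
  }
  if (any(is.na(labels)) || any(!is.finite(scores))) {
    stop("labels and scores must be complete and finite", call. = FALSE)
  }
  if (!any(labels) || all(labels)) {
    stop("a score sample needs at least one signal and one noise observation",
         call. = FALSE)
  }
  structure(list(labels = labels, scores = as.numeric(scores)),
            class = "score_sample")
}

#' Rebuild per-observation binary scores from contingency counts
#'
#' Expands a 2x2 table into the 0/1 decision scores that produced it, suitable
#' for [delong_unpaired()].
#'
#' @param counts a [contingency_counts] object.
#' @return A [score_sample].
#' @export
counts_to_scores <- function(counts) {
  stopifnot(inherits(counts, "contingency_counts"))
  score_sample(
    labels = rep(c(TRUE, FALSE),
                 c(counts$hit + counts$miss,
                   counts$false_alarm + counts$correct_rejection)),
    scores = c(rep(1, counts$hit), rep(0, counts$miss),
               rep(1, counts$false_alarm), rep(0, counts$correct_rejection))
  )
}

# DeLong placements: theta (AUC), X (placement of each case among controls),
# Y (placement of each control among cases)
.delong_placements <- function(sample) {
  cases <- sample$scores[sample$labels]
  controls <- sample$scores[!sample$labels]
  psi <- outer(cases, controls,
               function(x, y) (x > y) + 0.5 * (x == y))
  list(theta = mean(psi), X = rowMeans(psi), Y = colMeans(psi),
       m = length(cases), n = length(controls))
}

.delong_var <- function(pl) {
  sx <- if (pl$m > 1) var(pl$X) else 0
  sy <- if (pl$n > 1) var(pl$Y) else 0
  sx / pl$m + sy / pl$n
}

#' Unpaired DeLong test comparing two AUCs
#'
#' Estimates each sample's AUC by the Mann-Whitney statistic (ties one half)
#' and its variance from the DeLong structural components, forms
#' `D = (aucA - aucB) / sqrt(varA + varB)`, and returns a two-sided p-value
#' from a t reference with Welch-Satterthwaite degrees of freedom (the
#' convention that yields fractional df; set `normal_ref = TRUE` for the
#' standard-normal reference instead).
#'
#' @param a,b [score_sample] objects (independent groups).
#' @param normal_ref use the standard normal instead of the t reference
#'   (default `FALSE`).
#' @return An object of class `delong_result`: a list with `aucA`, `aucB`,
#'   `D`, `df`, `p`.
#' @examples
#' a <- score_sample(rep(c(1, 0), each = 20), c(rnorm(20, 1), rnorm(20)))
#' b <- score_sample(rep(c(1, 0), each = 20), rnorm(40))
#' delong_unpaired(a, b)
#' @export
delong_unpaired <- function(a, b, normal_ref = FALSE) {
  if (!inherits(a, "score_sample")) a <- score_sample(a$labels, a$scores)
  if (!inherits(b, "score_sample")) b <- score_sample(b$labels, b$scores)
  pa <- .delong_placements(a)
  pb <- .delong_placements(b)
  va <- .delong_var(pa)
  vb <- .delong_var(pb)
  diff <- pa$theta - pb$theta
  if (va + vb == 0) {
    D <- if (diff == 0) 0 else sign(diff) * Inf
    df <- NA_real_
    p <- if (diff == 0) 1 else 0
  } else {
    D <- diff / sqrt(va + vb)
    na <- pa$m + pa$n
    nb <- pb$m + pb$n
    df <- (va + vb)^2 / (va^2 / (na - 1) + vb^2 / (nb - 1))
    p <- if (normal_ref) 2 * pnorm(-abs(D)) else 2 * pt(-abs(D), df)
  }
  structure(list(aucA = pa$theta, aucB = pb$theta, D = D, df = df, p = p),
            class = "delong_result")
}

#' @export
print.delong_result <- function(x, ...) {
  cat(sprintf("DeLong unpaired AUC comparison: %.3f vs %.3f, D = %.3f, df = %.1f, p = %.4g\n",
              x$aucA, x$aucB, x$D, x$df, x$p))
  invisible(x)
}
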