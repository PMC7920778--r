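# Signal-detection analysis of mating-trial contingency counts.
#
# A behavioural response is scored against the "correct" signal: for male
# mating attempts the correct signal is a conspecific female (a hit is an
# attempt towards her); for female rejection behaviour the correct signal is a
# heterospecific male (a hit is rejecting him).

#' Contingency counts for one behaviour, species and year
#'
#' @param hit,miss responses to the correct signal (present / absent).
#' @param false_alarm,correct_rejection responses to the false signal
#'   (present / absent).
#' @param behavior `"male_mating_attempt"` or `"female_rejection"` (optional
#'   metadata).
#' @param species,year optional labels.
#' @return An object of class `contingency_counts`.
#' @examples
#' contingency_counts(47, 40, 10, 32)
#' @export
contingency_counts <- function(hit, miss, false_alarm, correct_rejection,
                               behavior = NA_character_,
                               species = NA_character_, year = NA) {
  counts <- c(hit = hit, miss = miss, false_alarm = false_alarm,
              correct_rejection = correct_rejection)
  if (any(!is.finite(counts)) || any(counts < 0) ||
      any(counts != round(counts))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  if (hit + miss <= 0) {
    stop("no observations of the correct signal (hit + miss = 0)", call. = FALSE)
  }
  if (false_alarm + correct_rejection <= 0) {
    stop("no observations of the false signal (false_alarm + correct_rejection = 0)",
         call. = FALSE)
  }
  if (!is.na(behavior) &&
      !behavior %in% c("male_mating_attempt", "female_rejection")) {
    stop("unknown behavior label: ", behavior, call. = FALSE)
  }
  structure(list(hit = hit, miss = miss, false_alarm = false_alarm,
                 correct_rejection = correct_rejection,
                 behavior = behavior, species = species, year = year),
            class = "contingency_counts")
}

#' @export
print.contingency_counts <- function(x, ...) {
  cat(sprintf("contingency counts%s%s%s: hit %d, miss %d, FA %d, CR %d\n",
              if (is.na(x$behavior)) "" else paste0(" [", x$behavior, "]"),
              if (is.na(x$species)) "" else paste0(" ", x$species),
              if (is.na(x$year)) "" else paste0(" ", x$year),
              x$hit, x$miss, x$false_alarm, x$correct_rejection))
  invisible(x)
}

#' Log-linear-corrected hit and false-alarm rates
#'
#' Applies the log-linear correction (add 0.5 to each response count and 1 to
#' each signal total) to every cell, keeping both rates strictly inside
#' `(0, 1)` so the normal quantile transform is always defined:
#' `H = (hit + 0.5) / (hit + miss + 1)`,
#' `F = (false_alarm + 0.5) / (false_alarm + correct_rejection + 1)`.
#'
#' @param counts a [contingency_counts] object.
#' @return Named numeric vector `c(hit_rate = , fa_rate = )`.
#' @examples
#' corrected_rates(contingency_counts(47, 40, 10, 32))
#' @export
corrected_rates <- function(counts) {
  stopifnot(inherits(counts, "contingency_counts"))
  c(hit_rate = (counts$hit + 0.5) / (counts$hit + counts$miss + 1),
    fa_rate = (counts$false_alarm + 0.5) /
      (counts$false_alarm + counts$correct_rejection + 1))
}

#' Signal-detection indices d', beta and criterion
#'
#' With `z()` the standard normal quantile and corrected rates `H`, `F`:
#' sensitivity `d' = z(H) - z(F)` (separation of the signal and noise
#' distributions in standard-normal units), decision criterion
#' `cr = -(z(H) + z(F)) / 2`, and response bias
#' `beta = exp((z(F)^2 - z(H)^2) / 2)`, the likelihood ratio of the two normal
#' densities at the criterion (`beta > 1`: conservative, `beta < 1`: liberal).
#' The identity `beta = exp(d' * cr)` holds exactly.
#'
#' @param counts a [contingency_counts] object.
#' @return An object of class `sdt_result`: a list with `hit_rate`, `fa_rate`,
#'   `dprime`, `beta`, `criterion`.
#' @examples
#' sdt_statistics(contingency_counts(47, 40, 10, 32)) # d' ~ 0.793
#' @export
sdt_statistics <- function(counts) {
  rates <- corrected_rates(counts)
  zH <- qnorm(rates[["hit_rate"]])
  zF <- qnorm(rates[["fa_rate"]])
  structure(list(hit_rate = rates[["hit_rate"]], fa_rate = rates[["fa_rate"]],
                 dprime = zH - zF,
                 beta = exp((zF^2 - zH^2) / 2),
                 criterion = -(zH + zF) / 2),
            class = "sdt_result")
}

#' @export
print.sdt_result <- function(x, ...) {
  cat(sprintf("d' = %.3f, beta = %.3f, criterion = %.3f (H = %.3f, F = %.3f)\n",
              x$dprime, x$beta, x$criterion, x$hit_rate, x$fa_rate))
  invisible(x)
}

#' ROC points and AUC of a binary decision
#'
#' For a yes/no decision the empirical ROC has a single interior point at the
#' uncorrected rates `(f, h)`; with ties counted one half the area under the
#' two-segment curve is `AUC = (1 + h - f) / 2`.
#'
#' @param counts a [contingency_counts] object.
#' @return A list with `auc` and `roc` (a data frame of the points
#'   `(0,0), (f,h), (1,1)` with columns `fpr`, `tpr`).
#' @examples
#' binary_auc(contingency_counts(47, 40, 10, 32))$auc # 0.651
#' @export
binary_auc <- function(counts) {
  stopifnot(inherits(counts, "contingency_counts"))
  h <- counts$hit / (counts$hit + counts$miss)
  f <- counts$false_alarm / (counts$false_alarm + counts$correct_rejection)
  list(auc = (1 + h - f) / 2,
       roc = data.frame(fpr = c(0, f, 1), tpr = c(0, h, 1)))
}

#' Read a contingency-counts table from CSV
#'
#' Expects the columns `behavior`, `year`, `species`, `hit`, `miss`,
#' `false_alarm`, `correct_rejection` (the layout written by
#' [make_fixtures()]).
#'
#' @param file path to the CSV file.
#' @return A data frame with those columns.
#' @export
read_counts <- function(file) {
  if (!file.exists(file)) stop("counts file not found: ", file, call. = FALSE)
  df <- read.csv(file, stringsAsFactors = FALSE)
  need <- c("behavior", "year", "species", "hit", "miss", "false_alarm",
            "correct_rejection")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop("counts file is missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  df
}

#' Signal-detection summary table
#'
#' Applies [sdt_statistics()] and [binary_auc()] row-wise to a counts table
#' (as returned by [read_counts()] or [sessions_to_counts()]).
#'
#' @param counts_df data frame with columns `behavior`, `year`, `species`,
#'   `hit`, `miss`, `false_alarm`, `correct_rejection`.
#' @return The input with appended columns `hit_rate`, `fa_rate`, `dprime`,
#'   `beta`, `criterion`, `auc`.
#' @export
sdt_table <- function(counts_df) {
  stopifnot(is.data.frame(counts_df), nrow(counts_df) > 0)
  res <- lapply(seq_len(nrow(counts_df)), function(i) {
    row <- counts_df[i, ]
    cc <- contingency_counts(row$hit, row$miss, row$false_alarm,
                             row$correct_rejection)
    s <- sdt_statistics(cc)
    data.frame(hit_rate = s$hit_rate, fa_rate = s$fa_rate, dprime = s$dprime,
               beta = s$beta, criterion = s$criterion, auc = binary_auc(cc)$auc)
  })
  cbind(counts_df, do.call(rbind, res))
}

#' Collapse mating-trial session records into contingency counts
#'
#' For `behavior = "male_mating_attempt"` the unit is the session and the
#' responder is the male: the correct signal is a conspecific female, and the
#' response is "at least one mating attempt in the session". For
#' `behavior = "female_rejection"` the unit is the individual attempt and the
#' responder is the female: the correct signal is a heterospecific male, and
#' the response is a rejection.
#'
#' @param sessions data frame with columns `female_species`, `male_species`,
#'   `year`, `n_attempts`, `n_rejections`, `copulated` (as produced by
#'   [simulate_sessions()]).
#' @param behavior `"male_mating_attempt"` or `"female_rejection"`.
#' @return A data frame of counts, one row per (species, year), with columns
#'   `behavior`, `year`, `species`, `hit`, `miss`, `false_alarm`,
#'   `correct_rejection`.
#' @export
sessions_to_counts <- function(sessions, behavior) {
  need <- c("female_species", "male_species", "year", "n_attempts",
            "n_rejections")
  missing <- setdiff(need, names(sessions))
  if (length(missing)) {
    stop("sessions table is missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (!behavior %in% c("male_mating_attempt", "female_rejection")) {
    stop("unknown behavior label: ", behavior, call. = FALSE)
  }
  species <- sort(unique(c(sessions$female_species, sessions$male_species)))
  years <- sort(unique(sessions$year))
  rows <- list()
  for (yr in years) {
    sy <- sessions[sessions$year == yr, ]
    for (sp in species) {
      if (behavior == "male_mating_attempt") {
        own <- sy[sy$male_species == sp, ]
        if (!nrow(own)) next
        con <- own$female_species == sp
        attempted <- own$n_attempts >= 1
        row <- data.frame(behavior = behavior, year = yr, species = sp,
                          hit = sum(con & attempted),
                          miss = sum(con & !attempted),
                          false_alarm = sum(!con & attempted),
                          correct_rejection = sum(!con & !attempted))
      } else {
        own <- sy[sy$female_species == sp, ]
        if (!nrow(own)) next
        het <- own$male_species != sp
        row <- data.frame(behavior = behavior, year = yr, species = sp,
                          hit = sum(own$n_rejections[het]),
                          miss = sum(own$n_attempts[het] - own$n_rejections[het]),
                          false_alarm = sum(own$n_rejections[!het]),
                          correct_rejection = sum(own$n_attempts[!het] -
                                                    own$n_rejections[!het]))
      }
      rows[[length(rows) + 1L]] <- row
    }
  }
  do.call(rbind, rows)
}
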