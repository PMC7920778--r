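test_that("log-linear correction gives strictly interior rates", {
  r1 <- corrected_rates(contingency_counts(47, 40, 10, 32))
  expect_equal(r1[["hit_rate"]], 47.5 / 88, tolerance = 1e-12)
  expect_equal(r1[["fa_rate"]], 10.5 / 43, tolerance = 1e-12)
  # all-miss / all-correct-rejection cells stay inside (0, 1)
  r2 <- corrected_rates(contingency_counts(0, 10, 0, 10))
  expect_equal(unname(r2), c(0.5 / 11, 0.5 / 11), tolerance = 1e-12)
  r3 <- corrected_rates(contingency_counts(10, 10, 10, 10))
  expect_equal(unname(r3), c(0.5, 0.5))
  expect_error(contingency_counts(0, 0, 5, 5), "correct signal")
  expect_error(contingency_counts(5, 5, 0, 0), "false signal")
  expect_error(contingency_counts(1.5, 2, 3, 4), "non-negative integers")
})

test_that("d-prime, beta and criterion satisfy their identities", {
  s <- sdt_statistics(contingency_counts(47, 40, 10, 32))
  expect_equal(s$dprime, qnorm(47.5 / 88) - qnorm(10.5 / 43), tolerance = 1e-12)
  expect_equal(s$beta, exp(s$dprime * s$criterion), tolerance = 1e-10)
  # equal rates: no sensitivity, no bias
  s0 <- sdt_statistics(contingency_counts(10, 10, 10, 10))
  expect_equal(s0$dprime, 0)
  expect_equal(s0$beta, 1)
  withr::with_seed(301, {
    for (i in 1:20) {
      n <- sample(1:200, 4)
      a <- sdt_statistics(contingency_counts(n[1], n[2], n[3], n[4]))
      # antisymmetry: swapping signal and noise responses negates d and inverts beta
      b <- sdt_statistics(contingency_counts(n[3], n[4], n[1], n[2]))
      expect_equal(b$dprime, -a$dprime, tolerance = 1e-10)
      expect_equal(b$beta, 1 / a$beta, tolerance = 1e-10)
      expect_equal(a$beta, exp(a$dprime * a$criterion), tolerance = 1e-10)
    }
  })
})

test_that("binary AUC follows the two-segment ROC formula", {
  res <- binary_auc(contingency_counts(47, 40, 10, 32))
  expect_equal(res$auc, (1 + 47 / 87 - 10 / 42) / 2, tolerance = 1e-12)
  expect_equal(res$roc$fpr, c(0, 10 / 42, 1))
  expect_equal(binary_auc(contingency_counts(10, 10, 10, 10))$auc, 0.5)
  expect_equal(binary_auc(contingency_counts(10, 0, 0, 10))$auc, 1)
  withr::with_seed(302, {
    for (i in 1:10) {
      n <- sample(1:100, 4)
      cc <- contingency_counts(n[1], n[2], n[3], n[4])
      h <- n[1] / (n[1] + n[2]); f <- n[3] / (n[3] + n[4])
      auc <- binary_auc(cc)$auc
      expect_equal(auc, 0.5 + (h - f) / 2, tolerance = 1e-12)
      expect_gte(auc, 0); expect_lte(auc, 1)
      # the binary AUC equals the midrank AUC of the reconstructed 0/1 scores
      sc <- counts_to_scores(cc)
      expect_equal(auc, rank_auc(sc$scores[sc$labels], sc$scores[!sc$labels]),
                   tolerance = 1e-12)
    }
  })
})

test_that("unpaired DeLong test matches pROC and behaves at the extremes", {
  # identical samples: no difference by construction
  a <- score_sample(rep(c(TRUE, FALSE), each = 30),
                    c(seq(0, 1, length.out = 30), seq(-0.5, 0.6, length.out = 30)))
  res0 <- delong_unpaired(a, a)
  expect_equal(res0$D, 0)
  expect_equal(res0$p, 1)
  # perfect separation vs chance: strongly significant, positive sign
  withr::with_seed(303, {
    perf <- score_sample(rep(c(TRUE, FALSE), each = 50),
                         c(runif(50, 1, 2), runif(50, 0, 0.5)))
    chance <- score_sample(rep(c(TRUE, FALSE), each = 50), rnorm(100))
    res1 <- delong_unpaired(perf, chance)
    expect_equal(res1$aucA, 1)
    expect_gt(res1$D, 0)
    expect_lt(res1$p, 0.01)
    # agreement with the reference implementation across random scenarios
    for (i in 1:8) {
      na <- sample(20:80, 2)
      nb <- sample(20:80, 2)
      a_i <- score_sample(rep(c(TRUE, FALSE), c(na[1], na[2])),
                          c(rnorm(na[1], runif(1, 0, 1.5)), rnorm(na[2])))
      b_i <- score_sample(rep(c(TRUE, FALSE), c(nb[1], nb[2])),
                          c(rnorm(nb[1], runif(1, 0, 1.5)), rnorm(nb[2])))
      mine <- delong_unpaired(a_i, b_i)
      ra <- pROC::roc(a_i$labels, a_i$scores, quiet = TRUE, direction = "<")
      rb <- pROC::roc(b_i$labels, b_i$scores, quiet = TRUE, direction = "<")
      ref <- pROC::roc.test(ra, rb, method = "delong", paired = FALSE)
      expect_equal(mine$aucA, as.numeric(pROC::auc(ra)), tolerance = 1e-12)
      expect_equal(mine$D, unname(ref$statistic), tolerance = 1e-9)
      expect_equal(mine$df, unname(ref$parameter), tolerance = 1e-6)
      expect_equal(mine$p, ref$p.value, tolerance = 1e-9)
    }
  })
  expect_error(score_sample(c(TRUE, TRUE), c(1, 2)), "at least one signal")
})

test_that("session records collapse to the correct contingency counts", {
  # deterministic design: males only ever court conspecific females
  des <- session_design(n_sessions = 40, attempt_con = 1, attempt_het = 0,
                        reject_con = 0, reject_het = 1)
  sessions <- simulate_sessions(des, seed = 11)
  counts <- sessions_to_counts(sessions, "male_mating_attempt")
  expect_equal(counts$hit, c(40, 40))
  expect_equal(counts$miss, c(0, 0))
  expect_equal(counts$false_alarm, c(0, 0))
  expect_equal(counts$correct_rejection, c(40, 40))
  # females reject every heterospecific attempt and accept every conspecific
  rej <- sessions_to_counts(sessions, "female_rejection")
  expect_true(all(rej$false_alarm == 0))
  expect_true(all(rej$miss == 0))
  # heterospecific sessions had no attempts here, so rejection hits are 0 too
  expect_true(all(rej$hit == 0))
  expect_error(sessions_to_counts(sessions, "grooming"), "unknown behavior")
  expect_error(sessions_to_counts(sessions[, 1:3], "female_rejection"),
               "missing columns")
})

test_that("the packaged counts fixture round-trips verbatim", {
  counts <- read_counts(response_counts_file())
  expect_equal(nrow(counts), 8L)
  row <- counts[counts$behavior == "male_mating_attempt" & counts$year == 2014 &
                  counts$species == "H. axyridis", ]
  expect_equal(unname(unlist(row[c("hit", "miss", "false_alarm",
                                   "correct_rejection")])),
               c(47, 40, 10, 32))
  # summary table computes every index for every printed row
  tab <- sdt_table(counts)
  expect_true(all(is.finite(tab$dprime)))
  expect_true(all(tab$beta > 0))
  expect_true(all(tab$auc >= 0 & tab$auc <= 1))
})
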