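test_that("two-shot conspecific mating probability matches worked values", {
  probs <- example_mating_probs()
  expect_equal(conspecific_mating_probability(probs, 1, 1, "X"), 0.28 / 0.6,
               tolerance = 1e-12)
  expect_equal(conspecific_mating_probability(probs, 1, 1, "Y"), 0.48 / 0.6,
               tolerance = 1e-12)
  # no heterospecific males: the first accepted mate must be conspecific
  expect_identical(conspecific_mating_probability(probs, 2, 0, "X"), 1)
  # focal species absent: it can never be encountered
  expect_identical(conspecific_mating_probability(probs, 0, 3, "X"), 0)
})

test_that("probability respects frequency limits and stays in [0, 1]", {
  withr::with_seed(101, {
    for (i in 1:25) {
      probs <- random_probs()
      NX <- runif(1, 0.1, 10)
      NY <- runif(1, 0.1, 10)
      P <- conspecific_mating_probability(probs, NX, NY, "X")
      expect_gte(P, 0)
      expect_lte(P, 1)
      # continuity/limits in own frequency
      expect_gt(conspecific_mating_probability(probs, 1e6, 1, "X"), P - 1e-12)
      expect_equal(conspecific_mating_probability(probs, 1e12, 1, "X"), 1,
                   tolerance = 1e-6)
      expect_lt(conspecific_mating_probability(probs, 1e-12, 1, "X"), 1e-6)
    }
  })
})

test_that("equal activity weights reproduce the unweighted result exactly", {
  withr::with_seed(102, {
    for (i in 1:10) {
      probs <- random_probs()
      NX <- runif(1, 0.1, 10)
      NY <- runif(1, 0.1, 10)
      a <- runif(1, 0.1, 5)
      expect_equal(
        conspecific_mating_probability(probs, NX, NY, "X", activities = c(a, a)),
        conspecific_mating_probability(probs, NX, NY, "X"),
        tolerance = 1e-14
      )
    }
  })
})

test_that("unequal activities bias the result through weighted frequencies", {
  probs <- example_mating_probs()
  # doubling X-male activity at equal densities equals doubling X density
  expect_equal(
    conspecific_mating_probability(probs, 1, 1, "X", activities = c(2, 1)),
    conspecific_mating_probability(probs, 2, 1, "X"),
    tolerance = 1e-12
  )
})

test_that("multiple-mating chain agrees with the closed form and is monotone", {
  withr::with_seed(103, {
    for (i in 1:15) {
      probs <- random_probs()
      NX <- runif(1, 0.1, 10)
      NY <- runif(1, 0.1, 10)
      P_prev <- 0
      for (m in c(1, 2, 3, 5, 10, 25)) {
        P <- conspecific_mating_probability(probs, NX, NY, "X", max_matings = m)
        expect_equal(P, oracle_P(probs, NX, NY, "X", m), tolerance = 1e-12)
        expect_gte(P, P_prev - 1e-12) # monotone whenever q_con >= 0
        P_prev <- P
      }
    }
  })
  # limit: many mating opportunities make conspecific sperm all but certain
  expect_gt(conspecific_mating_probability(example_mating_probs(), 1, 1, "X",
                                           max_matings = 50), 0.99)
})

test_that("expected fecundity matches the worked values and its bounds", {
  pars <- community_params(example_mating_probs(), c = 0.9)
  E <- expected_fecundity(pars, 1, 1)
  expect_equal(E[["EX"]], 13.0, tolerance = 1e-12)
  expect_equal(E[["EY"]], 20.5, tolerance = 1e-12)
  # no niche overlap: no interference, full output for any state
  pars0 <- community_params(example_mating_probs(), c = 0)
  expect_equal(unname(expected_fecundity(pars0, 3, 7)), c(25, 25))
  # heterospecifics absent: full output whatever the overlap
  expect_equal(expected_fecundity(pars, 4, 0)[["EX"]], 25)
  # affine bounds (1-c) r <= E <= r across random states
  withr::with_seed(104, {
    for (i in 1:10) {
      pars_i <- random_params()
      E_i <- expected_fecundity(pars_i, runif(1, 0.01, 10), runif(1, 0.01, 10))
      expect_true(all(E_i >= (1 - pars_i$c) * pars_i$r - 1e-12))
      expect_true(all(E_i <= pars_i$r + 1e-12))
    }
  })
})

test_that("degenerate inputs are rejected or flagged", {
  probs <- example_mating_probs()
  expect_error(conspecific_mating_probability(probs, 0, 0, "X"),
               "frequency is undefined")
  expect_error(conspecific_mating_probability(probs, 1, 1, "Z"), "focal")
  expect_error(conspecific_mating_probability(probs, 1, 1, "X", max_matings = 0),
               "positive integer")
  expect_error(mating_probabilities(1.2, 0.5, 0.5, 0.5, 0.5, 0.5), "\\[0, 1\\]")
  expect_error(community_params(probs, c = 1.5), "\\[0, 1\\]")
  expect_error(community_params(probs, c = 0.5, v = 0), "'v'")
  # no acceptable male at all: flagged and 0
  dead <- mating_probabilities(0, 0, 0.5, 0.5, 0.5, 0.5)
  expect_warning(P <- conspecific_mating_probability(dead, 1, 1, "X"),
                 "no male is acceptable")
  expect_identical(P, 0)
})

test_that("config files round-trip with defaults filled in", {
  cfg <- list(c = 0.9, pXX = 0.4, pXY = 0.8, pYX = 0.4, pYY = 0.8,
              qXX = 0.4, qYY = 0.8)
  json <- tempfile(fileext = ".json")
  jsonlite::write_json(cfg, json, auto_unbox = TRUE)
  pars <- read_community_config(json)
  expect_equal(pars$r, 25)
  expect_equal(pars$v, 1)
  expect_equal(pars$b, 0.3)
  expect_equal(pars$aX, 1)
  expect_equal(pars$probs$qXY, 0)
  expect_equal(pars$probs$pXY, 0.8)

  yml <- tempfile(fileext = ".yaml")
  yaml::write_yaml(c(cfg, list(r = 10, aY = 2)), yml)
  pars2 <- read_community_config(yml)
  expect_equal(pars2$r, 10)
  expect_equal(pars2$aY, 2)

  expect_error(read_community_config(tempfile()), "not found")
  jsonlite::write_json(list(c = 0.5), json, auto_unbox = TRUE)
  expect_error(read_community_config(json), "missing required keys")
  jsonlite::write_json(c(cfg, list(bogus = 1)), json, auto_unbox = TRUE)
  expect_error(read_community_config(json), "unknown config keys")
})
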