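test_that("default inferences follow the threshold rule", {
  mk <- function(p, r = 0.5)
    category_concept("c", stochastic_frame("s", dist = list(a = p)),
                     context_independent = "a", threshold_r = r)

  expect_equal(default_inferences(mk(c(u = 0.9, v = 0.1))), c(a = "u"))
  # strict threshold: 0.5 is not > 0.5
  expect_length(default_inferences(mk(c(u = 0.5, v = 0.5))), 0L)
  # tie above the threshold: warning, no feature
  tied <- mk(c(u = 0.45, v = 0.45, w = 0.1), r = 0.4)
  expect_warning(om <- default_inferences(tied), class = "n400frames_tie")
  expect_length(om, 0L)

  bp <- scenario_arg_concept(fixture_birthday_party())
  expect_equal(default_inferences(bp),
               c(taste = "sweet", nutrition_value = "not_healthy",
                 served_at = "birthday_party"))
})

test_that("raising r never adds default inferences", {
  for (seed in 1:20) {
    spec <- generate_random_scenario(seed)
    cc <- scenario_arg_concept(spec)
    rs <- c(0, 0.25, 0.5, 0.75, 0.9)
    omegas <- lapply(rs, function(r)
      suppressWarnings(default_inferences(cc, r = r)))
    for (i in seq_along(rs)[-1]) {
      hi <- omegas[[i]]
      lo <- omegas[[i - 1L]]
      expect_true(all(names(hi) %in% names(lo)))
      expect_equal(lo[names(hi)], hi)
    }
  }
})

test_that("is_member distinguishes in / negated_in / undefined / neither", {
  resort <- fixture_holiday_resort()
  pine <- scenario_cw_concept(resort, "pines")
  expect_equal(is_member(pine, "habitat", "moderate"), "in")
  expect_equal(is_member(pine, "habitat", "tropics"), "negated_in")
  expect_equal(is_member(pine, "animacy", "yes"), "undefined_attribute")

  seaside <- fixture_seaside_caution("HC")
  trainee <- scenario_cw_concept(seaside, "trainees")
  expect_equal(is_member(trainee, "location", "water"), "neither")
  drawer <- scenario_cw_concept(seaside, "drawer")
  expect_equal(is_member(drawer, "sentient", "yes"), "undefined_attribute")
})

test_that("prenominal updates reproduce the worked tables", {
  bp <- fixture_birthday_party()
  arg <- scenario_arg_concept(bp)

  after_sweet <- scenario_arg_concept(bp, prenominal = "sweet")
  expect_equal(after_sweet$frame$dist$taste, c(sweet = 1, not_sweet = 0))
  expect_equal(after_sweet$frame$dist$nutrition_value,
               c(healthy = 0.02, not_healthy = 0.98))
  expect_equal(after_sweet$frame$dist$served_at,
               c(birthday_party = 0.98, not_birthday_party = 0.02))

  after_healthy <- scenario_arg_concept(bp, prenominal = "healthy")
  expect_equal(after_healthy$frame$dist$nutrition_value,
               c(healthy = 1, not_healthy = 0))
  expect_equal(after_healthy$frame$dist$taste,
               c(sweet = 0.4, not_sweet = 0.6))
  expect_equal(after_healthy$frame$dist$served_at,
               c(birthday_party = 0.95, not_birthday_party = 0.05))

  # idempotent, and the evidence feature is always a default of the result
  u <- prenominal_update("taste", "sweet",
                         list(nutrition_value = c(healthy = 0.02,
                                                  not_healthy = 0.98)))
  once <- apply_prenominal(arg, u)
  expect_equal(apply_prenominal(once, u)$frame$dist, once$frame$dist)
  expect_equal(default_inferences(once)[["taste"]], "sweet")

  # empty revisions: only the evidence chain changes
  bare <- apply_prenominal(arg, prenominal_update("taste", "sweet"))
  expect_equal(bare$frame$dist$nutrition_value,
               arg$frame$dist$nutrition_value)
  expect_equal(bare$frame$dist$taste, c(sweet = 1, not_sweet = 0))

  expect_error(prenominal_update("taste", "sweet",
                                 list(nutrition_value = c(healthy = 0.5,
                                                          not_healthy = 0.4))),
               "sum")
})

test_that("contrast classes come from the declared antecedent variation", {
  resort <- fixture_holiday_resort()
  arg <- scenario_arg_concept(resort)
  cts <- contrast_classes(arg)
  expect_length(cts, 1L)  # only one alternative look value
  expect_equal(cts[[1]]$frame$dist$habitat,
               c(tropics = 0.1, moderate = 0.9))
  # chains not named by the contrast keep the argument concept's values
  expect_equal(cts[[1]]$frame$dist$height, arg$frame$dist$height)

  plain <- category_concept("plain", resort_t1_frame(),
                            context_independent = c("habitat", "height"))
  expect_equal(contrast_classes(plain), list())
})
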