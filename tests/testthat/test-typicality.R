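bp <- fixture_birthday_party()

test_that("similarity is the min of the two conditional probabilities", {
  sweet <- scenario_arg_concept(bp, prenominal = "sweet")
  cake <- scenario_cw_concept(bp, "cake")
  expect_equal(similarity(sweet, cake, "taste", "sweet"), 0.9)
  expect_equal(similarity(sweet, cake, "taste", "not_sweet"), 0)
  # symmetric, and sim(c, c | VA) is the concept's own probability
  for (v in c("healthy", "not_healthy")) {
    expect_equal(similarity(sweet, cake, "nutrition_value", v),
                 similarity(cake, sweet, "nutrition_value", v))
    expect_equal(similarity(cake, cake, "nutrition_value", v),
                 concept_prob(cake, "nutrition_value", v))
  }
  expect_error(similarity(sweet, cake, "color", "red"), "undefined")
})

test_that("cue-validity reproduces the worked 0.9 / 0.1 and edge cases", {
  arg <- scenario_arg_concept(fixture_holiday_resort())
  cts <- contrast_classes(arg)
  expect_equal(cue_validity(arg, cts, "habitat", "tropics"), 0.9)
  expect_equal(cue_validity(arg, cts, "habitat", "moderate"), 0.1)
  # cue-validities over all classes sum to 1 for a fixed feature
  classes <- c(list(arg), cts)
  cv_all <- vapply(seq_along(classes), function(i)
    cue_validity(classes[[i]], classes[-i], "habitat", "tropics"),
    numeric(1))
  expect_equal(sum(cv_all), 1)
  # no contrasts: 1 for any feature with nonzero probability
  expect_equal(cue_validity(arg, list(), "habitat", "moderate"), 1)
  # impossible feature everywhere: warning + 0
  z1 <- category_concept("z1",
    stochastic_frame("s", dist = list(a = c(u = 1, v = 0))),
    context_independent = "a")
  z2 <- category_concept("z2",
    stochastic_frame("s", dist = list(a = c(u = 1, v = 0))),
    context_independent = "a")
  expect_warning(cv <- cue_validity(z1, list(z2), "a", "v"), "undefined")
  expect_equal(cv, 0)
})

test_that("attribute d-values and diagnosticity profiles behave", {
  arg <- scenario_arg_concept(fixture_holiday_resort())
  cts <- contrast_classes(arg)
  expect_equal(attribute_d(arg, cts, "habitat"), 0.9)
  # contrast leaves height untouched: identical likelihoods, equal priors
  expect_equal(attribute_d(arg, cts, "height"), 0.5)
  expect_equal(attribute_d(arg, list(), "habitat"), 1)  # single class

  prof <- diagnosticity(arg)
  expect_equal(prof$source, "computed")
  expect_equal(sum(prof$weights), 1)
  expect_equal(unname(prof$weights[c("habitat", "height")]),
               c(0.9, 0.5) / 1.4)

  stip <- diagnosticity(scenario_arg_concept(bp))
  expect_equal(stip$source, "stipulated")
  expect_equal(stip$weights,
               c(taste = 0.45, nutrition_value = 0.1, served_at = 0.45))

  # identical distributions in all classes, equal priors -> d = 1/k
  same <- function(nm) category_concept(nm,
    stochastic_frame("s", dist = list(a = c(u = 0.7, v = 0.3))),
    context_independent = "a")
  expect_equal(attribute_d(same("c1"), list(same("c2"), same("c3")), "a"),
               1 / 3)
})

test_that("typicality reproduces the four printed values to 4 decimals", {
  cake <- scenario_cw_concept(bp, "cake")
  veg <- scenario_cw_concept(bp, "veggies")
  sweet <- scenario_arg_concept(bp, prenominal = "sweet")
  healthy <- scenario_arg_concept(bp, prenominal = "healthy")
  expect_equal(typicality(sweet, cake)$raw, 0.937, tolerance = 5e-5)
  expect_equal(typicality(healthy, cake)$raw, 0.6815, tolerance = 5e-5)
  expect_equal(typicality(healthy, veg)$raw, 0.4815, tolerance = 5e-5)
  expect_equal(typicality(sweet, veg)$raw, 0.12, tolerance = 5e-5)

  # per-feature table is internally consistent
  tp <- typicality(sweet, cake)
  expect_equal(sum(tp$per_feature$product), tp$raw)
  expect_equal(tp$per_feature$product,
               tp$per_feature$diag * tp$per_feature$sim)
})

test_that("typicality identities hold on random scenarios", {
  for (seed in 1:40) {
    spec <- generate_random_scenario(seed, n_values = 2L + seed %% 2L)
    arg <- scenario_arg_concept(spec)
    prof <- diagnosticity(arg)
    # self-typicality is 1 (raw and normalized)
    self <- typicality(arg, arg, profile = prof)
    expect_equal(self$raw, 1)
    expect_equal(self$normalized, 1)
    for (cw in names(spec$critical_words)) {
      ccw <- scenario_cw_concept(spec, cw)
      tp <- typicality(arg, ccw, profile = prof)
      expect_gte(tp$raw, -1e-12)
      expect_lte(tp$raw, 1 + 1e-12)
      # raw = 1 - sum_j w_j * TV_j
      tv <- sum(vapply(names(prof$weights), function(ch)
        prof$weights[[ch]] * tv_dist(arg$frame$dist[[ch]],
                                     ccw$frame$dist[[ch]]),
        numeric(1)))
      expect_equal(tp$raw, 1 - tv)
      # symmetric under a shared profile
      expect_equal(typicality(ccw, arg, profile = prof)$raw, tp$raw)
    }
  }
})

test_that("undefined profiled chains raise an error", {
  seaside <- fixture_seaside_caution("HC")
  arg <- scenario_arg_concept(seaside)
  drawer <- scenario_cw_concept(seaside, "drawer")
  expect_error(typicality(arg, drawer), "undefined")
})
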