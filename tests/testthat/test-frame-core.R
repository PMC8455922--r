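test_that("feature sets collect fixed chains and respect the union law", {
  f1 <- resort_t1_frame()
  expect_length(feature_set(f1), 0L)

  ftt <- fix_chain(fix_chain(f1, "habitat", "tropics"), "height", "tall")
  expect_equal(feature_set(ftt),
               c(habitat = "tropics", height = "tall"))
  fmt <- fix_chain(fix_chain(f1, "habitat", "moderate"), "height", "tall")
  expect_equal(feature_set(fmt),
               c(habitat = "moderate", height = "tall"))

  # degenerate distributions count as fixed even without a `fixed` entry
  fdeg <- stochastic_frame("plant",
                           dist = list(habitat = c(tropics = 1,
                                                   moderate = 0)))
  expect_equal(feature_set(fdeg), c(habitat = "tropics"))

  # feature_set(fix_chain(f, c, v)) == feature_set(f) + {c=v}
  ft <- fix_chain(f1, "height", "tall")
  expect_equal(feature_set(fix_chain(ft, "habitat", "moderate")),
               c(feature_set(ft), habitat = "moderate"))
})

test_that("frame construction rejects malformed distributions", {
  expect_error(stochastic_frame("x", dist = list(a = c(u = 0.5, v = 0.4))),
               "sum")
  expect_error(stochastic_frame("x", dist = list(a = c(u = 1.2, v = -0.2))),
               "outside")
  expect_error(
    stochastic_frame("x", dist = list(a = c(u = 0.6, v = 0.4)),
                     fixed = c(a = "u")),
    "non-degenerate")
})

test_that("subsumes is a partial order on a small frame fixture set", {
  f1 <- resort_t1_frame()
  fh <- fix_chain(f1, "height", "tall")
  ftt <- fix_chain(fh, "habitat", "tropics")
  fts <- fix_chain(fix_chain(f1, "height", "small"), "habitat", "tropics")
  fmt <- fix_chain(fh, "habitat", "moderate")
  frames <- list(f1, fh, ftt, fts, fmt)

  # minimal frame below everything; conflicting values incomparable
  expect_true(subsumes(f1, ftt))
  expect_false(subsumes(ftt, fts))
  expect_false(subsumes(fts, ftt))

  for (a in frames) expect_true(subsumes(a, a))  # reflexive
  for (a in frames) for (b in frames) {
    if (subsumes(a, b) && subsumes(b, a))        # antisymmetric
      expect_equal(feature_set(a), feature_set(b))
    for (c_ in frames)                           # transitive
      if (subsumes(a, b) && subsumes(b, c_))
        expect_true(subsumes(a, c_))
  }
})

test_that("subsumes uses the sort hierarchy for frame sorts", {
  sorts <- sort_table(c("plant", "tree"), c(NA, "plant"))
  fp <- stochastic_frame("plant", dist = resort_dists)
  ftree <- stochastic_frame("tree", dist = resort_dists)
  expect_true(subsumes(fp, ftree, sorts = sorts))
  expect_false(subsumes(ftree, fp, sorts = sorts))
  expect_error(subsumes(fp, ftree), "incompatible sort")
})

test_that("sort tables reject duplicates, dangling parents and cycles", {
  expect_error(sort_table(c("a", "a")), "unique")
  expect_error(sort_table("a", "ghost"), "unresolved")
  expect_error(sort_table(c("a", "b"), c("b", "a")), "cycle")
  tab <- sort_table(c("plant", "tree", "palm"), c(NA, "plant", "tree"))
  expect_true(sort_subsumes(tab, "plant", "palm"))
  expect_false(sort_subsumes(tab, "palm", "plant"))
})

test_that("extension probabilities follow the product rule", {
  f1 <- resort_t1_frame()
  expect_equal(extension_probability(f1, f1), 1)

  ftt <- fix_chain(fix_chain(f1, "habitat", "tropics"), "height", "tall")
  fms <- fix_chain(fix_chain(f1, "habitat", "moderate"), "height", "small")
  expect_equal(extension_probability(f1, ftt), 0.54)
  expect_equal(extension_probability(f1, fms), 0.04)

  # one-step extensions of any single chain sum to 1
  for (ch in names(f1$dist)) {
    one_step <- vapply(names(f1$dist[[ch]]), function(v)
      extension_probability(f1, fix_chain(f1, ch, v)), numeric(1))
    expect_equal(sum(one_step), 1)
  }

  # chain fixed in ext with no distribution in base
  bare <- stochastic_frame("plant",
                           dist = list(habitat = resort_dists$habitat))
  ext <- stochastic_frame("plant",
                          dist = list(habitat = resort_dists$habitat),
                          fixed = c(height = "tall"))
  expect_error(extension_probability(bare, ext), "no distribution in base")
})
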