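test_that("n400_index is anchored and monotone in both components", {
  expect_equal(n400_index(0.4, 0.4, 1), 0)   # best completion
  expect_equal(n400_index(0, 0.4, 0), 1)     # maximal amplitude
  # degenerate guard: nothing to predict
  expect_equal(n400_index(0, 0, 0.6, alpha = 0.5, beta = 0.5),
               0.5 * (1 - 0.6))
  expect_error(n400_index(0.1, 0.4, 0.5, alpha = 0.7, beta = 0.5), "sum")
  expect_error(n400_index(0.5, 0.4, 0.5), "delta_h")

  set.seed(42)
  for (i in 1:200) {
    hmax <- runif(1, 0.1, 2)
    dh <- sort(runif(2, 0, hmax))
    typ <- sort(runif(2))
    a <- runif(1)
    # more entropy reduction, typicality fixed: never larger
    expect_lte(n400_index(dh[2], hmax, typ[1], a, 1 - a),
               n400_index(dh[1], hmax, typ[1], a, 1 - a) + 1e-12)
    # more typicality, reduction fixed: never larger
    expect_lte(n400_index(dh[1], hmax, typ[2], a, 1 - a),
               n400_index(dh[1], hmax, typ[1], a, 1 - a) + 1e-12)
    expect_gte(n400_index(dh[1], hmax, typ[1], a, 1 - a), 0)
    expect_lte(n400_index(dh[1], hmax, typ[1], a, 1 - a), 1)
  }
})

test_that("evaluate_cw carries every intermediate of the pipeline", {
  bp <- fixture_birthday_party()
  rep <- evaluate_cw(bp, "cake", prenominal = "sweet")
  expect_s3_class(rep, "component_report")
  expect_false(rep$failed)
  expect_equal(rep$typicality_raw, 0.937, tolerance = 5e-5)
  expect_equal(unname(rep$partition_sizes), c(3L, 0L, 0L))
  expect_equal(rep$delta_h, rep$h_t1 - rep$h_t2)

  resort <- fixture_holiday_resort()
  palms <- evaluate_cw(resort, "palms")
  expect_printed(palms$delta_h, 0.433, 5e-4)
  expect_equal(palms$h_t2, 0)

  expect_error(evaluate_cw(resort, "cactus"), "unknown critical word")
})

test_that("categorization failure yields index 1 and no typicality", {
  seaside <- fixture_seaside_caution("HC")
  rep <- evaluate_cw(seaside, "drawer")
  expect_true(rep$failed)
  expect_equal(rep$n400_index, 1)
  expect_true(is.na(rep$typicality_raw))
  expect_true(is.na(rep$h_t1))
  # maximal: at least as large as any non-failed index in the scenario
  others <- evaluate_scenario(seaside)
  for (r in others)
    expect_lte(r$n400_index, rep$n400_index)
})

test_that("resort amplitude ordering holds for all weight settings", {
  resort <- fixture_holiday_resort()
  for (a in c(0.25, 0.5, 0.75)) {
    cfg <- run_config(alpha = a, beta = 1 - a)
    idx <- vapply(c("palms", "pines", "tulips"), function(w)
      evaluate_cw(resort, w, config = cfg)$n400_index, numeric(1))
    expect_lt(idx[["palms"]], idx[["pines"]])
    expect_lt(idx[["pines"]], idx[["tulips"]])
  }
})

test_that("birthday ordering follows typicality on the plausibility term", {
  bp <- fixture_birthday_party()
  conds <- list(c("sweet", "cake"), c("healthy", "cake"),
                c("healthy", "veggies"), c("sweet", "veggies"))
  typ <- vapply(conds, function(cd)
    evaluate_cw(bp, cd[2], prenominal = cd[1])$typicality_raw, numeric(1))
  expect_equal(typ, c(0.937, 0.6815, 0.4815, 0.12), tolerance = 5e-5)
  # plausibility term beta * (1 - typ) is strictly increasing across the
  # four conditions for every tested beta
  for (b in c(0.25, 0.5, 0.75))
    expect_true(all(diff(b * (1 - typ)) > 0))
  # the combined index realizes the ordering when plausibility dominates
  cfg <- run_config(alpha = 0.25, beta = 0.75)
  idx <- vapply(conds, function(cd)
    evaluate_cw(bp, cd[2], prenominal = cd[1], config = cfg)$n400_index,
    numeric(1))
  expect_true(all(diff(idx) > 0))
})

test_that("HC and LC seaside indices can approximately coincide", {
  # the compensation narrative: for low-cloze "trainees" the HC gain in
  # information offsets its lower typicality under suitable weights
  hc <- fixture_seaside_caution("HC")
  lc <- fixture_seaside_caution("LC")
  cfg <- run_config(alpha = 0.5, beta = 0.5)
  tr_hc <- evaluate_cw(hc, "trainees", config = cfg)
  tr_lc <- evaluate_cw(lc, "trainees", config = cfg)
  # HC gains full reduction but lower typicality; LC the reverse
  expect_gt(tr_hc$delta_h, tr_lc$delta_h)
  expect_lt(tr_hc$typicality_raw, tr_lc$typicality_raw)
})

test_that("role typicality reverses the prescription N400 ordering", {
  roles <- prescription_roles()
  cws <- prescription_cws()
  typ <- vapply(cws, function(ccw) role_typicality(roles, ccw), numeric(1))
  # N400: psychiatrist < schizophrenic < guard < pill < fence,
  # so typicality must be strictly decreasing in that order
  expect_true(all(diff(typ[c("psychiatrist", "schizophrenic", "guard",
                             "pill", "fence")]) < 0))
  # single role with weight 1 reduces to plain typicality
  solo <- list(list(role = "actor", weight = 1,
                    c_arg = roles[[1]]$c_arg,
                    profile = roles[[1]]$profile))
  expect_equal(role_typicality(solo, cws$psychiatrist),
               typicality(roles[[1]]$c_arg, cws$psychiatrist,
                          profile = roles[[1]]$profile)$raw)
  # undischarged-role match outweighs a discharged-role one
  expect_gt(roles[[1]]$weight * typicality(roles[[1]]$c_arg,
                                           cws$psychiatrist,
                                           profile = roles[[1]]$profile)$raw,
            roles[[2]]$weight * typicality(roles[[2]]$c_arg,
                                           cws$schizophrenic,
                                           profile = roles[[2]]$profile)$raw)
  bad <- roles
  bad[[1]]$weight <- 0.9
  expect_error(role_typicality(bad, cws$pill), "sum to 1")
})

test_that("report serialization is stable and complete", {
  resort <- fixture_holiday_resort()
  reports <- evaluate_scenario(resort)
  tab <- report_table(reports)
  expect_equal(names(tab),
               c("cw", "failed", "h_t1", "h_t2", "delta_h",
                 "typicality_raw", "typicality_normalized", "n400_index",
                 "n_conf", "n_comp", "n_disconf"))
  expect_equal(tab$cw, c("palms", "pines", "tulips"))
  # identical inputs => byte-identical JSON
  expect_identical(format_reports(reports), format_reports(reports))
  tsv <- strsplit(format_reports(reports, "tsv"), "\n")[[1]]
  expect_length(tsv, 4L)
  expect_match(tsv[1], "^cw\tfailed\t")
})
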