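test_that("the packaged specification reproduces the published counts exactly", {
  co <- generate_marginal_cohort(table1_spec(), seed = 1)
  expect_equal(nrow(co), 116)
  expect_equal(sum(co$place_of_death == "home"), 21)
  expect_equal(sum(co$place_of_death == "hospital"), 90)
  expect_equal(sum(co$place_of_death == "nursing_home"), 5)
  expect_equal(mean(co$assessment_to_death_days), 38)
  expect_equal(range(co$assessment_to_death_days), c(3, 89))
  expect_equal(as.integer(table(co$symptom_burden)[c("none_low", "medium",
                                                     "high")]),
               c(6L, 36L, 74L))
  expect_equal(sum(co$care_team_prediction == "hospital"), 75)
  expect_equal(sum(is.na(co$primary_tumour_site)), 1)
  expect_equal(mean(co$days_in_nursing_home_60), 0)
  expect_equal(mean(co$hospitalisations_60), 1)
  expect_equal(range(co$hospitalisations_60), c(0, 3))
})

test_that("summarize o generate is the identity on the spec across seeds", {
  spec <- table1_spec()
  for (seed in c(2, 19, 101, 7777)) {
    co <- generate_marginal_cohort(spec, seed = seed)
    s <- summarize_cohort(co)
    for (nm in names(spec$columns)) {
      col <- spec$columns[[nm]]
      if (col$type == "categorical") {
        expect_equal(s[[nm]]$counts[names(col$counts)[col$counts > 0]],
                     col$counts[col$counts > 0])
        expect_equal(s[[nm]]$missing_count, col$missing_count %||% 0L,
                     ignore_attr = TRUE)
      } else {
        expect_equal(s[[nm]]$mean, col$mean)
        if (isTRUE(col$attain_extremes)) {
          expect_equal(s[[nm]]$min, col$min)
          expect_equal(s[[nm]]$max, col$max)
        } else {
          expect_gte(s[[nm]]$min, col$min)
          expect_lte(s[[nm]]$max, col$max)
        }
      }
    }
  }
})

test_that("generation is deterministic in the seed and handles n = 0", {
  spec <- table1_spec()
  expect_identical(generate_marginal_cohort(spec, seed = 42),
                   generate_marginal_cohort(spec, seed = 42))
  expect_false(identical(generate_marginal_cohort(spec, seed = 1)$gender,
                         generate_marginal_cohort(spec, seed = 2)$gender))

  empty <- marginal_spec(0, list(
    a = list(type = "categorical", counts = c(x = 0L, y = 0L)),
    d = list(type = "integer", mean = 0, min = 0, max = 10,
             attain_extremes = FALSE)))
  co0 <- generate_marginal_cohort(empty, seed = 1)
  expect_equal(nrow(co0), 0)
  expect_named(attr(co0, "dictionary"), c("a", "d"))
})

test_that("invalid specifications are rejected with construction errors", {
  expect_error(marginal_spec(10, list(
    a = list(type = "categorical", counts = c(x = 4L, y = 4L)))),
    class = "credalpod_structural_error")
  expect_error(marginal_spec(10, list(
    d = list(type = "integer", mean = 20, min = 0, max = 10))),
    class = "credalpod_structural_error")
  expect_error(marginal_spec(3, list(
    d = list(type = "integer", mean = 1 / 3 + 1e-3, min = 0, max = 10))),
    class = "credalpod_structural_error")
})

test_that("model-driven cohorts track their generating Bayesian network", {
  net <- load_reference_model()
  co <- generate_model_cohort(net, rule = "midpoint", n = 10000, seed = 9)
  bn <- attr(co, "bn")
  expect_equal(nrow(co), 10000)
  ## root marginals within sampling error of the midpoint CPTs
  for (v in c("cancer_treatment", "symptom_burden", "area_of_residence")) {
    emp <- as.numeric(table(factor(co[[v]], net$variables[[v]]))) / 10000
    expect_lt(max(abs(emp - bn[[v]][, 1])), 0.02)
  }
  ## chi-square goodness of fit of child conditionals, alpha = 0.001
  for (v in c("eol_communication", "family_preference")) {
    par <- net$parents[[v]]
    grid <- credalpod:::parent_config_grid(net, v)
    for (j in seq_len(nrow(grid))) {
      sel <- rep(TRUE, nrow(co))
      for (pp in par) sel <- sel & co[[pp]] == grid[j, pp]
      if (sum(sel) < 100) next
      obs <- as.numeric(table(factor(co[[v]][sel], net$variables[[v]])))
      expected_p <- bn[[v]][, j]
      keep <- expected_p > 0
      ## rare states give small expected cells; the approximation
      ## warning is immaterial at alpha = 0.001
      pval <- suppressWarnings(
        stats::chisq.test(obs[keep], p = expected_p[keep])$p.value)
      expect_gt(pval, 0.001)
    }
  }
  ## determinism and the n = 1 edge case
  co2 <- generate_model_cohort(net, rule = "midpoint", n = 10000, seed = 9)
  expect_identical(co, co2)
  one <- generate_model_cohort(net, rule = "random", n = 1, seed = 5)
  expect_equal(nrow(one), 1)
  expect_true(one$place_of_death %in% net$variables$place_of_death)
})

test_that("cohort CSV files round-trip with metadata and missing markers", {
  co <- generate_marginal_cohort(table1_spec(), seed = 3)
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(co, path)
  lines <- readLines(path, n = 5)
  expect_match(lines[1], "^# credalpod cohort")
  expect_match(lines, "seed", all = FALSE)
  back <- read_cohort(path)
  expect_equal(as.data.frame(back), as.data.frame(co), ignore_attr = TRUE)
  expect_equal(sum(is.na(back$primary_tumour_site)), 1)
})
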