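toy_records <- function() {
  data.frame(x = c("x1", "x1", "x2", "x2"),
             y = c("h", "h", "h", "o"),
             stringsAsFactors = FALSE)
}

test_that("Laplace-smoothed fitting matches hand counts", {
  m <- fit_naive_bayes(toy_records(), "y", "x", alpha = 1)
  expect_equal(unname(m$prior["h"]), 2 / 3, tolerance = 1e-12)
  expect_equal(unname(m$cond$x["x2", "h"]), 0.4, tolerance = 1e-12)
  expect_equal(unname(m$cond$x["x2", "o"]), 2 / 3, tolerance = 1e-12)
  expect_equal(colSums(m$cond$x), c(h = 1, o = 1), tolerance = 1e-12)
  expect_true(all(unlist(m$cond) > 0))

  m0 <- fit_naive_bayes(toy_records(), "y", "x", alpha = 0)
  expect_equal(unname(m0$cond$x["x1", "o"]), 0)
})

test_that("degenerate cohorts are rejected or handled as documented", {
  expect_error(fit_naive_bayes(data.frame(), "y", "x"),
               class = "credalpod_fit_error")
  one_class <- data.frame(x = c("a", "b"), y = c("h", "h"))
  expect_error(fit_naive_bayes(one_class, "y", "x"),
               class = "credalpod_fit_error")
  with_missing_label <- data.frame(x = c("a", "b"), y = c("h", NA))
  expect_error(fit_naive_bayes(with_missing_label, "y", "x"),
               class = "credalpod_fit_error")
  all_missing <- data.frame(x = c(NA_character_, NA_character_),
                            z = c("u", "v"), y = c("h", "o"))
  expect_warning(m <- fit_naive_bayes(all_missing, "y", c("x", "z")),
                 "entirely missing")
  expect_equal(m$dropped_features, "x")
  expect_named(m$cond, "z")
})

test_that("prediction uses present features only and propagates zeros", {
  m <- fit_naive_bayes(toy_records(), "y", "x", alpha = 1)
  pr <- predict(m, data.frame(x = "x2"), type = "prob")
  expect_equal(unname(pr[1, "h"]), 0.26667 / (0.26667 + 0.22222),
               tolerance = 1e-4)
  expect_equal(as.character(predict(m, data.frame(x = "x2"))), "h")
  expect_equal(sum(pr), 1, tolerance = 1e-12)

  ## fully missing record: posterior equals the prior
  pr2 <- predict(m, data.frame(x = NA_character_), type = "prob")
  expect_equal(unname(pr2[1, ]), unname(m$prior), tolerance = 1e-12)

  ## zero conditional under alpha = 0 forces a zero posterior
  m0 <- fit_naive_bayes(toy_records(), "y", "x", alpha = 0)
  pr3 <- predict(m0, data.frame(x = "x1"), type = "prob")
  expect_equal(unname(pr3[1, "o"]), 0)

  expect_error(predict(m, data.frame(x = "x99")),
               class = "credalpod_prediction_error")
})

test_that("prediction is invariant to feature order", {
  set.seed(61)
  d <- data.frame(a = sample(c("u", "v"), 40, TRUE),
                  b = sample(c("p", "q", "r"), 40, TRUE),
                  y = sample(c("h", "o"), 40, TRUE),
                  stringsAsFactors = FALSE)
  m1 <- fit_naive_bayes(d, "y", c("a", "b"))
  m2 <- fit_naive_bayes(d, "y", c("b", "a"))
  p1 <- predict(m1, d, type = "prob")
  p2 <- predict(m2, d, type = "prob")
  expect_equal(p1, p2, tolerance = 1e-12)
})

test_that("evaluation reports model, baseline and LOOCV accuracy", {
  d <- toy_records()
  m <- fit_naive_bayes(d, "y", "x", alpha = 1)
  d$team <- d$y  # a perfect baseline
  ev <- evaluate_classifier(m, d, baseline = "team", loocv = FALSE)
  expect_equal(ev$baseline_accuracy, 1)
  expect_equal(ev$accuracy, mean(as.character(predict(m, d)) == d$y))
  expect_equal(sum(ev$confusion), nrow(d))

  ## LOOCV equals an explicit refit loop on a 6-record set
  set.seed(67)
  d6 <- data.frame(x = c("x1", "x1", "x2", "x2", "x1", "x2"),
                   z = c("a", "b", "a", "b", "b", "a"),
                   y = c("h", "h", "o", "o", "h", "o"),
                   stringsAsFactors = FALSE)
  m6 <- fit_naive_bayes(d6, "y", c("x", "z"))
  ev6 <- evaluate_classifier(m6, d6, loocv = TRUE)
  manual <- vapply(seq_len(6), function(i) {
    mi <- fit_naive_bayes(d6[-i, ], "y", c("x", "z"))
    as.character(predict(mi, d6[i, ])) == d6$y[i]
  }, TRUE)
  expect_equal(ev6$loocv_accuracy, mean(manual))

  bad <- d
  bad$team[1] <- "mars"
  expect_error(evaluate_classifier(m, bad, baseline = "team"),
               class = "credalpod_evaluation_error")
})

test_that("fitted conditionals are calibrated against the generating network", {
  ## recovery at the binomial-sampling scale: each fitted conditional
  ## must sit within 4 standard errors (floor 0.02) of the exact value
  ## computed from the Bayesian network the cohort was sampled from
  net <- load_reference_model()
  co <- generate_model_cohort(net, rule = "random", n = 10000, seed = 2024)
  bn <- attr(co, "bn")
  point_net <- net
  for (v in names(net$tables))
    point_net$tables[[v]] <- lapply(seq_along(net$tables[[v]]), function(j) {
      p <- bn[[v]][, j]
      credal_set(p, p, states = net$variables[[v]])
    })
  features <- c("family_preference", "hospital_days", "symptom_burden")
  fit <- fit_naive_bayes(co, "place_of_death", features, alpha = 1,
                         missing_values = character(0))
  class_n <- table(co$place_of_death)
  for (f in features) for (lev in rownames(fit$cond[[f]]))
    for (cl in colnames(fit$cond[[f]])) {
      truth <- bayesian_posterior(point_net, stats::setNames(lev, f),
                                  evidence = c(place_of_death = cl))
      se <- sqrt(truth * (1 - truth) / class_n[[cl]])
      expect_lt(abs(fit$cond[[f]][lev, cl] - truth), max(0.02, 4 * se))
    }
})

test_that("day-count discretization matches the documented bins", {
  d <- data.frame(days_in_hospital_60 = c(0, 1, 14, 15, 60),
                  assessment_to_death_days = c(3, 10, 38, 60, 89))
  out <- discretize_cohort(d)
  expect_equal(out$hospital_days, c("none", "short", "short", "long", "long"))
  expect_equal(sort(unique(out$assessment_interval)),
               c("long", "medium", "short"))
})

test_that("model JSON serialization preserves predictions exactly", {
  set.seed(71)
  d <- data.frame(a = sample(c("u", "v"), 30, TRUE),
                  b = sample(c("p", "q"), 30, TRUE),
                  y = sample(c("h", "o", "n"), 30, TRUE),
                  stringsAsFactors = FALSE)
  m <- fit_naive_bayes(d, "y", c("a", "b"))
  path <- withr::local_tempfile(fileext = ".json")
  write_nb_model(m, path)
  m2 <- read_nb_model(path)
  expect_equal(predict(m2, d, type = "prob"), predict(m, d, type = "prob"),
               tolerance = 1e-12)
})
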