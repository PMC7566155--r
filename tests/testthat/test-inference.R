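test_that("Bayesian posteriors match closed forms on the two-node chain", {
  net <- toy_chain_bn()
  expect_equal(bayesian_posterior(net, c(A = "a1"), c(B = "b1")), 0.8,
               tolerance = 1e-12)
  ## empty evidence: a root's marginal
  expect_equal(bayesian_posterior(net, c(A = "a1")), 0.5, tolerance = 1e-12)
  ## evidence on the target itself
  expect_equal(bayesian_posterior(net, c(B = "b1"), c(B = "b1")), 1)
  expect_equal(bayesian_posterior(net, c(B = "b1"), c(B = "b2")), 0)
  expect_error(bayesian_posterior(toy_ab_network(), c(B = "b1")),
               class = "credalpod_structural_error")
})

test_that("zero-probability evidence raises a conditioning error", {
  net <- credal_network(
    list(A = c("a1", "a2"), B = c("b1", "b2")),
    parents = list(B = "A"),
    tables = list(
      A = list(credal_set(c(1, 0), c(1, 0))),
      B = list(credal_set(c(0.8, 0.2), c(0.8, 0.2)),
               credal_set(c(0.2, 0.8), c(0.2, 0.8)))))
  expect_error(bayesian_posterior(net, c(B = "b1"), c(A = "a2")),
               class = "credalpod_conditioning_error")
  expect_error(posterior_bounds(net, c(B = "b1"), evidence = c(A = "a2")),
               class = "credalpod_conditioning_error")
})

test_that("strong-extension bounds reproduce the worked two-node values", {
  net <- toy_ab_network()
  b <- posterior_bounds(net, c(B = "b1"))
  expect_equal(b$lower, 0.34, tolerance = 1e-9)
  expect_equal(b$upper, 0.66, tolerance = 1e-9)
  expect_true(b$exact)
  expect_equal(b$n_extreme_combinations, 8)

  b2 <- posterior_bounds(net, c(A = "a1"), evidence = c(B = "b1"))
  expect_equal(b2$lower, 0.28 / 0.46, tolerance = 1e-9)
  expect_equal(b2$upper, 0.54 / 0.58, tolerance = 1e-9)

  b3 <- posterior_bounds(net, c(B = "b1"), do = c(A = "a1"))
  expect_equal(c(b3$lower, b3$upper), c(0.7, 0.9), tolerance = 1e-9)
})

test_that("exact bounds equal brute force over all vertex combinations", {
  set.seed(31)
  done <- 0
  while (done < 30) {
    net <- random_small_network(n_nodes = sample(3:4, 1))
    nverts <- unlist(lapply(net$tables, function(tab)
      vapply(tab, function(cs) nrow(enumerate_vertices(cs)), 1L)))
    if (prod(nverts) > 5000) next  # keep the exhaustive oracle tractable
    tv <- sample(names(net$variables), 1)
    target <- stats::setNames(sample(net$variables[[tv]], 1), tv)
    ev <- NULL
    if (runif(1) < 0.6) {
      evar <- sample(setdiff(names(net$variables), tv), 1)
      ev <- stats::setNames(sample(net$variables[[evar]], 1), evar)
    }
    oracle <- oracle_bounds(net, target, evidence = ev)
    if (is.null(oracle)) next  # evidence impossible everywhere; skip draw
    got <- posterior_bounds(net, target, evidence = ev,
                            control = bounds_control(exact_budget = 1e6))
    expect_true(got$exact)
    expect_equal(got$lower, oracle$lower, tolerance = 1e-9)
    expect_equal(got$upper, oracle$upper, tolerance = 1e-9)
    done <- done + 1
  }
})

test_that("random Bayesian-vertex posteriors always lie inside the bounds", {
  set.seed(37)
  for (rep in 1:5) {
    net <- random_small_network(n_nodes = 4)
    tv <- names(net$variables)[1L]
    target <- stats::setNames(net$variables[[tv]][1L], tv)
    got <- posterior_bounds(net, target,
                            control = bounds_control(exact_budget = 1e6))
    indexer <- oracle_joint_indexer(net$variables, net$parents)
    verts <- lapply(net$tables, function(tab)
      lapply(tab, enumerate_vertices))
    ps <- replicate(200, {
      cp <- random_vertex_cpts(verts, net$variables)
      oracle_posterior(indexer, cp, tv, 1L, list())
    })
    expect_true(all(ps >= got$lower - 1e-9 & ps <= got$upper + 1e-9))
  }
})

test_that("point networks reduce to Bayesian inference to 1e-12", {
  set.seed(41)
  for (rep in 1:20) {
    net <- pointify_network(random_small_network(n_nodes = 4))
    tv <- sample(names(net$variables), 1)
    target <- stats::setNames(sample(net$variables[[tv]], 1), tv)
    b <- posterior_bounds(net, target,
                          control = bounds_control(exact_budget = 1e6))
    p <- bayesian_posterior(net, target)
    expect_equal(b$lower, p, tolerance = 1e-12)
    expect_equal(b$upper, p, tolerance = 1e-12)
  }
})

test_that("intervening on a root equals observing it", {
  set.seed(43)
  for (rep in 1:15) {
    net <- pointify_network(random_small_network(n_nodes = 4))
    roots <- names(net$variables)[lengths(net$parents) == 0]
    r <- sample(roots, 1)
    others <- setdiff(names(net$variables), r)
    tv <- sample(others, 1)
    target <- stats::setNames(sample(net$variables[[tv]], 1), tv)
    s <- sample(net$variables[[r]], 1)
    pe <- tryCatch(
      bayesian_posterior(net, target,
                         evidence = stats::setNames(s, r)),
      credalpod_conditioning_error = function(e) NULL)
    if (is.null(pe)) next
    pd <- posterior_bounds(net, target, do = stats::setNames(s, r),
                           control = bounds_control(exact_budget = 1e6))
    expect_equal(pd$lower, pe, tolerance = 1e-12)
    expect_equal(pd$upper, pe, tolerance = 1e-12)
  }
})

test_that("widening any table's intervals never narrows query bounds", {
  set.seed(47)
  for (rep in 1:10) {
    net <- random_small_network(n_nodes = 3, p_interval = 0.5, width = 0.1)
    tv <- names(net$variables)[1L]
    target <- stats::setNames(net$variables[[tv]][1L], tv)
    ctrl <- bounds_control(exact_budget = 1e6)
    b0 <- posterior_bounds(net, target, control = ctrl)
    wide <- net
    for (v in names(wide$tables))
      wide$tables[[v]] <- lapply(wide$tables[[v]], function(cs) {
        credal_set(pmax(0, cs$base$lower - 0.05),
                   pmin(1, cs$base$upper + 0.05),
                   states = cs$base$states)
      })
    b1 <- posterior_bounds(wide, target, control = ctrl)
    expect_lte(b1$lower, b0$lower + 1e-9)
    expect_gte(b1$upper, b0$upper - 1e-9)
  }
})

test_that("partially impossible evidence triggers regular-extension handling", {
  ## P(a1) spans [0, 0.5]: some vertex combinations give the evidence
  ## a1 zero probability and must be excluded, not zeroed into [0, 1]
  net <- credal_network(
    list(A = c("a1", "a2"), B = c("b1", "b2")),
    parents = list(B = "A"),
    tables = list(
      A = list(credal_set(c(0, 0.5), c(0.5, 1))),
      B = list(credal_set(c(0.9, 0.1), c(0.9, 0.1)),
               credal_set(c(0.2, 0.8), c(0.2, 0.8)))))
  b <- posterior_bounds(net, c(B = "b1"), evidence = c(A = "a1"))
  expect_true(b$regular_extension)
  expect_equal(c(b$lower, b$upper), c(0.9, 0.9), tolerance = 1e-9)
})

test_that("the impact statistic behaves on worked, disconnected and point cases", {
  net <- toy_ab_network()
  im <- impact(net, c(B = "b1"), "A", mode = "do")
  expect_equal(im$impact, 60, tolerance = 1e-9)
  expect_equal(im$impact_display, 60)
  expect_equal(unname(im$breakdown["a1", "a2"]), 0.6, tolerance = 1e-9)

  ## disconnected manipulated variable: no influence
  net2 <- credal_network(
    list(A = c("a1", "a2"), B = c("b1", "b2"), C = c("c1", "c2")),
    parents = list(B = "A"),
    tables = list(
      A = list(credal_set(c(0.4, 0.4), c(0.6, 0.6))),
      B = list(credal_set(c(0.7, 0.1), c(0.9, 0.3)),
               credal_set(c(0.1, 0.7), c(0.3, 0.9))),
      C = list(credal_set(c(0.5, 0.5), c(0.5, 0.5)))))
  expect_equal(impact(net2, c(B = "b1"), "C", mode = "do")$impact, 0,
               tolerance = 1e-9)

  ## point network: impact equals the difference of exact posteriors
  bn <- toy_chain_bn()
  im2 <- impact(bn, c(B = "b1"), "A", mode = "observe")
  expect_equal(im2$impact, 60, tolerance = 1e-9)
  expect_error(impact(net, c(B = "b1"), "B"),
               class = "credalpod_validation_error")
})

test_that("the local-search fallback stays inside the exact bounds and is seeded", {
  set.seed(53)
  net <- random_small_network(n_nodes = 4, p_interval = 0.9)
  tv <- names(net$variables)[1L]
  target <- stats::setNames(net$variables[[tv]][1L], tv)
  exact <- posterior_bounds(net, target,
                            control = bounds_control(exact_budget = 1e6))
  approx1 <- posterior_bounds(net, target,
                              control = bounds_control(exact_budget = 1,
                                                       restarts = 4,
                                                       seed = 99))
  approx2 <- posterior_bounds(net, target,
                              control = bounds_control(exact_budget = 1,
                                                       restarts = 4,
                                                       seed = 99))
  expect_false(approx1$exact)
  expect_identical(approx1$lower, approx2$lower)
  expect_identical(approx1$upper, approx2$upper)
  ## inner approximation: never wider than the truth
  expect_gte(approx1$lower, exact$lower - 1e-9)
  expect_lte(approx1$upper, exact$upper + 1e-9)
})
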