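test_that("coherence checking flags exactly the violated inequalities", {
  expect_true(check_coherence(interval_distribution(c(0.2, 0.3),
                                                    c(0.5, 0.6)))$ok)
  r <- check_coherence(interval_distribution(c(0.6, 0.5), c(0.7, 0.6)))
  expect_false(r$ok)
  expect_match(r$violations, "sum\\(l\\)", all = FALSE)
  r2 <- check_coherence(interval_distribution(c(0, 0), c(0.3, 0.5)))
  expect_false(r2$ok)
  expect_match(r2$violations, "sum\\(u\\)", all = FALSE)
  expect_error(interval_distribution(c(0.2, 0.3), c(0.5, 0.6, 0.7)),
               class = "credalpod_structural_error")
  expect_false(check_coherence(interval_distribution(c(0.2, 0.8),
                                                     c(0.1, 0.9)))$ok)
})

test_that("reachability tightening matches the vertex-set min/max oracle", {
  d <- normalize_reachable(interval_distribution(c(0.3, 0.2), c(0.9, 0.6)))
  expect_equal(d$lower, c(0.4, 0.2))
  expect_equal(d$upper, c(0.8, 0.6))
  d2 <- normalize_reachable(interval_distribution(rep(0.1, 3), rep(0.9, 3)))
  expect_equal(d2$lower, rep(0.1, 3))
  expect_equal(d2$upper, rep(0.8, 3))
  pt <- normalize_reachable(interval_distribution(c(0.3, 0.7), c(0.3, 0.7)))
  expect_equal(pt$lower, c(0.3, 0.7))
  expect_equal(pt$upper, c(0.3, 0.7))
  expect_error(normalize_reachable(interval_distribution(c(0.6, 0.5),
                                                         c(0.7, 0.6))),
               class = "credalpod_coherence_error")

  set.seed(11)
  for (i in 1:100) {
    k <- sample(2:4, 1)
    s <- random_interval_spec(k)
    tight <- normalize_reachable(interval_distribution(s$l, s$u))
    V <- oracle_interval_vertices(s$l, s$u)
    expect_equal(tight$lower, apply(V, 2, min), tolerance = 1e-9)
    expect_equal(tight$upper, apply(V, 2, max), tolerance = 1e-9)
    ## idempotent, never enlarging
    again <- normalize_reachable(tight)
    expect_equal(again$lower, tight$lower)
    expect_equal(again$upper, tight$upper)
    expect_true(all(tight$lower >= s$l - 1e-12))
    expect_true(all(tight$upper <= s$u + 1e-12))
  }
})

test_that("vertex enumeration reproduces the worked examples", {
  expect_same_vertex_set(
    enumerate_vertices(credal_set(c(0.2, 0.4), c(0.6, 0.8))),
    rbind(c(0.2, 0.8), c(0.6, 0.4)))
  expect_same_vertex_set(
    enumerate_vertices(credal_set(c(0.1, 0.2, 0.3), c(0.5, 0.5, 0.5))),
    rbind(c(0.1, 0.4, 0.5), c(0.1, 0.5, 0.4), c(0.2, 0.5, 0.3),
          c(0.3, 0.2, 0.5), c(0.5, 0.2, 0.3)))
  expect_same_vertex_set(
    enumerate_vertices(credal_set(c(0.2, 0.4), c(0.6, 0.8),
                                  orderings = list(c(1, 2)))),
    rbind(c(0.5, 0.5), c(0.6, 0.4)))
})

test_that("vertex enumeration agrees with the bound-assignment oracle", {
  set.seed(23)
  for (i in 1:120) {
    k <- sample(2:4, 1)
    s <- random_interval_spec(k)
    V <- enumerate_vertices(credal_set(s$l, s$u))
    expect_same_vertex_set(V, oracle_interval_vertices(s$l, s$u))
    ## every vertex is a valid distribution inside the constraints
    expect_true(all(abs(rowSums(V) - 1) < 1e-9))
    expect_true(all(V >= matrix(s$l, nrow(V), k, byrow = TRUE) - 1e-9))
    ## convexity: midpoints of vertex pairs stay inside the box
    if (nrow(V) >= 2) {
      mid <- (V[1L, ] + V[nrow(V), ]) / 2
      expect_true(all(mid >= s$l - 1e-9) && all(mid <= s$u + 1e-9))
    }
  }
})

test_that("degenerate and infeasible credal sets behave as specified", {
  V <- enumerate_vertices(credal_set(c(0.3, 0.7), c(0.3, 0.7)))
  expect_equal(nrow(V), 1L)
  expect_equal(unname(V[1L, ]), c(0.3, 0.7))
  expect_error(enumerate_vertices(credal_set(c(0.6, 0.5), c(0.7, 0.6))),
               class = "credalpod_feasibility_error")
  ## orderings contradicting the intervals: p1 >= p2 but u1 < l2
  expect_error(
    enumerate_vertices(credal_set(c(0.0, 0.6), c(0.3, 0.9),
                                  orderings = list(c(1, 2)))),
    class = "credalpod_feasibility_error")
  expect_error(enumerate_vertices(credal_set(rep(0, 7), rep(1, 7))),
               class = "credalpod_size_error")
})

test_that("network validation reports cycles, gaps and bad tables by address", {
  net <- toy_ab_network()
  expect_true(validate_network(net)$ok)

  cyc <- net
  cyc$parents$A <- "B"
  r <- validate_network(cyc)
  expect_false(r$ok)
  expect_match(r$issues$problem, "cycle", all = FALSE)

  gap <- net
  gap$tables$B <- gap$tables$B[1L]
  r2 <- validate_network(gap)
  expect_false(r2$ok)
  expect_match(r2$issues$address, "^B", all = FALSE)

  bad <- net
  bad$tables$A <- list(credal_set(c(0, 0), c(0.3, 0.5)))
  r3 <- validate_network(bad)
  expect_false(r3$ok)
  expect_match(r3$issues$problem, "incoherent", all = FALSE)
})

test_that("graph mutilation severs parents and pins the intervened state", {
  net <- toy_ab_network()
  m <- mutilate(net, c(B = "b1"))
  expect_length(m$parents$B, 0)
  V <- enumerate_vertices(m$tables$B[[1L]])
  expect_equal(unname(V), matrix(c(1, 0), 1))
  expect_error(mutilate(net, c(B = "nope")),
               class = "credalpod_validation_error")
})
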