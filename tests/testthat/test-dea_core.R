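test_that("hand-solved CCR instances are reproduced exactly", {
  # single input/output: theta follows the output/input ratio
  d <- dmu_set(c("A", "B"), cbind(c(2, 4)), cbind(c(2, 2)))
  sc <- efficiency_scores(d)
  expect_equal(unname(sc["A"]), 1)
  expect_equal(unname(sc["B"]), 0.5)

  # two inputs, one output: C is enveloped by the A/B midpoint
  d3 <- dmu_set(c("A", "B", "C"),
                inputs = cbind(c(2, 4, 4), c(4, 2, 4)),
                outputs = cbind(c(1, 1, 1)))
  rc <- solve_ccr(d3, "C")
  expect_equal(rc$theta, 0.75)
  expect_setequal(rc$reference_set, c("A", "B"))
  expect_equal(unname(rc$lambdas[c("A", "B")]), c(0.5, 0.5), tolerance = 1e-9)
  expect_equal(solve_ccr(d3, "A")$theta, 1)
  expect_equal(solve_ccr(d3, "B")$theta, 1)

  # multiplier (dual) form agrees on the same instances
  expect_equal(solve_ccr_multiplier(d3, "C")$theta, 0.75, tolerance = 1e-9)
  expect_equal(solve_ccr_multiplier(d, "B")$theta, 0.5, tolerance = 1e-9)
})

test_that("a lone DMU envelops itself with theta = 1", {
  d <- dmu_set("only", cbind(3.2, 4e-4), cbind(0.04))
  expect_equal(solve_ccr(d, "only")$theta, 1)
  expect_equal(solve_ccr_multiplier(d, "only")$theta, 1)
})

test_that("envelopment and multiplier forms agree by duality on random instances", {
  for (i in 1:100) {
    set.seed(3000 + i)
    n <- sample(2:50, 1L)
    m <- sample(1:3, 1L)
    s <- sample(1:2, 1L)
    d <- rand_dmus(n, m, s, seed = 3000 + i, cohort_like = (i %% 2 == 0))
    target <- sample(d$ids, 1L)
    th_env <- solve_ccr(d, target)
    th_mul <- solve_ccr_multiplier(d, target)
    expect_equal(th_env$theta_raw, th_mul$theta_raw, tolerance = 1e-6,
                 label = sprintf("instance %d (n=%d m=%d s=%d)", i, n, m, s))
  }
})

test_that("envelopment scores match an independent LP solver", {
  for (seed in c(11, 12, 13)) {
    d <- rand_dmus(12L, seed = seed)
    target <- d$ids[seed %% 12 + 1L]
    expect_equal(solve_ccr(d, target)$theta_raw, linprog_theta(d, target),
                 tolerance = 1e-7)
  }
})

test_that("closed form holds for single-input single-output sets", {
  for (seed in 1:20) {
    set.seed(seed)
    n <- sample(2:30, 1L)
    d <- dmu_set(sprintf("u%d", 1:n), cbind(runif(n, 0.5, 9)),
                 cbind(runif(n, 0.5, 9)))
    expect_equal(efficiency_scores(d), closed_form_scores(d), tolerance = 1e-8)
  }
})

test_that("every score lies in (0, 1] and the frontier is attained", {
  for (seed in 1:10) {
    d <- rand_dmus(sample(5:40, 1L), seed = 400 + seed)
    sc <- efficiency_scores(d)
    expect_true(all(sc > 0 & sc <= 1))
    expect_equal(max(sc), 1, tolerance = 1e-6)
    # envelopment constraints hold at each reported optimum
    res <- solve_ccr(d, names(which.min(sc)))
    agg_in <- colSums(d$inputs * res$lambdas)
    agg_out <- colSums(d$outputs * res$lambdas)
    expect_true(all(agg_in <= res$theta_raw * d$inputs[match(res$dmu_id, d$ids), ] + 1e-7))
    expect_true(all(agg_out >= d$outputs[match(res$dmu_id, d$ids), ] - 1e-7))
  }
})

test_that("scores are invariant to DMU order and to duplicating a DMU", {
  d <- rand_dmus(15L, seed = 7)
  sc <- efficiency_scores(d)
  perm <- sample(15L)
  d2 <- dmu_set(d$ids[perm], d$inputs[perm, ], d$outputs[perm, ])
  expect_equal(efficiency_scores(d2)[names(sc)], sc, tolerance = 1e-9)

  dup <- dmu_set(c(d$ids, "copy"), rbind(d$inputs, d$inputs[3L, ]),
                 rbind(d$outputs, d$outputs[3L, ]))
  sc_dup <- efficiency_scores(dup)
  expect_equal(unname(sc_dup["copy"]), unname(sc_dup[d$ids[3L]]), tolerance = 1e-9)
  expect_equal(sc_dup[d$ids], sc, tolerance = 1e-8)
})

test_that("units invariance: rescaling a column changes no score", {
  for (i in 1:100) {
    d <- rand_dmus(sample(4:20, 1L), seed = 500 + i)
    sc <- efficiency_scores(d, solver_options(rescale = FALSE))
    cc <- exp(runif(1, -4, 4))
    col <- sample(2L, 1L)
    X <- d$inputs; X[, col] <- X[, col] * cc
    d2 <- dmu_set(d$ids, X, d$outputs)
    expect_equal(efficiency_scores(d2, solver_options(rescale = FALSE)), sc,
                 tolerance = 1e-8, label = paste("rescale case", i))
  }
})

test_that("CRS ray invariance: scaling one DMU's inputs and outputs together", {
  for (i in 1:20) {
    d <- rand_dmus(10L, seed = 600 + i)
    j <- sample(10L, 1L)
    cc <- runif(1, 0.3, 3)
    X <- d$inputs; Y <- d$outputs
    X[j, ] <- X[j, ] * cc; Y[j, ] <- Y[j, ] * cc
    d2 <- dmu_set(d$ids, X, Y)
    expect_equal(solve_ccr(d2, d$ids[j])$theta, solve_ccr(d, d$ids[j])$theta,
                 tolerance = 1e-7)
  }
})

test_that("dominance monotonicity: worsening one input never raises theta", {
  for (i in 1:100) {
    d <- rand_dmus(sample(4:20, 1L), seed = 700 + i)
    j <- sample(length(d$ids), 1L)
    col <- sample(2L, 1L)
    before <- solve_ccr(d, d$ids[j])$theta_raw
    X <- d$inputs
    X[j, col] <- X[j, col] * runif(1, 1.01, 2)
    after <- solve_ccr(dmu_set(d$ids, X, d$outputs), d$ids[j])$theta_raw
    expect_lte(after, before + 1e-8)
  }
})

test_that("invalid DMU data is rejected with the offending unit named", {
  expect_error(dmu_set(c("a", "b"), cbind(c(1, -2)), cbind(c(1, 1))),
               "DMU 'b'.*input_1")
  expect_error(dmu_set(c("a", "b"), cbind(c(1, 2)), cbind(c(0, 1))),
               "DMU 'a'.*output_1")
  expect_error(dmu_set(c("a", "a"), cbind(c(1, 2)), cbind(c(1, 1))),
               "duplicate")
  d <- rand_dmus(3L)
  expect_error(solve_ccr(d, "nope"), "not in the DMU set")
})

test_that("DMU sets round-trip through CSV", {
  d <- rand_dmus(8L, seed = 42)
  path <- withr::local_tempfile(fileext = ".csv")
  write_dmu_csv(d, path)
  d2 <- read_dmu_csv(path)
  expect_equal(d2$ids, d$ids)
  expect_equal(unname(d2$inputs), unname(d$inputs), tolerance = 1e-12)
  expect_equal(efficiency_scores(d2), efficiency_scores(d), tolerance = 1e-9)
})
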