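test_that("rank_compounds orders by score and honours tie policies", {
  s <- rank_compounds("t", c("a", "b", "c"), c(3, 1, 2), c(TRUE, FALSE, FALSE))
  expect_equal(s$entries$compound_id, c("a", "c", "b"))
  expect_equal(s$entries$rank, 1:3)

  # all-tied scores: stable keeps input order
  s2 <- rank_compounds("t", c("a", "b", "c"), c(1, 1, 1),
                       c(FALSE, TRUE, FALSE))
  expect_equal(s2$entries$compound_id, c("a", "b", "c"))

  # tie block of one active + one decoy: the two policies bound DE
  tie <- function(policy) rank_compounds("t", c("act", "dec"), c(5, 5),
                                         c(TRUE, FALSE), tie_policy = policy)
  expect_equal(docking_enrichment(tie("pessimistic"), 0.5), 0)
  expect_equal(docking_enrichment(tie("optimistic"), 0.5), 100)

  # ascending orientation for energy-like scores
  s3 <- rank_compounds("t", c("a", "b"), c(-9, -1), c(TRUE, FALSE),
                       ascending = TRUE)
  expect_equal(s3$entries$compound_id, c("a", "b"))

  expect_error(rank_compounds("t", c("a", "b"), c(1, NaN), c(TRUE, FALSE)),
               "b")
})

test_that("ranked_screen validates its invariants", {
  expect_error(make_screen(10, integer(0)), "at least one active")
  expect_error(make_screen(10, 1:10), "at least one active")
  expect_error(ranked_screen("t", data.frame(
    compound_id = c("a", "a"), score = 2:1, is_active = c(TRUE, FALSE))),
    "duplicate")
})

test_that("docking enrichment matches the ideal-screen maxima", {
  ideal <- make_screen(10000, 1:200)           # 2% actives, all on top
  expect_equal(docking_enrichment(ideal, 0.005), 25)
  expect_equal(docking_enrichment(ideal, 0.02), 100)
  bottom <- make_screen(1000, 981:1000)
  expect_equal(docking_enrichment(bottom, 0.02), 0)
  expect_error(docking_enrichment(ideal, 0), "fraction")
  expect_error(docking_enrichment(ideal, 1.2), "fraction")
})

test_that("docking enrichment is non-decreasing in the percentile", {
  set.seed(41)
  for (rep in 1:20) {
    s <- make_screen(400, sample(400, 8))
    de <- vapply(c(0.005, 0.02, 0.05, 0.1, 0.5, 1), function(x)
      docking_enrichment(s, x), 0)
    expect_true(all(diff(de) >= 0))
  }
})

test_that("bedroc hits its extremes and matches the summation oracle", {
  perf <- make_screen(1000, 1:20)
  worst <- make_screen(1000, 981:1000)
  for (a in c(321.9, 80.5, 20)) {
    expect_equal(suppressWarnings(bedroc(perf, a)), 1, tolerance = 1e-9)
    expect_lt(abs(suppressWarnings(bedroc(worst, a))), 1e-9)
  }
  s <- make_screen(100, c(1, 10, 20, 50, 90))
  expect_lt(abs(suppressWarnings(bedroc(s, 20)) -
                  bedroc_oracle(c(1, 10, 20, 50, 90), 100, 20)), 1e-12)

  set.seed(7)
  for (rep in 1:100) {
    N <- sample(20:500, 1)
    n <- sample(seq_len(max(1, N %/% 5)), 1)
    r <- sort(sample(N, n))
    alpha <- runif(1, 1, 150)
    expect_lt(abs(suppressWarnings(bedroc(make_screen(N, r), alpha)) -
                    bedroc_oracle(r, N, alpha)), 1e-12)
  }
})

test_that("bedroc depends only on ranks, not raw score values", {
  set.seed(13)
  for (rep in 1:20) {
    N <- 200; act <- sample(N, 6)
    sc <- sort(rnorm(N), decreasing = TRUE)
    s1 <- rank_compounds("t", paste0("c", 1:N), sc, seq_len(N) %in% act)
    s2 <- rank_compounds("t", paste0("c", 1:N), exp(3 * sc),
                         seq_len(N) %in% act)   # strictly monotone transform
    expect_identical(suppressWarnings(bedroc(s1, 80.5)),
                     suppressWarnings(bedroc(s2, 80.5)))
  }
})

test_that("bedroc rejects degenerate input and flags large alpha * R_a", {
  expect_error(bedroc(make_screen(100, 1:5), -1), "positive")
  expect_warning(bedroc(make_screen(100, 1:25), 80.5), "alpha")
  expect_silent(bedroc(make_screen(100, 1:2), 20))
})

test_that("weight_fraction reproduces the 80% calibration triple", {
  expect_equal(round(weight_fraction(80.5, 0.02), 2), 0.80)
  expect_equal(round(weight_fraction(321.9, 0.005), 2), 0.80)
  expect_equal(round(weight_fraction(20.0, 0.08), 2), 0.80)
  expect_equal(weight_fraction(50, 1), 1)
  # strictly increasing in both arguments
  a <- seq(5, 300, length.out = 30)
  expect_true(all(diff(weight_fraction(a, 0.02)) > 0))
  x <- seq(0.001, 0.3, length.out = 30)   # below double saturation of e^-ax
  expect_true(all(diff(weight_fraction(80.5, x)) > 0))
})

test_that("alpha_for_fraction inverts the calibration", {
  expect_equal(round(alpha_for_fraction(0.005, 0.8), 1), 321.9)
  expect_equal(round(alpha_for_fraction(0.02, 0.8), 1), 80.5)
  set.seed(3)
  for (rep in 1:20) {
    x <- runif(1, 0.001, 0.5)
    w <- runif(1, x + 0.05, 0.99)
    a <- alpha_for_fraction(x, w)
    expect_lt(abs(weight_fraction(a, x) - w), 1e-8)
  }
  expect_error(alpha_for_fraction(0.5, 0.2), "exceed")
})

test_that("success is a strict comparison", {
  expect_true(success(0.51))
  expect_false(success(0.50))
  expect_false(success(0.03))
  expect_equal(success(c(0.2, 0.7, 0.5)), c(FALSE, TRUE, FALSE))
})

test_that("net balance counts wins minus losses over shared targets", {
  a <- c(t1 = 0.6, t2 = 0.7, t3 = 0.2)
  expect_equal(net_balance(a, a), 0)
  b <- a - 0.1
  expect_equal(net_balance(a, b), 1)
  expect_equal(net_balance(b, a), -1)
  b2 <- c(t1 = 0.5, t2 = 0.8, t3 = 0.1)   # a wins 2, loses 1
  expect_equal(net_balance(a, b2), 1 / 3)
  # exact ties count for neither side
  b3 <- c(t1 = 0.6, t2 = 0.1, t3 = 0.2)
  expect_equal(net_balance(a, b3), 1 / 3)
  expect_error(net_balance(a, c(t1 = 1, t2 = 1, t9 = 1)), "t9")
})

test_that("restricted net balance only counts targets either program won", {
  a <- c(t1 = 0.9, t2 = 0.3, t3 = 0.45, t4 = 0.6)
  b <- c(t1 = 0.7, t2 = 0.2, t3 = 0.40, t4 = 0.8)
  # only t1 and t4 have max > 0.5; a wins t1, loses t4
  expect_equal(net_balance(a, b, restrict_to_success = TRUE), 0)
  low_a <- c(t1 = 0.1); low_b <- c(t1 = 0.2)
  expect_error(net_balance(low_a, low_b, restrict_to_success = TRUE),
               "empty")
})

test_that("net balance is antisymmetric and bounded on random inputs", {
  set.seed(5)
  for (rep in 1:50) {
    n <- sample(3:40, 1)
    a <- setNames(runif(n), paste0("t", 1:n))
    b <- setNames(runif(n), paste0("t", 1:n))
    if (rep %% 3 == 0) b[1] <- a[1]   # inject exact ties
    expect_equal(net_balance(a, b), -net_balance(b, a))
    expect_lte(abs(net_balance(a, b)), 1)
  }
})

test_that("metrics_table assembles DE and BEDROC columns per target", {
  screens <- gen_screen_collection(make_screen_specs(3, 510, 10,
                                                     enrichment_rate = 30,
                                                     seed = 2))
  m <- suppressWarnings(metrics_table(screens))
  expect_equal(nrow(m), 3)
  expect_named(m, c("target_id", "DE_0.5", "DE_2", "DE_8",
                    "BEDROC_321.9", "BEDROC_80.5", "BEDROC_20"))
  expect_true(all(m$BEDROC_80.5 >= 0 & m$BEDROC_80.5 <= 1))
})
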