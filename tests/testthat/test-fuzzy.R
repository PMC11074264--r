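test_that("gaussian membership closed forms and symmetry", {
  expect_equal(gaussianMembership(2, 2, 1), 1)
  expect_equal(gaussianMembership(1, 0, 1), exp(-0.5))
  expect_equal(gaussianMembership(3, 2, 1), exp(-0.5), tolerance = 1e-12)
  # symmetric in (u - m)
  set.seed(1)
  u <- rnorm(20); m <- 0.3; s <- 0.8
  expect_equal(gaussianMembership(u, m, s), gaussianMembership(2 * m - u, m, s))
  expect_error(gaussianMembership(0, 0, 1e-5), "sigmaMin")
})

test_that("fuzzify hits 1 at the rule centre and hand-computed values", {
  bank <- fuzzyRuleBank(matrix(c(0, 0, 2, 2), 2, 2), matrix(1, 2, 2))
  for (agg in c("geometric-mean", "product-log")) {
    s <- fuzzify(c(0, 0), bank, agg)
    expect_equal(s[1], 1, label = agg)
  }
  # n_inputs=2, n_rules=1, m=(0,0), sigma=(1,1), x=(1,1):
  # exponent (1/2+1/2)/2 = 1/2 under the geometric mean
  bank1 <- fuzzyRuleBank(matrix(0, 2, 1), matrix(1, 2, 1))
  expect_equal(fuzzify(c(1, 1), bank1, "geometric-mean"), exp(-0.5))
  expect_error(fuzzify(c(1, 2, 3), bank1), "length")
})

test_that("fuzzify strengths lie in (0,1] and decrease away from centres", {
  bank <- randomRuleBank(4, 3, seed = 8L)
  set.seed(9)
  for (i in 1:20) {
    s <- fuzzify(rnorm(4), bank)
    expect_true(all(s > 0 & s <= 1))
  }
  # moving one coordinate further from a rule's mean lowers that strength
  x <- bank@means[, 2] + 0.5
  s0 <- fuzzify(x, bank)
  x[3] <- x[3] + 1
  s1 <- fuzzify(x, bank)
  expect_lt(s1[2], s0[2])
})

test_that("fuzzify is invariant under consistent input permutation", {
  bank <- randomRuleBank(5, 2, seed = 3L)
  set.seed(4)
  x <- rnorm(5)
  perm <- c(4, 1, 5, 2, 3)
  bankP <- fuzzyRuleBank(bank@means[perm, ], bank@sigmas[perm, ])
  for (agg in c("geometric-mean", "product-log"))
    expect_equal(fuzzify(x[perm], bankP, agg), fuzzify(x, bank, agg))
})

test_that("defuzzify selects, interpolates, rescales and guards zero", {
  C <- matrix(c(3, -1), 1, 2)
  expect_equal(defuzzify(c(1, 0), C), 3, tolerance = 1e-6)
  expect_equal(defuzzify(c(1, 1), matrix(c(0, 4), 1, 2)), 2, tolerance = 1e-6)
  expect_equal(defuzzify(c(0, 0), C), 0)
  # invariance to positive rescaling
  set.seed(5)
  C2 <- matrix(rnorm(6), 2, 3)
  x <- runif(3, 0.1, 1)
  expect_equal(defuzzify(2.5 * x, C2), defuzzify(x, C2), tolerance = 1e-6)
  # bounded by the centre range for nonnegative x
  v <- defuzzify(x, C2)
  expect_true(all(v >= apply(C2, 1, min) - 1e-9 &
                  v <= apply(C2, 1, max) + 1e-9))
  expect_error(defuzzify(c(1, 2), C2), "columns")
  expect_error(defuzzify(c(Inf, 1, 1), C2), "finite")
})

test_that("analytic gradients match central finite differences", {
  for (seed in 1:4) {
    expect_lt(checkGradients("fuzzify", nInputs = 5L, nRules = 3L,
                             h = 1e-5, seed = seed), 1e-4)
    expect_lt(checkGradients("fuzzify", nInputs = 4L, nRules = 2L,
                             aggregation = "product-log", seed = seed), 1e-4)
    expect_lt(checkGradients("defuzzify", nRules = 4L, nOutputs = 2L,
                             seed = seed), 1e-4)
  }
  expect_error(checkGradients("fuzzify", h = 1e-2), "h must")
})

test_that("the gradient harness detects corrupted gradients", {
  expect_gt(checkGradients("fuzzify", corrupt = 0.1), 1e-2)
  expect_gt(checkGradients("defuzzify", corrupt = 0.1), 1e-2)
})

test_that("rule banks validate their shapes and floors", {
  expect_error(fuzzyRuleBank(matrix(0, 2, 2), matrix(1, 3, 2)), "identical")
  expect_error(fuzzyRuleBank(matrix(0, 2, 2), matrix(1e-6, 2, 2)), "sigmaMin")
  expect_error(fuzzyRuleBank(matrix(0, 2, 2), matrix(1, 2, 2),
                             consequents = c(1, 2, 3)), "per rule")
})
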