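mkPattern <- function(values, t0 = 0, fps = 8.7, label = "eye") {
  n <- length(values)
  new("ConditionedPattern", label = label,
      times = t0 + (seq_len(n) - 1L) / fps, values = values,
      cutoffHz = 0.08, fps = fps, report = list(), params = list(),
      sampleId = "s")
}

test_that("alignment restricts both patterns to their common span", {
  fps <- 1
  a <- mkPattern(sin(1:61), t0 = 0, fps = fps)
  b <- mkPattern(cos(1:56), t0 = 5, fps = fps, label = "muzzle")
  pr <- alignPair(a, b)
  expect_length(pr@v1, 56L)
  expect_equal(pr@times[1L], 5)
  expect_equal(pr@times[length(pr@times)], 60)
  expect_equal(pr@v1, a@values[6:61])
  expect_equal(pr@v2, b@values)

  ## identical grids pass through unchanged
  c2 <- mkPattern(cos(1:61), t0 = 0, fps = fps, label = "muzzle")
  pr2 <- alignPair(a, c2)
  expect_equal(pr2@v1, a@values)
  expect_equal(pr2@v2, c2@values)

  ## disjoint spans cannot be aligned
  d <- mkPattern(cos(1:10), t0 = 100, fps = fps)
  expect_error(alignPair(a, d), class = "alignmentError")
})

test_that("cosine similarity honours its algebraic identities", {
  set.seed(2)
  v <- rnorm(40)
  expect_equal(cosineSimilarity(v, v), 1)
  expect_equal(cosineSimilarity(v, -v), -1)
  expect_equal(cosineSimilarity(c(1, 0), c(0, 1)), 0)
  expect_equal(cosineSimilarity(c(1, 2), c(2, 4)), 1)
  ## bounds and positive-scale invariance over random pairs
  for (i in 1:25) {
    a <- rnorm(30); b <- rnorm(30)
    cs <- cosineSimilarity(a, b)
    expect_gte(cs, -1); expect_lte(cs, 1)
    expect_equal(cosineSimilarity(3.7 * a, b), cs)
    expect_equal(cosineSimilarity(a, 0.002 * b), cs)
  }
  expect_error(cosineSimilarity(rep(0, 5), rnorm(5)),
               class = "degenerateInputError")
  expect_error(cosineSimilarity(rnorm(4), rnorm(5)), class = "inputError")
})

test_that("cosine equals Pearson correlation on centred vectors", {
  set.seed(3)
  for (i in 1:10) {
    a <- rnorm(100); b <- rnorm(100)
    a <- a - mean(a); b <- b - mean(b)
    expect_equal(cosineSimilarity(a, b), cor(a, b), tolerance = 1e-8)
  }
})

test_that("Monte-Carlo permutation p matches exhaustive enumeration", {
  set.seed(7)
  for (n in c(4L, 5L, 6L)) {
    fixed <- rnorm(n); moving <- rnorm(n)
    pr <- new("AlignedPair", v1 = fixed, v2 = moving,
              times = seq_len(n), labels = c("eye", "muzzle"),
              sampleId = "s")
    exact <- exactPermutationP(fixed, moving)
    mc <- permutationTest(pr, nPermutations = 10000L, seed = 123L)
    expect_lt(abs(pValue(mc) - exact), 0.02)
  }
})

test_that("identical smooth patterns are unreachable by permutation", {
  ramp <- seq(-1, 1, length.out = 500)
  pr <- new("AlignedPair", v1 = ramp, v2 = ramp, times = seq_len(500),
            labels = c("eye", "muzzle"), sampleId = "s")
  res <- permutationTest(pr, nPermutations = 2000L, seed = 5L)
  expect_identical(pValue(res), 0)
  expect_lt(res@nullMax, 1)
})

test_that("permutation test edge cases and options behave as stated", {
  set.seed(9)
  pr <- new("AlignedPair", v1 = rnorm(20), v2 = rnorm(20),
            times = 1:20, labels = c("eye", "muzzle"), sampleId = "s")
  one <- permutationTest(pr, nPermutations = 1L, seed = 2L)
  expect_true(pValue(one) %in% c(0, 1))

  a <- permutationTest(pr, nPermutations = 500L, seed = 11L)
  b <- permutationTest(pr, nPermutations = 500L, seed = 11L)
  expect_identical(pValue(a), pValue(b))
  expect_identical(a@countGeObserved, b@countGeObserved)

  corr <- permutationTest(pr, nPermutations = 500L, seed = 11L,
                          correction = "add_one")
  expect_equal(pValue(corr), (a@countGeObserved + 1) / 501)

  ## permuting the other side is also seeded and valid
  other <- permutationTest(pr, nPermutations = 500L, seed = 11L,
                           permute = "v1")
  expect_gte(pValue(other), 0); expect_lte(pValue(other), 1)
})

test_that("similarity bands follow the lower-inclusive boundaries", {
  expect_identical(classifySimilarity(0.72), "0.5-1")
  expect_identical(classifySimilarity(1), "0.5-1")
  expect_identical(classifySimilarity(0.5), "0.5-1")
  expect_identical(classifySimilarity(0.3), "0.3-0.5")
  expect_identical(classifySimilarity(0.2999), "<0.3")
  expect_identical(classifySimilarity(-0.2), "<0.3")
  expect_identical(classifySimilarity(-1), "<0.3")
  expect_identical(classifySimilarity(c(0.72, 0.4, NA)),
                   c("0.5-1", "0.3-0.5", NA))
  expect_error(classifySimilarity(1.5), class = "inputError")
})
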