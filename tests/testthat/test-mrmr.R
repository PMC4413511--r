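test_that("discretize implements the three-state mean +/- theta*sd scheme", {
  expect_equal(discretize(rep(3.7, 10)), rep(2L, 10))

  v <- c(0, 0, 0, 10)   # mu = 2.5, sd = 5: 10 > mu + sd -> high
  expect_equal(discretize(v), c(2L, 2L, 2L, 3L))
  mu <- mean(v); s <- sd(v)
  expect_true(10 > mu + s && all(c(0) >= mu - s))

  expect_equal(discretize(c(0, 1, 0, 1), categorical = TRUE),
               c(1L, 2L, 1L, 2L))
  expect_error(discretize(numeric(0)), "empty")
})

test_that("mutual information matches closed forms", {
  x <- rep(c(0, 1), each = 4)
  expect_equal(mutual_information(x, x), 1)          # identical binary, 1 bit
  expect_equal(mutual_information(rep(1, 8), x), 0)  # constant -> 0
  expect_equal(mutual_information(c(0, 0, 1, 1), c(0, 1, 0, 1)), 0)
  expect_error(mutual_information(1:3, 1:4), "equal length")
  # agrees with the table-based oracle on random categorical data
  withr::with_seed(3, {
    for (i in 1:10) {
      a <- sample(1:3, 30, replace = TRUE)
      b <- sample(1:2, 30, replace = TRUE)
      expect_equal(mutual_information(a, b), mi_oracle(a, b))
    }
  })
})

test_that("mrmr_rank puts a label-identical feature first and penalises duplicates", {
  withr::with_seed(9, {
    # unbalanced classes: a balanced two-valued feature would discretize
    # entirely to "mid" under the mean +/- sd scheme and carry no signal
    labels <- c(rep(1L, 6), rep(-1L, 14))
    # informative but imperfect (two disagreements with the label), so the
    # step-2 criterion for its exact copy, I(f, c) - H(f), is strictly
    # negative while an independent noise feature scores near zero
    informative <- as.numeric(labels == 1L)
    informative[c(1, 7)] <- 1 - informative[c(1, 7)]
    noise <- rnorm(20)
    x <- cbind(informative, copy = informative, noise)
    fm <- fm_from_matrix(x, labels)
    r <- mrmr_rank(fm)
    expect_equal(r$order[1], 1L)
    # the copy is maximally redundant with feature 1, so the noise feature
    # is selected before it at step 2
    expect_equal(r$order[2], 3L)
    expect_equal(r$order[3], 2L)
    expect_lt(r$step_scores[3], 0)
  })
})

test_that("greedy ranking equals the exhaustive oracle on small instances", {
  withr::with_seed(17, {
    for (i in 1:10) {
      n <- sample(10:40, 1)
      p <- sample(2:12, 1)
      x <- matrix(rnorm(n * p), n, p)
      labels <- sample(c(-1L, 1L), n, replace = TRUE)
      if (length(unique(labels)) < 2) labels[1] <- -labels[1]
      fm <- fm_from_matrix(x, labels)
      expect_equal(mrmr_rank(fm)$order, mrmr_oracle(x, labels))
    }
  })
})

test_that("ranking respects invariants", {
  withr::with_seed(31, {
    n <- 30; p <- 8
    x <- matrix(rnorm(n * p), n, p)
    labels <- rep(c(1L, -1L), length.out = n)
    fm <- fm_from_matrix(x, labels)
    r <- mrmr_rank(fm)
    expect_setequal(r$order, seq_len(p))
    expect_true(all(r$relevance >= 0))
    expect_equal(r$order[1], which.max(r$relevance))

    # constant feature: zero relevance and zero redundancy contribution, so
    # the ranking is unchanged up to the step where the constant is taken
    # (once selected it enlarges m, the redundancy divisor, which the
    # printed criterion applies to later steps)
    fmc <- fm_from_matrix(cbind(x, const = 1), labels)
    rc <- mrmr_rank(fmc)
    expect_equal(rc$relevance[p + 1], 0)
    const_at <- which(rc$order == p + 1L)
    expect_equal(rc$order[seq_len(const_at - 1L)], r$order[seq_len(const_at - 1L)])
    expect_equal(rc$step_scores[const_at], 0)

    # top_n gives the same prefix as the full ranking
    expect_equal(mrmr_rank(fm, top_n = 3)$order, r$order[1:3])
  })
  expect_error(mrmr_rank(fm_from_matrix(matrix(rnorm(20), 10, 2),
                                        rep(1L, 10))), "degenerate")
})

test_that("rankings round-trip through TSV", {
  withr::with_seed(2, {
    fm <- fm_from_matrix(matrix(rnorm(80), 20, 4), rep(c(1L, -1L), 10))
  })
  r <- mrmr_rank(fm)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_ranking(r, path)
  back <- read_ranking(path)
  expect_equal(back$order, r$order)
  expect_equal(back$relevance[r$order], r$relevance[r$order])
  expect_equal(back$step_scores, r$step_scores)
})
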