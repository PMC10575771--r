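test_that("dip statistic reproduces exact constructions", {
  expect_equal(dip_stat(c(0, 1)), 0.25, tolerance = 1e-12)
  expect_equal(dip_stat(seq(0, 1, length.out = 50)), 0.01, tolerance = 1e-12)
  expect_equal(dip_stat(rep(3.7, 9)), 1 / 18, tolerance = 1e-12)  # constant
  expect_equal(dip_stat(c(0, 0, 0, 1, 1, 1)), 0.25, tolerance = 1e-12)
  expect_error(dip_stat(1), "at least two")
  expect_error(dip_stat(c(1, NA)), "non-finite")
})

test_that("dip statistic matches brute-force unimodal-CDF minimisation (n <= 8)", {
  set.seed(51)
  for (rep in 1:40) {
    n <- sample(2:8, 1)
    x <- switch(sample(1:4, 1),
                runif(n), rnorm(n), round(runif(n, 0, 3)),
                c(rnorm(ceiling(n / 2), -2), rnorm(floor(n / 2), 2)))
    expect_equal(dip_stat(x), oracle_dip(x), tolerance = 1e-9,
                 label = paste("dip of", paste(signif(x, 6), collapse = ",")))
  }
})

test_that("the two internal dip routes agree on continuous samples", {
  # the iterative hull algorithm (tie-free route) against the feasibility
  # search used for tied data -- independent formulations of the same value
  set.seed(52)
  for (rep in 1:40) {
    n <- sample(10:150, 1)
    x <- if (rep %% 2) rnorm(n) else c(rnorm(n, -2), rnorm(n, 2))
    expect_equal(glumeta:::dip_stat_cpp(x), glumeta:::dip_stat_feas_cpp(x),
                 tolerance = 1e-9)
  }
})

test_that("dip is invariant to affine maps and permutations, within bounds", {
  set.seed(53)
  for (rep in 1:25) {
    n <- sample(5:80, 1)
    x <- rnorm(n)
    D <- dip_stat(x)
    expect_gte(D, 1 / (2 * n))
    expect_lte(D, 0.25)
    a <- runif(1, 0.1, 100); b <- runif(1, -50, 50)
    expect_equal(dip_stat(a * x + b), D, tolerance = 1e-12)
    expect_equal(dip_stat(sample(x)), D, tolerance = 1e-15)
  }
})

test_that("duplicating a sample leaves the dip unchanged (same ecdf)", {
  set.seed(54)
  for (rep in 1:10) {
    x <- rnorm(sample(5:60, 1))
    expect_equal(dip_stat(c(x, x)), dip_stat(x), tolerance = 1e-12)
    expect_equal(dip_stat(rep(x, 3)), dip_stat(x), tolerance = 1e-12)
  }
})

test_that("Monte-Carlo p-values are calibrated at the extremes and reproducible", {
  # D at the theoretical minimum can never be exceeded downwards
  expect_equal(dip_pvalue(1 / 100, n = 50, n_sim = 500, seed = 9), 1,
               tolerance = 2e-3)
  p1 <- dip_pvalue(0.05, n = 100, n_sim = 500, seed = 7)
  p2 <- dip_pvalue(0.05, n = 100, n_sim = 500, seed = 7)
  expect_identical(p1, p2)
  expect_gte(p1, 1 / 501)
  expect_error(dip_pvalue(0.05, 100, n_sim = 100, seed = 1))  # n_sim >= 500
  expect_error(dip_pvalue(0.05, 100, n_sim = 500), "seed")
  # caller's RNG state is untouched
  set.seed(99); before <- rnorm(1)
  set.seed(99); invisible(dip_pvalue(0.05, 50, 500, seed = 3))
  expect_identical(rnorm(1), before)
})

test_that("a strongly separated mixture is rejected with high power", {
  set.seed(55)
  rej <- vapply(1:200, function(i) {
    x <- c(rnorm(100, -3), rnorm(100, 3))
    dip_pvalue(dip_stat(x), 200, n_sim = 500, seed = 1000 + i) < 0.05
  }, TRUE)
  expect_gte(mean(rej), 0.95)
})

test_that("rejection rate is monotone in mixture separation", {
  set.seed(56)
  rates <- vapply(c(0, 2, 4), function(sep) {
    mean(vapply(1:100, function(i) {
      x <- c(rnorm(50, -sep / 2), rnorm(50, sep / 2))
      dip_pvalue(dip_stat(x), 100, n_sim = 500, seed = 7000 + i) < 0.05
    }, TRUE))
  }, 1)
  # non-decreasing up to Monte-Carlo noise on 100 replicates
  expect_gte(rates[2], rates[1] - 0.05)
  expect_gte(rates[3], rates[2])
  expect_lt(rates[1], 0.15)
  expect_gt(rates[3], 0.5)
})

test_that("pool_and_test normalises, concatenates and reports per study", {
  set.seed(57)
  s1 <- rnorm(40, 10, 1.5)
  one <- pool_and_test(list(a = s1), scheme = "divide_by_mean",
                       n_sim = 500, seed = 11)
  expect_equal(one$pooled$statistic, dip_stat(s1 / mean(s1)), tolerance = 1e-12)
  # dividing by the mean is what makes differently-scaled studies poolable
  expect_equal(one$pooled$statistic, dip_stat(s1), tolerance = 1e-12)

  two <- pool_and_test(list(a = s1, b = s1), n_sim = 500, seed = 11)
  expect_equal(two$pooled$statistic, one$pooled$statistic, tolerance = 1e-12)

  cent <- pool_and_test(list(a = s1), scheme = "subtract_mean",
                        n_sim = 500, seed = 11)
  expect_equal(cent$pooled$statistic, dip_stat(s1 - mean(s1)), tolerance = 1e-12)

  expect_error(pool_and_test(list(c(-1, 1)), scheme = "divide_by_mean",
                             n_sim = 500, seed = 1), "zero")

  # long-format input
  df <- data.frame(study_id = rep(c("s1", "s2"), each = 40),
                   value = c(s1, rnorm(40, 20, 3)))
  pl <- pool_and_test(df, n_sim = 500, seed = 12)
  expect_named(pl$per_study, c("s1", "s2"))
  expect_equal(pl$pooled$n, 80)
  expect_output(print(pl), "Pooled dip test")
})

test_that("samples from one common distribution stay unimodal after pooling", {
  set.seed(58)
  ok <- vapply(1:50, function(i) {
    studies <- lapply(1:5, function(s) rnorm(30, mean = 8 + 2 * s, sd = 1 + 0.1 * s))
    pool_and_test(studies, scheme = "divide_by_mean",
                  n_sim = 500, seed = 300 + i)$pooled$p.value > 0.05
  }, TRUE)
  expect_gte(mean(ok), 0.9)
})
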