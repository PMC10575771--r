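test_that("lnCVR matches hand-derived arithmetic", {
  # doubled CV, equal n: bias terms cancel
  expect_equal(ln_cvr(10, 2, 16, 10, 1, 16)$yi, log(2), tolerance = 1e-12)
  # identical arms, equal n
  expect_equal(ln_cvr(10, 1.5, 20, 10, 1.5, 20)$yi, 0, tolerance = 1e-12)
  # identical arms, unequal n: only the bias terms remain
  expect_equal(ln_cvr(10, 1.5, 11, 10, 1.5, 21)$yi, 1 / 20 - 1 / 40,
               tolerance = 1e-12)
  expect_error(ln_cvr(-1, 1, 10, 10, 1, 10), "non-positive mean")
  expect_error(ln_cvr(10, 1, 1, 10, 1, 10), "bias term")
})

test_that("lnVR matches its formula and reduces to lnCVR at equal means", {
  expect_equal(ln_vr(10, 2, 16, 10, 1, 16)$yi, log(2), tolerance = 1e-12)
  expect_equal(ln_vr(9, 1.5, 25, 14, 1.5, 25)$yi, 0, tolerance = 1e-12)
  expect_equal(ln_vr(10, 2, 12, 10, 1, 30)$vi, 1 / 22 + 1 / 58, tolerance = 1e-12)
  set.seed(21)
  for (i in 1:20) {
    m <- runif(1, 5, 20); s <- runif(2, 0.5, 3); n <- sample(5:50, 2)
    expect_equal(ln_cvr(m, s[1], n[1], m, s[2], n[2])$yi,
                 ln_vr(m, s[1], n[1], m, s[2], n[2])$yi, tolerance = 1e-12)
  }
})

test_that("Hedges' g applies the small-sample correction and is antisymmetric", {
  g <- hedges_g(12, 2, 20, 10, 2, 20)
  expect_equal(g$yi, 1 - 3 / 151, tolerance = 1e-12)   # d = 1, J = 1 - 3/151
  expect_equal(g$df, 38)
  expect_equal(hedges_g(10, 2, 20, 10, 2, 20)$yi, 0)
  set.seed(22)
  for (i in 1:20) {
    mp <- runif(1, 5, 15); mc <- runif(1, 5, 15)
    sp <- runif(1, 0.5, 3); sc <- runif(1, 0.5, 3)
    np <- sample(5:60, 1); nc <- sample(5:60, 1)
    expect_equal(hedges_g(mp, sp, np, mc, sc, nc)$yi,
                 -hedges_g(mc, sc, nc, mp, sp, np)$yi, tolerance = 1e-12)
  }
  expect_error(hedges_g(1, 0, 10, 1, 0, 10), "non-positive SD")
})

test_that("all three measures are invariant to rescaling both arms", {
  set.seed(23)
  for (i in 1:15) {
    mp <- runif(1, 5, 15); mc <- runif(1, 5, 15)
    sp <- runif(1, 0.5, 3); sc <- runif(1, 0.5, 3)
    np <- sample(5:60, 1); nc <- sample(5:60, 1)
    for (cfac in c(1e-3, 7.3, 1e5)) {
      expect_equal(ln_cvr(mp, sp, np, mc, sc, nc),
                   ln_cvr(cfac * mp, cfac * sp, np, cfac * mc, cfac * sc, nc),
                   tolerance = 1e-10)
      expect_equal(ln_vr(mp, sp, np, mc, sc, nc)$yi,
                   ln_vr(cfac * mp, cfac * sp, np, cfac * mc, cfac * sc, nc)$yi,
                   tolerance = 1e-10)
      expect_equal(hedges_g(mp, sp, np, mc, sc, nc)$yi,
                   hedges_g(cfac * mp, cfac * sp, np, cfac * mc, cfac * sc, nc)$yi,
                   tolerance = 1e-10)
    }
  }
})

test_that("lnCVR minus lnVR equals log mean ratio of controls to patients", {
  set.seed(24)
  for (i in 1:20) {
    mp <- runif(1, 5, 15); mc <- runif(1, 5, 15)
    sp <- runif(1, 0.5, 3); sc <- runif(1, 0.5, 3)
    np <- sample(5:60, 1); nc <- sample(5:60, 1)
    expect_equal(ln_cvr(mp, sp, np, mc, sc, nc)$yi -
                 ln_vr(mp, sp, np, mc, sc, nc)$yi,
                 log(mc / mp), tolerance = 1e-12)
  }
})

test_that("effect sizes agree with the independent metafor implementation", {
  tab <- make_table(k = 12, seed = 25)
  for (pair in list(c("lnCVR", "CVR"), c("lnVR", "VR"))) {
    mine <- effect_sizes(tab, measure = pair[1])
    ref <- metafor::escalc(measure = pair[2],
                           m1i = tab$mean_p, sd1i = tab$sd_p, n1i = tab$n_p,
                           m2i = tab$mean_c, sd2i = tab$sd_c, n2i = tab$n_c)
    expect_equal(mine$yi, as.numeric(ref$yi), tolerance = 1e-10)
    expect_equal(mine$vi, as.numeric(ref$vi), tolerance = 1e-10)
  }
  # Hedges' g: this package uses the standard approximation
  # J = 1 - 3/(4 df - 1) with J^2 shrinkage on the whole variance; metafor's
  # default uses the exact gamma-ratio J, so estimates agree only to the
  # approximation's accuracy (the variance formula itself is validated
  # against simulation in the test above)
  mine_g <- effect_sizes(tab, measure = "SMD")
  ref_g <- metafor::escalc(measure = "SMD",
                           m1i = tab$mean_p, sd1i = tab$sd_p, n1i = tab$n_p,
                           m2i = tab$mean_c, sd2i = tab$sd_c, n2i = tab$n_c)
  expect_equal(mine_g$yi, as.numeric(ref_g$yi), tolerance = 1e-5)
  mine_ub <- effect_sizes(tab, measure = "SMD", g_variance = "UB")
  ref_ub <- metafor::escalc(measure = "SMD", vtype = "UB",
                            m1i = tab$mean_p, sd1i = tab$sd_p, n1i = tab$n_p,
                            m2i = tab$mean_c, sd2i = tab$sd_c, n2i = tab$n_c)
  expect_equal(mine_ub$vi, as.numeric(ref_ub$vi), tolerance = 1e-5)
})

test_that("lnCVR converges to the population log CV ratio as n grows", {
  # simulated bias shrinks roughly like 1/n
  set.seed(26)
  truth <- log((3 / 12) / (2 / 10))
  bias <- vapply(c(10, 40, 160), function(n) {
    est <- replicate(3000, {
      xp <- rnorm(n, 12, 3); xc <- rnorm(n, 10, 2)
      ln_cvr(mean(xp), sd(xp), n, mean(xc), sd(xc), n)$yi
    })
    mean(est) - truth
  }, 1)
  expect_lt(abs(bias[3]), abs(bias[1]) + 0.01)
  expect_lt(abs(bias[3]), 0.01)
})

test_that("the g sampling variance matches simulation at n = 20 + 20", {
  set.seed(27)
  n <- 20; delta <- 0.5
  gs <- replicate(10000, {
    xp <- rnorm(n, 10 + delta * 2, 2); xc <- rnorm(n, 10, 2)
    hedges_g(mean(xp), sd(xp), n, mean(xc), sd(xc), n)$yi
  })
  v_formula <- hedges_g(10 + delta * 2, 2, n, 10, 2, n)$vi
  expect_equal(var(gs), v_formula, tolerance = 0.05)
})

test_that("weighted Pearson behaves like a correlation", {
  x <- c(1, 2, 3, 5, 8)
  expect_equal(weighted_pearson(x, 2 * x, runif(5, 0.1, 2)), 1, tolerance = 1e-12)
  y <- c(2, 1, 4, 3, 7)
  expect_equal(weighted_pearson(x, y, rep(1, 5)), cor(x, y), tolerance = 1e-12)
  set.seed(28)
  w <- runif(5, 0.2, 3)
  perm <- sample(5)
  expect_equal(weighted_pearson(x, y, w),
               weighted_pearson(x[perm], y[perm], w[perm]), tolerance = 1e-12)
  expect_error(weighted_pearson(rep(1, 5), y, w), "zero weighted variance")
  expect_error(weighted_pearson(1:2, 1:2, c(1, 1)))
})
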