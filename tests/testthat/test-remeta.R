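test_that("REML tau^2 maximises the restricted likelihood (toy set)", {
  yi <- c(0.1, 0.3, -0.2, 0.5, 0.0, 0.25)
  vi <- rep(0.04, 6)
  fit <- remeta(yi, vi)
  # equal sampling variances give the closed form var(y) - v, and the
  # 1e-5-step grid search lands on the same point
  expect_lt(abs(fit$tau2 - (var(yi) - 0.04)), 1e-8)
  expect_lt(abs(fit$tau2 - 0.02041667), 1e-6)
  expect_lt(abs(grid_reml_tau2(yi, vi) - fit$tau2), 1e-4)
})

test_that("REML equals the grid-search maximiser on random small instances", {
  set.seed(31)
  for (i in 1:10) {
    k <- sample(3:8, 1)
    vi <- runif(k, 0.01, 0.2)
    yi <- rnorm(k, 0.2, sqrt(vi + runif(1, 0, 0.1)))
    expect_lt(abs(remeta(yi, vi)$tau2 - grid_reml_tau2(yi, vi)), 1e-4)
  }
})

test_that("identical studies imply no heterogeneity and equal-weight pooling", {
  fit <- remeta(c(0.3, 0.3), c(0.04, 0.04))
  expect_equal(fit$tau2, 0)
  expect_equal(fit$b[[1]], 0.3)
  expect_equal(fit$se[[1]], sqrt(0.02))
  expect_equal(fit$i2, 0)
})

test_that("tau^2 = 0 reduces to fixed-effect inverse-variance pooling", {
  set.seed(32)
  vi <- runif(6, 0.02, 0.1)
  yi <- rnorm(6, 0.1, sqrt(vi) * 0.3)   # underdispersed -> tau2 hits 0
  fit <- remeta(yi, vi)
  fe <- remeta(yi, vi, method = "FE")
  if (fit$tau2 == 0) {
    expect_equal(fit$b, fe$b)
    expect_equal(fit$se, fe$se)
  }
  w <- 1 / vi
  expect_equal(fe$b[[1]], sum(w * yi) / sum(w), tolerance = 1e-12)
  expect_equal(fe$se[[1]], 1 / sqrt(sum(w)), tolerance = 1e-12)
})

test_that("pooling and meta-regression agree with metafor", {
  set.seed(33)
  k <- 25
  vi <- runif(k, 0.01, 0.15)
  age <- runif(k, 20, 45)
  yi <- 0.5 - 0.01 * age + rnorm(k, 0, sqrt(vi + 0.02))
  fit <- remeta(yi, vi)
  ctrl <- list(threshold = 1e-12, maxiter = 1000)
  ref <- metafor::rma(yi, vi, method = "REML", control = ctrl)
  expect_lt(abs(fit$tau2 - ref$tau2), 1e-9)
  expect_lt(abs(fit$b[[1]] - as.numeric(ref$b)), 1e-9)
  expect_lt(abs(fit$se[[1]] - ref$se), 1e-9)
  expect_lt(abs(fit$i2 - ref$I2), 1e-5)

  dl <- remeta(yi, vi, method = "DL")
  ref_dl <- metafor::rma(yi, vi, method = "DL")
  expect_lt(abs(dl$tau2 - ref_dl$tau2), 1e-10)

  dat <- data.frame(yi = yi, vi = vi, age = age)
  mr <- remeta(yi, vi, mods = ~ age, data = dat)
  ref_mr <- metafor::rma(yi, vi, mods = ~ age, data = dat, method = "REML",
                         control = ctrl)
  expect_lt(abs(mr$b[[2]] - as.numeric(ref_mr$b)[2]), 1e-9)
  expect_lt(abs(mr$se[[2]] - ref_mr$se[2]), 1e-9)
  expect_lt(abs(mr$tau2 - ref_mr$tau2), 1e-9)
})

test_that("tau^2 recovery: tau = 0.2, k = 200, v = 0.01", {
  set.seed(34)
  est <- replicate(200, {
    yi <- rnorm(200, 0, sqrt(0.01 + 0.04))
    remeta(yi, rep(0.01, 200))$tau2
  })
  expect_lt(abs(median(est) - 0.04), 0.2 * 0.04)
})

test_that("meta-regression slope properties hold", {
  set.seed(35)
  k <- 30
  vi <- rep(0.05, k)
  yi <- rnorm(k)
  m0 <- rnorm(k)
  m_orth <- residuals(lm(m0 ~ yi))   # orthogonal to yi, equal weights
  fit <- remeta(yi, vi, mods = ~ m_orth, data = data.frame(yi, vi, m_orth))
  expect_equal(fit$b[[2]], 0, tolerance = 1e-10)

  age <- runif(k, 20, 50)
  dat <- data.frame(yi = yi, vi = vi, age = age, age_shift = age + 100)
  f1 <- remeta(yi, vi, mods = ~ age, data = dat)
  f2 <- remeta(yi, vi, mods = ~ age_shift, data = dat)
  expect_equal(f1$b[[2]], f2$b[[2]], tolerance = 1e-8)   # affine equivariance
  expect_equal(f1$b[[1]], f2$b[[1]] + 100 * f2$b[[2]], tolerance = 1e-6)

  expect_error(remeta(yi, vi, mods = ~ cst, data = data.frame(cst = rep(1, k))),
               "constant moderator")
  expect_error(remeta(yi[1:4], vi[1:4], mods = ~ a,
                      data = data.frame(a = rnorm(4))), "too few studies")
})

test_that("moderator rows with missing values drop from regressions only", {
  set.seed(36)
  k <- 12
  dat <- data.frame(yi = rnorm(k, 0.2, 0.3), vi = runif(k, 0.02, 0.1),
                    age = c(rnorm(8, 30, 5), rep(NA, 4)))
  pool <- remeta(dat$yi, dat$vi)
  expect_equal(pool$k, 12)
  mr <- remeta(dat$yi, dat$vi, mods = ~ age, data = dat)
  expect_equal(mr$k, 8)
})

test_that("I^2 is invariant to a common rescaling of all variances", {
  set.seed(37)
  vi <- runif(10, 0.02, 0.2)
  yi <- rnorm(10, 0, sqrt(vi + 0.05))
  f1 <- remeta(yi, vi)
  for (cfac in c(0.25, 4)) {
    f2 <- remeta(sqrt(cfac) * yi, cfac * vi)
    expect_equal(f2$i2, f1$i2, tolerance = 1e-6)
    expect_equal(f2$tau2, cfac * f1$tau2, tolerance = 1e-8)
  }
})

test_that("the fitted object supports the standard methods", {
  set.seed(38)
  dat <- data.frame(yi = rnorm(8, 0.3, 0.3), vi = runif(8, 0.02, 0.1),
                    study_id = paste0("s", 1:8))
  fit <- remeta(dat$yi, dat$vi, data = dat)
  expect_output(print(fit), "Random-effects pooling")
  expect_output(print(summary(fit)), "Q\\(df")
  expect_named(coef(fit), "intercept")
  expect_equal(dim(vcov(fit)), c(1, 1))
  expect_equal(unname(confint(fit)[1, ]),
               c(fit$ci.lb[[1]], fit$ci.ub[[1]]))
  expect_equal(residuals(fit), dat$yi - fit$b[[1]])
  sims <- simulate(fit, nsim = 3, seed = 1)
  expect_equal(dim(sims), c(8, 3))
  expect_identical(sims, simulate(fit, nsim = 3, seed = 1))
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(fit))
})

test_that("errors carry their cause", {
  expect_error(remeta(c(0.1, 0.2), c(0.04, -1)), "positive sampling variances")
  expect_error(remeta(0.1, 0.04), "too few studies")
  expect_error(suppressWarnings(
    remeta(c(0.1, 0.2, 0.3), c(0.1, 0.1, 0.1), method = "DL",
           mods = ~ a, data = data.frame(a = 1:3), min_k = 3)),
    "intercept-only")
})
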