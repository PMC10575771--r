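# Independent oracles used across the suite.

`%||%` <- function(a, b) if (is.null(a)) b else a

# --- restricted-likelihood grid search (intercept-only REML oracle) --------
grid_reml_tau2 <- function(yi, vi, step = 1e-5, upper = 1) {
  t2 <- seq(0, upper, by = step)
  V <- outer(vi, t2, "+")
  W <- 1 / V
  sw <- colSums(W)
  mu <- colSums(W * yi) / sw
  quad <- colSums(W * (outer(yi, mu, "-"))^2)
  ll <- -0.5 * (colSums(log(V)) + log(sw) + quad)
  t2[which.max(ll)]
}

# --- exact dip oracle -------------------------------------------------------
# D = min over unimodal CDFs G of sup|F_n - G|, by bisection on d with a
# feasibility check: G must pass through a box at every distinct value
# (l_i = F_i - d, u_i = F_{i-1} + d), be convex left of the mode and concave
# right of it (an atom at the mode is allowed), and run 0 -> 1 (distant
# anchors).  A convex path through boxes exists iff the greatest convex
# minorant of the upper bounds dominates the lower bounds; one steepest
# extrapolation line per point bounds where each side can reach, and all
# mode-in-gap constraints are linear in the mode position.
.oracle_gcm_vals <- function(xx, yy) {
  k <- length(xx)
  hx <- xx[1]; hy <- yy[1]
  for (i in 2:k) {
    while (length(hx) >= 2) {
      b <- length(hx); a <- b - 1L
      cr <- (hx[b] - hx[a]) * (yy[i] - hy[a]) - (hy[b] - hy[a]) * (xx[i] - hx[a])
      if (cr <= 0) { hx <- hx[-b]; hy <- hy[-b] } else break
    }
    hx <- c(hx, xx[i]); hy <- c(hy, yy[i])
  }
  if (length(hx) == 1) rep(hy, k) else approx(hx, hy, xout = xx, rule = 2)$y
}

oracle_dip <- function(x, tol = 1e-11) {
  n <- length(x)
  stopifnot(n >= 2, all(is.finite(x)))
  xs <- sort(x)
  ux <- unique(xs)
  m <- length(ux)
  if (m == 1) return(1 / (2 * n))
  cc <- cumsum(tabulate(match(xs, ux), m)) / n
  cp <- c(0, cc[-m])
  rng <- ux[m] - ux[1]
  X0 <- ux[1] - 10 * rng - 1
  X1 <- ux[m] + 10 * rng + 1
  EPS <- 1e-12

  feasible <- function(d) {
    l <- pmax(0, cc - d)
    u <- pmin(1, cp + d)
    pf <- logical(m); sf <- logical(m)
    for (j in 1:m) {
      xx <- c(X0, ux[1:j])
      pf[j] <- all(.oracle_gcm_vals(xx, c(0, u[1:j])) >= c(0, l[1:j]) - EPS)
    }
    for (j in m:1) {
      xx <- c(ux[j:m], X1)
      sf[j] <- all(.oracle_gcm_vals(xx, -c(l[j:m], 1)) >= -c(u[j:m], 1) - EPS)
    }
    pf0 <- c(TRUE, pf); sf0 <- c(sf, TRUE, TRUE)

    conv_lines <- function(j) {
      if (j == 0) return(list(B = 0, A = 0))
      xp <- c(X0, ux[seq_len(max(0, j - 1))]); up <- c(0, u[seq_len(max(0, j - 1))])
      B <- numeric(0); A <- numeric(0)
      for (q in 1:j) {
        kk <- which(xp < ux[q])
        if (length(kk)) {
          beta <- (l[q] - up[kk]) / (ux[q] - xp[kk])
          B <- c(B, beta); A <- c(A, l[q] - beta * ux[q])
        }
      }
      B <- c(B, rep(0, j), 0); A <- c(A, l[1:j], 0)
      list(B = B, A = A)
    }
    conc_lines <- function(j) {
      B <- numeric(0); A <- numeric(0)
      for (q in j:m) {
        idx <- seq(q + 1, m)[seq_len(max(0, m - q))]
        xp <- c(ux[idx], X1); lp <- c(l[idx], 1)
        beta <- (lp - u[q]) / (xp - ux[q])
        B <- c(B, beta); A <- c(A, u[q] - beta * ux[q])
      }
      B <- c(B, rep(0, m - j + 1), 0); A <- c(A, u[j:m], 1)
      list(B = B, A = A)
    }

    for (j in 1:m) {   # mode (and possibly an atom) at data point j
      if (!(pf0[j] && sf0[j + 1])) next
      cl <- conv_lines(j - 1)
      Amin <- max(cl$A + cl$B * ux[j], 0)
      t1A <- max(max(0, cp[j] - d), Amin)
      if (t1A > min(1, cp[j] + d) + 1e-11) next
      Bmax <- if (j < m) { sl <- conc_lines(j + 1); min(sl$A + sl$B * ux[j], 1) } else 1
      t2B <- min(min(1, cc[j] + d), Bmax)
      if (t2B < max(0, cc[j] - d) - 1e-11) next
      if (t1A <= t2B + 1e-11) return(TRUE)
    }
    for (j in 1:(m - 1)) {   # mode strictly inside gap (j, j+1)
      if (!(pf[j] && sf[j + 1])) next
      cl <- conv_lines(j)
      sl <- conc_lines(j + 1)
      lt <- max(0, cc[j] - d); ut <- min(1, cc[j] + d)
      mlo <- ux[j]; mhi <- ux[j + 1]
      ok <- TRUE
      for (r in seq_along(cl$B)) {
        if (cl$B[r] > 0) mhi <- min(mhi, (ut - cl$A[r]) / cl$B[r])
        else if (cl$A[r] > ut + 1e-11) { ok <- FALSE; break }
      }
      if (!ok || mlo > mhi + 1e-11) next
      for (s in seq_along(sl$B)) {
        if (sl$B[s] > 0) mlo <- max(mlo, (lt - sl$A[s]) / sl$B[s])
        else if (sl$A[s] < lt - 1e-11) { ok <- FALSE; break }
      }
      if (!ok || mlo > mhi + 1e-11) next
      for (r in seq_along(cl$B)) {
        for (s in seq_along(sl$B)) {
          db <- cl$B[r] - sl$B[s]; da <- cl$A[r] - sl$A[s]
          if (abs(db) < 1e-300) { if (da > 1e-11) { ok <- FALSE; break } }
          else if (db > 0) mhi <- min(mhi, -da / db)
          else mlo <- max(mlo, -da / db)
        }
        if (!ok || mlo > mhi + 1e-11) { ok <- FALSE; break }
      }
      if (ok && mlo <= mhi + 1e-11) return(TRUE)
    }
    FALSE
  }

  dlo <- 0; dhi <- 0.2600001
  while (dhi - dlo > tol) {
    mid <- (dlo + dhi) / 2
    if (feasible(mid)) dhi <- mid else dlo <- mid
  }
  max(dhi, 1 / (2 * n))
}

# --- tiny study-table builder ----------------------------------------------
make_table <- function(k = 6, region = "MFC", metabolite = "glutamate",
                       seed = 1, phi = 0.2, delta = -0.1, cv = 0.15,
                       base_mean = 10, n = 30,
                       medication = rep("medicated", k), ...) {
  set.seed(seed)
  rows <- lapply(seq_len(k), function(i) {
    mc <- base_mean * exp(rnorm(1, 0, 0.3))
    sc <- cv * mc
    mp <- mc + delta * sc
    sp <- cv * exp(phi) * mp
    xc <- rnorm(n, mc, sc); xp <- rnorm(n, mp, sp)
    data.frame(study_id = sprintf("%s_T%02d", region, i), region = region,
               metabolite = metabolite,
               mean_p = mean(xp), sd_p = sd(xp), n_p = n,
               mean_c = mean(xc), sd_c = sd(xc), n_c = n,
               medication_status = medication[i],
               stringsAsFactors = FALSE, ...)
  })
  do.call(rbind, rows)
}
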