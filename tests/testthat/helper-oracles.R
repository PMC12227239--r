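# Independent oracles used to validate the package's fitters and exact
# tests. These deliberately avoid the code paths they check: the 4PL
# oracle is a dense grid search with closed-form linear asymptotes, the
# test oracles are brute-force enumerations.

# Dense grid-search least-squares 4PL fit. For fixed (slope, tm_infl) the
# model is linear in (plateau, top); the grid scans (slope, tm_infl) and
# solves the 2x2 normal equations in closed form, then refines around the
# best cell. Returns the half-initial Tm like fit_melt_curve().
oracle_fit_4pl <- function(temp, y,
                           tm_range = range(temp) + c(-5, 5),
                           slope_range = c(0.05, 2)) {
  scan <- function(tms, slopes) {
    best <- list(sse = Inf)
    yy <- sum(y^2)
    for (s in slopes) {
      G <- 1 / (1 + exp(outer(tms, temp, function(m, tt) s * (tt - m))))
      U <- 1 - G
      Suu <- rowSums(U * U); Suv <- rowSums(U * G); Svv <- rowSums(G * G)
      Suy <- as.vector(U %*% y); Svy <- as.vector(G %*% y)
      det <- Suu * Svv - Suv^2
      plateau <- (Suy * Svv - Svy * Suv) / det
      top <- (Svy * Suu - Suy * Suv) / det
      # project onto plateau >= 0 (the fitter's constraint)
      negp <- which(plateau < 0)
      if (length(negp) > 0) {
        plateau[negp] <- 0
        top[negp] <- Svy[negp] / Svv[negp]
      }
      sse <- yy - 2 * (plateau * Suy + top * Svy) +
        plateau^2 * Suu + 2 * plateau * top * Suv + top^2 * Svv
      i <- which.min(sse)
      if (sse[i] < best$sse)
        best <- list(sse = sse[i], tm_infl = tms[i], slope = s,
                     plateau = plateau[i], top = top[i])
    }
    best
  }
  b <- scan(seq(tm_range[1], tm_range[2], by = 0.05),
            seq(slope_range[1], slope_range[2], by = 0.05))
  # polish the grid optimum continuously: profiled SSE over
  # (tm_infl, log slope), linear parameters solved in closed form
  prof_sse <- function(par) {
    m <- par[1]; s <- exp(par[2])
    g <- 1 / (1 + exp(s * (temp - m)))
    u <- 1 - g
    Suu <- sum(u * u); Suv <- sum(u * g); Svv <- sum(g * g)
    Suy <- sum(u * y); Svy <- sum(g * y)
    det <- Suu * Svv - Suv^2
    plateau <- (Suy * Svv - Svy * Suv) / det
    top <- (Svy * Suu - Suy * Suv) / det
    if (plateau < 0) { plateau <- 0; top <- Svy / Svv }
    sum((y - plateau * u - top * g)^2)
  }
  op <- stats::optim(c(b$tm_infl, log(b$slope)), prof_sse,
                     method = "Nelder-Mead",
                     control = list(reltol = 1e-16, maxit = 5000))
  for (r in 1:2)  # restart to escape simplex stalls
    op <- stats::optim(op$par, prof_sse, method = "Nelder-Mead",
                       control = list(reltol = 1e-16, maxit = 5000))
  if (op$value < b$sse) {
    m <- op$par[1]; s <- exp(op$par[2])
    g <- 1 / (1 + exp(s * (temp - m)))
    u <- 1 - g
    Suu <- sum(u * u); Suv <- sum(u * g); Svv <- sum(g * g)
    Suy <- sum(u * y); Svy <- sum(g * y)
    det <- Suu * Svv - Suv^2
    plateau <- (Suy * Svv - Svy * Suv) / det
    top <- (Svy * Suu - Suy * Suv) / det
    if (plateau < 0) { plateau <- 0; top <- Svy / Svv }
    b <- list(sse = op$value, tm_infl = m, slope = s, plateau = plateau,
              top = top)
  }
  y_ref <- b$plateau + (b$top - b$plateau) /
    (1 + exp(b$slope * (min(temp) - b$tm_infl)))
  target <- y_ref / 2
  tm <- if (target <= b$plateau || target >= b$top) NA_real_
        else b$tm_infl +
          log((b$top - b$plateau) / (target - b$plateau) - 1) / b$slope
  c(tm = tm, sse = b$sse)
}

# Exact two-sided binomial p by direct enumeration (minimum-likelihood
# method): sum the probabilities of all outcomes no more likely than the
# observed one.
oracle_binom_p <- function(k, n, p0 = 0.5) {
  probs <- stats::dbinom(0:n, n, p0)
  sum(probs[probs <= probs[k + 1] * (1 + 1e-7)])
}

# Exact two-sided paired Wilcoxon signed-rank p by enumerating all 2^n
# sign assignments (no ties, no zeros).
oracle_signed_rank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- as.vector(signs %*% r)
  min(1, 2 * min(mean(w_all <= w_obs), mean(w_all >= w_obs)))
}

# Fisher exact p for a 2x2 table by hypergeometric enumeration, and the
# conditional maximum-likelihood odds ratio via the noncentral
# hypergeometric likelihood.
oracle_fisher <- function(tab) {
  m1 <- sum(tab[1, ]); m2 <- sum(tab[2, ]); k <- sum(tab[, 1])
  x_obs <- tab[1, 1]
  lo <- max(0, k - m2); hi <- min(k, m1)
  xs <- lo:hi
  dens <- stats::dhyper(xs, m1, m2, k)
  p <- sum(dens[dens <= dens[xs == x_obs] * (1 + 1e-7)])
  # conditional MLE of the odds ratio: E_psi[X] = x_obs
  w <- lchoose(m1, xs) + lchoose(m2, k - xs)
  e_x <- function(lpsi) {
    lw <- w + xs * lpsi
    lw <- lw - max(lw)
    sum(xs * exp(lw)) / sum(exp(lw))
  }
  or <- if (x_obs == lo) 0
        else if (x_obs == hi) Inf
        else exp(stats::uniroot(function(l) e_x(l) - x_obs, c(-30, 30))$root)
  list(p = p, or = or)
}

# Brute-force Spearman rho with average ranks (tie handling), Pearson on
# ranks.
oracle_spearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}
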