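# Parametric melt-curve models and nonlinear least-squares fitters.
# All temperatures are degrees Celsius at the interface; the van 't Hoff
# model converts to Kelvin internally.

# gas constant, kcal mol^-1 K^-1
.R_KCAL <- 1.987e-3

#' Four-parameter logistic melt curve
#'
#' Decreasing sigmoid used to model the relative soluble fraction of a
#' protein across a temperature gradient:
#' \deqn{f(T) = plateau + \frac{top - plateau}{1 + e^{slope (T - tm)}}}
#' With `slope > 0` the curve decreases from `top` (low temperature) to
#' `plateau` (high temperature), with inflection at `tm`.
#'
#' @param temp Temperature(s), degrees Celsius.
#' @param top Upper asymptote (value as T -> -Inf).
#' @param plateau Lower asymptote (value as T -> +Inf).
#' @param slope Steepness, 1/degC; must be positive.
#' @param tm Inflection temperature, degC.
#' @return Numeric vector of curve values.
#' @export
logistic4 <- function(temp, top, plateau, slope, tm) {
  if (!is.numeric(slope) || length(slope) != 1L || is.na(slope) || slope <= 0)
    stop("'slope' must be a single positive number", call. = FALSE)
  plateau + (top - plateau) / (1 + exp(slope * (temp - tm)))
}

# Closure computing the profiled 4PL SSE over (tm_infl, log slope): the
# linear parameters (plateau, top) are solved from the normal equations,
# with plateau clamped at 0.
.profile_4pl <- function(tt, yy) {
  function(p) {
    m <- p[1]; s <- exp(p[2])
    z <- pmin(pmax(s * (tt - m), -700), 700)
    g <- 1 / (1 + exp(z))
    u <- 1 - g
    Suu <- sum(u * u); Suv <- sum(u * g); Svv <- sum(g * g)
    Suy <- sum(u * yy); Svy <- sum(g * yy)
    det <- Suu * Svv - Suv^2
    if (!is.finite(det) || det < 1e-300) {
      top <- Svy / Svv; plateau <- 0
    } else {
      plateau <- (Suy * Svv - Svy * Suv) / det
      top <- (Svy * Suu - Suy * Suv) / det
      if (plateau < 0) { plateau <- 0; top <- Svy / Svv }
    }
    list(sse = sum((yy - plateau * u - top * g)^2), top = top,
         plateau = plateau)
  }
}

# Temperature at which the 4PL curve equals half its value at t_ref.
# Closed form; NA when the half level lies below the lower plateau
# (no crossing).
.half_initial_tm <- function(top, plateau, slope, tm, t_ref) {
  y_ref <- logistic4(t_ref, top, plateau, slope, tm)
  target <- y_ref / 2
  if (!is.finite(target) || target <= plateau || target >= top) return(NA_real_)
  tm + log((top - plateau) / (target - plateau) - 1) / slope
}

#' Fit a four-parameter logistic melt curve
#'
#' Least-squares fit of [logistic4()] to a relative soluble-fraction
#' profile. The reported melting temperature `tm` is the temperature at
#' which the fitted curve falls to half its fitted value at the lowest
#' treatment temperature (the operational "reduced by half" definition);
#' with a nonzero lower plateau this differs from the inflection
#' parameter, which is also returned.
#'
#' The optimizer is Levenberg-Marquardt least squares
#' (\code{minpack.lm::nlsLM}) with three starts (inflection initialized at
#' the 25th/50th/75th percentile of the temperature range); ties are broken
#' by lowest residual sum of squares, then lowest tm. Fit failure yields a
#' flagged object rather than an error.
#'
#' @param temperature Numeric vector of treatment temperatures, degC,
#'   strictly increasing.
#' @param value Relative soluble fraction at each temperature.
#' @param protein_id Optional identifier carried into the result.
#' @param n_psm Optional PSM count carried into the result.
#' @return An object of class `"melt_fit"`: list with elements
#'   `tm` (half-initial melting temperature, degC), `par` (named vector
#'   top/plateau/slope/tm_infl), `r2`, `flag` (`"ok"`,
#'   `"insufficient_data"`, `"no_convergence"`, `"degenerate"`,
#'   `"no_half_crossing"`), `temperature`, `value`, `fitted`, `protein_id`,
#'   `n_psm`, `ci` (NULL until [bootstrap_tm_ci()] is used).
#' @seealso [bootstrap_tm_ci()], [build_profiles()]
#' @export
fit_melt_curve <- function(temperature, value, protein_id = NA_character_,
                           n_psm = NA_integer_) {
  stopifnot(length(temperature) == length(value))
  out <- structure(
    list(tm = NA_real_, par = c(top = NA_real_, plateau = NA_real_,
                                slope = NA_real_, tm_infl = NA_real_),
         r2 = NA_real_, flag = "ok", temperature = temperature,
         value = value, fitted = rep(NA_real_, length(value)),
         protein_id = protein_id, n_psm = n_psm, ci = NULL),
    class = "melt_fit")
  keep <- is.finite(temperature) & is.finite(value)
  tt <- temperature[keep]; yy <- value[keep]
  if (length(tt) < 5L) {
    out$flag <- "insufficient_data"
    return(out)
  }
  if (stats::sd(yy) == 0) {
    out$flag <- "degenerate"
    return(out)
  }
  rng <- range(tt)
  starts <- stats::quantile(rng, c(0.25, 0.5, 0.75), names = FALSE)
  lower <- c(top = 0, plateau = 0, slope = 1e-3, tm_infl = rng[1] - 10)
  upper <- c(top = max(yy) * 3 + 1, plateau = max(yy), slope = 10,
             tm_infl = rng[2] + 10)
  best <- NULL
  for (s0 in starts) {
    st <- list(top = max(yy), plateau = max(min(yy), 0), slope = 0.3,
               tm_infl = s0)
    fit <- tryCatch(
      suppressWarnings(minpack.lm::nlsLM(
        yy ~ plateau + (top - plateau) / (1 + exp(slope * (tt - tm_infl))),
        start = st, lower = lower, upper = upper,
        control = minpack.lm::nls.lm.control(maxiter = 200))),
      error = function(e) NULL)
    if (is.null(fit)) next
    sse <- sum(stats::resid(fit)^2)
    cf <- stats::coef(fit)
    if (is.null(best) || sse < best$sse - 1e-12 ||
        (abs(sse - best$sse) <= 1e-12 && cf[["tm_infl"]] < best$cf[["tm_infl"]]))
      best <- list(sse = sse, cf = cf)
  }
  if (is.null(best)) {
    out$flag <- "no_convergence"
    return(out)
  }
  # Profiled refinement to machine tolerance. The 4PL SSE surface is a
  # long flat valley and the LM stopping rule alone can leave the reported
  # Tm a few hundredths of a degree off the minimum. The model is linear
  # in (top, plateau) given (slope, tm_infl), so the two nonlinear
  # parameters are polished on the profiled SSE with the linear pair
  # solved in closed form (plateau clamped at 0).
  prof <- .profile_4pl(tt, yy)
  ref <- tryCatch({
    par <- c(best$cf[["tm_infl"]], log(best$cf[["slope"]]))
    fn <- function(p) prof(p)$sse
    r <- stats::nlminb(par, fn,
                       lower = c(lower[["tm_infl"]], log(lower[["slope"]])),
                       upper = c(upper[["tm_infl"]], log(upper[["slope"]])),
                       control = list(rel.tol = 1e-15, iter.max = 500))
    # quasi-Newton stalls in the ill-conditioned valley; finish with
    # restarted Nelder-Mead at machine tolerance
    op <- list(par = r$par, value = r$objective)
    for (k in 1:3)
      op <- stats::optim(op$par, fn, method = "Nelder-Mead",
                         control = list(reltol = 1e-16, maxit = 5000))
    op
  }, error = function(e) NULL)
  if (!is.null(ref) && is.finite(ref$value) && ref$value <= best$sse) {
    pr <- prof(ref$par)
    best$sse <- ref$value
    best$cf <- c(top = pr$top, plateau = pr$plateau,
                 slope = exp(ref$par[2]), tm_infl = ref$par[1])
  }
  cf <- best$cf
  out$par <- c(top = cf[["top"]], plateau = cf[["plateau"]],
               slope = cf[["slope"]], tm_infl = cf[["tm_infl"]])
  out$fitted[keep] <- logistic4(tt, cf[["top"]], cf[["plateau"]],
                                cf[["slope"]], cf[["tm_infl"]])
  sstot <- sum((yy - mean(yy))^2)
  out$r2 <- 1 - best$sse / sstot
  out$tm <- .half_initial_tm(cf[["top"]], cf[["plateau"]], cf[["slope"]],
                             cf[["tm_infl"]], min(tt))
  if (is.na(out$tm)) out$flag <- "no_half_crossing"
  out
}

#' @export
print.melt_fit <- function(x, ...) {
  cat("4PL melt-curve fit")
  if (!is.na(x$protein_id)) cat(" for", x$protein_id)
  cat("\n  flag:", x$flag, "\n")
  if (x$flag %in% c("ok", "no_half_crossing")) {
    cat(sprintf("  Tm (half-initial): %.2f degC   r2: %.3f\n", x$tm, x$r2))
    cat(sprintf("  top=%.3f plateau=%.3f slope=%.3f tm_infl=%.2f\n",
                x$par["top"], x$par["plateau"], x$par["slope"],
                x$par["tm_infl"]))
    if (!is.null(x$ci))
      cat(sprintf("  95%% bootstrap CI: [%.2f, %.2f]\n", x$ci[1], x$ci[2]))
  }
  invisible(x)
}

#' @export
coef.melt_fit <- function(object, ...) object$par

#' @export
predict.melt_fit <- function(object, newdata = NULL, ...) {
  temp <- if (is.null(newdata)) object$temperature
          else if (is.list(newdata)) newdata$temperature else newdata
  if (any(is.na(object$par))) return(rep(NA_real_, length(temp)))
  logistic4(temp, object$par["top"], object$par["plateau"],
            object$par["slope"], object$par["tm_infl"])
}

#' @export
residuals.melt_fit <- function(object, ...) object$value - object$fitted

#' @export
plot.melt_fit <- function(x, ...) {
  plot(x$temperature, x$value, xlab = "Temperature (°C)",
       ylab = "Relative soluble fraction",
       main = if (is.na(x$protein_id)) "Melt curve" else x$protein_id, ...)
  if (!any(is.na(x$par))) {
    tg <- seq(min(x$temperature), max(x$temperature), length.out = 200)
    graphics::lines(tg, predict(x, tg))
    if (!is.na(x$tm)) graphics::abline(v = x$tm, lty = 2)
  }
  invisible(x)
}

#' Bootstrap confidence interval for a melting temperature
#'
#' Percentile bootstrap over peptide-spectrum matches (PSMs). PSM rows are
#' resampled with replacement, the protein profile is rebuilt (channel sums
#' scaled to the lowest-temperature channel) and refit, and the 2.5/97.5
#' percentiles of the resampled Tm estimates are returned. Following common
#' practice for TPP data, intervals are only produced for proteins with at
#' least `min_psm` (default 8) PSMs; below that the CI is withheld (`NULL`).
#'
#' @param psm_intensities Numeric matrix, one row per PSM, one column per
#'   temperature channel (raw or standardized intensities).
#' @param temperature Temperature vector matching the columns.
#' @param n_boot Number of bootstrap resamples (default 100).
#' @param seed Integer seed; the resampling is deterministic given it.
#' @param min_psm Minimum PSM count for a CI (default 8).
#' @param level Confidence level (default 0.95).
#' @return `c(ci_low, ci_high)` in degC, or `NULL` when withheld.
#' @export
bootstrap_tm_ci <- function(psm_intensities, temperature, n_boot = 100,
                            seed = 1L, min_psm = 8L, level = 0.95) {
  psm_intensities <- as.matrix(psm_intensities)
  stopifnot(ncol(psm_intensities) == length(temperature))
  n <- nrow(psm_intensities)
  if (n < min_psm) return(NULL)
  tms <- numeric(n_boot)
  set.seed(as.integer(seed))
  for (b in seq_len(n_boot)) {
    idx <- sample.int(n, n, replace = TRUE)
    prof <- colSums(psm_intensities[idx, , drop = FALSE])
    if (prof[1] <= 0) { tms[b] <- NA_real_; next }
    fit <- fit_melt_curve(temperature, prof / prof[1])
    tms[b] <- fit$tm
  }
  tms <- tms[is.finite(tms)]
  if (length(tms) == 0L) return(NULL)
  alpha <- (1 - level) / 2
  unname(stats::quantile(tms, c(alpha, 1 - alpha)))
}

#' Mean residue molar ellipticity
#'
#' Normalizes a measured circular-dichroism ellipticity by cuvette path
#' length, protein concentration and residue count:
#' \deqn{[\theta]_{MR} = 100\,\theta / (l \cdot c \cdot N)}
#'
#' @param theta Measured ellipticity, millidegrees.
#' @param path_cm Cuvette path length, cm.
#' @param conc Protein concentration (mass/volume, e.g. mg/mL).
#' @param n_residues Number of residues in the protein.
#' @return Mean residue ellipticity (deg cm^2 dmol^-1 residue^-1).
#' @export
mean_residue_ellipticity <- function(theta, path_cm, conc, n_residues) {
  if (any(c(path_cm, conc, n_residues) <= 0))
    stop("path length, concentration and residue count must be positive",
         call. = FALSE)
  100 * theta / (path_cm * conc * n_residues)
}

#' Normalize a CD trace by its minimum mean-residue ellipticity
#'
#' Scales every value of a trace by the trace minimum, giving a
#' dimensionless index of remaining secondary structure (the most-folded
#' point maps to 1). Invariant to multiplying the whole trace by a
#' constant.
#'
#' @param values Numeric vector of mean residue ellipticities.
#' @return Vector of the same length, `values / min(values)`.
#' @export
normalize_secondary_structure <- function(values) {
  m <- min(values)
  if (m == 0) stop("trace minimum is zero; normalization undefined",
                   call. = FALSE)
  values / m
}

#' Two-state unfolding signal
#'
#' Van 't Hoff two-state folded/unfolded equilibrium with zero heat
#' capacity change: \eqn{K(T) = \exp(-\Delta H/R (1/T - 1/T_m))} with T in
#' Kelvin, fraction folded \eqn{f = 1/(1+K)}, so \eqn{f(T_m) = 0.5}
#' exactly. Model 1 returns the normalized fraction folded (flat baselines
#' 1 and 0); Model 2 allows linear pre- and post-transition baselines in
#' the observed signal:
#' \eqn{y = f (b_F + m_F T) + (1-f)(b_U + m_U T)} (T in degC at this
#' interface).
#'
#' @param temp_c Temperature(s), degC.
#' @param tm_c Melting temperature, degC.
#' @param dH Van 't Hoff enthalpy, kcal/mol; must be positive.
#' @param model 1 (normalized) or 2 (linear baselines).
#' @param bF,mF,bU,mU Folded/unfolded baseline intercepts and slopes
#'   (model 2; model 1 fixes them at 1,0,0,0).
#' @return Signal value(s).
#' @export
two_state_signal <- function(temp_c, tm_c, dH, model = 1,
                             bF = 1, mF = 0, bU = 0, mU = 0) {
  if (dH <= 0) stop("'dH' must be positive", call. = FALSE)
  tK <- temp_c + 273.15
  tmK <- tm_c + 273.15
  if (any(tK <= 0) || tmK <= 0)
    stop("temperatures must be above absolute zero", call. = FALSE)
  K <- exp(-dH / .R_KCAL * (1 / tK - 1 / tmK))
  f <- 1 / (1 + K)
  if (model == 1) f
  else if (model == 2) f * (bF + mF * temp_c) + (1 - f) * (bU + mU * temp_c)
  else stop("'model' must be 1 or 2", call. = FALSE)
}

#' Fit a two-state thermal unfolding model
#'
#' Nonlinear least squares of [two_state_signal()] to a melt trace
#' (typically normalized secondary structure from circular dichroism).
#' Model 1 fits (Tm, dH) to a normalized trace; Model 2 additionally fits
#' linear folded/unfolded baselines.
#'
#' @param temperature Temperatures, degC (>= 15 points spanning the
#'   transition recommended).
#' @param signal Observed signal.
#' @param model 1 or 2, see [two_state_signal()].
#' @return Object of class `"two_state_fit"`: `tm` (degC), `dH`
#'   (kcal/mol), `baselines` (bF, mF, bU, mU), `model`, `r2`, `flag`
#'   (`"ok"`, `"no_convergence"`, `"transition_outside_range"`), data and
#'   fitted values.
#' @export
fit_two_state <- function(temperature, signal, model = 2) {
  stopifnot(length(temperature) == length(signal))
  out <- structure(
    list(tm = NA_real_, dH = NA_real_,
         baselines = c(bF = 1, mF = 0, bU = 0, mU = 0), model = model,
         r2 = NA_real_, flag = "ok", temperature = temperature,
         signal = signal, fitted = rep(NA_real_, length(signal))),
    class = "two_state_fit")
  if (length(temperature) < 15L) {
    out$flag <- "insufficient_data"
    return(out)
  }
  # start tm where the signal crosses the midpoint of its observed range
  mid <- (max(signal) + min(signal)) / 2
  tm0 <- temperature[which.min(abs(signal - mid))]
  fml <- if (model == 1)
    signal ~ two_state_signal(temperature, tm, dH, model = 1)
  else
    signal ~ two_state_signal(temperature, tm, dH, model = 2,
                              bF = bF, mF = mF, bU = bU, mU = mU)
  st <- if (model == 1) list(tm = tm0, dH = 50)
        else list(tm = tm0, dH = 50, bF = max(signal), mF = 0,
                  bU = min(signal), mU = 0)
  lower <- if (model == 1) c(tm = -50, dH = 1)
           else c(tm = -50, dH = 1, bF = -Inf, mF = -Inf, bU = -Inf,
                  mU = -Inf)
  fit <- tryCatch(
    suppressWarnings(minpack.lm::nlsLM(
      fml, start = st, lower = lower,
      control = minpack.lm::nls.lm.control(maxiter = 500))),
    error = function(e) NULL)
  if (is.null(fit)) {
    out$flag <- "no_convergence"
    return(out)
  }
  cf <- stats::coef(fit)
  out$tm <- cf[["tm"]]
  out$dH <- cf[["dH"]]
  if (model == 2)
    out$baselines <- c(bF = cf[["bF"]], mF = cf[["mF"]], bU = cf[["bU"]],
                       mU = cf[["mU"]])
  out$fitted <- stats::fitted(fit)
  out$r2 <- 1 - sum(stats::resid(fit)^2) /
    sum((signal - mean(signal))^2)
  if (out$tm < min(temperature) || out$tm > max(temperature))
    out$flag <- "transition_outside_range"
  # a near-zero r2 means the sigmoid explained nothing (pure noise)
  if (is.finite(out$r2) && out$r2 < 0.2) out$flag <- "no_convergence"
  out
}

#' @export
print.two_state_fit <- function(x, ...) {
  cat("Two-state unfolding fit (model", x$model, ")\n  flag:", x$flag, "\n")
  if (is.finite(x$tm))
    cat(sprintf("  Tm: %.2f degC   dH: %.1f kcal/mol   r2: %.4f\n",
                x$tm, x$dH, x$r2))
  invisible(x)
}

#' @export
coef.two_state_fit <- function(object, ...) {
  c(tm = object$tm, dH = object$dH,
    if (object$model == 2) object$baselines)
}

#' @export
predict.two_state_fit <- function(object, newdata = NULL, ...) {
  temp <- if (is.null(newdata)) object$temperature else newdata
  b <- object$baselines
  two_state_signal(temp, object$tm, object$dH, model = object$model,
                   bF = b["bF"], mF = b["mF"], bU = b["bU"], mU = b["mU"])
}

#' @export
residuals.two_state_fit <- function(object, ...) object$signal - object$fitted

#' Fit a five-parameter logistic dose-response and estimate IT50
#'
#' Fits the asymmetric (Richards-type) five-parameter logistic
#' \deqn{y = B + \frac{Top - B}{\left(1 + 10^{\,b (m - T)}\right)^s}}
#' to a response-versus-temperature series and reports the half-inhibition
#' temperature IT50: the temperature at which the fitted response equals
#' half the fitted maximum over the observed range, solved numerically.
#' When the curve is symmetric (`s = 1`, `B = 0`) IT50 coincides with the
#' midpoint parameter `m`. The confidence interval is a seeded parametric
#' bootstrap of residuals.
#'
#' @param temperature Temperatures, degC; >= 6 points.
#' @param response Non-negative response (OD600 yield, residual activity).
#'   Negative blank-corrected values are tolerated; the bottom asymptote
#'   absorbs them.
#' @param n_boot Bootstrap resamples for the CI (0 = no CI).
#' @param seed Integer seed for the bootstrap.
#' @param level Confidence level (default 0.95).
#' @return Object of class `"it50_fit"`: `it50` (degC), `par`
#'   (bottom/top/slope/midpoint/asymmetry), `ci` (or NULL), `r2`, `flag`
#'   (`"ok"`, `"insufficient_data"`, `"no_convergence"`,
#'   `"no_half_crossing"`), data and fitted values.
#' @export
fit_it50 <- function(temperature, response, n_boot = 0, seed = 1L,
                     level = 0.95) {
  stopifnot(length(temperature) == length(response))
  out <- structure(
    list(it50 = NA_real_,
         par = c(bottom = NA_real_, top = NA_real_, slope = NA_real_,
                 midpoint = NA_real_, asymmetry = NA_real_),
         ci = NULL, r2 = NA_real_, flag = "ok",
         temperature = temperature, response = response,
         fitted = rep(NA_real_, length(response))),
    class = "it50_fit")
  if (length(temperature) < 6L) {
    out$flag <- "insufficient_data"
    return(out)
  }
  cf <- .fit_5pl(temperature, response)
  if (is.null(cf)) {
    out$flag <- "no_convergence"
    return(out)
  }
  out$par <- cf
  out$fitted <- .pl5(temperature, cf)
  sstot <- sum((response - mean(response))^2)
  out$r2 <- if (sstot > 0) 1 - sum((response - out$fitted)^2) / sstot
            else NA_real_
  out$it50 <- .it50_from_par(cf, range(temperature))
  if (is.na(out$it50)) {
    out$flag <- "no_half_crossing"
    return(out)
  }
  if (n_boot > 0) {
    res <- response - out$fitted
    set.seed(as.integer(seed))
    boots <- numeric(n_boot)
    for (b in seq_len(n_boot)) {
      yb <- out$fitted + sample(res, length(res), replace = TRUE)
      cfb <- .fit_5pl(temperature, yb)
      boots[b] <- if (is.null(cfb)) NA_real_
                  else .it50_from_par(cfb, range(temperature))
    }
    boots <- boots[is.finite(boots)]
    if (length(boots) > 0) {
      alpha <- (1 - level) / 2
      out$ci <- unname(stats::quantile(boots, c(alpha, 1 - alpha)))
    }
  }
  out
}

.pl5 <- function(temp, par) {
  par[["bottom"]] + (par[["top"]] - par[["bottom"]]) /
    (1 + 10^(par[["slope"]] * (par[["midpoint"]] - temp)))^par[["asymmetry"]]
}

.fit_5pl <- function(temp, y) {
  mid0 <- temp[which.min(abs(y - (max(y) + min(y)) / 2))]
  best <- NULL
  for (sl0 in c(-0.2, -0.05)) {
    fit <- tryCatch(
      suppressWarnings(minpack.lm::nlsLM(
        y ~ bottom + (top - bottom) /
          (1 + 10^(slope * (midpoint - temp)))^asymmetry,
        start = list(bottom = min(y), top = max(y), slope = sl0,
                     midpoint = mid0, asymmetry = 1),
        lower = c(bottom = -Inf, top = -Inf, slope = -5,
                  midpoint = min(temp) - 30, asymmetry = 0.05),
        upper = c(bottom = Inf, top = Inf, slope = 5,
                  midpoint = max(temp) + 30, asymmetry = 20),
        control = minpack.lm::nls.lm.control(maxiter = 500))),
      error = function(e) NULL)
    if (is.null(fit)) next
    sse <- sum(stats::resid(fit)^2)
    if (is.null(best) || sse < best$sse) best <- list(sse = sse,
                                                     cf = stats::coef(fit))
  }
  if (is.null(best)) NULL else best$cf
}

.it50_from_par <- function(par, trange) {
  g <- function(t) .pl5(t, par)
  tg <- seq(trange[1], trange[2], length.out = 512)
  fmax <- max(g(tg))
  target <- fmax / 2
  h <- function(t) g(t) - target
  hv <- h(tg)
  sgn <- sign(hv)
  # inhibition: the response must fall through the half-maximum as
  # temperature increases (descending crossing)
  idx <- which(sgn[-length(sgn)] > 0 & sgn[-1] < 0)
  if (length(idx) == 0L) return(NA_real_)
  i <- idx[length(idx)]
  stats::uniroot(h, c(tg[i], tg[i + 1]), tol = 1e-8)$root
}

#' @export
print.it50_fit <- function(x, ...) {
  cat("5PL dose-response fit\n  flag:", x$flag, "\n")
  if (is.finite(x$it50)) {
    cat(sprintf("  IT50: %.2f degC   r2: %.4f\n", x$it50, x$r2))
    if (!is.null(x$ci))
      cat(sprintf("  95%% CI: [%.2f, %.2f]\n", x$ci[1], x$ci[2]))
  }
  invisible(x)
}

#' @export
coef.it50_fit <- function(object, ...) object$par

#' @export
predict.it50_fit <- function(object, newdata = NULL, ...) {
  temp <- if (is.null(newdata)) object$temperature else newdata
  if (any(is.na(object$par))) return(rep(NA_real_, length(temp)))
  .pl5(temp, object$par)
}

#' @export
residuals.it50_fit <- function(object, ...) object$response - object$fitted

#' @export
plot.it50_fit <- function(x, ...) {
  plot(x$temperature, x$response, xlab = "Temperature (°C)",
       ylab = "Response", ...)
  if (!any(is.na(x$par))) {
    tg <- seq(min(x$temperature), max(x$temperature), length.out = 200)
    graphics::lines(tg, predict(x, tg))
    if (is.finite(x$it50)) graphics::abline(v = x$it50, lty = 2)
  }
  invisible(x)
}
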