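# Comparative statistics on ortholog pairs: direction (sign) tests,
# hybrid-versus-parent contrasts, annotation enrichment, covariate
# adjustment and rank correlations. Exact tests delegate to base stats.

#' Exact binomial sign test
#'
#' Two-sided exact binomial test (minimum-likelihood two-sided method, as
#' in `binom.test`) of `k` successes in `n` trials against probability
#' `p0`.
#'
#' @param k Number of successes.
#' @param n Number of trials (> 0).
#' @param p0 Null success probability (default 0.5).
#' @param two_sided Logical (default TRUE); FALSE gives the upper-tail
#'   test.
#' @return The p-value.
#' @export
sign_binomial_test <- function(k, n, p0 = 0.5, two_sided = TRUE) {
  if (n <= 0) stop("'n' must be positive", call. = FALSE)
  if (k < 0 || k > n) stop("'k' must lie in [0, n]", call. = FALSE)
  stats::binom.test(k, n, p = p0,
                    alternative = if (two_sided) "two.sided"
                                  else "greater")$p.value
}

#' Summarize melting-temperature divergence across ortholog pairs
#'
#' Computes the mean Tm difference, the fraction of pairs in which the
#' first species is more stable, and an exact binomial sign test against
#' 0.5. Exact zero differences are excluded from the sign-test denominator
#' (`zero_policy = "drop"`, the default) or counted as non-positive
#' (`"keep"`); both denominators are reported. When `dataset` is supplied,
#' the consistent-direction subset (same sign in every dataset) is also
#' summarized.
#'
#' @param delta_tm Numeric vector of Tm differences (first minus second
#'   species), degC.
#' @param dataset Optional factor/character of dataset labels, same
#'   length; pairs are matched across datasets by `id`.
#' @param id Optional pair identifiers (required with `dataset`).
#' @param zero_policy `"drop"` (default) or `"keep"`.
#' @return Object of class `"divergence_summary"`: `n_pairs`,
#'   `mean_delta_tm`, `fraction_positive`, `n_sign` (sign-test
#'   denominator), `binomial_p`, `fraction_positive_all` (zeroes in the
#'   denominator) and, when datasets are given, `consistent` (same fields
#'   on the consistent-direction subset).
#' @export
divergence_summary <- function(delta_tm, dataset = NULL, id = NULL,
                               zero_policy = c("drop", "keep")) {
  zero_policy <- match.arg(zero_policy)
  delta_tm <- delta_tm[is.finite(delta_tm)]
  if (length(delta_tm) == 0L) stop("no finite Tm differences", call. = FALSE)
  base <- .direction_stats(delta_tm, zero_policy)
  out <- structure(c(base, list(consistent = NULL)),
                   class = "divergence_summary")
  if (!is.null(dataset)) {
    if (is.null(id)) stop("'id' required with 'dataset'", call. = FALSE)
    sgn_by_id <- tapply(sign(delta_tm), id, function(s)
      if (all(s > 0) || all(s < 0)) s[1] else NA_real_)
    n_ds <- tapply(dataset, id, function(d) length(unique(d)))
    consistent_ids <- names(sgn_by_id)[!is.na(sgn_by_id) &
                                         n_ds == length(unique(dataset))]
    first <- dataset == unique(dataset)[1] & id %in% consistent_ids
    out$consistent <- .direction_stats(delta_tm[first], zero_policy)
  }
  out
}

.direction_stats <- function(delta, zero_policy) {
  pos <- sum(delta > 0); neg <- sum(delta < 0); zero <- sum(delta == 0)
  n_sign <- if (zero_policy == "drop") pos + neg else length(delta)
  p <- if (n_sign > 0) sign_binomial_test(pos, n_sign) else NA_real_
  list(n_pairs = length(delta),
       mean_delta_tm = mean(delta),
       fraction_positive = if (pos + neg > 0) pos / (pos + neg) else NaN,
       fraction_positive_all = pos / length(delta),
       n_sign = n_sign, n_zero = zero, binomial_p = p)
}

#' @export
print.divergence_summary <- function(x, ...) {
  cat("Ortholog Tm divergence summary\n")
  cat(sprintf("  pairs: %d   mean dTm: %+.3f degC\n", x$n_pairs,
              x$mean_delta_tm))
  cat(sprintf("  fraction positive: %.3f (n = %d)   binomial p: %.3g\n",
              x$fraction_positive, x$n_sign, x$binomial_p))
  if (!is.null(x$consistent))
    cat(sprintf("  consistent direction: %d pairs, fraction %.3f, p %.3g\n",
                x$consistent$n_pairs, x$consistent$fraction_positive,
                x$consistent$binomial_p))
  invisible(x)
}

#' Hybrid-versus-parent stability contrast
#'
#' Two complementary contrasts on proteins measured in both a parental and
#' a hybrid context. (1) Pooled: a Wilcoxon signed-rank test of paired
#' |dTm| between contexts, asking whether ortholog Tm differences shrink
#' in the hybrid's common cellular environment. (2) Per species: paired
#' t-tests of Tm(hybrid) - Tm(parent), asking which species' alleles
#' change stability. The Wilcoxon test uses the exact distribution for
#' n <= 25 and the normal approximation with continuity correction above.
#'
#' @param pairs_parent,pairs_hybrid Pair tables from [filter_fits()]
#'   (columns orthogroup_id, tm_1, tm_2, delta_tm) for the parental and
#'   hybrid datasets.
#' @return Object of class `"hybrid_contrast"`: `n`, `mean_abs_parent`,
#'   `mean_abs_hybrid`, `wilcoxon_p`, and per species `mean_shift_1`,
#'   `t_p_1`, `mean_shift_2`, `t_p_2` (species 1 = tm_1 column).
#' @export
hybrid_contrast <- function(pairs_parent, pairs_hybrid) {
  shared <- intersect(pairs_parent$orthogroup_id,
                      pairs_hybrid$orthogroup_id)
  if (length(shared) < 2L)
    stop("fewer than 2 proteins matched across contexts", call. = FALSE)
  pp <- pairs_parent[match(shared, pairs_parent$orthogroup_id), ]
  ph <- pairs_hybrid[match(shared, pairs_hybrid$orthogroup_id), ]
  abs_p <- abs(pp$delta_tm); abs_h <- abs(ph$delta_tm)
  d <- abs_h - abs_p
  n_eff <- sum(d != 0)
  wp <- if (n_eff == 0) 1
        else suppressWarnings(stats::wilcox.test(
          abs_h, abs_p, paired = TRUE, exact = n_eff <= 25,
          correct = TRUE)$p.value)
  shift1 <- ph$tm_1 - pp$tm_1
  shift2 <- ph$tm_2 - pp$tm_2
  tp <- function(x) if (stats::sd(x) == 0) 1
                    else stats::t.test(x)$p.value
  structure(list(n = length(shared),
                 mean_abs_parent = mean(abs_p),
                 mean_abs_hybrid = mean(abs_h),
                 wilcoxon_p = wp,
                 mean_shift_1 = mean(shift1), t_p_1 = tp(shift1),
                 mean_shift_2 = mean(shift2), t_p_2 = tp(shift2)),
            class = "hybrid_contrast")
}

#' @export
print.hybrid_contrast <- function(x, ...) {
  cat("Hybrid vs parent stability contrast (n =", x$n, ")\n")
  cat(sprintf("  mean |dTm|: parent %.3f, hybrid %.3f (Wilcoxon p %.3g)\n",
              x$mean_abs_parent, x$mean_abs_hybrid, x$wilcoxon_p))
  cat(sprintf("  species 1 shift: %+.3f degC (paired t p %.3g)\n",
              x$mean_shift_1, x$t_p_1))
  cat(sprintf("  species 2 shift: %+.3f degC (paired t p %.3g)\n",
              x$mean_shift_2, x$t_p_2))
  invisible(x)
}

#' Annotation enrichment of stabilized proteins
#'
#' Fisher's exact test of a binary outcome (e.g. "stabilized in the
#' hybrid") against a binary annotation, overall or per species; with a
#' species vector, additionally fits the logistic regression
#' `stabilized ~ annotation * species` and reports the interaction
#' p-value (does the enrichment differ between species?).
#'
#' @param stabilized Logical vector.
#' @param annotation Logical vector, same length.
#' @param species Optional character/factor, same length.
#' @return Data frame with one row per stratum (`"all"` or species
#'   levels): odds_ratio, fisher_p, n; attribute `interaction_p` when
#'   species is given.
#' @export
enrichment_test <- function(stabilized, annotation, species = NULL) {
  stopifnot(length(stabilized) == length(annotation))
  one <- function(st, an) {
    tab <- table(factor(st, c(TRUE, FALSE)), factor(an, c(TRUE, FALSE)))
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
      return(c(odds_ratio = NA_real_, fisher_p = NA_real_,
               n = length(st)))
    ft <- stats::fisher.test(tab)
    c(odds_ratio = unname(ft$estimate), fisher_p = ft$p.value,
      n = length(st))
  }
  if (is.null(species)) {
    res <- as.data.frame(t(one(stabilized, annotation)))
    res <- cbind(stratum = "all", res)
    return(res)
  }
  levs <- unique(as.character(species))
  res <- do.call(rbind, lapply(levs, function(sp)
    one(stabilized[species == sp], annotation[species == sp])))
  res <- cbind(data.frame(stratum = levs), as.data.frame(res))
  fit <- tryCatch(
    stats::glm(stabilized ~ annotation * species, family = stats::binomial),
    error = function(e) NULL, warning = function(w)
      suppressWarnings(stats::glm(stabilized ~ annotation * species,
                                  family = stats::binomial)))
  ip <- NA_real_
  if (!is.null(fit)) {
    cf <- summary(fit)$coefficients
    row <- grep(":", rownames(cf))
    if (length(row) == 1) ip <- cf[row, 4]
  }
  attr(res, "interaction_p") <- ip
  res
}

#' Species effect on Tm with and without an abundance covariate
#'
#' Ordinary least squares of Tm on species, with and without protein
#' abundance as a covariate (`tm ~ species` and
#' `tm ~ species + abundance`), to check whether expression level
#' confounds the interspecies stability difference. The reported
#' `p_abundance` is the Wald p-value of the abundance term in the adjusted
#' model.
#'
#' @param tm Numeric melting temperatures.
#' @param species Two-level factor/character.
#' @param abundance Numeric covariate (e.g. log2 intensity).
#' @return List: `effect_unadjusted`, `effect_adjusted` (species
#'   coefficient, degC), `p_species_adjusted`, `p_abundance`, `n`,
#'   `collinear` flag.
#' @export
abundance_adjusted_species_effect <- function(tm, species, abundance) {
  keep <- is.finite(tm) & !is.na(species) & is.finite(abundance)
  tm <- tm[keep]; species <- factor(species[keep])
  abundance <- abundance[keep]
  if (nlevels(species) != 2)
    stop("'species' must have exactly 2 levels", call. = FALSE)
  m0 <- stats::lm(tm ~ species)
  m1 <- stats::lm(tm ~ species + abundance)
  collinear <- any(is.na(stats::coef(m1)))
  s1 <- summary(m1)$coefficients
  list(effect_unadjusted = unname(stats::coef(m0)[2]),
       effect_adjusted = unname(stats::coef(m1)[2]),
       p_species_adjusted = s1[2, 4],
       p_abundance = if (collinear) NA_real_ else s1[3, 4],
       n = length(tm), collinear = collinear)
}

#' Spearman rank correlation
#'
#' Tie-corrected Spearman correlation with asymptotic p-value.
#'
#' @param x,y Equal-length numeric vectors, >= 4 complete pairs.
#' @return List with `rho`, `p` and `n`.
#' @export
rank_correlation <- function(x, y) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 4L) stop("need >= 4 complete pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("rank correlation undefined for a constant vector", call. = FALSE)
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                         exact = FALSE))
  list(rho = unname(ct$estimate), p = ct$p.value, n = length(x))
}
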