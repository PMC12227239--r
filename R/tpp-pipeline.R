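# From peptide evidence to filtered, normalized, cross-dataset-comparable
# per-protein melting temperatures: spike-in standardization, profile
# building, 4PL fitting, quality filtering into ortholog pairs,
# temperature-vector renormalization, and hybrid allele splitting.

#' Standardize evidence to the spike-in protein
#'
#' Divides every peptide's channel-k intensity by the spike-in protein's
#' summed channel-k intensity, removing per-channel loading/labeling
#' effects. Spike rows are retained and flagged in a `spike_flag` column.
#'
#' @param evidence Evidence data frame (see [read_evidence()]).
#' @param spec A [dataset_spec()]; `spike_protein_id` must be present with
#'   positive total intensity in every channel.
#' @return Evidence data frame with standardized intensities.
#' @export
standardize_to_spike <- function(evidence, spec) {
  stopifnot(inherits(spec, "dataset_spec"))
  ch <- spec$channels
  spike <- evidence$protein_id == spec$spike_protein_id
  if (!any(spike))
    stop("spike-in protein '", spec$spike_protein_id,
         "' not found in evidence", call. = FALSE)
  tot <- colSums(evidence[spike, ch, drop = FALSE])
  zero <- which(tot <= 0)
  if (length(zero) > 0)
    stop("spike-in intensity is zero in channel(s): ",
         paste(ch[zero], collapse = ", "), call. = FALSE)
  evidence[, ch] <- sweep(as.matrix(evidence[, ch]), 2, tot, "/")
  evidence$spike_flag <- spike
  evidence
}

#' Build per-protein melt profiles from standardized evidence
#'
#' Sums PSM intensities per channel for each protein (within species) and
#' scales by the lowest-temperature channel, giving the relative soluble
#' fraction (1 at the lowest treatment temperature). Proteins with fewer
#' than `min_psm` PSMs, or with zero summed intensity in the
#' lowest-temperature channel, are dropped and counted.
#'
#' @param evidence Standardized evidence (see [standardize_to_spike()]).
#' @param spec A [dataset_spec()].
#' @param min_psm Minimum PSM count to retain a protein (default 3).
#' @return List with `profiles` (long data frame: protein_id,
#'   orthogroup_id, species, n_psm, temperature, value) and `report`
#'   (named counts: proteins_in, removed_low_psm, removed_zero_reference,
#'   proteins_out).
#' @export
build_profiles <- function(evidence, spec, min_psm = 3L) {
  stopifnot(inherits(spec, "dataset_spec"))
  ch <- spec$channels
  ev <- evidence[evidence$protein_id != spec$spike_protein_id, ,
                 drop = FALSE]
  key <- paste(ev$protein_id, ev$species, sep = "\r")
  groups <- split(seq_len(nrow(ev)), key)
  n_in <- length(groups)
  low_psm <- 0L; zero_ref <- 0L
  out <- vector("list", n_in)
  j <- 0L
  for (g in groups) {
    n_psm <- length(g)
    if (n_psm < min_psm) { low_psm <- low_psm + 1L; next }
    sums <- colSums(as.matrix(ev[g, ch, drop = FALSE]))
    if (sums[1] <= 0) { zero_ref <- zero_ref + 1L; next }
    j <- j + 1L
    out[[j]] <- data.frame(
      protein_id = ev$protein_id[g[1]],
      orthogroup_id = ev$orthogroup_id[g[1]],
      species = ev$species[g[1]],
      n_psm = n_psm,
      temperature = spec$temperatures,
      value = unname(sums / sums[1]),
      stringsAsFactors = FALSE)
  }
  profiles <- if (j > 0) do.call(rbind, out[seq_len(j)]) else
    data.frame(protein_id = character(), orthogroup_id = character(),
               species = character(), n_psm = integer(),
               temperature = numeric(), value = numeric())
  list(profiles = profiles,
       report = c(proteins_in = n_in, removed_low_psm = low_psm,
                  removed_zero_reference = zero_ref,
                  proteins_out = j))
}

#' Fit melt curves to every profile in a dataset
#'
#' Applies [fit_melt_curve()] to each protein profile and collects the
#' results in a table.
#'
#' @param profiles Long profile data frame from [build_profiles()].
#' @return Data frame, one row per protein: protein_id, orthogroup_id,
#'   species, n_psm, tm, tm_infl, slope, plateau, top, r2, flag.
#' @export
fit_melt_curves <- function(profiles) {
  rows <- lapply(split(profiles, profiles$protein_id), function(p) {
    fit <- fit_melt_curve(p$temperature, p$value,
                          protein_id = p$protein_id[1],
                          n_psm = p$n_psm[1])
    data.frame(protein_id = p$protein_id[1],
               orthogroup_id = p$orthogroup_id[1],
               species = p$species[1], n_psm = p$n_psm[1],
               tm = fit$tm, tm_infl = unname(fit$par["tm_infl"]),
               slope = unname(fit$par["slope"]),
               plateau = unname(fit$par["plateau"]),
               top = unname(fit$par["top"]),
               r2 = fit$r2, flag = fit$flag, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Bootstrap melting-temperature confidence intervals for a dataset
#'
#' Computes [bootstrap_tm_ci()] for every protein with at least `min_psm`
#' PSMs and attaches `ci_low`/`ci_high` columns to the fit table.
#'
#' @param fits Fit table from [fit_melt_curves()].
#' @param evidence Standardized evidence the fits came from.
#' @param spec A [dataset_spec()].
#' @param n_boot Bootstrap resamples (default 100).
#' @param seed Integer seed.
#' @param min_psm Minimum PSM count for a CI (default 8).
#' @return `fits` with `ci_low` and `ci_high` columns (NA where withheld).
#' @export
add_tm_confidence <- function(fits, evidence, spec, n_boot = 100,
                              seed = 1L, min_psm = 8L) {
  fits$ci_low <- NA_real_
  fits$ci_high <- NA_real_
  eligible <- which(fits$n_psm >= min_psm & fits$flag == "ok")
  for (i in eligible) {
    rows <- evidence$protein_id == fits$protein_id[i]
    mat <- as.matrix(evidence[rows, spec$channels, drop = FALSE])
    ci <- bootstrap_tm_ci(mat, spec$temperatures, n_boot = n_boot,
                          seed = seed + i, min_psm = min_psm)
    if (!is.null(ci)) {
      fits$ci_low[i] <- ci[1]
      fits$ci_high[i] <- ci[2]
    }
  }
  fits
}

#' Filter fits into ortholog pairs
#'
#' Applies the quality funnel to a dataset's fit table: drop a-priori
#' excluded orthogroups, proteins without an ortholog assignment, fits
#' with r-squared below `r2_min` (the threshold is inclusive: r2 >= r2_min
#' is retained) or a non-`"ok"` flag, and orthogroups represented in only
#' one species. Survivors are paired into one row per orthogroup.
#'
#' @param fits Fit table from [fit_melt_curves()] (optionally with CI
#'   columns from [add_tm_confidence()]).
#' @param r2_min Minimum fit r-squared (default 0.8).
#' @param exclude Character vector of orthogroup IDs to drop a priori.
#' @param species Length-2 character giving the two species tags, in
#'   (first, second) order; `delta_tm = tm[first] - tm[second]`. Default
#'   `c("Scer", "Suva")`.
#' @return List with `pairs` (orthogroup_id, tm_1, tm_2, delta_tm, r2_1,
#'   r2_2, n_psm_1, n_psm_2, ci columns when available, ci_nonoverlap) and
#'   `report` (telescoping funnel counts).
#' @export
filter_fits <- function(fits, r2_min = 0.8, exclude = character(),
                        species = c("Scer", "Suva")) {
  n0 <- length(unique(fits$orthogroup_id[!is.na(fits$orthogroup_id)]))
  f <- fits[!(fits$orthogroup_id %in% exclude), , drop = FALSE]
  n_excl <- n0 - length(unique(f$orthogroup_id[!is.na(f$orthogroup_id)]))
  has_og <- !is.na(f$orthogroup_id) & nzchar(f$orthogroup_id)
  f1 <- f[has_og, , drop = FALSE]
  ok <- f1$flag == "ok" & is.finite(f1$r2) & f1$r2 >= r2_min &
    is.finite(f1$tm)
  f2 <- f1[ok, , drop = FALSE]
  n_after_r2 <- length(unique(f2$orthogroup_id))
  a <- f2[f2$species == species[1], , drop = FALSE]
  b <- f2[f2$species == species[2], , drop = FALSE]
  shared <- intersect(a$orthogroup_id, b$orthogroup_id)
  a <- a[match(shared, a$orthogroup_id), , drop = FALSE]
  b <- b[match(shared, b$orthogroup_id), , drop = FALSE]
  has_ci <- all(c("ci_low", "ci_high") %in% names(fits))
  pairs <- data.frame(
    orthogroup_id = shared,
    tm_1 = a$tm, tm_2 = b$tm, delta_tm = a$tm - b$tm,
    r2_1 = a$r2, r2_2 = b$r2,
    n_psm_1 = a$n_psm, n_psm_2 = b$n_psm,
    stringsAsFactors = FALSE)
  if (has_ci) {
    pairs$ci_low_1 <- a$ci_low; pairs$ci_high_1 <- a$ci_high
    pairs$ci_low_2 <- b$ci_low; pairs$ci_high_2 <- b$ci_high
    pairs$ci_nonoverlap <- !is.na(a$ci_low) & !is.na(b$ci_low) &
      (a$ci_high < b$ci_low | b$ci_high < a$ci_low)
  }
  report <- c(orthogroups_in = n0,
              removed_excluded = n_excl,
              removed_low_quality = n0 - n_excl - n_after_r2,
              removed_single_species = n_after_r2 - length(shared),
              pairs_out = length(shared),
              proteins_no_ortholog = sum(!has_og))
  list(pairs = pairs, report = report)
}

#' Renormalize a dataset's temperature vector to a reference
#'
#' Makes melting temperatures comparable across datasets run on different
#' effective temperature gradients. Tm values are first estimated in each
#' dataset separately; an ordinary least-squares regression of the
#' reference Tm on the other dataset's Tm over shared proteins gives an
#' affine map (intercept a, slope b), which is applied to the other
#' dataset's temperature vector (T -> a + b T); all of its profiles are
#' then refit on the adjusted vector. Because the map is affine with
#' b > 0, the rank order of the adjusted dataset's Tms is preserved.
#'
#' @param ref_fits Fit table of the reference dataset.
#' @param other_evidence Raw evidence of the dataset to adjust.
#' @param other_spec Its [dataset_spec()].
#' @param min_shared Minimum number of shared proteins with Tm in both
#'   datasets (default 20).
#' @param min_psm Passed to [build_profiles()].
#' @return List with `coef` (c(intercept, slope)), `spec` (adjusted
#'   [dataset_spec()]), `fits` (refitted fit table on the adjusted
#'   vector) and `n_shared`.
#' @export
renormalize_tm <- function(ref_fits, other_evidence, other_spec,
                           min_shared = 20L, min_psm = 3L) {
  std <- standardize_to_spike(other_evidence, other_spec)
  prof <- build_profiles(std, other_spec, min_psm = min_psm)
  other_fits <- fit_melt_curves(prof$profiles)
  ok_ref <- ref_fits[ref_fits$flag == "ok" & is.finite(ref_fits$tm), ]
  ok_oth <- other_fits[other_fits$flag == "ok" & is.finite(other_fits$tm), ]
  shared <- intersect(ok_ref$protein_id, ok_oth$protein_id)
  if (length(shared) < min_shared)
    stop("only ", length(shared), " shared proteins with Tm in both ",
         "datasets; >= ", min_shared, " required", call. = FALSE)
  x <- ok_oth$tm[match(shared, ok_oth$protein_id)]
  y <- ok_ref$tm[match(shared, ok_ref$protein_id)]
  cf <- stats::coef(stats::lm(y ~ x))
  a <- unname(cf[1]); b <- unname(cf[2])
  if (abs(b - 1) > 0.5)
    warning("renormalization slope ", signif(b, 3),
            " far from 1; suspect batch effect or bad pairing")
  adj_spec <- dataset_spec(other_spec$dataset_id,
                           a + b * other_spec$temperatures,
                           other_spec$spike_protein_id,
                           other_spec$channels)
  prof$profiles$temperature <- rep(adj_spec$temperatures,
                                   times = nrow(prof$profiles) /
                                     length(adj_spec$temperatures))
  refits <- fit_melt_curves(prof$profiles)
  list(coef = c(intercept = a, slope = b), spec = adj_spec,
       fits = refits, n_shared = length(shared))
}

#' Split hybrid evidence into per-species allele tables
#'
#' Removes species-ambiguous (shared) peptides and routes the remaining
#' peptides to their species' allele. Spike-in rows are kept in both
#' outputs so each can be standardized independently. Proteins whose
#' peptides are all shared disappear from both outputs.
#'
#' @param hybrid_evidence Evidence with a logical `shared_flag` column.
#' @param spike_protein_id Spike-in identifier kept in both halves.
#' @param species Species tags to split on (default `c("Scer", "Suva")`).
#' @return List with one evidence data frame per species,
#'   `shared_fraction` (fraction of non-spike peptides removed) and
#'   `n_removed`.
#' @export
split_hybrid_alleles <- function(hybrid_evidence, spike_protein_id = "BSA",
                                 species = c("Scer", "Suva")) {
  if (!is.logical(hybrid_evidence$shared_flag))
    stop("'shared_flag' must be logical", call. = FALSE)
  non_spike <- hybrid_evidence$protein_id != spike_protein_id
  shared_fraction <- mean(hybrid_evidence$shared_flag[non_spike])
  keep <- hybrid_evidence[!(hybrid_evidence$shared_flag & non_spike), ,
                          drop = FALSE]
  out <- lapply(species, function(sp)
    keep[keep$species == sp |
           keep$protein_id == spike_protein_id, , drop = FALSE])
  names(out) <- species
  c(out, list(shared_fraction = shared_fraction,
              n_removed = sum(hybrid_evidence$shared_flag & non_spike)))
}

#' Flag peptides present in both proteome sequence sets
#'
#' Marks a peptide as shared when its sequence occurs exactly (I and L
#' distinct) in proteins of both species' proteomes.
#'
#' @param evidence Evidence data frame.
#' @param proteome_1,proteome_2 Character vectors of protein sequences.
#' @return `evidence` with `shared_flag` set by the matcher.
#' @export
flag_shared_peptides <- function(evidence, proteome_1, proteome_2) {
  p1 <- paste(proteome_1, collapse = "|")
  p2 <- paste(proteome_2, collapse = "|")
  in1 <- vapply(evidence$peptide_seq, grepl, logical(1), x = p1,
                fixed = TRUE, USE.NAMES = FALSE)
  in2 <- vapply(evidence$peptide_seq, grepl, logical(1), x = p2,
                fixed = TRUE, USE.NAMES = FALSE)
  evidence$shared_flag <- in1 & in2
  evidence
}

#' Restrict ortholog pairs to non-overlapping confidence intervals
#'
#' Keeps pairs whose two species' bootstrap confidence intervals are
#' strictly disjoint (intervals touching at an endpoint count as
#' overlapping) in every supplied dataset.
#'
#' @param pairs_list List of pair tables (from [filter_fits()] with CI
#'   columns), one per dataset.
#' @return Pair table (from the first dataset) restricted to orthogroups
#'   with strictly disjoint CIs in all datasets.
#' @export
overlap_ci_pairs <- function(pairs_list) {
  if (inherits(pairs_list, "data.frame")) pairs_list <- list(pairs_list)
  ids <- lapply(pairs_list, function(p) {
    if (!"ci_nonoverlap" %in% names(p))
      stop("pairs lack CI columns; run add_tm_confidence() first",
           call. = FALSE)
    p$orthogroup_id[!is.na(p$ci_nonoverlap) & p$ci_nonoverlap]
  })
  keep <- Reduce(intersect, ids)
  first <- pairs_list[[1]]
  first[first$orthogroup_id %in% keep, , drop = FALSE]
}

#' Run the full single-dataset TPP analysis
#'
#' Convenience wrapper: spike standardization, profile building, 4PL
#' fitting, and optionally bootstrap CIs.
#'
#' @param evidence Raw evidence data frame.
#' @param spec A [dataset_spec()].
#' @param min_psm Minimum PSM count (default 3).
#' @param ci Logical; compute bootstrap CIs (default FALSE).
#' @param n_boot,seed Passed to [add_tm_confidence()].
#' @return List with `fits`, `profiles` and `report`.
#' @export
fit_dataset <- function(evidence, spec, min_psm = 3L, ci = FALSE,
                        n_boot = 100, seed = 1L) {
  std <- standardize_to_spike(evidence, spec)
  prof <- build_profiles(std, spec, min_psm = min_psm)
  fits <- fit_melt_curves(prof$profiles)
  if (ci) fits <- add_tm_confidence(fits, std, spec, n_boot = n_boot,
                                    seed = seed)
  list(fits = fits, profiles = prof$profiles, report = prof$report)
}
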