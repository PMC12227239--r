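# Ground-truth-labeled synthetic data for every stage of the analysis:
# TMT-style evidence tables for two parental replicates and an
# interspecific hybrid, CD melt traces, forward/reverse ddG prediction
# tables, and growth/activity thermotolerance series.

#' Simulation configuration
#'
#' Builds and validates the configuration for the synthetic-data
#' generators. Defaults describe the study conditions the package is
#' designed around: two yeast species whose proteomes differ by a mean
#' melting-temperature offset of 1.6 degC with 85% of offsets positive
#' (S. cerevisiae minus S. uvarum), ten-channel parental temperature
#' gradients and a sixteen-channel hybrid gradient spanning 30-72 degC,
#' hybrid-specific stabilization of S. uvarum alleles of 1.1 degC, and 43%
#' shared (species-ambiguous) peptides in the hybrid.
#'
#' @param n_proteins Number of ortholog pairs to simulate.
#' @param psm_per_protein List `(mean, dispersion)` of a shifted
#'   negative-binomial PSM-count distribution (minimum 1), so the PSM >= 3
#'   and >= 8 filters have bite.
#' @param parent_temps,hybrid_temps Strictly increasing treatment
#'   temperature vectors, degC.
#' @param tm_base_mean,tm_base_sd Mean/SD of the S. uvarum melting
#'   temperature, degC.
#' @param species_offset_mean Signed mean of the interspecies Tm offset
#'   (cerevisiae minus uvarum), degC.
#' @param species_offset_sd SD of the offset magnitude, degC.
#' @param frac_positive Fraction of ortholog pairs with a positive offset.
#' @param hybrid_stabilization_mean,hybrid_stabilization_sd Mean/SD of the
#'   hybrid-context stabilization applied to S. uvarum alleles, degC.
#' @param slope_mean,slope_sd Mean/SD of the 4PL melt slope, 1/degC.
#' @param intensity_noise_cv Coefficient of variation of the
#'   multiplicative lognormal reporter noise.
#' @param shared_peptide_frac Fraction of hybrid peptides mapping to both
#'   proteomes.
#' @param batch_tm_shift Length-2 numeric `(slope, intercept)`: affine
#'   distortion of the effective Tm used when generating the second
#'   parental replicate, to exercise cross-dataset renormalization.
#' @param seed Integer seed; identical config + seed gives identical data.
#' @return A validated list of class `"sim_config"`.
#' @export
sim_config <- function(n_proteins = 500,
                       psm_per_protein = list(mean = 6, dispersion = 2),
                       parent_temps = seq(30, 72, length.out = 10),
                       hybrid_temps = seq(30, 72, length.out = 16),
                       tm_base_mean = 50, tm_base_sd = 4,
                       species_offset_mean = 1.6, species_offset_sd = 1,
                       frac_positive = 0.85,
                       hybrid_stabilization_mean = 1.1,
                       hybrid_stabilization_sd = 0.3,
                       slope_mean = 0.6, slope_sd = 0.1,
                       intensity_noise_cv = 0.1,
                       shared_peptide_frac = 0.43,
                       batch_tm_shift = c(1, 0),
                       seed = 1L) {
  cfg <- list(n_proteins = as.integer(n_proteins),
              psm_per_protein = psm_per_protein,
              parent_temps = as.numeric(parent_temps),
              hybrid_temps = as.numeric(hybrid_temps),
              tm_base_mean = tm_base_mean, tm_base_sd = tm_base_sd,
              species_offset_mean = species_offset_mean,
              species_offset_sd = species_offset_sd,
              frac_positive = frac_positive,
              hybrid_stabilization_mean = hybrid_stabilization_mean,
              hybrid_stabilization_sd = hybrid_stabilization_sd,
              slope_mean = slope_mean, slope_sd = slope_sd,
              intensity_noise_cv = intensity_noise_cv,
              shared_peptide_frac = shared_peptide_frac,
              batch_tm_shift = as.numeric(batch_tm_shift),
              seed = as.integer(seed))
  .validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

.validate_sim_config <- function(cfg) {
  if (cfg$n_proteins < 1) stop("'n_proteins' must be >= 1", call. = FALSE)
  for (tv in list(cfg$parent_temps, cfg$hybrid_temps))
    if (length(tv) < 2 || any(diff(tv) <= 0))
      stop("temperature vectors must be strictly increasing", call. = FALSE)
  for (fr in c(cfg$frac_positive, cfg$shared_peptide_frac))
    if (fr < 0 || fr > 1)
      stop("fractions must lie in [0, 1]", call. = FALSE)
  for (s in c(cfg$tm_base_sd, cfg$species_offset_sd,
              cfg$hybrid_stabilization_sd, cfg$slope_sd,
              cfg$intensity_noise_cv))
    if (s < 0) stop("standard deviations must be >= 0", call. = FALSE)
  if (length(cfg$batch_tm_shift) != 2 || cfg$batch_tm_shift[1] <= 0)
    stop("'batch_tm_shift' must be (slope > 0, intercept)", call. = FALSE)
  if (abs(2 * cfg$frac_positive - 1) < 1e-12 &&
      abs(cfg$species_offset_mean) > 1e-12)
    stop("frac_positive = 0.5 forces a zero signed mean offset; set ",
         "'species_offset_mean' to 0", call. = FALSE)
  invisible(cfg)
}

#' Read a simulation configuration from YAML
#'
#' @param path Path to a YAML file whose keys match [sim_config()]
#'   arguments.
#' @return A `"sim_config"` object.
#' @export
read_sim_config <- function(path) {
  do.call(sim_config, yaml::read_yaml(path))
}

# mean of |N(mu, sd)| (folded normal)
.folded_mean <- function(mu, sd) {
  if (sd == 0) return(abs(mu))
  sd * sqrt(2 / pi) * exp(-mu^2 / (2 * sd^2)) +
    mu * (1 - 2 * stats::pnorm(-mu / sd))
}

# magnitude-distribution location such that
# (2 p - 1) * E|N(mu, sd)| = target signed mean
.solve_offset_mu <- function(target, p, sd) {
  w <- 2 * p - 1
  if (abs(target) < 1e-12) return(0)
  goal <- target / w
  if (goal < 0) stop("sign of 'species_offset_mean' inconsistent with ",
                     "'frac_positive'", call. = FALSE)
  if (sd == 0) return(goal)
  if (.folded_mean(0, sd) >= goal)
    stop("'species_offset_sd' too large for the requested signed mean ",
         "offset and 'frac_positive'", call. = FALSE)
  stats::uniroot(function(m) .folded_mean(m, sd) - goal,
                 c(0, goal + 10 * sd), extendInt = "upX")$root
}

.random_peptide <- function(n) {
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  vapply(sample(8:20, n, replace = TRUE),
         function(len) paste(c(sample(aa, len - 1, replace = TRUE), "K"),
                             collapse = ""),
         character(1))
}

# shifted negative binomial with minimum 1
.draw_psm_counts <- function(n, spec) {
  mu <- spec$mean - 1
  size <- spec$dispersion
  1L + stats::rnbinom(n, mu = mu, size = size)
}

# multiplicative lognormal noise with unit mean and given CV
.ln_noise <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

# evidence rows for one protein (or the spike-in) across channels
.emit_rows <- function(protein_id, orthogroup_id, species, n_psm, temps,
                       tm, slope, abundance, channel_fac, cv,
                       shared = FALSE, psm_prefix = "psm") {
  base <- stats::rlnorm(n_psm, meanlog = log(abundance / n_psm), sdlog = 0.5)
  frac <- if (is.na(tm)) rep(1, length(temps))
          else logistic4(temps, top = 1, plateau = 0, slope = slope, tm = tm)
  inten <- outer(base, frac * channel_fac) *
    matrix(.ln_noise(n_psm * length(temps), cv), nrow = n_psm)
  df <- data.frame(
    peptide_seq = .random_peptide(n_psm),
    protein_id = protein_id, orthogroup_id = orthogroup_id,
    species = species, shared_flag = shared,
    psm_id = paste0(psm_prefix, "_", protein_id, "_", seq_len(n_psm)),
    stringsAsFactors = FALSE)
  colnames(inten) <- paste0("channel_", seq_along(temps))
  cbind(df, as.data.frame(inten))
}

#' Simulate a two-replicate parental thermal proteome profiling experiment
#'
#' Generates TMT-style peptide evidence tables for two parental replicate
#' datasets, each containing both species, together with the ground truth.
#' Per ortholog pair, the S. uvarum Tm is drawn from
#' Normal(`tm_base_mean`, `tm_base_sd`); the interspecies offset has a
#' positive sign with probability `frac_positive` and a folded-normal
#' magnitude calibrated so the signed mean equals `species_offset_mean`.
#' Reporter intensities follow
#' `abundance x logistic4(T; tm, slope, plateau = 0) x channel factor x
#' lognormal noise`; a temperature-independent spike-in protein (`"BSA"`)
#' is included in every dataset, and per-channel multiplicative factors
#' (drawn once per dataset) make the spike standardization identifiable.
#' In replicate 2 the generating Tm is distorted to
#' `intercept + slope * Tm` (`batch_tm_shift`), to exercise
#' [renormalize_tm()].
#'
#' @param cfg A [sim_config()] object.
#' @param replicates Number of parental replicate datasets (default 2; the
#'   batch distortion applies from the second onward).
#' @return List with `evidence` (list of evidence data frames, one per
#'   replicate), `specs` (list of [dataset_spec()]s) and `truth`
#'   (data frame: protein_id, orthogroup_id, species, context, tm_true,
#'   slope_true, abundance_true, offset_true).
#' @export
simulate_tpp_experiment <- function(cfg, replicates = 2) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  n <- cfg$n_proteins
  og <- sprintf("OG%04d", seq_len(n))
  tm_uva <- stats::rnorm(n, cfg$tm_base_mean, cfg$tm_base_sd)
  mu_mag <- .solve_offset_mu(cfg$species_offset_mean, cfg$frac_positive,
                             cfg$species_offset_sd)
  mag <- abs(stats::rnorm(n, mu_mag, cfg$species_offset_sd))
  sgn <- ifelse(stats::runif(n) < cfg$frac_positive, 1, -1)
  offset <- sgn * mag
  tm_cer <- tm_uva + offset
  slope_cer <- pmax(stats::rnorm(n, cfg$slope_mean, cfg$slope_sd), 0.1)
  slope_uva <- pmax(stats::rnorm(n, cfg$slope_mean, cfg$slope_sd), 0.1)
  abund <- stats::rlnorm(n, meanlog = log(1e6), sdlog = 1)
  npsm <- .draw_psm_counts(2 * n, cfg$psm_per_protein)

  truth <- data.frame(
    protein_id = c(paste0("Scer_", og), paste0("Suva_", og)),
    orthogroup_id = c(og, og),
    species = rep(c("Scer", "Suva"), each = n),
    context = "parent",
    tm_true = c(tm_cer, tm_uva),
    slope_true = c(slope_cer, slope_uva),
    abundance_true = c(abund, abund),
    offset_true = c(offset, offset),
    stringsAsFactors = FALSE)

  evidence <- vector("list", replicates)
  specs <- vector("list", replicates)
  for (r in seq_len(replicates)) {
    ch_fac <- stats::rlnorm(length(cfg$parent_temps), 0, 0.2)
    shift <- if (r == 1) c(1, 0) else cfg$batch_tm_shift
    rows <- vector("list", 2 * n + 1)
    for (i in seq_len(n)) {
      rows[[i]] <- .emit_rows(
        paste0("Scer_", og[i]), og[i], "Scer", npsm[i], cfg$parent_temps,
        tm = shift[2] + shift[1] * tm_cer[i], slope = slope_cer[i],
        abundance = abund[i], channel_fac = ch_fac,
        cv = cfg$intensity_noise_cv, psm_prefix = paste0("r", r))
      rows[[n + i]] <- .emit_rows(
        paste0("Suva_", og[i]), og[i], "Suva", npsm[n + i],
        cfg$parent_temps,
        tm = shift[2] + shift[1] * tm_uva[i], slope = slope_uva[i],
        abundance = abund[i], channel_fac = ch_fac,
        cv = cfg$intensity_noise_cv, psm_prefix = paste0("r", r))
    }
    rows[[2 * n + 1]] <- .emit_rows(
      "BSA", NA_character_, "spike", 30L, cfg$parent_temps, tm = NA,
      slope = 1, abundance = 5e5, channel_fac = ch_fac,
      cv = cfg$intensity_noise_cv, psm_prefix = paste0("r", r))
    evidence[[r]] <- do.call(rbind, rows)
    rownames(evidence[[r]]) <- NULL
    specs[[r]] <- dataset_spec(paste0("parent_rep", r), cfg$parent_temps)
  }
  names(evidence) <- names(specs) <- paste0("rep", seq_len(replicates))
  list(evidence = evidence, specs = specs, truth = truth)
}

#' Simulate a hybrid thermal proteome profiling experiment
#'
#' Generates a single 16-channel evidence table for an interspecific
#' hybrid in which every ortholog pair appears as two alleles. S. uvarum
#' alleles receive a hybrid-context stabilization drawn from
#' Normal(`hybrid_stabilization_mean`, `hybrid_stabilization_sd`);
#' S. cerevisiae alleles keep their parental Tm. A `shared_peptide_frac`
#' share of peptides is flagged as mapping to both proteomes (these are
#' removed by [split_hybrid_alleles()] before any quantitation).
#'
#' @param cfg A [sim_config()] object.
#' @param truth Parental truth table from [simulate_tpp_experiment()].
#' @return List with `evidence` (one data frame), `spec` and `truth` (the
#'   input truth extended with `context = "hybrid"` rows).
#' @export
simulate_hybrid_experiment <- function(cfg, truth) {
  stopifnot(inherits(cfg, "sim_config"))
  if (missing(truth) || is.null(truth) ||
      !all(c("protein_id", "tm_true", "context") %in% names(truth)))
    stop("parental truth table required", call. = FALSE)
  set.seed(cfg$seed + 1L)
  par_truth <- truth[truth$context == "parent", ]
  n_rec <- nrow(par_truth)
  stab <- ifelse(par_truth$species == "Suva",
                 stats::rnorm(n_rec, cfg$hybrid_stabilization_mean,
                              cfg$hybrid_stabilization_sd),
                 0)
  tm_hyb <- par_truth$tm_true + stab
  npsm <- .draw_psm_counts(n_rec, cfg$psm_per_protein)
  ch_fac <- stats::rlnorm(length(cfg$hybrid_temps), 0, 0.2)
  rows <- vector("list", n_rec + 1)
  for (i in seq_len(n_rec)) {
    rows[[i]] <- .emit_rows(
      par_truth$protein_id[i], par_truth$orthogroup_id[i],
      par_truth$species[i], npsm[i], cfg$hybrid_temps,
      tm = tm_hyb[i], slope = par_truth$slope_true[i],
      abundance = par_truth$abundance_true[i], channel_fac = ch_fac,
      cv = cfg$intensity_noise_cv, psm_prefix = "hyb")
  }
  rows[[n_rec + 1]] <- .emit_rows(
    "BSA", NA_character_, "spike", 30L, cfg$hybrid_temps, tm = NA,
    slope = 1, abundance = 5e5, channel_fac = ch_fac,
    cv = cfg$intensity_noise_cv, psm_prefix = "hyb")
  ev <- do.call(rbind, rows)
  rownames(ev) <- NULL
  non_spike <- ev$species != "spike"
  ev$shared_flag[non_spike] <-
    stats::runif(sum(non_spike)) < cfg$shared_peptide_frac
  hyb_truth <- par_truth
  hyb_truth$context <- "hybrid"
  hyb_truth$tm_true <- tm_hyb
  hyb_truth$stabilization_true <- stab
  list(evidence = ev,
       spec = dataset_spec("hybrid", cfg$hybrid_temps),
       truth = rbind(cbind(truth, stabilization_true = 0), hyb_truth))
}

#' Simulate a circular dichroism melt trace
#'
#' Evaluates [two_state_signal()] on a temperature grid and adds Gaussian
#' noise.
#'
#' @param tm Melting temperature, degC.
#' @param dH Van 't Hoff enthalpy, kcal/mol (> 0).
#' @param temps Strictly increasing temperatures, degC.
#' @param noise_sd SD of additive Gaussian noise.
#' @param seed Integer seed.
#' @param model 1 or 2 (see [two_state_signal()]).
#' @param baselines Named list/vector bF, mF, bU, mU for model 2.
#' @return Data frame with `temperature` and `signal`.
#' @export
simulate_cd_trace <- function(tm, dH, temps = seq(4, 74, by = 0.5),
                              noise_sd = 0.01, seed = 1L, model = 2,
                              baselines = c(bF = 1, mF = -0.001,
                                            bU = 0.05, mU = 0.0005)) {
  if (dH <= 0) stop("'dH' must be positive", call. = FALSE)
  if (any(diff(temps) <= 0))
    stop("'temps' must be strictly increasing", call. = FALSE)
  set.seed(as.integer(seed))
  b <- as.list(baselines)
  sig <- two_state_signal(temps, tm, dH, model = model,
                          bF = b$bF, mF = b$mF, bU = b$bU, mU = b$mU)
  data.frame(temperature = temps,
             signal = sig + stats::rnorm(length(temps), 0, noise_sd))
}

#' Simulate forward/reverse per-substitution ddG prediction tables
#'
#' Per substitution, a true ddG is drawn from
#' Normal(`effect_mean`, `effect_sd`) (sign convention: negative means the
#' S. uvarum residue is less stable). The forward prediction is
#' `true + noise` and the reverse prediction `-true + independent noise`,
#' so noiseless tables are exactly antisymmetric and the combined estimate
#' `(forward - reverse)/2` has half the forward-only noise variance.
#' Per-protein structure-confidence scores are drawn so that roughly
#' `frac_low_confidence` of proteins fail the pLDDT >= 70 filter.
#'
#' @param n_proteins Number of proteins.
#' @param subs_per_protein Mean substitution count per protein (shifted
#'   Poisson, minimum 1).
#' @param effect_mean,effect_sd True-effect distribution, kcal/mol.
#' @param pred_noise_sd SD of the independent prediction noise (>= 0).
#' @param frac_low_confidence Share of proteins simulated with mean pLDDT
#'   below 70.
#' @param seed Integer seed.
#' @return List with `table` (columns orthogroup_id, position, aa_ref,
#'   aa_alt, ddg_forward, ddg_reverse, plddt_mean_pair,
#'   lddt_vs_reference) and `truth` (per-substitution true ddG and
#'   per-protein confidence labels).
#' @export
simulate_ddg_tables <- function(n_proteins = 200, subs_per_protein = 20,
                                effect_mean = -0.02, effect_sd = 0.5,
                                pred_noise_sd = 0.2,
                                frac_low_confidence = 0.2, seed = 1L) {
  if (pred_noise_sd < 0) stop("'pred_noise_sd' must be >= 0", call. = FALSE)
  set.seed(as.integer(seed))
  og <- sprintf("OG%04d", seq_len(n_proteins))
  nsub <- 1L + stats::rpois(n_proteins, max(subs_per_protein - 1, 0))
  low <- stats::runif(n_proteins) < frac_low_confidence
  plddt <- ifelse(low, stats::runif(n_proteins, 40, 69.5),
                  stats::runif(n_proteins, 70.5, 95))
  lddt <- pmin(stats::rbeta(n_proteins, 40, 3), 1)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  total <- sum(nsub)
  ddg_true <- stats::rnorm(total, effect_mean, effect_sd)
  fwd <- ddg_true + stats::rnorm(total, 0, pred_noise_sd)
  rev <- -ddg_true + stats::rnorm(total, 0, pred_noise_sd)
  prot <- rep(seq_len(n_proteins), nsub)
  pos <- unlist(lapply(nsub, function(k) sort(sample.int(600, k))),
                use.names = FALSE)
  aa_ref <- sample(aa, total, replace = TRUE)
  aa_alt <- vapply(aa_ref, function(a) sample(setdiff(aa, a), 1),
                   character(1), USE.NAMES = FALSE)
  tab <- data.frame(
    orthogroup_id = og[prot], position = pos,
    aa_ref = aa_ref, aa_alt = aa_alt,
    ddg_forward = fwd, ddg_reverse = rev,
    plddt_mean_pair = plddt[prot], lddt_vs_reference = lddt[prot],
    stringsAsFactors = FALSE)
  truth <- data.frame(
    orthogroup_id = og[prot], position = pos, ddg_true = ddg_true,
    low_confidence = low[prot], stringsAsFactors = FALSE)
  list(table = tab, truth = truth)
}

#' Simulate a thermotolerance response series
#'
#' `kind = "growth"`: final culture yield versus challenge temperature
#' from a five-parameter logistic whose half-maximum falls at `it50`, with
#' Gaussian noise. `kind = "activity"`: per challenge temperature, a
#' plate-reader absorbance time series whose slope is proportional to the
#' residual enzyme activity at that temperature (5PL in temperature), on
#' top of a blank slope; a matching substrate-blank series is returned.
#'
#' @param kind `"growth"` or `"activity"`.
#' @param it50 Target half-inhibition temperature, degC.
#' @param temps Strictly increasing challenge temperatures, degC.
#' @param params List of curve parameters: `top`, `bottom`, `slope`
#'   (decadic, negative for a decreasing response), `asymmetry`,
#'   `noise_sd`; for activity additionally `time` (seconds), `max_rate`
#'   (AU/s at full activity), `blank_rate` (AU/s).
#' @param seed Integer seed.
#' @return For growth, a data frame `temperature`, `response`. For
#'   activity, a list with `sample` and `blank` long data frames
#'   (`temperature`, `time`, `value`).
#' @export
simulate_response_series <- function(kind = c("growth", "activity"),
                                     it50 = 40,
                                     temps = seq(25, 55, length.out = 12),
                                     params = list(), seed = 1L) {
  kind <- match.arg(kind)
  if (any(diff(temps) <= 0))
    stop("'temps' must be strictly increasing", call. = FALSE)
  p <- utils::modifyList(
    list(top = 1, bottom = 0, slope = -0.15, asymmetry = 1,
         noise_sd = 0.02, time = seq(0, 900, by = 10),
         max_rate = 2e-3, blank_rate = 1e-4), params)
  # choose the 5PL midpoint so the curve's half-maximum sits at it50
  par0 <- c(bottom = p$bottom, top = p$top, slope = p$slope,
            midpoint = it50, asymmetry = p$asymmetry)
  fmax <- max(.pl5(seq(min(temps), max(temps), length.out = 512), par0))
  g <- function(m) {
    .pl5(it50, c(bottom = p$bottom, top = p$top, slope = p$slope,
                 midpoint = m, asymmetry = p$asymmetry)) - fmax / 2
  }
  m <- stats::uniroot(g, c(it50 - 30, it50 + 30), extendInt = "yes")$root
  par <- c(bottom = p$bottom, top = p$top, slope = p$slope,
           midpoint = m, asymmetry = p$asymmetry)
  set.seed(as.integer(seed))
  resp <- .pl5(temps, par)
  if (kind == "growth") {
    return(data.frame(temperature = temps,
                      response = resp + stats::rnorm(length(temps), 0,
                                                     p$noise_sd)))
  }
  frac <- resp / max(resp)
  mk <- function(rate) {
    do.call(rbind, lapply(seq_along(temps), function(i) {
      data.frame(temperature = temps[i], time = p$time,
                 value = 0.05 + rate[i] * p$time +
                   stats::rnorm(length(p$time), 0, p$noise_sd * 0.05))
    }))
  }
  list(sample = mk(p$blank_rate + p$max_rate * frac),
       blank = mk(rep(p$blank_rate, length(temps))))
}
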