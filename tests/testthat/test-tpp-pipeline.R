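# Shared small simulated dataset for pipeline tests
tpp_fixture <- local({
  cfg <- sim_config(n_proteins = 40, seed = 1234)
  sim <- simulate_tpp_experiment(cfg, replicates = 1)
  list(cfg = cfg, sim = sim, ev = sim$evidence$rep1, spec = sim$specs$rep1)
})

test_that("spike standardization divides by the spike channel sums", {
  ev <- tpp_fixture$ev; spec <- tpp_fixture$spec
  std <- standardize_to_spike(ev, spec)
  spike_rows <- ev$protein_id == "BSA"
  tot <- colSums(ev[spike_rows, spec$channels])
  expect_equal(as.numeric(std[1, spec$channels]),
               unname(as.numeric(ev[1, spec$channels]) / tot))
  expect_true(all(std$spike_flag == spike_rows))
  # doubling one spike channel halves that channel everywhere
  ev2 <- ev
  ev2[spike_rows, "channel_3"] <- ev2[spike_rows, "channel_3"] * 2
  std2 <- standardize_to_spike(ev2, spec)
  expect_equal(std2$channel_3[!spike_rows], std$channel_3[!spike_rows] / 2)
  expect_equal(std2$channel_1[!spike_rows], std$channel_1[!spike_rows])
  # missing or zero spike errors, naming the channel
  ev3 <- ev[!spike_rows, ]
  expect_error(standardize_to_spike(ev3, spec), "not found")
  ev4 <- ev
  ev4[spike_rows, "channel_2"] <- 0
  expect_error(standardize_to_spike(ev4, spec), "channel_2")
})

test_that("spike standardization recovers simulated channel factors", {
  # after standardization, per-channel medians of the lowest-T-relative
  # expectation no longer carry the channel factors: a noiseless flat
  # (spike-like) protein becomes exactly flat
  cfg <- sim_config(n_proteins = 10, intensity_noise_cv = 0, seed = 77)
  sim <- simulate_tpp_experiment(cfg, replicates = 1)
  std <- standardize_to_spike(sim$evidence$rep1, sim$specs$rep1)
  spike <- std[std$spike_flag, sim$specs$rep1$channels]
  sums <- colSums(spike)
  expect_equal(as.numeric(sums), rep(1, length(sums)))
})

test_that("build_profiles enforces PSM filter and normalizes to lowest T", {
  ev <- tpp_fixture$ev; spec <- tpp_fixture$spec
  std <- standardize_to_spike(ev, spec)
  res <- build_profiles(std, spec, min_psm = 3)
  psm_counts <- table(ev$protein_id[ev$protein_id != "BSA"])
  expect_equal(unname(res$report["removed_low_psm"]),
               sum(psm_counts < 3))
  # counts telescope
  expect_equal(unname(res$report["proteins_in"] -
                        res$report["removed_low_psm"] -
                        res$report["removed_zero_reference"]),
               unname(res$report["proteins_out"]))
  # every profile starts at 1
  first <- res$profiles[res$profiles$temperature == spec$temperatures[1], ]
  expect_true(all(abs(first$value - 1) < 1e-12))
  # proteins with exactly 2 PSMs are dropped
  two_psm <- names(psm_counts)[psm_counts == 2]
  expect_false(any(two_psm %in% res$profiles$protein_id))
})

test_that("profile aggregation equals the intensity-weighted PSM mean", {
  ev <- tpp_fixture$ev; spec <- tpp_fixture$spec
  std <- standardize_to_spike(ev, spec)
  res <- build_profiles(std, spec, min_psm = 3)
  pid <- res$profiles$protein_id[1]
  rows <- std[std$protein_id == pid, spec$channels]
  mat <- as.matrix(rows)
  # summed profile scaled to channel 1 == weighted mean of per-PSM
  # profiles with weights equal to each PSM's channel-1 intensity
  per_psm <- sweep(mat, 1, mat[, 1], "/")
  weighted <- colSums(per_psm * mat[, 1]) / sum(mat[, 1])
  prof <- res$profiles$value[res$profiles$protein_id == pid]
  expect_equal(prof, unname(weighted), tolerance = 1e-12)
})

test_that("filter_fits applies inclusive r2 rule and telescoping funnel", {
  fits <- data.frame(
    protein_id = c("a_cer", "a_uva", "b_cer", "b_uva", "c_cer", "d_uva",
                   "e_cer", "e_uva"),
    orthogroup_id = c("A", "A", "B", "B", "C", "D", "E", "E"),
    species = c("Scer", "Suva", "Scer", "Suva", "Scer", "Suva", "Scer",
                "Suva"),
    n_psm = 5L,
    tm = c(50, 49, 52, 51, 48, 47, 55, 54),
    r2 = c(0.95, 0.9, 0.80, 0.79, 0.9, 0.9, 0.99, 0.98),
    flag = "ok", stringsAsFactors = FALSE)
  res <- filter_fits(fits, r2_min = 0.8, exclude = "E")
  # boundary: r2 = 0.80 retained, 0.79 removed -> B loses its pair
  expect_false("B" %in% res$pairs$orthogroup_id)
  expect_true("A" %in% res$pairs$orthogroup_id)
  # C and D are single-species; E excluded a priori
  expect_equal(sort(res$pairs$orthogroup_id), "A")
  r <- res$report
  expect_equal(unname(r["orthogroups_in"]),
               unname(r["removed_excluded"] + r["removed_low_quality"] +
                        r["removed_single_species"] + r["pairs_out"]))
  expect_equal(res$pairs$delta_tm, res$pairs$tm_1 - res$pairs$tm_2)
})

test_that("filter funnel bookkeeping matches a constructed degradation", {
  cfg <- sim_config(n_proteins = 50, psm_per_protein = list(mean = 8,
                                                            dispersion = 20),
                    seed = 5)
  sim <- simulate_tpp_experiment(cfg, replicates = 1)
  res <- fit_dataset(sim$evidence$rep1, sim$specs$rep1)
  f <- res$fits
  # force 6 orthogroups to low quality in one species
  bad <- sprintf("OG%04d", 1:6)
  f$r2[f$orthogroup_id %in% bad & f$species == "Scer"] <- 0.5
  out <- filter_fits(f)
  expect_equal(unname(out$report["removed_single_species"]) >= 6, TRUE)
  expect_false(any(bad %in% out$pairs$orthogroup_id))
})

test_that("renormalization is the identity for an undistorted replicate", {
  cfg <- sim_config(n_proteins = 40, batch_tm_shift = c(1, 0), seed = 3)
  sim <- simulate_tpp_experiment(cfg)
  r1 <- fit_dataset(sim$evidence$rep1, sim$specs$rep1)
  rn <- renormalize_tm(r1$fits, sim$evidence$rep2, sim$specs$rep2)
  expect_lt(abs(rn$coef["slope"] - 1), 0.06)
  # Tms essentially unchanged: post-renormalization mean inter-replicate
  # offset stays small
  both <- intersect(r1$fits$protein_id[r1$fits$flag == "ok"],
                    rn$fits$protein_id[rn$fits$flag == "ok"])
  off <- rn$fits$tm[match(both, rn$fits$protein_id)] -
    r1$fits$tm[match(both, r1$fits$protein_id)]
  expect_lt(abs(mean(off)), 0.15)
})

test_that("renormalization regression equals the closed-form OLS", {
  cfg <- sim_config(n_proteins = 40, batch_tm_shift = c(0.95, 2), seed = 6)
  sim <- simulate_tpp_experiment(cfg)
  r1 <- fit_dataset(sim$evidence$rep1, sim$specs$rep1)
  r2 <- fit_dataset(sim$evidence$rep2, sim$specs$rep2)
  rn <- renormalize_tm(r1$fits, sim$evidence$rep2, sim$specs$rep2)
  ok1 <- r1$fits[r1$fits$flag == "ok", ]
  ok2 <- r2$fits[r2$fits$flag == "ok", ]
  shared <- intersect(ok1$protein_id, ok2$protein_id)
  x <- ok2$tm[match(shared, ok2$protein_id)]
  y <- ok1$tm[match(shared, ok1$protein_id)]
  b <- cov(x, y) / var(x)
  a <- mean(y) - b * mean(x)
  expect_equal(unname(rn$coef["slope"]), b, tolerance = 1e-8)
  expect_equal(unname(rn$coef["intercept"]), a, tolerance = 1e-8)
  # affine map with positive slope preserves the Tm rank order
  both <- intersect(r2$fits$protein_id[r2$fits$flag == "ok"],
                    rn$fits$protein_id[rn$fits$flag == "ok"])
  tm_raw <- r2$fits$tm[match(both, r2$fits$protein_id)]
  tm_adj <- rn$fits$tm[match(both, rn$fits$protein_id)]
  expect_equal(order(tm_raw), order(tm_adj))
  expect_error(renormalize_tm(r1$fits[1:5, ], sim$evidence$rep2,
                              sim$specs$rep2), "shared proteins")
})

test_that("hybrid allele splitting removes shared peptides and reports the fraction", {
  cfg <- sim_config(n_proteins = 60, shared_peptide_frac = 0.43, seed = 11)
  sim <- simulate_tpp_experiment(cfg, replicates = 1)
  hyb <- simulate_hybrid_experiment(cfg, sim$truth)
  sp <- split_hybrid_alleles(hyb$evidence)
  expect_lt(abs(sp$shared_fraction - 0.43), 0.05)
  expect_false(any(sp$Scer$shared_flag & sp$Scer$protein_id != "BSA"))
  expect_true(all(sp$Scer$species %in% c("Scer", "spike")))
  expect_true(all(sp$Suva$species %in% c("Suva", "spike")))
  # with no shared peptides the two tables partition the non-spike input
  cfg0 <- sim_config(n_proteins = 20, shared_peptide_frac = 0, seed = 12)
  sim0 <- simulate_tpp_experiment(cfg0, replicates = 1)
  hyb0 <- simulate_hybrid_experiment(cfg0, sim0$truth)
  sp0 <- split_hybrid_alleles(hyb0$evidence)
  expect_equal(sp0$shared_fraction, 0)
  n_non_spike <- sum(hyb0$evidence$protein_id != "BSA")
  expect_equal(sum(sp0$Scer$protein_id != "BSA") +
                 sum(sp0$Suva$protein_id != "BSA"), n_non_spike)
})

test_that("exact peptide matching flags peptides present in both proteomes", {
  ev <- data.frame(peptide_seq = c("ACDEFGHK", "MNPQRSTK", "WYACDEFK"),
                   protein_id = "p", species = "Scer", shared_flag = FALSE,
                   stringsAsFactors = FALSE)
  prot1 <- c("MMACDEFGHKLL", "MNPQRSTKAA")
  prot2 <- c("QQACDEFGHKPP", "WWYACDEFKR")
  out <- flag_shared_peptides(ev, prot1, prot2)
  expect_equal(out$shared_flag, c(TRUE, FALSE, FALSE))
})

test_that("CI non-overlap requires strictly disjoint intervals everywhere", {
  mk <- function(lo1, hi1, lo2, hi2) data.frame(
    orthogroup_id = "A", tm_1 = 51, tm_2 = 50, delta_tm = 1,
    ci_low_1 = lo1, ci_high_1 = hi1, ci_low_2 = lo2, ci_high_2 = hi2,
    ci_nonoverlap = hi1 < lo2 | hi2 < lo1)
  # touching endpoints count as overlap
  expect_equal(nrow(overlap_ci_pairs(list(mk(50, 52, 52, 54)))), 0)
  expect_equal(nrow(overlap_ci_pairs(list(mk(50, 51.9, 52, 54)))), 1)
  # must be disjoint in every dataset
  expect_equal(nrow(overlap_ci_pairs(list(mk(50, 51.9, 52, 54),
                                          mk(50, 52, 52, 54)))), 0)
  expect_error(overlap_ci_pairs(list(data.frame(orthogroup_id = "A"))),
               "CI columns")
})
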