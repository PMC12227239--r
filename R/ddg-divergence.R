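# Antisymmetric combination and aggregation of per-substitution
# forward/reverse folding free-energy (ddG) predictions into
# interspecies stability-divergence summaries.
#
# Sign convention, fixed once and used end-to-end: negative combined ddG
# means the S. uvarum (alt) residue is less stable, i.e. S. cerevisiae
# (reference) more stable.

#' Extract amino-acid substitutions from a pairwise alignment
#'
#' Walks an aligned ortholog pair and returns one record per aligned
#' column where both residues are present (non-gap) and differ. Columns
#' containing a gap (indels) are skipped and counted separately; positions
#' are 1-based over the ungapped reference (first) sequence.
#'
#' @param pair An `"aligned_pair"` from [read_aligned_fasta()], or a list
#'   with `seq1` (reference) and `seq2` elements.
#' @return List with `substitutions` (data frame: position, aa_ref,
#'   aa_alt) and `n_indel_columns`.
#' @export
extract_substitutions <- function(pair) {
  s1 <- strsplit(pair$seq1, "")[[1]]
  s2 <- strsplit(pair$seq2, "")[[1]]
  if (length(s1) != length(s2))
    stop("aligned sequences must have equal lengths", call. = FALSE)
  alpha <- c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], "-", "*")
  if (!all(c(s1, s2) %in% alpha))
    stop("non-amino-acid character in alignment", call. = FALSE)
  ref_pos <- cumsum(s1 != "-")
  gap <- s1 == "-" | s2 == "-"
  sub <- !gap & s1 != s2
  list(substitutions = data.frame(position = ref_pos[sub],
                                  aa_ref = s1[sub], aa_alt = s2[sub],
                                  stringsAsFactors = FALSE),
       n_indel_columns = sum(gap))
}

#' Combine forward and reverse ddG predictions
#'
#' Antisymmetric predictors satisfy ddG(X to Y) = -ddG(Y to X); averaging
#' the forward prediction with the negative of the reverse,
#' `(forward - reverse) / 2`, cancels symmetric prediction bias and
#' halves independent prediction noise variance.
#'
#' @param ddg_forward,ddg_reverse Numeric vectors, kcal/mol.
#' @return Combined ddG vector; records with a missing member yield NA.
#' @export
combine_forward_reverse <- function(ddg_forward, ddg_reverse) {
  (ddg_forward - ddg_reverse) / 2
}

#' Add combined ddG to a substitution table
#'
#' Computes `ddg_combined` for every record with both members present and
#' reports the forward/reverse antisymmetry correlation at table level.
#' Records missing either member get `ddg_combined = NA` and are excluded
#' from downstream aggregates.
#'
#' @param ddg_table Data frame from [read_ddg_table()] or
#'   [simulate_ddg_tables()].
#' @return `ddg_table` with a `ddg_combined` column; attribute
#'   `fr_correlation` holds cor(forward, reverse) over complete records.
#' @export
add_combined_ddg <- function(ddg_table) {
  ddg_table$ddg_combined <- combine_forward_reverse(ddg_table$ddg_forward,
                                                    ddg_table$ddg_reverse)
  cc <- is.finite(ddg_table$ddg_forward) & is.finite(ddg_table$ddg_reverse)
  attr(ddg_table, "fr_correlation") <-
    if (sum(cc) >= 3) stats::cor(ddg_table$ddg_forward[cc],
                                 ddg_table$ddg_reverse[cc])
    else NA_real_
  ddg_table
}

#' Aggregate per-substitution ddG values for one protein
#'
#' @param values Numeric vector of combined ddG values (>= 1).
#' @param method `"mean"`, `"sum"`, or `"max_min_mean"`
#'   (max + min - mean, a largest-deviation metric).
#' @return The aggregate, kcal/mol.
#' @export
aggregate_protein <- function(values,
                              method = c("mean", "sum", "max_min_mean")) {
  method <- match.arg(method)
  values <- values[is.finite(values)]
  if (length(values) == 0L)
    stop("no finite ddG values to aggregate", call. = FALSE)
  switch(method,
         mean = mean(values),
         sum = sum(values),
         max_min_mean = max(values) + min(values) - mean(values))
}

#' Per-protein ddG aggregates
#'
#' Aggregates combined ddG values within each orthogroup by all three
#' methods and carries the confidence scores along.
#'
#' @param ddg_table Table with `ddg_combined` (see [add_combined_ddg()]).
#' @return Data frame: orthogroup_id, n_substitutions, mean_ddg, sum_ddg,
#'   max_min_mean_ddg, mean_plddt, lddt_vs_reference.
#' @export
aggregate_ddg <- function(ddg_table) {
  if (!"ddg_combined" %in% names(ddg_table))
    ddg_table <- add_combined_ddg(ddg_table)
  rows <- lapply(split(ddg_table, ddg_table$orthogroup_id), function(d) {
    v <- d$ddg_combined[is.finite(d$ddg_combined)]
    if (length(v) == 0L) return(NULL)
    data.frame(orthogroup_id = d$orthogroup_id[1],
               n_substitutions = length(v),
               mean_ddg = mean(v), sum_ddg = sum(v),
               max_min_mean_ddg = max(v) + min(v) - mean(v),
               mean_plddt = mean(d$plddt_mean_pair),
               lddt_vs_reference = d$lddt_vs_reference[1],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Filter proteins by structure confidence
#'
#' Removes proteins whose cross-species mean pLDDT is below `plddt_min`
#' or whose lDDT versus the reference structure set is below `lddt_min`.
#' Both thresholds are inclusive: values equal to the cutoff are
#' retained. Proteins with missing confidence are excluded and counted
#' separately.
#'
#' @param proteins Data frame with `mean_plddt` and `lddt_vs_reference`
#'   (e.g. from [aggregate_ddg()]).
#' @param plddt_min Minimum mean pLDDT (default 70).
#' @param lddt_min Minimum lDDT (default 0.70).
#' @return List with `kept` (surviving rows) and `report` (counts:
#'   proteins_in, removed_plddt, removed_lddt, removed_missing,
#'   proteins_out).
#' @export
confidence_filter <- function(proteins, plddt_min = 70, lddt_min = 0.70) {
  miss <- !is.finite(proteins$mean_plddt) |
    !is.finite(proteins$lddt_vs_reference)
  fail_plddt <- !miss & proteins$mean_plddt < plddt_min
  fail_lddt <- !miss & !fail_plddt & proteins$lddt_vs_reference < lddt_min
  keep <- !miss & !fail_plddt & !fail_lddt
  list(kept = proteins[keep, , drop = FALSE],
       report = c(proteins_in = nrow(proteins),
                  removed_plddt = sum(fail_plddt),
                  removed_lddt = sum(fail_lddt),
                  removed_missing = sum(miss),
                  proteins_out = sum(keep)))
}

#' Proteome-wide stability direction summary
#'
#' Fraction of proteins whose aggregate ddG indicates the reference
#' species (S. cerevisiae) is more stable — i.e. negative aggregates under
#' the sign convention — with an exact binomial test against 0.5. Exact
#' zeroes are dropped from the test denominator; the all-protein
#' denominator is also reported.
#'
#' @param aggregates Numeric vector of per-protein aggregate ddG values.
#' @return List: `n`, `n_sign`, `fraction_ref_more_stable`, `binomial_p`.
#' @export
proteome_direction_summary <- function(aggregates) {
  aggregates <- aggregates[is.finite(aggregates)]
  if (length(aggregates) == 0L) stop("no aggregates", call. = FALSE)
  neg <- sum(aggregates < 0); pos <- sum(aggregates > 0)
  n_sign <- neg + pos
  list(n = length(aggregates), n_sign = n_sign,
       fraction_ref_more_stable = if (n_sign > 0) neg / n_sign else NaN,
       binomial_p = if (n_sign > 0) sign_binomial_test(neg, n_sign)
                    else NA_real_)
}

#' Effect-size-binned substitution summary
#'
#' Bins substitutions by |combined ddG| (half-open bins `[lo, hi)`, the
#' top bin open-ended) and reports, per bin, the number of substitutions
#' favouring each species' stability and the summed positive and negative
#' combined values. Optional bootstrap standard errors resample
#' substitutions within protein (seeded).
#'
#' @param ddg_table Table with `ddg_combined` and `orthogroup_id`.
#' @param bin_edges Increasing numeric vector starting at 0 (default
#'   `c(0, 0.1, 0.5, 1, 2)`; a final open bin `>= 2` is implied).
#' @param n_boot Bootstrap resamples for SEs (0 = none).
#' @param seed Integer seed.
#' @return Data frame, one row per bin: bin label, n, n_ref_more_stable
#'   (combined < 0), n_alt_more_stable, sum_positive, sum_negative, and
#'   with `n_boot > 0` bootstrap SEs of the counts and sums.
#' @export
effect_bin_summary <- function(ddg_table, bin_edges = c(0, 0.1, 0.5, 1, 2),
                               n_boot = 0, seed = 1L) {
  if (bin_edges[1] != 0 || any(diff(bin_edges) <= 0))
    stop("'bin_edges' must be increasing and start at 0", call. = FALSE)
  v <- ddg_table$ddg_combined
  keep <- is.finite(v)
  v <- v[keep]
  prot <- ddg_table$orthogroup_id[keep]
  edges <- c(bin_edges, Inf)
  labels <- c(paste0("[", utils::head(bin_edges, -1), ",",
                     utils::tail(bin_edges, -1), ")"),
              paste0(">=", bin_edges[length(bin_edges)]))
  stats_one <- function(vv) {
    bin <- findInterval(abs(vv), edges, rightmost.closed = FALSE)
    t(vapply(seq_along(labels), function(b) {
      x <- vv[bin == b]
      c(n = length(x), n_ref_more_stable = sum(x < 0),
        n_alt_more_stable = sum(x > 0),
        sum_positive = sum(x[x > 0]), sum_negative = sum(x[x < 0]))
    }, numeric(5)))
  }
  base <- stats_one(v)
  out <- data.frame(bin = labels, base, stringsAsFactors = FALSE)
  if (n_boot > 0) {
    set.seed(as.integer(seed))
    by_prot <- split(v, prot)
    boots <- array(NA_real_, dim = c(n_boot, length(labels), 5))
    for (b in seq_len(n_boot)) {
      vb <- unlist(lapply(by_prot, function(x)
        x[sample.int(length(x), length(x), replace = TRUE)]),
        use.names = FALSE)
      boots[b, , ] <- stats_one(vb)
    }
    se <- apply(boots, c(2, 3), stats::sd)
    colnames(se) <- paste0("se_", colnames(base))
    out <- cbind(out, as.data.frame(se))
  }
  out
}
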