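# Readers and writers for the tabular and sequence formats the pipeline
# consumes: MaxQuant-evidence-like TSV, aligned FASTA ortholog pairs, and
# per-substitution ddG prediction tables. Readers validate and reject
# malformed input; every row drop is reported with a count.

#' Dataset specification
#'
#' Describes one TPP dataset: its identifier, treatment temperature
#' vector, spike-in protein and channel labels.
#'
#' @param dataset_id Character scalar.
#' @param temperatures Strictly increasing numeric vector, degC.
#' @param spike_protein_id Identifier of the spike-in standard (default
#'   `"BSA"`).
#' @param channels Channel column labels; default `channel_1..channel_K`.
#' @return A list of class `"dataset_spec"`.
#' @export
dataset_spec <- function(dataset_id, temperatures,
                         spike_protein_id = "BSA",
                         channels = paste0("channel_",
                                           seq_along(temperatures))) {
  if (any(diff(temperatures) <= 0))
    stop("'temperatures' must be strictly increasing", call. = FALSE)
  if (length(channels) != length(temperatures))
    stop("one channel label per temperature required", call. = FALSE)
  structure(list(dataset_id = dataset_id,
                 temperatures = as.numeric(temperatures),
                 spike_protein_id = spike_protein_id,
                 channels = channels),
            class = "dataset_spec")
}

.evidence_meta_cols <- c("peptide_seq", "protein_id", "orthogroup_id",
                         "species", "shared_flag", "psm_id")

#' Read a peptide evidence table
#'
#' Reads a tab-separated evidence file (peptide sequence, protein and
#' orthogroup IDs, species tag, shared-peptide flag, PSM identifier, one
#' intensity column per channel) and validates it against a
#' [dataset_spec()]. Rows whose intensity vector contains non-finite
#' values or is all zero are dropped, and the drop count is reported via
#' `message()`.
#'
#' @param path Path to a TSV file.
#' @param spec A [dataset_spec()]; channel columns must match.
#' @return Validated evidence data frame.
#' @export
read_evidence <- function(path, spec) {
  stopifnot(inherits(spec, "dataset_spec"))
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  missing_meta <- setdiff(.evidence_meta_cols, names(df))
  if (length(missing_meta) > 0)
    stop("evidence file missing column(s): ",
         paste(missing_meta, collapse = ", "), call. = FALSE)
  missing_ch <- setdiff(spec$channels, names(df))
  if (length(missing_ch) > 0)
    stop("evidence file missing channel column(s): ",
         paste(missing_ch, collapse = ", "), call. = FALSE)
  extra_ch <- setdiff(grep("^channel_", names(df), value = TRUE),
                      spec$channels)
  if (length(extra_ch) > 0)
    stop("channel-count mismatch vs dataset spec: unexpected ",
         paste(extra_ch, collapse = ", "), call. = FALSE)
  inten <- as.matrix(df[, spec$channels, drop = FALSE])
  if (!is.numeric(inten))
    stop("non-numeric intensity values in channel columns", call. = FALSE)
  bad <- !apply(inten, 1, function(x) all(is.finite(x)) && any(x > 0))
  if (any(bad))
    message(sum(bad), " row(s) dropped: non-finite or all-zero intensities")
  df <- df[!bad, , drop = FALSE]
  if (anyDuplicated(df$psm_id))
    stop("'psm_id' must be unique within a dataset", call. = FALSE)
  if (any(as.matrix(df[, spec$channels]) < 0))
    stop("negative intensities are not allowed", call. = FALSE)
  rownames(df) <- NULL
  df
}

#' Write a peptide evidence table
#'
#' @param evidence Evidence data frame.
#' @param path Output TSV path.
#' @export
write_evidence <- function(evidence, path) {
  utils::write.table(evidence, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a pairwise aligned ortholog FASTA
#'
#' Reads an aligned FASTA with exactly two records of equal aligned length
#' (gap character `-`), as produced by a pairwise protein aligner.
#'
#' @param path Path to the FASTA file.
#' @return List of class `"aligned_pair"`: `id1`, `id2`, `seq1`, `seq2`
#'   (character scalars, aligned).
#' @export
read_aligned_fasta <- function(path) {
  seqs <- Biostrings::readBStringSet(path)
  if (length(seqs) != 2L)
    stop("aligned FASTA must contain exactly 2 records, found ",
         length(seqs), call. = FALSE)
  s1 <- as.character(seqs[[1]]); s2 <- as.character(seqs[[2]])
  if (nchar(s1) != nchar(s2))
    stop("aligned sequences must have equal lengths", call. = FALSE)
  ok <- "^[-ACDEFGHIKLMNPQRSTVWY*]+$"
  if (!grepl(ok, s1) || !grepl(ok, s2))
    stop("alignment contains characters outside the amino-acid alphabet",
         call. = FALSE)
  structure(list(id1 = names(seqs)[1], id2 = names(seqs)[2],
                 seq1 = s1, seq2 = s2),
            class = "aligned_pair")
}

.ddg_cols <- c("orthogroup_id", "position", "aa_ref", "aa_alt",
               "ddg_forward", "ddg_reverse", "plddt_mean_pair",
               "lddt_vs_reference")

#' Read a per-substitution ddG prediction table
#'
#' Reads and validates a TSV of forward/reverse folding free-energy
#' predictions for interspecies amino-acid substitutions, with
#' per-residue/per-protein structure-confidence scores.
#'
#' @param path Path to a TSV with columns orthogroup_id, position,
#'   aa_ref, aa_alt, ddg_forward, ddg_reverse, plddt_mean_pair,
#'   lddt_vs_reference.
#' @return Validated data frame.
#' @export
read_ddg_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  missing <- setdiff(.ddg_cols, names(df))
  if (length(missing) > 0)
    stop("ddG table missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  bad_aa <- !(df$aa_ref %in% aa) | !(df$aa_alt %in% aa)
  if (any(bad_aa))
    stop("unknown amino-acid code(s): ",
         paste(unique(c(df$aa_ref, df$aa_alt)[c(df$aa_ref, df$aa_alt)
                                              %in% aa == FALSE]),
               collapse = ", "), call. = FALSE)
  for (col in c("position", "ddg_forward", "ddg_reverse",
                "plddt_mean_pair", "lddt_vs_reference"))
    if (!is.numeric(df[[col]]))
      stop("non-numeric values in column '", col, "'", call. = FALSE)
  if (any(df$position < 1 | df$position != round(df$position)))
    stop("'position' must be a positive integer (1-based, ungapped ",
         "reference)", call. = FALSE)
  df
}

#' Write a generic results table as TSV
#'
#' @param x Data frame.
#' @param path Output path.
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
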