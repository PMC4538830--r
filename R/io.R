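# File formats: uptake CSV, results / track / regions TSV, FASTA, masses.
#
# Every file written here starts with a commented metadata header
# (tool version, seed, config) sufficient to reproduce it; readers skip
# '#' lines. Formatting: %HDX to 2 decimals, Da to 4, masses to 5.

metadata_header <- function(seed = NULL, config = list()) {
  kv <- c(list(generated_by = paste0("hdxmap ",
                                     as.character(utils::packageVersion("hdxmap")))),
          if (!is.null(seed)) list(seed = seed),
          config)
  paste0("# ", names(kv), ": ",
         vapply(kv, function(v) paste(format(v), collapse = " "), ""))
}

write_with_header <- function(df, path, seed = NULL, config = list(),
                              sep = "\t") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(metadata_header(seed, config), con)
  utils::write.table(df, con, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a peptide-level deuterium uptake table
#'
#' The CSV dialect mirrors a peptide-level HDX export: one row per
#' protein/state/peptide/timepoint/replicate with the centroid mass shift
#' in Da. Columns: `protein_id`, `state`, `start`, `end`, `sequence`,
#' `timepoint_s`, `replicate`, `uptake_Da`. Lines starting with `#` are
#' metadata and skipped.
#'
#' @param path CSV file path.
#' @param noise_sd Expected centroid noise in Da; rows with
#'   `uptake_Da < -3 * noise_sd` (more negative than noise explains) are
#'   flagged with a warning.
#' @return Validated data.frame.
#' @export
read_uptake_csv <- function(path, noise_sd = 0.1) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  tab <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  check_uptake_columns(tab)
  validate_uptake(tab, noise_sd)
}

#' @rdname read_uptake_csv
#' @param tab An in-memory uptake table to validate.
#' @export
validate_uptake <- function(tab, noise_sd = 0.1) {
  rown <- seq_len(nrow(tab))
  if (!is.numeric(tab$uptake_Da)) {
    bad <- rown[is.na(suppressWarnings(as.numeric(tab$uptake_Da)))][1L]
    stop("non-numeric uptake_Da at row ", bad, call. = FALSE)
  }
  if (any(tab$timepoint_s <= 0)) {
    stop("non-positive timepoint_s at row ",
         rown[tab$timepoint_s <= 0][1L], call. = FALSE)
  }
  len_ok <- nchar(tab$sequence) == tab$end - tab$start + 1L
  if (!all(len_ok)) {
    stop("sequence length inconsistent with start/end at row ",
         rown[!len_ok][1L], call. = FALSE)
  }
  state <- if ("state" %in% names(tab)) tab$state else ""
  key <- paste(tab$protein_id, state, tab$start, tab$end, tab$timepoint_s,
               tab$replicate)
  if (anyDuplicated(key)) {
    stop("duplicate replicate key at row ", rown[duplicated(key)][1L],
         call. = FALSE)
  }
  n_neg <- sum(tab$uptake_Da < -3 * noise_sd)
  if (n_neg > 0L) {
    warning(n_neg, " row(s) with uptake more negative than 3 x noise_sd",
            call. = FALSE)
  }
  tab
}

#' Write an uptake table as CSV with a metadata header
#'
#' @param tab Uptake table.
#' @param path Output path.
#' @param seed,config Recorded in the metadata header.
#' @export
write_uptake_csv <- function(tab, path, seed = NULL, config = list()) {
  tab$uptake_Da <- round(tab$uptake_Da, 4)
  write_with_header(tab, path, seed, config, sep = ",")
}

#' Write differential results as TSV
#'
#' One row per peptide: coordinates, per-timepoint differences, Delta-HDX,
#' its timepoint, Da difference, p-value, call, direction and reason codes.
#'
#' @param fit An [hdx_diff()] object.
#' @param path Output path.
#' @param seed Recorded in the metadata header.
#' @export
write_results_tsv <- function(fit, path, seed = NULL) {
  stopifnot(inherits(fit, "hdx_diff"))
  r <- fit$results
  tps <- r$timepoints_s[[1L]]
  flat <- as.data.frame(fit)
  for (j in seq_along(tps)) {
    flat[[sprintf("diff_pct_%gs", tps[j])]] <-
      round(vapply(r$diff_pct, `[`, numeric(1), j), 2)
    flat[[sprintf("diff_da_%gs", tps[j])]] <-
      round(vapply(r$diff_da, `[`, numeric(1), j), 4)
  }
  flat$delta_hdx <- round(flat$delta_hdx, 2)
  flat$delta_da <- round(flat$delta_da, 4)
  th <- fit$thresholds
  write_with_header(flat, path, seed, list(
    min_delta_pct = th$min_delta_pct, alpha = th$alpha, min_da = th$min_da,
    skip_first = fit$skip_first, t_test_scope = fit$t_test_scope,
    var_equal = fit$var_equal, n_tests = fit$n_tests,
    n_excluded = fit$n_excluded))
}

#' Write a residue track / extracted regions as TSV
#'
#' @param track A [project_residues()] track.
#' @param path Output path.
#' @param seed,config Metadata header fields.
#' @export
write_track_tsv <- function(track, path, seed = NULL, config = list()) {
  stopifnot(inherits(track, "residue_track"))
  out <- as.data.frame(track)
  out$value <- round(out$value, 2)
  write_with_header(out, path, seed,
                    c(list(protein_id = attr(track, "protein_id")), config))
}

#' @rdname write_track_tsv
#' @param regions An [extract_regions()] data.frame.
#' @export
write_regions_tsv <- function(regions, path, seed = NULL, config = list()) {
  regions$mean_delta_hdx <- round(regions$mean_delta_hdx, 2)
  write_with_header(regions, path, seed, config)
}

#' Read protein sequences from FASTA
#'
#' @param path FASTA file.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  seqs <- Biostrings::readAAStringSet(path)
  out <- as.character(seqs)
  names(out) <- sub("\\s.*$", "", names(seqs))
  out
}

#' Read observed neutral masses (single-column CSV, Da)
#'
#' @param path CSV with a `mass` column (or a single unnamed column).
#' @return Numeric vector of masses.
#' @export
read_observed_masses <- function(path) {
  tab <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  col <- if ("mass" %in% names(tab)) tab$mass else tab[[1L]]
  if (!is.numeric(col)) stop("masses must be numeric", call. = FALSE)
  col
}
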