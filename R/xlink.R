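# BS3 d0/d4 crosslink candidate enumeration and mass-doublet matching.

#' Neutral peptide mass from sequence
#'
#' Sum of residue masses plus one water.
#'
#' @param sequence Amino-acid sequence (standard 20 residues).
#' @param kind `"monoisotopic"` (default) or `"average"`.
#' @return Mass in Da.
#' @examples
#' peptide_mass("GG")  # 132.05349
#' @export
peptide_mass <- function(sequence, kind = c("monoisotopic", "average")) {
  kind <- match.arg(kind)
  chars <- aa_split(sequence)
  if (kind == "monoisotopic") {
    sum(AA_MONO[chars]) + WATER_MONO
  } else {
    sum(AA_AVG[chars]) + WATER_AVG
  }
}

#' In-silico tryptic digestion
#'
#' Cleaves after Lys or Arg except when the next residue is Pro, and emits
#' every peptide with up to `max_missed` internal missed cleavages. The
#' default of 2 reflects that a crosslinked lysine necessarily blocks
#' cleavage, creating missed-cleavage peptides.
#'
#' Each peptide carries its crosslinkable amine sites: lysine side chains
#' and, for the first peptide, the protein N-terminal amine. A lysine at a
#' peptide's C-terminus is linkable only when it is the protein C-terminus
#' (a crosslinked lysine could not have been cleaved).
#'
#' @param sequence Protein sequence.
#' @param max_missed Maximum internal missed cleavages (default 2).
#' @param protein_id Identifier carried into the output.
#' @return data.frame with `protein_id`, `start`, `end`, `sequence`,
#'   `missed_cleavages`, `monoisotopic_mass` and the list-column
#'   `linkable_sites` (absolute residue positions).
#' @examples
#' tryptic_digest("AKRPGK", max_missed = 0)$sequence  # "AK", "RPGK"
#' @export
tryptic_digest <- function(sequence, max_missed = 2L, protein_id = "protein") {
  chars <- aa_split(sequence)
  n <- length(chars)
  max_missed <- as.integer(max_missed)
  # cut after position i: K/R not followed by P
  cuts <- which(chars %in% c("K", "R"))
  cuts <- cuts[cuts < n & chars[pmin(cuts + 1L, n)] != "P"]
  bounds <- c(0L, cuts, n)  # fragment f spans bounds[f]+1 .. bounds[f+1]
  n_frag <- length(bounds) - 1L

  rows <- list()
  for (f in seq_len(n_frag)) {
    for (m in 0:min(max_missed, n_frag - f)) {
      s <- bounds[f] + 1L
      e <- bounds[f + m + 1L]
      pep <- substr(sequence, s, e)
      k_pos <- s - 1L + which(chars[s:e] == "K")
      # C-terminal K linkable only at the protein C-terminus
      k_pos <- k_pos[k_pos != e | e == n]
      sites <- sort(unique(c(if (s == 1L) 1L, k_pos)))
      rows[[length(rows) + 1L]] <- data.frame(
        protein_id = protein_id, start = s, end = e, sequence = pep,
        missed_cleavages = m,
        monoisotopic_mass = peptide_mass(pep),
        stringsAsFactors = FALSE
      )
      rows[[length(rows)]]$linkable_sites <- list(sites)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Enumerate BS3 crosslink candidates between two digests
#'
#' All normalized pairs of digestion peptides in which both partners carry
#' at least one linkable amine; the theoretical mass is the sum of the two
#' peptide masses plus the light (d0) linker. Loop-links (a peptide paired
#' with itself) are excluded; intra-protein pairs between different
#' peptides are kept.
#'
#' @param peptides_a,peptides_b [tryptic_digest()] outputs (may be the same
#'   object for intra-protein candidates).
#' @param linker_d0 Mass added by the crosslink (default [BS3_D0]).
#' @return data.frame with peptide coordinates, `sites_a` / `sites_b`
#'   (comma-joined linkable positions) and `theoretical_mass`.
#' @export
enumerate_candidates <- function(peptides_a, peptides_b,
                                 linker_d0 = BS3_D0) {
  pa <- peptides_a[lengths(peptides_a$linkable_sites) > 0L, ]
  pb <- peptides_b[lengths(peptides_b$linkable_sites) > 0L, ]
  if (nrow(pa) == 0L || nrow(pb) == 0L) {
    return(empty_candidates())
  }
  pep_key <- function(p) paste(p$protein_id, p$start, p$end, sep = ":")
  ka <- pep_key(pa); kb <- pep_key(pb)
  grid <- expand.grid(i = seq_len(nrow(pa)), j = seq_len(nrow(pb)))
  # normalize unordered pairs and drop loop-links
  key_lo <- pmin(ka[grid$i], kb[grid$j])
  key_hi <- pmax(ka[grid$i], kb[grid$j])
  keep <- key_lo != key_hi & !duplicated(paste(key_lo, key_hi))
  grid <- grid[keep, ]
  out <- data.frame(
    protein_a = pa$protein_id[grid$i], start_a = pa$start[grid$i],
    end_a = pa$end[grid$i], seq_a = pa$sequence[grid$i],
    sites_a = vapply(pa$linkable_sites[grid$i], paste, "", collapse = ","),
    protein_b = pb$protein_id[grid$j], start_b = pb$start[grid$j],
    end_b = pb$end[grid$j], seq_b = pb$sequence[grid$j],
    sites_b = vapply(pb$linkable_sites[grid$j], paste, "", collapse = ","),
    theoretical_mass = pa$monoisotopic_mass[grid$i] +
      pb$monoisotopic_mass[grid$j] + linker_d0,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

empty_candidates <- function() {
  data.frame(protein_a = character(0), start_a = integer(0),
             end_a = integer(0), seq_a = character(0), sites_a = character(0),
             protein_b = character(0), start_b = integer(0),
             end_b = integer(0), seq_b = character(0), sites_b = character(0),
             theoretical_mass = numeric(0), stringsAsFactors = FALSE)
}

#' Match observed neutral masses to candidates with d0/d4 confirmation
#'
#' A candidate matches when some observed mass lies within `tol_ppm` of its
#' theoretical (d0) mass; it is doublet-confirmed when a second observed
#' mass sits at `doublet_delta` above the matched mass within
#' `doublet_tol`. The d0/d4 doublet is the identification signature of the
#' mixed light/heavy BS3 reagent.
#'
#' @param observed Numeric vector of observed neutral masses (Da), or a
#'   data.frame with a `mass` column.
#' @param candidates [enumerate_candidates()] output.
#' @param tol_ppm Relative match tolerance in ppm.
#' @param doublet_delta Heavy-light separation (default [BS3_D4_DELTA]).
#' @param doublet_tol Absolute tolerance on the partner mass in Da.
#' @return The matched candidates with `matched_observed`, `ppm_error` and
#'   `doublet_confirmed`, sorted by absolute ppm error.
#' @export
match_doublets <- function(observed, candidates, tol_ppm = 10,
                           doublet_delta = BS3_D4_DELTA,
                           doublet_tol = 0.02) {
  stopifnot(tol_ppm > 0, doublet_tol > 0)
  if (is.data.frame(observed)) observed <- observed$mass
  if (nrow(candidates) == 0L || length(observed) == 0L) {
    out <- candidates
    out$matched_observed <- numeric(nrow(out))[seq_len(nrow(out))]
    out$ppm_error <- numeric(nrow(out))[seq_len(nrow(out))]
    out$doublet_confirmed <- logical(nrow(out))[seq_len(nrow(out))]
    return(out[0L, ])
  }
  matched <- vector("list", nrow(candidates))
  for (i in seq_len(nrow(candidates))) {
    theo <- candidates$theoretical_mass[i]
    ppm <- (observed - theo) / theo * 1e6
    hits <- which(abs(ppm) <= tol_ppm)
    if (length(hits) == 0L) next
    best <- hits[which.min(abs(ppm[hits]))]
    m <- observed[best]
    partner <- any(abs(observed - (m + doublet_delta)) <= doublet_tol)
    row <- candidates[i, , drop = FALSE]
    row$matched_observed <- m
    row$ppm_error <- ppm[best]
    row$doublet_confirmed <- partner
    matched[[i]] <- row
  }
  matched <- matched[!vapply(matched, is.null, logical(1))]
  if (length(matched) == 0L) {
    out <- candidates[0L, ]
    out$matched_observed <- numeric(0)
    out$ppm_error <- numeric(0)
    out$doublet_confirmed <- logical(0)
    return(out)
  }
  out <- do.call(rbind, matched)
  out <- out[order(abs(out$ppm_error)), ]
  rownames(out) <- NULL
  out
}
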