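# Peptide-to-residue projection, region extraction, PDB B-factor export.

#' Project peptide-level Delta-HDX onto residues
#'
#' Residue r receives the mean Delta-HDX of all peptides whose
#' exchange-contributing span covers r (the span excludes each peptide's
#' first `skip_first` residues and all prolines, matching the
#' exchangeable-amide convention). Residues covered by no peptide are `NA`
#' with coverage 0 — "no data", never silently zero.
#'
#' @param x An [hdx_diff()] object, or a results data.frame carrying
#'   `protein_id`, `start`, `end`, `sequence`, `delta_hdx`, `significant`
#'   (e.g. a results TSV read back from disk).
#' @param protein_length Length of the protein in residues.
#' @param protein_id Protein to project (default: the first in the fit).
#' @param contributing `"all"` (default) averages every peptide;
#'   `"significant_only"` restricts to called peptides.
#' @param skip_first Exchangeable-amide convention; taken from the fit when
#'   `x` is an `hdx_diff` object.
#' @return A `residue_track`: data.frame with `residue`, `value` (signed
#'   mean Delta-HDX, %), `coverage` (contributing peptide count) and
#'   `mixed_sign` (TRUE where covering peptides disagree in sign).
#' @export
project_residues <- function(x, protein_length, protein_id = NULL,
                             contributing = c("all", "significant_only"),
                             skip_first = 1L) {
  contributing <- match.arg(contributing)
  if (inherits(x, "hdx_diff")) {
    r <- x$results
    skip_first <- x$skip_first
  } else {
    r <- x
  }
  skip_first <- check_skip_first(skip_first)
  protein_id <- protein_id %||% r$protein_id[1L]
  r <- r[r$protein_id == protein_id, ]
  if (contributing == "significant_only") r <- r[r$significant, ]
  protein_length <- as.integer(protein_length)
  if (nrow(r) > 0L && max(r$end) > protein_length) {
    stop("peptides extend beyond protein_length", call. = FALSE)
  }

  sums <- numeric(protein_length)
  pos_n <- integer(protein_length)
  neg_n <- integer(protein_length)
  cov <- integer(protein_length)
  for (i in seq_len(nrow(r))) {
    pos <- exchange_positions(r$start[i], r$end[i], r$sequence[i],
                              skip_first)
    if (length(pos) == 0L) next
    v <- r$delta_hdx[i]
    sums[pos] <- sums[pos] + v
    cov[pos] <- cov[pos] + 1L
    if (v > 0) pos_n[pos] <- pos_n[pos] + 1L
    if (v < 0) neg_n[pos] <- neg_n[pos] + 1L
  }
  value <- ifelse(cov > 0L, sums / pmax(cov, 1L), NA_real_)
  track <- data.frame(residue = seq_len(protein_length), value = value,
                      coverage = cov,
                      mixed_sign = pos_n > 0L & neg_n > 0L)
  structure(track, protein_id = protein_id,
            class = c("residue_track", "data.frame"))
}

#' @export
print.residue_track <- function(x, ...) {
  cat("Residue-level Delta-HDX track for", sQuote(attr(x, "protein_id")),
      "\n")
  cat("  residues:", nrow(x), " covered:", sum(x$coverage > 0L), "\n")
  if (any(x$coverage > 0L)) {
    cat(sprintf("  value range: [%.2f, %.2f] %%\n",
                min(x$value, na.rm = TRUE), max(x$value, na.rm = TRUE)))
  }
  invisible(x)
}

#' @export
plot.residue_track <- function(x, threshold = 10, ...) {
  graphics::plot(x$residue, x$value, type = "l",
                 xlab = "residue", ylab = expression(Delta * "HDX (%)"),
                 main = attr(x, "protein_id"), ...)
  graphics::abline(h = c(-threshold, threshold), lty = 3)
  graphics::abline(h = 0, col = "grey")
  invisible(x)
}

#' Extract contiguous protected / deprotected regions from a track
#'
#' Maximal runs of consecutive covered residues whose absolute value
#' exceeds `threshold` with constant sign, of length at least `min_len`
#' (default 2, suppressing single-residue speckle). Because a residue
#' without any amide signal (a proline, or a coverage gap) can never report
#' exchange, up to `bridge_gaps` consecutive uncovered residues flanked on
#' both sides by same-sign above-threshold residues are absorbed into the
#' surrounding region rather than splitting it; the region mean is taken
#' over its covered residues only. `bridge_gaps = 0` disables bridging.
#'
#' @param track A [project_residues()] track.
#' @param threshold Absolute %HDX cutoff (> 0).
#' @param min_len Minimum region length in residues.
#' @param bridge_gaps Maximum width of uncovered gaps absorbed into a
#'   region (default 1: isolated amide-less residues).
#' @return data.frame with `start`, `end`, `length`, `mean_delta_hdx`,
#'   `direction` (`decrease` for negative values, `increase` for positive).
#' @export
extract_regions <- function(track, threshold = 10, min_len = 2L,
                            bridge_gaps = 1L) {
  stopifnot(inherits(track, "residue_track"), threshold > 0, min_len >= 1,
            bridge_gaps >= 0)
  covered <- track$coverage > 0L & !is.na(track$value)
  sgn <- ifelse(covered & abs(track$value) > threshold,
                sign(track$value), 0)
  if (bridge_gaps > 0L) {
    gap_runs <- rle(covered)
    gends <- cumsum(gap_runs$lengths)
    gstarts <- gends - gap_runs$lengths + 1L
    for (g in which(!gap_runs$values & gap_runs$lengths <= bridge_gaps)) {
      lo <- gstarts[g] - 1L; hi <- gends[g] + 1L
      if (lo >= 1L && hi <= length(sgn) && sgn[lo] != 0 &&
          sgn[lo] == sgn[hi]) {
        sgn[gstarts[g]:gends[g]] <- sgn[lo]
      }
    }
  }
  runs <- rle(sgn)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  keep <- runs$values != 0 & runs$lengths >= min_len
  out <- data.frame(
    start = starts[keep], end = ends[keep],
    length = runs$lengths[keep],
    mean_delta_hdx = vapply(which(keep), function(i) {
      mean(track$value[starts[i]:ends[i]], na.rm = TRUE)
    }, numeric(1)),
    direction = ifelse(runs$values[keep] < 0, "decrease", "increase"),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Half-plateau threshold for interface delineation
#'
#' Peptide-mean projection spreads a region's signal linearly over about
#' one peptide length past its true boundary, and the value at the true
#' boundary is close to half the region's plateau. Cutting the track at
#' half its plateau therefore places region edges near the true interface
#' boundary regardless of the plateau's absolute magnitude. The plateau is
#' estimated robustly as an upper quantile of the absolute track values.
#'
#' @param track A [project_residues()] track.
#' @param q Quantile of |value| used as the plateau estimate.
#' @param floor Lower bound on the returned threshold (default 10, the
#'   peptide-level calling floor), so a flat null track yields no regions
#'   below the calling threshold.
#' @return Threshold in %HDX for [extract_regions()].
#' @export
half_plateau_threshold <- function(track, q = 0.97, floor = 10) {
  stopifnot(inherits(track, "residue_track"))
  v <- abs(track$value)
  if (all(is.na(v))) return(floor)
  max(floor, 0.5 * stats::quantile(v, q, na.rm = TRUE, names = FALSE))
}

#' Write a residue track into the B-factor column of a PDB file
#'
#' Sets the temperature-factor field (columns 61-66) of every atom in the
#' selected chain to its residue's track value (clipped to
#' [-99.99, 999.99], two decimals) so molecular viewers can color the
#' structure by Delta-HDX. Atoms of residues without coverage get B = 0.00
#' and occupancy 0.00 as a "no data" sentinel; every other character of
#' every line is preserved byte for byte.
#'
#' @param pdb Path to a PDB file, or a character vector of its lines.
#' @param track A [project_residues()] track.
#' @param chain Chain identifier (column 22) to annotate.
#' @param offset Added to the structure's residue numbers to obtain track
#'   positions (construct vs full-length numbering, e.g. a fragment
#'   starting at residue 77 with author numbering from 1 needs offset 76).
#' @param path Optional output path; when given the lines are also written
#'   there.
#' @return Invisibly, the modified PDB lines.
#' @export
write_bfactor_pdb <- function(pdb, track, chain, offset = 0L, path = NULL) {
  stopifnot(inherits(track, "residue_track"))
  lines <- if (length(pdb) == 1L && file.exists(pdb)) readLines(pdb) else pdb
  is_atom <- grepl("^(ATOM  |HETATM)", lines)
  chains <- substr(lines, 22L, 22L)
  if (!any(is_atom & chains == chain)) {
    stop("chain ", sQuote(chain), " not found in structure", call. = FALSE)
  }
  sel <- which(is_atom & chains == chain)
  resno <- suppressWarnings(as.integer(substr(lines[sel], 23L, 26L)))
  pos <- resno + as.integer(offset)

  covered <- pos >= 1L & pos <= nrow(track) &
    !is.na(pos) & track$coverage[pmax(pmin(pos, nrow(track)), 1L)] > 0L
  val <- rep(0, length(sel))
  val[covered] <- track$value[pos[covered]]
  val <- pmin(pmax(val, -99.99), 999.99)

  bfield <- sprintf("%6.2f", val)
  for (i in seq_along(sel)) {
    ln <- lines[sel[i]]
    if (nchar(ln) < 66L) ln <- formatC(ln, width = -66L)
    substr(ln, 61L, 66L) <- bfield[i]
    if (!covered[i]) substr(ln, 55L, 60L) <- "  0.00"
    lines[sel[i]] <- ln
  }
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}
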