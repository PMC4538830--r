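# Peptide bookkeeping and the %HDX normalization.

#' Count theoretically exchangeable backbone amide hydrogens
#'
#' The maximum number of backbone amide hydrogens a peptide can exchange:
#' peptide length minus the first `skip_first` residues (whose amide
#' deuterium is lost to back-exchange essentially instantaneously) minus
#' every proline beyond them (prolines carry no amide hydrogen).
#'
#' @param sequence Peptide amino-acid sequence (one-letter codes, standard
#'   20 residues).
#' @param skip_first Number of N-terminal residues excluded from exchange;
#'   1 (default) excludes the N-terminal residue, 2 additionally excludes
#'   position 2 as some workflows do.
#' @return Integer count, never negative.
#' @examples
#' count_exchangeable("GLSDGEWQL")   # 8
#' count_exchangeable("APPLE")       # 2: both prolines excluded
#' @export
count_exchangeable <- function(sequence, skip_first = 1L) {
  chars <- aa_split(sequence)
  skip_first <- check_skip_first(skip_first)
  n <- length(chars) - skip_first
  if (n <= 0L) return(0L)
  pro <- sum(chars[(skip_first + 1L):length(chars)] == "P")
  max(0L, n - as.integer(pro))
}

check_skip_first <- function(skip_first) {
  skip_first <- as.integer(skip_first)
  if (length(skip_first) != 1L || is.na(skip_first) ||
      !skip_first %in% c(1L, 2L)) {
    stop("skip_first must be 1 or 2", call. = FALSE)
  }
  skip_first
}

#' Convert a centroid mass shift in Da to a deuteron count
#'
#' Divides by the deuterium-protium mass difference ([DH_MASS], 1.006277 Da),
#' making the Da-to-#D unit bridge explicit.
#'
#' @param mass_shift Numeric vector of mass shifts in Da.
#' @return Deuteron counts (#D), same length.
#' @export
deuterons_from_da <- function(mass_shift) {
  mass_shift / DH_MASS
}

#' Percent deuterium uptake of a peptide
#'
#' %HDX is the number of incorporated deuterium atoms divided by the maximum
#' number of hydrogen atoms theoretically available for exchange on the
#' peptide, times 100.
#'
#' @param n_deuterons Deuteron count (#D), possibly fractional.
#' @param n_max Maximum exchangeable amides (see [count_exchangeable()]);
#'   must be >= 1.
#' @return Percent uptake. Values above 100 x the labeling fraction can
#'   occur under measurement noise and are returned unclipped.
#' @export
pct_hdx <- function(n_deuterons, n_max) {
  if (any(n_max < 1)) {
    stop("pct_hdx undefined for n_max < 1; exclude such peptides",
         call. = FALSE)
  }
  100 * n_deuterons / n_max
}

# Absolute residue positions of a peptide that contribute exchange signal:
# everything after the first skip_first residues, prolines excluded.
exchange_positions <- function(start, end, sequence, skip_first = 1L) {
  start <- as.integer(start); end <- as.integer(end)
  chars <- aa_split(sequence)
  if (length(chars) != end - start + 1L) {
    stop("sequence length does not match start/end coordinates",
         call. = FALSE)
  }
  skip_first <- check_skip_first(skip_first)
  if (length(chars) <= skip_first) return(integer(0))
  idx <- (skip_first + 1L):length(chars)
  idx <- idx[chars[idx] != "P"]
  start - 1L + idx
}
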