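# Physical constants used throughout. All masses monoisotopic unless noted.

#' Mass difference between deuterium and protium
#'
#' Monoisotopic mass difference 2H - 1H in Da (2.014102 - 1.007825).
#' Converts centroid mass shifts to deuteron counts.
#' @export
DH_MASS <- 1.006277

# water, added once per peptide chain
WATER_MONO <- 18.010565
WATER_AVG <- 18.0153

#' BS3 crosslinker mass constants
#'
#' `BS3_D0` is the mass added by a BS3 (bis(sulfosuccinimidyl) suberate)
#' crosslink between two amines (C8H10O2, both NHS esters reacted).
#' `BS3_D4_DELTA` is the shift of the 4-deuterium heavy form relative to the
#' light form (4 x [DH_MASS]); a 1:1 d0/d4 reagent mix therefore produces
#' diagnostic mass doublets separated by this delta. `BS3_DEADEND` is a
#' hydrolyzed mono-link (one ester reacted, one hydrolyzed).
#' @name bs3-constants
#' @export
BS3_D0 <- 138.06808

#' @rdname bs3-constants
#' @export
BS3_D4_DELTA <- 4.025108

#' @rdname bs3-constants
#' @export
BS3_DEADEND <- 156.07864

# residue (monomer) masses of the 20 standard amino acids
AA_MONO <- c(
  A = 71.03711, R = 156.10111, N = 114.04293, D = 115.02694, C = 103.00919,
  E = 129.04259, Q = 128.05858, G = 57.02146, H = 137.05891, I = 113.08406,
  L = 113.08406, K = 128.09496, M = 131.04049, F = 147.06841, P = 97.05276,
  S = 87.03203, T = 101.04768, W = 186.07931, Y = 163.06333, V = 99.06841
)

AA_AVG <- c(
  A = 71.0788, R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  E = 129.1155, Q = 128.1307, G = 57.0519, H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
  S = 87.0782, T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326
)

# Gill & von Hippel molar extinction coefficients at 280 nm, M^-1 cm^-1
EPS_TRP <- 5500
EPS_TYR <- 1490
EPS_CYSTINE <- 125

# split a sequence string into residue letters, validating the alphabet
aa_split <- function(sequence, what = "sequence") {
  if (!is.character(sequence) || length(sequence) != 1L || is.na(sequence) ||
      nchar(sequence) == 0L) {
    stop(what, " must be a non-empty character string", call. = FALSE)
  }
  chars <- strsplit(toupper(sequence), "", fixed = TRUE)[[1L]]
  bad <- setdiff(unique(chars), names(AA_MONO))
  if (length(bad) > 0L) {
    stop("non-standard residue character(s) in ", what, ": ",
         paste(sQuote(bad), collapse = ", "), call. = FALSE)
  }
  chars
}

# run a block with a deterministic, locally-scoped RNG state
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  code
}
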