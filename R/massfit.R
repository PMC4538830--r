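# Sequence masses, extinction coefficients, SEC-MALS stoichiometry fitting.

#' Average molecular mass of a protein sequence in kDa
#'
#' SEC-MALS measures average molar mass, so average (not monoisotopic)
#' residue masses are used.
#'
#' @param sequence Amino-acid sequence; include any tag remnants, they are
#'   part of the measured species.
#' @return Mass in kDa.
#' @examples
#' sequence_mass("GG")  # 0.1321191 kDa
#' @export
sequence_mass <- function(sequence) {
  peptide_mass(sequence, kind = "average") / 1000
}

#' Molar extinction coefficient at 280 nm
#'
#' Gill-von Hippel composition rule: 5500 per Trp, 1490 per Tyr, 125 per
#' cystine. By default cysteines are assumed reduced (no cystine term);
#' `oxidized = TRUE` counts `floor(nCys / 2)` cystines.
#'
#' @param sequence Amino-acid sequence.
#' @param oxidized Count disulfide-bonded cystines?
#' @return Extinction coefficient in M^-1 cm^-1.
#' @export
extinction_280 <- function(sequence, oxidized = FALSE) {
  chars <- aa_split(sequence)
  eps <- EPS_TRP * sum(chars == "W") + EPS_TYR * sum(chars == "Y")
  if (oxidized) eps <- eps + EPS_CYSTINE * (sum(chars == "C") %/% 2L)
  eps
}

#' Infer a homo-oligomer copy number from a SEC-MALS mass
#'
#' @param measured Measured molar mass in kDa (> 0).
#' @param monomer Monomer mass in kDa (> 0), e.g. from [sequence_mass()].
#' @return List with `n` (nearest positive integer to measured/monomer),
#'   `predicted_mass` and `residual` (kDa). Warns when the residual exceeds
#'   10% of the measured mass.
#' @examples
#' infer_oligomer(165, 55)  # homotrimer, residual 0
#' @export
infer_oligomer <- function(measured, monomer) {
  stopifnot(monomer > 0)
  if (measured <= 0) stop("measured mass must be > 0", call. = FALSE)
  n <- max(1L, as.integer(round(measured / monomer)))
  predicted <- n * monomer
  residual <- abs(predicted - measured)
  if (residual > 0.1 * measured) {
    warning(sprintf("residual %.1f kDa exceeds 10%% of the measured mass",
                    residual), call. = FALSE)
  }
  list(n = n, predicted_mass = predicted, residual = residual)
}

#' Infer complex stoichiometry from a SEC-MALS molar mass
#'
#' Exhaustive search over copy-number vectors (0..`max_copies` per
#' component, the all-zero vector excluded), ranked by the absolute mass
#' residual, ties broken by fewer total copies. When both `uv_weight` and
#' `eps_observed` are given, ranking uses
#' `residual + uv_weight * |eps_predicted - eps_observed| / eps_observed`,
#' folding in a UV-absorbance constraint the way SEC-MALS practitioners
#' cross-check stoichiometries.
#'
#' @param measured Measured molar mass in kDa.
#' @param components data.frame with columns `name` and `mass_kda`
#'   (optionally `epsilon_280`), or a named numeric vector of masses.
#' @param max_copies Per-component copy bound (default 4; <= 6).
#' @param uv_weight Optional weight (kDa per unit relative epsilon error)
#'   for the UV term.
#' @param eps_observed Observed extinction coefficient backing the UV term.
#' @return A `stoich_fit` data.frame: one row per candidate vector with the
#'   copy numbers, `predicted_mass`, `residual`, `epsilon_predicted` and
#'   `score`, best first.
#' @examples
#' infer_stoichiometry(100, c(A = 50, B = 30, C = 20))[1, ]
#' @export
infer_stoichiometry <- function(measured, components, max_copies = 4L,
                                uv_weight = NULL, eps_observed = NULL) {
  if (length(components) == 0L) stop("empty component list", call. = FALSE)
  if (is.numeric(components)) {
    components <- data.frame(
      name = names(components) %||% paste0("c", seq_along(components)),
      mass_kda = as.numeric(components), stringsAsFactors = FALSE)
  }
  k <- nrow(components)
  if (is.null(k) || k < 1L) stop("empty component list", call. = FALSE)
  if (k > 5L) stop("at most 5 components supported", call. = FALSE)
  max_copies <- as.integer(max_copies)
  if (max_copies < 1L || max_copies > 6L) {
    stop("max_copies must be in 1..6", call. = FALSE)
  }
  stopifnot(measured > 0, all(components$mass_kda > 0))

  grid <- as.matrix(expand.grid(rep(list(0:max_copies), k)))
  colnames(grid) <- components$name
  grid <- grid[rowSums(grid) > 0L, , drop = FALSE]
  predicted <- as.numeric(grid %*% components$mass_kda)
  residual <- abs(predicted - measured)

  eps_pred <- if (!is.null(components$epsilon_280)) {
    as.numeric(grid %*% components$epsilon_280)
  } else {
    rep(NA_real_, nrow(grid))
  }
  score <- residual
  if (!is.null(uv_weight) && !is.null(eps_observed)) {
    if (anyNA(eps_pred)) {
      stop("uv_weight given but components lack epsilon_280", call. = FALSE)
    }
    score <- score + uv_weight * abs(eps_pred - eps_observed) / eps_observed
  }
  ord <- order(score, rowSums(grid),
               apply(grid, 1L, paste, collapse = ","))
  out <- data.frame(grid[ord, , drop = FALSE],
                    predicted_mass = predicted[ord],
                    residual = residual[ord],
                    epsilon_predicted = eps_pred[ord],
                    score = score[ord], check.names = FALSE)
  rownames(out) <- NULL
  class(out) <- c("stoich_fit", "data.frame")
  attr(out, "measured") <- measured
  out
}

#' @export
print.stoich_fit <- function(x, n = 5L, ...) {
  cat("Stoichiometry fit to measured mass",
      sprintf("%.1f kDa\n", attr(x, "measured")))
  print.data.frame(utils::head(x, n), digits = 4)
  if (nrow(x) > n) cat("... and", nrow(x) - n, "more candidate vectors\n")
  invisible(x)
}
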