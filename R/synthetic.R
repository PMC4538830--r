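# Synthetic two-state HDX experiments with known ground truth.
#
# Exchange follows the EX2 limit: residue i exchanges at k_int_i / P_i, so
# its deuterium fraction after time t in f_D2O deuterated solvent is
#   d_i(t) = f_D2O * (1 - exp(-k_int_i * t / P_i)).
# A peptide's noiseless centroid shift is the sum of d_i over its
# exchangeable residues times the D-H mass difference, times a back-exchange
# retention factor.

#' Construct a synthetic two-state protein with planted interface regions
#'
#' Builds a protein whose bound-state protection factors differ from the
#' free state only inside the given regions, so the set of truly perturbed
#' residues (the "interface truth") is known exactly.
#'
#' @param length Protein length in residues.
#' @param interface_regions List of numeric triples `c(start, end, factor)`.
#'   In each region `pf_bound = pf_free * factor`: `factor > 1` plants
#'   protection (slower exchange when bound, uptake decrease), `factor < 1`
#'   plants deprotection (uptake increase). Overlapping regions with
#'   conflicting factors are an error.
#' @param k_int Intrinsic amide exchange rates in s^-1: a single constant,
#'   a length-2 range for a per-residue log-uniform draw (default
#'   `c(0.01, 100)`, spanning the 3-3000 s labeling window), or a full
#'   per-residue vector.
#' @param pf_free Free-state protection factors (scalar or per-residue),
#'   all >= 1. Default 1 (fully unprotected free state).
#' @param sequence Optional amino-acid sequence; random if omitted.
#' @param protein_id Identifier carried into uptake tables.
#' @param seed Integer seed; the result is deterministic given it.
#' @return An object of class `two_state_protein` with fields `protein_id`,
#'   `sequence`, `k_int`, `pf_free`, `pf_bound` and `interface_truth` (the
#'   residue positions where the two states differ).
#' @examples
#' p <- make_two_state_protein(120, list(c(40, 60, 100)), seed = 1)
#' range(p$interface_truth)  # 40 60
#' @export
make_two_state_protein <- function(length, interface_regions = list(),
                                   k_int = c(0.01, 100), pf_free = 1,
                                   sequence = NULL, protein_id = "synthetic",
                                   seed = NULL) {
  length <- as.integer(length)
  if (length < 1L) stop("length must be >= 1", call. = FALSE)
  if (is.numeric(interface_regions)) interface_regions <- list(interface_regions)

  pf_free <- rep_len(as.numeric(pf_free), length)
  if (any(pf_free < 1)) stop("protection factors must be >= 1", call. = FALSE)

  with_seed(seed, {
    if (is.null(sequence)) {
      sequence <- paste(sample(names(AA_MONO), length, replace = TRUE),
                        collapse = "")
    }
    chars <- aa_split(sequence)
    if (base::length(chars) != length) {
      stop("sequence length does not match length", call. = FALSE)
    }
    k <- as.numeric(k_int)
    if (base::length(k) == 1L) {
      k <- rep(k, length)
    } else if (base::length(k) == 2L) {
      k <- exp(stats::runif(length, log(k[1L]), log(k[2L])))
    } else if (base::length(k) != length) {
      stop("k_int must be a constant, a range, or a per-residue vector",
           call. = FALSE)
    }
    if (any(k <= 0)) stop("all intrinsic rates must be positive", call. = FALSE)

    factor <- rep(NA_real_, length)
    for (reg in interface_regions) {
      if (base::length(reg) != 3L) {
        stop("each region must be c(start, end, factor)", call. = FALSE)
      }
      s <- as.integer(reg[1L]); e <- as.integer(reg[2L]); f <- reg[3L]
      if (s < 1L || e > length || s > e) {
        stop("region [", s, ",", e, "] out of bounds for length ", length,
             call. = FALSE)
      }
      if (f <= 0) stop("region factor must be > 0", call. = FALSE)
      idx <- s:e
      clash <- !is.na(factor[idx]) & factor[idx] != f
      if (any(clash)) {
        stop("overlapping regions with conflicting factors at residue ",
             idx[which(clash)[1L]], call. = FALSE)
      }
      factor[idx] <- f
    }
    pf_bound <- ifelse(is.na(factor), pf_free, pf_free * factor)
    if (any(pf_bound < 1)) {
      stop("pf_bound < 1: deprotection (factor < 1) requires pf_free high ",
           "enough that pf_free * factor >= 1", call. = FALSE)
    }

    structure(
      list(protein_id = protein_id, sequence = sequence, k_int = k,
           pf_free = pf_free, pf_bound = pf_bound,
           interface_truth = which(pf_bound != pf_free)),
      class = "two_state_protein"
    )
  })
}

#' @export
print.two_state_protein <- function(x, ...) {
  cat("Two-state synthetic protein", sQuote(x$protein_id), "\n")
  cat("  length:", nchar(x$sequence), "residues\n")
  cat("  perturbed residues:", length(x$interface_truth), "\n")
  invisible(x)
}

#' Labeling conditions for a simulated HDX experiment
#'
#' @param d2o_fraction Deuterium fraction of the labeling buffer (default
#'   0.8, i.e. 80% D2O).
#' @param timepoints Labeling times in seconds, strictly increasing
#'   (default 3, 30, 300, 3000 s).
#' @param back_exchange Multiplicative deuterium retention factor in (0, 1]
#'   applied to the noiseless shift; 1 means no back-exchange loss.
#' @param noise_sd Standard deviation of zero-mean Gaussian replicate noise
#'   on the centroid mass shift, in Da.
#' @param n_replicates Technical replicates per peptide and timepoint
#'   (>= 2, default 3).
#' @return A `labeling_conditions` list.
#' @export
labeling_conditions <- function(d2o_fraction = 0.8,
                                timepoints = c(3, 30, 300, 3000),
                                back_exchange = 1, noise_sd = 0.1,
                                n_replicates = 3L) {
  stopifnot(d2o_fraction > 0, d2o_fraction <= 1,
            all(timepoints > 0), !is.unsorted(timepoints, strictly = TRUE),
            back_exchange > 0, back_exchange <= 1,
            noise_sd >= 0, n_replicates >= 2)
  structure(list(d2o_fraction = d2o_fraction, timepoints = timepoints,
                 back_exchange = back_exchange, noise_sd = noise_sd,
                 n_replicates = as.integer(n_replicates)),
            class = "labeling_conditions")
}

#' Generate an overlapping peptide map
#'
#' Emulates overlapping pepsin coverage: peptides of roughly `mean_len`
#' residues start every `step` residues, with lengths jittered by up to
#' `len_jitter`. Whenever `step <= mean_len - 2` every residue is covered by
#' at least one peptide (jittered lengths are floored at `step + 1` to keep
#' the tiling contiguous).
#'
#' @param length Protein length.
#' @param mean_len Target peptide length (>= 3).
#' @param step Offset between consecutive peptide starts (>= 1).
#' @param len_jitter Maximum +/- jitter on peptide length.
#' @param seed Integer seed for the jitter draw.
#' @return data.frame with columns `start`, `end` (1-based inclusive).
#' @examples
#' make_peptide_map(30, mean_len = 10, step = 5, len_jitter = 0)
#' @export
make_peptide_map <- function(length, mean_len = 10L, step = 4L,
                             len_jitter = 2L, seed = NULL) {
  length <- as.integer(length); mean_len <- as.integer(mean_len)
  step <- as.integer(step); len_jitter <- as.integer(len_jitter)
  if (mean_len < 3L) stop("mean_len must be >= 3", call. = FALSE)
  if (step < 1L) stop("step must be >= 1", call. = FALSE)
  if (len_jitter < 0L) stop("len_jitter must be >= 0", call. = FALSE)
  if (length < mean_len) {
    return(data.frame(start = 1L, end = length))
  }
  with_seed(seed, {
    starts <- seq.int(1L, length - mean_len + 1L, by = step)
    if (starts[base::length(starts)] != length - mean_len + 1L) {
      starts <- c(starts, length - mean_len + 1L)
    }
    jit <- if (len_jitter > 0L) {
      sample(seq.int(-len_jitter, len_jitter), base::length(starts),
             replace = TRUE)
    } else {
      rep(0L, base::length(starts))
    }
    lens <- pmax(mean_len + jit, step + 1L)
    ends <- pmin(starts + lens - 1L, length)
    ends[base::length(ends)] <- length
    data.frame(start = starts, end = ends)
  })
}

#' Simulate peptide-level deuterium uptake for one state
#'
#' Applies the EX2 kinetic model (see file header) to every peptide,
#' timepoint and replicate, adding independent Gaussian centroid noise.
#'
#' @param pair A [make_two_state_protein()] object.
#' @param state `"free"` or `"bound"`; selects which protection-factor
#'   vector drives the kinetics and labels the output rows.
#' @param peptides data.frame with `start`, `end` columns (e.g. from
#'   [make_peptide_map()]).
#' @param cond [labeling_conditions()].
#' @param skip_first N-terminal residues per peptide excluded from exchange
#'   (must match the convention used downstream).
#' @param seed Integer seed; output is reproducible given it.
#' @return data.frame of uptake records: `protein_id`, `state`, `start`,
#'   `end`, `sequence`, `timepoint_s`, `replicate`, `uptake_Da` — one row
#'   per peptide x timepoint x replicate.
#' @export
simulate_uptake <- function(pair, state = c("free", "bound"), peptides,
                            cond = labeling_conditions(), skip_first = 1L,
                            seed = NULL) {
  stopifnot(inherits(pair, "two_state_protein"),
            inherits(cond, "labeling_conditions"))
  state <- match.arg(state)
  pf <- if (state == "free") pair$pf_free else pair$pf_bound
  len <- nchar(pair$sequence)
  if (any(peptides$start < 1L) || any(peptides$end > len) ||
      any(peptides$start > peptides$end)) {
    stop("peptide outside the protein sequence", call. = FALSE)
  }
  k_obs <- pair$k_int / pf

  tps <- cond$timepoints
  n_pep <- nrow(peptides)
  seqs <- substring(pair$sequence, peptides$start, peptides$end)

  # noiseless shift per peptide x timepoint
  shift <- matrix(0, n_pep, length(tps))
  for (p in seq_len(n_pep)) {
    pos <- exchange_positions(peptides$start[p], peptides$end[p], seqs[p],
                              skip_first)
    if (length(pos) == 0L) next
    # residues x timepoints deuterium fractions
    d <- cond$d2o_fraction *
      (1 - exp(-outer(k_obs[pos], tps)))
    shift[p, ] <- cond$back_exchange * DH_MASS * colSums(d)
  }

  grid <- expand.grid(replicate = seq_len(cond$n_replicates),
                      timepoint = seq_along(tps),
                      peptide = seq_len(n_pep))
  out <- data.frame(
    protein_id = pair$protein_id,
    state = state,
    start = peptides$start[grid$peptide],
    end = peptides$end[grid$peptide],
    sequence = seqs[grid$peptide],
    timepoint_s = tps[grid$timepoint],
    replicate = grid$replicate,
    uptake_Da = shift[cbind(grid$peptide, grid$timepoint)],
    stringsAsFactors = FALSE
  )
  with_seed(seed, {
    if (cond$noise_sd > 0) {
      out$uptake_Da <- out$uptake_Da +
        stats::rnorm(nrow(out), 0, cond$noise_sd)
    }
    out
  })
}

#' Ground-truth sidecar table for a synthetic protein
#'
#' @param pair A [make_two_state_protein()] object.
#' @return data.frame with `residue`, `pf_free`, `pf_bound`, `in_interface`.
#' @export
ground_truth_table <- function(pair) {
  stopifnot(inherits(pair, "two_state_protein"))
  n <- nchar(pair$sequence)
  data.frame(residue = seq_len(n), pf_free = pair$pf_free,
             pf_bound = pair$pf_bound,
             in_interface = seq_len(n) %in% pair$interface_truth)
}

#' Simulate observed neutral masses with d0/d4 doublets and decoys
#'
#' For every true crosslink mass m emits a light observation `m * (1 + e)`
#' (e a Gaussian relative error of sd `ppm_sd` ppm) and its heavy partner at
#' exactly +[BS3_D4_DELTA] Da; decoys are uniform masses with no partner.
#'
#' @param true_masses Numeric vector of theoretical d0 crosslink masses, or
#'   a candidate data.frame with a `theoretical_mass` column.
#' @param n_decoys Number of partner-less decoy masses.
#' @param ppm_sd Relative mass error standard deviation in ppm.
#' @param decoy_range Length-2 range for the uniform decoy masses; defaults
#'   to the span of the true masses (or 400-2000 Da when there are none).
#' @param seed Integer seed.
#' @return data.frame with `mass` (Da) and `is_decoy`.
#' @export
simulate_xlink_observations <- function(true_masses, n_decoys = 0L,
                                        ppm_sd = 0, decoy_range = NULL,
                                        seed = NULL) {
  if (is.data.frame(true_masses)) true_masses <- true_masses$theoretical_mass
  stopifnot(ppm_sd >= 0, n_decoys >= 0)
  with_seed(seed, {
    masses <- numeric(0); decoy <- logical(0)
    if (length(true_masses) > 0L) {
      eps <- stats::rnorm(length(true_masses), 0, ppm_sd * 1e-6)
      light <- true_masses * (1 + eps)
      masses <- c(light, light + BS3_D4_DELTA)
      decoy <- rep(FALSE, 2L * length(true_masses))
    }
    if (n_decoys > 0L) {
      rng <- decoy_range %||%
        (if (length(true_masses) > 0L)
           range(true_masses) + c(-50, 50) else c(400, 2000))
      masses <- c(masses, stats::runif(n_decoys, rng[1L], rng[2L]))
      decoy <- c(decoy, rep(TRUE, n_decoys))
    }
    data.frame(mass = masses, is_decoy = decoy)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
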