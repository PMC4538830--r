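# Shared fixtures and independent oracles, all built in code.

# uptake table with given replicate Da values per timepoint, one peptide
uptake_table <- function(reps_by_tp, start = 1L, sequence = "AAAAAAAAAAA",
                         protein_id = "p1", state = "free") {
  end <- start + nchar(sequence) - 1L
  do.call(rbind, lapply(names(reps_by_tp), function(tp) {
    vals <- reps_by_tp[[tp]]
    data.frame(protein_id = protein_id, state = state, start = start,
               end = end, sequence = sequence,
               timepoint_s = as.numeric(tp),
               replicate = seq_along(vals), uptake_Da = vals,
               stringsAsFactors = FALSE)
  }))
}

# n-residue proline-free peptide table at a single timepoint
simple_pair <- function(da_free, da_bound, n_len = 11L, tp = "300") {
  seqc <- strrep("A", n_len)
  list(free = uptake_table(stats::setNames(list(da_free), tp),
                           sequence = seqc),
       bound = uptake_table(stats::setNames(list(da_bound), tp),
                            sequence = seqc, state = "bound"))
}

# results data.frame usable by project_residues()
fake_results <- function(start, end, sequence, delta_hdx,
                         significant = TRUE, protein_id = "p1") {
  n <- length(start)
  data.frame(protein_id = rep_len(protein_id, n), start = start, end = end,
             sequence = sequence, delta_hdx = delta_hdx,
             significant = rep_len(significant, n),
             stringsAsFactors = FALSE)
}

# minimal two-chain PDB: chains A (residues 1..n_res) and B (1 residue)
make_test_pdb <- function(n_res = 6L, atoms_per_res = 2L) {
  lines <- character(0)
  serial <- 0L
  for (r in seq_len(n_res)) {
    for (a in seq_len(atoms_per_res)) {
      serial <- serial + 1L
      name <- if (a == 1L) " N  " else " CA "
      lines <- c(lines, sprintf(
        "ATOM  %5d %s ALA A%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           %s",
        serial, name, r, r * 1.5, a * 1.1, 0, 1.00, 20.00,
        substr(trimws(name), 1, 1)))
    }
  }
  serial <- serial + 1L
  lines <- c(lines, sprintf(
    "ATOM  %5d  N   GLY B%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           N",
    serial, 1L, 0, 0, 0, 1.00, 30.00))
  c(lines, "TER", "END")
}

# brute-force oracle for doublet matching: loops over every
# (candidate, observed) pair, independent of the package implementation
brute_force_match <- function(observed, candidates, tol_ppm,
                              doublet_delta = 4.025108,
                              doublet_tol = 0.02) {
  hits <- list()
  for (i in seq_len(nrow(candidates))) {
    theo <- candidates$theoretical_mass[i]
    best <- NULL
    for (m in observed) {
      ppm <- (m - theo) / theo * 1e6
      if (abs(ppm) <= tol_ppm &&
          (is.null(best) || abs(ppm) < abs(best$ppm))) {
        best <- list(mass = m, ppm = ppm)
      }
    }
    if (is.null(best)) next
    partner <- FALSE
    for (m2 in observed) {
      if (abs(m2 - (best$mass + doublet_delta)) <= doublet_tol) partner <- TRUE
    }
    hits[[length(hits) + 1L]] <- data.frame(
      idx = i, matched_observed = best$mass, ppm_error = best$ppm,
      doublet_confirmed = partner)
  }
  if (length(hits) == 0L) return(NULL)
  do.call(rbind, hits)
}

# independent re-implementation of the stoichiometry search (nested loops)
stoich_brute <- function(measured, masses, max_copies) {
  best <- NULL
  grid <- rep(list(0:max_copies), length(masses))
  combos <- do.call(expand.grid, grid)
  for (i in seq_len(nrow(combos))) {
    v <- as.numeric(combos[i, ])
    if (sum(v) == 0) next
    res <- abs(sum(v * masses) - measured)
    if (is.null(best) || res < best$res - 1e-12 ||
        (abs(res - best$res) <= 1e-12 && sum(v) < sum(best$v))) {
      best <- list(v = v, res = res)
    }
  }
  best
}

jaccard <- function(a, b) length(intersect(a, b)) / length(union(a, b))

region_residues <- function(regions) {
  if (nrow(regions) == 0L) return(integer(0))
  unlist(mapply(seq, regions$start, regions$end, SIMPLIFY = FALSE))
}
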