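# Stage orchestration behind the command-line entry point.

#' Run one pipeline stage
#'
#' Thin orchestration over the package functions so the stages compose
#' into a shell pipeline: `simulate` writes free/bound uptake CSVs plus a
#' ground-truth sidecar; `analyze` reads two uptake CSVs and writes the
#' differential results TSV; `project` reads a results TSV and writes the
#' residue track, extracted regions and optionally a B-factor-annotated
#' PDB; `xlink` digests FASTA sequences, matches observed masses and
#' writes confirmed candidates; `stoich` ranks copy-number vectors against
#' a measured molar mass; `report` summarizes a results TSV. Identical
#' inputs, config and seed produce identical outputs.
#'
#' @param subcommand One of `"simulate"`, `"analyze"`, `"project"`,
#'   `"xlink"`, `"stoich"`, `"report"`.
#' @param config Named list of stage parameters; unspecified entries take
#'   the documented defaults (see Details in the stage functions).
#' @return Invisibly, a named list of the artifact paths (or objects)
#'   produced. Progress and warnings go to standard error.
#' @export
run_pipeline <- function(subcommand = c("simulate", "analyze", "project",
                                        "xlink", "stoich", "report"),
                         config = list()) {
  subcommand <- match.arg(subcommand)
  cfg <- function(name, default = NULL) config[[name]] %||% default
  message("[hdxmap] stage: ", subcommand)

  if (subcommand == "simulate") {
    seed <- cfg("seed", 1L)
    len <- cfg("length", 563L)
    prot <- make_two_state_protein(
      len, cfg("regions", list(c(88, 114, 100))),
      k_int = cfg("k_int", c(0.01, 100)), seed = seed)
    map <- make_peptide_map(len, mean_len = cfg("mean_len", 10L),
                            step = cfg("step", 4L),
                            len_jitter = cfg("len_jitter", 2L),
                            seed = seed + 1L)
    cond <- labeling_conditions(
      d2o_fraction = cfg("d2o_fraction", 0.8),
      timepoints = cfg("timepoints", c(3, 30, 300, 3000)),
      back_exchange = cfg("back_exchange", 1),
      noise_sd = cfg("noise_sd", 0.1),
      n_replicates = cfg("n_replicates", 3L))
    free <- simulate_uptake(prot, "free", map, cond, seed = seed + 2L)
    bound <- simulate_uptake(prot, "bound", map, cond, seed = seed + 3L)
    meta <- list(length = len, noise_sd = cond$noise_sd)
    out <- list(free = cfg("out_free", "uptake_free.csv"),
                bound = cfg("out_bound", "uptake_bound.csv"),
                truth = cfg("out_truth", "ground_truth.tsv"))
    write_uptake_csv(free, out$free, seed, meta)
    write_uptake_csv(bound, out$bound, seed, meta)
    write_with_header(ground_truth_table(prot), out$truth, seed, meta)
    return(invisible(out))
  }

  if (subcommand == "analyze") {
    thresholds <- hdx_thresholds(cfg("min_delta_pct", 10),
                                 cfg("alpha", 0.05), cfg("min_da", 0.5))
    fit <- hdx_diff(read_uptake_csv(cfg("free", "uptake_free.csv")),
                    read_uptake_csv(cfg("bound", "uptake_bound.csv")),
                    thresholds = thresholds,
                    skip_first = cfg("skip_first", 1L),
                    t_test_scope = cfg("t_test_scope", "max_timepoint"))
    message("[hdxmap] ", fit$n_tests, " peptides, ",
            sum(fit$results$significant), " significant, ",
            fit$n_excluded, " excluded")
    path <- cfg("out", "results.tsv")
    write_results_tsv(fit, path, cfg("seed"))
    return(invisible(list(results = path, fit = fit)))
  }

  if (subcommand == "project") {
    res <- utils::read.delim(cfg("results", "results.tsv"),
                             comment.char = "#", stringsAsFactors = FALSE)
    len <- cfg("protein_length") %||% max(res$end)
    track <- project_residues(res, len, cfg("protein_id"),
                              contributing = cfg("contributing", "all"),
                              skip_first = cfg("skip_first", 1L))
    regions <- extract_regions(track, threshold = cfg("threshold", 10),
                               min_len = cfg("min_len", 2L))
    out <- list(track = cfg("out_track", "track.tsv"),
                regions = cfg("out_regions", "regions.tsv"))
    meta <- list(threshold = cfg("threshold", 10),
                 min_len = cfg("min_len", 2L))
    write_track_tsv(track, out$track, cfg("seed"), meta)
    write_regions_tsv(regions, out$regions, cfg("seed"), meta)
    if (!is.null(cfg("pdb"))) {
      out$pdb <- cfg("out_pdb", "annotated.pdb")
      write_bfactor_pdb(cfg("pdb"), track, chain = cfg("chain", "A"),
                        offset = cfg("pdb_offset", 0L), path = out$pdb)
    }
    return(invisible(out))
  }

  if (subcommand == "xlink") {
    seqs <- read_fasta(cfg("fasta"))
    digests <- lapply(names(seqs), function(id) {
      tryptic_digest(seqs[[id]], cfg("max_missed", 2L), protein_id = id)
    })
    cand <- do.call(rbind, lapply(seq_along(digests), function(i) {
      do.call(rbind, lapply(seq.int(i, length(digests)), function(j) {
        enumerate_candidates(digests[[i]], digests[[j]])
      }))
    }))
    matched <- match_doublets(read_observed_masses(cfg("observed")), cand,
                              tol_ppm = cfg("tol_ppm", 10))
    message("[hdxmap] ", nrow(cand), " candidates, ",
            sum(matched$doublet_confirmed), " doublet-confirmed")
    path <- cfg("out", "xlinks.tsv")
    tab <- matched
    tab$theoretical_mass <- round(tab$theoretical_mass, 5)
    tab$matched_observed <- round(tab$matched_observed, 5)
    tab$ppm_error <- round(tab$ppm_error, 2)
    write_with_header(tab, path, cfg("seed"),
                      list(tol_ppm = cfg("tol_ppm", 10)))
    return(invisible(list(xlinks = path)))
  }

  if (subcommand == "stoich") {
    comps <- if (!is.null(cfg("fasta"))) {
      seqs <- read_fasta(cfg("fasta"))
      data.frame(name = names(seqs),
                 mass_kda = vapply(seqs, sequence_mass, numeric(1)),
                 epsilon_280 = vapply(seqs, extinction_280, numeric(1)),
                 stringsAsFactors = FALSE)
    } else {
      cfg("components")
    }
    fit <- infer_stoichiometry(cfg("measured"), comps,
                               max_copies = cfg("max_copies", 4L),
                               uv_weight = cfg("uv_weight"),
                               eps_observed = cfg("eps_observed"))
    path <- cfg("out", "stoichiometry.tsv")
    tab <- as.data.frame(fit)
    tab$predicted_mass <- round(tab$predicted_mass, 5)
    tab$residual <- round(tab$residual, 5)
    write_with_header(tab, path, cfg("seed"),
                      list(measured = cfg("measured")))
    return(invisible(list(stoichiometry = path, fit = fit)))
  }

  # report
  res <- utils::read.delim(cfg("results", "results.tsv"),
                           comment.char = "#", stringsAsFactors = FALSE)
  lines <- c(
    metadata_header(cfg("seed")),
    paste0("peptides_analyzed\t", nrow(res)),
    paste0("significant\t", sum(res$significant)),
    paste0("decrease\t", sum(res$direction == "decrease")),
    paste0("increase\t", sum(res$direction == "increase"))
  )
  path <- cfg("out", "report.tsv")
  writeLines(lines, path)
  invisible(list(report = path))
}
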