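# Differential uptake: the Delta-HDX statistic and the three-criterion call.

#' Significance thresholds for differential calling
#'
#' A peptide is called significant when all three hold: the absolute
#' Delta-HDX exceeds `min_delta_pct` (strict), the unpaired two-tailed
#' t-test p-value is below `alpha` (strict), and the absolute mean mass
#' difference at the Delta-HDX timepoint is at least `min_da` (inclusive).
#'
#' @param min_delta_pct Minimum %HDX difference (default 10).
#' @param alpha t-test significance level (default 0.05).
#' @param min_da Minimum absolute signal difference in Da (default 0.5).
#' @return A `hdx_thresholds` list.
#' @export
hdx_thresholds <- function(min_delta_pct = 10, alpha = 0.05, min_da = 0.5) {
  stopifnot(min_delta_pct > 0, alpha > 0, min_da > 0)
  structure(list(min_delta_pct = min_delta_pct, alpha = alpha,
                 min_da = min_da), class = "hdx_thresholds")
}

# two-sample two-tailed t-test on replicate deuteron counts.
# Degenerate variance: equal means -> 1, unequal -> 0.
unpaired_t_test <- function(reps_a, reps_b, var_equal = TRUE) {
  if (length(reps_a) < 2L || length(reps_b) < 2L) {
    stop("need >= 2 replicates per group", call. = FALSE)
  }
  va <- stats::var(reps_a); vb <- stats::var(reps_b)
  scale <- max(abs(c(reps_a, reps_b)), 1)
  if (va + vb <= (1e-10 * scale)^2) {
    return(if (isTRUE(all.equal(mean(reps_a), mean(reps_b)))) 1 else 0)
  }
  stats::t.test(reps_a, reps_b, var.equal = var_equal)$p.value
}

#' Differential HDX analysis of two states
#'
#' The central fit: compares peptide-level deuterium uptake between a
#' reference state (`free`) and a comparison state (`bound`) over a shared
#' peptide map. For every peptide the replicate-mean uptake difference
#' (bound minus free) is computed at each timepoint, in Da and as %HDX; the
#' signed difference of maximal magnitude over the timepoints is the
#' peptide's Delta-HDX (ties broken toward the earliest timepoint). An
#' unpaired two-tailed t-test on replicate deuteron counts and the
#' three-criterion rule of [hdx_thresholds()] yield the significance call.
#'
#' @param free,bound Uptake tables (see [simulate_uptake()] or
#'   [read_uptake_csv()]): one row per peptide x timepoint x replicate with
#'   columns `protein_id`, `start`, `end`, `sequence`, `timepoint_s`,
#'   `replicate`, `uptake_Da`. `free` is the reference; a negative
#'   Delta-HDX (direction `decrease`) means the bound state exchanges less.
#' @param thresholds [hdx_thresholds()].
#' @param skip_first Exchangeable-amide convention passed to
#'   [count_exchangeable()].
#' @param t_test_scope `"max_timepoint"` (default) tests the replicates at
#'   the Delta-HDX timepoint; `"any"` takes the smallest p-value over all
#'   timepoints.
#' @param var_equal Use the pooled-variance Student t (default) rather than
#'   Welch.
#' @return An object of class `hdx_diff`; its `$results` data.frame has one
#'   row per shared peptide, sorted by protein then start position, with
#'   per-timepoint differences in the list-columns `diff_pct`, `diff_da`
#'   and `p_by_timepoint`, and scalar columns `delta_hdx`,
#'   `delta_timepoint_s`, `delta_da`, `p_value`, `significant`, `direction`
#'   and `reasons`.
#' @examples
#' prot <- make_two_state_protein(60, list(c(20, 35, 100)), seed = 1)
#' map <- make_peptide_map(60, seed = 1)
#' cond <- labeling_conditions(noise_sd = 0.05)
#' fit <- hdx_diff(simulate_uptake(prot, "free", map, cond, seed = 2),
#'                 simulate_uptake(prot, "bound", map, cond, seed = 3))
#' summary(fit)
#' @export
hdx_diff <- function(free, bound, thresholds = hdx_thresholds(),
                     skip_first = 1L,
                     t_test_scope = c("max_timepoint", "any"),
                     var_equal = TRUE) {
  t_test_scope <- match.arg(t_test_scope)
  stopifnot(inherits(thresholds, "hdx_thresholds"))
  skip_first <- check_skip_first(skip_first)
  for (tab in list(free, bound)) check_uptake_columns(tab)

  key <- function(tab) paste(tab$protein_id, tab$start, tab$end, tab$sequence,
                             sep = "\r")
  keys_a <- unique(key(free)); keys_b <- unique(key(bound))
  shared <- intersect(keys_a, keys_b)
  if (length(shared) == 0L) {
    stop("the two states share no peptides (disjoint maps)", call. = FALSE)
  }
  dropped <- length(union(keys_a, keys_b)) - length(shared)
  if (dropped > 0L) {
    warning(dropped, " peptide(s) present in only one state were excluded",
            call. = FALSE)
  }

  fa <- split(free, key(free))[shared]
  fb <- split(bound, key(bound))[shared]

  n_excluded <- dropped
  rows <- vector("list", length(shared))
  for (i in seq_along(shared)) {
    a <- fa[[i]]; b <- fb[[i]]
    pep <- a[1L, c("protein_id", "start", "end", "sequence")]
    n_max <- count_exchangeable(pep$sequence, skip_first)
    if (n_max < 1L) {
      warning("peptide ", pep$sequence, " (", pep$start, "-", pep$end,
              ") has no exchangeable amides; excluded", call. = FALSE)
      n_excluded <- n_excluded + 1L
      next
    }
    tps_a <- sort(unique(a$timepoint_s)); tps_b <- sort(unique(b$timepoint_s))
    if (!identical(tps_a, tps_b)) {
      warning("peptide ", pep$start, "-", pep$end,
              " has mismatched timepoints between states; excluded",
              call. = FALSE)
      n_excluded <- n_excluded + 1L
      next
    }
    reps_a <- split(a$uptake_Da, a$timepoint_s)
    reps_b <- split(b$uptake_Da, b$timepoint_s)
    if (any(lengths(reps_a) < 2L) || any(lengths(reps_b) < 2L)) {
      warning("peptide ", pep$start, "-", pep$end,
              " has < 2 replicates at some timepoint; excluded",
              call. = FALSE)
      n_excluded <- n_excluded + 1L
      next
    }
    tps <- tps_a
    diff_da <- vapply(seq_along(tps), function(j) {
      mean(reps_b[[j]]) - mean(reps_a[[j]])
    }, numeric(1))
    diff_pct <- pct_hdx(deuterons_from_da(diff_da), n_max)
    p_by_tp <- vapply(seq_along(tps), function(j) {
      unpaired_t_test(deuterons_from_da(reps_a[[j]]),
                      deuterons_from_da(reps_b[[j]]), var_equal)
    }, numeric(1))

    idx <- which.max(abs(diff_pct))  # first max = earliest timepoint on ties
    p_value <- if (t_test_scope == "any") min(p_by_tp) else p_by_tp[idx]

    delta_hdx <- diff_pct[idx]
    delta_da <- diff_da[idx]
    fail <- character(0)
    if (!(abs(delta_hdx) > thresholds$min_delta_pct)) fail <- c(fail, "min_delta_pct")
    if (!(p_value < thresholds$alpha)) fail <- c(fail, "p_value")
    if (!(abs(delta_da) >= thresholds$min_da)) fail <- c(fail, "min_da")
    significant <- length(fail) == 0L

    rows[[i]] <- data.frame(
      pep, n_max = n_max,
      delta_hdx = delta_hdx, delta_timepoint_s = tps[idx],
      delta_da = delta_da, p_value = p_value,
      significant = significant,
      direction = if (!significant) "none" else
        if (delta_hdx < 0) "decrease" else "increase",
      reasons = paste(fail, collapse = ","),
      stringsAsFactors = FALSE
    )
    rows[[i]]$timepoints_s <- list(tps)
    rows[[i]]$diff_pct <- list(diff_pct)
    rows[[i]]$diff_da <- list(diff_da)
    rows[[i]]$p_by_timepoint <- list(p_by_tp)
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L) stop("no analyzable peptides", call. = FALSE)
  results <- do.call(rbind, rows)
  results <- results[order(results$protein_id, results$start, results$end), ]
  rownames(results) <- NULL

  structure(
    list(results = results, thresholds = thresholds,
         skip_first = skip_first, t_test_scope = t_test_scope,
         var_equal = var_equal, n_tests = nrow(results),
         n_excluded = n_excluded, call = match.call()),
    class = "hdx_diff"
  )
}

check_uptake_columns <- function(tab) {
  needed <- c("protein_id", "start", "end", "sequence", "timepoint_s",
              "replicate", "uptake_Da")
  missing <- setdiff(needed, names(tab))
  if (length(missing) > 0L) {
    stop("uptake table lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  invisible(tab)
}

#' @export
print.hdx_diff <- function(x, ...) {
  cat("Differential HDX analysis\n")
  cat("  peptides analyzed:", x$n_tests,
      " excluded:", x$n_excluded, "\n")
  cat("  significant:", sum(x$results$significant),
      sprintf("(%d decrease, %d increase)\n",
              sum(x$results$direction == "decrease"),
              sum(x$results$direction == "increase")))
  th <- x$thresholds
  cat(sprintf("  call rule: |dHDX| > %g%%, p < %g (%s t), |dDa| >= %g\n",
              th$min_delta_pct, th$alpha,
              if (x$var_equal) "pooled" else "Welch", th$min_da))
  invisible(x)
}

#' @export
summary.hdx_diff <- function(object, ...) {
  r <- object$results
  s <- r[r$significant, c("protein_id", "start", "end", "delta_hdx",
                          "delta_timepoint_s", "delta_da", "p_value",
                          "direction")]
  rownames(s) <- NULL
  structure(list(n_tests = object$n_tests, n_excluded = object$n_excluded,
                 significant = s, thresholds = object$thresholds),
            class = "summary.hdx_diff")
}

#' @export
print.summary.hdx_diff <- function(x, ...) {
  cat("Differential HDX analysis:", x$n_tests, "peptides,",
      nrow(x$significant), "significant\n\n")
  if (nrow(x$significant) > 0L) {
    print(x$significant, digits = 4)
  }
  invisible(x)
}

#' @export
as.data.frame.hdx_diff <- function(x, ...) {
  r <- x$results
  r$timepoints_s <- NULL
  r$diff_pct <- NULL
  r$diff_da <- NULL
  r$p_by_timepoint <- NULL
  r
}

#' @export
coef.hdx_diff <- function(object, ...) {
  r <- object$results
  stats::setNames(r$delta_hdx,
                  paste0(r$protein_id, ":", r$start, "-", r$end))
}

#' Woods-style plot of peptide-level Delta-HDX
#'
#' Draws each peptide as a horizontal segment from start to end at its
#' Delta-HDX, with the calling thresholds as dotted lines; significant
#' decreases in blue, increases in orange.
#'
#' @param x An `hdx_diff` object.
#' @param protein_id Protein to plot (default: the first).
#' @param ... Passed to [graphics::plot()].
#' @export
plot.hdx_diff <- function(x, protein_id = NULL, ...) {
  r <- x$results
  protein_id <- protein_id %||% r$protein_id[1L]
  r <- r[r$protein_id == protein_id, ]
  th <- x$thresholds$min_delta_pct
  ylim <- range(c(r$delta_hdx, th, -th)) * 1.1
  graphics::plot(NA, xlim = c(min(r$start), max(r$end)), ylim = ylim,
                 xlab = "residue", ylab = expression(Delta * "HDX (%)"),
                 main = protein_id, ...)
  graphics::abline(h = c(-th, th), lty = 3)
  graphics::abline(h = 0, col = "grey")
  col <- ifelse(!r$significant, "grey40",
                ifelse(r$direction == "decrease", "blue3", "darkorange2"))
  graphics::segments(r$start, r$delta_hdx, r$end, r$delta_hdx, col = col,
                     lwd = 2)
  invisible(x)
}
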