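#' Randomized balanced-subsampling robustness experiment
#'
#' Repeatedly draws balanced subsamples (`n_per_group` individuals per group,
#' without replacement within a replicate; replicates are independent draws,
#' so subsamples overlap), runs [ildsr2()] on each, and records which
#' canonical top ILDs reach the within-subsample bootstrap support threshold.
#' Aggregating across replicates measures how strongly the selection depends
#' on sample composition.
#'
#' @param data a [landmark_array], `gpa_array` or `ild_matrix` (the full
#'   sample; ILDs are computed once and rows are subset per replicate).
#' @param target two-level factor or [factor_table].
#' @param n_per_group individuals drawn per group in each replicate.
#' @param n_reps number of randomized subsamples (default 100).
#' @param support_threshold within-subsample bootstrap support needed for a
#'   top ILD to count, inclusive (default 0.5, "at least 50% of bootstraps").
#' @param r2tol,wg_rounds,canonical_only passed to [ildsr2()].
#' @param seed master seed; the whole experiment is bit-reproducible given
#'   it (each replicate gets an independent substream).
#' @param map optional [symmetry_map] when `data` holds coordinates.
#' @return Object of class `ild_subsample`: `table` (one row per canonical
#'   ILD ever supported: `name`, `n_supporting`, `frequency`,
#'   `support_median/min/max`, `r2_median/min/max`), the per-replicate
#'   `records`, and the parameters.
#' @export
run_subsample_experiment <- function(data, target, n_per_group,
                                     n_reps = 100L, support_threshold = 0.5,
                                     r2tol = 0.98, wg_rounds = 99L,
                                     seed = NULL, map = NULL,
                                     canonical_only = FALSE) {
  ilds <- if (inherits(data, "ild_matrix")) data else compute_ilds(data, map = map)
  tgt <- resolve_target(target, ilds$ids)
  if (tgt$mode != "factor") stop_("the subsampling experiment needs a two-level factor")
  if (!is_count(n_reps, 1L)) stop_("'n_reps' must be a positive integer")
  if (support_threshold <= 0 || support_threshold > 1)
    stop_("'support_threshold' must lie in (0, 1]")
  f <- tgt$f
  g1 <- which(f == levels(f)[1L]); g2 <- which(f == levels(f)[2L])
  if (!is_count(n_per_group, 2L) || n_per_group > min(length(g1), length(g2)))
    stop_(sprintf("'n_per_group' must be between 2 and the smaller group size (%d)",
                  min(length(g1), length(g2))))

  if (!is.null(seed)) set.seed(seed)
  rep_seeds <- draw_seeds(2L * n_reps)

  records <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    set.seed(rep_seeds[r])
    rows <- c(sample(g1, n_per_group), sample(g2, n_per_group))
    sub <- subset_ild_rows(ilds, rows)
    res <- ildsr2(sub, f[rows], r2tol = r2tol, wg_rounds = wg_rounds,
                  seed = rep_seeds[n_reps + r], canonical_only = canonical_only)
    ok <- res$top$support >= support_threshold
    records[[r]] <- if (any(ok))
      data.frame(rep = r, name = res$top$name[ok],
                 support = res$top$support[ok], r2 = res$top$rsq[ok])
    else NULL
  }
  rec <- do.call(rbind, records)
  tab <- aggregate_subsamples(rec, n_reps)
  structure(list(table = tab, records = rec, n_reps = n_reps,
                 n_per_group = n_per_group,
                 support_threshold = support_threshold,
                 r2tol = r2tol, wg_rounds = wg_rounds, seed = seed),
            class = "ild_subsample")
}

# cross-replicate aggregation: counts and median/min/max of support and R2
# over the supporting subsamples only
aggregate_subsamples <- function(records, n_reps) {
  if (is.null(records) || nrow(records) == 0L) {
    return(data.frame(name = character(0), n_supporting = integer(0),
                      frequency = numeric(0),
                      support_median = numeric(0), support_min = numeric(0),
                      support_max = numeric(0), r2_median = numeric(0),
                      r2_min = numeric(0), r2_max = numeric(0)))
  }
  sp <- split(records, records$name)
  tab <- do.call(rbind, lapply(sp, function(d) {
    data.frame(name = d$name[1L], n_supporting = nrow(d),
               frequency = nrow(d) / n_reps,
               support_median = stats::median(d$support),
               support_min = min(d$support), support_max = max(d$support),
               r2_median = stats::median(d$r2),
               r2_min = min(d$r2), r2_max = max(d$r2))
  }))
  tab <- tab[order(-tab$frequency, tab$name), , drop = FALSE]
  rownames(tab) <- NULL
  tab
}

#' Final ILD selection across randomized subsamples
#'
#' Canonical ILDs supported by strictly more than `freq_threshold` of the
#' randomized subsamples, ordered by frequency (descending) then name.
#'
#' @param summary an `ild_subsample` object (or its `table`).
#' @param freq_threshold cross-subsample frequency threshold, strict
#'   (default 0.5, "more than 50% of the randomizations").
#' @return Character vector of ILD names; empty (with a warning) when
#'   nothing passes — a legal outcome.
#' @export
final_ild_selection <- function(summary, freq_threshold = 0.5) {
  tab <- if (inherits(summary, "ild_subsample")) summary$table else summary
  if (!is.data.frame(tab) || !all(c("name", "frequency") %in% names(tab)))
    stop_("'summary' must be an ild_subsample result")
  sel <- tab[tab$frequency > freq_threshold, , drop = FALSE]
  if (nrow(sel) == 0L) {
    warn_("no ILD exceeds the frequency threshold; returning an empty selection")
    return(character(0))
  }
  sel <- sel[order(-sel$frequency, sel$name), , drop = FALSE]
  sel$name
}

#' @export
print.ild_subsample <- function(x, digits = 3, ...) {
  cat(sprintf("Randomized subsampling: %d replicates of %d + %d, support threshold %.2f\n",
              x$n_reps, x$n_per_group, x$n_per_group, x$support_threshold))
  tab <- x$table
  if (nrow(tab) == 0L) { cat("No supported top ILDs.\n"); return(invisible(x)) }
  num <- vapply(tab, is.numeric, TRUE)
  tab[num] <- lapply(tab[num], round, digits)
  print(utils::head(tab, 15L), row.names = FALSE)
  if (nrow(x$table) > 15L) cat(sprintf("... and %d more\n", nrow(x$table) - 15L))
  invisible(x)
}

#' Three-panel summary plot of a subsampling experiment
#'
#' (a) percentage of subsamples supporting each top ILD; (b) median and range
#' of the bootstrap support, over supporting subsamples; (c) median and range
#' of the R-squared.  ILDs with more than `highlight` support frequency are
#' drawn in violet.
#'
#' @param x an `ild_subsample`.
#' @param highlight frequency above which bars are emphasized (default 0.5).
#' @param max_ilds show at most this many ILDs, highest frequency first.
#' @param ... unused.
#' @return `x`, invisibly.
#' @export
plot.ild_subsample <- function(x, highlight = 0.5, max_ilds = 20L, ...) {
  tab <- utils::head(x$table, max_ilds)
  if (nrow(tab) == 0L) stop_("nothing to plot: no supported top ILDs")
  op <- graphics::par(mfrow = c(3L, 1L), mar = c(1, 4, 1, 1), oma = c(9, 0, 0, 0))
  on.exit(graphics::par(op))
  cols <- ifelse(tab$frequency > highlight, "mediumorchid4", "grey65")
  mids <- graphics::barplot(100 * tab$frequency, col = cols, border = NA,
                            ylab = "% of subsamples", names.arg = FALSE)
  rng <- function(m, lo, hi, ylab) {
    graphics::plot(mids, 100 * m, ylim = c(0, 100 * max(hi, na.rm = TRUE)),
                   pch = 16, col = cols, xlab = "", ylab = ylab, xaxt = "n")
    graphics::segments(mids, 100 * lo, mids, 100 * hi, col = cols)
  }
  rng(tab$support_median, tab$support_min, tab$support_max, "% bootstrap support")
  rng(tab$r2_median, tab$r2_min, tab$r2_max, "Rsq x 100")
  graphics::axis(1, at = mids, labels = tab$name, las = 2, cex.axis = 0.7)
  invisible(x)
}

#' Export a subsampling summary to CSV
#'
#' @param x an `ild_subsample`.
#' @param path output CSV.
#' @export
write_subsample_summary <- function(x, path) {
  if (!inherits(x, "ild_subsample")) stop_("'x' must be an ild_subsample")
  utils::write.csv(x$table, path, row.names = FALSE)
  invisible(NULL)
}
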