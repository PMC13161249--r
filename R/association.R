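#' Coefficient of determination of a variable against a two-group factor
#'
#' Between-group sum of squares over total sum of squares — identical to the
#' R-squared of the one-predictor linear model on a group indicator.
#'
#' @param values numeric vector.
#' @param factor two-level grouping, both levels present, `n >= 3`.
#' @return R-squared in `[0, 1]`.  Constant `values` (zero total SS) return 0
#'   with attribute `degenerate = TRUE` so the ranking stays total.
#' @examples
#' rsq_two_group(c(1, 2, 3, 4), factor(c("A", "A", "B", "B")))  # 0.8
#' @export
rsq_two_group <- function(values, factor) {
  f <- as.factor(factor)
  f <- droplevels(f)
  if (nlevels(f) != 2L) stop_("'factor' must have exactly two levels, both present")
  if (length(values) != length(f) || length(values) < 3L)
    stop_("'values' and 'factor' must have equal length n >= 3")
  m <- mean(values)
  sst <- sum((values - m)^2)
  if (sst <= 0) return(structure(0, degenerate = TRUE))
  g1 <- f == levels(f)[1L]
  n1 <- sum(g1); n2 <- sum(!g1)
  ssb <- n1 * (mean(values[g1]) - m)^2 + n2 * (mean(values[!g1]) - m)^2
  min(max(ssb / sst, 0), 1)
}

#' Coefficient of determination of a variable against a covariate
#'
#' The squared Pearson correlation — identical to the R-squared of the
#' simple linear regression of `values` on `covariate`.
#'
#' @param values numeric vector, `n >= 3`.
#' @param covariate numeric vector, non-constant.
#' @return R-squared in `[0, 1]`; constant `values` return 0 with attribute
#'   `degenerate = TRUE`.
#' @export
rsq_covariate <- function(values, covariate) {
  if (length(values) != length(covariate) || length(values) < 3L)
    stop_("'values' and 'covariate' must have equal length n >= 3")
  if (stats::sd(covariate) == 0) stop_("'covariate' is constant")
  if (stats::sd(values) == 0) return(structure(0, degenerate = TRUE))
  min(stats::cor(values, covariate)^2, 1)
}

# vectorized scorer over all columns of X; returns R-squared per column,
# constant columns scored 0
score_columns <- function(X, target) {
  n <- nrow(X)
  cm <- colMeans(X)
  sst <- colSums(X^2) - n * cm^2
  if (target$mode == "factor") {
    f <- target$f
    g1 <- f == levels(f)[1L]
    n1 <- sum(g1); n2 <- n - n1
    m1 <- colMeans(X[g1, , drop = FALSE])
    m2 <- colMeans(X[!g1, , drop = FALSE])
    ssb <- n1 * (m1 - cm)^2 + n2 * (m2 - cm)^2
  } else {
    z <- target$z
    zc <- z - mean(z)
    szz <- sum(zc^2)
    sxz <- as.vector(crossprod(X, zc))
    ssb <- sxz^2 / szz
  }
  r2 <- ifelse(sst > 0, ssb / sst, 0)
  pmin(pmax(r2, 0), 1)
}

#' Select the top upper-percentile scores
#'
#' Returns the `k = ceiling((1 - r2tol) * M)` highest-scoring entries — with
#' `M = 465` ILDs and `r2tol = 0.98` that is the "top-ten" (top 2%).  Ties at
#' the cut are broken by name ascending, then by position, so the selection
#' is deterministic.
#'
#' @param all_r2 named numeric vector of scores.
#' @param r2tol upper percentile threshold in `(0, 1)` (default 0.98).
#' @return Integer indices of the selected entries, highest score first.
#' @examples
#' select_top(setNames(runif(465), paste0("ild", 1:465)), 0.98)  # 10 indices
#' @export
select_top <- function(all_r2, r2tol = 0.98) {
  if (!is.numeric(r2tol) || length(r2tol) != 1L || r2tol <= 0 || r2tol >= 1)
    stop_("'r2tol' must lie strictly between 0 and 1")
  M <- length(all_r2)
  if (M < 1L) stop_("need at least one score")
  # guard against binary representation of (1 - r2tol): 0.02 * 100 must give
  # k = 2, not ceiling(2.0000000000000018) = 3
  k <- max(1L, as.integer(ceiling((1 - r2tol) * M - 1e-9)))
  nms <- names(all_r2) %||% as.character(seq_len(M))
  ord <- order(-all_r2, nms, seq_len(M))
  ord[seq_len(k)]
}

#' Bootstrap-supported selection of factor-associated ILDs
#'
#' The core screening procedure: (1) score every ILD against the target by
#' R-squared; (2) select the top `ceiling((1 - r2tol) * M)` ILDs; (3) for
#' each of `wg_rounds` bootstrap replicates, resample and re-run the scoring
#' and selection, counting how often each observed top ILD re-enters the top
#' set.  With a two-group factor, each group is resampled with replacement
#' independently at its own size (within-group bootstrap); with a covariate,
#' rows are resampled jointly.  The bootstrap support of a top ILD is
#' `(1 + hits) / (wg_rounds + 1)` — the observed analysis counts in both the
#' numerator and the denominator, so `wg_rounds = 99` yields supports in
#' whole percent.
#'
#' Scoring runs over all `q(q-1)/2` columns by default (mirror-redundant
#' ones included); the reported top set is de-duplicated to canonical ILD
#' names.  Set `canonical_only = TRUE` to take the percentile over canonical
#' columns only.
#'
#' @param data a [landmark_array], `gpa_array` or precomputed `ild_matrix`.
#' @param target two-level factor, numeric covariate, or [factor_table].
#' @param r2tol upper percentile threshold (default 0.98).
#' @param wg_rounds number of bootstrap replicates (default 99).  With 0, a
#'   warning is issued and all supports are exactly 1.
#' @param seed optional integer seed; given the seed the result is
#'   bit-reproducible.
#' @param map optional [symmetry_map] (used when `data` are coordinates).
#' @param canonical_only score only canonical columns?
#' @return Object of class `ildsr2`: `all_r2` (scores sorted descending,
#'   named), `top` (data frame: name, rsq, hits, support), `k`, `n_boot`,
#'   the scored `ilds` matrix and call parameters.
#' @export
ildsr2 <- function(data, target, r2tol = 0.98, wg_rounds = 99L, seed = NULL,
                   map = NULL, canonical_only = FALSE) {
  ilds <- if (inherits(data, "ild_matrix")) data else compute_ilds(data, map = map)
  tgt <- resolve_target(target, ilds$ids)
  n <- nrow(ilds$values)
  if (tgt$mode == "factor") {
    sizes <- table(tgt$f)
    if (any(sizes < 2L)) stop_("each group needs at least 2 individuals")
  }
  if (!is_count(wg_rounds)) stop_("'wg_rounds' must be a non-negative integer")

  cols <- if (canonical_only) which(ilds$canonical) else seq_along(ilds$names)
  X <- ilds$values[, cols, drop = FALSE]
  keys <- ilds$names[cols]

  r2 <- score_columns(X, tgt)
  names(r2) <- keys
  top_idx <- select_top(r2, r2tol)
  k <- length(top_idx)
  top_keys <- keys[top_idx]

  hits <- integer(k)
  if (wg_rounds == 0L) {
    warn_("wg_rounds = 0: no bootstrap performed, all supports are 1")
  } else {
    if (!is.null(seed)) set.seed(seed)
    boot_seeds <- draw_seeds(wg_rounds)
    if (tgt$mode == "factor") {
      g1 <- which(tgt$f == levels(tgt$f)[1L])
      g2 <- which(tgt$f == levels(tgt$f)[2L])
    }
    for (b in seq_len(wg_rounds)) {
      set.seed(boot_seeds[b])
      rows <- if (tgt$mode == "factor")
        c(sample(g1, replace = TRUE), sample(g2, replace = TRUE))
      else sample.int(n, replace = TRUE)
      tb <- if (tgt$mode == "factor") list(mode = "factor", f = tgt$f[rows])
            else list(mode = "covariate", z = tgt$z[rows])
      rb <- score_columns(X[rows, , drop = FALSE], tb)
      names(rb) <- keys
      boot_top <- unique(keys[select_top(rb, r2tol)])
      hits <- hits + (top_keys %in% boot_top)
    }
  }
  support <- (1 + hits) / (wg_rounds + 1)

  # de-duplicate mirror twins: identical canonical names collapse to one row
  keep <- !duplicated(top_keys)
  top <- data.frame(name = top_keys[keep], rsq = r2[top_idx][keep],
                    hits = hits[keep], support = support[keep],
                    row.names = NULL)
  structure(list(all_r2 = sort(r2, decreasing = TRUE),
                 top = top, k = k, r2tol = r2tol, n_boot = wg_rounds,
                 mode = tgt$mode,
                 levels = if (tgt$mode == "factor") levels(tgt$f) else NULL,
                 target = if (tgt$mode == "factor") tgt$f else tgt$z,
                 ilds = ilds, canonical_only = canonical_only, seed = seed),
            class = "ildsr2")
}

#' @export
print.ildsr2 <- function(x, digits = 3, ...) {
  cat(sprintf("ILD screening: %d ILDs scored against a %s (%s)\n",
              length(x$all_r2), x$mode,
              if (x$mode == "factor") paste(x$levels, collapse = " vs ")
              else "covariate"))
  cat(sprintf("Top %d ILDs (R2tol = %.2f), bootstrap support over %d + 1 analyses:\n",
              x$k, x$r2tol, x$n_boot))
  tab <- x$top
  tab$rsq <- round(tab$rsq, digits)
  tab$support <- round(tab$support, digits)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' @export
summary.ildsr2 <- function(object, ...) {
  out <- list(n_scored = length(object$all_r2), k = object$k,
              top = object$top,
              r2_range = range(object$all_r2),
              well_supported = object$top$name[object$top$support >= 0.5])
  class(out) <- "summary.ildsr2"
  out
}

#' @export
print.summary.ildsr2 <- function(x, ...) {
  cat(sprintf("%d ILDs scored; top set of %d; R2 range %.3f-%.3f\n",
              x$n_scored, x$k, x$r2_range[1L], x$r2_range[2L]))
  cat("Well supported (support >= 0.5):",
      if (length(x$well_supported)) paste(x$well_supported, collapse = ", ")
      else "none", "\n")
  invisible(x)
}
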