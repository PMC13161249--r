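#' Number of pairwise interlandmark distances
#'
#' A configuration of `q` landmarks yields `q(q-1)/2` unordered pairwise
#' distances.
#'
#' @param q integer number of landmarks, at least 2.
#' @return Integer count of ILDs.
#' @examples
#' ild_count(31)  # 465
#' ild_count(50)  # 1225
#' @export
ild_count <- function(q) {
  if (!is_count(q, min = 2L)) stop_("'q' must be an integer >= 2")
  as.integer(q * (q - 1) / 2)
}

#' Number of non-redundant ILDs under bilateral symmetry
#'
#' After symmetrization, mirror-image distance pairs are numerically
#' identical and only one member of each pair is informative.  For `m`
#' midplane landmarks and `p` bilateral pairs the canonical count is
#' `choose(m, 2) + m * p + p + p * (p - 1)`:
#' midplane-midplane distances, midplane-to-side (one side only), the
#' left-right span of each pair, and, for each pair of bilateral pairs, one
#' same-side plus one cross-side distance.
#'
#' @param m_mid number of midplane landmarks (>= 0).
#' @param p_pairs number of bilateral pairs (>= 0).
#' @return Integer count of canonical ILDs.
#' @examples
#' count_nonredundant(7, 12)  # 249, down from ild_count(31) = 465
#' @export
count_nonredundant <- function(m_mid, p_pairs) {
  if (!is_count(m_mid) || !is_count(p_pairs))
    stop_("'m_mid' and 'p_pairs' must be non-negative integers")
  if (m_mid + 2 * p_pairs < 2) stop_("need at least two landmarks")
  as.integer(choose(m_mid, 2) + m_mid * p_pairs + p_pairs + p_pairs * (p_pairs - 1))
}

#' Human-readable name for an interlandmark distance
#'
#' Base names (side letters dropped) joined by `-`.  When both landmarks are
#' bilateral and lie on the same side, the suffix `-ss` is appended; a
#' cross-side pair carries no suffix.  Sides are interchangeable after
#' symmetrization, so the specific side never appears in the name.
#'
#' @param pair integer vector of two landmark indices.
#' @param map a [symmetry_map].
#' @param landmark_names optional names (defaults to the map's).
#' @return A single string.
#' @examples
#' side <- c("midplane", "left", "right")
#' map <- symmetry_map(side, pair_name = c("", "alare", "alare"),
#'                     landmarks = c("glabella", "alare_L", "alare_R"))
#' render_name(c(1, 2), map)  # "glabella-alare"
#' @export
render_name <- function(pair, map, landmark_names = NULL) {
  a <- pair[1L]; b <- pair[2L]
  base <- map$base
  suffix <- ""
  lateral <- map$side[a] != "midplane" && map$side[b] != "midplane"
  if (lateral && map$side[a] == map$side[b] && base[a] != base[b]) suffix <- "-ss"
  paste0(base[a], "-", base[b], suffix)
}

#' Identify mirror-redundant ILD columns
#'
#' The mirror image of pair `{a, b}` is `{sigma(a), sigma(b)}`, where `sigma`
#' swaps left and right and fixes midplane landmarks.  When the mirrored pair
#' differs from the original, the lexicographically smaller index pair is the
#' canonical representative and the other points at it through `mirror_of`.
#' Self-mirror pairs (midplane-midplane, or the left-right span of one
#' bilateral pair) are canonical.  Redundancy is structural — it does not
#' inspect coordinate values, so it applies to unsymmetrized data too.
#'
#' @param pairs `m x 2` integer matrix of landmark index pairs (`a < b`).
#' @param map a [symmetry_map].
#' @return List with `canonical_mask` (logical per column) and `mirror_of`
#'   (integer column index or `NA` per column).
#' @export
classify_redundancy <- function(pairs, map) {
  q <- length(map$side)
  check_map(map, q)
  sigma <- mirror_permutation(map)
  a <- pairs[, 1L]; b <- pairs[, 2L]
  ma <- pmin(sigma[a], sigma[b]); mb <- pmax(sigma[a], sigma[b])
  key <- a * (q + 1) + b
  mkey <- ma * (q + 1) + mb
  mirror_idx <- match(mkey, key)
  self <- mkey == key
  smaller <- key < mkey
  canonical <- self | smaller
  mirror_of <- ifelse(canonical, NA_integer_, mirror_idx)
  list(canonical_mask = canonical, mirror_of = as.integer(mirror_of))
}

#' Compute all pairwise interlandmark distances
#'
#' Euclidean distance for every unordered landmark pair, ordered
#' lexicographically by index pair `(a, b)`.  ILDs are invariant under the
#' rigid motions of Procrustes superimposition, so raw and form-space
#' coordinates give identical values.
#'
#' @param data a [landmark_array] (raw or superimposed) or a plain
#'   `n x q x d` array.
#' @param map optional [symmetry_map]; when supplied, columns are labelled
#'   with [render_name()] names and mirror-redundant columns are flagged via
#'   [classify_redundancy()].
#' @return An object of class `ild_matrix`: list with `values` (`n x m`
#'   matrix, mm), `pairs` (`m x 2`), `names`, `canonical` (logical),
#'   `mirror_of`, and the `map` used (or `NULL`).
#' @examples
#' a <- array(c(0, 3, 0, 4, 0, 0), c(1, 2, 3))  # 3-4-5 triangle legs
#' @export
compute_ilds <- function(data, map = NULL) {
  if (is.array(data) && length(dim(data)) == 3L) data <- landmark_array(data)
  if (!inherits(data, "landmark_array")) stop_("'data' must be a landmark_array")
  co <- data$coords
  n <- dim(co)[1L]; q <- dim(co)[2L]
  if (q < 2L) stop_("need at least two landmarks")
  pairs <- t(utils::combn(q, 2L))
  m <- nrow(pairs)
  vals <- matrix(NA_real_, n, m)
  flat <- matrix(co, n)  # n x (q*d), column-major over (landmark, axis)
  d <- dim(co)[3L]
  for (k in seq_len(m)) {
    a <- pairs[k, 1L]; b <- pairs[k, 2L]
    s2 <- 0
    for (ax in seq_len(d)) {
      s2 <- s2 + (co[, a, ax] - co[, b, ax])^2
    }
    vals[, k] <- sqrt(s2)
  }
  if (!is.null(map)) {
    check_map(map, q)
    red <- classify_redundancy(pairs, map)
    nms <- vapply(seq_len(m), function(k) render_name(pairs[k, ], map), "")
    canonical <- red$canonical_mask
    mirror_of <- red$mirror_of
  } else {
    nms <- paste(data$landmarks[pairs[, 1L]], data$landmarks[pairs[, 2L]], sep = "-")
    canonical <- rep(TRUE, m)
    mirror_of <- rep(NA_integer_, m)
  }
  colnames(vals) <- nms
  rownames(vals) <- data$ids
  structure(list(values = vals, pairs = pairs, names = nms,
                 canonical = canonical, mirror_of = mirror_of,
                 map = map, landmarks = data$landmarks, ids = data$ids),
            class = "ild_matrix")
}

#' @export
print.ild_matrix <- function(x, ...) {
  cat(sprintf("ILD matrix: %d individuals x %d distances (%d canonical)\n",
              nrow(x$values), ncol(x$values), sum(x$canonical)))
  invisible(x)
}

#' @export
as.matrix.ild_matrix <- function(x, ...) x$values

#' Canonical (non-redundant) subset of an ILD matrix
#'
#' @param x an `ild_matrix` from [compute_ilds()].
#' @return An `ild_matrix` restricted to the canonical columns.
#' @export
canonical_ilds <- function(x) {
  if (!inherits(x, "ild_matrix")) stop_("'x' must be an ild_matrix")
  subset_ild_cols(x, which(x$canonical))
}

subset_ild_cols <- function(x, cols) {
  structure(list(values = x$values[, cols, drop = FALSE],
                 pairs = x$pairs[cols, , drop = FALSE],
                 names = x$names[cols],
                 canonical = x$canonical[cols],
                 mirror_of = rep(NA_integer_, length(cols)),
                 map = x$map, landmarks = x$landmarks, ids = x$ids),
            class = "ild_matrix")
}

subset_ild_rows <- function(x, rows) {
  out <- x
  out$values <- x$values[rows, , drop = FALSE]
  out$ids <- x$ids[rows]
  out
}

#' Export an ILD matrix and its column metadata to CSV
#'
#' Writes the `n x m` distance matrix (rows = individuals, columns = ILD
#' names) and, next to it, a companion table of column metadata
#' (`<stem>_columns.csv`) with pair indices, names, canonical flags and
#' mirror pointers (1-based, as in reports).
#'
#' @param x an `ild_matrix`.
#' @param path output CSV for the value matrix.
#' @export
write_ilds <- function(x, path) {
  if (!inherits(x, "ild_matrix")) stop_("'x' must be an ild_matrix")
  df <- data.frame(individual = x$ids, x$values, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  meta <- data.frame(index_a = x$pairs[, 1L], index_b = x$pairs[, 2L],
                     name = x$names, canonical = x$canonical,
                     mirror_of = x$mirror_of)
  utils::write.csv(meta, sub("\\.csv$", "_columns.csv", path), row.names = FALSE)
  invisible(NULL)
}
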