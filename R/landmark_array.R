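#' Landmark configuration array
#'
#' Container for a sample of landmark configurations: an `n x q x d` array of
#' Cartesian coordinates (individuals x landmarks x axes, in millimetres)
#' together with individual identifiers and landmark names.  Landmark order is
#' authoritative for all downstream indexing (reports use 1-based indices).
#'
#' @param coords numeric array indexed (individual, landmark, axis), in mm.
#' @param individual_ids character vector of length `n`; defaults to
#'   `"ind1" ... "indn"`.
#' @param landmark_names character vector of length `q`, unique; defaults to
#'   `"lm01" ... "lmq"`.
#' @return An object of class `landmark_array` with elements `coords`, `ids`,
#'   `landmarks` and `dim` (2 or 3).
#' @examples
#' a <- array(rnorm(2 * 4 * 3), c(2, 4, 3))
#' landmark_array(a)
#' @export
landmark_array <- function(coords, individual_ids = NULL, landmark_names = NULL) {
  if (!is.array(coords) || length(dim(coords)) != 3L)
    stop_("'coords' must be a 3-way array (individual, landmark, axis)")
  storage.mode(coords) <- "double"
  n <- dim(coords)[1L]; q <- dim(coords)[2L]; d <- dim(coords)[3L]
  if (n < 1L) stop_("need at least one individual")
  if (q < 3L) stop_("need at least 3 landmarks")
  if (!d %in% c(2L, 3L)) stop_("trailing dimension must be 2 or 3 coordinates")
  if (anyNA(coords) || any(!is.finite(coords)))
    stop_("missing or non-finite coordinates are not allowed")
  ids <- individual_ids %||% dimnames(coords)[[1L]] %||% paste0("ind", seq_len(n))
  lms <- landmark_names %||% dimnames(coords)[[2L]] %||% sprintf("lm%02d", seq_len(q))
  if (length(ids) != n) stop_("individual_ids length must equal n")
  if (length(lms) != q) stop_("landmark_names length must equal q")
  if (anyDuplicated(lms)) stop_("landmark names must be unique")
  dimnames(coords) <- list(ids, lms, c("x", "y", "z")[seq_len(d)])
  structure(list(coords = coords, ids = as.character(ids),
                 landmarks = as.character(lms), dim = d),
            class = "landmark_array")
}

#' @export
print.landmark_array <- function(x, ...) {
  cat(sprintf("Landmark array: %d individuals, %d landmarks, %dD\n",
              length(x$ids), length(x$landmarks), x$dim))
  invisible(x)
}

#' @export
print.gpa_array <- function(x, ...) {
  cat(sprintf("Superimposed landmark array: %d individuals, %d landmarks, %dD\n",
              length(x$ids), length(x$landmarks), x$dim))
  cat(sprintf("  scaled: %s   symmetrized: %s\n",
              x$scaled, x$symmetrized))
  cat(sprintf("  centroid size: %.2f - %.2f mm\n",
              min(x$centroid_sizes), max(x$centroid_sizes)))
  invisible(x)
}

# n, q, d accessors used internally
n_ind <- function(x) dim(x$coords)[1L]
n_lmk <- function(x) dim(x$coords)[2L]

#' Bilateral symmetry map
#'
#' Describes which landmarks lie on the midplane and which form left/right
#' pairs.  Together the midplane indices and the pairs partition all `q`
#' landmarks.
#'
#' @param side character vector of length `q` with entries `"midplane"`,
#'   `"left"` or `"right"`, in landmark order.
#' @param pair_name base name shared by the two members of a bilateral pair
#'   (ignored for midplane landmarks); defaults to the landmark name stripped
#'   of a trailing `_L`/`_R`.
#' @param landmarks optional landmark names (length `q`).
#' @return Object of class `symmetry_map` with elements `midplane` (indices),
#'   `pairs` (p x 2 integer matrix, columns left/right), `side`, `base`
#'   (per-landmark base name used for ILD naming) and `landmarks`.
#' @seealso [read_symmetry_map()]
#' @export
symmetry_map <- function(side, pair_name = NULL, landmarks = NULL) {
  side <- tolower(as.character(side))
  q <- length(side)
  if (!all(side %in% c("midplane", "left", "right")))
    stop_("side entries must be 'midplane', 'left' or 'right'")
  landmarks <- landmarks %||% sprintf("lm%02d", seq_len(q))
  if (length(landmarks) != q) stop_("landmarks length must match side")
  if (is.null(pair_name)) pair_name <- sub("_[LRlr]$", "", landmarks)
  pair_name <- as.character(pair_name)
  base <- ifelse(side == "midplane", landmarks, pair_name)

  left <- which(side == "left"); right <- which(side == "right")
  pairs <- matrix(integer(0), 0L, 2L)
  if (length(left) || length(right)) {
    for (nm in unique(pair_name[c(left, right)])) {
      l <- left[pair_name[left] == nm]
      r <- right[pair_name[right] == nm]
      if (length(l) != 1L || length(r) != 1L)
        stop_(sprintf("landmark '%s' is not pairable: %d left / %d right entries",
                      nm, length(l), length(r)))
      pairs <- rbind(pairs, c(l, r))
    }
  }
  colnames(pairs) <- c("left", "right")
  structure(list(midplane = which(side == "midplane"),
                 pairs = pairs, side = side, base = base,
                 landmarks = as.character(landmarks)),
            class = "symmetry_map")
}

#' @export
print.symmetry_map <- function(x, ...) {
  cat(sprintf("Symmetry map: %d landmarks (%d midplane, %d bilateral pairs)\n",
              length(x$side), length(x$midplane), nrow(x$pairs)))
  invisible(x)
}

# permutation swapping left and right, fixing midplane landmarks
mirror_permutation <- function(map) {
  sigma <- seq_along(map$side)
  sigma[map$pairs[, 1L]] <- map$pairs[, 2L]
  sigma[map$pairs[, 2L]] <- map$pairs[, 1L]
  sigma
}

check_map <- function(map, q) {
  if (!inherits(map, "symmetry_map")) stop_("'map' must be a symmetry_map")
  cover <- sort(c(map$midplane, as.vector(map$pairs)))
  if (length(map$side) != q || !identical(cover, seq_len(q)))
    stop_(sprintf("symmetry map does not partition the %d landmarks", q))
  invisible(map)
}

#' Factor / covariate table for a landmark sample
#'
#' Binds individual identifiers to either a two-level grouping factor (the
#' first level is the "start" group, the second the "target" group, e.g.
#' females then males) or a single numeric covariate.
#'
#' @param individual_ids character vector of ids matching a [landmark_array].
#' @param factor two-level factor (or vector coercible to one), or `NULL`.
#' @param covariate numeric vector, or `NULL`.  Exactly one of `factor` and
#'   `covariate` must be given.
#' @return Object of class `factor_table`.
#' @export
factor_table <- function(individual_ids, factor = NULL, covariate = NULL) {
  if (is.null(factor) == is.null(covariate))
    stop_("give exactly one of 'factor' or 'covariate'")
  ids <- as.character(individual_ids)
  if (!is.null(factor)) {
    f <- as.factor(factor)
    if (length(f) != length(ids)) stop_("factor length must match ids")
    if (nlevels(f) != 2L || !all(levels(f) %in% unique(as.character(f))))
      stop_("factor must have exactly two levels, both present")
    structure(list(ids = ids, factor = f, covariate = NULL),
              class = "factor_table")
  } else {
    if (!is.numeric(covariate) || length(covariate) != length(ids))
      stop_("covariate must be numeric and match ids")
    structure(list(ids = ids, factor = NULL, covariate = as.numeric(covariate)),
              class = "factor_table")
  }
}

# accepts a factor_table, a factor, or a numeric covariate; returns a list
# (mode = "factor"/"covariate", f or z) aligned with the given ids
resolve_target <- function(target, ids) {
  if (inherits(target, "factor_table")) {
    ord <- match(ids, target$ids)
    if (anyNA(ord)) stop_("factor table ids do not match the landmark data")
    if (!is.null(target$factor))
      return(list(mode = "factor", f = target$factor[ord]))
    return(list(mode = "covariate", z = target$covariate[ord]))
  }
  if (is.numeric(target)) {
    if (length(target) != length(ids)) stop_("covariate length must match n")
    return(list(mode = "covariate", z = as.numeric(target)))
  }
  f <- as.factor(target)
  if (length(f) != length(ids)) stop_("factor length must match n")
  f <- droplevels(f)
  if (nlevels(f) != 2L) stop_("grouping factor must have exactly two levels")
  list(mode = "factor", f = f)
}
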