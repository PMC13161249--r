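#' Read landmark configurations from disk
#'
#' Supported dialects:
#' \describe{
#'   \item{`tps`}{classic morphometrics interchange format; one record per
#'     individual starting with `LM=q` (2D) or `LM3=q` (3D), followed by `q`
#'     whitespace-separated coordinate rows.  An `ID=` line is used as the
#'     individual id when present (ordinal ids otherwise); `SCALE=`, `IMAGE=`
#'     and other auxiliary lines are ignored.  TPS files carry no landmark
#'     names, so landmarks are named `lm01, lm02, ...` in file order.}
#'   \item{`csv_wide`}{one row per individual, columns `individual` then
#'     `<landmark>_<axis>` with axes `x`, `y` (and `z` for 3D).}
#'   \item{`csv_long`}{columns `individual, landmark, x, y[, z]`, one row per
#'     (individual, landmark).}
#' }
#' Coordinates are treated as millimetres throughout; landmark order is the
#' file order and is authoritative for downstream indexing.
#'
#' @param path file to read.
#' @param format one of `"tps"`, `"csv_wide"`, `"csv_long"`.
#' @return A [landmark_array].
#' @seealso [write_landmarks()]
#' @export
read_landmarks <- function(path, format = c("tps", "csv_wide", "csv_long")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop_(sprintf("file not found: %s", path))
  switch(format,
         tps      = read_tps(path),
         csv_wide = read_csv_wide(path),
         csv_long = read_csv_long(path))
}

#' Write landmark configurations to disk
#'
#' Files are written with 17 significant digits so that a write/read
#' round-trip reproduces the coordinates bit-for-bit.
#'
#' @param data a [landmark_array] (or superimposed array).
#' @param path output file.
#' @param format one of `"tps"`, `"csv_wide"`, `"csv_long"`.
#' @export
write_landmarks <- function(data, path, format = c("tps", "csv_wide", "csv_long")) {
  format <- match.arg(format)
  if (!inherits(data, "landmark_array")) stop_("'data' must be a landmark_array")
  ok <- tryCatch({ file(path, "w") }, error = function(e)
    stop_(sprintf("cannot open '%s' for writing: %s", path, conditionMessage(e))))
  close(ok)
  switch(format,
         tps      = write_tps(data, path),
         csv_wide = write_csv_wide(data, path),
         csv_long = write_csv_long(data, path))
  invisible(NULL)
}

read_tps <- function(path) {
  lines <- readLines(path, warn = FALSE)
  configs <- list(); ids <- character(0); i <- 1L; dims <- integer(0)
  while (i <= length(lines)) {
    ln <- trimws(lines[i])
    m <- regmatches(ln, regexec("^LM(3?)\\s*=\\s*([0-9]+)$", ln, ignore.case = TRUE))[[1]]
    if (length(m)) {
      d <- if (nzchar(m[2])) 3L else 2L
      q <- as.integer(m[3])
      rows <- matrix(NA_real_, q, d)
      for (j in seq_len(q)) {
        i <- i + 1L
        if (i > length(lines)) stop_(sprintf("truncated TPS record near line %d", i))
        vals <- suppressWarnings(as.numeric(strsplit(trimws(lines[i]), "\\s+")[[1]]))
        if (length(vals) != d || anyNA(vals))
          stop_(sprintf("non-numeric or malformed coordinate at line %d", i))
        rows[j, ] <- vals
      }
      configs[[length(configs) + 1L]] <- rows
      dims <- c(dims, d)
      ids <- c(ids, NA_character_)
      i <- i + 1L
    } else if (grepl("^ID\\s*=", ln, ignore.case = TRUE)) {
      if (length(ids)) ids[length(ids)] <- sub("^ID\\s*=\\s*", "", ln, ignore.case = TRUE)
      i <- i + 1L
    } else i <- i + 1L
  }
  if (!length(configs)) stop_("no LM=/LM3= records found")
  qs <- vapply(configs, nrow, 1L)
  if (length(unique(qs)) != 1L)
    stop_(sprintf("ragged landmark counts: individual %d has %d landmarks, expected %d",
                  which(qs != qs[1L])[1L], qs[qs != qs[1L]][1L], qs[1L]))
  if (length(unique(dims)) != 1L) stop_("mixed 2D/3D records in TPS file")
  ids[is.na(ids)] <- paste0("ind", which(is.na(ids)))
  arr <- aperm(simplify2array(configs), c(3L, 1L, 2L))
  landmark_array(arr, individual_ids = ids)
}

write_tps <- function(data, path) {
  co <- data$coords; d <- data$dim; q <- n_lmk(data)
  out <- character(0)
  for (i in seq_len(n_ind(data))) {
    out <- c(out,
             sprintf("LM%s=%d", if (d == 3L) "3" else "", q),
             apply(co[i, , , drop = FALSE], 2L,
                   function(r) paste(fmt_num(r), collapse = " ")),
             sprintf("ID=%s", data$ids[i]))
  }
  writeLines(out, path)
}

write_csv_wide <- function(data, path) {
  co <- data$coords
  ax <- c("x", "y", "z")[seq_len(data$dim)]
  # columns grouped by landmark: <lm>_x, <lm>_y[, <lm>_z]
  flat <- sapply(seq_len(n_lmk(data) * data$dim), function(k) {
    lm <- (k - 1L) %/% data$dim + 1L; a <- (k - 1L) %% data$dim + 1L
    fmt_num(co[, lm, a])
  })
  flat <- matrix(flat, nrow = n_ind(data))
  colnames(flat) <- as.vector(t(outer(data$landmarks, ax, paste, sep = "_")))
  df <- data.frame(individual = data$ids, flat, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
}

read_csv_wide <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, colClasses = "character")
  if (!"individual" %in% names(df)) stop_("csv_wide needs an 'individual' column")
  cc <- setdiff(names(df), "individual")
  parts <- regmatches(cc, regexec("^(.*)_([xyz])$", cc))
  bad <- vapply(parts, length, 1L) == 0L
  if (any(bad)) stop_(sprintf("column '%s' is not of the form <landmark>_<axis>", cc[bad][1L]))
  lm <- vapply(parts, `[`, "", 2L); ax <- vapply(parts, `[`, "", 3L)
  lms <- unique(lm)
  d <- length(unique(ax))
  if (!all(table(lm) == d)) stop_("incomplete axis columns for some landmark")
  arr <- array(NA_real_, c(nrow(df), length(lms), d))
  axes <- c("x", "y", "z")[seq_len(d)]
  for (k in seq_along(cc)) {
    v <- suppressWarnings(as.numeric(df[[cc[k]]]))
    if (anyNA(v)) {
      row <- which(is.na(v))[1L]
      stop_(sprintf("non-numeric coordinate for individual '%s', column '%s' (line %d)",
                    df$individual[row], cc[k], row + 1L))
    }
    arr[, match(lm[k], lms), match(ax[k], axes)] <- v
  }
  landmark_array(arr, individual_ids = df$individual, landmark_names = lms)
}

write_csv_long <- function(data, path) {
  co <- data$coords
  ax <- c("x", "y", "z")[seq_len(data$dim)]
  rows <- expand.grid(landmark = seq_len(n_lmk(data)),
                      individual = seq_len(n_ind(data)))
  vals <- sapply(seq_len(data$dim), function(a)
    fmt_num(co[cbind(rows$individual, rows$landmark, a)]))
  df <- data.frame(individual = data$ids[rows$individual],
                   landmark = data$landmarks[rows$landmark],
                   vals)
  names(df)[3:(2 + data$dim)] <- ax
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
}

read_csv_long <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, colClasses = "character")
  need <- c("individual", "landmark", "x", "y")
  if (!all(need %in% names(df)))
    stop_("csv_long needs columns individual, landmark, x, y[, z]")
  d <- if ("z" %in% names(df)) 3L else 2L
  axes <- c("x", "y", "z")[seq_len(d)]
  ids <- unique(df$individual)
  lms <- unique(df$landmark[df$individual == ids[1L]])
  arr <- array(NA_real_, c(length(ids), length(lms), d))
  for (a in seq_len(d)) {
    v <- suppressWarnings(as.numeric(df[[axes[a]]]))
    if (anyNA(v)) {
      row <- which(is.na(v))[1L]
      stop_(sprintf("missing or non-numeric %s coordinate for individual '%s', landmark '%s' (line %d)",
                    axes[a], df$individual[row], df$landmark[row], row + 1L))
    }
    i <- match(df$individual, ids); j <- match(df$landmark, lms)
    if (anyNA(j)) {
      row <- which(is.na(j))[1L]
      stop_(sprintf("individual '%s' has landmark '%s' not present for individual '%s'",
                    df$individual[row], df$landmark[row], ids[1L]))
    }
    arr[cbind(i, j, a)] <- v
  }
  if (anyNA(arr)) {
    miss <- which(is.na(arr[, , 1L]), arr.ind = TRUE)
    stop_(sprintf("missing coordinates for individual '%s', landmark '%s'",
                  ids[miss[1L, 1L]], lms[miss[1L, 2L]]))
  }
  counts <- table(df$individual)
  if (length(unique(counts)) != 1L)
    stop_(sprintf("ragged landmark counts: individual '%s' has %d rows, expected %d",
                  names(counts)[counts != length(lms)][1L],
                  counts[counts != length(lms)][1L], length(lms)))
  landmark_array(arr, individual_ids = ids, landmark_names = lms)
}

#' Read a bilateral symmetry map from CSV
#'
#' The file must have columns `landmark`, `side` (one of `midplane`, `left`,
#' `right`) and `pair_name` (the base name shared by the two members of a
#' bilateral pair; may be empty for midplane landmarks).  Row order must match
#' the landmark order of the configurations the map will be used with.
#'
#' @param path CSV file.
#' @return A [symmetry_map].
#' @examples
#' map <- read_symmetry_map(system.file("extdata", "cranial31_symmetry.csv",
#'                                      package = "ildsel"))
#' length(map$midplane)  # 7
#' nrow(map$pairs)       # 12
#' @export
read_symmetry_map <- function(path) {
  if (!file.exists(path)) stop_(sprintf("file not found: %s", path))
  df <- utils::read.csv(path, check.names = FALSE, colClasses = "character",
                        strip.white = TRUE)
  if (!all(c("landmark", "side") %in% names(df)))
    stop_("symmetry map needs columns 'landmark' and 'side'")
  if (anyDuplicated(df$landmark))
    stop_(sprintf("duplicate assignment for landmark '%s'",
                  df$landmark[duplicated(df$landmark)][1L]))
  pair_name <- if ("pair_name" %in% names(df)) df$pair_name else NULL
  if (!is.null(pair_name)) {
    blank <- !nzchar(pair_name)
    pair_name[blank] <- df$landmark[blank]
  }
  symmetry_map(df$side, pair_name = pair_name, landmarks = df$landmark)
}

#' Read a factor/covariate table from CSV
#'
#' Expects a column `individual` plus either a two-level `factor` column or a
#' numeric `covariate` column.  Factor level order follows first appearance
#' unless the column is already encoded with explicit levels; the first level
#' is the "start" group and the second the "target" group.
#'
#' @param path CSV file with columns `individual` and one of
#'   `factor`/`covariate`.
#' @param levels optional explicit level order for the factor.
#' @return A [factor_table].
#' @export
read_factor_table <- function(path, levels = NULL) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (!"individual" %in% names(df)) stop_("need an 'individual' column")
  if ("factor" %in% names(df)) {
    f <- if (is.null(levels)) factor(df$factor, levels = unique(df$factor))
         else factor(df$factor, levels = levels)
    factor_table(df$individual, factor = f)
  } else if ("covariate" %in% names(df)) {
    factor_table(df$individual, covariate = as.numeric(df$covariate))
  } else stop_("need a 'factor' or 'covariate' column")
}
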