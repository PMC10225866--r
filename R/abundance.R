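#' Validate and coerce a species-by-patch abundance matrix
#'
#' The universal input of the package is a non-negative integer count
#' matrix with species in rows and patches (sites, transects, quadrats)
#' in columns. `as_abundance()` accepts a matrix or a data frame (an
#' optional first character column is treated as species labels) and
#' returns a validated integer matrix with species and patch dimnames.
#'
#' "Observed species" are rows with a positive total; observed richness
#' `S` is their number. All-zero rows are retained (they carry no
#' information but are harmless and arise naturally in simulations).
#'
#' @param x matrix or data frame of counts, species x patch.
#' @param species_ids,patch_ids optional label vectors; defaults are
#'   taken from dimnames or generated (`sp1..`, `patch1..`).
#' @return an integer matrix with `dimnames`, invisibly classed
#'   `"abundance_matrix"` for printing only; all package functions
#'   accept any plain matrix.
#' @examples
#' m <- as_abundance(rbind(c(2, 1, 0), c(1, 0, 0), c(0, 1, 0)))
#' observed_species(m)
#' @export
as_abundance <- function(x, species_ids = NULL, patch_ids = NULL) {
  if (is.data.frame(x)) {
    first_chr <- ncol(x) > 1 &&
      (is.character(x[[1]]) || is.factor(x[[1]]))
    if (first_chr) {
      if (is.null(species_ids)) species_ids <- as.character(x[[1]])
      x <- x[, -1, drop = FALSE]
    }
    x <- as.matrix(x)
  }
  if (!is.matrix(x)) x <- matrix(x, nrow = length(x))
  if (nrow(x) < 1L || ncol(x) < 1L) {
    abort("abundance matrix must have at least one species row and one patch column")
  }
  if (!is.numeric(x)) {
    bad <- which(!apply(x, 2, is.numeric))
    abort(paste0("non-numeric counts in column(s): ",
                 paste(head(bad, 5), collapse = ", ")))
  }
  if (anyNA(x)) {
    idx <- which(is.na(x), arr.ind = TRUE)[1, ]
    abort(sprintf("missing count at row %d, column %d", idx[1], idx[2]))
  }
  if (any(x < 0)) {
    idx <- which(x < 0, arr.ind = TRUE)[1, ]
    abort(sprintf("negative count at row %d (%s), column %d (%s)",
                  idx[1], rownames(x)[idx[1]] %||% idx[1],
                  idx[2], colnames(x)[idx[2]] %||% idx[2]))
  }
  if (any(abs(x - round(x)) > 1e-8)) {
    idx <- which(abs(x - round(x)) > 1e-8, arr.ind = TRUE)[1, ]
    abort(sprintf("non-integer count at row %d, column %d", idx[1], idx[2]))
  }
  storage.mode(x) <- "integer"
  rownames(x) <- species_ids %||% rownames(x) %||% paste0("sp", seq_len(nrow(x)))
  colnames(x) <- patch_ids %||% colnames(x) %||% paste0("patch", seq_len(ncol(x)))
  x
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Observed species of an abundance matrix
#'
#' @param x abundance matrix (see [as_abundance()]).
#' @return character vector of row labels with positive row totals.
#' @export
observed_species <- function(x) {
  x <- as_abundance(x)
  rownames(x)[rowSums(x) > 0]
}

#' Read a species-by-patch abundance table
#'
#' Reads either a wide table (rows = species with a leading label
#' column, columns = patches) or a long table with columns
#' `species, patch, count` and optionally `time` (year or census
#' label). Duplicate `(species, patch)` records in long format are
#' summed. Wide CSV/TSV is the canonical on-disk format.
#'
#' @param path file path (CSV, or TSV when the extension is `.tsv`).
#' @param format `"wide"` (default) or `"long"`.
#' @return for single-time data an abundance matrix; for long data with
#'   a `time` column, a named list of matrices, one per time label
#'   (every estimator operates on a single survey).
#' @export
read_abundance <- function(path, format = c("wide", "long")) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  delim <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  df <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                          progress = FALSE)
  if (nrow(df) == 0L) abort("empty abundance table")
  if (format == "wide") {
    return(as_abundance(as.data.frame(df)))
  }
  names(df) <- tolower(names(df))
  need <- c("species", "patch", "count")
  if (!all(need %in% names(df))) {
    abort("long format requires columns species, patch, count")
  }
  split_one <- function(d) {
    wide <- tidyr::pivot_wider(
      dplyr::summarise(
        dplyr::group_by(d, .data$species, .data$patch),
        count = sum(.data$count), .groups = "drop"),
      names_from = "patch", values_from = "count", values_fill = 0)
    as_abundance(as.data.frame(wide))
  }
  if ("time" %in% names(df)) {
    out <- lapply(split(df, df$time), split_one)
    if (length(out) == 1L) out[[1]] else out
  } else {
    split_one(df)
  }
}

#' Write an abundance matrix
#'
#' @param x abundance matrix.
#' @param path output file path.
#' @param format `"wide"` (default, species label column + one column
#'   per patch) or `"long"` (`species, patch, count`, zero cells
#'   dropped).
#' @return `path`, invisibly.
#' @export
write_abundance <- function(x, path, format = c("wide", "long")) {
  format <- match.arg(format)
  x <- as_abundance(x)
  if (format == "wide") {
    df <- tibble::as_tibble(x, rownames = "species")
    readr::write_csv(df, path, progress = FALSE)
  } else {
    long <- tibble::tibble(
      species = rep(rownames(x), ncol(x)),
      patch = rep(colnames(x), each = nrow(x)),
      count = as.vector(x))
    readr::write_csv(long[long$count > 0, ], path, progress = FALSE)
  }
  invisible(path)
}

#' Convert percent-cover records to abundance counts
#'
#' Percent cover recorded on a grid is discrete in steps of 0.5, with
#' 0.5 denoting trace presence (one grid cell partially filled).
#' Dividing by the 0.5 step turns cover into integer abundance units;
#' values that are not exact multiples of 0.5 (entry noise in real
#' data) are rounded to the nearest count with a warning.
#'
#' @param cover numeric matrix of percent cover, species x patch.
#' @param trace the recording step (default 0.5).
#' @return an abundance matrix of counts `round(cover / trace)`.
#' @examples
#' percent_cover_to_counts(matrix(c(0, 0.5, 37.5), 1))
#' @export
percent_cover_to_counts <- function(cover, trace = 0.5) {
  if (!is.matrix(cover)) cover <- as.matrix(cover)
  if (anyNA(cover) || any(cover < 0)) abort("cover values must be >= 0")
  scaled <- cover / trace
  off <- abs(scaled - round(scaled)) > 1e-8
  if (any(off)) {
    warn(sprintf(
      "%d cover value(s) are not multiples of %.2g; rounded to nearest count",
      sum(off), trace))
  }
  as_abundance(round(scaled))
}

#' Aggregate patches into coarser spatial units
#'
#' Sums counts within groups of patches, e.g. quadrats into the
#' transect they belong to, so that the coarser (more spatially
#' independent) unit becomes the patch.
#'
#' @param x abundance matrix.
#' @param grouping named character/factor vector mapping every patch id
#'   (names) to its group, or an unnamed vector of length `ncol(x)` in
#'   column order.
#' @return abundance matrix with one column per group; every species'
#'   total count is preserved.
#' @export
aggregate_patches <- function(x, grouping) {
  x <- as_abundance(x)
  if (is.null(names(grouping))) {
    if (length(grouping) != ncol(x)) {
      abort("unnamed grouping must have one entry per patch")
    }
    names(grouping) <- colnames(x)
  }
  missing <- setdiff(colnames(x), names(grouping))
  if (length(missing) > 0) {
    abort(paste0("patch(es) not assigned to a group: ",
                 paste(head(missing, 5), collapse = ", ")))
  }
  g <- factor(as.character(grouping[colnames(x)]))
  out <- t(rowsum(t(x), g))
  as_abundance(out, species_ids = rownames(x), patch_ids = levels(g))
}

#' Convert counts to presence/absence incidence
#'
#' @param x abundance matrix.
#' @return binary abundance matrix: 1 where the count is positive.
#' @export
to_incidence <- function(x) {
  x <- as_abundance(x)
  as_abundance((x > 0) + 0L, species_ids = rownames(x),
               patch_ids = colnames(x))
}

#' Inflate incidence data to pseudo-abundances
#'
#' Incidence-only surveys can be fed to the abundance-based omega
#' estimators by assigning every presence a large fixed abundance, so
#' the within-occupied-patch observation probability
#' `1 - exp(-mn/P)` is effectively 1 and per-patch detection reduces
#' to occupancy. A floor above 10 makes the residual failure rate at
#' most `exp(-11)` (about 2e-5).
#'
#' @param x binary incidence matrix.
#' @param mn_floor pseudo-abundance per presence, must be > 10;
#'   non-integers are rounded up.
#' @return abundance matrix with presences replaced by
#'   `ceiling(mn_floor)`.
#' @export
incidence_to_pseudocounts <- function(x, mn_floor = 11) {
  x <- as_abundance(x)
  if (any(x > 1)) abort("input must be binary; use to_incidence() first")
  if (mn_floor <= 10) abort("mn_floor must be greater than 10")
  as_abundance(x * as.integer(ceiling(mn_floor)),
               species_ids = rownames(x), patch_ids = colnames(x))
}
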