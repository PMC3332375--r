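#' Person-year tables for grouped cohort mortality data
#'
#' A person-year table is the grouped form in which large mortality cohorts
#' (such as the Life Span Study of atomic-bomb survivors) are distributed:
#' one row per cell of the cross-classification by city, sex, age at
#' exposure, attained age, calendar period and dose category.  Each cell
#' carries person-year-weighted means of attained age, age at exposure and
#' weighted organ dose (Gy), the accumulated person-years at risk, and
#' death counts per cause.  All modelling in this package operates on the
#' cell means, never on the category indices.
#'
#' The canonical file format is a plain CSV with one header row and fixed
#' column names: `city, sex, agexcat, agecat, periodcat, dosecat, mean_age,
#' mean_agex, mean_dose_gy, pyr, deaths_<cause>` (one `deaths_` column per
#' cause label).  Column names can be remapped through `col_map`.
#'
#' @name person_year_table
NULL

.pyt_key_cols <- c("city", "sex", "agexcat", "agecat", "periodcat", "dosecat")
.pyt_num_cols <- c("mean_age", "mean_agex", "mean_dose_gy", "pyr")

#' Construct a person-year table
#'
#' Validates a data frame of grouped cohort cells and stamps it with the
#' `pyt` class.  Rows violating the cell invariants (positive person-years,
#' non-negative integral death counts, non-negative dose, age at exposure
#' not exceeding attained age, no duplicated stratum keys) are rejected
#' with their row indices named in the error.
#'
#' @param cells data frame with the canonical columns (see
#'   [person_year_table]) and one `deaths_<cause>` column per cause.
#' @param causes character vector of cause labels; defaults to the causes
#'   implied by the `deaths_` columns present.
#' @param provenance optional free-text note (follow-up window, dose
#'   weighting) stored as an attribute.
#' @return a `pyt` object: the validated data frame with attributes
#'   `causes` and `provenance`.
#' @export
person_year_table <- function(cells, causes = NULL, provenance = NULL) {
  stopifnot(is.data.frame(cells))
  cells <- as.data.frame(cells, stringsAsFactors = FALSE)
  death_cols <- grep("^deaths_", names(cells), value = TRUE)
  if (is.null(causes)) causes <- sub("^deaths_", "", death_cols)
  need <- c(.pyt_key_cols, .pyt_num_cols, paste0("deaths_", causes))
  missing <- setdiff(need, names(cells))
  if (length(missing) > 0L) {
    stop("person-year table is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  for (col in c(.pyt_num_cols, paste0("deaths_", causes))) {
    if (!is.numeric(cells[[col]])) {
      stop("column '", col, "' must be numeric", call. = FALSE)
    }
  }
  bad <- function(cond, what) {
    idx <- which(cond)
    if (length(idx) > 0L) {
      stop("invalid person-year cell(s) at row(s) ",
           paste(utils::head(idx, 10L), collapse = ", "), ": ", what,
           call. = FALSE)
    }
  }
  bad(!(cells$pyr > 0), "person_years must be > 0")
  bad(cells$mean_dose_gy < 0, "mean_dose_gy must be >= 0")
  bad(cells$mean_agex > cells$mean_age, "mean_agex must be <= mean_age")
  for (cause in causes) {
    d <- cells[[paste0("deaths_", cause)]]
    bad(d < 0 | abs(d - round(d)) > 1e-8,
        paste0("deaths_", cause, " must be non-negative integers"))
  }
  key <- do.call(paste, c(cells[.pyt_key_cols], sep = "\r"))
  bad(duplicated(key), "duplicated stratum key")
  structure(cells,
            causes = causes,
            provenance = provenance,
            class = c("pyt", "data.frame"))
}

#' @export
print.pyt <- function(x, ...) {
  causes <- attr(x, "causes")
  cat("Person-year table: ", nrow(x), " cells, ",
      format(sum(x$pyr), big.mark = ","), " person-years\n", sep = "")
  for (cause in causes) {
    cat("  deaths[", cause, "]: ",
        sum(x[[paste0("deaths_", cause)]]), "\n", sep = "")
  }
  if (!is.null(attr(x, "provenance"))) {
    cat("  provenance: ", attr(x, "provenance"), "\n", sep = "")
  }
  invisible(x)
}

#' Read a person-year table from CSV
#'
#' @param path path to a CSV file in the canonical dialect (see
#'   [person_year_table]).
#' @param causes cause labels to require; default: all `deaths_` columns.
#' @param col_map named character vector remapping file column names to
#'   canonical ones, e.g. `c(pyr = "person_years")` if the file calls the
#'   person-year column `person_years`.
#' @return a validated [person_year_table()].
#' @export
read_pyt <- function(path, causes = NULL, col_map = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(col_map)) {
    for (canon in names(col_map)) {
      idx <- match(col_map[[canon]], names(raw))
      if (!is.na(idx)) names(raw)[idx] <- canon
    }
  }
  person_year_table(raw, causes = causes)
}

#' Write a person-year table to CSV
#'
#' Inverse of [read_pyt()]: `read_pyt(write_pyt(x, p))` reproduces `x`
#' field by field.
#'
#' @param table a `pyt` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pyt <- function(table, path) {
  stopifnot(inherits(table, "pyt"))
  utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}

#' Assign cells to (dose, age) groups
#'
#' Internal helper shared by [stratify_totals()] and
#' [deviance_decomposition()].  Bins are half-open `[lo, hi)` by default;
#' `right_closed = TRUE` switches to `(lo, hi]` which matches the
#' "0.1 < D <= 0.5" style of printed stratified tables.
#'
#' @noRd
.pyt_group_index <- function(values, breaks, right_closed = FALSE,
                             what = "value") {
  if (is.unsorted(breaks, strictly = TRUE)) {
    stop(what, " bin boundaries must be strictly increasing", call. = FALSE)
  }
  idx <- findInterval(values, breaks,
                      left.open = right_closed,
                      rightmost.closed = FALSE)
  out <- which(idx < 1L | idx >= length(breaks))
  if (length(out) > 0L) {
    stop("cell(s) at row(s) ", paste(utils::head(out, 10L), collapse = ", "),
         " fall outside the ", what, " bins", call. = FALSE)
  }
  idx
}

.bin_labels <- function(breaks, right_closed = FALSE) {
  lo <- utils::head(breaks, -1L)
  hi <- utils::tail(breaks, -1L)
  if (right_closed) paste0("(", lo, ",", hi, "]") else paste0("[", lo, ",", hi, ")")
}

#' Stratified person-year and death totals
#'
#' Partitions the cells of a person-year table into a (dose x attained-age)
#' grid by their cell means and accumulates person-years and deaths per
#' group.  Any stratification conserves the grand totals exactly.
#'
#' @param table a `pyt` object.
#' @param dose_bins strictly increasing Gy boundaries covering every cell
#'   mean dose (length >= 2; use `Inf` for an open top bin).
#' @param age_bins strictly increasing year boundaries covering every cell
#'   mean attained age.
#' @param cause cause label whose deaths are accumulated.
#' @param right_closed logical; `FALSE` (default) bins by `[lo, hi)`,
#'   `TRUE` by `(lo, hi]`.
#' @return data frame with columns `dose_bin`, `age_bin`, `pyr`, `deaths`,
#'   one row per non-degenerate grid combination (all combinations kept,
#'   zero-filled).
#' @export
stratify_totals <- function(table, dose_bins, age_bins, cause,
                            right_closed = FALSE) {
  stopifnot(inherits(table, "pyt"))
  dcol <- paste0("deaths_", cause)
  if (!dcol %in% names(table)) stop("unknown cause: ", cause, call. = FALSE)
  di <- .pyt_group_index(table$mean_dose_gy, dose_bins, right_closed, "dose")
  ai <- .pyt_group_index(table$mean_age, age_bins, right_closed, "age")
  dl <- factor(di, levels = seq_len(length(dose_bins) - 1L),
               labels = .bin_labels(dose_bins, right_closed))
  al <- factor(ai, levels = seq_len(length(age_bins) - 1L),
               labels = .bin_labels(age_bins, right_closed))
  agg <- aggregate(cbind(pyr = table$pyr, deaths = table[[dcol]]),
                   by = list(dose_bin = dl, age_bin = al),
                   FUN = sum, drop = FALSE)
  agg$pyr[is.na(agg$pyr)] <- 0
  agg$deaths[is.na(agg$deaths)] <- 0
  agg[order(agg$dose_bin, agg$age_bin), , drop = FALSE]
}
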