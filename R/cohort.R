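#' @keywords internal
"_PACKAGE"

# Canonical long-format column set: one row per participant-visit.
.cohort_cols <- c("id", "visit_index", "sex", "baseline_age",
                  "g0", "g60", "g120", "i0", "i60", "i120", "hba1c",
                  "bmi", "fat_mass", "on_medication")

.cohort_numeric <- c("baseline_age", "g0", "g60", "g120",
                     "i0", "i60", "i120", "hba1c", "bmi", "fat_mass")

#' Construct a longitudinal OGTT cohort
#'
#' A cohort is a long-format data frame with one row per participant-visit
#' holding the 0/60/120-min OGTT glucose and insulin values (mg/dL, uU/mL),
#' HbA1c (%), anthropometrics and the antidiabetic-medication flag. Visits are
#' indexed 0..5 on the biannual schedule (years 0, 2, ..., 10). Missing
#' measurements are `NA`; there are no numeric sentinels.
#'
#' @param df data frame containing at least `id` and `visit_index`; any of the
#'   canonical columns `g0, g60, g120, i0, i60, i120, hba1c, bmi, fat_mass,
#'   sex, baseline_age, on_medication` are used if present, others are filled
#'   with `NA`.
#' @param provenance short label recording where the rows came from.
#' @return an object of class `glyco_cohort` (a data frame).
#' @seealso [read_cohort()], [write_cohort()], [generate_cohort()]
#' @export
as_cohort <- function(df, provenance = "unspecified") {
  stopifnot(is.data.frame(df))
  for (col in c("id", "visit_index")) {
    if (!col %in% names(df)) stop("mandatory column missing: ", col)
  }
  out <- data.frame(id = as.character(df$id),
                    visit_index = as.integer(df$visit_index),
                    stringsAsFactors = FALSE)
  out$sex <- if ("sex" %in% names(df)) as.character(df$sex) else NA_character_
  for (col in .cohort_numeric) {
    out[[col]] <- if (col %in% names(df)) as.numeric(df[[col]]) else NA_real_
  }
  out$on_medication <- if ("on_medication" %in% names(df)) {
    as.logical(df$on_medication)
  } else NA
  out <- out[, .cohort_cols]

  bad_visit <- is.na(out$visit_index) | out$visit_index < 0 | out$visit_index > 5
  if (any(bad_visit)) {
    stop("visit_index must be an integer in 0..5; offending rows: ",
         paste(utils::head(which(bad_visit), 5), collapse = ", "))
  }
  key <- paste(out$id, out$visit_index, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)][1]
    stop("duplicated (id, visit_index): ",
         gsub("\r", ", visit ", dup, fixed = TRUE))
  }
  out <- out[order(out$id, out$visit_index), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("glyco_cohort", "data.frame"),
            provenance = provenance)
}

# Row-level range validation. Returns indices of invalid rows and reasons.
# Out-of-range values are rejected, never clamped.
.validate_rows <- function(df) {
  reasons <- character(nrow(df))
  flag <- function(bad, msg) {
    bad <- which(bad)
    reasons[bad] <<- ifelse(reasons[bad] == "", msg,
                            paste(reasons[bad], msg, sep = "; "))
  }
  for (col in c("g0", "g60", "g120")) {
    v <- df[[col]]
    flag(!is.na(v) & (v <= 0 | v >= 1000),
         paste0(col, " outside (0, 1000) mg/dL"))
  }
  for (col in c("i0", "i60", "i120")) {
    v <- df[[col]]
    flag(!is.na(v) & (v <= 0 | v >= 1000),
         paste0(col, " outside (0, 1000) uU/mL"))
  }
  v <- df$hba1c
  flag(!is.na(v) & (v < 3 | v > 20), "hba1c outside [3, 20] %")
  for (col in c("bmi", "fat_mass")) {
    v <- df[[col]]
    flag(!is.na(v) & v <= 0, paste0(col, " must be positive"))
  }
  reasons
}

#' Read a cohort from CSV
#'
#' Reads a comma-separated, UTF-8, headered file with one row per
#' participant-visit. Empty cells become missing values. Rows with
#' out-of-range or unparseable numeric cells are rejected (not clamped) and
#' reported in the `rejected` attribute; duplicated `(id, visit_index)` pairs
#' are a hard error.
#'
#' @param path CSV file path.
#' @param schema optional named character vector mapping logical column names
#'   (`id`, `visit_index`, `g0`, ...) to the column names used in the file,
#'   e.g. `c(id = "SUBJID", g0 = "GLU_FASTING")`. Unmapped logical names are
#'   looked up under their own name.
#' @return a [as_cohort()] object; attribute `rejected` holds a data frame of
#'   dropped rows (`row`, `reason`).
#' @export
read_cohort <- function(path, schema = NULL) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         na.strings = "", colClasses = "character")
  if (!is.null(schema)) {
    for (logical_name in names(schema)) {
      file_name <- schema[[logical_name]]
      if (!file_name %in% names(raw)) {
        stop("schema maps '", logical_name, "' to missing column '",
             file_name, "'")
      }
      names(raw)[names(raw) == file_name] <- logical_name
    }
  }
  for (col in c("id", "visit_index")) {
    if (!col %in% names(raw)) stop("mandatory column missing: ", col)
  }

  n <- nrow(raw)
  reasons <- character(n)
  df <- data.frame(id = raw$id, stringsAsFactors = FALSE)
  vi <- suppressWarnings(as.integer(raw$visit_index))
  bad <- is.na(vi) & !is.na(raw$visit_index)
  reasons[bad] <- "unparseable visit_index"
  df$visit_index <- vi
  df$sex <- if ("sex" %in% names(raw)) raw$sex else NA_character_
  for (col in .cohort_numeric) {
    if (col %in% names(raw)) {
      v <- suppressWarnings(as.numeric(raw[[col]]))
      bad <- is.na(v) & !is.na(raw[[col]])
      reasons[bad] <- ifelse(reasons[bad] == "",
                             paste0("unparseable ", col),
                             paste0(reasons[bad], "; unparseable ", col))
      df[[col]] <- v
    } else df[[col]] <- NA_real_
  }
  df$on_medication <- if ("on_medication" %in% names(raw)) {
    as.logical(raw$on_medication)
  } else NA

  range_reasons <- .validate_rows(df)
  reasons <- ifelse(reasons == "", range_reasons,
                    ifelse(range_reasons == "", reasons,
                           paste(reasons, range_reasons, sep = "; ")))
  keep <- reasons == "" & !is.na(df$visit_index)
  reasons[reasons == "" & is.na(df$visit_index)] <- "missing visit_index"
  rejected <- data.frame(row = which(!keep), reason = reasons[!keep],
                         stringsAsFactors = FALSE)
  cohort <- as_cohort(df[keep, , drop = FALSE], provenance = path)
  attr(cohort, "rejected") <- rejected
  cohort
}

#' Write a cohort to CSV
#'
#' Missing values are written as empty cells so that
#' `read_cohort(write_cohort(x))` round-trips exactly.
#'
#' @param cohort a `glyco_cohort`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(inherits(cohort, "glyco_cohort"))
  df <- as.data.frame(cohort)[, .cohort_cols]
  utils::write.csv(df, path, row.names = FALSE, na = "", quote = FALSE)
  invisible(path)
}

#' @export
print.glyco_cohort <- function(x, ...) {
  n_part <- length(unique(x$id))
  cat("Longitudinal OGTT cohort: ", n_part, " participants, ",
      nrow(x), " visits (provenance: ",
      attr(x, "provenance") %||% "unspecified", ")\n", sep = "")
  tab <- table(factor(x$visit_index, levels = 0:5))
  cat("  visits per index 0..5:", paste(as.integer(tab), collapse = " "), "\n")
  rej <- attr(x, "rejected")
  if (!is.null(rej) && nrow(rej) > 0)
    cat("  rejected rows on read:", nrow(rej), "\n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
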