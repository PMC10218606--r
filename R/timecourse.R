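.tc_columns <- c("time_min", "E_area", "Z_area", "adduct1_area",
                 "adduct2_area")

new_timecourse <- function(df, meta = list(), concentrations = NULL) {
  stopifnot(all(.tc_columns %in% names(df)))
  df <- df[, .tc_columns]
  structure(df, class = c("timecourse", "data.frame"),
            meta = meta, concentrations = concentrations)
}

#' Metadata of a time course
#' @param tc A `timecourse`.
#' @return Named list of run metadata (compound, thiol, pH pair, seed, ...).
#' @export
tc_meta <- function(tc) attr(tc, "meta")

#' @export
print.timecourse <- function(x, ...) {
  m <- tc_meta(x)
  cat(sprintf("<timecourse> %s + %s, pH %s/%s, %d timepoints\n",
              m$compound %||% "?", m$thiol %||% "?",
              m$pH_aqueous %||% "?", m$pH_virtual %||% "?", nrow(x)))
  print.data.frame(x, ...)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0 || all(is.na(a))) b else a

#' Write a time course to CSV
#'
#' CSV dialect: `#`-prefixed metadata comment lines (`key: value`), one
#' header row `time_min,E_area,Z_area,adduct1_area,adduct2_area`, UTF-8, dot
#' decimal. Numeric formatting is fixed so that a given simulation seed
#' reproduces the file byte for byte.
#'
#' @param tc A `timecourse`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_timecourse <- function(tc, path) {
  stopifnot(inherits(tc, "timecourse"))
  meta <- tc_meta(tc)
  con <- file(path, open = "wb")
  on.exit(close(con))
  for (k in names(meta)) {
    if (!is.null(meta[[k]]) && !is.na(meta[[k]])) {
      writeLines(sprintf("# %s: %s", k, format(meta[[k]], digits = 15)),
                 con, sep = "\n")
    }
  }
  writeLines(paste(.tc_columns, collapse = ","), con, sep = "\n")
  rows <- apply(as.matrix(as.data.frame(tc)), 1,
                function(r) paste(sprintf("%.8g", r), collapse = ","))
  writeLines(rows, con, sep = "\n")
  invisible(path)
}

#' Read a time course CSV
#'
#' Parses the dialect written by [write_timecourse()], validating the schema:
#' all five columns present, areas non-negative, strictly increasing times.
#' Rows out of time order are re-sorted with a warning; any other violation
#' is an error naming the offending column or row.
#'
#' @param path CSV file path.
#' @return A `timecourse` with metadata recovered from the comment lines.
#' @export
load_timecourse <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("file not found: %s", path), call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE)
  if (!length(lines)) stop(sprintf("empty time-course file: %s", path),
                           call. = FALSE)
  is_meta <- grepl("^#", lines)
  meta <- list()
  for (l in lines[is_meta]) {
    kv <- regmatches(l, regexec("^#\\s*([^:]+):\\s*(.*)$", l))[[1]]
    if (length(kv) == 3) {
      val <- kv[3]
      num <- suppressWarnings(as.numeric(val))
      meta[[trimws(kv[2])]] <- if (!is.na(num)) num else val
    }
  }
  body <- lines[!is_meta]
  if (length(body) < 2L) {
    stop(sprintf("no data rows in time-course file: %s", path), call. = FALSE)
  }
  df <- utils::read.csv(textConnection(paste(body, collapse = "\n")),
                        stringsAsFactors = FALSE)
  missing_cols <- setdiff(.tc_columns, names(df))
  if (length(missing_cols)) {
    stop(sprintf("time-course file %s is missing column '%s'",
                 path, missing_cols[1]), call. = FALSE)
  }
  df <- df[, .tc_columns]
  if (any(!vapply(df, is.numeric, logical(1)))) {
    stop(sprintf("non-numeric values in time-course file %s", path),
         call. = FALSE)
  }
  if (anyDuplicated(df$time_min)) {
    stop(sprintf("duplicated timepoints in %s", path), call. = FALSE)
  }
  if (is.unsorted(df$time_min, strictly = TRUE)) {
    warning(sprintf("rows in %s were not in time order; re-sorted", path),
            call. = FALSE)
    df <- df[order(df$time_min), , drop = FALSE]
    rownames(df) <- NULL
  }
  neg <- which(as.matrix(df[, -1]) < 0, arr.ind = TRUE)
  if (nrow(neg)) {
    stop(sprintf("negative area at row %d, column '%s' in %s",
                 neg[1, 1], .tc_columns[-1][neg[1, 2]], path), call. = FALSE)
  }
  new_timecourse(df, meta = meta)
}
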