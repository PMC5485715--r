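# Tabular reader/writer for expression time-course spreadsheets exported as
# CSV/TSV: one header row of observation times (after N leading annotation
# columns), one row per sample; rows sharing a name are replicates.

num_or_na <- function(x) suppressWarnings(as.numeric(x))

#' Read an expression time-course table
#'
#' The expected layout is a delimited text file (CSV or TSV) whose header
#' row carries the observation times; the first `annotation_columns` cells
#' of the header (auto-detected as the leading maximal run of non-numeric
#' header cells when `"auto"`) are annotation columns, the first of which is
#' the sample name. Each subsequent row is one observed sample; rows sharing
#' a name are grouped as replicates of one series. Blank or non-numeric
#' cells are treated as missing and dropped from that replicate only.
#'
#' @param path Path to a CSV (`.csv`) or TSV (anything else) file.
#' @param profile_type `"mRNA"` or `"protein"` for every series in the file.
#' @param annotation_columns Number of leading annotation columns, or
#'   `"auto"`.
#'
#' @return An object of class `expression_dataset`: list with `series` (a
#'   list of [expression_series()]), `annotation_column_count`, `times` (the
#'   header grid), `source` and `profile_type`.
#' @export
read_expression_table <- function(path, profile_type = c("mRNA", "protein"),
                                  annotation_columns = "auto") {
  profile_type <- match.arg(profile_type)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  raw <- utils::read.table(path, sep = sep, header = FALSE,
                           colClasses = "character", stringsAsFactors = FALSE,
                           check.names = FALSE, quote = "\"",
                           blank.lines.skip = TRUE, fill = TRUE)
  if (nrow(raw) < 2L) stop("table must have a header row and at least one data row")
  header <- as.character(raw[1, ])

  if (identical(annotation_columns, "auto")) {
    numeric_hdr <- !is.na(num_or_na(header))
    n_ann <- if (any(numeric_hdr)) which(numeric_hdr)[1] - 1L else length(header)
  } else {
    n_ann <- as.integer(annotation_columns)
  }
  if (n_ann >= length(header))
    stop("no numeric time columns found in header: ",
         paste(utils::head(header, 8), collapse = ", "))
  times <- num_or_na(header[(n_ann + 1L):length(header)])
  if (any(is.na(times)))
    stop("non-numeric time cell(s) in header: ",
         paste(header[(n_ann + 1L):length(header)][is.na(times)], collapse = ", "))
  if (any(diff(times) <= 0))
    stop("header observation times must be strictly increasing")

  body <- raw[-1, , drop = FALSE]
  names_col <- if (n_ann >= 1L) as.character(body[[1]]) else
    paste0("series", seq_len(nrow(body)))
  series <- list()
  for (nm in unique(names_col)) {
    rows <- which(names_col == nm)
    tt <- list(); vv <- list()
    for (i in rows) {
      vals <- num_or_na(as.character(body[i, (n_ann + 1L):ncol(body)]))
      keep <- !is.na(vals)
      tt[[length(tt) + 1L]] <- times[keep]
      vv[[length(vv) + 1L]] <- vals[keep]
    }
    ann <- if (n_ann >= 2L) as.character(body[rows[1], 2:n_ann]) else character()
    series[[nm]] <- expression_series(
      name = nm, times = tt, values = vv, profile_type = profile_type,
      annotations = ann,
      replicate_ids = paste0("r", seq_along(rows)))
  }

  structure(list(series = series, annotation_column_count = n_ann,
                 times = times, source = path, profile_type = profile_type),
            class = "expression_dataset")
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat(sprintf("<expression_dataset> %d series (%s), %d time points, %d annotation column(s)\n",
              length(x$series), x$profile_type, length(x$times),
              x$annotation_column_count))
  invisible(x)
}

#' Write an expression dataset back to a delimited table
#'
#' Inverse of [read_expression_table()]: one header row of times after the
#' annotation columns, one row per replicate. Values are written at full
#' precision so that a read/write round trip reproduces the numeric content.
#'
#' @param dataset An `expression_dataset`.
#' @param path Output path; `.csv` selects comma separation, otherwise tab.
#' @return Invisibly, `path`.
#' @export
write_expression_table <- function(dataset, path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  times <- dataset$times
  n_ann <- max(dataset$annotation_column_count, 1L)
  rows <- list(c("name", if (n_ann > 1) paste0("annotation", seq_len(n_ann - 1L)),
                 format(times, digits = 17, trim = TRUE, scientific = FALSE)))
  for (s in dataset$series) {
    ann <- c(s$name, rep("", n_ann - 1L))
    if (length(s$annotations)) ann[seq_along(s$annotations) + 1L] <- s$annotations
    for (r in seq_along(s$times)) {
      vals <- rep("", length(times))
      idx <- match(s$times[[r]], times)
      vals[idx] <- format(s$values[[r]], digits = 17, trim = TRUE)
      rows[[length(rows) + 1L]] <- c(ann, vals)
    }
  }
  con <- file(path, "w")
  on.exit(close(con))
  for (r in rows) writeLines(paste(r, collapse = sep), con)
  invisible(path)
}

#' Combine or split replicates of every series in a dataset
#'
#' @param dataset An `expression_dataset`.
#' @param mode `"pool"` keeps all replicate points as repeated observations
#'   of one series; `"median"` collapses replicates to per-time medians;
#'   `"separate"` yields one series per replicate.
#' @return A new `expression_dataset`.
#' @export
combine_replicates <- function(dataset, mode = c("pool", "median", "separate")) {
  mode <- match.arg(mode)
  out <- list()
  for (s in dataset$series) {
    if (length(s$times) == 1L || mode == "pool") {
      out[[s$name]] <- s      # pooling is representational: replicates kept
      next
    }
    if (mode == "median") {
      tt <- sort(unique(unlist(s$times)))
      med <- vapply(tt, function(t0) {
        stats::median(unlist(mapply(function(ts, vs) vs[ts == t0],
                                    s$times, s$values, SIMPLIFY = FALSE)))
      }, numeric(1))
      out[[s$name]] <- expression_series(s$name, tt, med,
                                         profile_type = s$profile_type,
                                         annotations = s$annotations)
    } else {
      for (r in seq_along(s$times)) {
        nm <- paste0(s$name, ".", s$replicate_ids[r])
        out[[nm]] <- expression_series(nm, s$times[[r]], s$values[[r]],
                                       profile_type = s$profile_type,
                                       annotations = s$annotations)
      }
    }
  }
  structure(list(series = out,
                 annotation_column_count = dataset$annotation_column_count,
                 times = dataset$times, source = dataset$source,
                 profile_type = dataset$profile_type),
            class = "expression_dataset")
}

#' Linear detrend of a series
#'
#' Removes an ordinary least-squares straight-line trend from each replicate
#' (fitted on the pooled observations) and restores the series mean, as a
#' pre-processing option for slowly drifting reporter baselines.
#'
#' @param series An [expression_series()].
#' @return A detrended `expression_series`.
#' @export
detrend_linear <- function(series) {
  pl <- pool_series(series)
  co <- stats::coef(stats::lm.fit(cbind(1, pl$times), pl$values))
  m <- mean(pl$values)
  values <- lapply(seq_along(series$times), function(r)
    series$values[[r]] - (co[1] + co[2] * series$times[[r]]) + m)
  series$values <- values
  series
}
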