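#' Write concentration time courses to a tidy CSV
#'
#' Long format, one row per sample, with explicit units in the column
#' names: \code{animal_id}, \code{group}, \code{analyte}, \code{time_h},
#' \code{concentration_ng_ml}, \code{below_loq}.
#'
#' @param series_list List of \code{\link{conc_series}}.
#' @param path Output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_timecourses <- function(series_list, path) {
  stopifnot(is.list(series_list), length(series_list) >= 1)
  rows <- lapply(series_list, function(s) {
    stopifnot(inherits(s, "conc_series"))
    data.frame(animal_id = s$animal_id, group = s$group,
               analyte = s$analyte, time_h = s$time_h,
               concentration_ng_ml = s$conc_ng_ml,
               below_loq = s$below_loq, stringsAsFactors = FALSE)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Read concentration time courses from a tidy CSV
#'
#' Expects the schema written by \code{\link{write_timecourses}}
#' (\code{below_loq} optional) and splits rows into one
#' \code{\link{conc_series}} per animal x analyte, sorted by time.
#' Validates the series invariants and names the offending row on
#' failure.
#'
#' @param path CSV path.
#' @return A list of \code{\link{conc_series}}.
#' @export
read_timecourses <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("animal_id", "group", "analyte", "time_h",
                "concentration_ng_ml")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("missing required columns: ", paste(missing, collapse = ", "))
  }
  if (!"below_loq" %in% names(df)) df$below_loq <- FALSE
  bad <- which(df$time_h < 0)
  if (length(bad)) {
    stop("negative time_h at row ", bad[1])
  }
  key <- interaction(df$animal_id, df$analyte, drop = TRUE)
  out <- lapply(split(df, key), function(d) {
    d <- d[order(d$time_h), ]
    if (any(duplicated(d$time_h))) {
      stop("duplicated time points for animal ", d$animal_id[1],
           ", analyte ", d$analyte[1])
    }
    conc_series(animal_id = d$animal_id[1], group = d$group[1],
                analyte = d$analyte[1], time_h = d$time_h,
                conc_ng_ml = d$concentration_ng_ml,
                below_loq = as.logical(d$below_loq))
  })
  names(out) <- NULL
  out
}

#' Write a per-animal feature table to CSV
#'
#' @param features Data.frame as produced by
#'   \code{\link{generate_features}} (or assembled from measurements).
#' @param path Output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_features <- function(features, path) {
  stopifnot(is.data.frame(features))
  utils::write.csv(features, path, row.names = FALSE)
  invisible(path)
}

#' Read a per-animal feature table from CSV
#'
#' @param path CSV path; must contain \code{animal_id} and \code{group}
#'   columns.
#' @return A data.frame.
#' @export
read_features <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(c("animal_id", "group"), names(df))
  if (length(missing)) {
    stop("missing required columns: ", paste(missing, collapse = ", "))
  }
  df
}
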