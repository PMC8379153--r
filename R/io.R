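#' Read a molecule-list localization table
#'
#' Parses a CSV with header columns `x_nm,y_nm,frame`. Extra columns are
#' preserved untouched in the table's `extra` slot and written back by
#' [writeLocalizations()].
#'
#' @param path path to the CSV file.
#' @return a [LocalizationTable].
#' @export
readLocalizations <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE)
  need <- c("x_nm", "y_nm", "frame")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("missing required column(s): ", paste(miss, collapse = ", "))
  }
  for (colname in c("x_nm", "y_nm")) {
    v <- df[[colname]]
    if (!is.numeric(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(as.character(v)))))[1]
      stop(sprintf("non-numeric %s at data line %d of %s", colname, bad, path))
    }
    if (any(!is.finite(v))) {
      stop(sprintf("non-finite %s at data line %d of %s", colname,
                   which(!is.finite(v))[1], path))
    }
  }
  extra <- df[setdiff(names(df), need)]
  localizationTable(df$x_nm, df$y_nm, as.integer(df$frame), extra = extra)
}

#' Write a localization table as molecule-list CSV
#'
#' @param table a [LocalizationTable].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeLocalizations <- function(table, path) {
  stopifnot(is(table, "LocalizationTable"))
  utils::write.csv(as.data.frame(table), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write / read a ground-truth sidecar table
#'
#' The sidecar has one row per designed site:
#' `object_id,site_index,x_true_nm,y_true_nm,visible,dx_gel_nm,dy_gel_nm`.
#'
#' @param truth the `truth` data.frame from [simulateField()].
#' @param path file path.
#' @return `path` (write) or the data.frame (read).
#' @export
writeGroundTruth <- function(truth, path) {
  utils::write.csv(truth, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeGroundTruth
#' @export
readGroundTruth <- function(path) {
  utils::read.csv(path)
}
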