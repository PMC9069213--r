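#' Read and write the samples-by-arms Z matrix as TSV
#'
#' First column `sample_id`, one column per arm; values written in full
#' precision so write-read is an identity.
#'
#' @param z Numeric matrix with sample row names and arm column names.
#' @param path File path.
#' @return `write_z_matrix` the path invisibly; `read_z_matrix` the matrix.
#' @export
write_z_matrix <- function(z, path) {
  df <- data.frame(sample_id = rownames(z), z, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_z_matrix
#' @export
read_z_matrix <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE)
  if (nrow(df) == 0) stop("empty Z matrix in ", path)
  z <- as.matrix(df[, -1, drop = FALSE])
  rownames(z) <- df$sample_id
  z
}

#' Read and write the cohort sample sheet (CSV)
#'
#' Columns: `sample_id`, `group` (PCa/BPH/PIN), optional `gleason` (as
#' `"a+b"` text), `psa_total`, `psa_free`, `ft_percent`. Dash entries
#' (`-` or the typographic dash) are read as missing, as printed in
#' clinical tables.
#'
#' @param sheet data.frame to write.
#' @param path File path.
#' @return `write_sample_sheet` the path invisibly; `read_sample_sheet`
#'   a data.frame.
#' @export
read_sample_sheet <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        na.strings = c("NA", "", "-", "–"))
  if (!all(c("sample_id", "group") %in% names(df)))
    stop("sample sheet needs sample_id and group columns: ", path)
  df$sample_id <- as.character(df$sample_id)
  df
}

#' @rdname read_sample_sheet
#' @export
write_sample_sheet <- function(sheet, path) {
  utils::write.csv(sheet, path, row.names = FALSE, na = "-")
  invisible(path)
}

#' Write diagnostic metrics as JSON
#'
#' Fractions, display percents (half-up, 1 decimal) and CI bounds for each
#' metric, plus Youden's J and the counts.
#'
#' @param metrics A [confusion_metrics()] object.
#' @param path File path.
#' @return The path, invisibly.
#' @export
write_metrics_json <- function(metrics, path) {
  stopifnot(inherits(metrics, "diag_metrics"))
  out <- list(counts = metrics$counts[c("tn", "tp", "fn", "fp")],
              fraction = as.list(metrics$estimate),
              percent = as.list(metrics$percent),
              ci = apply(metrics$ci, 1, function(r) as.list(r), simplify = FALSE),
              youden_j = metrics$youden_j, conf = metrics$conf)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Write ROC points as CSV
#' @param roc A [roc_auc()] result.
#' @param path File path.
#' @return The path, invisibly.
#' @export
write_roc_csv <- function(roc, path) {
  stopifnot(inherits(roc, "roc_result"))
  utils::write.csv(roc$points, path, row.names = FALSE)
  invisible(path)
}
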