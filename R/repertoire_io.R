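# Reading and writing clonotype tables, cohort manifests, and metrics tables.
#
# Input is the AIRR Rearrangement TSV dialect (columns v_call, j_call,
# junction, optional junction_aa and duplicate_count). junction_aa from the
# file is always ignored and recomputed by translation so that the nucleotide
# and amino-acid levels are internally consistent.

#' Read a repertoire sample from an AIRR rearrangement TSV
#'
#' Parses a tab-delimited rearrangement table, validates the junctions, and
#' collapses records into clonotypes. Unproductive junctions (out of frame or
#' containing a stop codon) are excluded with their read mass recorded in the
#' sample's discard tally; parsing is lossless for counts
#' (`depth + discarded_reads` equals the file's total `duplicate_count`).
#'
#' @param path Path to the TSV file. Must contain columns `v_call`, `j_call`,
#'   `junction`; `duplicate_count` is optional and defaults to 1 per record.
#' @param format Input dialect; only `"airr_tsv"` is supported.
#' @param sample_id Identifier stored in the returned sample; defaults to the
#'   file name without extension.
#' @return A [repertoire_sample()].
#' @export
read_repertoire <- function(path, format = c("airr_tsv"), sample_id = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- tryCatch(
    read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
               colClasses = NA, check.names = FALSE),
    error = function(e) stop("empty or unreadable input: ", path, call. = FALSE)
  )
  required <- c("v_call", "j_call", "junction")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols)) {
    stop("format error: missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (nrow(raw) == 0L) stop("empty input: no records in ", path, call. = FALSE)
  cl <- collapse_clonotypes(raw)
  discarded <- attr(cl, "discarded_reads")
  attr(cl, "discarded_reads") <- NULL
  repertoire_sample(
    cl,
    sample_id = sample_id %||% sub("\\.[^.]*$", "", basename(path)),
    discarded_reads = discarded
  )
}

#' Read a cohort manifest
#'
#' The manifest is a comma-delimited file with one row per patient and columns
#' `patient_id`, `response` (PR, SD, PD, or NE), `os_days`, `event`
#' (1 = death, 0 = censored), and one path column per time point (`T1`, `T2`,
#' `T3`). An empty path encodes sample unavailability (death, QC failure,
#' withdrawal), so attrition can be tabulated; non-empty relative paths are
#' resolved against the manifest's directory. The response group is derived:
#' PR/SD form the disease control group (DCG), PD stays PD, NE is left
#' unclassified (`NA`).
#'
#' @param path Path to the manifest CSV.
#' @return A data.frame of class `cohort_manifest` with columns `patient_id`,
#'   `response`, `group`, `os_days`, `event`, `T1`, `T2`, `T3`.
#' @export
read_cohort_manifest <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  m <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  required <- c("patient_id", "response", "os_days", "event")
  missing_cols <- setdiff(required, names(m))
  if (length(missing_cols)) {
    stop("manifest missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  tp_cols <- intersect(c("T1", "T2", "T3"), names(m))
  if (!length(tp_cols)) {
    stop("manifest must contain at least one time-point path column (T1/T2/T3)",
         call. = FALSE)
  }
  for (tp in setdiff(c("T1", "T2", "T3"), tp_cols)) m[[tp]] <- ""
  if (anyDuplicated(m$patient_id)) {
    stop("duplicate patient_id in manifest: ",
         paste(unique(m$patient_id[duplicated(m$patient_id)]), collapse = ", "),
         call. = FALSE)
  }
  bad_resp <- !m$response %in% c("PR", "SD", "PD", "NE")
  if (any(bad_resp)) {
    stop("invalid response value(s): ",
         paste(unique(m$response[bad_resp]), collapse = ", "), call. = FALSE)
  }
  if (any(is.na(m$os_days)) || any(m$os_days < 0)) {
    stop("os_days must be non-negative", call. = FALSE)
  }
  if (!all(m$event %in% c(0, 1))) {
    stop("event must be 0 (censored) or 1 (death)", call. = FALSE)
  }
  m$group <- ifelse(m$response %in% c("PR", "SD"), "DCG",
                    ifelse(m$response == "PD", "PD", NA_character_))
  base <- dirname(normalizePath(path))
  for (tp in c("T1", "T2", "T3")) {
    p <- m[[tp]]
    p[is.na(p)] <- ""
    rel <- nzchar(p) & !grepl("^(/|[A-Za-z]:)", p)
    p[rel] <- file.path(base, p[rel])
    m[[tp]] <- p
  }
  out <- m[, c("patient_id", "response", "group", "os_days", "event",
               "T1", "T2", "T3")]
  class(out) <- c("cohort_manifest", "data.frame")
  out
}

.metrics_columns <- c("patient_id", "timepoint", "group", "depth",
                      "unique_clones", "shannon", "evenness", "convergence")

#' Write a per-sample metrics table
#'
#' Writes one row per sample in the fixed column order (`patient_id`,
#' `timepoint`, `group`, `depth`, `unique_clones`, `shannon`, `evenness`,
#' `convergence`) as tab-delimited text. Real-valued columns are serialized
#' with 17 significant digits so that [read_metrics_table()] reproduces the
#' stored values exactly.
#'
#' @param metrics A non-empty data.frame of per-sample metrics.
#' @param path Output path.
#' @export
write_metrics_table <- function(metrics, path) {
  if (!is.data.frame(metrics) || nrow(metrics) == 0L) {
    stop("`metrics` must be a non-empty data.frame", call. = FALSE)
  }
  missing_cols <- setdiff(.metrics_columns, names(metrics))
  if (length(missing_cols)) {
    stop("metrics table missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  out <- metrics[, .metrics_columns, drop = FALSE]
  for (col in c("shannon", "evenness", "convergence")) {
    out[[col]] <- ifelse(is.na(out[[col]]), NA_character_,
                         formatC(out[[col]], digits = 17, format = "g"))
  }
  ok <- tryCatch({
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                na = "NA")
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop("could not write metrics table to ", path, call. = FALSE)
  invisible(path)
}

#' Read a per-sample metrics table written by [write_metrics_table()]
#'
#' @param path Path to the tab-delimited metrics table.
#' @return A data.frame with the fixed metrics columns.
#' @export
read_metrics_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  m <- read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  missing_cols <- setdiff(.metrics_columns, names(m))
  if (length(missing_cols)) {
    stop("metrics table missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  m[, .metrics_columns, drop = FALSE]
}
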