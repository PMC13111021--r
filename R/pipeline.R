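# End-to-end orchestration: ingest -> rarefaction QC -> per-sample metrics ->
# longitudinal deltas -> clone-frequency PCA -> primary tests with BH-FDR ->
# Kaplan-Meier survival -> attrition accounting.
#
# Pooled inferential analyses are restricted to T1/T2; T3 samples are
# summarized descriptively per patient and never enter group tests. The BH
# family is exactly the registered primary tests (default three), because
# only the primary inferential family is FDR-corrected while other reported
# p-values stay descriptive.

#' Pipeline run configuration
#'
#' @param manifest Path to a cohort manifest CSV (see
#'   [read_cohort_manifest()]).
#' @param out_dir Output directory for the report tables and run log.
#' @param rarefaction_depth Either `"min"` (rarefy every sample to the
#'   minimum depth observed across loaded samples) or a fixed positive
#'   integer; samples below a fixed target are excluded with a logged
#'   reason.
#' @param seed Single global seed governing every rarefaction draw; recorded
#'   in the run log.
#' @param top_m Maximum clonotype columns for the PCA frequency matrix.
#' @param primary_tests Names of the registered primary tests forming the
#'   BH family. Available: `"spearman_convergence_trend_dcg"`,
#'   `"wilcoxon_delta_clones"`, `"wilcoxon_pc1_group"`.
#' @param alpha Significance threshold applied to both p and q.
#' @return A list of class `run_config`.
#' @export
run_config <- function(manifest, out_dir = tempfile("tcrdyn_run_"),
                       rarefaction_depth = "min", seed = 1L, top_m = 500L,
                       primary_tests = c("spearman_convergence_trend_dcg",
                                         "wilcoxon_delta_clones",
                                         "wilcoxon_pc1_group"),
                       alpha = 0.05) {
  known <- c("spearman_convergence_trend_dcg", "wilcoxon_delta_clones",
             "wilcoxon_pc1_group")
  if (!length(primary_tests) || !all(primary_tests %in% known)) {
    stop("`primary_tests` must be a non-empty subset of: ",
         paste(known, collapse = ", "), call. = FALSE)
  }
  if (!identical(rarefaction_depth, "min") &&
      (!is.numeric(rarefaction_depth) || rarefaction_depth <= 0)) {
    stop("`rarefaction_depth` must be \"min\" or a positive number",
         call. = FALSE)
  }
  structure(
    list(manifest = manifest, out_dir = out_dir,
         rarefaction_depth = rarefaction_depth, seed = as.integer(seed),
         top_m = as.integer(top_m), primary_tests = primary_tests,
         alpha = alpha),
    class = "run_config"
  )
}

#' Attrition accounting across study stages
#'
#' Tabulates how many patients survive each evaluability stage given a list
#' of per-patient exclusions. Stages are ordered `enrolled`,
#' `T1-evaluable`, `T2-evaluable`, `T3-evaluable`; sampling attrition is
#' sequential (a patient excluded at T2 is also absent at T3). The
#' `OS-evaluable` stage is counted from the T1-evaluable population minus
#' exclusions recorded at the OS stage (survival follow-up is independent of
#' later sample availability: death before T2 removes a patient from the T2
#' analysis but not from the survival analysis).
#'
#' @param manifest A `cohort_manifest` data.frame of enrolled patients, or a
#'   single integer giving the enrolled count.
#' @param exclusions `NULL`, or a data.frame with columns `patient_id`,
#'   `stage` (one of `"T1-evaluable"`, `"T2-evaluable"`, `"T3-evaluable"`,
#'   `"OS-evaluable"`), and `reason`.
#' @return A list of class `attrition_table` with `counts` (stage, n) and
#'   `reasons` (stage, reason, n).
#' @examples
#' excl <- data.frame(
#'   patient_id = paste0("X", 1:8),
#'   stage = "T1-evaluable",
#'   reason = "insufficient RNA quality"
#' )
#' attrition_accounting(42, excl)$counts
#' @export
attrition_accounting <- function(manifest, exclusions = NULL) {
  n_enrolled <- if (is.numeric(manifest) && length(manifest) == 1L) {
    as.integer(manifest)
  } else if (is.data.frame(manifest)) {
    nrow(manifest)
  } else {
    stop("`manifest` must be a cohort manifest or an enrolled count",
         call. = FALSE)
  }
  stages <- c("T1-evaluable", "T2-evaluable", "T3-evaluable", "OS-evaluable")
  if (is.null(exclusions)) {
    exclusions <- data.frame(patient_id = character(), stage = character(),
                             reason = character(), stringsAsFactors = FALSE)
  }
  needed <- c("patient_id", "stage", "reason")
  if (!is.data.frame(exclusions) || !all(needed %in% names(exclusions))) {
    stop("`exclusions` must have columns ", paste(needed, collapse = ", "),
         call. = FALSE)
  }
  unknown <- setdiff(unique(exclusions$stage), stages)
  if (length(unknown)) {
    stop("unknown stage(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  n_at <- function(stage) sum(exclusions$stage == stage)
  t1 <- n_enrolled - n_at("T1-evaluable")
  t2 <- t1 - n_at("T2-evaluable")
  t3 <- t2 - n_at("T3-evaluable")
  os <- t1 - n_at("OS-evaluable")
  counts <- data.frame(
    stage = c("enrolled", stages),
    n = c(n_enrolled, t1, t2, t3, os),
    stringsAsFactors = FALSE
  )
  reasons <- if (nrow(exclusions)) {
    agg <- aggregate(patient_id ~ stage + reason, exclusions, length)
    names(agg)[3L] <- "n"
    agg[order(agg$stage, agg$reason), , drop = FALSE]
  } else {
    data.frame(stage = character(), reason = character(), n = integer(),
               stringsAsFactors = FALSE)
  }
  rownames(reasons) <- NULL
  structure(list(counts = counts, reasons = reasons),
            class = "attrition_table")
}

#' @export
print.attrition_table <- function(x, ...) {
  cat("<attrition_table>\n")
  print(x$counts, row.names = FALSE)
  invisible(x)
}

# One registered primary test; failures become not-evaluable rows so the
# pipeline keeps going when a test's inputs are degenerate.
.not_evaluable <- function(name, note) {
  out <- test_result(name, NA_real_, NA_real_)
  out$evaluable <- FALSE
  out$note <- note
  out
}

.run_primary_test <- function(name, metrics12, deltas, pca, pca_groups) {
  res <- tryCatch({
    if (name == "spearman_convergence_trend_dcg") {
      d <- metrics12[!is.na(metrics12$group) & metrics12$group == "DCG", ,
                     drop = FALSE]
      if (nrow(d) < 3L) stop("fewer than 3 DCG samples")
      out <- spearman_trend(d$convergence, d$timepoint,
                            name = "spearman_convergence_trend_dcg")
    } else if (name == "wilcoxon_delta_clones") {
      x <- deltas$delta_clones[deltas$group %in% "DCG"]
      y <- deltas$delta_clones[deltas$group %in% "PD"]
      if (!length(x) || !length(y)) stop("a response group is empty")
      out <- wilcoxon_rank_sum(x, y, name = "wilcoxon_delta_clones")
    } else if (name == "wilcoxon_pc1_group") {
      if (is.null(pca)) stop("PCA unavailable")
      out <- pc_group_test(pca, pca_groups, component = 1L)$test
      out$name <- "wilcoxon_pc1_group"
    } else {
      stop("unknown primary test: ", name)
    }
    out$evaluable <- TRUE
    out$note <- ""
    out
  }, error = function(e) .not_evaluable(name, conditionMessage(e)))
  res
}

#' Run the full repertoire-dynamics analysis
#'
#' Ingests a cohort manifest and its AIRR rearrangement tables, applies
#' rarefaction QC, computes per-sample metrics and per-patient T1-to-T2
#' deltas, performs clone-frequency PCA, runs the registered primary tests
#' with Benjamini-Hochberg correction over exactly that family, estimates
#' Kaplan-Meier survival by response group, and tabulates attrition. All
#' randomness (the rarefaction draws) is governed by `config$seed`;
#' re-running with the same config and inputs reproduces every numeric
#' output bit-identically. Outputs are written as delimited tables plus a
#' JSON-lines run log under `config$out_dir`.
#'
#' @param config A [run_config()].
#' @return A list of class `run_report`: `metrics`, `deltas`, `tests`
#'   (one row per registered test with `p`, `q`, `significant`),
#'   `pca` (`pca_result` or `NULL`), `pca_scores` (data.frame), `km`
#'   (`km_result` or `NULL`), `attrition`, `exclusions`,
#'   `rarefaction_depth`, `seed`.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "run_config")) {
    stop("`config` must be a run_config", call. = FALSE)
  }
  manifest <- read_cohort_manifest(config$manifest)
  timepoints <- c("T1", "T2", "T3")

  # -- ingest ---------------------------------------------------------------
  raw_samples <- list()
  sample_info <- list()
  exclusions <- list()
  for (i in seq_len(nrow(manifest))) {
    for (tp in timepoints) {
      path <- manifest[[tp]][i]
      if (!nzchar(path)) {
        exclusions[[length(exclusions) + 1L]] <- data.frame(
          patient_id = manifest$patient_id[i],
          stage = paste0(tp, "-evaluable"),
          reason = "no sample available", stringsAsFactors = FALSE
        )
        next
      }
      key <- paste0(manifest$patient_id[i], "_", tp)
      raw_samples[[key]] <- read_repertoire(path, sample_id = key)
      sample_info[[key]] <- data.frame(
        patient_id = manifest$patient_id[i], timepoint = tp,
        group = manifest$group[i], stringsAsFactors = FALSE
      )
    }
  }
  if (!length(raw_samples)) stop("no readable samples in manifest", call. = FALSE)

  # -- rarefaction QC -------------------------------------------------------
  depths <- vapply(raw_samples, function(s) s$depth, numeric(1))
  target <- if (identical(config$rarefaction_depth, "min")) {
    min(depths)
  } else {
    as.numeric(config$rarefaction_depth)
  }
  pass <- depths >= target
  if (!any(pass)) {
    stop("no sample meets the rarefaction depth of ", target, call. = FALSE)
  }
  for (key in names(raw_samples)[!pass]) {
    info <- sample_info[[key]]
    exclusions[[length(exclusions) + 1L]] <- data.frame(
      patient_id = info$patient_id,
      stage = paste0(info$timepoint, "-evaluable"),
      reason = paste0("below rarefaction depth (", depths[[key]], " < ",
                      target, ")"),
      stringsAsFactors = FALSE
    )
  }
  keys <- names(raw_samples)[pass]
  rarefied <- lapply(seq_along(keys), function(i) {
    rarefy(raw_samples[[keys[i]]], target, seed = config$seed + i)
  })
  names(rarefied) <- keys

  # -- per-sample metrics and deltas ---------------------------------------
  metrics <- do.call(rbind, lapply(keys, function(key) {
    info <- sample_info[[key]]
    sample_metrics(rarefied[[key]], info$patient_id, info$timepoint,
                   info$group)
  }))
  rownames(metrics) <- NULL
  metrics12 <- metrics[metrics$timepoint %in% c("T1", "T2"), , drop = FALSE]
  deltas <- delta_metrics(metrics12)

  # -- PCA on T1/T2 samples of classified patients --------------------------
  pca_keys <- keys[vapply(keys, function(key) {
    info <- sample_info[[key]]
    info$timepoint %in% c("T1", "T2") && !is.na(info$group)
  }, logical(1))]
  pca <- NULL
  pca_groups <- character(0)
  pca_scores_tab <- data.frame()
  if (length(pca_keys) >= 3L) {
    fm <- build_frequency_matrix(rarefied[pca_keys], top_m = config$top_m)
    k <- min(2L, nrow(fm) - 1L, ncol(fm))
    pca_try <- tryCatch(pca_scores(fm, k), error = function(e) NULL)
    if (!is.null(pca_try)) {
      pca <- pca_try
      pca_groups <- vapply(pca_keys, function(key) sample_info[[key]]$group,
                           "")
      pca_scores_tab <- data.frame(
        sample = rownames(pca$scores),
        patient_id = vapply(pca_keys,
                            function(key) sample_info[[key]]$patient_id, ""),
        timepoint = vapply(pca_keys,
                           function(key) sample_info[[key]]$timepoint, ""),
        group = pca_groups,
        stringsAsFactors = FALSE
      )
      for (c in seq_len(ncol(pca$scores))) {
        pca_scores_tab[[paste0("PC", c)]] <- pca$scores[, c]
      }
      rownames(pca_scores_tab) <- NULL
    }
  }

  # -- primary tests with BH over the registered family ---------------------
  tests <- do.call(rbind, lapply(config$primary_tests, .run_primary_test,
                                 metrics12 = metrics12, deltas = deltas,
                                 pca = pca, pca_groups = pca_groups))
  ok <- !is.na(tests$p)
  if (any(ok)) tests$q[ok] <- bh_adjust(tests$p[ok])
  tests$significant <- !is.na(tests$p) & !is.na(tests$q) &
    tests$p < config$alpha & tests$q < config$alpha
  rownames(tests) <- NULL

  # -- survival -------------------------------------------------------------
  surv_rows <- manifest[!is.na(manifest$group), , drop = FALSE]
  km <- NULL
  if (nrow(surv_rows) && length(unique(surv_rows$group)) >= 1L) {
    km <- km_logrank(surv_rows$os_days, surv_rows$event, surv_rows$group)
  }

  # -- attrition ------------------------------------------------------------
  excl_tab <- if (length(exclusions)) do.call(rbind, exclusions) else NULL
  attrition <- attrition_accounting(manifest, excl_tab)

  # -- write report ---------------------------------------------------------
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  write_metrics_table(metrics, file.path(config$out_dir, "metrics.tsv"))
  if (nrow(deltas)) {
    write.table(deltas, file.path(config$out_dir, "deltas.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  write.table(tests, file.path(config$out_dir, "tests.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  if (nrow(pca_scores_tab)) {
    write.table(pca_scores_tab, file.path(config$out_dir, "pca_scores.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  write.table(attrition$counts, file.path(config$out_dir, "attrition.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  log_path <- file.path(config$out_dir, "run_log.jsonl")
  log_lines <- c(
    jsonlite::toJSON(list(event = "run", seed = config$seed,
                          rarefaction_depth = target,
                          n_samples = length(keys),
                          n_patients = nrow(manifest)),
                    auto_unbox = TRUE),
    if (!is.null(excl_tab)) {
      vapply(seq_len(nrow(excl_tab)), function(i) {
        as.character(jsonlite::toJSON(
          list(event = "exclusion", patient_id = excl_tab$patient_id[i],
               stage = excl_tab$stage[i], reason = excl_tab$reason[i]),
          auto_unbox = TRUE))
      }, "")
    }
  )
  writeLines(log_lines, log_path)

  structure(
    list(metrics = metrics, deltas = deltas, tests = tests, pca = pca,
         pca_scores = pca_scores_tab, km = km, attrition = attrition,
         exclusions = excl_tab, rarefaction_depth = target,
         seed = config$seed, out_dir = config$out_dir),
    class = "run_report"
  )
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report> seed", x$seed, "| rarefaction depth",
      x$rarefaction_depth, "\n")
  cat("  samples:", nrow(x$metrics), " patients with deltas:",
      nrow(x$deltas), "\n")
  cat("  primary tests:\n")
  print(x$tests[, c("name", "statistic", "p", "q", "significant")],
        row.names = FALSE, digits = 4)
  if (!is.null(x$km) && x$km$p_defined) {
    cat("  log-rank p:", signif(x$km$p, 4), "\n")
  }
  invisible(x)
}
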