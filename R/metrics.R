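# Per-sample repertoire summary statistics and rarefaction.
#
# All metrics are intended to be computed on samples rarefied to a common
# sequencing depth so that they are comparable across samples. Shannon
# diversity uses the natural logarithm (the base cancels in Pielou evenness).

#' Rarefy a repertoire sample to a target depth
#'
#' Draws exactly `depth` reads without replacement from the sample's reads
#' (multivariate hypergeometric over clonotype counts, via
#' [vegan::rrarefy()]). Clonotypes that receive zero drawn reads are removed.
#' The draw is deterministic given `seed` and leaves the caller's RNG state
#' untouched.
#'
#' @param sample A `repertoire_sample`.
#' @param depth Target depth; must be positive and at most the sample depth.
#'   When equal to the sample depth the draw is exhaustive and the counts are
#'   returned unchanged.
#' @param seed Integer seed for the subsampling draw.
#' @return A rarefied `repertoire_sample` whose depth equals `depth`.
#' @export
rarefy <- function(sample, depth, seed) {
  if (!inherits(sample, "repertoire_sample")) {
    stop("`sample` must be a repertoire_sample", call. = FALSE)
  }
  if (!is.numeric(depth) || length(depth) != 1L || depth <= 0 ||
      depth != floor(depth)) {
    stop("`depth` must be a positive integer", call. = FALSE)
  }
  if (depth > sample$depth) {
    stop("target depth (", depth, ") exceeds sample depth (", sample$depth,
         "): sample fails rarefaction QC", call. = FALSE)
  }
  if (depth == sample$depth) return(sample)
  counts <- sample$clonotypes$count
  drawn <- with_seed(seed, {
    withCallingHandlers(
      as.vector(vegan::rrarefy(matrix(counts, nrow = 1L), depth)),
      # vegan flags repertoires whose rarest clonotype has >1 read as possibly
      # non-count data; our inputs are genuine read counts
      warning = function(w) {
        if (grepl("smallest count", conditionMessage(w))) {
          invokeRestart("muffleWarning")
        }
      }
    )
  })
  keep <- drawn > 0
  cl <- sample$clonotypes[keep, , drop = FALSE]
  cl$count <- drawn[keep]
  cl <- cl[order(-cl$count, cl$cdr3_nt, cl$v_gene, cl$j_gene), , drop = FALSE]
  rownames(cl) <- NULL
  repertoire_sample(cl, sample_id = sample$sample_id,
                    discarded_reads = sample$discarded_reads)
}

#' Shannon diversity of a clonotype frequency vector
#'
#' `H = -sum(p_i * ln(p_i))`, in nats. All frequencies must be strictly
#' positive and sum to 1 within a tolerance of 1e-9.
#'
#' @param freqs Numeric vector of clonotype relative frequencies.
#' @return Shannon diversity in nats (0 for a single clone).
#' @examples
#' shannon_diversity(rep(0.25, 4))        # ln 4
#' shannon_diversity(c(0.5, 0.25, 0.25))  # 1.039721
#' @export
shannon_diversity <- function(freqs) {
  if (!is.numeric(freqs) || length(freqs) == 0L) {
    stop("`freqs` must be a non-empty numeric vector", call. = FALSE)
  }
  if (any(is.na(freqs)) || any(freqs <= 0)) {
    stop("frequencies must be strictly positive", call. = FALSE)
  }
  if (abs(sum(freqs) - 1) > 1e-9) {
    stop("frequencies must sum to 1 (tolerance 1e-9); got ", sum(freqs),
         call. = FALSE)
  }
  unname(vegan::diversity(freqs, index = "shannon"))
}

#' Pielou evenness of a clonotype frequency vector
#'
#' `J = H / ln(S)` where `S` is the number of clones. Undefined (returned as
#' `NA`) for a single-clone repertoire.
#'
#' @inheritParams shannon_diversity
#' @return Evenness in `[0, 1]`, or `NA` when `S = 1`.
#' @examples
#' pielou_evenness(rep(1 / 5, 5))        # 1
#' pielou_evenness(c(0.5, 0.25, 0.25))   # 0.946395
#' @export
pielou_evenness <- function(freqs) {
  h <- shannon_diversity(freqs)
  s <- length(freqs)
  if (s == 1L) return(NA_real_)
  h / log(s)
}

#' Convergence frequency of a repertoire sample
#'
#' The cumulative frequency (proportion of total reads, range 0-1) of
#' clonotypes belonging to convergent groups: identical CDR3 amino-acid
#' sequence and V gene, encoded by two or more distinct nucleotide sequences.
#'
#' @param sample A `repertoire_sample` with positive depth.
#' @return A proportion in `[0, 1]`; 0 when no convergent group exists.
#' @export
convergence_frequency <- function(sample) {
  groups <- convergent_groups(sample)
  if (nrow(groups) == 0L) return(0)
  sum(groups$aggregate_count) / sample$depth
}

#' Number of unique clonotypes in a sample
#'
#' Counts distinct (CDR3 nucleotide, V gene, J gene) keys.
#'
#' @param sample A `repertoire_sample`.
#' @return A non-negative integer.
#' @export
unique_clone_count <- function(sample) {
  if (!inherits(sample, "repertoire_sample")) {
    stop("`sample` must be a repertoire_sample", call. = FALSE)
  }
  nrow(sample$clonotypes)
}

#' Percent decline from a pre- to a post-treatment value
#'
#' `(pre - post) / pre * 100`. Reported unrounded; round to the nearest
#' integer for display (e.g. a clone-count drop from 2,248 to 1,335 is a
#' ~41% reduction).
#'
#' @param pre Positive baseline value.
#' @param post Non-negative follow-up value.
#' @return Percent decline (negative when the value increased).
#' @examples
#' percent_decline(2248, 1335)  # 40.6 -> displays as 41
#' percent_decline(3318, 2790)  # 15.9 -> displays as 16
#' @export
percent_decline <- function(pre, post) {
  if (!is.numeric(pre) || !is.numeric(post) || length(pre) != length(post)) {
    stop("`pre` and `post` must be numeric vectors of equal length",
         call. = FALSE)
  }
  if (any(pre <= 0)) stop("`pre` must be positive", call. = FALSE)
  if (any(post < 0)) stop("`post` must be non-negative", call. = FALSE)
  (pre - post) / pre * 100
}

#' Compute the per-sample metrics row
#'
#' Summarizes one repertoire sample into the standard metrics record: depth,
#' unique clone count, Shannon diversity, Pielou evenness, and convergence
#' frequency. Evenness is `NA` for repertoires with at most one clone.
#'
#' @param sample A `repertoire_sample` with positive depth.
#' @param patient_id,timepoint,group Provenance fields copied into the row;
#'   `timepoint` is one of `"T1"`, `"T2"`, `"T3"`.
#' @return A one-row data.frame with the fixed metrics columns.
#' @export
sample_metrics <- function(sample, patient_id, timepoint,
                           group = NA_character_) {
  if (!inherits(sample, "repertoire_sample")) {
    stop("`sample` must be a repertoire_sample", call. = FALSE)
  }
  if (sample$depth <= 0) stop("sample depth is zero", call. = FALSE)
  if (!timepoint %in% c("T1", "T2", "T3")) {
    stop("`timepoint` must be one of T1, T2, T3", call. = FALSE)
  }
  freqs <- sample$clonotypes$count / sample$depth
  data.frame(
    patient_id = patient_id,
    timepoint = timepoint,
    group = group,
    depth = sample$depth,
    unique_clones = unique_clone_count(sample),
    shannon = shannon_diversity(freqs),
    evenness = pielou_evenness(freqs),
    convergence = convergence_frequency(sample),
    stringsAsFactors = FALSE
  )
}

#' Per-patient longitudinal clone-count deltas (T1 to T2)
#'
#' For every patient with metrics at both T1 and T2, computes the change in
#' unique clone count (`delta_clones = T2 - T1`) and the percent decline
#' (`(T1 - T2) / T1 * 100`, defined only when the baseline count is
#' positive).
#'
#' @param metrics A metrics data.frame with at least `patient_id`,
#'   `timepoint`, `group`, `unique_clones`.
#' @return A data.frame with one row per evaluable patient: `patient_id`,
#'   `group`, `pre_clones`, `post_clones`, `delta_clones`, `percent_decline`.
#' @export
delta_metrics <- function(metrics) {
  needed <- c("patient_id", "timepoint", "group", "unique_clones")
  if (!is.data.frame(metrics) || !all(needed %in% names(metrics))) {
    stop("`metrics` must contain columns ", paste(needed, collapse = ", "),
         call. = FALSE)
  }
  t1 <- metrics[metrics$timepoint == "T1", , drop = FALSE]
  t2 <- metrics[metrics$timepoint == "T2", , drop = FALSE]
  both <- intersect(t1$patient_id, t2$patient_id)
  if (!length(both)) {
    return(data.frame(patient_id = character(), group = character(),
                      pre_clones = integer(), post_clones = integer(),
                      delta_clones = integer(), percent_decline = numeric(),
                      stringsAsFactors = FALSE))
  }
  pre <- t1$unique_clones[match(both, t1$patient_id)]
  post <- t2$unique_clones[match(both, t2$patient_id)]
  out <- data.frame(
    patient_id = both,
    group = t1$group[match(both, t1$patient_id)],
    pre_clones = pre,
    post_clones = post,
    delta_clones = post - pre,
    percent_decline = ifelse(pre > 0, (pre - post) / pre * 100, NA_real_),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}
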