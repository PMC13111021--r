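# Inferential layer: normality gate, rank tests, trend correlation,
# Benjamini-Hochberg correction, response summarization, and survival.
#
# Two-sided tests throughout. Exact small-sample null distributions are used
# where computationally trivial because the study design involves groups of
# roughly 4 and 11 patients.

test_result <- function(name, statistic, p, n1 = NA_integer_,
                        n2 = NA_integer_, two_sided = TRUE) {
  data.frame(name = name, statistic = as.numeric(statistic),
             p = as.numeric(p), q = NA_real_, two_sided = two_sided,
             n1 = as.integer(n1), n2 = as.integer(n2),
             stringsAsFactors = FALSE)
}

#' Shapiro-Wilk normality gate
#'
#' Decides between parametric and nonparametric downstream testing: a
#' Shapiro-Wilk p-value below 0.05 routes to rank-based methods
#' (Spearman/Wilcoxon), otherwise to parametric ones (Pearson).
#'
#' @param values Numeric vector, `n >= 3`, not constant.
#' @return `"parametric"` or `"nonparametric"`.
#' @export
shapiro_gate <- function(values) {
  if (!is.numeric(values) || length(values) < 3L) {
    stop("need at least 3 values", call. = FALSE)
  }
  if (length(unique(values)) == 1L) {
    stop("constant vector: Shapiro-Wilk W undefined", call. = FALSE)
  }
  p <- shapiro.test(values)$p.value
  if (p < 0.05) "nonparametric" else "parametric"
}

#' Two-sided Wilcoxon rank-sum (Mann-Whitney) test
#'
#' Uses the exact null distribution when the smaller group has at most 10
#' observations and there are no ties; otherwise the normal approximation
#' with tie and continuity correction (mid-ranks for ties).
#'
#' @param x,y Non-empty numeric vectors, one per group.
#' @param name Label stored in the result row.
#' @return A one-row data.frame: `name`, `statistic` (Mann-Whitney U for
#'   `x`), `p`, `q` (`NA` until filled by a BH family), `two_sided`, `n1`,
#'   `n2`.
#' @examples
#' wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6))  # exact p = 0.10
#' @export
wilcoxon_rank_sum <- function(x, y, name = "wilcoxon_rank_sum") {
  if (!length(x) || !length(y)) stop("empty vector", call. = FALSE)
  ties <- anyDuplicated(c(x, y)) > 0L
  exact <- min(length(x), length(y)) <= 10L && !ties
  wt <- suppressWarnings(
    wilcox.test(x, y, alternative = "two.sided", exact = exact,
                correct = TRUE)
  )
  test_result(name, unname(wt$statistic), wt$p.value,
              n1 = length(x), n2 = length(y))
}

#' Spearman rank correlation against an ordinal covariate
#'
#' Computes rho as the Pearson correlation of mid-ranks. The two-sided
#' p-value uses the full permutation null for `n <= 8` (tie-safe) and the
#' t approximation on `n - 2` degrees of freedom otherwise.
#'
#' @param values Numeric vector (e.g. per-sample convergence frequencies);
#'   must not be constant.
#' @param timepoints Ordinal covariate, either numeric codes or the labels
#'   `"T1"`/`"T2"`/`"T3"` (coded 1/2/3).
#' @param name Label stored in the result row.
#' @return A one-row test-result data.frame with `statistic` = rho.
#' @export
spearman_trend <- function(values, timepoints, name = "spearman_trend") {
  if (is.character(timepoints) || is.factor(timepoints)) {
    codes <- c(T1 = 1, T2 = 2, T3 = 3)[as.character(timepoints)]
    if (any(is.na(codes))) stop("unknown time-point label", call. = FALSE)
    timepoints <- as.numeric(codes)
  }
  n <- length(values)
  if (n < 3L || length(timepoints) != n) {
    stop("need n >= 3 paired observations", call. = FALSE)
  }
  if (var(values) == 0) stop("constant values: rho undefined", call. = FALSE)
  if (var(timepoints) == 0) {
    stop("constant timepoints: rho undefined", call. = FALSE)
  }
  rx <- rank(values)
  ry <- rank(timepoints)
  rho <- cor(rx, ry)
  if (n <= 8L) {
    perms <- all_permutations(n)
    # rho is linear in sum(rx[perm] * ry); enumerate that cross-product
    s <- matrix(rx[perms], nrow = nrow(perms)) %*% ry
    rho_all <- (s - n * mean(rx) * mean(ry)) / ((n - 1) * sd(rx) * sd(ry))
    p <- mean(abs(rho_all) >= abs(rho) - 1e-12)
  } else if (abs(rho) >= 1 - 1e-14) {
    p <- 0
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  }
  test_result(name, rho, p, n1 = n)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Returns BH-adjusted q-values in input order, capped at 1. The adjustment
#' is monotone: the ordering of p-values is never reversed in q.
#'
#' @param pvals Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted q-values, same length and order.
#' @examples
#' bh_adjust(c(0.030, 0.020, 0.030))  # all 0.030
#' @export
bh_adjust <- function(pvals) {
  if (!is.numeric(pvals) || length(pvals) == 0L) {
    stop("`pvals` must be a non-empty numeric vector", call. = FALSE)
  }
  if (any(is.na(pvals)) || any(pvals < 0 | pvals > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  p.adjust(pvals, method = "BH")
}

#' Summarize RECIST responses
#'
#' Tabulates partial response (PR), stable disease (SD), and progressive
#' disease (PD) with exact and integer-rounded percentages, plus the disease
#' control rate `(PR + SD) / N`.
#'
#' @param responses Character vector with values in `{"PR", "SD", "PD"}`.
#' @return A data.frame with rows PR, SD, PD, disease_control and columns
#'   `category`, `n`, `percent` (exact), `percent_display` (rounded).
#' @examples
#' response_summary(c(rep("PR", 4), rep("SD", 7), rep("PD", 4)))
#' @export
response_summary <- function(responses) {
  responses <- as.character(responses)
  if (!length(responses)) stop("empty response list", call. = FALSE)
  bad <- !responses %in% c("PR", "SD", "PD")
  if (any(bad)) {
    stop("invalid response value(s): ",
         paste(unique(responses[bad]), collapse = ", "), call. = FALSE)
  }
  n <- length(responses)
  counts <- vapply(c("PR", "SD", "PD"), function(r) sum(responses == r),
                   integer(1))
  dc <- counts[["PR"]] + counts[["SD"]]
  out <- data.frame(
    category = c("PR", "SD", "PD", "disease_control"),
    n = c(counts, dc),
    percent = c(counts, dc) / n * 100,
    stringsAsFactors = FALSE
  )
  out$percent_display <- round(out$percent)
  rownames(out) <- NULL
  out
}

#' Kaplan-Meier curves and two-group log-rank test
#'
#' Product-limit estimation with right censoring via [survival::survfit()],
#' and the log-rank chi-square test via [survival::survdiff()] when two
#' groups are present. When no events occurred in any group the test is
#' undefined and the p-value is returned missing with an explanatory note.
#'
#' @param times Non-negative follow-up times.
#' @param events Event indicators (1 = death, 0 = censored).
#' @param groups Group labels, one per observation.
#' @return An object of class `km_result`: list with `curves` (a named list
#'   of per-group data.frames `time`, `n_risk`, `n_event`, `surv`, each
#'   starting at time 0 with survival 1), `chisq`, `df`, `p`, and
#'   `p_defined` (FALSE with a `note` when the test could not be computed).
#' @export
km_logrank <- function(times, events, groups) {
  if (length(times) != length(events) || length(times) != length(groups)) {
    stop("`times`, `events`, `groups` must have equal length", call. = FALSE)
  }
  if (any(is.na(times)) || any(times < 0)) {
    stop("negative or missing time", call. = FALSE)
  }
  ev <- as.integer(events)
  if (!all(ev %in% c(0L, 1L))) stop("events must be 0/1", call. = FALSE)
  g <- as.character(groups)
  df <- data.frame(t = as.numeric(times), e = ev, g = g,
                   stringsAsFactors = FALSE)
  fit <- survival::survfit(survival::Surv(t, e) ~ g, data = df)
  strata_grp <- if (is.null(fit$strata)) {
    rep(unique(g), length(fit$time))
  } else {
    rep(sub("^g=", "", names(fit$strata)), fit$strata)
  }
  steps <- data.frame(time = fit$time, n_risk = fit$n.risk,
                      n_event = fit$n.event, surv = fit$surv,
                      group = strata_grp, stringsAsFactors = FALSE)
  labs <- sort(unique(g))
  curves <- lapply(labs, function(lab) {
    d <- steps[steps$group == lab, , drop = FALSE]
    d <- d[order(d$time), c("time", "n_risk", "n_event", "surv")]
    out <- rbind(
      data.frame(time = 0, n_risk = sum(g == lab), n_event = 0L, surv = 1),
      d
    )
    rownames(out) <- NULL
    out
  })
  names(curves) <- labs
  chisq <- NA_real_
  dfree <- NA_integer_
  p <- NA_real_
  p_defined <- FALSE
  note <- NULL
  if (length(labs) < 2L) {
    note <- "single group: log-rank test not applicable"
  } else if (sum(ev) == 0L) {
    note <- "no events in any group: log-rank test undefined"
  } else {
    sdiff <- survival::survdiff(survival::Surv(t, e) ~ g, data = df)
    chisq <- sdiff$chisq
    dfree <- length(labs) - 1L
    p <- pchisq(chisq, df = dfree, lower.tail = FALSE)
    p_defined <- TRUE
  }
  structure(
    list(curves = curves, chisq = chisq, df = dfree, p = p,
         p_defined = p_defined, note = note),
    class = "km_result"
  )
}

#' @export
print.km_result <- function(x, ...) {
  cat("<km_result>", length(x$curves), "group(s)\n")
  if (x$p_defined) {
    cat("  log-rank chisq =", signif(x$chisq, 4), " p =", signif(x$p, 4), "\n")
  } else {
    cat("  log-rank:", x$note %||% "not computed", "\n")
  }
  invisible(x)
}

#' Median survival time from a Kaplan-Meier curve
#'
#' The smallest time at which the survival curve drops to 0.5 or below;
#' `Inf` when the curve never reaches 0.5 (median not attained).
#'
#' @param curve A per-group curve data.frame from [km_logrank()].
#' @return The median survival time, or `Inf`.
#' @export
km_median <- function(curve) {
  if (!is.data.frame(curve) || !all(c("time", "surv") %in% names(curve))) {
    stop("`curve` must be a km_logrank curve data.frame", call. = FALSE)
  }
  hit <- curve$time[curve$surv <= 0.5 + 1e-12]
  if (!length(hit)) return(Inf)
  min(hit)
}
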