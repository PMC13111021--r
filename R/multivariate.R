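# Cross-sample clone-frequency matrix and principal component analysis.
#
# The matrix is keyed at the (V gene, CDR3 amino-acid) level because the
# biological questions (convergence, shared antigen recognition) operate at
# the amino-acid level; nucleotide-level keying is available via `level`.

#' Build a cross-sample clone-frequency matrix
#'
#' Clonotypes are aggregated per sample to the chosen key level, the union of
#' keys is taken across samples, and the matrix is restricted to the `top_m`
#' keys by mean frequency across samples (ties broken lexicographically),
#' zero-filled where a key is absent from a sample.
#'
#' @param samples A list of at least two `repertoire_sample` objects. Row
#'   names are taken from the list names, falling back to each sample's
#'   `sample_id`.
#' @param top_m Maximum number of clonotype columns retained (default 500).
#' @param level `"aa"` (default) keys columns by (V gene, CDR3 amino acid);
#'   `"nt"` keys by (V gene, J gene, CDR3 nucleotide).
#' @return A numeric matrix of proportions, samples in rows (each row sums to
#'   at most 1), clonotype keys in columns.
#' @export
build_frequency_matrix <- function(samples, top_m = 500, level = c("aa", "nt")) {
  level <- match.arg(level)
  if (!is.list(samples) || length(samples) < 2L) {
    stop("need at least 2 samples", call. = FALSE)
  }
  if (!all(vapply(samples, inherits, TRUE, "repertoire_sample"))) {
    stop("all elements of `samples` must be repertoire_sample objects",
         call. = FALSE)
  }
  if (!is.numeric(top_m) || top_m < 1) stop("`top_m` must be >= 1", call. = FALSE)
  ids <- names(samples) %||% rep(NA_character_, length(samples))
  fallback <- vapply(samples, function(s) s$sample_id, "")
  ids[is.na(ids) | !nzchar(ids)] <- fallback[is.na(ids) | !nzchar(ids)]
  ids[is.na(ids) | !nzchar(ids)] <-
    paste0("sample_", which(is.na(ids) | !nzchar(ids)))
  long <- do.call(rbind, lapply(seq_along(samples), function(i) {
    s <- samples[[i]]
    cl <- s$clonotypes
    if (nrow(cl) == 0L) return(NULL)
    key <- if (level == "aa") {
      paste(cl$v_gene, cl$cdr3_aa, sep = "|")
    } else {
      paste(cl$v_gene, cl$j_gene, cl$cdr3_nt, sep = "|")
    }
    freq <- tapply(cl$count, key, sum) / s$depth
    data.frame(row = i, key = names(freq), freq = as.vector(freq),
               stringsAsFactors = FALSE)
  }))
  keys <- sort(unique(long$key))
  m <- matrix(0, nrow = length(samples), ncol = length(keys),
              dimnames = list(ids, keys))
  m[cbind(long$row, match(long$key, keys))] <- long$freq
  if (ncol(m) > top_m) {
    ord <- order(-colMeans(m), colnames(m))
    m <- m[, ord[seq_len(top_m)], drop = FALSE]
  }
  m
}

#' Principal component analysis of a clone-frequency matrix
#'
#' Column-mean centering with no variance scaling, as raw proportions carry
#' the signal of interest. A deterministic sign convention is applied: for
#' each component the loading of largest absolute value is made positive, so
#' scores are reproducible across linear-algebra backends.
#'
#' @param m A samples-by-clonotypes frequency matrix.
#' @param k Number of components to keep; must satisfy
#'   `k <= min(nrow(m) - 1, ncol(m))`.
#' @return An object of class `pca_result`: list with `scores`
#'   (samples x k, column means zero), `loadings` (clonotypes x k), and
#'   `explained_variance_ratio` (length k, non-increasing).
#' @export
pca_scores <- function(m, k) {
  if (!is.matrix(m) || !is.numeric(m)) stop("`m` must be a numeric matrix",
                                            call. = FALSE)
  kmax <- min(nrow(m) - 1L, ncol(m))
  if (!is.numeric(k) || length(k) != 1L || k < 1 || k > kmax) {
    stop("`k` must be between 1 and min(rows - 1, columns) = ", kmax,
         call. = FALSE)
  }
  col_var <- apply(m, 2L, var)
  if (max(col_var) == 0) stop("constant matrix: zero variance", call. = FALSE)
  fit <- stats::prcomp(m, center = TRUE, scale. = FALSE)
  scores <- fit$x[, seq_len(k), drop = FALSE]
  loadings <- fit$rotation[, seq_len(k), drop = FALSE]
  for (c in seq_len(k)) {
    i <- which.max(abs(loadings[, c]))
    if (loadings[i, c] < 0) {
      loadings[, c] <- -loadings[, c]
      scores[, c] <- -scores[, c]
    }
  }
  evr <- fit$sdev^2 / sum(fit$sdev^2)
  structure(
    list(scores = scores, loadings = loadings,
         explained_variance_ratio = evr[seq_len(k)]),
    class = "pca_result"
  )
}

#' @export
print.pca_result <- function(x, ...) {
  cat("<pca_result>", nrow(x$scores), "samples,", ncol(x$scores),
      "components\n")
  cat("  explained variance ratio:",
      paste(signif(x$explained_variance_ratio, 3), collapse = ", "), "\n")
  invisible(x)
}

#' Group comparison and dispersion of principal component scores
#'
#' Two-sided Wilcoxon rank-sum test on the chosen component's scores between
#' the two groups, plus per-group dispersion (score range and standard
#' deviation), used to quantify e.g. wide PC2 scatter in one group versus
#' compact clustering in the other.
#'
#' @param result A `pca_result`.
#' @param groups Per-sample group labels (exactly two distinct values, both
#'   non-empty), aligned with the score rows.
#' @param component Component index to test (default 1).
#' @return A list with `test` (a test-result row, see
#'   [wilcoxon_rank_sum()]) and `dispersion` (data.frame with one row per
#'   group: `group`, `n`, `range`, `sd`).
#' @export
pc_group_test <- function(result, groups, component = 1L) {
  if (!inherits(result, "pca_result")) {
    stop("`result` must be a pca_result", call. = FALSE)
  }
  scores <- result$scores
  if (length(groups) != nrow(scores)) {
    stop("`groups` must have one label per score row", call. = FALSE)
  }
  if (component < 1 || component > ncol(scores)) {
    stop("`component` out of range", call. = FALSE)
  }
  g <- as.character(groups)
  labs <- sort(unique(g))
  if (length(labs) != 2L) {
    stop("need exactly two non-empty groups; got: ",
         paste(labs, collapse = ", "), call. = FALSE)
  }
  x <- scores[g == labs[1L], component]
  y <- scores[g == labs[2L], component]
  test <- wilcoxon_rank_sum(x, y,
                            name = paste0("wilcoxon_pc", component, "_group"))
  dispersion <- data.frame(
    group = labs,
    n = c(length(x), length(y)),
    range = c(diff(range(x)), diff(range(y))),
    sd = c(sd(x), sd(y)),
    stringsAsFactors = FALSE
  )
  list(test = test, dispersion = dispersion)
}
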