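# Clonotype identity, junction translation, and convergent-group detection.
#
# A clonotype is a unique CDR3 nucleotide sequence combined with V and J gene
# usage. Convergent rearrangement is the presence of two or more distinct
# nucleotide sequences that encode the same CDR3 amino-acid sequence with the
# same V gene segment -- a surrogate for antigen-driven selection.

#' Normalize an IMGT-style gene call to gene level
#'
#' Strips the allele suffix (`*NN`) and, for multi-assignment calls separated
#' by `/` or `,`, keeps the first listed gene. Convergence is defined at the
#' V *gene* level, so allele resolution is deliberately discarded. The same
#' rule is applied to J calls when collapsing clonotypes.
#'
#' @param v_call Character vector of gene calls, e.g. `"TRBV12-3*01"`.
#' @return Character vector of gene-level names, e.g. `"TRBV12-3"`.
#' @examples
#' normalize_v_call(c("TRBV12-3*01", "TRBV20-1", "TRBV6-2/TRBV6-3"))
#' @export
normalize_v_call <- function(v_call) {
  if (!is.character(v_call)) stop("gene calls must be character", call. = FALSE)
  v <- trimws(v_call)
  if (length(v) == 0L || any(is.na(v)) || any(!nzchar(v))) {
    stop("empty gene call", call. = FALSE)
  }
  v <- sub("[/,].*$", "", v)       # first-listed gene of a multi-assignment
  v <- sub("\\*.*$", "", v)        # drop allele suffix
  trimws(v)
}

#' Translate CDR3 junction nucleotide sequences
#'
#' Standard-genetic-code translation in frame 1. A junction is *productive*
#' when its length is divisible by three and the translation contains no stop
#' codon. Out-of-frame junctions are reported with a missing amino-acid
#' sequence; in-frame junctions containing a stop are translated (stops shown
#' as `*`) but flagged unproductive.
#'
#' @param cdr3_nt Character vector of uppercase ACGT junction sequences.
#' @return A data.frame with columns `cdr3_aa` (character, `NA` when out of
#'   frame) and `productive` (logical).
#' @examples
#' translate_junction("TGTGCCAGCAGC")   # "CASS", productive
#' translate_junction("TGTTAAAGC")      # in-frame stop, unproductive
#' @export
translate_junction <- function(cdr3_nt) {
  if (!is.character(cdr3_nt)) stop("`cdr3_nt` must be character", call. = FALSE)
  nt <- toupper(cdr3_nt)
  bad <- is.na(nt) | !nzchar(nt) | grepl("[^ACGT]", nt)
  if (any(bad)) {
    stop("non-ACGT junction character at record(s): ",
         paste(which(bad), collapse = ", "), call. = FALSE)
  }
  in_frame <- nchar(nt) %% 3L == 0L
  aa <- rep(NA_character_, length(nt))
  if (any(in_frame)) {
    aa[in_frame] <- as.character(Biostrings::translate(
      Biostrings::DNAStringSet(nt[in_frame]),
      no.init.codon = TRUE
    ))
  }
  productive <- in_frame & !grepl("*", aa, fixed = TRUE)
  productive[!in_frame] <- FALSE
  data.frame(cdr3_aa = aa, productive = productive, stringsAsFactors = FALSE)
}

#' Collapse raw rearrangement records into clonotypes
#'
#' Records are grouped by the clonotype key (CDR3 nucleotide sequence,
#' gene-level V, gene-level J) with read counts summed. Unproductive records
#' (out of frame or containing a stop codon) are removed before collapsing;
#' their total read count is recorded in the `discarded_reads` attribute so
#' that parsing remains lossless for counts.
#'
#' @param records A data.frame with columns `v_call`, `j_call`, `junction`,
#'   and optionally `duplicate_count` (defaults to 1 per record when absent
#'   or missing).
#' @return A data.frame of clonotypes with columns `cdr3_nt`, `cdr3_aa`,
#'   `v_gene`, `j_gene`, `count`, ordered by descending count then
#'   lexicographic key, carrying attribute `discarded_reads`.
#' @examples
#' recs <- data.frame(
#'   v_call = c("TRBV5-1*01", "TRBV5-1"),
#'   j_call = c("TRBJ2-7", "TRBJ2-7"),
#'   junction = c("TGTGCCAGCAGC", "TGTGCCAGCAGC"),
#'   duplicate_count = c(5, 7)
#' )
#' collapse_clonotypes(recs)
#' @export
collapse_clonotypes <- function(records) {
  if (!is.data.frame(records)) stop("`records` must be a data.frame", call. = FALSE)
  required <- c("v_call", "j_call", "junction")
  missing_cols <- setdiff(required, names(records))
  if (length(missing_cols)) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  empty <- data.frame(cdr3_nt = character(), cdr3_aa = character(),
                      v_gene = character(), j_gene = character(),
                      count = integer(), stringsAsFactors = FALSE)
  if (nrow(records) == 0L) {
    attr(empty, "discarded_reads") <- 0
    return(empty)
  }
  count <- if ("duplicate_count" %in% names(records)) {
    cnt <- records$duplicate_count
    cnt[is.na(cnt)] <- 1
    cnt
  } else {
    rep(1, nrow(records))
  }
  count <- as.numeric(count)
  if (any(count < 1 | count != floor(count))) {
    stop("duplicate_count must be a positive integer after defaulting",
         call. = FALSE)
  }
  tr <- translate_junction(records$junction)
  keep <- tr$productive
  discarded <- sum(count[!keep])
  if (!any(keep)) {
    attr(empty, "discarded_reads") <- discarded
    return(empty)
  }
  df <- data.frame(
    cdr3_nt = toupper(records$junction[keep]),
    cdr3_aa = tr$cdr3_aa[keep],
    v_gene = normalize_v_call(records$v_call[keep]),
    j_gene = normalize_v_call(records$j_call[keep]),
    count = count[keep],
    stringsAsFactors = FALSE
  )
  key <- paste(df$cdr3_nt, df$v_gene, df$j_gene, sep = "\r")
  sums <- tapply(df$count, key, sum)
  first <- !duplicated(key)
  out <- df[first, , drop = FALSE]
  out$count <- as.vector(sums[paste(out$cdr3_nt, out$v_gene, out$j_gene,
                                    sep = "\r")])
  out <- out[order(-out$count, out$cdr3_nt, out$v_gene, out$j_gene), ,
             drop = FALSE]
  rownames(out) <- NULL
  if (max(out$count) <= .Machine$integer.max) {
    storage.mode(out$count) <- "integer"
  }
  attr(out, "discarded_reads") <- discarded
  out
}

#' Construct a repertoire sample
#'
#' Bundles a collapsed clonotype table with its total sequencing depth and
#' provenance. Depth is the sum of clonotype read counts.
#'
#' @param clonotypes A clonotype data.frame as returned by
#'   [collapse_clonotypes()].
#' @param sample_id Optional sample identifier.
#' @param discarded_reads Read count removed as unproductive upstream.
#' @return An object of class `repertoire_sample`: a list with elements
#'   `clonotypes`, `depth`, `sample_id`, `discarded_reads`.
#' @export
repertoire_sample <- function(clonotypes, sample_id = NA_character_,
                              discarded_reads = 0) {
  needed <- c("cdr3_nt", "cdr3_aa", "v_gene", "j_gene", "count")
  if (!is.data.frame(clonotypes) || !all(needed %in% names(clonotypes))) {
    stop("`clonotypes` must be a data.frame with columns ",
         paste(needed, collapse = ", "), call. = FALSE)
  }
  if (nrow(clonotypes) && any(clonotypes$count < 1)) {
    stop("clonotype counts must be >= 1", call. = FALSE)
  }
  structure(
    list(
      clonotypes = clonotypes,
      depth = sum(clonotypes$count),
      sample_id = sample_id,
      discarded_reads = discarded_reads
    ),
    class = "repertoire_sample"
  )
}

#' @export
print.repertoire_sample <- function(x, ...) {
  cat("<repertoire_sample>", if (!is.na(x$sample_id)) x$sample_id else "", "\n")
  cat("  clonotypes:", nrow(x$clonotypes),
      " depth:", x$depth,
      " discarded reads:", x$discarded_reads, "\n")
  invisible(x)
}

#' Detect convergent clonotype groups
#'
#' Clonotypes are grouped by (V gene, CDR3 amino-acid sequence); groups whose
#' members span two or more *distinct* nucleotide sequences are convergent.
#' The J gene is not part of the convergence key. Aggregate frequency uses
#' the sample depth as denominator.
#'
#' @param sample A `repertoire_sample`.
#' @return A data.frame with one row per convergent group: `v_gene`,
#'   `cdr3_aa`, `n_variants` (distinct nucleotide sequences), `members`
#'   (list column of the distinct nucleotide sequences, sorted),
#'   `aggregate_count`, `aggregate_frequency`.
#' @export
convergent_groups <- function(sample) {
  if (!inherits(sample, "repertoire_sample")) {
    stop("`sample` must be a repertoire_sample", call. = FALSE)
  }
  if (sample$depth <= 0) stop("sample depth is zero", call. = FALSE)
  cl <- sample$clonotypes
  empty <- data.frame(v_gene = character(), cdr3_aa = character(),
                      n_variants = integer(), aggregate_count = numeric(),
                      aggregate_frequency = numeric(), stringsAsFactors = FALSE)
  empty$members <- list()
  if (nrow(cl) == 0L) return(empty)
  key <- paste(cl$v_gene, cl$cdr3_aa, sep = "\r")
  nts <- split(cl$cdr3_nt, key)
  counts <- split(cl$count, key)
  n_var <- vapply(nts, function(x) length(unique(x)), integer(1))
  hit <- names(n_var)[n_var >= 2L]
  if (!length(hit)) return(empty)
  parts <- strsplit(hit, "\r", fixed = TRUE)
  out <- data.frame(
    v_gene = vapply(parts, `[`, "", 1L),
    cdr3_aa = vapply(parts, `[`, "", 2L),
    n_variants = unname(n_var[hit]),
    aggregate_count = vapply(counts[hit], sum, numeric(1)),
    stringsAsFactors = FALSE
  )
  out$aggregate_frequency <- out$aggregate_count / sample$depth
  out$members <- lapply(nts[hit], function(x) sort(unique(x)))
  out <- out[order(-out$aggregate_count, out$v_gene, out$cdr3_aa), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}
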