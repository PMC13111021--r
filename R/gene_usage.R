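#' TRBV/TRBJ gene usage table for the repertoire simulator
#'
#' A small built-in table of human TRBV and TRBJ gene-segment names with
#' plausible peripheral-blood usage weights. The simulator draws V and J
#' assignments from these weights; no germline sequence realism is attempted
#' (gene names only, no alleles).
#'
#' @param segment Either `"V"` or `"J"`.
#' @return A data.frame with columns `gene` and `weight` (weights sum to 1).
#' @examples
#' head(trb_gene_usage("V"))
#' trb_gene_usage("J")
#' @export
trb_gene_usage <- function(segment = c("V", "J")) {
  segment <- match.arg(segment)
  if (segment == "V") {
    tab <- data.frame(
      gene = c(
        "TRBV2",    "TRBV3-1",  "TRBV4-1",  "TRBV4-2",  "TRBV5-1",
        "TRBV5-4",  "TRBV5-6",  "TRBV6-1",  "TRBV6-2",  "TRBV6-4",
        "TRBV6-5",  "TRBV7-2",  "TRBV7-3",  "TRBV7-8",  "TRBV7-9",
        "TRBV9",    "TRBV10-3", "TRBV11-2", "TRBV12-3", "TRBV12-5",
        "TRBV13",   "TRBV14",   "TRBV15",   "TRBV18",   "TRBV19",
        "TRBV20-1", "TRBV24-1", "TRBV25-1", "TRBV27",   "TRBV28",
        "TRBV29-1", "TRBV30"
      ),
      weight = c(
        3.0, 1.2, 2.4, 1.0, 5.5,
        2.2, 1.4, 1.6, 2.6, 1.5,
        4.2, 3.4, 1.1, 1.0, 3.6,
        3.2, 2.4, 2.8, 3.8, 1.5,
        1.2, 1.8, 1.4, 2.2, 4.6,
        6.5, 1.6, 1.5, 2.8, 3.6,
        4.4, 2.0
      ),
      stringsAsFactors = FALSE
    )
  } else {
    tab <- data.frame(
      gene = c(
        "TRBJ1-1", "TRBJ1-2", "TRBJ1-3", "TRBJ1-4", "TRBJ1-5", "TRBJ1-6",
        "TRBJ2-1", "TRBJ2-2", "TRBJ2-3", "TRBJ2-4", "TRBJ2-5", "TRBJ2-6",
        "TRBJ2-7"
      ),
      weight = c(
        6.5, 6.0, 3.5, 2.5, 5.5, 3.0,
        14.0, 6.5, 11.0, 2.5, 10.0, 2.0,
        16.0
      ),
      stringsAsFactors = FALSE
    )
  }
  tab$weight <- tab$weight / sum(tab$weight)
  tab
}
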