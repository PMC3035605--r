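#' Count SXL consensus sites in a 3'UTR sequence
#'
#' Scans for the SXL binding consensus — the poly-U octamers `AUUUUUUU` or
#' `UUUUUUUU` — case-insensitively, with T and U treated identically. The
#' default counts non-overlapping occurrences by a greedy left-to-right scan
#' (a site is a bound protein footprint); `overlap = TRUE` instead counts
#' every start position at which a motif matches. `N` never matches.
#'
#' @param seq character vector of sequences (DNA or RNA alphabet, sense
#'   strand of the mRNA; characters outside A/C/G/T/U/N are an error).
#' @param overlap count overlapping matches (default FALSE).
#' @return Integer vector of site counts.
#' @export
#' @examples
#' count_sxl_sites("AUUUUUUU")                    # 1
#' count_sxl_sites("UUUUUUUUU")                   # 1 (greedy, 9 U)
#' count_sxl_sites("UUUUUUUUU", overlap = TRUE)   # 2
count_sxl_sites <- function(seq, overlap = FALSE) {
  s <- toupper(as.character(seq))
  if (any(grepl("[^ACGTUN]", s))) {
    stop("sequence contains characters outside the A/C/G/T/U/N alphabet",
         call. = FALSE)
  }
  s <- gsub("T", "U", s, fixed = TRUE)
  pat <- if (overlap) "(?=(AU{7}|U{8}))" else "AU{7}|U{8}"
  vapply(s, function(x) {
    m <- gregexpr(pat, x, perl = TRUE)[[1L]]
    if (m[1L] == -1L) 0L else length(m)
  }, integer(1), USE.NAMES = FALSE)
}

#' Read 3'UTR sequences from FASTA
#'
#' Headers are parsed as `gene_id [arm=ARM]`; the first whitespace-separated
#' token is the gene id and an optional `arm=` tag supplies the chromosome
#' arm.
#'
#' @param path FASTA file.
#' @return Data frame `gene_id arm sequence`.
#' @export
read_utr_fasta <- function(path) {
  if (!file.exists(path)) stop("missing input file: ", path, call. = FALSE)
  ss <- Biostrings::readBStringSet(path)
  headers <- names(ss)
  gene_id <- sub("\\s.*$", "", headers)
  arm <- ifelse(grepl("arm=", headers),
                sub(".*arm=([^[:space:]]+).*", "\\1", headers), NA_character_)
  data.frame(gene_id = gene_id, arm = arm,
             sequence = as.character(ss), row.names = NULL)
}

#' Flag predicted SXL targets and tally them per chromosome arm
#'
#' A gene is a predicted SXL target when its 3'UTR carries at least
#' `min_sites` consensus sites (default 3, inclusive). For genes supplied
#' with several records (isoform UTRs) the maximum site count is used.
#'
#' @param utrs data frame from [read_utr_fasta()] (columns `gene_id`, `arm`,
#'   `sequence`), or a named character vector of sequences.
#' @param min_sites site-count threshold (default 3).
#' @param overlap passed to [count_sxl_sites()].
#' @return Data frame `gene_id arm n_sites flagged`, one row per gene, with
#'   the per-arm tally of flagged genes in attribute `tally`.
#' @export
#' @examples
#' scan_sxl(c(run = "AUUUUUUUCCUUUUUUUUGGAUUUUUUU"))
scan_sxl <- function(utrs, min_sites = 3, overlap = FALSE) {
  if (is.character(utrs)) {
    utrs <- data.frame(gene_id = names(utrs), arm = NA_character_,
                       sequence = unname(utrs))
  }
  n_sites <- count_sxl_sites(utrs$sequence, overlap = overlap)
  per_gene <- stats::aggregate(n_sites,
                               by = list(gene_id = utrs$gene_id), FUN = max)
  names(per_gene)[2L] <- "n_sites"
  per_gene$arm <- utrs$arm[match(per_gene$gene_id, utrs$gene_id)]
  per_gene <- per_gene[, c("gene_id", "arm", "n_sites")]
  per_gene$flagged <- per_gene$n_sites >= min_sites
  arm_grp <- ifelse(is.na(per_gene$arm), "unknown", per_gene$arm)
  tally <- stats::aggregate(per_gene$flagged,
                            by = list(arm = arm_grp), FUN = sum)
  names(tally)[2L] <- "n_flagged"
  attr(per_gene, "tally") <- tally
  per_gene
}
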