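#' Configuration of the fixed-SNP caller
#'
#' The rule the caller implements: a position is callable in a strain when at
#' least `min_depth` reads cover the base and the most common base accounts
#' for at least `min_major_freq` of the A/C/G/T reads; a position is a fixed
#' SNP when both strains are callable and their consensus bases differ.
#' Ambiguous (N) reads are excluded from the frequency denominator.
#'
#' @param min_depth minimum A+C+G+T read depth per strain (default 13).
#' @param min_major_freq minimum major-allele fraction per strain
#'   (default 0.95; "at least", so 19/20 qualifies).
#' @return An object of class `caller_config`.
#' @export
caller_config <- function(min_depth = 13, min_major_freq = 0.95) {
  if (min_depth < 1) stop("min_depth must be at least 1", call. = FALSE)
  if (min_major_freq <= 0.5 || min_major_freq > 1) {
    stop("min_major_freq must be in (0.5, 1]", call. = FALSE)
  }
  structure(list(min_depth = as.integer(min_depth),
                 min_major_freq = min_major_freq),
            class = "caller_config")
}

# Vectorized consensus over an n x 4 count matrix (columns A C G T).
# Returns a data frame: base, called, reason, depth, freq.
consensus_calls <- function(counts, cfg) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("base counts must be nonnegative", call. = FALSE)
  bases <- c("A", "C", "G", "T")
  depth <- rowSums(counts)
  j <- max.col(counts, ties.method = "first")
  major <- counts[cbind(seq_len(nrow(counts)), j)]
  n_at_max <- rowSums(counts == matrix(major, nrow(counts), 4L))
  tie <- n_at_max > 1L
  freq <- ifelse(depth > 0, major / depth, 0)
  called <- depth >= cfg$min_depth & !tie & freq >= cfg$min_major_freq
  # reasons in rule order: depth, then frequency, then the (defensive) tie
  # branch — a tied site cannot reach a 95% major fraction, so "tie" is
  # reachable only under nonstandard configurations.
  reason <- rep(NA_character_, nrow(counts))
  reason[depth < cfg$min_depth] <- "low_depth"
  reason[depth >= cfg$min_depth & freq < cfg$min_major_freq] <- "polymorphic"
  reason[depth >= cfg$min_depth & freq >= cfg$min_major_freq & tie] <- "tie"
  data.frame(base = ifelse(called, bases[j], NA_character_),
             called = called, reason = reason, depth = depth, freq = freq)
}

#' Consensus base of one strain at one position
#'
#' @param counts named numeric vector of read counts for bases A, C, G, T
#'   (an `N` element, if present, is ignored: ambiguous reads do not enter
#'   the frequency denominator).
#' @param cfg a [caller_config()].
#' @return List with `base` (the consensus base, or `NA` if not callable),
#'   `called`, `reason` (`NA`, or one of `"low_depth"`, `"polymorphic"`,
#'   `"tie"`), `depth` and `freq`.
#' @export
#' @examples
#' strain_consensus(c(A = 19, G = 1))$base     # "A": 19/20 meets the 95% rule
#' strain_consensus(c(A = 12))$reason          # "low_depth"
strain_consensus <- function(counts, cfg = caller_config()) {
  bases <- c("A", "C", "G", "T")
  v <- setNames(numeric(4L), bases)
  hit <- intersect(names(counts), bases)
  v[hit] <- as.numeric(counts[hit])
  res <- consensus_calls(matrix(v, 1L, 4L, dimnames = list(NULL, bases)), cfg)
  list(base = res$base, called = res$called, reason = res$reason,
       depth = res$depth, freq = res$freq)
}

#' Call SNPs fixed between two strains from base-count pileups
#'
#' Applies [strain_consensus()] to every position present in both pileups and
#' reports the positions where both strains are callable and the consensus
#' bases differ. Positions absent from either pileup are skipped. Positions
#' that are deeply covered yet fail the major-allele frequency rule in a
#' strain are tallied in the `residual_polymorphism` attribute (a diagnostic
#' of within-strain heterogeneity; not used downstream).
#'
#' @param pileup_a,pileup_b data frames with columns `chrom pos A C G T`
#'   (extra columns such as `ref`/`N` are carried along but ignored).
#' @param cfg a [caller_config()].
#' @return Data frame with one row per fixed SNP: `chrom pos allele_a
#'   allele_b depth_a depth_b freq_a freq_b`, sorted by (chrom, pos), with
#'   attribute `residual_polymorphism` (per-strain counts of deeply covered
#'   polymorphic positions).
#' @export
call_fixed_snps <- function(pileup_a, pileup_b, cfg = caller_config()) {
  for (p in list(pileup_a, pileup_b)) {
    need <- c("chrom", "pos", "A", "C", "G", "T")
    if (!all(need %in% names(p))) {
      stop("pileup must have columns ", paste(need, collapse = " "), call. = FALSE)
    }
    if (anyDuplicated(paste(p$chrom, p$pos))) {
      stop("duplicate (chrom, pos) within one strain pileup", call. = FALSE)
    }
  }
  key_a <- paste(pileup_a$chrom, pileup_a$pos)
  key_b <- paste(pileup_b$chrom, pileup_b$pos)
  shared <- intersect(key_a, key_b)
  ia <- match(shared, key_a)
  ib <- match(shared, key_b)
  ca <- consensus_calls(as.matrix(pileup_a[ia, c("A", "C", "G", "T")]), cfg)
  cb <- consensus_calls(as.matrix(pileup_b[ib, c("A", "C", "G", "T")]), cfg)
  keep <- ca$called & cb$called & ca$base != cb$base
  out <- data.frame(chrom = pileup_a$chrom[ia][keep],
                    pos = pileup_a$pos[ia][keep],
                    allele_a = ca$base[keep], allele_b = cb$base[keep],
                    depth_a = ca$depth[keep], depth_b = cb$depth[keep],
                    freq_a = ca$freq[keep], freq_b = cb$freq[keep])
  out <- out[order(out$chrom, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "residual_polymorphism") <- data.frame(
    strain = c("a", "b"),
    n_polymorphic = c(sum(ca$reason %in% "polymorphic"),
                      sum(cb$reason %in% "polymorphic"))
  )
  out
}

#' Count fixed SNPs overlapping each gene
#'
#' Counts SNPs falling inside each gene's exonic intervals (RNA-seq reads
#' span exons, so only exonic SNPs are allele-informative); set
#' `scope = "span"` to count over the whole genomic span instead. Genes with
#' zero SNPs are listed explicitly. SNPs on chromosomes absent from the
#' annotation are skipped with a warning.
#'
#' @param snps data frame from [call_fixed_snps()] (needs `chrom`, `pos`).
#' @param annotation data frame with columns `gene_id chrom exon_starts
#'   exon_ends` (1-based inclusive, comma-separated interval lists).
#' @param scope count over `"exon"` intervals (default) or the whole gene
#'   `"span"`.
#' @return Data frame `gene_id`, `n_snps`.
#' @export
genes_with_snp <- function(snps, annotation, scope = c("exon", "span")) {
  scope <- match.arg(scope)
  starts <- lapply(strsplit(as.character(annotation$exon_starts), ","), as.integer)
  ends <- lapply(strsplit(as.character(annotation$exon_ends), ","), as.integer)
  if (scope == "span") {
    starts <- lapply(starts, min)
    ends <- lapply(ends, max)
  }
  n_iv <- lengths(starts)
  iv <- GenomicRanges::GRanges(
    seqnames = rep(annotation$chrom, n_iv),
    ranges = IRanges::IRanges(start = unlist(starts), end = unlist(ends))
  )
  gene_of_iv <- rep(seq_len(nrow(annotation)), n_iv)

  known <- snps$chrom %in% annotation$chrom
  if (any(!known)) {
    warning(sum(!known), " SNP record(s) on chromosome(s) absent from the ",
            "annotation were skipped: ",
            paste(unique(snps$chrom[!known]), collapse = ", "), call. = FALSE)
    snps <- snps[known, , drop = FALSE]
  }
  n_snps <- integer(nrow(annotation))
  if (nrow(snps)) {
    sg <- GenomicRanges::GRanges(snps$chrom, IRanges::IRanges(snps$pos, snps$pos))
    hits <- GenomicRanges::findOverlaps(sg, iv)
    pair <- unique(data.frame(snp = S4Vectors::queryHits(hits),
                              gene = gene_of_iv[S4Vectors::subjectHits(hits)]))
    tab <- table(factor(pair$gene, levels = seq_len(nrow(annotation))))
    n_snps <- as.integer(tab)
  }
  data.frame(gene_id = annotation$gene_id, n_snps = n_snps)
}
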