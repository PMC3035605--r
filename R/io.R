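#' Read and write the pipeline's TSV dialects
#'
#' Plain tab-separated formats used by every stage: per-strain pileups
#' (`chrom pos ref A C G T N`), the expression matrix (`gene_id` plus one
#' column per sample), sample metadata (`sample_id sex stage replicate`),
#' gene metadata (`gene_id arm length`), and long-format allelic counts
#' (`gene_id sample_id maternal_reads paternal_reads`).
#'
#' @param path file path.
#' @return `read_pileup()` returns the pileup data frame;
#'   `read_expression()` a numeric matrix with gene rownames;
#'   `read_allelic_counts()` a list of two integer matrices
#'   (`maternal`, `paternal`) aligned to `genes` x `samples`.
#' @name pipeline-io
NULL

#' @rdname pipeline-io
#' @export
read_pileup <- function(path) {
  p <- read_tsv(path)
  need <- c("chrom", "pos", "A", "C", "G", "T")
  if (!all(need %in% names(p))) {
    stop("pileup file lacks columns: ",
         paste(setdiff(need, names(p)), collapse = ", "), call. = FALSE)
  }
  p
}

#' @rdname pipeline-io
#' @param x object to write.
#' @export
write_pileup <- function(x, path) write_tsv(x, path)

#' @rdname pipeline-io
#' @export
read_expression <- function(path) {
  d <- read_tsv(path)
  m <- as.matrix(d[, -1, drop = FALSE])
  rownames(m) <- d$gene_id
  storage.mode(m) <- "double"
  m
}

#' @rdname pipeline-io
#' @param expr expression matrix with gene rownames.
#' @export
write_expression <- function(expr, path) {
  write_tsv(data.frame(gene_id = rownames(expr), expr, check.names = FALSE), path)
}

#' @rdname pipeline-io
#' @export
read_sample_meta <- function(path) check_sample_meta(read_tsv(path))

#' @rdname pipeline-io
#' @param genes,samples character vectors of gene and sample ids defining the
#'   matrix layout for the long-format allelic counts.
#' @export
read_allelic_counts <- function(path, genes, samples) {
  d <- read_tsv(path)
  need <- c("gene_id", "sample_id", "maternal_reads", "paternal_reads")
  if (!all(need %in% names(d))) {
    stop("allelic counts file lacks columns: ",
         paste(setdiff(need, names(d)), collapse = ", "), call. = FALSE)
  }
  mk <- function(col) {
    m <- matrix(0L, length(genes), length(samples),
                dimnames = list(genes, samples))
    m[cbind(match(d$gene_id, genes), match(d$sample_id, samples))] <- as.integer(col)
    m
  }
  list(maternal = mk(d$maternal_reads), paternal = mk(d$paternal_reads))
}

#' @rdname pipeline-io
#' @param maternal,paternal count matrices as in [mzt_dataset()].
#' @export
write_allelic_counts <- function(maternal, paternal, path) {
  long <- data.frame(
    gene_id = rep(rownames(maternal), ncol(maternal)),
    sample_id = rep(colnames(maternal), each = nrow(maternal)),
    maternal_reads = as.vector(maternal),
    paternal_reads = as.vector(paternal)
  )
  write_tsv(long[long$maternal_reads + long$paternal_reads > 0, ], path)
}

#' Write a fixed-SNP table as minimal VCF
#'
#' Emits one record per SNP with the strain-A allele as REF and the strain-B
#' allele as ALT, and the per-strain alleles, depths and major-allele
#' frequencies in INFO (`SA`, `SB`, `DPA`, `DPB`).
#'
#' @param snps data frame from [call_fixed_snps()].
#' @param path output path.
#' @return The path, invisibly.
#' @export
write_snp_vcf <- function(snps, path) {
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=SA,Number=1,Type=String,Description=\"Strain A allele\">",
    "##INFO=<ID=SB,Number=1,Type=String,Description=\"Strain B allele\">",
    "##INFO=<ID=DPA,Number=1,Type=Integer,Description=\"Strain A depth\">",
    "##INFO=<ID=DPB,Number=1,Type=Integer,Description=\"Strain B depth\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"
  )
  rec <- sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\tSA=%s;SB=%s;DPA=%d;DPB=%d",
                 snps$chrom, as.integer(snps$pos), snps$allele_a, snps$allele_b,
                 snps$allele_a, snps$allele_b,
                 as.integer(snps$depth_a), as.integer(snps$depth_b))
  writeLines(c(hdr, rec), path)
  invisible(path)
}

#' Read a GTF file into the exon-level annotation table
#'
#' Collapses exon records per gene into the comma-separated interval lists
#' consumed by [genes_with_snp()]; overlapping exons are merged before the
#' exonic length is computed.
#'
#' @param path GTF file.
#' @return Data frame `gene_id chrom strand exon_starts exon_ends
#'   exonic_length`.
#' @export
read_gtf_annotation <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[gr$type == "exon"]
  if (length(gr) == 0L) stop("no exon records in GTF: ", path, call. = FALSE)
  by_gene <- split(gr, gr$gene_id)
  rows <- lapply(names(by_gene), function(g) {
    ex <- GenomicRanges::reduce(by_gene[[g]])
    data.frame(gene_id = g,
               chrom = as.character(GenomicRanges::seqnames(ex))[1],
               strand = as.character(GenomicRanges::strand(by_gene[[g]]))[1],
               exon_starts = paste(GenomicRanges::start(ex), collapse = ","),
               exon_ends = paste(GenomicRanges::end(ex), collapse = ","),
               exonic_length = sum(GenomicRanges::width(ex)))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
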