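#' Bundle an expression matrix with metadata and allelic counts
#'
#' Light container used throughout the pipeline: a genes x samples RPKM
#' matrix, per-gene metadata (chromosome arm, exonic length), per-sample
#' metadata (sex, stage, replicate) and the matched matrices of
#' allele-informative read counts assigned to the maternal and paternal
#' chromosome.
#'
#' @param expr numeric genes x samples matrix of RPKM; rownames are gene ids,
#'   colnames sample ids.
#' @param genes data frame with columns `gene_id`, `arm` and optionally
#'   `length`; one row per expression row, same order.
#' @param samples data frame with columns `sample_id`, `sex`, `stage`,
#'   `replicate`; one row per expression column, same order.
#' @param maternal_counts,paternal_counts integer matrices of
#'   allele-informative reads, same dimensions as `expr`. Genes without a
#'   fixed SNP have all-zero rows.
#' @return An object of class `mzt_dataset`.
#' @export
mzt_dataset <- function(expr, genes, samples, maternal_counts, paternal_counts) {
  expr <- as.matrix(expr)
  if (any(expr < 0)) stop("expression matrix must be nonnegative", call. = FALSE)
  if (anyDuplicated(genes$gene_id)) stop("gene ids must be unique", call. = FALSE)
  if (nrow(genes) != nrow(expr) || nrow(samples) != ncol(expr)) {
    stop("metadata dimensions do not match the expression matrix", call. = FALSE)
  }
  check_sample_meta(samples)
  for (m in list(maternal_counts, paternal_counts)) {
    if (!all(dim(m) == dim(expr))) {
      stop("allelic count matrices must match the expression matrix", call. = FALSE)
    }
    if (any(m < 0) || any(m != round(m))) {
      stop("allelic counts must be nonnegative integers", call. = FALSE)
    }
  }
  dimnames(expr) <- list(genes$gene_id, samples$sample_id)
  dimnames(maternal_counts) <- dimnames(paternal_counts) <- dimnames(expr)
  structure(list(expr = expr, genes = as.data.frame(genes),
                 samples = as.data.frame(samples),
                 maternal_counts = maternal_counts,
                 paternal_counts = paternal_counts),
            class = "mzt_dataset")
}

#' @export
print.mzt_dataset <- function(x, ...) {
  cat(sprintf("mzt_dataset: %d genes x %d samples (%d female, %d male)\n",
              nrow(x$expr), ncol(x$expr),
              sum(x$samples$sex == "F"), sum(x$samples$sex == "M")))
  cat(sprintf("  arms: %s\n",
              paste(sprintf("%s:%d", names(table(x$genes$arm)),
                            as.integer(table(x$genes$arm))), collapse = " ")))
  cat(sprintf("  genes with informative reads: %d\n",
              sum(rowSums(x$maternal_counts + x$paternal_counts) > 0)))
  invisible(x)
}

#' Report male X-linked entries with paternal-allele reads
#'
#' Males carry a single, maternally inherited X, so a valid data set has zero
#' paternal-allele reads for every X-linked gene in every male sample.
#' Violations typically indicate an embryo sexing or genotyping error; they
#' are reported rather than repaired.
#'
#' @param dataset an [mzt_dataset()].
#' @return Data frame of offending (gene, sample) pairs with the paternal
#'   read count; zero rows when the invariant holds.
#' @export
check_male_x <- function(dataset) {
  stopifnot(inherits(dataset, "mzt_dataset"))
  male <- dataset$samples$sex == "M"
  xg <- dataset$genes$arm == "X"
  bad <- which(dataset$paternal_counts[xg, male, drop = FALSE] > 0, arr.ind = TRUE)
  if (nrow(bad) == 0L) {
    return(data.frame(gene_id = character(), sample_id = character(),
                      paternal_reads = integer()))
  }
  data.frame(
    gene_id = dataset$genes$gene_id[xg][bad[, 1L]],
    sample_id = dataset$samples$sample_id[male][bad[, 2L]],
    paternal_reads = dataset$paternal_counts[xg, male, drop = FALSE][bad]
  )
}
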