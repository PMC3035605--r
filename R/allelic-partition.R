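#' Normalize samples to a constant autosomal RPKM total
#'
#' Each sample is scaled by a single scalar so that its summed autosomal
#' RPKM equals the mean pre-normalization autosomal total across samples
#' (any constant would do; the mean keeps values near the input scale).
#' X-linked genes are scaled by the same per-sample scalar, so within-sample
#' ratios are untouched.
#'
#' @param expr genes x samples RPKM matrix.
#' @param genes gene metadata data frame with columns `gene_id` and `arm`,
#'   aligned to the rows of `expr`.
#' @return The rescaled matrix, with the per-sample scalars in attribute
#'   `norm_factors`.
#' @export
#' @examples
#' expr <- rbind(a = c(10, 20), b = c(90, 180), x = c(5, 5))
#' genes <- data.frame(gene_id = c("a", "b", "x"), arm = c("2L", "3R", "X"))
#' colSums(normalize_autosomal(expr, genes)[1:2, ])  # equal autosomal totals
normalize_autosomal <- function(expr, genes) {
  expr <- as.matrix(expr)
  auto <- is_autosome(genes$arm)
  if (!any(auto)) stop("no autosomal genes to normalize against", call. = FALSE)
  totals <- colSums(expr[auto, , drop = FALSE])
  if (any(totals == 0)) {
    stop("sample(s) with zero autosomal total: ",
         paste(colnames(expr)[totals == 0], collapse = ", "), call. = FALSE)
  }
  f <- mean(totals) / totals
  out <- sweep(expr, 2L, f, `*`)
  attr(out, "norm_factors") <- f
  out
}

#' Partition RPKM into maternal- and paternal-allele components
#'
#' Splits each gene's RPKM in each sample in proportion to the fraction of
#' allele-informative reads assigned to the maternal or paternal chromosome.
#' Entries with zero informative reads are undefined (flagged, not zeroed);
#' such genes are later classified by correlation against the clustered
#' profiles rather than directly.
#'
#' @param expr genes x samples RPKM matrix.
#' @param maternal_counts,paternal_counts matching matrices of
#'   allele-informative read counts.
#' @return An object of class `partitioned_expr`: list with matrices
#'   `maternal`, `paternal` (NA where undefined), logical `defined`, and the
#'   input `expr`. Wherever defined, `maternal + paternal == expr` exactly.
#' @export
#' @examples
#' p <- partition_rpkm(matrix(30), matrix(20L), matrix(10L))
#' c(p$maternal, p$paternal)  # 20, 10
partition_rpkm <- function(expr, maternal_counts, paternal_counts) {
  expr <- as.matrix(expr)
  m <- as.matrix(maternal_counts)
  p <- as.matrix(paternal_counts)
  if (!all(dim(m) == dim(expr)) || !all(dim(p) == dim(expr))) {
    stop("count matrices must match the expression matrix", call. = FALSE)
  }
  if (any(m < 0) || any(p < 0)) stop("allelic counts must be nonnegative", call. = FALSE)
  tot <- m + p
  defined <- tot > 0
  frac_m <- ifelse(defined, m / ifelse(defined, tot, 1), NA_real_)
  maternal <- expr * frac_m
  paternal <- expr - maternal
  paternal[!defined] <- NA_real_
  structure(list(maternal = maternal, paternal = paternal,
                 defined = defined, expr = expr),
            class = "partitioned_expr")
}

#' @export
print.partitioned_expr <- function(x, ...) {
  cat(sprintf("partitioned_expr: %d genes x %d samples; %.1f%% of entries defined\n",
              nrow(x$expr), ncol(x$expr), 100 * mean(x$defined)))
  invisible(x)
}

#' Per-gene, per-sample zygotic fraction
#'
#' Zygotic transcription is biallelic on autosomes and the female X, so the
#' paternal-allele share represents half of the zygotic pool; the default
#' doubles it: `min(1, 2 p / (m + p))`. Set `doubling = FALSE` for the raw
#' paternal fraction `p / (m + p)`. The fraction is undefined (NA) where no
#' informative reads exist and for X-linked genes in male samples, where the
#' paternal allele is absent and the fraction carries no information.
#'
#' @param part a [partition_rpkm()] result.
#' @param genes,samples metadata data frames aligned to `part`.
#' @param doubling double the paternal share (default TRUE).
#' @return genes x samples matrix of fractions in \[0, 1\] (NA where
#'   undefined). Invariant to any per-sample rescaling of the expression
#'   matrix, since it depends on allele fractions only.
#' @export
zygotic_fraction <- function(part, genes, samples, doubling = TRUE) {
  stopifnot(inherits(part, "partitioned_expr"))
  frac_p <- part$paternal / ifelse(part$expr > 0, part$expr, NA_real_)
  frac_p[!part$defined] <- NA_real_
  z <- frac_p
  if (doubling) {
    z <- 2 * frac_p
    z[!is.na(z) & z > 1] <- 1
  }
  z[genes$arm == "X", samples$sex == "M"] <- NA_real_
  dimnames(z) <- dimnames(part$expr)
  z
}

#' Impute the female cycle-13 sample from its stage neighbours
#'
#' Replaces the female C13 expression column by the arithmetic mean of the
#' female C12 and female 14A columns (replicates of a neighbour stage are
#' averaged first). Intended for single-gene displays where the C13 embryo is
#' suspect; the operation is optional, flagged, and idempotent.
#'
#' @param expr genes x samples RPKM matrix.
#' @param samples sample metadata aligned to the columns.
#' @param enabled apply the imputation (default TRUE); when FALSE the matrix
#'   is returned unchanged.
#' @return The matrix, with imputed sample ids in attribute
#'   `imputed_samples`.
#' @export
impute_f13 <- function(expr, samples, enabled = TRUE) {
  if (!enabled) return(expr)
  expr <- as.matrix(expr)
  fcol <- function(stage) which(samples$sex == "F" & samples$stage == stage)
  i12 <- fcol("C12"); i14a <- fcol("14A"); i13 <- fcol("C13")
  if (length(i12) == 0L || length(i14a) == 0L) {
    stop("imputation needs female C12 and 14A samples", call. = FALSE)
  }
  if (length(i13) == 0L) stop("no female C13 sample to impute", call. = FALSE)
  imputed <- (rowMeans(expr[, i12, drop = FALSE]) +
              rowMeans(expr[, i14a, drop = FALSE])) / 2
  expr[, i13] <- imputed
  attr(expr, "imputed_samples") <- samples$sample_id[i13]
  expr
}
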