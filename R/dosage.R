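#' Replicate-averaged stage profiles for one sex
#'
#' @param expr genes x samples RPKM matrix.
#' @param samples sample metadata aligned to the columns.
#' @param sex `"F"` or `"M"`.
#' @return genes x 8 matrix, stages in order, replicates averaged.
#' @export
stage_means <- function(expr, samples, sex) {
  stages <- stage_levels()
  out <- vapply(stages, function(s) {
    cols <- which(samples$sex == sex & samples$stage == s)
    if (length(cols) == 0L) return(rep(NA_real_, nrow(expr)))
    rowMeans(expr[, cols, drop = FALSE])
  }, numeric(nrow(expr)))
  if (is.null(dim(out))) out <- matrix(out, nrow = 1L)
  dimnames(out) <- list(rownames(expr), stages)
  out
}

#' Female:male expression ratios under an expression filter
#'
#' Per-gene, per-stage ratios of replicate-averaged female to male RPKM,
#' defined only where both sexes reach `min_rpkm` (default 2, inclusive) —
#' low-expression ratios are noise-dominated and are excluded, not imputed.
#'
#' @param expr genes x samples RPKM matrix.
#' @param samples sample metadata.
#' @param gene_ids optional gene ids to restrict to (e.g. the zygotic class).
#' @param min_rpkm both-sexes expression filter (default 2).
#' @return genes x 8 matrix of ratios (NA where undefined).
#' @export
#' @examples
#' # F = 3, M = 2 -> 1.5; F = 3, M = 1 -> undefined under the filter
fm_ratio <- function(expr, samples, gene_ids = NULL, min_rpkm = 2) {
  if (!is.null(gene_ids)) expr <- expr[rownames(expr) %in% gene_ids, , drop = FALSE]
  f <- stage_means(expr, samples, "F")
  m <- stage_means(expr, samples, "M")
  ratio <- ifelse(f >= min_rpkm & m >= min_rpkm, f / m, NA_real_)
  dimnames(ratio) <- dimnames(f)
  ratio
}

#' Per-gene compensation score
#'
#' Through-origin least-squares slope of the female stage levels on the male
#' stage levels, `sum(f * m) / sum(m^2)`: a ratio estimator, so a score of
#' 1.0 means equal expression in the sexes and 2.0 means female expression
#' twice the male (an uncompensated X-linked gene). Scale-equivariant in the
#' female levels and invariant to a common rescaling of both sexes.
#'
#' @param female,male numeric stage vectors of equal length.
#' @return The slope; NA if `sum(male^2)` is zero.
#' @export
#' @examples
#' compensation_score(c(2, 4, 6), c(1, 2, 3))  # 2
compensation_score <- function(female, male) {
  if (length(female) != length(male)) {
    stop("female and male level vectors must have equal length", call. = FALSE)
  }
  ok <- is.finite(female) & is.finite(male)
  denom <- sum(male[ok]^2)
  if (denom == 0) return(NA_real_)
  sum(female[ok] * male[ok]) / denom
}

#' Compensation scores for all zygotic genes passing an expression filter
#'
#' One record per zygotic gene whose maximum RPKM over all samples strictly
#' exceeds `min_max_rpkm` (default 3.0): the per-gene score from
#' [compensation_score()] over the 8 replicate-averaged stage points, the
#' chromosome arm and the max RPKM. Scores against 1.0 (compensated) and
#' 1.5 can be tallied per arm with [score_summary()].
#'
#' @param expr genes x samples RPKM matrix.
#' @param samples,genes metadata aligned to `expr`.
#' @param classes a [classify_genes()] result, or a data frame with
#'   `gene_id`/`class` columns, or a character vector of zygotic gene ids.
#' @param min_max_rpkm expression filter (strict, default 3.0).
#' @param log2_values fit the slope on log2(RPKM + 1) instead of raw levels
#'   (off by default).
#' @return Data frame `gene_id arm score max_rpkm n_stages`.
#' @export
score_table <- function(expr, samples, genes, classes, min_max_rpkm = 3,
                        log2_values = FALSE) {
  zyg <- zygotic_ids(classes)
  keep <- genes$gene_id %in% zyg
  expr_z <- expr[keep, , drop = FALSE]
  arm_z <- genes$arm[keep]
  max_rpkm <- apply(expr_z, 1L, max)
  pass <- max_rpkm > min_max_rpkm
  expr_z <- expr_z[pass, , drop = FALSE]
  f <- stage_means(expr_z, samples, "F")
  m <- stage_means(expr_z, samples, "M")
  if (log2_values) { f <- log2(f + 1); m <- log2(m + 1) }
  score <- rowSums(f * m) / rowSums(m^2)
  data.frame(gene_id = genes$gene_id[keep][pass], arm = arm_z[pass],
             score = unname(score), max_rpkm = unname(max_rpkm[pass]),
             n_stages = ncol(f))
}

zygotic_ids <- function(classes) {
  if (is.character(classes)) return(classes)
  if (is.data.frame(classes) && all(c("gene_id", "class") %in% names(classes))) {
    return(classes$gene_id[classes$class == "zygotic"])
  }
  stop("classes must be a gene_class_table, a gene_id/class data frame, ",
       "or a character vector of zygotic gene ids", call. = FALSE)
}

#' Per-arm summary of compensation scores
#'
#' @param scores a [score_table()] result.
#' @param thresholds score thresholds to count exceedances of (strict).
#' @return Data frame with one row per chromosome arm: gene count, median
#'   score and counts above each threshold.
#' @export
score_summary <- function(scores, thresholds = c(1, 1.5)) {
  arms <- sort(unique(scores$arm))
  rows <- lapply(arms, function(a) {
    s <- scores$score[scores$arm == a]
    cnt <- vapply(thresholds, function(th) sum(s > th), integer(1))
    cbind(data.frame(arm = a, n = length(s), median_score = stats::median(s)),
          as.data.frame(as.list(setNames(cnt, paste0("n_gt_", thresholds)))))
  })
  do.call(rbind, rows)
}

#' Bin female:male ratios per stage and chromosome group
#'
#' Distributes defined ratios from [fm_ratio()] into bins (default edges at
#' 1/2, 1/1.75, 1/1.5, 1/1.25, 1, 1.25, 1.5, 1.75, 2 on the F:M axis) for
#' each stage, separately for X-linked genes and autosomes. Proportions are
#' over the genes with a defined ratio, so each (stage, group) sums to 1.
#'
#' @param ratios genes x 8 ratio matrix from [fm_ratio()].
#' @param genes gene metadata (needs `gene_id`, `arm`) for the rows of
#'   `ratios`.
#' @param bin_edges increasing numeric vector of interior bin edges.
#' @return Long data frame `stage group bin proportion n`.
#' @export
ratio_bins <- function(ratios, genes,
                       bin_edges = c(1/2, 1/1.75, 1/1.5, 1/1.25, 1,
                                     1.25, 1.5, 1.75, 2)) {
  stopifnot(!is.unsorted(bin_edges, strictly = TRUE))
  arm <- genes$arm[match(rownames(ratios), genes$gene_id)]
  group <- ifelse(arm == "X", "X", "autosomes")
  breaks <- c(0, bin_edges, Inf)
  lab <- levels(cut(1, breaks = breaks, include.lowest = TRUE, right = FALSE))
  rows <- list()
  for (s in colnames(ratios)) {
    for (g in c("autosomes", "X")) {
      r <- ratios[group == g, s]
      r <- r[!is.na(r)]
      if (length(r) == 0L) next
      b <- table(cut(r, breaks = breaks, include.lowest = TRUE, right = FALSE))
      rows[[length(rows) + 1L]] <- data.frame(
        stage = s, group = g, bin = lab,
        proportion = as.numeric(b) / length(r), n = as.integer(b))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Chromosome-level parental-origin aggregates for zygotic genes
#'
#' Sums the maternal- and paternal-allele expression components of zygotic
#' genes per (chromosome arm, sex, stage); replicates are averaged within a
#' stage before summing. Entries with undefined partition (no informative
#' reads) are excluded from both the components and the matched total, so
#' maternal + paternal = total holds exactly.
#'
#' @param part a [partition_rpkm()] result.
#' @param samples,genes metadata aligned to `part`.
#' @param classes zygotic gene ids (any form accepted by [score_table()]).
#' @return Long data frame `arm sex stage maternal paternal total n_genes`.
#' @export
chrom_aggregate <- function(part, samples, genes, classes) {
  stopifnot(inherits(part, "partitioned_expr"))
  zyg <- zygotic_ids(classes)
  keep <- genes$gene_id %in% zyg
  mat <- part$maternal[keep, , drop = FALSE]
  pat <- part$paternal[keep, , drop = FALSE]
  def <- part$defined[keep, , drop = FALSE]
  tot <- part$expr[keep, , drop = FALSE] * ifelse(def, 1, NA_real_)
  arm <- genes$arm[keep]
  rows <- list()
  for (a in sort(unique(arm))) {
    ra <- arm == a
    for (sex in c("F", "M")) {
      for (s in stage_levels()) {
        cols <- which(samples$sex == sex & samples$stage == s)
        if (length(cols) == 0L) next
        msum <- mean(colSums(mat[ra, cols, drop = FALSE], na.rm = TRUE))
        psum <- mean(colSums(pat[ra, cols, drop = FALSE], na.rm = TRUE))
        tsum <- mean(colSums(tot[ra, cols, drop = FALSE], na.rm = TRUE))
        rows[[length(rows) + 1L]] <- data.frame(
          arm = a, sex = sex, stage = s, maternal = msum, paternal = psum,
          total = tsum, n_genes = sum(ra))
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
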