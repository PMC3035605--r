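#' Allele-resolved female time profiles
#'
#' Builds, for every gene, the 8-stage female profile used by the
#' classifier: replicate-averaged total RPKM, maternal- and paternal-allele
#' components obtained by read-weighted pooling (counts are summed over the
#' replicates of a stage before the allele fraction is applied to the stage
#' mean), and the total allele-informative read count over all female
#' samples. Only female samples enter: X-linked genes in males lack the
#' paternal allele, so assignments are based on females throughout.
#'
#' When a stage has zero pooled informative reads the allele fraction is
#' unknown; the components fall back to maternal = total, paternal = 0
#' (at negligible coverage the total is itself near zero, so the choice has
#' no practical weight).
#'
#' @param dataset an [mzt_dataset()].
#' @return Object of class `gene_profiles`: list of matrices `maternal`,
#'   `paternal`, `total` (genes x 8 stages), integer vector `reads`, and
#'   `gene_id`.
#' @export
build_gene_profiles <- function(dataset) {
  stopifnot(inherits(dataset, "mzt_dataset"))
  stages <- stage_levels()
  fem <- dataset$samples$sex == "F"
  missing <- setdiff(stages, unique(dataset$samples$stage[fem]))
  if (length(missing)) {
    stop("missing female samples for stage(s): ",
         paste(paste0("(F,", missing, ")"), collapse = " "), call. = FALSE)
  }
  n <- nrow(dataset$expr)
  total <- maternal <- paternal <- matrix(0, n, 8L,
                                          dimnames = list(dataset$genes$gene_id, stages))
  for (s in seq_along(stages)) {
    cols <- which(fem & dataset$samples$stage == stages[s])
    tot <- rowMeans(dataset$expr[, cols, drop = FALSE])
    m <- rowSums(dataset$maternal_counts[, cols, drop = FALSE])
    p <- rowSums(dataset$paternal_counts[, cols, drop = FALSE])
    frac_m <- ifelse(m + p > 0, m / pmax(m + p, 1), 1)
    total[, s] <- tot
    maternal[, s] <- tot * frac_m
    paternal[, s] <- tot * (1 - frac_m)
  }
  reads <- rowSums(dataset$maternal_counts[, fem, drop = FALSE] +
                   dataset$paternal_counts[, fem, drop = FALSE])
  structure(list(maternal = maternal, paternal = paternal, total = total,
                 reads = as.integer(reads), gene_id = dataset$genes$gene_id),
            class = "gene_profiles")
}

#' Genes with enough allele-informative reads for direct classification
#'
#' @param profiles a [build_gene_profiles()] result.
#' @param min_reads minimum summed informative reads over the female samples
#'   (default 10, inclusive).
#' @return The subset `gene_profiles` object.
#' @export
select_informative <- function(profiles, min_reads = 10) {
  stopifnot(inherits(profiles, "gene_profiles"))
  keep <- profiles$reads >= min_reads
  structure(list(maternal = profiles$maternal[keep, , drop = FALSE],
                 paternal = profiles$paternal[keep, , drop = FALSE],
                 total = profiles$total[keep, , drop = FALSE],
                 reads = profiles$reads[keep],
                 gene_id = profiles$gene_id[keep]),
            class = "gene_profiles")
}

#' Kinetic label of a cluster centroid
#'
#' Applies the rule-based reading of the three canonical archetypes to a
#' centroid on the linear RPKM scale: *maternal* if no paternal signal ever
#' reaches the detection floor and the maternal level declines from C10 to
#' 14D; *zygotic* if there is no detectable mRNA at C10 but paternal signal
#' appears; *maternal+zygotic* if maternal mRNA is present at C10 and
#' paternal signal appears later; otherwise *unclassified*.
#'
#' @param maternal,paternal numeric length-8 stage vectors (linear RPKM).
#' @param eps detection floor in RPKM (default 0.5).
#' @return One of `"maternal"`, `"zygotic"`, `"maternal_zygotic"`,
#'   `"unclassified"`.
#' @export
label_cluster <- function(maternal, paternal, eps = 0.5) {
  stopifnot(length(maternal) == 8L, length(paternal) == 8L)
  total_c10 <- maternal[1L] + paternal[1L]
  if (max(paternal) < eps && maternal[8L] < maternal[1L]) return("maternal")
  if (total_c10 < eps && max(paternal) >= eps) return("zygotic")
  if (maternal[1L] >= eps && max(paternal) >= eps) return("maternal_zygotic")
  "unclassified"
}

#' Assign a gene to the best-correlated cluster
#'
#' Pearson (or Spearman) correlation between an 8-stage total-expression
#' profile and each cluster's mean total profile; the best cluster's label is
#' adopted only if the correlation strictly exceeds `r_threshold`. Ties go to
#' the lower cluster index. A constant (zero-variance) profile has no defined
#' correlation and stays unclassified.
#'
#' @param total numeric length-8 total-expression profile.
#' @param cluster_means k x 8 matrix of cluster mean total profiles.
#' @param labels character vector of cluster labels.
#' @param r_threshold propagation threshold (default 0.8, strict).
#' @param method correlation type.
#' @return List with `class`, `cluster` (NA if unassigned), `r`.
#' @export
propagate <- function(total, cluster_means, labels, r_threshold = 0.8,
                      method = c("pearson", "spearman")) {
  method <- match.arg(method)
  stopifnot(length(total) == ncol(cluster_means))
  if (!all(is.finite(total)) || stats::sd(total) == 0) {
    return(list(class = "unclassified", cluster = NA_integer_, r = NA_real_))
  }
  r <- apply(cluster_means, 1L, function(cm) {
    if (stats::sd(cm) == 0) return(NA_real_)
    stats::cor(total, cm, method = method)
  })
  if (all(is.na(r))) {
    return(list(class = "unclassified", cluster = NA_integer_, r = NA_real_))
  }
  best <- which.max(r)  # first max: ties break to the lower index
  if (r[best] > r_threshold) {
    list(class = labels[best], cluster = as.integer(best), r = unname(r[best]))
  } else {
    list(class = "unclassified", cluster = NA_integer_, r = unname(r[best]))
  }
}

#' Classify genes as maternal, zygotic or maternal+zygotic
#'
#' End-to-end classifier. Female allele-resolved profiles are built; genes
#' with at least `min_reads` informative reads are clustered by k-medians on
#' the log2(RPKM + 1) transformed 16-vector (maternal 8 + paternal 8); each
#' cluster is labeled from its back-transformed centroid; every remaining
#' gene is assigned the label of the cluster whose mean total-expression
#' profile best correlates with its own, provided the correlation strictly
#' exceeds `r_threshold` and the gene is ever detected above the `eps` floor.
#'
#' @param dataset an [mzt_dataset()]; female samples must cover all 8 stages.
#' @param k number of clusters (default 20).
#' @param seed RNG seed for the clustering restarts.
#' @param n_restarts k-medians restarts.
#' @param min_reads direct-route read threshold (default 10).
#' @param r_threshold propagation correlation threshold (default 0.8).
#' @param eps detection floor in RPKM used for labeling and as the minimum
#'   detected level for propagation (default 0.5).
#' @param cor_method correlation type for propagation.
#' @return Object of class `gene_class_table`: data frame with columns
#'   `gene_id`, `class`, `route` (`direct`, `propagated`, `none`), `cluster`,
#'   `correlation`; the fitted [kmedians()] model, cluster labels and cluster
#'   mean profiles are in attribute `model`.
#' @export
#' @examples
#' sim <- simulate_timecourse(sim_config(n_genes = 300, seed = 3))
#' cl <- classify_genes(sim$dataset, k = 10, seed = 17)
#' summary(cl)
classify_genes <- function(dataset, k = 20, seed = 17L, n_restarts = 20,
                           min_reads = 10, r_threshold = 0.8, eps = 0.5,
                           cor_method = c("pearson", "spearman")) {
  cor_method <- match.arg(cor_method)
  profiles <- build_gene_profiles(dataset)
  inf <- select_informative(profiles, min_reads)
  if (nrow(inf$total) < k) {
    stop("fewer informative genes (", nrow(inf$total),
         ") than clusters (k = ", k, ")", call. = FALSE)
  }
  xv <- log2(cbind(inf$maternal, inf$paternal) + 1)
  km <- kmedians(xv, k = k, seed = seed, n_restarts = n_restarts)
  back <- pmax(2^km$centroids - 1, 0)
  labels <- vapply(seq_len(k), function(j) {
    label_cluster(back[j, 1:8], back[j, 9:16], eps = eps)
  }, character(1))
  # Mean total-expression pattern per cluster, on the same log2(x + 1)
  # scale as the clustering: the log scale preserves the early-stage
  # maternal baseline that separates maternal+zygotic patterns from pure
  # zygotic ones, which linear Pearson correlation would centre away.
  cluster_means <- t(vapply(seq_len(k), function(j) {
    colMeans(log2(inf$total[km$cluster == j, , drop = FALSE] + 1))
  }, numeric(8L)))

  n <- length(profiles$gene_id)
  out <- data.frame(gene_id = profiles$gene_id,
                    class = "unclassified",
                    route = "none",
                    cluster = NA_integer_,
                    correlation = NA_real_)
  direct <- match(inf$gene_id, profiles$gene_id)
  out$class[direct] <- labels[km$cluster]
  out$route[direct] <- "direct"
  out$cluster[direct] <- km$cluster

  rest <- setdiff(seq_len(n), direct)
  for (i in rest) {
    tot <- profiles$total[i, ]
    if (max(tot) < eps) next  # never detected: no class can be claimed
    pr <- propagate(log2(tot + 1), cluster_means, labels, r_threshold, cor_method)
    out$correlation[i] <- pr$r
    if (pr$class != "unclassified") {
      out$class[i] <- pr$class
      out$route[i] <- "propagated"
      out$cluster[i] <- pr$cluster
    }
  }
  structure(out, class = c("gene_class_table", "data.frame"),
            model = list(kmedians = km, labels = labels,
                         cluster_means = cluster_means, eps = eps,
                         min_reads = min_reads, r_threshold = r_threshold))
}

#' @export
summary.gene_class_table <- function(object, ...) {
  tab <- table(class = object$class, route = object$route)
  cat("Gene classification summary\n")
  print(tab)
  invisible(tab)
}

#' @export
print.gene_class_table <- function(x, ...) {
  cat(sprintf("gene_class_table: %d genes (%d direct, %d propagated, %d unassigned)\n",
              nrow(x), sum(x$route == "direct"), sum(x$route == "propagated"),
              sum(x$route == "none")))
  cls <- table(x$class)
  cat("  classes:", paste(sprintf("%s:%d", names(cls), as.integer(cls)),
                          collapse = " "), "\n")
  invisible(x)
}

#' Export the cluster model for audit
#'
#' @param classes a [classify_genes()] result.
#' @return Data frame with one row per cluster: label, size, and the 16
#'   centroid coordinates (log2 scale, maternal then paternal stages).
#' @export
cluster_model_table <- function(classes) {
  model <- attr(classes, "model")
  km <- model$kmedians
  cent <- km$centroids
  colnames(cent) <- c(paste0("mat_", stage_levels()), paste0("pat_", stage_levels()))
  data.frame(cluster = seq_len(km$k), label = model$labels,
             size = tabulate(km$cluster, km$k), cent, check.names = FALSE)
}
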