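#' Pipeline configuration
#'
#' One nested configuration covering every stage. The defaults are the
#' thresholds the analysis is built around: SNP calling at depth >= 13 and
#' major-allele frequency >= 0.95; direct classification for genes with >= 10
#' informative reads, k = 20 clusters, propagation at correlation > 0.8;
#' female:male ratios filtered at >= 2 RPKM in both sexes and compensation
#' scores at maximum RPKM > 3.0; SXL targets at >= 3 consensus sites.
#'
#' @param seed global seed; per-stage seeds are derived from it
#'   deterministically so stages can be rerun in isolation.
#' @param simulate generate inputs with the synthetic-data module (default)
#'   instead of reading them from `inputs`.
#' @param sim a [sim_config()] for the simulated inputs (its own seed is
#'   overridden by a seed derived from `seed`).
#' @param caller,classify,dosage,sxl per-stage settings (lists).
#' @param inputs named paths for a real-data run: `expr`, `samples`,
#'   `counts`, `genes` (gene metadata with `gene_id` and `arm`), `pileup_a`,
#'   `pileup_b`, and optionally `annotation` (exon-level table for SNP-in-gene
#'   counting) and `utr_fasta`.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L,
                            simulate = TRUE,
                            sim = sim_config(),
                            caller = list(min_depth = 13, min_major_freq = 0.95),
                            classify = list(k = 20, n_restarts = 20,
                                            min_reads = 10, r_threshold = 0.8,
                                            eps = 0.5),
                            dosage = list(min_rpkm = 2, min_max_rpkm = 3),
                            sxl = list(min_sites = 3),
                            inputs = list()) {
  structure(list(seed = as.integer(seed), simulate = isTRUE(simulate),
                 sim = sim, caller = caller, classify = classify,
                 dosage = dosage, sxl = sxl, inputs = inputs),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Keys mirror the arguments of [pipeline_config()]; omitted keys keep their
#' defaults, and `sim` keys are passed through to [sim_config()].
#'
#' @param path YAML file.
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("missing input file: ", path, call. = FALSE)
  y <- yaml::read_yaml(path)
  defaults <- pipeline_config()
  cfg <- utils::modifyList(unclass(defaults), y[setdiff(names(y), "sim")])
  if (!is.null(y$sim)) cfg$sim <- do.call(sim_config, y$sim)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Run the full analysis end to end
#'
#' Executes (simulate ->) SNP calling -> normalization and allelic partition
#' -> maternal/zygotic classification -> dosage-compensation scoring
#' (-> SXL scan when UTR sequences are supplied) and writes every
#' intermediate and final table to `out_dir` as TSV, together with a
#' `manifest.yaml` (configuration, derived seeds, package version, file
#' checksums) and a plain-text `summary.txt`. A fixed seed makes the run
#' byte-identical.
#'
#' @param config a [pipeline_config()] or a path to a YAML file.
#' @param out_dir output directory (created if needed).
#' @return Invisibly, a list with the main in-memory results.
#' @export
#' @examples
#' \donttest{
#' out <- run_pipeline(pipeline_config(seed = 7, sim = sim_config(n_genes = 300)),
#'                     out_dir = tempfile("mztrun"))
#' }
run_pipeline <- function(config = pipeline_config(), out_dir) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_stage <- function(...) message("[mztcomp] ", ...)
  stage <- function(name, code) {
    log_stage("stage: ", name)
    tryCatch(code, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  paths <- character(0)
  put <- function(x, file) {
    p <- file.path(out_dir, file)
    write_tsv(x, p)
    paths[[length(paths) + 1L]] <<- p
    p
  }

  sim_seed <- derive_seed(config$seed, 1L)
  cluster_seed <- derive_seed(config$seed, 2L)

  if (config$simulate) {
    inputs <- stage("simulate", {
      scfg <- config$sim
      scfg$seed <- sim_seed
      sim <- simulate_timecourse(scfg)
      piles <- simulate_strain_pileups(scfg)
      annotation <- simulate_annotation(n_genes = 100, seed = sim_seed)
      put(data.frame(sim$truth$genes), "truth.tsv")
      put(piles$truth, "pileup_truth.tsv")
      list(dataset = sim$dataset, pileup_a = piles$pileup_a,
           pileup_b = piles$pileup_b, annotation = annotation,
           utr_fasta = NULL, truth = sim$truth)
    })
  } else {
    inputs <- stage("read-inputs", {
      req <- c("expr", "samples", "counts", "genes", "pileup_a", "pileup_b")
      for (k in req) {
        if (is.null(config$inputs[[k]])) {
          stop("config$inputs$", k, " is required when simulate = FALSE")
        }
      }
      expr <- read_expression(config$inputs$expr)
      samples <- read_sample_meta(config$inputs$samples)
      counts <- read_allelic_counts(config$inputs$counts,
                                    rownames(expr), samples$sample_id)
      genes_meta <- read_tsv(config$inputs$genes)
      gm <- data.frame(gene_id = rownames(expr),
                       arm = genes_meta$arm[match(rownames(expr),
                                                  genes_meta$gene_id)])
      ann <- if (!is.null(config$inputs$annotation)) {
        read_tsv(config$inputs$annotation)
      }
      list(dataset = mzt_dataset(expr, gm, samples,
                                 counts$maternal, counts$paternal),
           pileup_a = read_pileup(config$inputs$pileup_a),
           pileup_b = read_pileup(config$inputs$pileup_b),
           annotation = ann,
           utr_fasta = config$inputs$utr_fasta, truth = NULL)
    })
  }
  ds <- inputs$dataset
  put(ds$samples, "samples.tsv")
  put(ds$genes, "genes.tsv")
  write_expression(ds$expr, file.path(out_dir, "expr.tsv"))
  write_allelic_counts(ds$maternal_counts, ds$paternal_counts,
                       file.path(out_dir, "allelic.tsv"))
  put(inputs$pileup_a, "pileup_a.tsv")
  put(inputs$pileup_b, "pileup_b.tsv")

  snps <- stage("callsnps", {
    cc <- caller_config(config$caller$min_depth, config$caller$min_major_freq)
    s <- call_fixed_snps(inputs$pileup_a, inputs$pileup_b, cc)
    put(s, "snps.tsv")
    write_snp_vcf(s, file.path(out_dir, "snps.vcf"))
    if (!is.null(inputs$annotation)) {
      put(genes_with_snp(s, inputs$annotation), "gene_snp_counts.tsv")
    }
    s
  })

  part <- stage("partition", {
    norm <- normalize_autosomal(ds$expr, ds$genes)
    p <- partition_rpkm(norm, ds$maternal_counts, ds$paternal_counts)
    write_expression(norm, file.path(out_dir, "expr_normalized.tsv"))
    write_expression(ifelse(is.na(p$maternal), 0, p$maternal),
                     file.path(out_dir, "maternal_component.tsv"))
    write_expression(ifelse(is.na(p$paternal), 0, p$paternal),
                     file.path(out_dir, "paternal_component.tsv"))
    ds$expr <- norm
    p
  })
  nds <- mzt_dataset(part$expr, ds$genes, ds$samples,
                     ds$maternal_counts, ds$paternal_counts)

  classes <- stage("classify", {
    cl <- classify_genes(nds, k = config$classify$k, seed = cluster_seed,
                         n_restarts = config$classify$n_restarts,
                         min_reads = config$classify$min_reads,
                         r_threshold = config$classify$r_threshold,
                         eps = config$classify$eps)
    put(as.data.frame(cl), "classes.tsv")
    put(cluster_model_table(cl), "cluster_model.tsv")
    cl
  })

  dosage <- stage("score", {
    scores <- score_table(nds$expr, nds$samples, nds$genes, classes,
                          min_max_rpkm = config$dosage$min_max_rpkm)
    ratios <- fm_ratio(nds$expr, nds$samples, zygotic_ids(classes),
                       min_rpkm = config$dosage$min_rpkm)
    bins <- ratio_bins(ratios, nds$genes)
    aggr <- chrom_aggregate(part, nds$samples, nds$genes, classes)
    put(scores, "scores.tsv")
    put(data.frame(gene_id = rownames(ratios), ratios, check.names = FALSE),
        "ratios.tsv")
    put(bins, "bins.tsv")
    put(aggr, "aggregates.tsv")
    list(scores = scores, ratios = ratios, bins = bins, aggregates = aggr)
  })

  sxl <- NULL
  if (!is.null(inputs$utr_fasta)) {
    sxl <- stage("scan-sxl", {
      flags <- scan_sxl(read_utr_fasta(inputs$utr_fasta),
                        min_sites = config$sxl$min_sites)
      put(flags, "sxl.tsv")
      flags
    })
  }

  stage("manifest", {
    cfg_path <- file.path(out_dir, "config.yaml")
    yaml::write_yaml(serializable_config(config), cfg_path)
    manifest <- list(
      package = "mztcomp",
      version = as.character(utils::packageVersion("mztcomp")),
      seed = config$seed,
      derived_seeds = list(simulate = sim_seed, cluster = cluster_seed),
      config_md5 = unname(tools::md5sum(cfg_path)),
      outputs = as.list(setNames(unname(tools::md5sum(unlist(paths))),
                                 basename(unlist(paths))))
    )
    yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))

    cls <- table(classes$class)
    lines <- c(
      "mztcomp pipeline summary",
      sprintf("genes: %d  samples: %d", nrow(nds$expr), ncol(nds$expr)),
      sprintf("fixed SNPs called: %d", nrow(snps)),
      sprintf("classes: %s",
              paste(sprintf("%s=%d", names(cls), as.integer(cls)), collapse = " ")),
      sprintf("zygotic genes scored (max RPKM > %.1f): %d",
              config$dosage$min_max_rpkm, nrow(dosage$scores)),
      capture_summary(score_summary(dosage$scores))
    )
    writeLines(lines, file.path(out_dir, "summary.txt"))
  })
  log_stage("done: ", out_dir)
  invisible(list(dataset = nds, snps = snps, partition = part,
                 classes = classes, dosage = dosage, sxl = sxl,
                 truth = inputs$truth))
}

capture_summary <- function(df) {
  utils::capture.output(print(df, row.names = FALSE))
}

serializable_config <- function(config) {
  x <- unclass(config)
  x$sim <- unclass(x$sim)
  x
}
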