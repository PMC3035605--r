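#' Simulate the staged single-embryo expression time course
#'
#' Generates the full 24-sample design with known ground truth: per-gene true
#' class (maternal, zygotic, maternal+zygotic or silent), expected expression
#' profiles per sex, and allele-informative read counts.
#'
#' Kinetics are parameterized on the integer stage axis t = 0..7 over
#' C10..14D. Maternal transcripts start at a per-gene scale M0 and decay as
#' `M0 * exp(-d_g * t)` with a gene-specific rate `d_g` (lognormal around
#' `decay_rate`); all their informative reads carry the maternal allele.
#' Zygotic transcripts rise as `Z0 * plogis(steepness * (t - onset_g))` with
#' a gene-jittered onset centre
#' and their reads split Binomial(n, 1/2) between the parental alleles on
#' autosomes and the female X. For X-linked genes in males the paternal
#' allele is absent: all reads are maternal and the expected male level is the
#' per-X-copy female level times `2 / c`, i.e. female_total / c, where c is
#' the gene's true compensation target (c = 1 fully compensated, c = 2
#' proportional to X copy number). Observed RPKM is the expected level times
#' multiplicative lognormal noise; informative depth per (gene, sample) is
#' Poisson with mean `depth_mean * RPKM` (zero for SNP-free genes).
#'
#' @param cfg a [sim_config()].
#' @return An object of class `mzt_sim`: a list with elements `dataset`
#'   (an [mzt_dataset()]) and `truth` (list with per-gene data frame `genes`
#'   and expected-profile matrices `expected_female`, `expected_male`,
#'   `expected_maternal`, `expected_zygotic_female`, `expected_zygotic_male`,
#'   all genes x 8 stages).
#' @export
#' @examples
#' sim <- simulate_timecourse(sim_config(n_genes = 100, seed = 7))
#' sim$dataset
#' table(sim$truth$genes$class)
simulate_timecourse <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(cfg$seed, {
    n <- cfg$n_genes
    t <- 0:7
    gene_id <- sprintf("g%05d", seq_len(n))

    arm <- ifelse(stats::runif(n) < cfg$frac_x, "X",
                  sample(c("2L", "2R", "3L", "3R"), n, replace = TRUE))
    len <- as.integer(round(stats::rlnorm(n, log(2000), 0.5)))
    frac_silent <- 1 - cfg$frac_maternal - cfg$frac_zygotic - cfg$frac_mat_zyg
    cls <- sample(c("maternal", "zygotic", "maternal_zygotic", "silent"), n,
                  replace = TRUE,
                  prob = c(cfg$frac_maternal, cfg$frac_zygotic,
                           cfg$frac_mat_zyg, frac_silent))
    has_snp <- stats::runif(n) < cfg$frac_with_snp
    amp_m <- stats::rlnorm(n, cfg$expr_meanlog, cfg$expr_sdlog)
    amp_z <- stats::rlnorm(n, cfg$expr_meanlog, cfg$expr_sdlog)
    M0 <- ifelse(cls %in% c("maternal", "maternal_zygotic"), amp_m, 0)
    Z0 <- ifelse(cls %in% c("zygotic", "maternal_zygotic"), amp_z, 0)
    comp <- ifelse(arm == "X",
                   stats::runif(n, cfg$compensation_range[1], cfg$compensation_range[2]),
                   NA_real_)

    decay_g <- cfg$decay_rate * exp(stats::rnorm(n, 0, cfg$decay_cv))
    onset_g <- cfg$onset_stage + stats::rnorm(n, 0, cfg$onset_sd)
    tmat <- matrix(t, n, 8L, byrow = TRUE)
    maternal <- M0 * exp(-decay_g * tmat)
    zyg_f <- Z0 * stats::plogis(cfg$onset_steepness * (tmat - onset_g))
    zyg_m <- zyg_f
    on_x <- arm == "X"
    if (any(on_x)) zyg_m[on_x, ] <- zyg_f[on_x, , drop = FALSE] / comp[on_x]
    bg <- ifelse(cls == "silent", cfg$silent_rpkm, 0)
    exp_f <- maternal + zyg_f + bg
    exp_m <- maternal + zyg_m + bg
    stage_names <- cfg$stages
    dimnames(exp_f) <- dimnames(exp_m) <- dimnames(maternal) <-
      dimnames(zyg_f) <- dimnames(zyg_m) <- list(gene_id, stage_names)

    samples <- do.call(rbind, lapply(c("F", "M"), function(sex) {
      do.call(rbind, lapply(seq_along(stage_names), function(s) {
        data.frame(sample_id = sprintf("%s_%s_%d", sex, stage_names[s],
                                       seq_len(cfg$replicates[s])),
                   sex = sex, stage = stage_names[s],
                   replicate = seq_len(cfg$replicates[s]))
      }))
    }))
    ns <- nrow(samples)
    stage_idx <- match(samples$stage, stage_names)

    expected <- matrix(0, n, ns)
    zyg_expected <- matrix(0, n, ns)
    mat_expected <- matrix(0, n, ns)
    for (j in seq_len(ns)) {
      src_z <- if (samples$sex[j] == "F") zyg_f else zyg_m
      zyg_expected[, j] <- src_z[, stage_idx[j]]
      mat_expected[, j] <- maternal[, stage_idx[j]] + bg
      expected[, j] <- mat_expected[, j] + zyg_expected[, j]
    }
    noise <- matrix(stats::rlnorm(n * ns, 0, cfg$noise_sd), n, ns)
    rpkm <- expected * noise
    if (is.finite(cfg$count_scale)) {
      # read-count quantization: lowly expressed genes give 0, 1, 2 reads
      rpkm <- matrix(stats::rpois(n * ns, rpkm * cfg$count_scale), n, ns) /
        cfg$count_scale
    }

    # Allele-informative reads: zygotic reads are biallelic except on the
    # male X, maternal deposit and silent background are maternal-allele only.
    depth_lambda <- cfg$depth_mean * rpkm * has_snp
    n_reads <- matrix(stats::rpois(n * ns, depth_lambda), n, ns)
    p_pat <- zyg_expected / ifelse(expected > 0, expected, 1) / 2
    male_col <- samples$sex == "M"
    p_pat[on_x, male_col] <- 0
    pat <- matrix(stats::rbinom(n * ns, as.vector(n_reads), as.vector(p_pat)), n, ns)
    mat_reads <- n_reads - pat

    dataset <- mzt_dataset(
      expr = rpkm,
      genes = data.frame(gene_id = gene_id, arm = arm, length = len),
      samples = samples,
      maternal_counts = mat_reads,
      paternal_counts = pat
    )
    truth <- list(
      genes = data.frame(gene_id = gene_id, class = cls, arm = arm,
                         has_snp = has_snp, compensation = comp,
                         maternal_scale = M0, zygotic_scale = Z0,
                         decay_rate = decay_g, onset_stage = onset_g),
      expected_female = exp_f, expected_male = exp_m,
      expected_maternal = maternal,
      expected_zygotic_female = zyg_f, expected_zygotic_male = zyg_m
    )
    structure(list(dataset = dataset, truth = truth, config = cfg),
              class = "mzt_sim")
  })
}

#' @export
print.mzt_sim <- function(x, ...) {
  cat("Synthetic embryo time course (with ground truth)\n")
  print(x$dataset)
  cat("  true classes:",
      paste(sprintf("%s:%d", names(table(x$truth$genes$class)),
                    as.integer(table(x$truth$genes$class))), collapse = " "),
      "\n")
  invisible(x)
}
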