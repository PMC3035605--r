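#' Configuration for the synthetic embryo time-course generator
#'
#' Bundles every tunable of the synthetic-data module. The defaults emulate
#' the study design the package targets: 24 single-embryo samples (12 female,
#' 12 male; one embryo per sex at mitotic cycles 10-13, two per sex at the
#' cellularization sub-stages 14A-14D), maternally deposited transcripts that
#' decay exponentially over the stage axis, zygotic transcripts that rise by a
#' logistic onset centred in mid cycle 14, roughly 70% of genes carrying at
#' least one fixed SNP between the parental strains, biallelic zygotic
#' transcription on autosomes and the female X, and a per-gene X compensation
#' level giving female:male ratios between 1.0 and 2.0.
#'
#' @param n_genes number of genes to simulate.
#' @param frac_x fraction of genes placed on the X chromosome arm.
#' @param frac_maternal,frac_zygotic,frac_mat_zyg fractions of genes in the
#'   maternal, zygotic and maternal+zygotic classes; the remainder is silent
#'   (low constant background). Must be nonnegative and sum to at most 1.
#' @param frac_with_snp fraction of genes carrying at least one fixed SNP and
#'   therefore yielding allele-informative reads.
#' @param stages ordered stage labels; length 8.
#' @param replicates embryos per sex at each stage; length 8.
#' @param decay_rate median exponential decay of maternal transcript level
#'   per unit of the integer stage axis t = 0..7.
#' @param decay_cv lognormal spread (sd on the log scale) of per-gene decay
#'   rates around `decay_rate`; transcripts of different genes degrade at
#'   different rates, which is what makes time-profile clustering informative.
#' @param onset_stage,onset_steepness centre and steepness of the logistic
#'   zygotic onset on the stage axis.
#' @param onset_sd per-gene normal jitter of the onset centre.
#' @param compensation_range range (within \[1, 2\]) from which each X-linked
#'   gene's true female:male compensation target is drawn uniformly; use
#'   `c(c, c)` to fix a single level. 1.0 is fully compensated, 2.0 is
#'   transcription strictly proportional to X copy number.
#' @param noise_sd standard deviation (log scale) of the multiplicative
#'   lognormal noise applied to every expression value.
#' @param count_scale reads per RPKM unit used to emulate the discreteness
#'   of read counting: observed RPKM is Poisson-quantized at this resolution,
#'   so lowly expressed genes yield exact zeros and tied low values, as real
#'   single-embryo libraries do. `Inf` disables quantization (continuous
#'   RPKM), which is convenient for closed-form checks.
#' @param depth_mean expected allele-informative reads per RPKM unit per
#'   sample; per-(gene, sample) depths are Poisson with this rate times the
#'   observed RPKM (zero for genes without a fixed SNP).
#' @param expr_meanlog,expr_sdlog lognormal parameters of the per-gene
#'   maternal and zygotic amplitude scales (RPKM).
#' @param silent_rpkm constant background level of silent genes.
#' @param n_positions,frac_fixed_snp,pileup_depth genome/pileup simulation:
#'   number of simulated positions, fraction of them that are genuinely fixed
#'   differences, and mean read depth at callable positions.
#' @param seed RNG seed; a fixed seed reproduces all outputs exactly.
#'
#' @return An object of class `sim_config` (a validated list).
#' @seealso [simulate_timecourse()], [simulate_strain_pileups()]
#' @export
#' @examples
#' cfg <- sim_config(n_genes = 200, seed = 42)
#' cfg$frac_with_snp
sim_config <- function(n_genes = 2000,
                       frac_x = 0.15,
                       frac_maternal = 0.38,
                       frac_zygotic = 0.15,
                       frac_mat_zyg = 0.08,
                       frac_with_snp = 0.70,
                       stages = stage_levels(),
                       replicates = c(1, 1, 1, 1, 2, 2, 2, 2),
                       decay_rate = 0.3,
                       decay_cv = 0.4,
                       onset_stage = 5,
                       onset_steepness = 1.5,
                       onset_sd = 0.4,
                       compensation_range = c(1, 2),
                       noise_sd = 0.2,
                       count_scale = 30,
                       depth_mean = 2,
                       expr_meanlog = log(20),
                       expr_sdlog = 1,
                       silent_rpkm = 0.01,
                       n_positions = 500,
                       frac_fixed_snp = 0.2,
                       pileup_depth = 30,
                       seed = 1L) {
  bad <- function(msg) stop("sim_config: ", msg, call. = FALSE)
  fr <- c(frac_maternal, frac_zygotic, frac_mat_zyg)
  if (any(!is.finite(fr)) || any(fr < 0)) bad("class fractions must be nonnegative")
  if (sum(fr) > 1 + 1e-12) bad("class fractions must sum to at most 1")
  if (frac_x < 0 || frac_x > 1) bad("frac_x must be in [0, 1]")
  if (frac_with_snp < 0 || frac_with_snp > 1) bad("frac_with_snp must be in [0, 1]")
  if (length(stages) != 8L) bad("stages must list exactly 8 labels")
  if (length(replicates) != 8L || any(replicates < 1)) {
    bad("replicates must give a positive count for each of the 8 stages")
  }
  if (n_genes < 1) bad("n_genes must be positive")
  if (decay_rate < 0) bad("decay_rate must be nonnegative")
  if (decay_cv < 0 || onset_sd < 0) bad("kinetic spreads must be nonnegative")
  if (length(compensation_range) != 2L ||
      compensation_range[1] > compensation_range[2] ||
      compensation_range[1] < 1 || compensation_range[2] > 2) {
    bad("compensation_range must be lo <= hi within [1, 2]")
  }
  if (noise_sd < 0) bad("noise_sd must be nonnegative")
  if (count_scale <= 0) bad("count_scale must be positive (Inf for continuous)")
  if (depth_mean < 0) bad("depth_mean must be nonnegative")
  if (n_positions < 1) bad("n_positions must be positive")
  if (frac_fixed_snp < 0 || frac_fixed_snp > 1) bad("frac_fixed_snp must be in [0, 1]")
  if (pileup_depth < 13) bad("pileup_depth must be at least the callable depth (13)")

  structure(list(
    n_genes = as.integer(n_genes), frac_x = frac_x,
    frac_maternal = frac_maternal, frac_zygotic = frac_zygotic,
    frac_mat_zyg = frac_mat_zyg, frac_with_snp = frac_with_snp,
    stages = as.character(stages), replicates = as.integer(replicates),
    decay_rate = decay_rate, decay_cv = decay_cv,
    onset_stage = onset_stage, onset_steepness = onset_steepness,
    onset_sd = onset_sd,
    compensation_range = as.numeric(compensation_range),
    noise_sd = noise_sd, count_scale = count_scale,
    depth_mean = depth_mean,
    expr_meanlog = expr_meanlog, expr_sdlog = expr_sdlog,
    silent_rpkm = silent_rpkm,
    n_positions = as.integer(n_positions), frac_fixed_snp = frac_fixed_snp,
    pileup_depth = as.integer(pileup_depth),
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic time-course configuration\n")
  cat(sprintf("  genes: %d (X fraction %.2f, SNP fraction %.2f)\n",
              x$n_genes, x$frac_x, x$frac_with_snp))
  cat(sprintf("  classes: maternal %.2f, zygotic %.2f, maternal+zygotic %.2f, silent %.2f\n",
              x$frac_maternal, x$frac_zygotic, x$frac_mat_zyg,
              1 - x$frac_maternal - x$frac_zygotic - x$frac_mat_zyg))
  cat(sprintf("  stages: %s; embryos/sex: %s\n",
              paste(x$stages, collapse = " "),
              paste(x$replicates, collapse = " ")))
  cat(sprintf("  kinetics: decay %.2f, onset at t=%.1f (steepness %.1f)\n",
              x$decay_rate, x$onset_stage, x$onset_steepness))
  cat(sprintf("  compensation F:M in [%.2f, %.2f]; noise sd %.2f; seed %d\n",
              x$compensation_range[1], x$compensation_range[2],
              x$noise_sd, x$seed))
  invisible(x)
}
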