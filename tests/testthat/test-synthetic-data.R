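test_that("a fixed seed reproduces the simulated time course exactly", {
  cfg <- sim_config(n_genes = 150, seed = 99)
  a <- simulate_timecourse(cfg)
  b <- simulate_timecourse(cfg)
  expect_identical(a$dataset$expr, b$dataset$expr)
  expect_identical(a$dataset$maternal_counts, b$dataset$maternal_counts)
  expect_identical(a$truth$genes, b$truth$genes)
  p1 <- simulate_strain_pileups(cfg)
  p2 <- simulate_strain_pileups(cfg)
  expect_identical(p1, p2)
})

test_that("the simulated design matches the 24-embryo staged layout", {
  sim <- default_sim()
  s <- sim$dataset$samples
  expect_equal(ncol(sim$dataset$expr), 24L)
  expect_equal(sum(s$sex == "F"), 12L)
  expect_equal(sum(s$sex == "M"), 12L)
  per_stage <- table(s$sex, factor(s$stage, levels = stage_levels()))
  expect_equal(unname(per_stage["F", ]), c(1, 1, 1, 1, 2, 2, 2, 2))
  expect_equal(unname(per_stage["M", ]), c(1, 1, 1, 1, 2, 2, 2, 2))
})

test_that("maternal transcripts and the male X never yield paternal reads", {
  sim <- default_sim()
  tr <- sim$truth$genes
  mat <- tr$class %in% c("maternal", "silent")
  expect_true(all(sim$dataset$paternal_counts[mat, ] == 0))
  expect_equal(nrow(check_male_x(sim$dataset)), 0L)
})

test_that("noise-free uncompensated X genes have female RPKM exactly twice male", {
  cfg <- sim_config(n_genes = 60, frac_x = 1, frac_maternal = 0,
                    frac_zygotic = 1, frac_mat_zyg = 0,
                    compensation_range = c(2, 2), noise_sd = 0,
                    count_scale = Inf, seed = 5)
  sim <- simulate_timecourse(cfg)
  s <- sim$dataset$samples
  f14d <- which(s$sex == "F" & s$stage == "14D")[1]
  m14d <- which(s$sex == "M" & s$stage == "14D")[1]
  zyg <- sim$truth$genes$class == "zygotic"
  expect_equal(sim$dataset$expr[zyg, f14d], 2 * sim$dataset$expr[zyg, m14d],
               tolerance = 1e-12)
})

test_that("the fraction of expressed genes with informative reads tracks frac_with_snp", {
  cfg <- sim_config(n_genes = 1500, depth_mean = 10, seed = 23)
  sim <- simulate_timecourse(cfg)
  expressed <- sim$truth$genes$class != "silent"
  got <- rowSums(sim$dataset$maternal_counts + sim$dataset$paternal_counts) > 0
  expect_equal(mean(got[expressed]), cfg$frac_with_snp, tolerance = 0.03)
})

test_that("autosomal zygotic allele counts are binomially symmetric at late stages", {
  sim <- default_sim()
  tr <- sim$truth$genes
  zyg <- tr$class == "zygotic" & tr$arm != "X"
  late <- sim$dataset$samples$stage %in% c("14C", "14D")
  m <- rowSums(sim$dataset$maternal_counts[zyg, late])
  p <- rowSums(sim$dataset$paternal_counts[zyg, late])
  keep <- m + p >= 10
  expect_equal(mean(p[keep] / (m + p)[keep]), 0.5, tolerance = 0.02)
})

test_that("pileup truth contains the configured number of fixed SNPs and failure modes", {
  cfg <- sim_config(n_positions = 100, frac_fixed_snp = 0.2, seed = 1)
  piles <- simulate_strain_pileups(cfg)
  expect_equal(sum(piles$truth$fixed), 20L)
  expect_setequal(unique(piles$truth$status),
                  c("fixed", "identical", "low_depth", "polymorphic"))
  # engineered low-depth positions really are shallow in strain A
  low <- piles$truth$status == "low_depth"
  depth_a <- rowSums(piles$pileup_a[low, c("A", "C", "G", "T")])
  expect_true(all(depth_a < 13))
  # fixed positions have different alleles, other statuses identical ones
  expect_true(all(piles$truth$allele_a[piles$truth$fixed] !=
                  piles$truth$allele_b[piles$truth$fixed]))
  expect_true(all(piles$truth$allele_a[!piles$truth$fixed] ==
                  piles$truth$allele_b[!piles$truth$fixed]))
})

test_that("the generator's zygotic fraction is recovered from noise-free allele counts", {
  cfg <- sim_config(n_genes = 400, frac_x = 0, frac_maternal = 0,
                    frac_zygotic = 0, frac_mat_zyg = 0.999, frac_with_snp = 1,
                    noise_sd = 0, count_scale = Inf, depth_mean = 30, seed = 8)
  sim <- simulate_timecourse(cfg)
  part <- partition_rpkm(sim$dataset$expr, sim$dataset$maternal_counts,
                         sim$dataset$paternal_counts)
  z <- zygotic_fraction(part, sim$dataset$genes, sim$dataset$samples)
  s14a <- which(sim$dataset$samples$sex == "F" & sim$dataset$samples$stage == "14A")
  truth_frac <- sim$truth$expected_zygotic_female[, "14A"] /
    sim$truth$expected_female[, "14A"]
  got <- rowMeans(z[, s14a, drop = FALSE])
  mz <- sim$truth$genes$class == "maternal_zygotic"
  # doubling convention: min(1, 2 * p/(m+p)) estimates zyg/(mat+zyg)
  expect_lt(mean(abs(got[mz] - pmin(1, truth_frac[mz])), na.rm = TRUE), 0.03)
})
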