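test_that("female:male ratios honour the both-sexes expression filter", {
  meta <- make_meta(rep(1, 8))
  expr <- matrix(0, 3, nrow(meta),
                 dimnames = list(c("g1", "g2", "g3"), meta$sample_id))
  expr["g1", meta$sex == "F"] <- 3; expr["g1", meta$sex == "M"] <- 2
  expr["g2", meta$sex == "F"] <- 3; expr["g2", meta$sex == "M"] <- 1
  expr["g3", ] <- 4
  r <- fm_ratio(expr, meta)
  expect_equal(unname(r["g1", "C10"]), 1.5)
  expect_true(is.na(r["g2", "C10"]))  # male below 2 RPKM
  expect_equal(unname(r["g3", "C10"]), 1.0)
})

test_that("the compensation score is the through-origin slope with its symmetries", {
  expect_equal(compensation_score(c(2, 4, 6), c(1, 2, 3)), 2)
  f <- runif(8, 1, 10)
  expect_equal(compensation_score(f, f), 1)
  expect_error(compensation_score(1:3, 1:4), "equal length")
  expect_true(is.na(compensation_score(1:3, rep(0, 3))))
  m <- runif(8, 1, 10)
  s <- compensation_score(f, m)
  expect_equal(compensation_score(3 * f, m), 3 * s)       # scale-equivariant
  expect_equal(compensation_score(3 * f, 3 * m), s)       # joint-scale invariant
})

test_that("the score table filters at max RPKM strictly greater than 3", {
  meta <- make_meta(rep(1, 8))
  genes <- data.frame(gene_id = c("lo", "hi"), arm = "2L")
  expr <- matrix(1, 2, nrow(meta), dimnames = list(genes$gene_id, meta$sample_id))
  expr["lo", ] <- 3        # max exactly 3.0: excluded by the strict filter
  expr["hi", ] <- 3.5
  st <- score_table(expr, meta, genes, c("lo", "hi"))
  expect_equal(st$gene_id, "hi")
  expect_equal(st$score, 1)
})

test_that("autosomal null scores centre at 1 and uncompensated X aggregates halve in males", {
  cfg <- sim_config(n_genes = 400, frac_x = 0, frac_maternal = 0,
                    frac_zygotic = 1, frac_mat_zyg = 0, seed = 19)
  sim <- simulate_timecourse(cfg)
  st <- score_table(sim$dataset$expr, sim$dataset$samples, sim$dataset$genes,
                    sim$truth$genes$gene_id)
  expect_equal(median(st$score), 1.0, tolerance = 0.05)

  cfgx <- sim_config(n_genes = 400, frac_x = 1, frac_maternal = 0,
                     frac_zygotic = 1, frac_mat_zyg = 0,
                     compensation_range = c(2, 2), frac_with_snp = 1, seed = 20)
  simx <- simulate_timecourse(cfgx)
  part <- partition_rpkm(simx$dataset$expr, simx$dataset$maternal_counts,
                         simx$dataset$paternal_counts)
  aggr <- chrom_aggregate(part, simx$dataset$samples, simx$dataset$genes,
                          simx$truth$genes$gene_id)
  late <- aggr$stage == "14D" & aggr$arm == "X"
  f <- aggr[late & aggr$sex == "F", ]
  m <- aggr[late & aggr$sex == "M", ]
  # c = 2: the male X total matches each female per-chromosome total
  expect_equal(m$total / f$total, 0.5, tolerance = 0.05)
  expect_equal(f$maternal / f$paternal, 1, tolerance = 0.1)
  expect_equal(m$paternal, 0)
})

test_that("autosomal zygotic aggregates are parentally balanced at late stages", {
  sim <- default_sim()
  part <- partition_rpkm(sim$dataset$expr, sim$dataset$maternal_counts,
                         sim$dataset$paternal_counts)
  zyg <- sim$truth$genes$gene_id[sim$truth$genes$class == "zygotic"]
  aggr <- chrom_aggregate(part, sim$dataset$samples, sim$dataset$genes, zyg)
  late <- aggr[aggr$stage == "14D" & aggr$arm != "X", ]
  expect_equal(late$maternal / late$paternal, rep(1, nrow(late)),
               tolerance = 0.15)
  # components add up to the matched totals
  expect_equal(aggr$maternal + aggr$paternal, aggr$total, tolerance = 1e-9)
})

test_that("ratio bins partition the defined genes and detect uncompensated X genes", {
  meta <- make_meta(rep(1, 8))
  genes <- data.frame(gene_id = sprintf("g%02d", 1:20),
                      arm = rep(c("2L", "X"), each = 10))
  expr <- matrix(5, 20, nrow(meta), dimnames = list(genes$gene_id, meta$sample_id))
  r <- fm_ratio(expr, meta)
  b <- ratio_bins(r, genes)
  sums <- tapply(b$proportion, paste(b$stage, b$group), sum)
  expect_true(all(abs(sums - 1) < 1e-12))
  central <- b[b$bin == "[1,1.25)", ]
  expect_true(all(central$proportion == 1))

  cfgx <- sim_config(n_genes = 300, frac_x = 1, frac_maternal = 0,
                     frac_zygotic = 1, frac_mat_zyg = 0,
                     compensation_range = c(2, 2), seed = 27)
  simx <- simulate_timecourse(cfgx)
  rx <- fm_ratio(simx$dataset$expr, simx$dataset$samples)
  bx <- ratio_bins(rx, simx$dataset$genes)
  high <- sum(bx$proportion[bx$stage == "14D" &
                              bx$bin %in% c("[1.75,2)", "[2,Inf]")])
  low <- sum(bx$proportion[bx$stage == "14D" &
                             bx$bin %in% c("[1,1.25)", "[1.25,1.5)")])
  expect_gt(high, 0.6)     # mass concentrated at and beyond 1.75
  expect_gt(high, 5 * low) # and far exceeding the near-parity bins
})
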