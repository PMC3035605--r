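test_that("strain consensus applies the depth and frequency rule literally", {
  expect_equal(strain_consensus(c(A = 20))$base, "A")
  # 19/20 = 0.95 meets "at least 95%"
  expect_equal(strain_consensus(c(A = 19, G = 1))$base, "A")
  expect_equal(strain_consensus(c(A = 18, G = 2))$reason, "polymorphic")
  expect_equal(strain_consensus(c(A = 12))$reason, "low_depth")
  expect_equal(strain_consensus(c(A = 10, G = 10))$reason, "polymorphic")
  # ambiguous reads are excluded from the frequency denominator
  expect_equal(strain_consensus(c(A = 19, G = 1, N = 5))$base, "A")
  expect_error(strain_consensus(c(A = -1)), "nonnegative")
})

test_that("fixed-SNP calling records differing consensus pairs only", {
  pa <- data.frame(chrom = "X", pos = 1:2, A = c(20L, 20L), C = 0L, G = 0L, T = 0L)
  pb <- data.frame(chrom = "X", pos = 1:2, A = c(0L, 20L), C = 0L,
                   G = c(15L, 0L), T = 0L)
  out <- call_fixed_snps(pa, pb)
  expect_equal(nrow(out), 1L)
  expect_equal(out$pos, 1L)
  expect_equal(out$allele_a, "A")
  expect_equal(out$allele_b, "G")
  dup <- rbind(pa, pa[1, ])
  expect_error(call_fixed_snps(dup, pb), "duplicate")
})

test_that("caller output is independent of input row order", {
  pa <- random_pileup(300, seed = 2)
  pb <- random_pileup(300, seed = 3)
  base <- call_fixed_snps(pa, pb)
  shuf <- call_fixed_snps(pa[sample(nrow(pa)), ], pb[sample(nrow(pb)), ])
  expect_equal(as.data.frame(base), as.data.frame(shuf),
               ignore_attr = TRUE)
})

test_that("tightening the caller thresholds never adds SNP records", {
  pa <- random_pileup(500, seed = 4)
  pb <- random_pileup(500, seed = 5)
  loose <- call_fixed_snps(pa, pb, caller_config(10, 0.9))
  for (cfg in list(caller_config(13, 0.9), caller_config(10, 0.95),
                   caller_config(20, 0.99))) {
    tight <- call_fixed_snps(pa, pb, cfg)
    expect_true(all(paste(tight$chrom, tight$pos) %in%
                    paste(loose$chrom, loose$pos)))
  }
})

test_that("caller matches the brute-force rule on random columns", {
  pa <- random_pileup(500, seed = 6)
  pb <- random_pileup(500, seed = 7)
  got <- call_fixed_snps(pa, pb)
  want <- oracle_fixed_snps(pa, pb)
  expect_equal(got[, c("chrom", "pos", "allele_a", "allele_b")], want,
               ignore_attr = TRUE)
})

test_that("caller reproduces the generator truth at callable positions", {
  piles <- simulate_strain_pileups(sim_config(n_positions = 400, seed = 13))
  got <- call_fixed_snps(piles$pileup_a, piles$pileup_b)
  want <- piles$truth[piles$truth$fixed, c("chrom", "pos", "allele_a", "allele_b")]
  rownames(want) <- NULL
  expect_equal(got[, c("chrom", "pos", "allele_a", "allele_b")], want)
})

test_that("residual within-strain polymorphism is tallied as a side table", {
  piles <- simulate_strain_pileups(sim_config(n_positions = 400, seed = 13))
  res <- attr(call_fixed_snps(piles$pileup_a, piles$pileup_b),
              "residual_polymorphism")
  n_poly <- sum(piles$truth$status == "polymorphic")
  expect_equal(res$n_polymorphic[res$strain == "b"], n_poly)
})

test_that("SNP-in-gene counts use exonic intervals and match a brute-force scan", {
  ann <- data.frame(gene_id = c("g1", "g2"), chrom = c("2L", "2L"),
                    strand = "+", exon_starts = c("100,300", "1000"),
                    exon_ends = c("200,400", "1500"),
                    exonic_length = c(202L, 501L))
  snps <- data.frame(chrom = "2L", pos = c(150L, 250L, 400L, 999L, 1500L))
  out <- genes_with_snp(snps, ann)
  # 150 and 400 exonic in g1; 250 is intronic; 1500 is the inclusive end of g2
  expect_equal(out$n_snps[out$gene_id == "g1"], 2L)
  expect_equal(out$n_snps[out$gene_id == "g2"], 1L)

  ann_r <- simulate_annotation(n_genes = 40, seed = 3)
  piles <- simulate_strain_pileups(sim_config(n_positions = 600, seed = 17))
  snps_r <- call_fixed_snps(piles$pileup_a, piles$pileup_b)
  got <- genes_with_snp(snps_r, ann_r)
  brute <- vapply(seq_len(nrow(ann_r)), function(i) {
    st <- as.integer(strsplit(ann_r$exon_starts[i], ",")[[1]])
    en <- as.integer(strsplit(ann_r$exon_ends[i], ",")[[1]])
    hit <- 0L
    for (j in seq_len(nrow(snps_r))) {
      if (snps_r$chrom[j] != ann_r$chrom[i]) next
      if (any(snps_r$pos[j] >= st & snps_r$pos[j] <= en)) hit <- hit + 1L
    }
    hit
  }, integer(1))
  expect_equal(got$n_snps, brute)
})

test_that("SNPs on chromosomes missing from the annotation are skipped with a warning", {
  ann <- data.frame(gene_id = "g1", chrom = "2L", strand = "+",
                    exon_starts = "1", exon_ends = "100", exonic_length = 100L)
  snps <- data.frame(chrom = c("2L", "U"), pos = c(50L, 10L))
  expect_warning(out <- genes_with_snp(snps, ann), "skipped")
  expect_equal(out$n_snps, 1L)
})
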