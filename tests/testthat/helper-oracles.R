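# Independent brute-force oracles, deliberately literal and loop-based.

# The SNP-calling rule applied verbatim to one column of base counts.
oracle_consensus <- function(counts, min_depth = 13, min_freq = 0.95) {
  counts <- counts[c("A", "C", "G", "T")]
  depth <- sum(counts)
  if (depth < min_depth) return(NA_character_)
  mx <- max(counts)
  if (mx / depth < min_freq) return(NA_character_)
  if (sum(counts == mx) > 1) return(NA_character_)
  c("A", "C", "G", "T")[which.max(counts)]
}

# Position-by-position application of the fixed-SNP rule to two pileups.
# (Lookups are pre-indexed; the rule itself is applied literally per site.)
oracle_fixed_snps <- function(pa, pb, min_depth = 13, min_freq = 0.95) {
  ma <- as.matrix(pa[, c("A", "C", "G", "T")])
  mb <- as.matrix(pb[, c("A", "C", "G", "T")])
  jb <- match(paste(pa$chrom, pa$pos), paste(pb$chrom, pb$pos))
  out <- list()
  for (i in seq_len(nrow(pa))) {
    j <- jb[i]
    if (is.na(j)) next
    ca <- oracle_consensus(ma[i, ], min_depth, min_freq)
    cb <- oracle_consensus(mb[j, ], min_depth, min_freq)
    if (!is.na(ca) && !is.na(cb) && ca != cb) {
      out[[length(out) + 1L]] <- data.frame(chrom = pa$chrom[i], pos = pa$pos[i],
                                            allele_a = ca, allele_b = cb)
    }
  }
  if (length(out) == 0L) {
    return(data.frame(chrom = character(), pos = integer(),
                      allele_a = character(), allele_b = character()))
  }
  res <- do.call(rbind, out)
  res[order(res$chrom, res$pos), , drop = FALSE]
}

# Random pileup columns mixing near-monomorphic, polymorphic and shallow
# sites so that every branch of the rule fires.
random_pileup <- function(n, seed) {
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  major <- sample(4L, n, replace = TRUE)
  depth <- sample(0:40, n, replace = TRUE)
  minor_frac <- sample(c(0, 0.02, 0.04, 0.05, 0.06, 0.2, 0.5), n,
                       replace = TRUE)
  counts <- matrix(0L, n, 4L, dimnames = list(NULL, bases))
  for (i in seq_len(n)) {
    minor <- round(depth[i] * minor_frac[i])
    counts[i, major[i]] <- depth[i] - minor
    counts[i, sample(setdiff(1:4, major[i]), 1L)] <- minor
  }
  data.frame(chrom = "2L", pos = seq_len(n), ref = "A", counts,
             N = sample(0:3, n, replace = TRUE))
}

# Exhaustive 2-cluster k-medians optimum: enumerate all bipartitions and
# take the best total L1 cost to coordinate-wise medians.
oracle_kmedians2 <- function(x) {
  n <- nrow(x)
  part_cost <- function(idx) {
    cost_of <- function(rows) {
      if (length(rows) == 0L) return(Inf)
      med <- apply(x[rows, , drop = FALSE], 2L, median)
      sum(abs(sweep(x[rows, , drop = FALSE], 2L, med, `-`)))
    }
    cost_of(which(idx)) + cost_of(which(!idx))
  }
  best <- Inf
  for (mask in 1:(2^(n - 1) - 1)) {
    idx <- as.logical(bitwAnd(mask, 2^(0:(n - 1))))
    best <- min(best, part_cost(idx))
  }
  best
}

# Literal motif scan: greedy non-overlapping and all-start-positions counts.
oracle_sxl <- function(seq) {
  s <- chartr("tT", "uU", toupper(seq))
  s <- gsub("T", "U", s)
  hits <- function(i) {
    sub <- substring(s, i, i + 7L)
    nchar(sub) == 8L && (sub == "AUUUUUUU" || sub == "UUUUUUUU")
  }
  pos <- which(vapply(seq_len(max(nchar(s) - 7L, 0L)), hits, logical(1)))
  greedy <- 0L
  i <- 1L
  while (i <= nchar(s) - 7L) {
    if (hits(i)) { greedy <- greedy + 1L; i <- i + 8L } else i <- i + 1L
  }
  list(greedy = greedy, overlap = length(pos))
}

# Small default simulation shared by several test files.
default_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- simulate_timecourse(sim_config(seed = 11))
    cache
  }
})

# Standard 24-sample metadata layout used by several test files.
make_meta <- function(n_rep = c(1, 1, 1, 1, 2, 2, 2, 2)) {
  do.call(rbind, lapply(c("F", "M"), function(sex) {
    do.call(rbind, lapply(seq_along(stage_levels()), function(s) {
      data.frame(sample_id = sprintf("%s_%s_%d", sex, stage_levels()[s],
                                     seq_len(n_rep[s])),
                 sex = sex, stage = stage_levels()[s],
                 replicate = seq_len(n_rep[s]))
    }))
  }))
}
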