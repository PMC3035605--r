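#' Simulate per-strain base-count pileups with a truth table
#'
#' Generates two pileup tables over a common set of positions, engineered so
#' that every branch of the fixed-SNP calling rule is exercised: genuinely
#' fixed differences (both strains deeply covered and near-monomorphic for
#' different bases), positions identical between strains, positions with
#' insufficient depth in one strain, and positions with residual within-strain
#' polymorphism (major-allele frequency well below the callable threshold).
#'
#' The number of fixed rows is exactly `round(n_positions * frac_fixed_snp)`;
#' the remaining positions are split roughly 70/15/15 between identical,
#' low-depth and polymorphic statuses. Counts are constructed so the intended
#' status always holds: callable positions get depth `13 + Poisson`, a
#' sequencing-error count capped below 5% of the depth, low-depth positions
#' get 0-12 reads, and polymorphic positions a minor-allele fraction of
#' 20-40%.
#'
#' @param cfg a [sim_config()]; uses `n_positions`, `frac_fixed_snp`,
#'   `pileup_depth` and `seed`.
#' @return List with data frames `pileup_a`, `pileup_b` (columns
#'   `chrom pos ref A C G T N`) and `truth` (columns `chrom pos status
#'   allele_a allele_b fixed`), where `status` is one of `fixed`, `identical`,
#'   `low_depth`, `polymorphic`.
#' @export
#' @examples
#' sim <- simulate_strain_pileups(sim_config(n_positions = 100,
#'                                           frac_fixed_snp = 0.2, seed = 1))
#' sum(sim$truth$fixed)
simulate_strain_pileups <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(derive_seed(cfg$seed, 101L), {
    n <- cfg$n_positions
    bases <- c("A", "C", "G", "T")
    n_fixed <- round(n * cfg$frac_fixed_snp)
    n_rest <- n - n_fixed
    n_low <- round(n_rest * 0.15)
    n_poly <- round(n_rest * 0.15)
    n_ident <- n_rest - n_low - n_poly
    status <- sample(c(rep("fixed", n_fixed), rep("identical", n_ident),
                       rep("low_depth", n_low), rep("polymorphic", n_poly)))

    chrom <- sample(c("X", "2L", "2R", "3L", "3R"), n, replace = TRUE)
    pos <- sample.int(1e6L, n)
    o <- order(chrom, pos)
    chrom <- chrom[o]; pos <- pos[o]; status <- status[o]

    allele_a <- sample(bases, n, replace = TRUE)
    allele_b <- allele_a
    is_fixed <- status == "fixed"
    allele_b[is_fixed] <- vapply(allele_a[is_fixed], function(a) {
      sample(setdiff(bases, a), 1L)
    }, character(1))

    # depth 13 + Poisson keeps callable positions callable by construction;
    # error reads are capped strictly below the 5% polymorphism allowance.
    callable_counts <- function(consensus, n_pos) {
      depth <- 13L + stats::rpois(n_pos, max(cfg$pileup_depth - 13L, 1L))
      max_err <- floor(depth * 0.049)
      err <- pmin(stats::rbinom(n_pos, depth, 0.01), max_err)
      list(depth = depth, err = err,
           err_base = vapply(consensus, function(a) sample(setdiff(bases, a), 1L),
                             character(1)))
    }
    fill <- function(mat, i, base, count) {
      mat[cbind(i, match(base, bases))] <- mat[cbind(i, match(base, bases))] + count
      mat
    }
    counts_a <- counts_b <- matrix(0L, n, 4L, dimnames = list(NULL, bases))

    for (strain in c("a", "b")) {
      allele <- if (strain == "a") allele_a else allele_b
      callable <- if (strain == "a") status != "low_depth" else status != "polymorphic"
      i_call <- which(callable)
      cc <- callable_counts(allele[i_call], length(i_call))
      m <- if (strain == "a") counts_a else counts_b
      m <- fill(m, i_call, allele[i_call], cc$depth - cc$err)
      m <- fill(m, i_call, cc$err_base, cc$err)
      i_fail <- which(!callable)
      if (length(i_fail)) {
        if (strain == "a") {
          # low-depth in strain A: 0-12 reads of the consensus base
          d <- sample(0:12, length(i_fail), replace = TRUE)
          m <- fill(m, i_fail, allele[i_fail], d)
        } else {
          # residual polymorphism in strain B: minor fraction 20-40%
          d <- 13L + stats::rpois(length(i_fail), max(cfg$pileup_depth - 13L, 1L))
          minor <- pmax(round(d * stats::runif(length(i_fail), 0.2, 0.4)), 2L)
          minor_base <- vapply(allele[i_fail], function(a) {
            sample(setdiff(bases, a), 1L)
          }, character(1))
          m <- fill(m, i_fail, allele[i_fail], d - minor)
          m <- fill(m, i_fail, minor_base, minor)
        }
      }
      if (strain == "a") counts_a <- m else counts_b <- m
    }

    ref <- sample(bases, n, replace = TRUE)
    n_a <- stats::rpois(n, 0.3)
    n_b <- stats::rpois(n, 0.3)
    pile <- function(counts, ncol_n) {
      data.frame(chrom = chrom, pos = pos, ref = ref,
                 A = counts[, "A"], C = counts[, "C"],
                 G = counts[, "G"], T = counts[, "T"], N = ncol_n)
    }
    list(
      pileup_a = pile(counts_a, n_a),
      pileup_b = pile(counts_b, n_b),
      truth = data.frame(chrom = chrom, pos = pos, status = status,
                         allele_a = allele_a, allele_b = allele_b,
                         fixed = is_fixed)
    )
  })
}

#' Simulate a small exon-level gene annotation
#'
#' Produces an annotation table in the layout consumed by
#' [genes_with_snp()]: 1-based inclusive, comma-separated exon interval
#' lists with a precomputed exonic length. Genes are laid out with 1-3 exons
#' on the same chromosome arms used by [simulate_strain_pileups()].
#'
#' @param n_genes number of genes.
#' @param seed RNG seed.
#' @return Data frame with columns `gene_id chrom strand exon_starts
#'   exon_ends exonic_length`.
#' @export
simulate_annotation <- function(n_genes = 100, seed = 1L) {
  with_seed(derive_seed(seed, 202L), {
    chrom <- sample(c("X", "2L", "2R", "3L", "3R"), n_genes, replace = TRUE)
    start <- sample.int(9e5L, n_genes)
    strand <- sample(c("+", "-"), n_genes, replace = TRUE)
    rows <- lapply(seq_len(n_genes), function(i) {
      n_ex <- sample(1:3, 1L)
      widths <- sample(200:2000, n_ex, replace = TRUE)
      gaps <- if (n_ex > 1L) sample(50:500, n_ex - 1L, replace = TRUE) else integer()
      s <- start[i] + cumsum(c(0L, widths[-n_ex] + gaps))
      e <- s + widths - 1L
      data.frame(gene_id = sprintf("ann%04d", i), chrom = chrom[i],
                 strand = strand[i],
                 exon_starts = paste(s, collapse = ","),
                 exon_ends = paste(e, collapse = ","),
                 exonic_length = sum(widths))
    })
    do.call(rbind, rows)
  })
}
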