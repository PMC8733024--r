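test_that("genetic values are the dosage-effect linear combination", {
  Q <- matrix(c(0, 2, 2, 0), 2, 2, byrow = TRUE,
              dimnames = list(c("a", "b"), c("l1", "l2")))
  expect_equal(unname(genetic_values(Q, c(1, -1))), c(-2, 2))
  expect_equal(unname(genetic_values(Q, c(0, 0))), c(0, 0))
  expect_error(genetic_values(Q, 1), "dimension mismatch")
})

test_that("var_1n uses divisor n", {
  expect_equal(var_1n(c(-2, 2)), 4)
  expect_equal(var_1n(c(0, 4, 4, 0)), 4)
  expect_equal(var_1n(rep(3.7, 5)), 0)
  expect_equal(var_1n(1), 0)
  expect_error(var_1n(numeric(0)), "empty")
  # relation to the n-1 sample variance
  x <- rnorm(11)
  expect_equal(var_1n(x), var(x) * 10 / 11)
})

test_that("partition_by_group applies var_1n within each label", {
  out <- partition_by_group(c(0, 4, 4, 0), c("A", "A", "B", "B"))
  expect_equal(out$variance, c(4, 4))
  expect_equal(out$group, c("A", "B"))
  one <- partition_by_group(c(1, 2, 3), rep("all", 3))
  expect_equal(one$variance, var_1n(c(1, 2, 3)))
  expect_equal(partition_by_group(5, "solo")$variance, 0)
})

test_that("genomic partition matches hand-enumerated toy cases", {
  # single locus, half 0 / half 2: empirical variance 1, double the
  # Hardy-Weinberg 2p(1-p) = 0.5 at p = 0.5
  Q1 <- matrix(c(0, 2, 0, 2), ncol = 1,
               dimnames = list(NULL, "l1"))
  vp1 <- genomic_partition(Q1, 1, chr = 1L)
  expect_equal(vp1$total, 1.0)
  expect_equal(unname(vp1$genic), 1.0)
  expect_equal(unname(vp1$within), 0)
  expect_equal(sum(vp1$between), 0)
  # two perfectly coupled loci on one chromosome
  Q2 <- matrix(c(0, 0, 2, 2, 2, 2, 0, 0), 4, 2, byrow = TRUE)
  colnames(Q2) <- c("l1", "l2")
  vp2 <- genomic_partition(Q2, c(1, 1), chr = c(1L, 1L))
  expect_equal(vp2$total, 4)
  expect_equal(unname(vp2$genic), 2)   # 1 + 1
  expect_equal(unname(vp2$within), 2)  # 2 x cov of 1
  # one locus per chromosome: no within term by construction
  vp3 <- genomic_partition(Q2, c(1, 1), chr = c(1L, 2L))
  expect_equal(unname(vp3$within), c(0, 0))
  expect_equal(sum(vp3$between), 4 - 2)
})

test_that("aggregated route equals the explicit locus-pair double sum", {
  for (seed in 1:6) {
    inst <- random_instance(n_ind = sample(5:30, 1), n_loci = sample(6:50, 1),
                            n_chr = sample(2:4, 1), seed = seed)
    vp <- genomic_partition(inst$Q, inst$effects, inst$chr)
    oracle <- brute_partition(inst$Q, inst$effects, inst$chr)
    expect_equal(sum(vp$genic), oracle$genic, tolerance = 1e-10)
    expect_equal(sum(vp$within), oracle$within, tolerance = 1e-10)
    expect_equal(sum(vp$between), oracle$between, tolerance = 1e-10)
    expect_equal(vp$total, oracle$total, tolerance = 1e-10)
    # identity
    expect_equal(vp$total, sum(vp$genic) + sum(vp$within) + sum(vp$between),
                 tolerance = 1e-8 * max(1, abs(vp$total)))
  }
})

test_that("partition is invariant to permutations and quadratic in effects", {
  inst <- random_instance(20, 30, 3, seed = 99)
  vp <- genomic_partition(inst$Q, inst$effects, inst$chr)
  # permuting individuals changes nothing
  perm <- sample(nrow(inst$Q))
  vp_p <- genomic_partition(inst$Q[perm, ], inst$effects, inst$chr)
  expect_equal(genome_components(vp_p), genome_components(vp))
  # permuting loci within a chromosome keeps genic and within per chromosome
  ord <- unlist(lapply(split(seq_along(inst$chr), inst$chr), sample))
  vp_l <- genomic_partition(inst$Q[, ord], inst$effects[ord], inst$chr[ord])
  expect_equal(vp_l$genic, vp$genic)
  expect_equal(vp_l$within, vp$within, tolerance = 1e-12)
  # scaling all effects by c scales every component by c^2
  vp_s <- genomic_partition(inst$Q, 3 * inst$effects, inst$chr)
  expect_equal(genome_components(vp_s), 9 * genome_components(vp))
})

test_that("inbred dosages give the (1 + F) = 2 genic variance closed form", {
  # dosages in {0, 2} at frequency p: empirical variance 4p(1-p) per locus
  set.seed(21)
  p <- 0.3
  x <- c(rep(2L, 30), rep(0L, 70)) # exact frequency 0.3
  Q <- matrix(x, ncol = 1, dimnames = list(NULL, "l1"))
  a <- 1.7
  vp <- genomic_partition(Q, a, chr = 1L)
  expect_equal(unname(vp$genic), 4 * p * (1 - p) * a^2, tolerance = 1e-12)
})

test_that("tidy() lays the partition out by component and chromosome pair", {
  inst <- random_instance(15, 20, 2, seed = 4)
  vp <- genomic_partition(inst$Q, inst$effects, inst$chr, group = "toy")
  td <- tidy(vp)
  genome <- td[is.na(td$chromosome), ]
  expect_setequal(genome$component,
                  c("total", "genic", "within_ld", "between_ld"))
  expect_equal(genome$value[genome$component == "total"],
               sum(genome$value[genome$component != "total"]))
  # between rows carry both chromosomes and the factor 2
  btw <- td[!is.na(td$chromosome2), ]
  expect_equal(sum(btw$value), genome$value[genome$component == "between_ld"])
})

test_that("term counts reproduce the decomposition combinatorics", {
  tc <- term_counts(21, 100)
  expect_equal(tc$locus_combinations, 4410000)
  expect_equal(tc$within_chr_locus_pairs, 207900)
  expect_equal(tc$between_chr_locus_pairs, 4200000)
  expect_equal(tc$chromosome_combinations, 441)
  expect_equal(tc$between_chr_pairs, 420)
  tiny <- term_counts(1, 1)
  expect_equal(tiny$locus_combinations, 1)
  expect_equal(tiny$within_chr_locus_pairs, 0)
  expect_equal(tiny$between_chr_locus_pairs, 0)
  # brute-force enumeration for (2, 2)
  chr <- rep(1:2, each = 2)
  pairs <- expand.grid(l1 = 1:4, l2 = 1:4)
  same <- chr[pairs$l1] == chr[pairs$l2]
  distinct <- pairs$l1 != pairs$l2
  tc22 <- term_counts(2, 2)
  expect_equal(tc22$locus_combinations, nrow(pairs))
  expect_equal(tc22$within_chr_locus_pairs, sum(same & distinct))
  expect_equal(tc22$between_chr_locus_pairs, sum(!same))
  expect_equal(tc22$chromosome_combinations, 4)
  expect_equal(tc22$between_chr_pairs, 2)
  expect_error(term_counts(0, 5), "positive")
})
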