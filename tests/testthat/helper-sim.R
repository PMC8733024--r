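# Shared fixtures, built in code and cached per test run.

.fixtures <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixtures)) assign(key, expr, envir = .fixtures)
  get(key, envir = .fixtures)
}

# A small genome/founder panel for unit tests.
mini_params <- function(...) {
  base <- list(n_chr = 3L, loci_per_chr = 60L, qtl_per_chr = 10L,
               n_founders = 20L, n_crosses = 20L, n_f1_per_cross = 10L,
               n_pyt = 40L, n_ayt = 10L, n_eyt = 4L, years = 10L)
  do.call(sim_params, utils::modifyList(base, list(...)))
}

mini_founders <- function() cached("mini_founders", {
  simulate_founders(mini_params(), seed = 42L)
})

# A complete miniature programme run with cohort genotypes kept.
mini_sim <- function() cached("mini_sim", {
  run_programme(mini_params(), seed = 3L, keep_cohort_genotypes = TRUE)
})

# A full-Bayes fit on the miniature training set (reduced chain profile).
mini_fit <- function() cached("mini_fit", {
  sim <- mini_sim()
  fit_marker_model(sim$training$phenotypes, sim$training$genotypes,
                   approach = "full", chain = chain_control(4000L, 500L, 5L),
                   seed = 9L)
})

# Random small dosage matrix with a chromosome assignment, for oracles.
random_instance <- function(n_ind, n_loci, n_chr, seed) {
  set.seed(seed)
  Q <- matrix(sample(0:2, n_ind * n_loci, replace = TRUE), n_ind, n_loci,
              dimnames = list(sprintf("i%03d", seq_len(n_ind)),
                              sprintf("l%03d", seq_len(n_loci))))
  list(Q = Q, effects = rnorm(n_loci),
       chr = sort(rep_len(seq_len(n_chr), n_loci)))
}

# Brute-force oracle: the decomposition as an explicit double sum over all
# locus pairs of e_l' * cov_1n(Q[, l'], Q[, l]) * e_l.
brute_partition <- function(Q, effects, chr) {
  n <- nrow(Q)
  Qc <- sweep(Q, 2L, colMeans(Q))
  Cq <- crossprod(Qc) / n
  term <- outer(effects, effects) * Cq
  same_chr <- outer(chr, chr, "==")
  diag_idx <- diag(TRUE, length(effects))
  list(genic = sum(term[diag_idx]),
       within = sum(term[same_chr & !diag_idx]),
       between = sum(term[!same_chr]),
       total = sum(term))
}
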