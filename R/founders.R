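# Founder haplotype generation: a neutral coalescent generator with
# recombination approximated by independent genealogy blocks.

# One Kingman coalescent tree for n leaves, returned as a list of branches,
# each with its subtended leaf set and length (time units are arbitrary since
# mutations are placed proportionally to branch length). The two branches
# below the root carry complementary leaf subsets, so every mutation placed
# on any branch is segregating among the n leaves.
coalescent_branches <- function(n) {
  sets <- as.list(seq_len(n))
  start <- rep(0, n)
  branch_sets <- vector("list", 2L * (n - 1L))
  branch_len <- numeric(2L * (n - 1L))
  t <- 0
  b <- 0L
  while (length(sets) > 1L) {
    k <- length(sets)
    t <- t + rexp(1, k * (k - 1) / 2)
    ij <- sample.int(k, 2L)
    for (x in ij) {
      b <- b + 1L
      branch_sets[[b]] <- sets[[x]]
      branch_len[b] <- t - start[x]
    }
    merged <- c(sets[[ij[1]]], sets[[ij[2]]])
    sets <- c(sets[-ij], list(merged))
    start <- c(start[-ij], t)
  }
  list(sets = branch_sets, len = branch_len)
}

# Haplotypes for one genealogy block: n_leaves x n_sites 0/1 matrix where each
# site is one mutation dropped on a branch chosen proportionally to length.
block_haplotypes <- function(n_leaves, n_sites) {
  tree <- coalescent_branches(n_leaves)
  picks <- sample.int(length(tree$len), n_sites, replace = TRUE,
                      prob = tree$len)
  hap <- matrix(0L, n_leaves, n_sites)
  for (s in seq_len(n_sites)) hap[tree$sets[[picks[s]]], s] <- 1L
  hap
}

#' Simulate founder lines and their genome map
#'
#' Generates `n_founders` fully inbred founder lines: one haplotype per
#' founder is sampled from a neutral coalescent (independent genealogy blocks
#' along each chromosome, mutations dropped on branches proportionally to
#' branch length, so every site is segregating) and then doubled, giving
#' dosages in \{0, 2\}. A candidate pool of `candidate_factor * loci_per_chr`
#' segregating sites is simulated per chromosome and the requested number of
#' loci is sampled from it; per chromosome, `qtl_per_chr` loci are randomly
#' flagged as QTL and the remainder as markers.
#'
#' @param params A [sim_params()] object.
#' @param seed Integer seed.
#' @return A list with `map` (tibble: `locus`, `chr`, `pos` in Morgans,
#'   `role`, `chr_len`) and `panel` (a `haplotype_panel` of inbred founders).
#' @export
simulate_founders <- function(params = sim_params(), seed = 1L) {
  params <- validate_sim_params(unclass(params))
  set.seed(sub_seed(seed, "founders"))
  n_cand <- as.integer(ceiling(params$candidate_factor * params$loci_per_chr))
  map_list <- vector("list", params$n_chr)
  hap_list <- vector("list", params$n_chr)
  for (chr in seq_len(params$n_chr)) {
    per_block <- diff(round(seq(0, n_cand, length.out = params$founder_blocks + 1L)))
    bounds <- seq(0, params$chr_length, length.out = params$founder_blocks + 1L)
    cand_hap <- vector("list", params$founder_blocks)
    cand_pos <- vector("list", params$founder_blocks)
    for (b in seq_len(params$founder_blocks)) {
      if (per_block[b] == 0L) next
      cand_hap[[b]] <- block_haplotypes(params$n_founders, per_block[b])
      cand_pos[[b]] <- sort(runif(per_block[b], bounds[b], bounds[b + 1L]))
    }
    hap <- do.call(cbind, cand_hap)
    pos <- unlist(cand_pos)
    seg <- which(colSums(hap) > 0L & colSums(hap) < params$n_founders)
    if (length(seg) < params$loci_per_chr)
      stopf("chromosome %d: only %d segregating sites available, %d requested",
            chr, length(seg), params$loci_per_chr)
    keep <- sort(sample(seg, params$loci_per_chr))
    hap_list[[chr]] <- hap[, keep, drop = FALSE]
    role <- rep("marker", params$loci_per_chr)
    role[sample.int(params$loci_per_chr, params$qtl_per_chr)] <- "qtl"
    map_list[[chr]] <- tibble::tibble(
      locus = sprintf("chr%02d_loc%04d", chr, seq_len(params$loci_per_chr)),
      chr = chr, pos = pos[keep], role = role,
      chr_len = params$chr_length)
  }
  map <- dplyr::bind_rows(map_list)
  hap <- do.call(cbind, hap_list)
  storage.mode(hap) <- "raw"
  ids <- sprintf("FND%03d", seq_len(params$n_founders))
  panel <- new_panel(hap, hap, ids, map$locus, inbred = TRUE)
  list(map = map, panel = panel)
}

# 0-based chromosome segment boundaries for the C++ meiosis kernel; assumes
# map rows ordered by chromosome then position (as simulate_founders emits).
map_segments <- function(map) {
  stopifnot(!is.unsorted(map$chr))
  counts <- as.integer(table(factor(map$chr, levels = unique(map$chr))))
  list(chr_start = as.integer(cumsum(c(0L, counts[-length(counts)]))),
       chr_len_loci = counts,
       pos = map$pos,
       chr_len = map$chr_len[cumsum(counts)])
}
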