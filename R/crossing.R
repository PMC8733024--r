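#' Make biparental crosses
#'
#' Crosses pairs of panel individuals: each F1 receives one recombinant gamete
#' from each parent, produced by meiosis with a Poisson crossover count per
#' chromosome (mean = genetic length in Morgans) and uniform crossover
#' placement, no interference (Haldane model). When no `pairs` are supplied,
#' `n_crosses` distinct unordered pairs are drawn at random without selfing.
#'
#' @param panel Parent `haplotype_panel`.
#' @param map Genome map tibble.
#' @param n_crosses Number of biparental crosses (ignored when `pairs` given).
#' @param n_f1_per_cross F1 individuals per cross.
#' @param pairs Optional tibble with columns `p1`, `p2` of parent ids.
#' @param seed Integer seed.
#' @return List with `panel` (the possibly heterozygous F1
#'   `haplotype_panel`) and `pedigree` (tibble: `id`, `p1`, `p2`, `cross`).
#' @export
make_crosses <- function(panel, map, n_crosses = 100L, n_f1_per_cross = 100L,
                         pairs = NULL, seed = 1L) {
  if (n_ind(panel) < 2L) stopf("need at least two parents")
  set.seed(sub_seed(seed, "crosses"))
  if (is.null(pairs)) {
    all_pairs <- utils::combn(n_ind(panel), 2L)
    if (n_crosses > ncol(all_pairs))
      stopf("cannot draw %d distinct pairs from %d parents", n_crosses,
            n_ind(panel))
    take <- all_pairs[, sample.int(ncol(all_pairs), n_crosses), drop = FALSE]
    pairs <- tibble::tibble(p1 = panel$ids[take[1L, ]],
                            p2 = panel$ids[take[2L, ]])
  }
  i1 <- match(pairs$p1, panel$ids)
  i2 <- match(pairs$p2, panel$ids)
  if (anyNA(i1) || anyNA(i2))
    stopf("parent ids not in panel: %s",
          paste(unique(c(pairs$p1[is.na(i1)], pairs$p2[is.na(i2)])),
                collapse = ", "))
  seg <- map_segments(map)
  cross_of <- rep(seq_len(nrow(pairs)), each = n_f1_per_cross)
  r1 <- rep(i1, each = n_f1_per_cross) - 1L
  r2 <- rep(i2, each = n_f1_per_cross) - 1L
  # one gamete from each parent's own pair of haplotypes
  gam1 <- meiosis_gametes_cpp(panel$hap_a, panel$hap_b, r1, r1,
                              seg$chr_start, seg$chr_len_loci, seg$pos,
                              seg$chr_len)
  gam2 <- meiosis_gametes_cpp(panel$hap_a, panel$hap_b, r2, r2,
                              seg$chr_start, seg$chr_len_loci, seg$pos,
                              seg$chr_len)
  ids <- sprintf("%s_x_%s_F1%03d", pairs$p1[cross_of], pairs$p2[cross_of],
                 sequence(rep(n_f1_per_cross, nrow(pairs))))
  f1 <- new_panel(gam1, gam2, ids, panel$loci, inbred = FALSE)
  list(panel = f1,
       pedigree = tibble::tibble(id = ids, p1 = pairs$p1[cross_of],
                                 p2 = pairs$p2[cross_of], cross = cross_of))
}

#' Derive doubled-haploid lines
#'
#' Each doubled haploid is one recombinant gamete of its (F1) parent,
#' duplicated into both haplotypes, giving a fully homozygous line.
#'
#' @param panel F1 `haplotype_panel`.
#' @param map Genome map tibble.
#' @param ids Optional ids for the new lines (default parent id + "_DH").
#' @param seed Integer seed.
#' @return An inbred `haplotype_panel` of one DH line per input individual.
#' @export
double_haploids <- function(panel, map, ids = NULL, seed = 1L) {
  set.seed(sub_seed(seed, "dh"))
  seg <- map_segments(map)
  rows <- seq_len(n_ind(panel)) - 1L
  gam <- meiosis_gametes_cpp(panel$hap_a, panel$hap_b, rows, rows,
                             seg$chr_start, seg$chr_len_loci, seg$pos,
                             seg$chr_len)
  ids <- ids %||% paste0(panel$ids, "_DH")
  new_panel(gam, gam, ids, panel$loci, inbred = TRUE)
}
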