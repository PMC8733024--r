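#' Breeding-programme simulation parameters
#'
#' Collects every tunable of the simulated doubled-haploid breeding programme.
#' The defaults describe a 21-year wheat-like programme: 21 chromosomes with
#' 600 segregating loci each (100 randomly flagged as QTL, 500 as markers), 70
#' fully inbred founder lines with additive genetic variance calibrated to
#' 0.1, 100 biparental crosses of 100 F1 each, and a selection cascade of
#' 10,000 headrows -> 500 preliminary -> 50 advanced -> 10 elite yield trial
#' entries per year, phenotyped at stage heritabilities 0.1 / 0.2 / 0.5 /
#' 0.67. Elite lines are trialled in two consecutive years and one variety is
#' released per completed cycle.
#'
#' @param n_chr Number of chromosome pairs.
#' @param loci_per_chr Segregating loci extracted per chromosome.
#' @param qtl_per_chr Loci per chromosome randomly flagged as QTL; the rest
#'   are markers. Scenario values: 10, 100 (default) or 1000.
#' @param n_founders Number of fully inbred founder lines.
#' @param chr_length Genetic length per chromosome, Morgans.
#' @param founder_blocks Independent genealogy blocks per chromosome in the
#'   founder coalescent generator (see the methods vignette).
#' @param candidate_factor Candidate segregating sites simulated per
#'   chromosome, as a multiple of `loci_per_chr`; the requested loci are
#'   sampled from this pool.
#' @param target_va Additive genetic variance among founders after trait
#'   calibration (1/n convention), trait units squared.
#' @param h2 Named numeric vector of stage heritabilities
#'   (`HDRW`, `PYT`, `AYT`, `EYT`).
#' @param n_crosses,n_f1_per_cross Biparental crosses per cycle and F1 per
#'   cross.
#' @param n_pyt,n_ayt,n_eyt Lines advanced into the preliminary, advanced and
#'   elite yield trials.
#' @param years Simulated years.
#' @param training_years Years whose PYT/AYT/EYT records form the exported
#'   training set; default the last six years.
#' @param gxy_variance Phenotypic variance added through genotype-by-year
#'   interaction (0 disables it; the sensitivity scenario uses 0.2).
#' @param selection `"phenotype"` for truncation selection on stage
#'   phenotypes, `"random"` for random advancement (a drift-only control).
#' @return A validated list of class `sim_params`.
#' @export
sim_params <- function(n_chr = 21L, loci_per_chr = 600L, qtl_per_chr = 100L,
                       n_founders = 70L, chr_length = 1, founder_blocks = 10L,
                       candidate_factor = 2,
                       target_va = 0.1,
                       h2 = c(HDRW = 0.1, PYT = 0.2, AYT = 0.5, EYT = 0.67),
                       n_crosses = 100L, n_f1_per_cross = 100L,
                       n_pyt = 500L, n_ayt = 50L, n_eyt = 10L,
                       years = 21L, training_years = NULL,
                       gxy_variance = 0,
                       selection = c("phenotype", "random")) {
  p <- list(n_chr = as.integer(n_chr), loci_per_chr = as.integer(loci_per_chr),
            qtl_per_chr = as.integer(qtl_per_chr),
            n_founders = as.integer(n_founders), chr_length = chr_length,
            founder_blocks = as.integer(founder_blocks),
            candidate_factor = candidate_factor, target_va = target_va,
            h2 = h2, n_crosses = as.integer(n_crosses),
            n_f1_per_cross = as.integer(n_f1_per_cross),
            n_pyt = as.integer(n_pyt), n_ayt = as.integer(n_ayt),
            n_eyt = as.integer(n_eyt), years = as.integer(years),
            training_years = training_years, gxy_variance = gxy_variance,
            selection = match.arg(selection))
  validate_sim_params(p)
}

validate_sim_params <- function(p) {
  assert_scalar_number(p$target_va, "target_va", lower = 1e-12)
  assert_scalar_number(p$gxy_variance, "gxy_variance", lower = 0)
  assert_scalar_number(p$chr_length, "chr_length", lower = 1e-6)
  if (p$qtl_per_chr >= p$loci_per_chr)
    stopf("qtl_per_chr (%d) must be smaller than loci_per_chr (%d)",
          p$qtl_per_chr, p$loci_per_chr)
  need <- c("HDRW", "PYT", "AYT", "EYT")
  if (!all(need %in% names(p$h2)))
    stopf("h2 must be named with %s", paste(need, collapse = ", "))
  if (any(p$h2 <= 0 | p$h2 > 1)) stopf("heritabilities must lie in (0, 1]")
  n_hdrw <- p$n_crosses * p$n_f1_per_cross
  if (p$n_pyt > n_hdrw || p$n_ayt > p$n_pyt || p$n_eyt > p$n_ayt)
    stopf("stage sizes must be non-increasing along the cascade (%d -> %d -> %d -> %d)",
          n_hdrw, p$n_pyt, p$n_ayt, p$n_eyt)
  if (is.null(p$training_years))
    p$training_years <- seq(max(1L, p$years - 5L), p$years)
  p$training_years <- as.integer(p$training_years)
  if (any(p$training_years < 1L | p$training_years > p$years))
    stopf("training_years must fall inside 1..%d", p$years)
  structure(p, class = "sim_params")
}
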