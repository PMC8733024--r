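#' Assign an additive trait architecture
#'
#' Samples QTL effects from a standard normal and rescales them by a single
#' common factor so that the 1/n variance of genetic values among the supplied
#' (founder) panel equals `target_va` exactly. Genetic values are the linear
#' combination of QTL dosages and effects.
#'
#' @param panel Founder `haplotype_panel`.
#' @param map Genome map tibble with a `role` column flagging QTL.
#' @param target_va Calibration target for the founder genetic variance
#'   (1/n convention).
#' @param seed Integer seed.
#' @return A `trait_arch` object: QTL locus ids, calibrated additive effects
#'   (trait units per allele copy), zero intercept and an empty
#'   genotype-by-year slot.
#' @export
assign_trait <- function(panel, map, target_va = 0.1, seed = 1L) {
  assert_scalar_number(target_va, "target_va", lower = 1e-12)
  set.seed(sub_seed(seed, "trait"))
  qtl <- map$locus[map$role == "qtl"]
  if (length(qtl) == 0L) stopf("map contains no QTL")
  effects <- rnorm(length(qtl))
  Q <- panel_dosages(panel, qtl)
  g <- drop(Q %*% effects)
  v <- var_1n(g)
  if (v <= 0)
    stopf("sampled effects give zero genetic variance among the %d founders; %s",
          n_ind(panel), "genotypes are degenerate at the QTL")
  effects <- effects * sqrt(target_va / v)
  structure(list(qtl = qtl, effects = setNames(effects, qtl),
                 intercept = 0, target_va = target_va,
                 gxy = NULL, gxy_variance = 0),
            class = "trait_arch")
}

#' @export
print.trait_arch <- function(x, ...) {
  cat(sprintf("<trait_arch> %d QTL, founder Va = %g%s\n", length(x$qtl),
              x$target_va,
              if (is.null(x$gxy)) ""
              else sprintf(", GxY variance = %g", x$gxy_variance)))
  invisible(x)
}

#' Add genotype-by-year effect deviations to a trait
#'
#' Draws independent per-year deviations of every QTL effect and scales them
#' by one common factor so that the expected 1/n variance (over the founder
#' genotypes used for calibration) of the year-deviation genetic values equals
#' `gxy_variance`. With deviations `d_t ~ N(0, s2 I)`, the expected variance
#' of `Q d_t` is `s2 * sum_l Var(Q[, l])`, which fixes `s2`.
#'
#' @param trait A `trait_arch`.
#' @param years Integer vector of year indices to cover.
#' @param gxy_variance Target phenotypic variance contributed by
#'   genotype-by-year interaction (0 returns the trait unchanged).
#' @param panel Founder panel used for calibration.
#' @param seed Integer seed.
#' @return The trait with a `gxy` matrix (QTL x years) of effect deviations.
#' @export
add_gxy_deviations <- function(trait, years, gxy_variance, panel, seed = 1L) {
  assert_scalar_number(gxy_variance, "gxy_variance", lower = 0)
  if (gxy_variance == 0) return(trait)
  set.seed(sub_seed(seed, "gxy"))
  Q <- panel_dosages(panel, trait$qtl)
  sum_locus_var <- sum(apply(Q, 2L, var_1n))
  s <- sqrt(gxy_variance / sum_locus_var)
  dev <- matrix(rnorm(length(trait$qtl) * length(years), sd = s),
                nrow = length(trait$qtl),
                dimnames = list(trait$qtl, as.character(years)))
  trait$gxy <- dev
  trait$gxy_variance <- gxy_variance
  trait
}

#' True genetic values of a panel
#'
#' @param panel A `haplotype_panel`.
#' @param trait A `trait_arch`.
#' @param year Optional year index; when the trait carries genotype-by-year
#'   deviations, the returned values include the year-specific deviation
#'   (used for phenotyping). Base genetic values are returned otherwise.
#' @return Named numeric vector of genetic values.
#' @export
true_genetic_values <- function(panel, trait, year = NULL) {
  Q <- panel_dosages(panel, trait$qtl)
  eff <- trait$effects
  if (!is.null(year) && !is.null(trait$gxy)) {
    ycol <- as.character(year)
    if (!ycol %in% colnames(trait$gxy))
      stopf("no genotype-by-year deviations for year %s", ycol)
    eff <- eff + trait$gxy[, ycol]
  }
  setNames(drop(Q %*% eff), panel$ids)
}

#' Phenotype a cohort at a stage heritability
#'
#' Phenotype = genetic value (+ genotype-by-year deviation when present) +
#' normal residual. The residual variance is fixed per stage from the founder
#' calibration target: `Ve = target_va * (1 - h2) / h2`, so realised
#' heritability drifts with the cohort's actual genetic variance rather than
#' being re-standardised each year.
#'
#' @param panel Cohort `haplotype_panel`.
#' @param trait A `trait_arch`.
#' @param h2 Stage heritability in (0, 1]; `h2 = 1` returns the genetic
#'   values themselves.
#' @param year Year index of the record.
#' @param stage Stage label for the record.
#' @param seed Integer seed.
#' @return Tibble with one record per line: `id`, `year`, `stage`, `value`,
#'   `h2`.
#' @export
phenotype_cohort <- function(panel, trait, h2, year, stage, seed = 1L) {
  if (!is.numeric(h2) || length(h2) != 1L || h2 <= 0 || h2 > 1)
    stopf("h2 must lie in (0, 1], got %s", format(h2))
  g <- true_genetic_values(panel, trait, year = year)
  ve <- trait$target_va * (1 - h2) / h2
  set.seed(sub_seed(seed, sprintf("pheno_%s_%s", stage, year)))
  e <- if (ve > 0) rnorm(length(g), sd = sqrt(ve)) else 0
  tibble::tibble(id = panel$ids, year = as.integer(year),
                 stage = as.character(stage), value = unname(g) + e, h2 = h2)
}

#' Truncation selection on phenotype
#'
#' Averages records per line (lines with several records use their mean) and
#' returns the ids of the `n` highest-ranking lines. Ties break
#' deterministically on the line id.
#'
#' @param phenotypes Tibble with `id` and `value` columns.
#' @param n Number of lines to keep.
#' @return Character vector of the selected ids, best first.
#' @export
select_top <- function(phenotypes, n) {
  means <- dplyr::summarise(dplyr::group_by(phenotypes, .data$id),
                            value = mean(.data$value), .groups = "drop")
  if (n > nrow(means))
    stopf("cannot select %d lines from %d candidates", n, nrow(means))
  ranked <- dplyr::arrange(means, dplyr::desc(.data$value), .data$id)
  ranked$id[seq_len(n)]
}
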