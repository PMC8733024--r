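#' Run the full breeding programme simulation
#'
#' Simulates the complete multi-year doubled-haploid programme: founders are
#' crossed into biparental F1 families, F1 are doubled into headrow lines,
#' and truncation selection advances lines through preliminary, advanced and
#' elite yield trials (two elite years, then one released variety per
#' completed cycle). Parents are refreshed every cycle from the previous
#' year's advanced and elite trial lines. A crop born of the parents of year
#' `p` appears as F1 in year `p + 1`, headrows in `p + 2`, PYT in `p + 3`,
#' AYT in `p + 4` and the two elite years in `p + 5` and `p + 6`. True
#' genetic values and the true genic / linkage-disequilibrium variance
#' partition are recorded for every cohort-year, and the phenotype and marker
#' records of the training window are exported.
#'
#' @param params A [sim_params()] object.
#' @param seed Integer master seed; every stochastic step draws from a named
#'   sub-stream so runs are reproducible end to end.
#' @param keep_cohort_genotypes Keep per-cohort marker dosage matrices (for
#'   estimated-variance analyses over cohorts). Memory-hungry at default
#'   scale; intended for reduced configurations.
#' @return A `breeding_sim` object: `map`, `trait`, `founders`, `cohorts`,
#'   `pedigree`, `phenotypes`, `true_values`, `true_partitions` (tidy),
#'   `training` (phenotype tibble + marker dosage matrix), `varieties`.
#' @export
run_programme <- function(params = sim_params(), seed = 1L,
                          keep_cohort_genotypes = FALSE) {
  params <- validate_sim_params(unclass(params))
  fnd <- simulate_founders(params, seed)
  map <- fnd$map
  trait <- assign_trait(fnd$panel, map, params$target_va, seed)
  if (params$gxy_variance > 0)
    trait <- add_gxy_deviations(trait, seq_len(params$years),
                                params$gxy_variance, fnd$panel, seed)
  qtl_cols <- which(map$role == "qtl")
  chr_qtl <- map$chr[qtl_cols]
  marker_cols <- which(map$role == "marker")
  eff <- unname(trait$effects)
  fnd_qtl_allele <- matrix(as.integer(fnd$panel$hap_a[, qtl_cols]),
                           nrow = n_ind(fnd$panel))

  cohorts <- list(); phenos <- list(); truths <- list(); parts <- list()
  pedigree <- list(); varieties <- list(); cohort_geno <- list()
  crops <- vector("list", params$years)
  n_parents <- params$n_ayt + 2L * params$n_eyt

  record_cohort <- function(ids, year, stage) {
    cohorts[[length(cohorts) + 1L]] <<-
      tibble::tibble(id = ids, year = year, stage = stage)
  }
  record_truth <- function(ids, g, year, stage) {
    truths[[length(truths) + 1L]] <<-
      tibble::tibble(id = ids, year = year, stage = stage, g = unname(g))
  }
  record_partition <- function(Q, year, stage) {
    vp <- genomic_partition(Q, eff, chr_qtl, group = stage)
    parts[[length(parts) + 1L]] <<-
      dplyr::mutate(tidy(vp), year = year, stage = stage,
                    .before = "component")
  }
  record_geno <- function(panel_or_Q, year, stage) {
    if (!keep_cohort_genotypes) return(invisible())
    g <- if (inherits(panel_or_Q, "haplotype_panel"))
      panel_dosages(panel_or_Q, map$locus[marker_cols]) else panel_or_Q
    cohort_geno[[sprintf("%s_y%02d", stage, year)]] <<- g
  }
  pick <- function(phen, n, label) {
    if (params$selection == "random") {
      set.seed(sub_seed(seed, paste0("random_", label)))
      sample(unique(phen$id), n)
    } else select_top(phen, n)
  }

  for (y in seq_len(params$years)) {
    seed_y <- sub_seed(seed, sprintf("year%02d", y))
    # -- parents of year y --------------------------------------------------
    if (y == 1L) {
      parents <- fnd$panel
    } else {
      pools <- list()
      if (y - 5L >= 1L && !is.null(crops[[y - 5L]]$ayt_panel))
        pools <- c(pools, list(crops[[y - 5L]]$ayt_panel))
      if (y - 6L >= 1L && !is.null(crops[[y - 6L]]$eyt_panel))
        pools <- c(pools, list(crops[[y - 6L]]$eyt_panel))
      if (y - 7L >= 1L && !is.null(crops[[y - 7L]]$eyt_panel))
        pools <- c(pools, list(crops[[y - 7L]]$eyt_panel))
      have <- sum(vapply(pools, n_ind, integer(1)))
      if (have < n_parents) { # warm-up: top up with founder lines
        extra <- min(n_parents - have, n_ind(fnd$panel))
        pools <- c(pools, list(subset_panel(fnd$panel,
                                            fnd$panel$ids[seq_len(extra)])))
      }
      parents <- combine_panels(pools)
    }
    record_cohort(parents$ids, y, "PARENTS")
    g_par <- true_genetic_values(parents, trait)
    record_truth(parents$ids, g_par, y, "PARENTS")
    record_partition(panel_dosages(parents, map$locus[qtl_cols]), y, "PARENTS")
    record_geno(parents, y, "PARENTS")

    if (y + 1L > params$years) next
    # -- crosses -> F1 (year y + 1) ----------------------------------------
    set.seed(sub_seed(seed_y, "crossplan"))
    all_pairs <- utils::combn(n_ind(parents), 2L)
    take <- all_pairs[, sample.int(ncol(all_pairs), params$n_crosses),
                      drop = FALSE]
    i1 <- take[1L, ]; i2 <- take[2L, ]
    par_allele <- matrix(as.integer(parents$hap_a[, qtl_cols]),
                         nrow = n_ind(parents))
    f1_Q <- par_allele[i1, , drop = FALSE] + par_allele[i2, , drop = FALSE]
    g_cross <- drop(f1_Q %*% eff)
    f1_ids <- sprintf("Y%02d_C%03d_%03d", y + 1L,
                      rep(seq_len(params$n_crosses), each = params$n_f1_per_cross),
                      sequence(rep(params$n_f1_per_cross, params$n_crosses)))
    g_f1 <- rep(g_cross, each = params$n_f1_per_cross)
    record_cohort(f1_ids, y + 1L, "F1")
    record_truth(f1_ids, g_f1, y + 1L, "F1")
    # equal replication within crosses: the partition over the unique cross
    # genotypes equals the partition over all F1 individuals
    record_partition(f1_Q, y + 1L, "F1")
    if (keep_cohort_genotypes) {
      par_mark <- matrix(as.integer(parents$hap_a[, marker_cols]),
                         nrow = n_ind(parents))
      f1_W <- par_mark[i1, , drop = FALSE] + par_mark[i2, , drop = FALSE]
      f1_W <- f1_W[rep(seq_len(params$n_crosses),
                       each = params$n_f1_per_cross), , drop = FALSE]
      dimnames(f1_W) <- list(f1_ids, map$locus[marker_cols])
      record_geno(f1_W, y + 1L, "F1")
    }

    if (y + 2L > params$years) next
    # -- doubled haploids -> headrows (year y + 2) --------------------------
    set.seed(sub_seed(seed_y, "dh"))
    segm <- map_segments(map)
    r1 <- rep(i1, each = params$n_f1_per_cross) - 1L
    r2 <- rep(i2, each = params$n_f1_per_cross) - 1L
    gam <- meiosis_gametes_cpp(parents$hap_a, parents$hap_a, r1, r2,
                               segm$chr_start, segm$chr_len_loci, segm$pos,
                               segm$chr_len)
    dh_ids <- sprintf("Y%02d_C%03d_DH%03d", y + 2L,
                      rep(seq_len(params$n_crosses), each = params$n_f1_per_cross),
                      sequence(rep(params$n_f1_per_cross, params$n_crosses)))
    dh <- new_panel(gam, gam, dh_ids, map$locus, inbred = TRUE)
    pedigree[[length(pedigree) + 1L]] <- tibble::tibble(
      id = dh_ids, p1 = parents$ids[i1][rep(seq_len(params$n_crosses),
                                            each = params$n_f1_per_cross)],
      p2 = parents$ids[i2][rep(seq_len(params$n_crosses),
                               each = params$n_f1_per_cross)])
    Q_dh <- panel_dosages(dh, map$locus[qtl_cols])
    record_cohort(dh_ids, y + 2L, "HDRW")
    record_truth(dh_ids, genetic_values(Q_dh, eff), y + 2L, "HDRW")
    record_partition(Q_dh, y + 2L, "HDRW")
    record_geno(dh, y + 2L, "HDRW")
    ph <- phenotype_cohort(dh, trait, params$h2[["HDRW"]], y + 2L, "HDRW",
                           seed = seed_y)
    phenos[[length(phenos) + 1L]] <- ph
    sel <- pick(ph, params$n_pyt, sprintf("hdrw_y%02d", y + 2L))
    crops[[y]]$pyt_panel <- subset_panel(dh, sel)
    rm(dh, gam, Q_dh)

    # -- yield trials -------------------------------------------------------
    advance <- list(
      list(stage = "PYT", year = y + 3L, h2 = params$h2[["PYT"]],
           keep = params$n_ayt),
      list(stage = "AYT", year = y + 4L, h2 = params$h2[["AYT"]],
           keep = params$n_eyt))
    panel <- crops[[y]]$pyt_panel
    for (st in advance) {
      if (st$year > params$years) { panel <- NULL; break }
      record_cohort(panel$ids, st$year, st$stage)
      Qs <- panel_dosages(panel, map$locus[qtl_cols])
      record_truth(panel$ids, genetic_values(Qs, eff), st$year, st$stage)
      record_partition(Qs, st$year, st$stage)
      record_geno(panel, st$year, st$stage)
      ph <- phenotype_cohort(panel, trait, st$h2, st$year, st$stage,
                             seed = seed_y)
      phenos[[length(phenos) + 1L]] <- ph
      sel <- pick(ph, st$keep, sprintf("%s_y%02d", st$stage, st$year))
      panel <- subset_panel(panel, sel)
      if (st$stage == "PYT") crops[[y]]$ayt_panel <- panel
    }
    if (is.null(panel)) next
    crops[[y]]$eyt_panel <- panel
    eyt_recs <- list()
    for (k in 1:2) {
      yy <- y + 4L + k
      if (yy > params$years) break
      record_cohort(panel$ids, yy, paste0("EYT", k))
      Qs <- panel_dosages(panel, map$locus[qtl_cols])
      record_truth(panel$ids, genetic_values(Qs, eff), yy, paste0("EYT", k))
      record_partition(Qs, yy, paste0("EYT", k))
      ph <- phenotype_cohort(panel, trait, params$h2[["EYT"]], yy, "EYT",
                             seed = seed_y)
      phenos[[length(phenos) + 1L]] <- ph
      eyt_recs[[k]] <- ph
      if (k == 2L) {
        vid <- select_top(dplyr::bind_rows(eyt_recs), 1L)
        varieties[[length(varieties) + 1L]] <-
          tibble::tibble(id = vid, year = yy)
        record_cohort(vid, yy, "VARIETY")
      }
    }
  }

  # -- combined elite-trial cohorts (EYT1 + EYT2 of each year) --------------
  for (y in seq_len(params$years)) {
    pools <- list()
    if (y - 5L >= 1L && !is.null(crops[[y - 5L]]$eyt_panel))
      pools <- c(pools, list(crops[[y - 5L]]$eyt_panel))
    if (y - 6L >= 1L && !is.null(crops[[y - 6L]]$eyt_panel))
      pools <- c(pools, list(crops[[y - 6L]]$eyt_panel))
    if (length(pools) == 0L) next
    eyt <- combine_panels(pools)
    record_partition(panel_dosages(eyt, map$locus[qtl_cols]), y, "EYT")
    record_geno(eyt, y, "EYT")
  }

  phenotypes <- dplyr::bind_rows(phenos)
  training <- extract_training(params, crops, phenotypes, map, marker_cols)

  structure(list(params = params, seed = seed, map = map, trait = trait,
                 founders = fnd$panel,
                 cohorts = dplyr::bind_rows(cohorts),
                 pedigree = dplyr::bind_rows(pedigree),
                 phenotypes = phenotypes,
                 true_values = dplyr::bind_rows(truths),
                 true_partitions = dplyr::bind_rows(parts),
                 training = training,
                 varieties = dplyr::bind_rows(varieties),
                 cohort_genotypes = if (keep_cohort_genotypes) cohort_geno),
            class = "breeding_sim")
}

# Training window: all PYT/AYT/EYT phenotype records of the configured years
# plus the marker dosages of every line appearing in them.
extract_training <- function(params, crops, phenotypes, map, marker_cols) {
  recs <- dplyr::filter(phenotypes,
                        .data$year %in% params$training_years,
                        .data$stage %in% c("PYT", "AYT", "EYT"))
  ids <- sort(unique(recs$id))
  geno <- matrix(NA_integer_, length(ids), length(marker_cols),
                 dimnames = list(ids, map$locus[marker_cols]))
  for (crop in crops) {
    if (is.null(crop$pyt_panel)) next
    hit <- intersect(crop$pyt_panel$ids, ids)
    if (length(hit) == 0L) next
    geno[hit, ] <- panel_dosages(subset_panel(crop$pyt_panel, hit),
                                 map$locus[marker_cols])
  }
  if (anyNA(geno))
    stopf("internal error: training lines without stored genotypes")
  list(phenotypes = recs, genotypes = geno,
       map = map[map$role == "marker", ])
}

#' @export
print.breeding_sim <- function(x, ...) {
  cat(sprintf("<breeding_sim> %d years, seed %s\n", x$params$years,
              format(x$seed)))
  cat(sprintf("  %d phenotype records, %d cohort-year partitions\n",
              nrow(x$phenotypes), nrow(dplyr::distinct(
                x$true_partitions, .data$year, .data$stage))))
  cat(sprintf("  training window %s-%s: %d lines, %d records, %d markers\n",
              min(x$params$training_years), max(x$params$training_years),
              nrow(x$training$genotypes), nrow(x$training$phenotypes),
              ncol(x$training$genotypes)))
  invisible(x)
}

#' Whole-genome true variance components by cohort and year
#'
#' @param sim A `breeding_sim`.
#' @return Tidy tibble (`year`, `stage`, `component`, `value`) of the
#'   genome-level totals of each recorded true partition.
#' @export
true_components <- function(sim) {
  dplyr::filter(sim$true_partitions, is.na(.data$chromosome)) |>
    dplyr::select("year", "stage", "component", "value")
}
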