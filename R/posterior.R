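#' Posterior distribution of variance partitions
#'
#' Treats marker genotypes and sampled marker effects as if they were QTL
#' genotypes and effects: for every posterior draw the genetic values
#' `a = W m` are computed, then for every group of individuals the total
#' (1/n) genetic variance and its genic / within-chromosome LD /
#' between-chromosome LD decomposition. Groups default to breeding
#' stage-by-year cohorts.
#'
#' @param samples An `effect_samples` or `marker_fit` object.
#' @param W Marker dosage matrix (individuals x markers) with rownames; may
#'   contain individuals beyond the training lines.
#' @param groups Tibble with `id` and `group` columns assigning each row of
#'   `W` to one group; every group must have at least one member in `W`.
#' @param map Genome map tibble covering `W`'s columns (`locus`, `chr`).
#' @param level `"genome"` for whole-genome component totals per draw (fast,
#'   vectorised) or `"chromosome"` to also keep per-chromosome and
#'   chromosome-pair terms (loops over draws).
#' @return A `partition_posterior`: tidy tibble of draws (`group`, `draw`,
#'   `component`, `chromosome`, `chromosome2`, `value`) with the draw count
#'   in `attr(, "n_draws")`. Every draw satisfies
#'   total = genic + within_ld + between_ld.
#' @export
partition_posterior <- function(samples, W, groups, map,
                                level = c("genome", "chromosome")) {
  level <- match.arg(level)
  if (inherits(samples, "marker_fit")) samples <- samples$samples
  M <- samples$m
  if (anyNA(match(colnames(W), map$locus)))
    stopf("map does not cover all marker columns of W")
  chr <- map$chr[match(colnames(W), map$locus)]
  grp_rows <- split(match(groups$id, rownames(W)), groups$group)
  bad <- names(grp_rows)[vapply(grp_rows, anyNA, logical(1))]
  if (length(bad) > 0L)
    stopf("group members missing from W (groups: %s)",
          paste(head(bad, 5L), collapse = ", "))
  if (any(lengths(grp_rows) == 0L)) stopf("group with zero members")
  S <- nrow(M)

  if (level == "chromosome") {
    out <- vector("list", S * length(grp_rows))
    k <- 0L
    for (s in seq_len(S)) {
      for (gname in names(grp_rows)) {
        rows <- grp_rows[[gname]]
        vp <- genomic_partition(W[rows, , drop = FALSE], M[s, ], chr,
                                group = gname)
        k <- k + 1L
        out[[k]] <- dplyr::mutate(tidy(vp), draw = s, .after = "group")
      }
    }
    res <- dplyr::bind_rows(out)
  } else {
    chr_f <- factor(chr, levels = unique(chr))
    cols_by_chr <- split(seq_len(ncol(W)), chr_f)
    Mt <- t(M)
    acc <- list()
    for (gname in names(grp_rows)) {
      rows <- grp_rows[[gname]]
      Wg <- W[rows, , drop = FALSE]
      n <- length(rows)
      Asum <- matrix(0, n, S)
      chromvar <- matrix(0, length(cols_by_chr), S)
      genic <- numeric(S)
      for (ci in seq_along(cols_by_chr)) {
        cols <- cols_by_chr[[ci]]
        Wc <- Wg[, cols, drop = FALSE]
        Ac <- Wc %*% Mt[cols, , drop = FALSE]
        Asum <- Asum + Ac
        Ac <- sweep(Ac, 2L, colMeans(Ac))
        chromvar[ci, ] <- colSums(Ac^2) / n
        lvar <- colMeans(Wc^2) - colMeans(Wc)^2
        genic <- genic + colSums(lvar * Mt[cols, , drop = FALSE]^2)
      }
      Asum <- sweep(Asum, 2L, colMeans(Asum))
      total <- colSums(Asum^2) / n
      sum_chromvar <- colSums(chromvar)
      res_g <- tibble::tibble(
        group = gname,
        draw = rep(seq_len(S), 4L),
        component = rep(c("total", "genic", "within_ld", "between_ld"),
                        each = S),
        chromosome = NA_character_,
        chromosome2 = NA_character_,
        value = c(total, genic, sum_chromvar - genic, total - sum_chromvar))
      acc[[gname]] <- res_g
    }
    res <- dplyr::bind_rows(acc)
  }
  structure(res, n_draws = S, class = c("partition_posterior",
                                        class(res)))
}

#' Summarise a partition posterior
#'
#' Posterior mean, standard deviation (divisor S - 1 across draws, a summary
#' of samples rather than the 1/n genetic-variance convention) and empirical
#' quantiles (linear interpolation of order statistics) per group and
#' component.
#'
#' @param posterior A `partition_posterior`.
#' @param probs Length-2 vector of lower/upper quantile probabilities
#'   (default 2.5% and 97.5%).
#' @return Tibble with `group`, `component` (and chromosome columns when
#'   present), `mean`, `sd`, `q_low`, `q_high`.
#' @export
summarize_posterior <- function(posterior, probs = c(0.025, 0.975)) {
  if (nrow(posterior) == 0L) stopf("empty posterior")
  stopifnot(length(probs) == 2L, probs[1] <= probs[2])
  dplyr::summarise(
    dplyr::group_by(tibble::as_tibble(posterior), .data$group,
                    .data$component, .data$chromosome, .data$chromosome2),
    mean = mean(.data$value),
    sd = stats::sd(.data$value),
    q_low = quantile(.data$value, probs[1], names = FALSE, type = 7),
    q_high = quantile(.data$value, probs[2], names = FALSE, type = 7),
    .groups = "drop")
}

#' Stage-by-year group labels for a simulated programme
#'
#' Builds the individual-to-group assignment used for cohort-level posterior
#' analysis, one group per breeding stage and year (elite-trial years 1 and 2
#' are merged into a single EYT group per year).
#'
#' @param sim A `breeding_sim`.
#' @param stages Stages to include.
#' @param years Years to include (default all).
#' @return Tibble with `id`, `group`, `stage`, `year`.
#' @export
sim_groups <- function(sim, stages = c("PARENTS", "F1", "HDRW", "PYT",
                                       "AYT", "EYT"),
                       years = NULL) {
  coh <- dplyr::mutate(sim$cohorts,
                       stage = sub("^EYT[12]$", "EYT", .data$stage))
  coh <- dplyr::filter(coh, .data$stage %in% stages)
  if (!is.null(years)) coh <- dplyr::filter(coh, .data$year %in% years)
  dplyr::transmute(coh, id = .data$id,
                   group = sprintf("%s_y%02d", .data$stage, .data$year),
                   stage = .data$stage, year = .data$year)
}
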