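#' Genetic values from genotype dosages and effects
#'
#' `a = Q %*% effects`; an intercept, when present on the effects object, is
#' deliberately excluded so downstream variances are unaffected by it.
#'
#' @param Q Numeric/integer dosage matrix (individuals x loci, values 0/1/2).
#' @param effects Numeric vector of per-locus allele substitution effects,
#'   optionally named by locus; must match `Q`'s columns.
#' @return Numeric vector of genetic values, named by `Q`'s rownames.
#' @export
genetic_values <- function(Q, effects) {
  if (ncol(Q) != length(effects))
    stopf("dimension mismatch: %d loci in Q, %d effects", ncol(Q),
          length(effects))
  if (!is.null(names(effects)) && !is.null(colnames(Q)) &&
      !identical(colnames(Q), names(effects)))
    stopf("locus ids of Q and effects disagree")
  setNames(drop(Q %*% effects), rownames(Q))
}

#' Population variance with divisor n
#'
#' The genetic-variance convention used throughout: the mean squared
#' deviation from the mean, with divisor `n` rather than `n - 1`. A single
#' value has variance 0.
#'
#' @param x Numeric vector (non-empty).
#' @return A single number.
#' @export
var_1n <- function(x) {
  if (length(x) == 0L) stopf("empty vector has no variance")
  m <- mean(x)
  mean((x - m)^2)
}

# Covariance matrix of the columns of A with divisor n.
cov_1n <- function(A) {
  A <- sweep(A, 2L, colMeans(A))
  crossprod(A) / nrow(A)
}

#' Genetic variance by group (temporal partition)
#'
#' Applies the 1/n variance within each time (or other) partition of a vector
#' of genetic values.
#'
#' @param values Numeric vector of genetic values.
#' @param groups Vector of group labels, one per value.
#' @return Tibble with `group`, `n` and `variance`, one row per group in
#'   first-appearance order. Groups of size one have variance 0.
#' @export
partition_by_group <- function(values, groups) {
  if (length(values) != length(groups))
    stopf("one group label per value required (%d values, %d labels)",
          length(values), length(groups))
  if (length(values) == 0L) stopf("empty group set")
  f <- factor(groups, levels = unique(groups))
  tibble::tibble(group = levels(f),
                 n = as.integer(table(f)),
                 variance = as.numeric(tapply(values, f, var_1n)))
}

#' Decompose genetic variance into genic and linkage-disequilibrium parts
#'
#' Partitions the 1/n genetic variance of `Q %*% effects` into, per
#' chromosome, the genic variance (sum over loci of the empirical dosage
#' variance times the squared effect), the within-chromosome
#' linkage-disequilibrium covariance (all ordered locus pairs on the
#' chromosome) and, between chromosomes, the linkage-disequilibrium
#' covariances of chromosome genetic values. The empirical dosage variance is
#' used throughout -- not the Hardy-Weinberg expectation `2p(1-p)` -- so
#' inbred panels (dosages in \{0, 2\}) get their doubled variance without any
#' inbreeding coefficient.
#'
#' Locus pairs are never materialised: per-chromosome genetic-value columns
#' give the chromosome covariance matrix, whose diagonal minus the genic part
#' is the within-chromosome term, which is mathematically identical to the
#' explicit double sum over locus pairs.
#'
#' @param Q Dosage matrix (individuals x loci).
#' @param effects Per-locus effects aligned with `Q`'s columns.
#' @param chr Chromosome assignment per locus (vector, one entry per column
#'   of `Q`), or a genome map tibble with `locus` and `chr` columns covering
#'   `Q`'s colnames.
#' @param group Optional label carried into the result.
#' @return A `variance_partition` object: `total`, per-chromosome `genic` and
#'   `within`, the symmetric zero-diagonal `between` chromosome matrix and
#'   the group label. `sum(genic) + sum(within) + sum(between)` equals
#'   `total` to numerical precision.
#' @export
genomic_partition <- function(Q, effects, chr, group = NA_character_) {
  if (is.data.frame(chr)) {
    idx <- match(colnames(Q), chr$locus)
    if (anyNA(idx))
      stopf("map does not cover loci: %s",
            paste(colnames(Q)[is.na(idx)][1:5], collapse = ", "))
    chr <- chr$chr[idx]
  }
  if (ncol(Q) != length(effects) || ncol(Q) != length(chr))
    stopf("Q, effects and chr must agree on the locus count")
  if (nrow(Q) < 1L) stopf("empty group: no individuals")
  chr_f <- factor(chr, levels = unique(chr))
  n_c <- nlevels(chr_f)
  cols_by_chr <- split(seq_along(chr), chr_f)
  n <- nrow(Q)
  A_c <- matrix(0, n, n_c)
  genic <- numeric(n_c)
  for (k in seq_len(n_c)) {
    cols <- cols_by_chr[[k]]
    Qc <- Q[, cols, drop = FALSE]
    ec <- effects[cols]
    A_c[, k] <- Qc %*% ec
    cm <- colMeans(Qc)
    locus_var <- colMeans(Qc^2) - cm^2
    genic[k] <- sum(ec^2 * locus_var)
  }
  C <- cov_1n(A_c)
  chrom_var <- diag(C)
  within <- chrom_var - genic
  between <- C
  diag(between) <- 0
  lv <- levels(chr_f)
  dimnames(between) <- list(lv, lv)
  structure(list(group = group, n = n,
                 total = sum(C),
                 genic = setNames(genic, lv),
                 within = setNames(within, lv),
                 between = between,
                 chromosomes = lv),
            class = "variance_partition")
}

#' @export
print.variance_partition <- function(x, ...) {
  s <- genome_components(x)
  cat(sprintf("<variance_partition> group %s (n = %d)\n", x$group, x$n))
  cat(sprintf("  total %.6g = genic %.6g + within-LD %.6g + between-LD %.6g\n",
              s["total"], s["genic"], s["within_ld"], s["between_ld"]))
  invisible(x)
}

#' Whole-genome component totals of a variance partition
#'
#' The between-chromosome total counts each unordered chromosome pair twice
#' (both off-diagonal cells), matching the factor 2 of the decomposition
#' identity.
#'
#' @param x A `variance_partition`.
#' @return Named numeric vector: `total`, `genic`, `within_ld`, `between_ld`.
#' @export
genome_components <- function(x) {
  c(total = x$total, genic = sum(x$genic), within_ld = sum(x$within),
    between_ld = sum(x$between))
}

#' @describeIn genomic_partition Tidy a variance partition into one row per
#'   component: genome-level rows (`chromosome` NA) plus per-chromosome genic
#'   and within-LD rows and per-chromosome-pair between-LD rows.
#' @param x A `variance_partition`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
#' @export
tidy.variance_partition <- function(x, ...) {
  g <- genome_components(x)
  genome <- tibble::tibble(group = x$group,
                           component = names(g),
                           chromosome = NA_character_,
                           chromosome2 = NA_character_,
                           value = unname(g))
  per_chr <- tibble::tibble(
    group = x$group,
    component = rep(c("genic", "within_ld"), each = length(x$chromosomes)),
    chromosome = rep(x$chromosomes, 2L),
    chromosome2 = NA_character_,
    value = c(unname(x$genic), unname(x$within)))
  pairs <- which(upper.tri(x$between), arr.ind = TRUE)
  between <- tibble::tibble(
    group = x$group, component = "between_ld",
    chromosome = x$chromosomes[pairs[, 1L]],
    chromosome2 = x$chromosomes[pairs[, 2L]],
    value = 2 * x$between[pairs])
  dplyr::bind_rows(genome, per_chr, between)
}

#' Term counts of the genomic decomposition
#'
#' Closed-form combinatorics for `n_c` chromosomes with `n_lc` loci each:
#' locus combinations `(n_c n_lc)^2`, within-chromosome ordered locus pairs
#' `n_c n_lc (n_lc - 1)`, between-chromosome ordered locus pairs
#' `(n_c n_lc)^2 - n_c n_lc^2`, chromosome combinations `n_c^2` and ordered
#' between-chromosome pairs `n_c^2 - n_c`.
#'
#' @param n_c Number of chromosomes (positive integer).
#' @param n_lc Loci per chromosome (positive integer).
#' @return One-row tibble with the five counts.
#' @export
term_counts <- function(n_c, n_lc) {
  if (n_c < 1 || n_lc < 1) stopf("n_c and n_lc must be positive")
  n_l <- as.numeric(n_c) * n_lc
  tibble::tibble(
    locus_combinations = n_l^2,
    within_chr_locus_pairs = n_c * n_lc * (n_lc - 1),
    between_chr_locus_pairs = n_l^2 - n_c * n_lc^2,
    chromosome_combinations = as.numeric(n_c)^2,
    between_chr_pairs = as.numeric(n_c)^2 - n_c)
}
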