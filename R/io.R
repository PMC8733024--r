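# Workbench: plain-text dataset interchange, configuration and manifests.
# TSV is the canonical format (header row, UTF-8, "." for missing).

#' Write a dataset bundle to a directory
#'
#' Writes the phenotype table, the marker dosage matrix, the genome map and
#' (for simulated data) the truth tables as TSV, plus a `manifest.tsv`
#' listing every file with the seed and a configuration hash. Re-running
#' with the same inputs produces byte-identical files.
#'
#' @param x A `breeding_sim` or a `dataset_bundle`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the manifest tibble.
#' @export
write_bundle <- function(x, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (inherits(x, "breeding_sim")) {
    bundle <- list(phenotypes = x$training$phenotypes,
                   genotypes = x$training$genotypes,
                   map = x$training$map,
                   true_values = x$true_values,
                   true_partitions = x$true_partitions,
                   qtl_effects = tibble::tibble(
                     locus = names(x$trait$effects),
                     effect = unname(x$trait$effects)),
                   seed = x$seed, params = x$params)
  } else bundle <- x
  paths <- character()
  wr <- function(df, name) {
    p <- file.path(dir, name)
    readr::write_tsv(df, p, progress = FALSE)
    paths[[name]] <<- p
  }
  wr(bundle$phenotypes, "phenotypes.tsv")
  geno_df <- tibble::as_tibble(bundle$genotypes, rownames = "id")
  wr(geno_df, "genotypes.tsv")
  wr(bundle$map, "map.tsv")
  if (!is.null(bundle$true_values)) wr(bundle$true_values, "true_values.tsv")
  if (!is.null(bundle$true_partitions))
    wr(bundle$true_partitions, "true_partitions.tsv")
  if (!is.null(bundle$qtl_effects)) wr(bundle$qtl_effects, "qtl_effects.tsv")
  manifest <- tibble::tibble(
    file = names(paths),
    rows = vapply(paths, function(p) length(readr::read_lines(p)) - 1L,
                  integer(1)),
    seed = bundle$seed %||% NA_integer_,
    config_hash = rlang::hash(bundle$params %||% list()))
  readr::write_tsv(manifest, file.path(dir, "manifest.tsv"),
                   progress = FALSE)
  invisible(manifest)
}

#' Read and validate a dataset bundle
#'
#' Loads a directory written by [write_bundle()] (or hand-assembled TSVs with
#' the same layout) and enforces cross-file consistency: dosages in
#' \{0, 1, 2\}, no duplicated loci, the map covering every genotype column
#' and every phenotyped line genotyped.
#'
#' @param dir Directory with `phenotypes.tsv`, `genotypes.tsv`, `map.tsv`.
#' @return A `dataset_bundle` list: `phenotypes`, `genotypes` (integer
#'   matrix), `map` and any truth tables present.
#' @export
read_bundle <- function(dir) {
  need <- c("phenotypes.tsv", "genotypes.tsv", "map.tsv")
  missing_files <- need[!file.exists(file.path(dir, need))]
  if (length(missing_files) > 0L)
    stopf("bundle incomplete, missing: %s",
          paste(missing_files, collapse = ", "))
  phen <- readr::read_tsv(file.path(dir, "phenotypes.tsv"),
                          show_col_types = FALSE, progress = FALSE)
  geno_df <- readr::read_tsv(file.path(dir, "genotypes.tsv"),
                             show_col_types = FALSE, progress = FALSE)
  map <- readr::read_tsv(file.path(dir, "map.tsv"), show_col_types = FALSE,
                         progress = FALSE)
  geno <- as.matrix(geno_df[, -1L])
  rownames(geno) <- geno_df[[1L]]
  storage.mode(geno) <- "integer"
  validate_bundle(phen, geno, map)
  out <- list(phenotypes = phen, genotypes = geno, map = map)
  for (extra in c("true_values", "true_partitions", "qtl_effects")) {
    p <- file.path(dir, paste0(extra, ".tsv"))
    if (file.exists(p))
      out[[extra]] <- readr::read_tsv(p, show_col_types = FALSE,
                                      progress = FALSE)
  }
  structure(out, class = "dataset_bundle")
}

validate_bundle <- function(phenotypes, genotypes, map) {
  vals <- unique(as.vector(genotypes))
  bad <- setdiff(vals, c(0L, 1L, 2L, NA_integer_))
  if (length(bad) > 0L)
    stopf("genotype dosages outside {0,1,2}: %s",
          paste(head(bad, 5L), collapse = ", "))
  if (anyDuplicated(map$locus))
    stopf("duplicated loci in map: %s",
          paste(head(map$locus[duplicated(map$locus)], 5L), collapse = ", "))
  unmapped <- setdiff(colnames(genotypes), map$locus)
  if (length(unmapped) > 0L)
    stopf("genotype markers missing from map: %s%s",
          paste(head(unmapped, 5L), collapse = ", "),
          if (length(unmapped) > 5L)
            sprintf(" (+%d more)", length(unmapped) - 5L) else "")
  miss <- setdiff(unique(phenotypes$id), rownames(genotypes))
  if (length(miss) > 0L)
    stopf("phenotyped lines without genotypes: %s",
          paste(head(miss, 5L), collapse = ", "))
  invisible(TRUE)
}

#' Import genotype dosages from a VCF file
#'
#' Converts diploid GT fields to counts of the alternative allele (0/1/2);
#' homozygous-only VCFs (inbred panels) yield dosages in \{0, 2\}. Requires
#' the `vcfR` package.
#'
#' @param path Path to an (uncompressed or gzipped) VCF.
#' @return Integer dosage matrix, samples in rows, variant ids in columns.
#' @export
import_vcf_genotypes <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stopf("vcfR is required for VCF import")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  count_alt <- function(g) {
    ifelse(is.na(g), NA_integer_,
           vapply(strsplit(g, "[/|]"), function(a)
             sum(as.integer(a) > 0L), integer(1)))
  }
  dos <- apply(gt, 2L, count_alt)
  if (is.null(dim(dos))) dos <- matrix(dos, nrow = 1L,
                                       dimnames = list(rownames(gt),
                                                       colnames(gt)))
  ids <- rownames(gt) %||% sprintf("var%04d", seq_len(nrow(gt)))
  t(matrix(as.integer(dos), nrow = nrow(gt),
           dimnames = list(ids, colnames(gt))))
}

#' Write / read posterior effect samples as TSV
#'
#' The draws-by-markers matrix plus the per-draw variance components go into
#' two TSV files that reopen to equal values.
#'
#' @param samples An `effect_samples`.
#' @param dir Output directory.
#' @return Invisibly, the file paths.
#' @export
write_effect_samples <- function(samples, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  m_df <- tibble::as_tibble(samples$m)
  m_df <- dplyr::bind_cols(tibble::tibble(draw = seq_len(nrow(samples$m))),
                           m_df)
  b_df <- tibble::as_tibble(samples$b)
  paths <- c(marker = file.path(dir, "marker_samples.tsv"),
             fixed = file.path(dir, "fixed_samples.tsv"),
             varcomp = file.path(dir, "varcomp_trace.tsv"))
  readr::write_tsv(m_df, paths[["marker"]], progress = FALSE)
  readr::write_tsv(dplyr::bind_cols(
    tibble::tibble(draw = seq_len(nrow(samples$b))), b_df),
    paths[["fixed"]], progress = FALSE)
  readr::write_tsv(samples$varcomp, paths[["varcomp"]], progress = FALSE)
  invisible(paths)
}

#' @rdname write_effect_samples
#' @param approach Label restored on the reloaded object.
#' @export
read_effect_samples <- function(dir, approach = "unknown") {
  m_df <- readr::read_tsv(file.path(dir, "marker_samples.tsv"),
                          show_col_types = FALSE, progress = FALSE)
  b_df <- readr::read_tsv(file.path(dir, "fixed_samples.tsv"),
                          show_col_types = FALSE, progress = FALSE)
  vc <- readr::read_tsv(file.path(dir, "varcomp_trace.tsv"),
                        show_col_types = FALSE, progress = FALSE)
  m <- as.matrix(m_df[, -1L])
  b <- as.matrix(b_df[, -1L, drop = FALSE])
  new_effect_samples(b, m, vc, approach, NULL, NA_integer_, colnames(m))
}

#' Read a run configuration
#'
#' YAML configuration with `simulation`, `fitting`, `decomposition` and
#' `evaluation` blocks plus top-level `seed` and `output_dir`. Unknown keys
#' are rejected.
#'
#' @param path Path to a YAML file.
#' @return A `run_config` list.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  allowed <- c("simulation", "fitting", "decomposition", "evaluation",
               "seed", "output_dir")
  unknown <- setdiff(names(cfg), allowed)
  if (length(unknown) > 0L)
    stopf("unknown config keys: %s", paste(unknown, collapse = ", "))
  sim_allowed <- names(formals(sim_params))
  unknown_sim <- setdiff(names(cfg$simulation %||% list()), sim_allowed)
  if (length(unknown_sim) > 0L)
    stopf("unknown simulation keys: %s", paste(unknown_sim, collapse = ", "))
  cfg$seed <- as.integer(cfg$seed %||% 1L)
  structure(cfg, class = "run_config")
}

sim_params_from_config <- function(cfg) {
  sim <- cfg$simulation %||% list()
  if (!is.null(sim$h2)) sim$h2 <- unlist(sim$h2)
  do.call(sim_params, sim)
}
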