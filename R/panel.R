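#' Haplotype panels
#'
#' A haplotype panel stores the two haplotypes of a set of individuals as raw
#' (one byte per allele) matrices of 0/1 alleles, individuals in rows and loci
#' in columns in genome-map order. Fully inbred individuals (founder lines and
#' doubled haploids) share a single matrix for both haplotypes, so a panel of
#' 10,000 lines at 12,600 loci stays compact.
#'
#' @param hap_a,hap_b Raw matrices of alleles (individuals x loci). For an
#'   inbred panel pass the same object twice.
#' @param ids Character vector of individual ids (one per row).
#' @param loci Character vector of locus ids (one per column), matching the
#'   genome map order.
#' @param inbred Logical, `TRUE` when both haplotypes are identical by
#'   construction.
#' @return An object of class `haplotype_panel`.
#' @keywords internal
new_panel <- function(hap_a, hap_b, ids, loci, inbred) {
  stopifnot(is.raw(hap_a), is.raw(hap_b), nrow(hap_a) == length(ids),
            ncol(hap_a) == length(loci))
  structure(list(hap_a = hap_a, hap_b = hap_b, ids = as.character(ids),
                 loci = as.character(loci), inbred = isTRUE(inbred)),
            class = "haplotype_panel")
}

#' @export
print.haplotype_panel <- function(x, ...) {
  cat(sprintf("<haplotype_panel> %d individuals x %d loci (%s)\n",
              length(x$ids), length(x$loci),
              if (x$inbred) "fully inbred" else "possibly heterozygous"))
  invisible(x)
}

#' Number of individuals in a panel
#' @param panel A `haplotype_panel`.
#' @return Integer count.
#' @export
n_ind <- function(panel) length(panel$ids)

#' Extract a dosage matrix from a haplotype panel
#'
#' Dosages count copies of the derived (alternative) allele, so values are in
#' \{0, 1, 2\}; inbred individuals only show 0 or 2.
#'
#' @param panel A `haplotype_panel`.
#' @param loci Optional character vector of locus ids (defaults to all loci,
#'   in map order).
#' @return Integer matrix (individuals x loci) with row and column names.
#' @export
panel_dosages <- function(panel, loci = NULL) {
  cols <- if (is.null(loci)) seq_along(panel$loci) else match(loci, panel$loci)
  if (anyNA(cols))
    stopf("unknown loci: %s", paste(loci[is.na(cols)], collapse = ", "))
  out <- dosage_cpp(panel$hap_a, panel$hap_b, as.integer(cols - 1L))
  dimnames(out) <- list(panel$ids, panel$loci[cols])
  out
}

#' Subset a panel by individual id
#' @param panel A `haplotype_panel`.
#' @param ids Ids to keep (order preserved as given).
#' @return A `haplotype_panel`.
#' @export
subset_panel <- function(panel, ids) {
  idx <- match(ids, panel$ids)
  if (anyNA(idx))
    stopf("ids not in panel: %s", paste(ids[is.na(idx)], collapse = ", "))
  new_panel(panel$hap_a[idx, , drop = FALSE],
            if (panel$inbred) panel$hap_a[idx, , drop = FALSE]
            else panel$hap_b[idx, , drop = FALSE],
            panel$ids[idx], panel$loci, panel$inbred)
}

#' Stack panels over the same loci
#' @param ... `haplotype_panel` objects sharing the same locus set.
#' @return A `haplotype_panel`; inbred only if all inputs are.
#' @export
combine_panels <- function(...) {
  panels <- list(...)
  if (length(panels) == 1L && is.list(panels[[1]]) &&
      !inherits(panels[[1]], "haplotype_panel"))
    panels <- panels[[1]]
  loci <- panels[[1]]$loci
  for (p in panels)
    if (!identical(p$loci, loci)) stopf("panels have different locus sets")
  new_panel(do.call(rbind, lapply(panels, `[[`, "hap_a")),
            do.call(rbind, lapply(panels, `[[`, "hap_b")),
            unlist(lapply(panels, `[[`, "ids")), loci,
            all(vapply(panels, `[[`, logical(1), "inbred")))
}

# Heterozygosity per individual: fraction of loci with differing alleles.
panel_heterozygosity <- function(panel) {
  if (panel$inbred) return(setNames(rep(0, n_ind(panel)), panel$ids))
  a <- matrix(as.integer(panel$hap_a), nrow = nrow(panel$hap_a))
  b <- matrix(as.integer(panel$hap_b), nrow = nrow(panel$hap_b))
  setNames(rowMeans(a != b), panel$ids)
}
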