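#' Enumerate CpG sites on a genome
#'
#' One site per CG dinucleotide occurrence, identified by the 0-based
#' position of the C on the plus strand. A CpG site is always counted as a
#' single strand-combined unit; region membership downstream uses the C
#' position alone, so no site is double-counted at class boundaries even when
#' the G falls outside a region.
#'
#' @param genome A [Biostrings::DNAStringSet] or named character vector.
#' @return Tibble with columns `chrom`, `pos`, sorted.
#' @examples
#' enumerate_cpg_sites(c(chr1 = "ACGCGT"))
#' @export
enumerate_cpg_sites <- function(genome) {
  if (is.character(genome)) {
    genome <- Biostrings::DNAStringSet(toupper(genome))
  }
  stopifnot(methods::is(genome, "DNAStringSet"), !is.null(names(genome)))
  hits <- Biostrings::vmatchPattern("CG", genome)
  out <- purrr::imap(as.list(hits), function(ir, nm) {
    tibble(chrom = nm, pos = as.numeric(IRanges::start(ir)) - 1)
  })
  bind_rows(out) %>% arrange(.data$chrom, .data$pos)
}

#' Per-region-class CpG census of a capture target
#'
#' For every region class, counts the CpG sites inside the class and inside
#' the class-target intersection, plus a `TOTAL` row over the merged target.
#' When a reference census is supplied (e.g. the census of the original
#' source-genome panel), per-class coverage is reported as
#' `100 * in_target / reference`, at 0.1% precision; classes with a zero
#' reference count yield `NA`. Because classes may overlap, per-class counts
#' need not sum to `TOTAL`.
#'
#' @param target Region tibble (e.g. the redefined target).
#' @param classes Named list of region tibbles (e.g. from
#'   [build_region_map()]).
#' @param cpg_sites Tibble (`chrom`, `pos`) from [enumerate_cpg_sites()], or
#'   a genome from which sites are enumerated.
#' @param reference Optional reference census: tibble with `region_class` and
#'   a count column (`cg_sites_in_target` or `cg_sites`), or a named numeric
#'   vector.
#' @return Tibble of class `cg_census`: `region_class`, `cg_sites_in_class`,
#'   `cg_sites_in_target`, and `coverage_vs_reference` when a reference is
#'   given.
#' @export
cg_census <- function(target, classes, cpg_sites, reference = NULL) {
  if (!is.data.frame(cpg_sites)) cpg_sites <- enumerate_cpg_sites(cpg_sites)
  stopifnot(is.list(classes), !is.null(names(classes)))
  target <- merge_regions(as_regions(target, genome = region_genome(target)))
  in_target <- sites_in_regions(cpg_sites, target)
  rows <- purrr::imap(classes, function(cls, nm) {
    check_same_genome(target, as_regions(cls, genome = region_genome(cls)))
    in_class <- sites_in_regions(cpg_sites, cls)
    tibble(region_class = nm,
           cg_sites_in_class = sum(in_class),
           cg_sites_in_target = sum(in_class & in_target))
  })
  out <- bind_rows(rows) %>%
    bind_rows(tibble(region_class = "TOTAL",
                     cg_sites_in_class = nrow(cpg_sites),
                     cg_sites_in_target = sum(in_target)))
  if (!is.null(reference)) {
    ref <- census_reference_counts(reference)
    refv <- ref[out$region_class]
    out$coverage_vs_reference <- unname(ifelse(
      is.na(refv) | refv == 0, NA_real_,
      round(100 * out$cg_sites_in_target / refv, 1)
    ))
  }
  class(out) <- c("cg_census", class(out))
  out
}

census_reference_counts <- function(reference) {
  if (is.numeric(reference) && !is.null(names(reference))) {
    return(reference)
  }
  if (is.data.frame(reference)) {
    cnt_col <- intersect(c("cg_sites_in_target", "cg_sites"),
                         names(reference))
    if ("region_class" %in% names(reference) && length(cnt_col) > 0) {
      return(setNames(as.numeric(reference[[cnt_col[1]]]),
                      reference$region_class))
    }
  }
  abort("reference census must be a named vector or a tibble with region_class and a count column")
}
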