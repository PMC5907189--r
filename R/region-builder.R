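#' Promoters from gene models
#'
#' One promoter per gene symbol: the TSS is the start site of the longest
#' transcript associated with the symbol (largest genomic span `end - start`;
#' ties broken by lexicographically smallest `transcript_id`), and the
#' promoter is the `upstream` bp 5' of the TSS — `[TSS - upstream, TSS)` on
#' `+`, `[TSS, TSS + upstream)` on `-` — clipped to chromosome bounds when
#' lengths are supplied.
#'
#' @param models A `gene_models` object (see [read_gtf()]).
#' @param upstream Promoter width in bp upstream of the TSS (default 2000).
#' @param chrom_lengths Optional named lengths for boundary clipping.
#' @return Tibble with one row per gene: `gene`, `transcript_id`, `chrom`,
#'   `strand`, `tss`, `start`, `end`.
#' @export
gene_promoters <- function(models, upstream = 2000, chrom_lengths = NULL) {
  stopifnot(inherits(models, "gene_models"), upstream > 0)
  tx <- models$transcripts
  if (nrow(tx) == 0) abort("gene models contain no transcripts")
  longest <- tx %>%
    mutate(span = .data$end - .data$start) %>%
    arrange(.data$gene, desc(.data$span), .data$transcript_id) %>%
    group_by(.data$gene) %>%
    slice(1) %>%
    ungroup()
  tss <- ifelse(longest$strand == "+", longest$start, longest$end)
  p_start <- ifelse(longest$strand == "+", tss - upstream, tss)
  p_end <- ifelse(longest$strand == "+", tss, tss + upstream)
  p_start <- pmax(0, p_start)
  if (!is.null(chrom_lengths)) {
    cl <- chrom_lengths(chrom_lengths)
    if (!all(longest$chrom %in% names(cl))) {
      abort("transcript chromosome absent from chromosome lengths")
    }
    p_end <- pmin(cl[longest$chrom], p_end)
  }
  keep <- p_start < p_end
  tibble(
    gene = longest$gene[keep],
    transcript_id = longest$transcript_id[keep],
    chrom = longest$chrom[keep],
    strand = longest$strand[keep],
    tss = as.numeric(tss[keep]),
    start = as.numeric(p_start[keep]),
    end = as.numeric(p_end[keep])
  ) %>% arrange(.data$chrom, .data$start)
}

#' Build the region-class taxonomy
#'
#' Assembles the classes used for the census and methylation summaries:
#' `CGI`, `SHORE` and `SHELF` (mutually exclusive, precedence-trimmed),
#' `PROMOTER`, `EXON` (merged union of all exons), `CDS` (merged union of all
#' CDS) and `INTERGENIC` (genome minus merged gene spans and promoters).
#' Classes are deliberately non-exclusive across groups — a base may be both
#' CGI and PROMOTER — because per-class summaries are reported independently.
#' A CDS base outside every exon indicates a malformed annotation and is
#' reported with a warning, never silently repaired.
#'
#' @param cgis,shores,shelves Region tibbles (see [find_cgis()],
#'   [derive_shores_shelves()]).
#' @param promoters Promoter tibble from [gene_promoters()] (or any region
#'   tibble).
#' @param models A `gene_models` object supplying exons, CDS and gene spans.
#' @param chrom_lengths Named chromosome lengths (or genome) defining the
#'   universe for `INTERGENIC`.
#' @return Named list of normalised region tibbles, class `region_map`.
#' @export
build_region_map <- function(cgis, shores, shelves, promoters, models,
                             chrom_lengths) {
  stopifnot(inherits(models, "gene_models"))
  cl <- chrom_lengths(chrom_lengths)
  genome_regions <- as_regions(tibble(chrom = names(cl), start = 0,
                                      end = as.numeric(cl)))
  exon <- merge_regions(as_regions(models$exons))
  cds <- if (nrow(models$cds) > 0) {
    merge_regions(as_regions(models$cds))
  } else {
    empty_regions()
  }
  if (nrow(cds) > 0) {
    stray <- subtract_regions(cds, exon)
    if (nrow(stray) > 0) {
      warn(paste0("annotation malformed: ", region_total_length(stray),
                  " CDS bases fall outside every exon"))
    }
  }
  gene_spans <- merge_regions(as_regions(models$transcripts))
  prom <- merge_regions(as_regions(promoters))
  intergenic <- subtract_regions(genome_regions,
                                 union_regions(gene_spans, prom))
  structure(list(
    CGI = merge_regions(as_regions(cgis)),
    SHORE = merge_regions(as_regions(shores)),
    SHELF = merge_regions(as_regions(shelves)),
    PROMOTER = prom,
    EXON = exon,
    CDS = cds,
    INTERGENIC = intergenic
  ), class = c("region_map", "list"))
}

#' @export
print.region_map <- function(x, ...) {
  cat("<region_map>\n")
  for (nm in names(x)) {
    cat(sprintf("  %-10s %8d intervals %12.0f bp\n", nm, nrow(x[[nm]]),
                region_total_length(x[[nm]])))
  }
  invisible(x)
}
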