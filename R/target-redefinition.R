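#' Pipeline parameters
#'
#' Central knob set for target redefinition and methylome summarisation.
#' Defaults follow the published protocol: probes align usefully at identity
#' >= 85% and e-value <= 1e-10 (boundaries inclusive), a promoter counts as
#' panel-covered only when strictly more than 60% of it overlaps probes,
#' promoters/shores/shelves are 2 kb, and methylation levels are called at
#' >= 5-fold strand-merged depth. `target_mean_depth_goal` (30x) and
#' `dedup_depth_goal` (40x) are data-acquisition goals surfaced in QC
#' reporting only, never per-site filters.
#'
#' @param promoter_upstream Promoter width upstream of the TSS, bp.
#' @param shore_width,shelf_width Island flank widths, bp.
#' @param hpr_min_identity Minimum percent identity for an alignment to enter
#'   the HPR (inclusive).
#' @param hpr_max_evalue Maximum e-value (inclusive).
#' @param opr_min_overlap Promoter/probe overlap fraction that must be
#'   strictly exceeded for the gene symbol to count as panel-covered.
#' @param min_call_depth Minimum strand-merged depth for a CpG site to enter
#'   level summaries.
#' @param depth_thresholds Depth cut-offs for cumulative coverage reporting.
#' @param target_mean_depth_goal,dedup_depth_goal QC goals (x-fold).
#' @return A list of class `pipeline_params`.
#' @export
pipeline_params <- function(promoter_upstream = 2000,
                            shore_width = 2000, shelf_width = 2000,
                            hpr_min_identity = 85, hpr_max_evalue = 1e-10,
                            opr_min_overlap = 0.60, min_call_depth = 5,
                            depth_thresholds = c(1, 5, 10, 20, 30, 40),
                            target_mean_depth_goal = 30,
                            dedup_depth_goal = 40) {
  stopifnot(promoter_upstream > 0, shore_width > 0, shelf_width > 0,
            hpr_min_identity >= 0, hpr_min_identity <= 100,
            hpr_max_evalue >= 0, opr_min_overlap >= 0, opr_min_overlap <= 1,
            min_call_depth >= 0, all(diff(depth_thresholds) > 0))
  structure(as.list(environment()), class = "pipeline_params")
}

#' Filter probe alignments by identity and e-value
#'
#' Keeps records with `identity >= hpr_min_identity` and
#' `evalue <= hpr_max_evalue` (both boundaries inclusive). With
#' `mode = "best"` (default) a single record is retained per probe — highest
#' bit score, ties broken by lowest e-value, then highest identity, then
#' smallest (subject, start) — which prevents paralogous hits from inflating
#' the target. `mode = "all"` keeps every passing record for sensitivity
#' analysis. Probes with no passing record are listed in the `dropped_probes`
#' attribute.
#'
#' @param aln Alignment tibble from [read_blast8()].
#' @param params A [pipeline_params()] list.
#' @param mode `"best"` or `"all"`.
#' @return Tibble of passing records (attribute `dropped_probes`).
#' @export
filter_alignments <- function(aln, params = pipeline_params(),
                              mode = c("best", "all")) {
  mode <- arg_match(mode)
  pass <- aln %>%
    filter(.data$identity >= params$hpr_min_identity,
           .data$evalue <= params$hpr_max_evalue)
  if (mode == "best" && nrow(pass) > 0) {
    pass <- pass %>%
      arrange(.data$query_id, desc(.data$bitscore), .data$evalue,
              desc(.data$identity), .data$subject, .data$start) %>%
      group_by(.data$query_id) %>%
      slice(1) %>%
      ungroup()
  }
  attr(pass, "dropped_probes") <- setdiff(unique(aln$query_id),
                                          unique(pass$query_id))
  pass
}

#' Homologous probe region (HPR) from passing alignments
#'
#' Subject intervals of the filtered alignments, strand-ignored and merged:
#' the portion of the target genome reachable by the source-genome capture
#' probes.
#'
#' @param passing Tibble from [filter_alignments()] (needs `chrom`, `start`,
#'   `end`).
#' @param genome Optional genome identifier to attach.
#' @return Normalised region tibble.
#' @export
build_hpr <- function(passing, genome = NULL) {
  if (nrow(passing) == 0) return(empty_regions(genome))
  merge_regions(as_regions(passing[, c("chrom", "start", "end")],
                           genome = genome))
}

#' Probe coverage of source promoters
#'
#' `promoter_probe_coverage()` annotates each source-genome promoter with the
#' fraction of its bases covered by the probe panel;
#' `covered_gene_symbols()` returns the symbols whose promoters are covered
#' strictly more than `min_overlap` (default "more than 60%").
#'
#' @param promoters Promoter tibble (needs `gene`, `chrom`, `start`, `end`).
#' @param probes Region tibble of capture-probe intervals on the same genome.
#' @param min_overlap Strict lower bound on the covered fraction.
#' @return `promoter_probe_coverage()`: the promoter tibble with a
#'   `covered_fraction` column; `covered_gene_symbols()`: character vector of
#'   gene symbols.
#' @export
promoter_probe_coverage <- function(promoters, probes) {
  stopifnot("gene" %in% names(promoters))
  promoters %>%
    mutate(covered_fraction = overlap_fraction(promoters, probes))
}

#' @rdname promoter_probe_coverage
#' @export
covered_gene_symbols <- function(promoters, probes, min_overlap = 0.60) {
  cov <- promoter_probe_coverage(promoters, probes)
  sort(unique(cov$gene[cov$covered_fraction > min_overlap]))
}

#' Orthologous promoter region (OPR)
#'
#' For each panel-covered source gene symbol present in the target
#' annotation (exact string match by default; set `ignore_case = TRUE` to
#' case-fold), the target-genome promoter is recomputed 2 kb (or
#' `upstream` bp) in the 5' direction from the target TSS via
#' [gene_promoters()], and the union is merged. Symbols absent from the
#' target annotation are recorded in the `unmatched_symbols` attribute.
#'
#' @param symbols Character vector from [covered_gene_symbols()].
#' @param target_models `gene_models` for the target genome.
#' @param upstream Promoter width, bp.
#' @param chrom_lengths Optional lengths for clipping.
#' @param ignore_case Case-insensitive symbol matching.
#' @return Normalised region tibble (attributes `matched_symbols`,
#'   `unmatched_symbols`, `promoters` with the per-gene intervals).
#' @export
build_opr <- function(symbols, target_models, upstream = 2000,
                      chrom_lengths = NULL, ignore_case = FALSE) {
  stopifnot(inherits(target_models, "gene_models"))
  prom <- gene_promoters(target_models, upstream = upstream,
                         chrom_lengths = chrom_lengths)
  key <- if (ignore_case) toupper(prom$gene) else prom$gene
  want <- if (ignore_case) toupper(symbols) else symbols
  sel <- prom[key %in% want, ]
  matched <- unique(sel$gene)
  unmatched <- setdiff(symbols, symbols[want %in% key])
  out <- if (nrow(sel) == 0) empty_regions() else merge_regions(as_regions(sel))
  attr(out, "matched_symbols") <- sort(matched)
  attr(out, "unmatched_symbols") <- sort(unmatched)
  attr(out, "promoters") <- sel
  out
}

#' Assemble the redefined target region
#'
#' The redefined target is the merged union HPR + OPR. When CpG site
#' positions are supplied, the census of what the OPR adds is reported both
#' ways: raw CG sites under the OPR and CG sites in OPR-minus-HPR (the bases
#' the OPR genuinely adds).
#'
#' @param hpr,opr Region tibbles on the target genome.
#' @param cpg_sites Optional tibble (`chrom`, `pos`) from
#'   [enumerate_cpg_sites()].
#' @param probe_stats Optional list with `n_probes`, `n_mapped` used to carry
#'   the probe mapping rate (filled in by [redefine_target()]).
#' @return A `target_definition` object: list with `hpr`, `opr`, `redefined`
#'   region tibbles and a `stats` list.
#' @export
assemble_target <- function(hpr, opr, cpg_sites = NULL, probe_stats = NULL) {
  g <- check_same_genome(hpr, opr)
  redefined <- union_regions(hpr, opr)
  opr_only <- subtract_regions(opr, hpr)
  stats <- list(
    hpr_length = region_total_length(hpr),
    opr_length = region_total_length(opr),
    redefined_length = region_total_length(redefined),
    opr_added_bases = region_total_length(opr_only)
  )
  if (!is.null(cpg_sites)) {
    stats$target_cg_sites <- sum(sites_in_regions(cpg_sites, redefined))
    stats$hpr_cg_sites <- sum(sites_in_regions(cpg_sites, hpr))
    stats$opr_cg_sites <- sum(sites_in_regions(cpg_sites, opr))
    stats$opr_added_cg_sites <- sum(sites_in_regions(cpg_sites, opr_only))
  }
  if (!is.null(probe_stats)) {
    stats$n_probes <- probe_stats$n_probes
    stats$n_probes_mapped <- probe_stats$n_mapped
    stats$probe_mapping_rate <- probe_stats$n_mapped / probe_stats$n_probes
  }
  structure(list(hpr = merge_regions(hpr), opr = merge_regions(opr),
                 redefined = redefined, genome = g, stats = stats),
            class = "target_definition")
}

#' One-shot target redefinition
#'
#' Runs the whole redefinition: filter alignments, build the HPR, find
#' panel-covered source promoters, build the OPR from symbol-matched target
#' promoters, and assemble the union. The probe mapping rate is the fraction
#' of panel probes with at least one passing alignment; the panel size is
#' taken from `probes` (falling back to the distinct query ids seen in
#' `aln`, which undercounts probes that produced no alignment at all).
#'
#' @param aln Alignment tibble ([read_blast8()]).
#' @param probes Probe panel on the source genome (region tibble with `name`).
#' @param source_promoters Source-genome promoter tibble
#'   ([gene_promoters()]).
#' @param target_models Target-genome `gene_models`.
#' @param params [pipeline_params()].
#' @param chrom_lengths Target chromosome lengths (optional, for clipping).
#' @param cpg_sites Optional target CpG positions for census stats.
#' @param mode Alignment selection mode, see [filter_alignments()].
#' @return A `target_definition` (see [assemble_target()]) with additional
#'   elements `passing`, `covered_symbols`.
#' @export
redefine_target <- function(aln, probes = NULL, source_promoters = NULL,
                            target_models = NULL,
                            params = pipeline_params(),
                            chrom_lengths = NULL, cpg_sites = NULL,
                            mode = "best") {
  passing <- filter_alignments(aln, params, mode = mode)
  hpr <- build_hpr(passing)
  n_probes <- if (!is.null(probes) && nrow(probes) > 0) {
    nrow(probes)
  } else {
    dplyr::n_distinct(aln$query_id)
  }
  probe_stats <- list(n_probes = n_probes,
                      n_mapped = dplyr::n_distinct(passing$query_id))
  covered <- character()
  opr <- empty_regions()
  if (!is.null(source_promoters) && !is.null(probes) &&
      !is.null(target_models)) {
    covered <- covered_gene_symbols(source_promoters, probes,
                                    min_overlap = params$opr_min_overlap)
    opr <- build_opr(covered, target_models,
                     upstream = params$promoter_upstream,
                     chrom_lengths = chrom_lengths)
  }
  td <- assemble_target(hpr, opr, cpg_sites = cpg_sites,
                        probe_stats = probe_stats)
  td$passing <- passing
  td$covered_symbols <- covered
  td
}

#' @export
print.target_definition <- function(x, ...) {
  s <- x$stats
  cat("<target_definition>\n")
  cat(sprintf("  HPR       %10.0f bp (%d intervals)\n", s$hpr_length,
              nrow(x$hpr)))
  cat(sprintf("  OPR       %10.0f bp (%d intervals; adds %.0f bp)\n",
              s$opr_length, nrow(x$opr), s$opr_added_bases))
  cat(sprintf("  redefined %10.0f bp (%d intervals)\n", s$redefined_length,
              nrow(x$redefined)))
  if (!is.null(s$probe_mapping_rate)) {
    cat(sprintf("  probe mapping rate %.1f%% (%d / %d probes)\n",
                100 * s$probe_mapping_rate, s$n_probes_mapped, s$n_probes))
  }
  if (!is.null(s$target_cg_sites)) {
    cat(sprintf("  CG sites: %d in target (OPR adds %d)\n",
                s$target_cg_sites, s$opr_added_cg_sites))
  }
  invisible(x)
}
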