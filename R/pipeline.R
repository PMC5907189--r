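#' Run the full target-redefinition and methylome pipeline
#'
#' End-to-end driver over files: island detection on the target genome,
#' shore/shelf derivation, region taxonomy from the target annotation,
#' alignment filtering into the HPR, orthologous-promoter matching into the
#' OPR, assembly of the redefined target, CpG census (optionally against the
#' source probe panel as reference), and — when a cytosine report is
#' supplied — the methylome summary. All randomness-free; `seed` is only
#' echoed into output headers so a caller's pipeline runs are
#' self-describing. Outputs are plain BED/TSV plus a JSON run summary, and
#' repeated runs with the same inputs are byte-identical.
#'
#' @param fasta Target genome FASTA path.
#' @param target_gtf Target annotation (GTF) path.
#' @param blast8 Probe-alignment file (blast8) path.
#' @param probes_bed Probe panel BED (source genome) path.
#' @param source_gtf Source annotation (GTF) path; with `probes_bed`,
#'   enables the OPR.
#' @param cx_report Optional Bismark-style cytosine report path.
#' @param reads_bed Optional de-duplicated read intervals (BED) path.
#' @param out_dir Output directory (created; existing files are only
#'   overwritten with `force = TRUE`).
#' @param params [pipeline_params()].
#' @param cgi_params [cgi_params()].
#' @param cgi_bed Optional precomputed island BED; when given the detector
#'   is skipped and these islands are used for the taxonomy.
#' @param seed Integer echoed into output headers (the analysis itself is
#'   deterministic).
#' @param force Overwrite existing outputs.
#' @return (Invisibly) a list with the main in-memory results: `cgis`,
#'   `region_map`, `target` (a `target_definition`), `census`, `summary`
#'   (a `methylome_summary` or `NULL`) and `files`.
#' @export
run_pipeline <- function(fasta, target_gtf, blast8, probes_bed = NULL,
                         source_gtf = NULL, cx_report = NULL,
                         reads_bed = NULL, out_dir = "methlift_out",
                         params = pipeline_params(),
                         cgi_params = methlift::cgi_params(),
                         cgi_bed = NULL, seed = NULL, force = FALSE) {
  inputs <- c(fasta = fasta, target_gtf = target_gtf, blast8 = blast8,
              probes_bed = probes_bed, source_gtf = source_gtf,
              cx_report = cx_report, reads_bed = reads_bed,
              cgi_bed = cgi_bed)
  missing <- inputs[!file.exists(inputs)]
  if (length(missing) > 0) {
    abort(paste0("missing input file(s): ",
                 paste(paste0(names(missing), "=", missing), collapse = ", ")))
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  meta <- c(paste0("seed=", if (is.null(seed)) "NA" else seed),
            paste0("identity>=", params$hpr_min_identity,
                   " evalue<=", params$hpr_max_evalue,
                   " opr_overlap>", params$opr_min_overlap,
                   " min_depth=", params$min_call_depth))
  out <- function(name) {
    path <- file.path(out_dir, name)
    if (file.exists(path) && !force) {
      abort(paste0("output exists (use force = TRUE to overwrite): ", path))
    }
    path
  }
  stage <- function(name, expr) {
    t0 <- Sys.time()
    res <- withCallingHandlers(
      expr,
      error = function(e) {
        abort(paste0("pipeline stage '", name, "' failed: ",
                     conditionMessage(e)))
      }
    )
    message(sprintf("[methlift] %-10s %6.1fs", name,
                    as.numeric(difftime(Sys.time(), t0, units = "secs"))))
    res
  }

  genome <- stage("load", read_genome_fasta(fasta))
  cl <- chrom_lengths(genome)
  cpg_sites <- stage("cpg", enumerate_cpg_sites(genome))

  cgis <- stage("cgi", {
    if (!is.null(cgi_bed)) read_bed(cgi_bed) else find_cgis(genome, cgi_params)
  })
  ss <- stage("flanks", derive_shores_shelves(
    cgis, cl, shore_width = params$shore_width,
    shelf_width = params$shelf_width))

  target_models <- stage("annot", read_gtf(target_gtf))
  promoters <- gene_promoters(target_models,
                              upstream = params$promoter_upstream,
                              chrom_lengths = cl)
  region_map <- stage("regions", build_region_map(
    cgis, ss$shores, ss$shelves, promoters, target_models, cl))

  aln <- stage("align", read_blast8(blast8))
  probes <- if (!is.null(probes_bed)) read_bed(probes_bed) else NULL
  source_promoters <- NULL
  if (!is.null(source_gtf)) {
    source_models <- stage("annot-src", read_gtf(source_gtf))
    source_promoters <- gene_promoters(source_models,
                                       upstream = params$promoter_upstream)
  }
  target <- stage("target", redefine_target(
    aln, probes = probes, source_promoters = source_promoters,
    target_models = target_models, params = params, chrom_lengths = cl,
    cpg_sites = cpg_sites))

  reference <- if (!is.null(probes)) {
    cg_census(probes, region_map, cpg_sites)
  } else {
    NULL
  }
  census <- stage("census", cg_census(target$redefined, region_map,
                                      cpg_sites, reference = reference))

  summary <- NULL
  if (!is.null(cx_report)) {
    cx <- stage("cx", read_cytosine_report(cx_report))
    reads <- if (!is.null(reads_bed)) read_bed(reads_bed) else NULL
    summary <- stage("summarize", summarize_methylome(
      cx, cpg_sites, target$redefined, region_map, reads = reads,
      params = params))
  }

  files <- list()
  wb <- function(x, name) {
    path <- out(name)
    write_bed(x, path)
    files[[name]] <<- path
  }
  wb(cgis, "cgi.bed")
  wb(ss$shores, "shores.bed")
  wb(ss$shelves, "shelves.bed")
  wb(promoters[, c("chrom", "start", "end", "gene")] %>%
       rename(name = "gene"), "promoters.bed")
  wb(target$hpr, "hpr.bed")
  wb(target$opr, "opr.bed")
  wb(target$redefined, "redefined_target.bed")
  write_tsv_with_header(census, out("census.tsv"), meta)
  files[["census.tsv"]] <- file.path(out_dir, "census.tsv")
  if (!is.null(summary)) {
    write_tsv_with_header(summary$class_summary,
                          out("class_methylation.tsv"), meta)
    write_tsv_with_header(summary$depth$coverage, out("depth_profile.tsv"),
                          meta)
    files[["class_methylation.tsv"]] <-
      file.path(out_dir, "class_methylation.tsv")
    files[["depth_profile.tsv"]] <- file.path(out_dir, "depth_profile.tsv")
  }
  run_summary <- c(
    list(tool = "methlift",
         version = as.character(packageVersion("methlift")),
         seed = if (is.null(seed)) NA else seed,
         params = unclass(params)[c("hpr_min_identity", "hpr_max_evalue",
                                    "opr_min_overlap", "promoter_upstream",
                                    "shore_width", "shelf_width",
                                    "min_call_depth")]),
    target$stats,
    list(on_target_read_rate = if (is.null(summary)) NA else
      summary$on_target_rate,
      mean_depth = if (is.null(summary)) NA else summary$depth$mean_depth)
  )
  json_path <- out("run_summary.json")
  jsonlite::write_json(run_summary, json_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, na = "null")
  files[["run_summary.json"]] <- json_path

  invisible(list(cgis = cgis, region_map = region_map, target = target,
                 census = census, summary = summary, files = files))
}
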