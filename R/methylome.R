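#' Strand-merge cytosine calls into CpG-site calls
#'
#' Combines the plus-strand C at position `p` and the minus-strand C at
#' `p + 1` (the complementary G) of every enumerated CpG site into one
#' strand-combined call: counts add, missing strands contribute zero, and
#' total methylated/unmethylated counts are conserved. All enumerated sites
#' are returned, with depth 0 where neither strand was observed, so that
#' downstream depth statistics can count uncovered sites. CpG-context records
#' at positions not explicable by any enumerated site (an annotation/genome
#' mismatch signal) trigger a warning and are excluded; they are returned in
#' the `excluded` attribute.
#'
#' @param cx Cytosine-report tibble from [read_cytosine_report()] (only
#'   `is_cpg` rows are used).
#' @param cpg_sites Tibble (`chrom`, `pos`) from [enumerate_cpg_sites()].
#' @return Tibble with one row per CpG site: `chrom`, `pos`, `meth`,
#'   `unmeth`, `depth`, `level` (`NA` at depth 0).
#' @export
merge_strands <- function(cx, cpg_sites) {
  cpg <- filter(cx, .data$is_cpg)
  sites <- cpg_sites %>% select("chrom", "pos") %>% distinct()
  site_pos <- mutate(sites, .site = .data$pos)
  plus <- cpg %>%
    filter(.data$strand == "+") %>%
    mutate(.site = .data$pos)
  minus <- cpg %>%
    filter(.data$strand == "-") %>%
    mutate(.site = .data$pos - 1)
  obs <- bind_rows(plus, minus) %>%
    inner_join(site_pos %>% select("chrom", ".site") %>%
                 mutate(.known = TRUE),
               by = c("chrom", ".site"))
  n_excluded <- nrow(plus) + nrow(minus) - nrow(obs)
  excluded <- NULL
  if (n_excluded > 0) {
    excluded <- bind_rows(plus, minus) %>%
      anti_join(site_pos %>% select("chrom", ".site"),
                by = c("chrom", ".site")) %>%
      select(-".site")
    warn(paste0(n_excluded, " CpG-context record(s) do not match any ",
                "enumerated CpG site and were excluded (annotation/genome ",
                "mismatch?)"))
  }
  sums <- obs %>%
    group_by(chrom = .data$chrom, pos = .data$.site) %>%
    summarise(meth = sum(.data$meth), unmeth = sum(.data$unmeth),
              .groups = "drop")
  out <- sites %>%
    left_join(sums, by = c("chrom", "pos")) %>%
    mutate(meth = dplyr::coalesce(.data$meth, 0),
           unmeth = dplyr::coalesce(.data$unmeth, 0),
           depth = .data$meth + .data$unmeth,
           level = ifelse(.data$depth > 0, .data$meth / .data$depth,
                          NA_real_)) %>%
    arrange(.data$chrom, .data$pos)
  attr(out, "excluded") <- excluded
  out
}

#' Restrict CpG-site calls to a target region
#'
#' A site is on-target when its C position lies inside the (half-open)
#' target; a site exactly at a target end coordinate is off-target.
#'
#' @param calls Site-call tibble from [merge_strands()].
#' @param target Region tibble.
#' @return The on-target subset of `calls`.
#' @export
on_target_sites <- function(calls, target) {
  calls[sites_in_regions(calls, target), ]
}

#' On-target read rate
#'
#' Fraction of (de-duplicated) read intervals overlapping the target by at
#' least `min_overlap` bases (default 1 bp). Returns `NA` for an empty read
#' set.
#'
#' @param reads Region tibble of read intervals (BED).
#' @param target Region tibble.
#' @param min_overlap Minimum overlapping bases for a read to count.
#' @return Fraction in `[0, 1]`, or `NA`.
#' @export
on_target_read_rate <- function(reads, target, min_overlap = 1) {
  reads <- as_regions(reads, genome = region_genome(reads))
  if (nrow(reads) == 0) return(NA_real_)
  target <- merge_regions(target)
  if (nrow(target) == 0) return(0)
  hits <- GenomicRanges::findOverlaps(regions_to_gr(reads),
                                      regions_to_gr(target),
                                      minoverlap = as.integer(min_overlap))
  length(unique(S4Vectors::queryHits(hits))) / nrow(reads)
}

#' Depth statistics over target CpG sites
#'
#' Mean strand-merged calling depth over the target CpG sites, and cumulative
#' coverage: for each threshold `d`, the percentage of target CpG sites with
#' depth >= `d`. Sites absent from the calls count as depth 0, so coverage is
#' non-increasing in `d` by construction.
#'
#' @param calls Site-call tibble from [merge_strands()] (any superset of the
#'   target sites).
#' @param target Region tibble defining the target.
#' @param thresholds Ascending depth cut-offs (default 1,5,10,20,30,40).
#' @return A `depth_profile` object: list with `n_sites`, `mean_depth` and a
#'   `coverage` tibble (`depth`, `pct_sites`).
#' @export
depth_profile <- function(calls, target, thresholds = c(1, 5, 10, 20, 30, 40)) {
  stopifnot(all(diff(thresholds) > 0))
  on_t <- on_target_sites(calls, target)
  if (nrow(on_t) == 0) {
    cov <- tibble(depth = thresholds, pct_sites = NA_real_)
    out <- list(n_sites = 0L, mean_depth = NA_real_, coverage = cov)
    class(out) <- "depth_profile"
    return(out)
  }
  cov <- tibble(
    depth = thresholds,
    pct_sites = vapply(thresholds,
                       function(d) 100 * mean(on_t$depth >= d), 0)
  )
  out <- list(n_sites = nrow(on_t), mean_depth = mean(on_t$depth),
              coverage = cov)
  class(out) <- "depth_profile"
  out
}

#' @export
print.depth_profile <- function(x, ...) {
  cat(sprintf("<depth_profile> %d target CpG sites, mean depth %.1fx\n",
              x$n_sites, x$mean_depth))
  print(x$coverage)
  invisible(x)
}

#' Per-region-class methylation levels
#'
#' For each class, over the CpG sites lying in the class-target intersection
#' with strand-merged depth >= `min_depth`: the unweighted mean of per-site
#' methylation levels, the sample standard deviation (n - 1 denominator) and
#' a normal-approximation 95% interval (`mean ± 1.96 sd / sqrt(n)`).
#' Per-site averaging is the default because per-class averages are reported
#' over sites; `weighted = TRUE` instead pools counts
#' (`sum(meth) / sum(depth)`) for comparison.
#'
#' @param calls Site-call tibble from [merge_strands()].
#' @param classes Named list of region tibbles.
#' @param target Optional region tibble; when given, each class is first
#'   intersected with it.
#' @param min_depth Minimum depth for a site to qualify (default 5).
#' @param weighted Pool counts instead of averaging per-site levels.
#' @return Tibble of class `class_methylation`: `region_class`, `n_sites`,
#'   `mean_level`, `sd_level`, `ci_lower`, `ci_upper`.
#' @export
class_methylation <- function(calls, classes, target = NULL, min_depth = 5,
                              weighted = FALSE) {
  stopifnot(is.list(classes), !is.null(names(classes)))
  rows <- purrr::imap(classes, function(cls, nm) {
    cls <- as_regions(cls, genome = region_genome(cls))
    set <- if (is.null(target)) cls else intersect_regions(cls, target)
    sub <- calls[sites_in_regions(calls, set), ]
    sub <- filter(sub, .data$depth >= min_depth)
    n <- nrow(sub)
    if (n == 0) {
      return(tibble(region_class = nm, n_sites = 0L, mean_level = NA_real_,
                    sd_level = NA_real_, ci_lower = NA_real_,
                    ci_upper = NA_real_))
    }
    m <- if (weighted) sum(sub$meth) / sum(sub$depth) else mean(sub$level)
    s <- if (n > 1) sd(sub$level) else NA_real_
    half <- if (n > 1) 1.96 * s / sqrt(n) else NA_real_
    tibble(region_class = nm, n_sites = n, mean_level = m, sd_level = s,
           ci_lower = m - half, ci_upper = m + half)
  })
  out <- bind_rows(rows)
  class(out) <- c("class_methylation", class(out))
  out
}

#' Summarise a methylome against a capture target
#'
#' End-to-end summary of a bisulfite cytosine report: strand-merged CpG-site
#' calls, on-target depth statistics with cumulative coverage, per-class
#' methylation levels, and (when read intervals are supplied) the on-target
#' read rate.
#'
#' @param cx Cytosine-report tibble ([read_cytosine_report()]).
#' @param genome Target genome ([read_genome_fasta()]) or a precomputed CpG
#'   site tibble.
#' @param target Region tibble — the redefined capture target.
#' @param classes Named list of region tibbles ([build_region_map()]).
#' @param reads Optional de-duplicated read intervals (region tibble).
#' @param params [pipeline_params()] (supplies `min_call_depth` and
#'   `depth_thresholds`).
#' @param weighted See [class_methylation()].
#' @return A `methylome_summary` object: list with `sites` (all site calls),
#'   `class_summary`, `depth`, `on_target_rate`, `params`.
#' @export
summarize_methylome <- function(cx, genome, target, classes, reads = NULL,
                                params = pipeline_params(),
                                weighted = FALSE) {
  cpg_sites <- if (is.data.frame(genome)) genome else enumerate_cpg_sites(genome)
  calls <- merge_strands(cx, cpg_sites)
  depth <- depth_profile(calls, target, thresholds = params$depth_thresholds)
  cls <- class_methylation(calls, classes, target = target,
                           min_depth = params$min_call_depth,
                           weighted = weighted)
  rate <- if (is.null(reads)) NA_real_ else on_target_read_rate(reads, target)
  structure(list(sites = calls, class_summary = cls, depth = depth,
                 on_target_rate = rate, params = params),
            class = "methylome_summary")
}

#' @export
print.methylome_summary <- function(x, ...) {
  cat("<methylome_summary>\n")
  cat(sprintf("  target CpG sites: %d, mean depth %.1fx\n",
              x$depth$n_sites, x$depth$mean_depth))
  at5 <- x$depth$coverage$pct_sites[x$depth$coverage$depth == 5]
  if (length(at5) == 1 && !is.na(at5)) {
    cat(sprintf("  sites at >= 5x: %.1f%%\n", at5))
  }
  if (!is.na(x$on_target_rate)) {
    cat(sprintf("  on-target read rate: %.1f%%\n", 100 * x$on_target_rate))
  }
  print(as_tibble(x$class_summary))
  invisible(x)
}
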