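#' Construct a region tibble
#'
#' Regions are plain tibbles with columns `chrom` (character), `start`, `end`
#' (0-based half-open, in bp) and optionally `name`, `score`, `strand`.
#' `as_regions()` validates an existing data frame; `regions()` builds one from
#' vectors. A `genome` identifier can be attached; binary set operations refuse
#' to combine regions from different genomes.
#'
#' Strand, when present, is carried along but ignored by all set algebra:
#' capture and methylation coverage are strand-agnostic at region level, and
#' only promoter construction interprets strand.
#'
#' @param chrom Character vector of sequence names.
#' @param start,end Numeric vectors, 0-based half-open.
#' @param ... Further columns (e.g. `name`, `score`, `strand`).
#' @param genome Optional genome/assembly identifier (string).
#' @return A tibble of validated regions (attribute `"genome"` set when given).
#' @examples
#' regions("chr1", c(0, 50), c(10, 80))
#' @export
regions <- function(chrom, start, end, ..., genome = NULL) {
  as_regions(tibble(chrom = as.character(chrom),
                    start = as.numeric(start),
                    end = as.numeric(end), ...),
             genome = genome)
}

#' @param x A data frame with at least `chrom`, `start`, `end`.
#' @rdname regions
#' @export
as_regions <- function(x, genome = NULL) {
  x <- as_tibble(x)
  req <- c("chrom", "start", "end")
  missing_cols <- setdiff(req, names(x))
  if (length(missing_cols) > 0) {
    abort(paste0("region table lacks column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  x$chrom <- as.character(x$chrom)
  x$start <- as.numeric(x$start)
  x$end <- as.numeric(x$end)
  bad <- which(is.na(x$chrom) | x$chrom == "" |
                 is.na(x$start) | is.na(x$end) |
                 x$start < 0 | x$start >= x$end)
  if (length(bad) > 0) {
    abort(paste0("invalid interval(s) at row(s) ",
                 paste(head(bad, 5), collapse = ", "),
                 if (length(bad) > 5) " ..." else "",
                 ": need non-empty chrom and 0 <= start < end"))
  }
  if (!is.null(genome)) attr(x, "genome") <- genome
  x
}

#' @rdname regions
#' @export
region_genome <- function(x) attr(x, "genome", exact = TRUE)

empty_regions <- function(genome = NULL) {
  as_regions(tibble(chrom = character(), start = numeric(), end = numeric()),
             genome = genome)
}

check_same_genome <- function(a, b) {
  ga <- region_genome(a)
  gb <- region_genome(b)
  if (!is.null(ga) && !is.null(gb) && !identical(ga, gb)) {
    abort(paste0("genome mismatch: '", ga, "' vs '", gb, "'"))
  }
  if (!is.null(ga)) ga else gb
}

# tibble (0-based half-open) <-> GRanges (1-based closed); strand dropped.
regions_to_gr <- function(x) {
  GenomicRanges::GRanges(
    seqnames = x$chrom,
    ranges = IRanges::IRanges(start = x$start + 1, end = x$end)
  )
}

# per-chromosome IRanges representation: cheap set algebra without the
# seqinfo bookkeeping of full GRanges objects
regions_to_irl <- function(x) {
  idx <- split(seq_len(nrow(x)), x$chrom)
  lapply(idx, function(i) IRanges::IRanges(start = x$start[i] + 1,
                                           end = x$end[i]))
}

irl_to_regions <- function(irl, genome = NULL) {
  irl <- irl[lengths(irl) > 0]
  if (length(irl) == 0) return(empty_regions(genome))
  irl <- irl[order(names(irl))]
  n <- lengths(irl)
  out <- tibble::new_tibble(list(
    chrom = rep(names(irl), n),
    start = as.numeric(unlist(lapply(irl, IRanges::start),
                              use.names = FALSE)) - 1,
    end = as.numeric(unlist(lapply(irl, IRanges::end), use.names = FALSE))
  ), nrow = sum(n))
  if (!is.null(genome)) attr(out, "genome") <- genome
  out
}

irl_binary_op <- function(a, b, fun) {
  ia <- regions_to_irl(a)
  ib <- regions_to_irl(b)
  chroms <- union(names(ia), names(ib))
  none <- IRanges::IRanges()
  out <- lapply(chroms, function(ch) {
    fun(IRanges::reduce(ia[[ch]] %||% none),
        IRanges::reduce(ib[[ch]] %||% none))
  })
  names(out) <- chroms
  out
}

#' Region set algebra
#'
#' `merge_regions()` normalises a set: intervals are sorted by
#' `(chrom, start)` and overlapping or book-ended (end == next start)
#' intervals are coalesced, so covered bases are unchanged.
#' `intersect_regions()`, `subtract_regions()` and `union_regions()` operate on
#' covered bases and return normalised sets. Extra columns (name/score/strand)
#' are dropped because coalesced output intervals have no unique provenance.
#'
#' @param x,a,b Region tibbles (see [regions()]).
#' @return A normalised region tibble.
#' @examples
#' merge_regions(regions("chr1", c(0, 5), c(10, 20)))
#' intersect_regions(regions("chr1", 0, 10), regions("chr1", 5, 20))
#' @export
merge_regions <- function(x) {
  g <- region_genome(x)
  x <- as_regions(x, genome = g)
  irl_to_regions(lapply(regions_to_irl(x), IRanges::reduce), genome = g)
}

#' @rdname merge_regions
#' @export
intersect_regions <- function(a, b) {
  g <- check_same_genome(a, b)
  a <- as_regions(a); b <- as_regions(b)
  irl_to_regions(irl_binary_op(a, b, IRanges::intersect), genome = g)
}

#' @rdname merge_regions
#' @export
subtract_regions <- function(a, b) {
  g <- check_same_genome(a, b)
  a <- as_regions(a); b <- as_regions(b)
  irl_to_regions(irl_binary_op(a, b, IRanges::setdiff), genome = g)
}

#' @rdname merge_regions
#' @export
union_regions <- function(a, b) {
  g <- check_same_genome(a, b)
  merge_regions(as_regions(bind_rows(as_regions(a)[, c("chrom", "start", "end")],
                                     as_regions(b)[, c("chrom", "start", "end")]),
                           genome = g))
}

#' Total covered bases of a region set
#'
#' The set is normalised first, so overlapping input intervals are not
#' double-counted.
#'
#' @param x A region tibble.
#' @return Total covered length in bp (numeric scalar).
#' @export
region_total_length <- function(x) {
  m <- merge_regions(x)
  sum(m$end - m$start)
}

#' Fraction of each query interval covered by a region set
#'
#' For every row of `query`, returns (covered bases) / (interval length), the
#' statistic used to decide whether a promoter is covered "by more than 60%"
#' by the capture panel.
#'
#' @param query Region tibble of query intervals (one fraction per row).
#' @param set Region tibble giving the covering set.
#' @return Numeric vector in `[0, 1]`, one value per row of `query`.
#' @examples
#' overlap_fraction(regions("chr1", 0, 2000),
#'                  regions("chr1", c(500, 1500), c(1000, 1800)))
#' @export
overlap_fraction <- function(query, set) {
  query <- as_regions(query, genome = region_genome(query))
  check_same_genome(query, set)
  if (nrow(query) == 0) return(numeric(0))
  set_irl <- lapply(regions_to_irl(as_regions(set)), IRanges::reduce)
  cov <- rep(0, nrow(query))
  idx <- split(seq_len(nrow(query)), query$chrom)
  for (ch in names(idx)) {
    s_ir <- set_irl[[ch]]
    if (is.null(s_ir) || length(s_ir) == 0) next
    i <- idx[[ch]]
    q_ir <- IRanges::IRanges(query$start[i] + 1, query$end[i])
    hits <- IRanges::findOverlaps(q_ir, s_ir)
    if (length(hits) == 0) next
    qi <- S4Vectors::queryHits(hits)
    ov <- IRanges::pintersect(q_ir[qi], s_ir[S4Vectors::subjectHits(hits)])
    cov_by_hit <- rowsum(as.numeric(IRanges::width(ov)), qi)
    cov[i[as.integer(rownames(cov_by_hit))]] <- as.numeric(cov_by_hit)
  }
  cov / (query$end - query$start)
}

#' Which point positions fall inside a region set
#'
#' @param sites Tibble with columns `chrom` and `pos` (0-based positions).
#' @param set Region tibble.
#' @return Logical vector, one per row of `sites`.
#' @export
sites_in_regions <- function(sites, set) {
  stopifnot(all(c("chrom", "pos") %in% names(sites)))
  set <- as_regions(set)
  if (nrow(sites) == 0) return(logical(0))
  if (nrow(set) == 0) return(rep(FALSE, nrow(sites)))
  pgr <- GenomicRanges::GRanges(sites$chrom,
                                IRanges::IRanges(sites$pos + 1, width = 1))
  GenomicRanges::countOverlaps(pgr, regions_to_gr(set)) > 0
}
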