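#' CpG-island detector parameters
#'
#' The detector scans dinucleotides with a running score that gains
#' `cg_reward` at every CG, loses `non_cg_penalty` otherwise, and is clamped
#' at zero; maximal positive-score segments whose peak reaches
#' `min_peak_score` are reported as islands. The defaults (+17 / -1 / 17)
#' reproduce the published scoring scheme of the classic EMBOSS running-score
#' island predictor run with default parameters.
#'
#' @param cg_reward Score added at each CG dinucleotide (> 0; default 17).
#' @param non_cg_penalty Score subtracted per non-CG dinucleotide (> 0;
#'   default 1).
#' @param min_peak_score Minimum segment peak score to report (> 0;
#'   default 17).
#' @return A list of class `cgi_params`.
#' @export
cgi_params <- function(cg_reward = 17, non_cg_penalty = 1,
                       min_peak_score = 17) {
  stopifnot(cg_reward > 0, non_cg_penalty > 0, min_peak_score > 0)
  structure(list(cg_reward = cg_reward, non_cg_penalty = non_cg_penalty,
                 min_peak_score = min_peak_score),
            class = "cgi_params")
}

#' Predict CpG islands with a clamped running score
#'
#' For each chromosome, dinucleotides are scanned left to right with score
#' `S` starting at 0: `S += cg_reward` at a CG, else `S -= non_cg_penalty`,
#' clamped at 0. A candidate segment opens when `S` rises from 0 and closes
#' when it returns to 0 (or at the sequence end). The reported island spans
#' from the segment's first CG to the CG at which `S` attained its maximum
#' (rightmost on ties), inclusive of both bases of that CG, and is reported
#' iff the peak reaches `min_peak_score`. Islands are therefore CG-bounded,
#' non-overlapping and sorted. `N` bases never form a CG and incur the
#' ordinary penalty.
#'
#' The clamped scan is computed in closed form
#' (`y = S - min(0, cummin(S))` on the unclamped cumulative sum), which is
#' algebraically identical to the sequential recursion.
#'
#' @param genome A [Biostrings::DNAStringSet] or named character vector of
#'   sequences over `A,C,G,T,N` (case-insensitive).
#' @param params A [cgi_params()] list.
#' @return Tibble with columns `chrom`, `start`, `end` (0-based half-open),
#'   `peak_score`, `cg_count`.
#' @examples
#' find_cgis(c(chr1 = "CGCG"))
#' @export
find_cgis <- function(genome, params = cgi_params()) {
  seqs <- as_genome_seqs(genome)
  out <- purrr::imap(seqs, function(s, nm) {
    calls <- cgi_scan_one(s, params)
    if (nrow(calls) > 0) calls$chrom <- nm
    calls
  })
  res <- bind_rows(out)
  if (nrow(res) == 0) {
    return(tibble(chrom = character(), start = numeric(), end = numeric(),
                  peak_score = numeric(), cg_count = integer()))
  }
  res <- res[, c("chrom", "start", "end", "peak_score", "cg_count")]
  arrange(res, .data$chrom, .data$start)
}

cgi_scan_one <- function(seq, params) {
  empty <- tibble(start = numeric(), end = numeric(),
                  peak_score = numeric(), cg_count = integer())
  n <- nchar(seq)
  if (n < 2) return(empty)
  r <- charToRaw(chartr("acgtn", "ACGTN", seq))
  allowed <- charToRaw("ACGTN")
  if (!all(r %in% allowed)) {
    bad <- rawToChar(r[which(!(r %in% allowed))[1]])
    abort(paste0("sequence contains disallowed character '", bad,
                 "' (only A,C,G,T,N permitted)"))
  }
  is_cg <- r[-n] == charToRaw("C") & r[-1] == charToRaw("G")
  d <- ifelse(is_cg, params$cg_reward, -params$non_cg_penalty)
  S <- cumsum(d)
  y <- S - pmin(0, cummin(S))        # clamped running score
  pos <- y > 0
  if (!any(pos)) return(empty)
  runs <- rle(pos)
  gid <- rep(seq_along(runs$lengths), runs$lengths)
  dt <- data.table::data.table(i = which(pos), y = y[pos], g = gid[pos])
  data.table::setorderv(dt, c("g", "y", "i"))
  peaks <- dt[, list(peak = y[.N], peak_i = i[.N]), by = "g"]
  starts <- dt[, list(start_i = min(i)), by = "g"]
  seg <- merge(starts, peaks, by = "g")
  seg <- seg[seg$peak >= params$min_peak_score, ]
  if (nrow(seg) == 0) return(empty)
  cs <- c(0L, cumsum(is_cg))
  tibble(
    start = as.numeric(seg$start_i - 1),
    end = as.numeric(seg$peak_i + 1),
    peak_score = as.numeric(seg$peak),
    cg_count = as.integer(cs[seg$peak_i + 1] - cs[seg$start_i])
  ) %>% arrange(.data$start)
}

#' Derive CGI shores and shelves
#'
#' Shores are the two windows of width `shore_width` (default 2 kb)
#' immediately flanking each island; shelves are the two windows of width
#' `shelf_width` beyond each shore (2–4 kb from the island with defaults).
#' Windows are clipped to chromosome bounds, then precedence
#' CGI > shore > shelf is enforced by subtraction, so the three classes are
#' pairwise disjoint and inter-island flanks are counted once.
#'
#' @param cgis Region tibble of islands.
#' @param chrom_lengths Named vector of chromosome lengths (bp), or a genome
#'   accepted by [chrom_lengths()].
#' @param shore_width,shelf_width Flank widths in bp (default 2000).
#' @return List with region tibbles `shores` and `shelves`.
#' @export
derive_shores_shelves <- function(cgis, chrom_lengths,
                                  shore_width = 2000, shelf_width = 2000) {
  cl <- chrom_lengths(chrom_lengths)
  cgis <- merge_regions(cgis)
  if (nrow(cgis) == 0) {
    return(list(shores = empty_regions(), shelves = empty_regions()))
  }
  if (!all(cgis$chrom %in% names(cl))) {
    abort("island chromosome absent from chromosome lengths")
  }
  lim <- cl[cgis$chrom]
  if (any(cgis$end > lim)) {
    abort("island extends beyond chromosome length")
  }
  clip <- function(s, e, chrom) {
    lim <- cl[chrom]
    s2 <- pmax(0, s); e2 <- pmin(lim, e)
    keep <- s2 < e2
    as_regions(tibble(chrom = chrom[keep], start = s2[keep], end = e2[keep]))
  }
  shores_raw <- bind_rows(
    clip(cgis$start - shore_width, cgis$start, cgis$chrom),
    clip(cgis$end, cgis$end + shore_width, cgis$chrom)
  )
  shelves_raw <- bind_rows(
    clip(cgis$start - shore_width - shelf_width, cgis$start - shore_width,
         cgis$chrom),
    clip(cgis$end + shore_width, cgis$end + shore_width + shelf_width,
         cgis$chrom)
  )
  shores_raw <- merge_regions(as_regions(shores_raw))
  shelves_raw <- merge_regions(as_regions(shelves_raw))
  shores <- subtract_regions(shores_raw, cgis)
  shelves <- subtract_regions(subtract_regions(shelves_raw, cgis), shores_raw)
  list(shores = shores, shelves = shelves)
}
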