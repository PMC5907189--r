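# Independent brute-force oracles. These deliberately avoid the package's
# GenomicRanges-based code paths: set algebra is checked against per-base
# boolean arrays, the island detector against a plain positional walk, and
# CpG enumeration against a regex scan.

oracle_bases <- function(set, lens) {
  out <- lapply(lens, function(L) logical(L))
  for (i in seq_len(nrow(set))) {
    ch <- set$chrom[i]
    out[[ch]][(set$start[i] + 1):set$end[i]] <- TRUE
  }
  out
}

bool_to_regions <- function(bases) {
  rows <- lapply(names(bases), function(ch) {
    v <- bases[[ch]]
    if (!any(v)) return(NULL)
    r <- rle(v)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    data.frame(chrom = ch, start = starts[r$values], end = ends[r$values])
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric()))
  }
  out[order(out$chrom, out$start), , drop = FALSE]
}

oracle_op <- function(a, b, lens, op) {
  ba <- oracle_bases(a, lens)
  bb <- oracle_bases(b, lens)
  res <- lapply(names(lens), function(ch) {
    switch(op,
           intersect = ba[[ch]] & bb[[ch]],
           subtract = ba[[ch]] & !bb[[ch]],
           union = ba[[ch]] | bb[[ch]])
  })
  names(res) <- names(lens)
  bool_to_regions(res)
}

random_region_set <- function(n, lens, max_width = 500) {
  ch <- sample(names(lens), n, replace = TRUE)
  L <- lens[ch]
  w <- sample(max_width, n, replace = TRUE)
  s <- floor(runif(n) * pmax(1, L - w))
  data.frame(chrom = ch, start = s, end = pmin(L, s + w),
             row.names = NULL, stringsAsFactors = FALSE)
}

region_key <- function(df) {
  paste(df$chrom, as.numeric(df$start), as.numeric(df$end), sep = ":")
}

expect_same_bases <- function(x, expected_df) {
  got <- merge_regions(x)
  same <- identical(region_key(got), region_key(expected_df))
  if (!same) {
    # slow path only on failure, for a readable diff
    expect_equal(as.data.frame(got)[, c("chrom", "start", "end")],
                 as.data.frame(expected_df), ignore_attr = TRUE)
  } else {
    expect_true(same)
  }
}

# positional-walk reference implementation of the clamped running-score
# island caller (open when score rises from 0, close at 0 / sequence end,
# island = first CG .. rightmost score-maximum CG, report iff peak >= min)
cgi_oracle <- function(seq, cg_reward = 17, non_cg_penalty = 1,
                       min_peak_score = 17) {
  s <- toupper(seq)
  n <- nchar(s)
  res <- list()
  if (n >= 2) {
    score <- 0
    open <- FALSE
    first_i <- NA
    peak <- 0
    peak_i <- NA
    for (i in seq_len(n - 1)) {
      di <- substr(s, i, i + 1)
      score <- score + if (di == "CG") cg_reward else -non_cg_penalty
      if (score < 0) score <- 0
      if (!open && score > 0) {
        open <- TRUE
        first_i <- i
        peak <- score
        peak_i <- i
      } else if (open) {
        if (score >= peak && score > 0) {
          peak <- score
          peak_i <- i
        }
        if (score == 0) {
          if (peak >= min_peak_score) {
            res[[length(res) + 1]] <- c(first_i - 1, peak_i + 1, peak)
          }
          open <- FALSE
        }
      }
    }
    if (open && peak >= min_peak_score) {
      res[[length(res) + 1]] <- c(first_i - 1, peak_i + 1, peak)
    }
  }
  if (length(res) == 0) {
    return(data.frame(start = numeric(), end = numeric(),
                      peak_score = numeric()))
  }
  m <- do.call(rbind, res)
  data.frame(start = m[, 1], end = m[, 2], peak_score = m[, 3])
}

random_dna <- function(n, gc = 0.45) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

cpg_scan_oracle <- function(seq) {
  m <- gregexpr("(?=CG)", toupper(seq), perl = TRUE)[[1]]
  if (m[1] == -1) return(numeric(0))
  as.numeric(m) - 1
}
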