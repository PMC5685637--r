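# From a shape-difference profile to filtered TSS candidate peaks and
# ranked transcript contigs for one test sample.

#' Local maxima of the shape-difference profile
#'
#' A candidate peak is a run of equal RMSD values whose flanking values are
#' both strictly lower; the run collapses to its middle window (5'-of-center
#' for even runs). Runs touching the first or last window of a sequence are
#' never peaks (one-sided evidence), and peaks in windows overlapping masked
#' positions are dropped.
#'
#' @param diff a [shape_difference()] result.
#' @return a `candidate_peaks` data frame: `seqname`, `index` (window
#'   index), `pos` (anchor position), `rmsd`.
#' @export
find_peaks <- function(diff) {
  out <- list()
  for (sq in names(diff$data)) {
    d <- diff$data[[sq]]
    r <- d$rmsd
    if (length(r) < 3L) next
    rl <- rle(r)
    k <- length(rl$values)
    if (k < 3L) next
    ends <- cumsum(rl$lengths)
    starts <- ends - rl$lengths + 1L
    runs <- 2:(k - 1L)
    is_peak <- rl$values[runs] > rl$values[runs - 1L] &
      rl$values[runs] > rl$values[runs + 1L]
    runs <- runs[is_peak]
    if (!length(runs)) next
    mid <- as.integer(floor((starts[runs] + ends[runs]) / 2))
    keep <- !d$masked[mid]
    mid <- mid[keep]
    if (!length(mid)) next
    out[[sq]] <- data.frame(
      seqname = sq, index = mid, pos = d$anchors[mid], rmsd = r[mid],
      stringsAsFactors = FALSE
    )
  }
  res <- if (length(out)) do.call(rbind, out) else data.frame(
    seqname = character(), index = integer(), pos = integer(),
    rmsd = numeric(), stringsAsFactors = FALSE
  )
  rownames(res) <- NULL
  class(res) <- c("candidate_peaks", "data.frame")
  res
}

# Mean of v over [s, e] (clamped); 0 for an empty range.
range_mean <- function(cs, s, e, n) {
  s <- max(1L, s)
  e <- min(n, e)
  if (e < s) return(0)
  (cs[e] - if (s > 1L) cs[s - 1L] else 0) / (e - s + 1L)
}

#' Classify candidate peaks as TES-like or TSS-like
#'
#' A transcription end site produces the mirror image of a start site: more
#' coverage in the flank immediately 5' of the peak (in the direction of
#' transcription) than in the 3' flank. Peaks with `5'-mean > 3'-mean` of
#' the test sample's coverage are TES-like and removed downstream. The
#' orientation comes from the annotated gene overlapping the peak; peaks
#' overlapping no gene (or genes on both strands) are kept in the
#' orientation in which they are TSS-like and flagged `strand-ambiguous`.
#'
#' @param peaks a `candidate_peaks` data frame.
#' @param test the test sample's (smoothed) track.
#' @param annot a `gene_annotation` data frame.
#' @param flank flank width in nt (default 150, the analysis window).
#' @return `peaks` with added columns `strand`, `strand_source`
#'   (`"gene"`/`"inferred"`), `host_gene`, `tes_like`, `left_mean`,
#'   `right_mean`.
#' @export
classify_tes <- function(peaks, test, annot, flank = 150L) {
  n_pk <- nrow(peaks)
  strand <- character(n_pk)
  source <- character(n_pk)
  host <- rep(NA_character_, n_pk)
  tes <- logical(n_pk)
  lm <- numeric(n_pk)
  rm_ <- numeric(n_pk)
  cs_by_seq <- list()
  for (i in seq_len(n_pk)) {
    sq <- peaks$seqname[i]
    p <- peaks$pos[i]
    if (is.null(cs_by_seq[[sq]])) cs_by_seq[[sq]] <- cumsum(test$values[[sq]])
    cs <- cs_by_seq[[sq]]
    n <- length(cs)
    lm[i] <- range_mean(cs, p - flank, p - 1L, n)
    rm_[i] <- range_mean(cs, p + 1L, p + flank, n)
    g <- which(annot$seqname == sq & annot$start <= p & annot$end >= p)
    gs <- unique(annot$strand[g])
    if (length(gs) == 1L) {
      strand[i] <- gs
      source[i] <- "gene"
      host[i] <- annot$gene_id[g[1]]
      tes[i] <- if (gs == "+") lm[i] > rm_[i] else rm_[i] > lm[i]
    } else {
      # No host gene (or conflicting strands): keep the peak in the
      # orientation in which it looks like a start site.
      strand[i] <- if (lm[i] > rm_[i]) "-" else "+"
      source[i] <- "inferred"
      tes[i] <- FALSE
    }
  }
  peaks$strand <- strand
  peaks$strand_source <- source
  peaks$host_gene <- host
  peaks$tes_like <- tes
  peaks$left_mean <- lm
  peaks$right_mean <- rm_
  peaks
}

#' Percentile thresholds for peak filtering
#'
#' Pools, computed genome-wide: the RMSD of every non-masked window (its
#' median is the noise floor); the per-position sum of control + test
#' smoothed coverage over unmasked positions (median and 95th percentile
#' bound the informative expression band); and the per-position test - ctrl
#' difference (its 90th percentile is the contig-defining threshold).
#' Percentiles use linear interpolation ([pctile()]).
#'
#' @param ctrl,test smoothed, depth-normalized tracks.
#' @param diff the [shape_difference()] of the pair.
#' @param rmsd_p,cov_band,diff_p percentile probabilities (defaults 0.5,
#'   c(0.5, 0.95), 0.9).
#' @return a `threshold_set` list: `rmsd_median`, `cov_median`, `cov_p95`,
#'   `diff_p90`.
#' @export
compute_thresholds <- function(ctrl, test, diff, rmsd_p = 0.5,
                               cov_band = c(0.5, 0.95), diff_p = 0.9) {
  if (!layout_identical(ctrl$layout, test$layout)) {
    stop("control and test tracks have different layouts")
  }
  rpool <- unlist(lapply(diff$data, function(d) d$rmsd[!d$masked]),
                  use.names = FALSE)
  if (!length(rpool)) stop("empty RMSD pool")
  cpool <- list()
  dpool <- list()
  for (sq in seq_names(ctrl$layout)) {
    a <- ctrl$values[[sq]]
    b <- test$values[[sq]]
    keep <- if (!is.null(ctrl$mask)) !ctrl$mask[[sq]] else TRUE
    cpool[[sq]] <- (a + b)[keep]
    dpool[[sq]] <- (b - a)[keep]
  }
  cpool <- unlist(cpool, use.names = FALSE)
  dpool <- unlist(dpool, use.names = FALSE)
  if (!length(cpool)) stop("empty coverage pool")
  cb <- pctile(cpool, cov_band)
  structure(
    list(
      rmsd_median = pctile(rpool, rmsd_p),
      cov_median = cb[1], cov_p95 = cb[2],
      diff_p90 = pctile(dpool, diff_p),
      n_windows = length(rpool), n_positions = length(cpool)
    ),
    class = "threshold_set"
  )
}

#' @export
print.threshold_set <- function(x, ...) {
  cat(
    "<threshold_set> rmsd_median=", format(x$rmsd_median),
    " cov=(", format(x$cov_median), ", ", format(x$cov_p95), ")",
    " diff_p90=", format(x$diff_p90), "\n",
    sep = ""
  )
  invisible(x)
}

#' Apply the three TSS filtering criteria
#'
#' At each candidate peak's anchor position, all comparisons strict:
#' (1) RMSD larger than the median of all shape-difference values;
#' (2) control + test smoothed coverage strictly between its median and
#' 95th percentile; (3) test - control difference larger than its 90th
#' percentile. TES-like peaks are removed regardless.
#'
#' @param peaks classified peaks ([classify_tes()] output).
#' @param thresholds a `threshold_set` from the same pair of tracks.
#' @param ctrl,test the smoothed, depth-normalized tracks.
#' @return `peaks` with columns `cov_sum`, `diff_val`, `pass_rmsd`,
#'   `pass_cov`, `pass_diff`, `keep`.
#' @export
filter_candidates <- function(peaks, thresholds, ctrl, test) {
  n_pk <- nrow(peaks)
  cov_sum <- numeric(n_pk)
  diff_val <- numeric(n_pk)
  for (i in seq_len(n_pk)) {
    sq <- peaks$seqname[i]
    p <- peaks$pos[i]
    cov_sum[i] <- ctrl$values[[sq]][p] + test$values[[sq]][p]
    diff_val[i] <- test$values[[sq]][p] - ctrl$values[[sq]][p]
  }
  peaks$cov_sum <- cov_sum
  peaks$diff_val <- diff_val
  peaks$pass_rmsd <- peaks$rmsd > thresholds$rmsd_median
  peaks$pass_cov <- cov_sum > thresholds$cov_median &
    cov_sum < thresholds$cov_p95
  peaks$pass_diff <- diff_val > thresholds$diff_p90
  peaks$keep <- peaks$pass_rmsd & peaks$pass_cov & peaks$pass_diff &
    !peaks$tes_like
  peaks
}

# Resolve a contig's transcription orientation from the annotation: the
# strand of the gene(s) overlapping its span when they agree, otherwise
# keep the peak-level inference. The TSS is the contig's 5' end in that
# orientation.
resolve_contig_strands <- function(contigs, annot) {
  for (i in seq_len(nrow(contigs))) {
    g <- which(annot$seqname == contigs$seqname[i] &
                 annot$start <= contigs$end[i] &
                 annot$end >= contigs$start[i])
    gs <- unique(annot$strand[g])
    if (length(gs) == 1L) {
      contigs$strand[i] <- gs
      contigs$strand_source[i] <- "gene"
    } else if (contigs$strand_source[i] != "gene") {
      contigs$flags[i] <- join_flags(contigs$flags[i], "strand-ambiguous")
    }
    contigs$tss[i] <- if (contigs$strand[i] == "-") {
      contigs$end[i]
    } else {
      contigs$start[i]
    }
  }
  contigs
}

# Per-sequence test - ctrl difference vectors.
diff_values <- function(ctrl, test) {
  stats::setNames(
    lapply(seq_names(ctrl$layout), function(sq) {
      test$values[[sq]] - ctrl$values[[sq]]
    }),
    seq_names(ctrl$layout)
  )
}

#' Build transcript contigs around surviving peaks
#'
#' From each kept peak, positions are scanned 5' and 3' while the
#' per-position test - control difference stays at or above the
#' contig-defining threshold (`diff_p90`); the first position below it
#' bounds the contig (exclusive). The averaged difference is the mean of
#' the difference over the contig; the TSS is the contig's 5' end in
#' transcription orientation.
#'
#' @param peaks filtered peaks; only rows with `keep == TRUE` are used.
#' @param ctrl,test smoothed, depth-normalized tracks.
#' @param thresholds the `threshold_set` used for filtering.
#' @param sample sample label stored on the contigs.
#' @return a `transcript_contigs` data frame: `seqname`, `start`, `end`,
#'   `tss`, `strand`, `strand_source`, `avg_diff`, `size`, `sample`,
#'   `flags`.
#' @export
build_contigs <- function(peaks, ctrl, test, thresholds,
                          sample = test$sample) {
  kept <- peaks[peaks$keep, , drop = FALSE]
  dv <- diff_values(ctrl, test)
  thr <- thresholds$diff_p90
  rows <- vector("list", nrow(kept))
  prev_by_seq <- list()
  next_by_seq <- list()
  for (i in seq_len(nrow(kept))) {
    sq <- kept$seqname[i]
    v <- dv[[sq]]
    n <- length(v)
    if (is.null(prev_by_seq[[sq]])) {
      below <- v < thr
      idx <- seq_len(n)
      prev_by_seq[[sq]] <- cummax(ifelse(below, idx, 0L))
      next_by_seq[[sq]] <- rev(cummin(rev(ifelse(below, idx, n + 1L))))
    }
    p <- kept$pos[i]
    flags <- character(0)
    if (p == 1L) {
      s <- 1L
      flags <- c(flags, "clamped5")
    } else {
      pb <- prev_by_seq[[sq]][p - 1L]
      if (pb == 0L) {
        s <- 1L
        flags <- c(flags, "clamped5")
      } else {
        s <- pb + 1L
      }
    }
    if (p == n) {
      e <- n
      flags <- c(flags, "clamped3")
    } else {
      nb <- next_by_seq[[sq]][p + 1L]
      if (nb == n + 1L) {
        e <- n
        flags <- c(flags, "clamped3")
      } else {
        e <- nb - 1L
      }
    }
    size <- e - s + 1L
    if (size == 1L) flags <- c(flags, "degenerate")
    if (kept$strand_source[i] == "inferred") {
      flags <- c(flags, "strand-ambiguous")
    }
    rows[[i]] <- data.frame(
      seqname = sq, start = s, end = e,
      tss = if (kept$strand[i] == "-") e else s,
      strand = kept$strand[i], strand_source = kept$strand_source[i],
      avg_diff = mean(v[s:e]), size = size, sample = sample,
      flags = paste(flags, collapse = ","), stringsAsFactors = FALSE
    )
  }
  res <- if (length(rows)) do.call(rbind, rows) else data.frame(
    seqname = character(), start = integer(), end = integer(),
    tss = integer(), strand = character(), strand_source = character(),
    avg_diff = numeric(), size = integer(), sample = character(),
    flags = character(), stringsAsFactors = FALSE
  )
  rownames(res) <- NULL
  class(res) <- c("transcript_contigs", "data.frame")
  res
}

#' Merge nearby contigs of similar expression
#'
#' Repeatedly merges, in 5'-to-3' order until a fixed point, any pair of
#' contigs on one sequence whose 5' boundaries lie less than `max_gap` nt
#' apart (strict) and whose averaged differences vary by less than
#' `max_fold` (strict). A merged contig spans the union and its averaged
#' difference is recomputed over that span.
#'
#' @param contigs a `transcript_contigs` data frame (one sample).
#' @param ctrl,test the tracks the contigs were called from.
#' @param max_gap boundary proximity in nt (default 1000).
#' @param max_fold fold-variation bound (default 3).
#' @return the merged `transcript_contigs`.
#' @export
merge_contigs <- function(contigs, ctrl, test, max_gap = 1000L,
                          max_fold = 3) {
  dv <- diff_values(ctrl, test)
  out <- list()
  for (sq in unique(contigs$seqname)) {
    df <- contigs[contigs$seqname == sq, , drop = FALSE]
    v <- dv[[sq]]
    repeat {
      df <- df[order(df$start, df$end), , drop = FALSE]
      k <- nrow(df)
      merged <- FALSE
      for (i in seq_len(max(0L, k - 1L))) {
        for (j in (i + 1L):k) {
          if (df$start[j] - df$start[i] >= max_gap) break
          lo <- min(df$avg_diff[i], df$avg_diff[j])
          hi <- max(df$avg_diff[i], df$avg_diff[j])
          if (lo <= 0) next
          if (hi / lo < max_fold) {
            s <- min(df$start[i], df$start[j])
            e <- max(df$end[i], df$end[j])
            strand <- if (df$strand[i] == df$strand[j]) df$strand[i] else "*"
            src <- if (df$strand_source[i] == df$strand_source[j]) {
              df$strand_source[i]
            } else {
              "inferred"
            }
            row <- df[i, , drop = FALSE]
            row$start <- s
            row$end <- e
            row$strand <- strand
            row$strand_source <- src
            row$tss <- if (strand == "-") e else s
            row$avg_diff <- mean(v[s:e])
            row$size <- e - s + 1L
            row$flags <- join_flags(df$flags[i], df$flags[j], "merged")
            df <- rbind(row, df[-c(i, j), , drop = FALSE])
            merged <- TRUE
            break
          }
        }
        if (merged) break
      }
      if (!merged) break
    }
    out[[sq]] <- df
  }
  res <- if (length(out)) do.call(rbind, out) else contigs
  rownames(res) <- NULL
  class(res) <- c("transcript_contigs", "data.frame")
  res
}

#' Score and rank contigs
#'
#' Confidence score = averaged difference of smoothed coverage x contig
#' size; rank 1 is the highest score. Ties break by 5'-most coordinate,
#' then sequence name.
#'
#' @param contigs merged `transcript_contigs`.
#' @return the contigs with `score` and `rank`, sorted by rank.
#' @export
score_and_rank <- function(contigs) {
  contigs$score <- contigs$avg_diff * contigs$size
  o <- order(-contigs$score, contigs$start, contigs$seqname)
  contigs <- contigs[o, , drop = FALSE]
  contigs$rank <- seq_len(nrow(contigs))
  rownames(contigs) <- NULL
  contigs
}

#' Call ranked contigs for one test sample
#'
#' Runs the per-sample stage chain: shape difference, peak finding, TES
#' classification, three-criterion filtering, contig construction, merging,
#' scoring/ranking.
#'
#' @param ctrl_n,test_n smoothed, depth-normalized control and test tracks.
#' @param annot gene annotation (strand context for TES classification).
#' @param window,step,tes_flank,rmsd_p,cov_band,diff_p,merge_gap,merge_fold
#'   stage parameters (defaults are the pipeline defaults).
#' @return a `sample_scan` list: `contigs`, `peaks`, `thresholds`, `diff`,
#'   `stage_counts`.
#' @export
call_contigs <- function(ctrl_n, test_n, annot, window = 150L, step = 5L,
                         tes_flank = 150L, rmsd_p = 0.5,
                         cov_band = c(0.5, 0.95), diff_p = 0.9,
                         merge_gap = 1000L, merge_fold = 3) {
  diff <- shape_difference(ctrl_n, test_n, window = window, step = step)
  peaks <- find_peaks(diff)
  n_peaks <- nrow(peaks)
  peaks <- classify_tes(peaks, test_n, annot, flank = tes_flank)
  thresholds <- compute_thresholds(
    ctrl_n, test_n, diff,
    rmsd_p = rmsd_p, cov_band = cov_band, diff_p = diff_p
  )
  peaks <- filter_candidates(peaks, thresholds, ctrl_n, test_n)
  contigs <- resolve_contig_strands(
    build_contigs(peaks, ctrl_n, test_n, thresholds), annot
  )
  merged <- resolve_contig_strands(
    merge_contigs(
      contigs, ctrl_n, test_n,
      max_gap = merge_gap, max_fold = merge_fold
    ),
    annot
  )
  ranked <- score_and_rank(merged)
  structure(
    list(
      contigs = ranked, peaks = peaks, thresholds = thresholds, diff = diff,
      stage_counts = c(
        peaks = n_peaks,
        after_tes = sum(!peaks$tes_like),
        after_criteria = sum(peaks$keep),
        contigs = nrow(contigs),
        after_merge = nrow(ranked)
      )
    ),
    class = "sample_scan"
  )
}
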