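# Cross-sample consensus calls and ORF-internal classification.

#' Group contigs across samples
#'
#' Contigs from different samples cluster together iff their spans overlap
#' and their 5' (leftmost) boundaries lie less than `max_gap` nt apart,
#' with single-linkage closure within each sequence (the proximity constant
#' is shared with intra-sample merging).
#'
#' @param contigs combined `transcript_contigs` from >= 2 samples (must
#'   carry a `sample` column).
#' @param max_gap boundary proximity in nt (default 1000).
#' @return the contigs with an added `cluster` column.
#' @export
match_across_samples <- function(contigs, max_gap = 1000L) {
  contigs$cluster <- rep(NA_character_, nrow(contigs))
  for (sq in unique(contigs$seqname)) {
    idx <- which(contigs$seqname == sq)
    k <- length(idx)
    parent <- seq_len(k)
    find <- function(i) {
      while (parent[i] != i) {
        parent[i] <<- parent[parent[i]]
        i <- parent[i]
      }
      i
    }
    st <- contigs$start[idx]
    en <- contigs$end[idx]
    sm <- contigs$sample[idx]
    if (k > 1L) {
      for (i in 1:(k - 1L)) {
        for (j in (i + 1L):k) {
          if (sm[i] == sm[j]) next
          if (st[i] <= en[j] && st[j] <= en[i] &&
                abs(st[i] - st[j]) < max_gap) {
            ri <- find(i)
            rj <- find(j)
            if (ri != rj) parent[rj] <- ri
          }
        }
      }
    }
    roots <- vapply(seq_len(k), find, integer(1))
    contigs$cluster[idx] <- sprintf("%s_c%d", sq, roots)
  }
  contigs
}

#' Build consensus calls from contig clusters
#'
#' Clusters supported by fewer than `min_support` distinct samples, or
#' whose union span exceeds `max_span` nt, are discarded. Surviving calls
#' get an averaged rank (mean of member ranks), a consensus TSS (mean of
#' member TSSs, rounded half-up) and a TSS range (maximum deviation of a
#' member TSS from the mean).
#'
#' @param contigs clustered contigs ([match_across_samples()] output).
#' @param min_support minimum number of distinct supporting samples
#'   (default 2).
#' @param max_span maximum consensus span in nt (default 4000).
#' @return a `consensus_calls` data frame sorted by averaged rank, with a
#'   `counts` attribute recording how many clusters each filter removed.
#' @export
consensus_calls <- function(contigs, min_support = 2L, max_span = 4000L) {
  groups <- split(seq_len(nrow(contigs)), contigs$cluster)
  rows <- list()
  n_single <- 0L
  n_long <- 0L
  for (g in groups) {
    mem <- contigs[g, , drop = FALSE]
    support <- length(unique(mem$sample))
    if (support < min_support) {
      n_single <- n_single + 1L
      next
    }
    s <- min(mem$start)
    e <- max(mem$end)
    if (e - s + 1L > max_span) {
      n_long <- n_long + 1L
      next
    }
    tss_mean <- mean(mem$tss)
    strand <- unique(mem$strand)
    strand <- if (length(strand) == 1L) strand else "*"
    rows[[length(rows) + 1L]] <- data.frame(
      seqname = mem$seqname[1], start = s, end = e, span = e - s + 1L,
      tss = as.integer(round_half_up(tss_mean)),
      tss_range = as.integer(round_half_up(max(abs(mem$tss - tss_mean)))),
      avg_rank = mean(mem$rank), support = support,
      samples = paste(sort(unique(mem$sample)), collapse = ","),
      strand = strand, n_members = nrow(mem),
      flags = join_flags(mem$flags), stringsAsFactors = FALSE
    )
  }
  res <- if (length(rows)) do.call(rbind, rows) else data.frame(
    seqname = character(), start = integer(), end = integer(),
    span = integer(), tss = integer(), tss_range = integer(),
    avg_rank = numeric(), support = integer(), samples = character(),
    strand = character(), n_members = integer(), flags = character(),
    stringsAsFactors = FALSE
  )
  res <- res[order(res$avg_rank, res$seqname, res$start), , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "counts") <- c(
    clusters = length(groups), singleton = n_single, too_long = n_long,
    kept = nrow(res)
  )
  class(res) <- c("consensus_calls", "data.frame")
  res
}

#' Classify consensus calls as ORF-internal TSSs
#'
#' A call is internal iff its consensus TSS lies within an annotated ORF at
#' least `min_dist` nt from both the start and stop codon, and its averaged
#' rank is at most `rank_cutoff`. The host is the overlapping ORF whose
#' strand matches the call's orientation when that is resolvable; otherwise
#' all overlapping ORFs are reported and flagged. The reported offset is
#' strand-aware, with the first ORF base = +1.
#'
#' @param calls a `consensus_calls` data frame.
#' @param annot gene annotation.
#' @param min_dist minimum distance to start/stop codon in nt (default 75).
#' @param rank_cutoff maximum averaged rank (default 800, inclusive).
#' @return an `internal_tss_calls` data frame, one row per (call, host ORF),
#'   sorted by averaged rank.
#' @export
classify_internal <- function(calls, annot, min_dist = 75L,
                              rank_cutoff = 800) {
  rows <- list()
  for (i in seq_len(nrow(calls))) {
    t <- calls$tss[i]
    g <- which(annot$seqname == calls$seqname[i] &
                 annot$start <= t & annot$end >= t)
    if (!length(g)) next
    flags <- calls$flags[i]
    if (calls$strand[i] %in% c("+", "-")) {
      gm <- g[annot$strand[g] == calls$strand[i]]
      if (length(gm)) {
        g <- gm
      } else {
        flags <- join_flags(flags, "host-strand-mismatch")
      }
    } else {
      flags <- join_flags(flags, "host-ambiguous")
    }
    if (length(g) > 1L) flags <- join_flags(flags, "multi-host")
    for (gi in g) {
      if (annot$strand[gi] == "+") {
        offset <- t - annot$start[gi] + 1L
        dist_stop <- annot$end[gi] - t + 1L
      } else {
        offset <- annot$end[gi] - t + 1L
        dist_stop <- t - annot$start[gi] + 1L
      }
      dist_start <- offset
      if (dist_start < min_dist || dist_stop < min_dist) next
      if (calls$avg_rank[i] > rank_cutoff) next
      rows[[length(rows) + 1L]] <- data.frame(
        gene_id = annot$gene_id[gi], gene_name = annot$gene_name[gi],
        seqname = calls$seqname[i], host_strand = annot$strand[gi],
        orf_start = annot$start[gi], orf_end = annot$end[gi],
        tss = t, tss_range = calls$tss_range[i], offset = offset,
        dist_start = dist_start, dist_stop = dist_stop,
        avg_rank = calls$avg_rank[i], support = calls$support[i],
        samples = calls$samples[i], start = calls$start[i],
        end = calls$end[i], span = calls$span[i], flags = flags,
        stringsAsFactors = FALSE
      )
    }
  }
  res <- if (length(rows)) do.call(rbind, rows) else data.frame(
    gene_id = character(), gene_name = character(), seqname = character(),
    host_strand = character(), orf_start = integer(), orf_end = integer(),
    tss = integer(), tss_range = integer(), offset = integer(),
    dist_start = integer(), dist_stop = integer(), avg_rank = numeric(),
    support = integer(), samples = character(), start = integer(),
    end = integer(), span = integer(), flags = character(),
    stringsAsFactors = FALSE
  )
  res <- res[order(res$avg_rank, res$seqname, res$tss), , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("internal_tss_calls", "data.frame")
  res
}

#' Write the internal-TSS report
#'
#' Tab-separated report, one row per call sorted by averaged rank, with the
#' start location written as `+offset±range` relative to the first ORF
#' base. Motif columns show Yes/No when the calls carry motif flags and ND
#' otherwise.
#'
#' @param calls an `internal_tss_calls` data frame.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_internal_report <- function(calls, path) {
  fmt_hit <- function(col) {
    if (col %in% names(calls)) {
      ifelse(calls[[col]], "Yes", "No")
    } else {
      rep("ND", nrow(calls))
    }
  }
  df <- data.frame(
    orf_id = calls$gene_id,
    gene_name = ifelse(is.na(calls$gene_name), "", calls$gene_name),
    start_location = sprintf("+%d±%d", calls$offset, calls$tss_range),
    avg_rank = calls$avg_rank,
    support = calls$support,
    mse = fmt_hit("mse_hit"),
    urs1 = fmt_hit("urs1_hit"),
    span = calls$span,
    flags = calls$flags,
    stringsAsFactors = FALSE
  )
  df <- df[order(calls$avg_rank), , drop = FALSE]
  utils::write.table(
    df, path,
    sep = "\t", quote = FALSE, row.names = FALSE, fileEncoding = "UTF-8"
  )
  invisible(path)
}

#' Write consensus contigs as BED6
#'
#' The BED score column carries the averaged rank (rounded); strand `*`
#' becomes `.`.
#'
#' @param calls a `consensus_calls` (or `internal_tss_calls`) data frame.
#' @param path output file.
#' @param name_col column used for the BED name field.
#' @return `path`, invisibly.
#' @export
write_contigs_bed <- function(calls, path, name_col = NULL) {
  if (is.null(name_col)) {
    nm <- if ("gene_id" %in% names(calls)) {
      calls$gene_id
    } else {
      sprintf("call_%d", seq_len(nrow(calls)))
    }
  } else {
    nm <- calls[[name_col]]
  }
  strand <- calls$strand %||% rep(".", nrow(calls))
  strand[!strand %in% c("+", "-")] <- "."
  writeLines(sprintf(
    "%s\t%d\t%d\t%s\t%d\t%s",
    calls$seqname, calls$start - 1L, calls$end, nm,
    as.integer(round_half_up(calls$avg_rank)), strand
  ), path)
  invisible(path)
}
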