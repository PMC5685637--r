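# Position-weight-matrix scanning of upstream windows and exact motif
# enrichment.

#' Construct a motif model from a log-odds matrix
#'
#' Low-level constructor; most users should call [load_pwm()]. Column order
#' is motif position; row order is A, C, G, T.
#'
#' @param mat 4-row numeric log-odds matrix.
#' @param name motif name.
#' @return a `motif_model`.
#' @export
motif_model <- function(mat, name = "motif") {
  if (!is.matrix(mat) || nrow(mat) != 4L || ncol(mat) < 1L) {
    stop("motif matrix must have 4 rows (A, C, G, T) and >= 1 column")
  }
  if (any(!is.finite(mat))) stop("motif matrix must be finite")
  rownames(mat) <- c("A", "C", "G", "T")
  col_min <- apply(mat, 2, min)
  col_max <- apply(mat, 2, max)
  # accumulate bounds column-by-column in double precision, the same order
  # the scanner sums a site's columns, so a consensus site scores exactly
  # max_score (relative score exactly 1)
  min_score <- 0
  max_score <- 0
  for (j in seq_len(ncol(mat))) {
    min_score <- min_score + col_min[[j]]
    max_score <- max_score + col_max[[j]]
  }
  if (max_score - min_score <= 0) {
    stop("degenerate motif: score range is zero")
  }
  structure(
    list(
      name = name, mat = mat, length = ncol(mat),
      col_min = col_min, min_score = min_score, max_score = max_score,
      consensus = paste(rownames(mat)[apply(mat, 2, which.max)],
                        collapse = "")
    ),
    class = "motif_model"
  )
}

#' @export
print.motif_model <- function(x, ...) {
  cat(
    "<motif_model> ", x$name, ": ", x$length, " nt, consensus ",
    x$consensus, ", score range [", format(x$min_score), ", ",
    format(x$max_score), "]\n",
    sep = ""
  )
  invisible(x)
}

#' Load a JASPAR-style position frequency matrix
#'
#' Reads a 4-row count (or probability) matrix — plain whitespace-separated
#' rows, optionally prefixed with the base letter and bracketed
#' (`A [ 3 1 ... ]`), optionally headed by a `>name` line — and converts it
#' to log-odds: a pseudocount is added to every cell, columns are
#' normalized, and each probability is log-transformed against the
#' background (natural log).
#'
#' @param path matrix file.
#' @param name motif name (default: header line or file name).
#' @param pseudocount per-cell pseudocount (default 0.25).
#' @param background per-base background probabilities (default uniform).
#' @return a [motif_model()].
#' @export
load_pwm <- function(path, name = NULL, pseudocount = 0.25,
                     background = rep(0.25, 4)) {
  stopifnot(length(background) == 4L, all(background > 0))
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  if (length(lines) && startsWith(lines[1], ">")) {
    if (is.null(name)) name <- sub("^>\\s*", "", lines[1])
    lines <- lines[-1]
  }
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  if (length(lines) != 4L) {
    stop("PWM format error: expected 4 matrix rows, found ", length(lines))
  }
  base_order <- c("A", "C", "G", "T")
  rows <- vector("list", 4L)
  labels <- character(4L)
  for (i in 1:4) {
    ln <- lines[i]
    lab <- regmatches(ln, regexpr("^[ACGTacgt]\\b", ln))
    if (length(lab)) {
      labels[i] <- toupper(lab)
      ln <- sub("^[ACGTacgt]\\s*", "", ln)
    }
    ln <- gsub("[][]", " ", ln)
    v <- suppressWarnings(as.numeric(strsplit(trimws(ln), "\\s+")[[1]]))
    if (any(is.na(v)) || !length(v)) {
      stop("PWM format error: non-numeric entries in row ", i)
    }
    rows[[i]] <- v
  }
  if (length(unique(lengths(rows))) != 1L) {
    stop("PWM format error: rows have unequal lengths")
  }
  counts <- do.call(rbind, rows)
  if (all(nzchar(labels))) {
    if (anyDuplicated(labels)) stop("PWM format error: duplicate base rows")
    counts <- counts[match(base_order, labels), , drop = FALSE]
  }
  rownames(counts) <- base_order
  if (any(counts < 0)) stop("PWM format error: negative counts")
  if (pseudocount <= 0 && any(colSums(counts == 0) > 0)) {
    stop("zero PWM entries require a positive pseudocount")
  }
  p <- counts + pseudocount
  p <- sweep(p, 2, colSums(p), "/")
  lo <- log(p / background)
  motif_model(lo, name = name)
}

# A/C/G/T -> 1..4; other letters (N, ...) -> NA.
encode_dna <- function(seq) {
  match(strsplit(toupper(seq), "", fixed = TRUE)[[1]], c("A", "C", "G", "T"))
}

score_offsets <- function(code, motif) {
  L <- motif$length
  k <- length(code) - L + 1L
  s <- numeric(k)
  for (j in seq_len(L)) {
    sj <- motif$mat[, j][code[j:(j + k - 1L)]]
    sj[is.na(sj)] <- motif$col_min[j]
    s <- s + sj
  }
  s
}

#' Scan a sequence with a motif model
#'
#' Scores every offset on both strands; ambiguous bases score as the
#' column minimum. Hits are positions whose relative score
#' `(score - min) / (max - min)` exceeds `threshold` (strict), i.e. sites
#' scoring above that fraction of the possible score range.
#'
#' @param seq nucleotide sequence (character scalar).
#' @param motif a [motif_model()].
#' @param threshold relative-score threshold fraction (default 0.85).
#' @return a data frame of hits (`offset` of the site's leftmost base on
#'   the given sequence, `strand`, `score`, `rel_score`), sorted by offset;
#'   attribute `best` holds the best relative score over all offsets. A
#'   sequence shorter than the motif yields an empty result with a warning.
#' @export
scan_motif <- function(seq, motif, threshold = 0.85) {
  empty <- data.frame(
    offset = integer(), strand = character(), score = numeric(),
    rel_score = numeric(), stringsAsFactors = FALSE
  )
  code <- encode_dna(seq)
  n <- length(code)
  if (n < motif$length) {
    warning("sequence shorter than motif (", n, " < ", motif$length, ")")
    attr(empty, "best") <- NA_real_
    return(empty)
  }
  fw <- score_offsets(code, motif)
  rc <- rev(5L - code)
  rv <- score_offsets(rc, motif)
  rng <- motif$max_score - motif$min_score
  df <- data.frame(
    offset = c(seq_along(fw), n - motif$length + 2L - rev(seq_along(rv))),
    strand = rep(c("+", "-"), c(length(fw), length(rv))),
    score = c(fw, rev(rv)),
    stringsAsFactors = FALSE
  )
  df$rel_score <- (df$score - motif$min_score) / rng
  best <- max(df$rel_score)
  df <- df[df$rel_score > threshold, , drop = FALSE]
  df <- df[order(df$offset, df$strand), , drop = FALSE]
  rownames(df) <- NULL
  attr(df, "best") <- best
  df
}

#' Flag internal-TSS calls whose upstream window contains a motif
#'
#' For each call the anchor is the 3'-most position of the TSS range
#' (consensus offset + range, strand-aware on the host ORF) and the
#' `window` nt immediately 5' of it are scanned. The flag records whether
#' any site exceeds the relative-score threshold.
#'
#' @param calls an `internal_tss_calls` data frame.
#' @param genome a `DNAStringSet`.
#' @param motif a [motif_model()].
#' @param window upstream window in nt (default 300).
#' @param threshold relative-score threshold (default 0.85).
#' @param prefix column prefix (default the lower-cased motif name): adds
#'   `<prefix>_hit` and `<prefix>_n_hits`.
#' @return `calls` with the flag columns added.
#' @export
flag_upstream_sites <- function(calls, genome, motif, window = 300L,
                                threshold = 0.85,
                                prefix = tolower(motif$name)) {
  hit <- logical(nrow(calls))
  nh <- integer(nrow(calls))
  for (i in seq_len(nrow(calls))) {
    off3 <- calls$offset[i] + calls$tss_range[i]
    anchor <- if (calls$host_strand[i] == "+") {
      calls$orf_start[i] + off3 - 1L
    } else {
      calls$orf_end[i] - off3 + 1L
    }
    up <- extract_upstream(
      genome, calls$seqname[i], anchor, calls$host_strand[i], window
    )
    hits <- scan_motif(up$sequence, motif, threshold)
    hit[i] <- nrow(hits) > 0L
    nh[i] <- nrow(hits)
  }
  calls[[paste0(prefix, "_hit")]] <- hit
  calls[[paste0(prefix, "_n_hits")]] <- nh
  calls
}

#' Motif presence upstream of every ORF
#'
#' Scans the `window` nt immediately upstream of each annotated ORF start
#' (strand-aware) — the negative-control background for enrichment testing.
#' Windows truncated at sequence ends are scanned as-is.
#'
#' @param annot gene annotation.
#' @param genome a `DNAStringSet`.
#' @param motif a [motif_model()].
#' @param window upstream window in nt (default 300).
#' @param threshold relative-score threshold (default 0.85).
#' @return named logical vector (one element per gene): any hit?
#' @export
upstream_orf_hits <- function(annot, genome, motif, window = 300L,
                              threshold = 0.85) {
  res <- logical(nrow(annot))
  for (i in seq_len(nrow(annot))) {
    anchor <- if (annot$strand[i] == "+") annot$start[i] else annot$end[i]
    up <- suppressWarnings(extract_upstream(
      genome, annot$seqname[i], anchor, annot$strand[i], window
    ))
    if (nchar(up$sequence) < motif$length) next
    res[i] <- nrow(scan_motif(up$sequence, motif, threshold)) > 0L
  }
  stats::setNames(res, annot$gene_id)
}

#' Two-sided Fisher exact test by hypergeometric enumeration
#'
#' Tests whether `k` hits among `n` foreground genes is enriched relative
#' to `K` hits among `N` background genes. The two-sided p-value sums the
#' probabilities of all tables (at fixed margins) no more probable than the
#' observed one.
#'
#' @param k foreground genes with a hit.
#' @param n foreground genes total.
#' @param K background genes with a hit.
#' @param N background genes total.
#' @return an `enrichment_result`: `p` (two-sided), `p_over` (one-sided
#'   over-representation), the counts, and the 2x2 table.
#' @export
exact_enrichment <- function(k, n, K, N) {
  vals <- c(k = k, n = n, K = K, N = N)
  if (any(vals != floor(vals)) || any(vals < 0)) {
    stop("counts must be non-negative integers")
  }
  if (k > n || K > N || n < 1 || N < 1) {
    stop("invalid margins: need 0 <= k <= n and 0 <= K <= N")
  }
  m <- k + K
  total <- n + N
  lo <- max(0, n - (total - m))
  hi <- min(n, m)
  x <- lo:hi
  d <- stats::dhyper(x, m, total - m, n)
  d_obs <- stats::dhyper(k, m, total - m, n)
  p <- min(1, sum(d[d <= d_obs * (1 + 1e-7)]))
  p_over <- stats::phyper(k - 1, m, total - m, n, lower.tail = FALSE)
  structure(
    list(
      p = p, p_over = p_over, k = k, n = n, K = K, N = N,
      table = matrix(c(k, n - k, K, N - K), nrow = 2, byrow = TRUE,
                     dimnames = list(c("foreground", "background"),
                                     c("hit", "no_hit")))
    ),
    class = "enrichment_result"
  )
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(
    "<enrichment_result> ", x$k, "/", x$n, " foreground vs ",
    x$K, "/", x$N, " background; two-sided exact p = ",
    format(x$p, digits = 4), "\n",
    sep = ""
  )
  invisible(x)
}
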