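# Tiny in-code fixtures shared across tests.

make_layout <- function(...) genome_layout(c(...))

# A one-sequence track from a plain numeric vector.
vec_track <- function(v, name = "chrI", sample = "s") {
  coverage_track(stats::setNames(list(v), name), sample = sample)
}

write_tmp <- function(lines, ext = ".txt") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}

# Random-ish small coverage vector under a fixed-seed RNG already set by
# the caller.
random_cov <- function(n, depth = 10) {
  v <- stats::rpois(n, depth)
  # plant a couple of blocky features so windows are not pure noise
  if (n >= 400) {
    s <- sample.int(n - 200, 1)
    v[s:(s + 199)] <- v[s:(s + 199)] + stats::rpois(200, depth * 3)
  }
  as.numeric(v)
}

# Write a minimal single-motif JASPAR file with given count rows.
write_pfm <- function(counts, name = "TEST") {
  stopifnot(nrow(counts) == 4)
  write_tmp(c(
    paste0(">", name),
    sprintf("A [ %s ]", paste(counts[1, ], collapse = " ")),
    sprintf("C [ %s ]", paste(counts[2, ], collapse = " ")),
    sprintf("G [ %s ]", paste(counts[3, ], collapse = " ")),
    sprintf("T [ %s ]", paste(counts[4, ], collapse = " "))
  ), ext = ".pfm")
}

one_gene_annot <- function(seqname = "chrI", start = 1001L, end = 2000L,
                           strand = "+", id = "G1") {
  a <- data.frame(
    gene_id = id, seqname = seqname, start = start, end = end,
    strand = strand, gene_name = NA_character_, stringsAsFactors = FALSE
  )
  class(a) <- c("gene_annotation", "data.frame")
  a
}

empty_annot <- function() one_gene_annot()[0, ]

mk_sample_contigs_acc <- function(sample, starts, ends, ranks) {
  data.frame(
    seqname = "chrI", start = as.integer(starts), end = as.integer(ends),
    tss = as.integer(starts), strand = "+", strand_source = "gene",
    avg_diff = 1, size = as.integer(ends - starts + 1L), sample = sample,
    flags = "", score = 1, rank = as.integer(ranks), stringsAsFactors = FALSE
  )
}

mk_call_acc <- function(tss, avg_rank = 10, tss_range = 0L) {
  df <- data.frame(
    seqname = "chrI", start = tss - 50L, end = tss + 500L, span = 551L,
    tss = as.integer(tss), tss_range = as.integer(tss_range),
    avg_rank = avg_rank, support = 2L, samples = "A,B", strand = "+",
    n_members = 2L, flags = "", stringsAsFactors = FALSE
  )
  class(df) <- c("consensus_calls", "data.frame")
  df
}

# Flag-string membership (tests only; mirrors the package's flag format).
has_flag <- function(flags, flag) {
  vapply(strsplit(flags, ",", fixed = TRUE), function(f) flag %in% f,
         logical(1))
}
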