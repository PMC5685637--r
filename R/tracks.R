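# Core containers: genome layout and per-base coverage tracks.
#
# Coordinates are 1-based inclusive everywhere inside the package; bedGraph
# and BED input/output converts at the boundary (those formats are 0-based,
# half-open). Coverage is unstranded; strand enters only through the gene
# annotation.

#' Genome layout
#'
#' Named sequence lengths defining the coordinate space all tracks share.
#'
#' @param lengths named numeric vector of sequence lengths (nt, > 0); names
#'   must be unique.
#' @return a `genome_layout` object.
#' @export
genome_layout <- function(lengths) {
  nm <- names(lengths)
  if (is.null(nm) || any(!nzchar(nm))) {
    stop("sequence lengths must be a named vector")
  }
  if (anyDuplicated(nm)) stop("duplicate sequence names in layout")
  if (any(!is.finite(lengths)) || any(lengths <= 0)) {
    stop("sequence lengths must be finite and > 0")
  }
  structure(
    list(lengths = stats::setNames(as.integer(lengths), nm)),
    class = "genome_layout"
  )
}

#' @export
print.genome_layout <- function(x, ...) {
  cat(
    "<genome_layout> ", length(x$lengths), " sequence(s), ",
    format(sum(as.numeric(x$lengths)), big.mark = ","), " nt total\n",
    sep = ""
  )
  invisible(x)
}

seq_names <- function(layout) names(layout$lengths)

seq_len_of <- function(layout, seqname) {
  n <- layout$lengths[[seqname]]
  if (is.null(n)) stop("unknown sequence: ", seqname)
  n
}

layout_identical <- function(a, b) {
  identical(a$lengths, b$lengths)
}

#' Per-base coverage track
#'
#' One sample's non-negative per-base signal over every position of a genome
#' layout, with an optional exclusion mask (masked positions are ignored by
#' depth sums and percentile pools).
#'
#' @param values named list of numeric vectors, one per sequence.
#' @param layout a [genome_layout()]; derived from `values` if omitted.
#' @param sample sample label.
#' @param mask optional named list of logical vectors (TRUE = excluded).
#' @return a `coverage_track` object.
#' @export
coverage_track <- function(values, layout = NULL, sample = "sample",
                           mask = NULL) {
  if (is.null(layout)) {
    layout <- genome_layout(vapply(values, length, numeric(1)))
  }
  if (!identical(sort(names(values)), sort(seq_names(layout)))) {
    stop("track values do not match layout sequence names")
  }
  values <- values[seq_names(layout)]
  for (sq in seq_names(layout)) {
    v <- values[[sq]]
    if (length(v) != seq_len_of(layout, sq)) {
      stop("value vector length mismatch for ", sq)
    }
    if (any(!is.finite(v)) || any(v < 0)) {
      stop("coverage values must be finite and >= 0 (", sq, ")")
    }
  }
  if (!is.null(mask)) {
    mask <- mask[seq_names(layout)]
    stopifnot(identical(
      vapply(mask, length, integer(1)),
      vapply(values, length, integer(1))
    ))
  }
  structure(
    list(layout = layout, values = values, mask = mask, sample = sample),
    class = "coverage_track"
  )
}

#' @export
print.coverage_track <- function(x, ...) {
  cat(
    "<", class(x)[1], "> sample=", x$sample, ", ",
    length(x$values), " sequence(s), total signal ",
    format(total_signal(x)), "\n",
    sep = ""
  )
  invisible(x)
}

#' Total unmasked signal of a track
#'
#' Sum of per-base values over all positions not covered by an exclusion
#' mask; this is the depth-normalization denominator.
#'
#' @param track a `coverage_track`.
#' @return numeric scalar.
#' @export
total_signal <- function(track) {
  tot <- 0
  for (sq in names(track$values)) {
    v <- track$values[[sq]]
    if (!is.null(track$mask)) v <- v[!track$mask[[sq]]]
    tot <- tot + sum(v)
  }
  tot
}

#' Mask excluded features out of a coverage track
#'
#' Sets values inside the excluded intervals to zero and records the
#' positions in the track mask so that depth sums and percentile pools
#' ignore them. This is the coverage-level equivalent of removing reads
#' mapping to contaminant features (rRNA/tRNA, mitochondrial DNA, plasmids)
#' before quantification. Idempotent.
#'
#' @param track a `coverage_track`.
#' @param excl an `exclusion_set` from [read_exclusions()], or NULL.
#' @return the masked `coverage_track`.
#' @export
apply_exclusions <- function(track, excl) {
  if (is.null(excl) || nrow(excl) == 0L) {
    return(track)
  }
  mask <- track$mask
  if (is.null(mask)) {
    mask <- lapply(track$values, function(v) rep(FALSE, length(v)))
  }
  for (i in seq_len(nrow(excl))) {
    sq <- excl$seqname[i]
    if (!sq %in% names(track$values)) stop("exclusion on unknown sequence: ", sq)
    s <- excl$start[i]
    e <- excl$end[i]
    track$values[[sq]][s:e] <- 0
    mask[[sq]][s:e] <- TRUE
  }
  track$mask <- mask
  track
}
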