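# Small shared helpers.

#' Linear-interpolation percentile
#'
#' Percentile of a numeric pool using linear interpolation between order
#' statistics (the type-7 definition: `h = (n-1)p + 1`). All thresholding in
#' the pipeline goes through this one definition so results are reproducible
#' across implementations.
#'
#' @param x numeric vector (the pool).
#' @param p probability (or vector of probabilities) in `[0, 1]`.
#' @return numeric vector of percentiles.
#' @export
pctile <- function(x, p) {
  if (length(x) == 0L) stop("empty pool: cannot compute a percentile")
  as.numeric(stats::quantile(x, probs = p, type = 7, names = FALSE))
}

# Round half away from zero upward (2.5 -> 3), used wherever fractional
# base positions are reported as integers.
round_half_up <- function(x) floor(x + 0.5)

`%||%` <- function(a, b) if (is.null(a)) b else a

# Combine flag strings ("a,b") dropping empties/duplicates.
join_flags <- function(...) {
  f <- unlist(strsplit(c(...), ",", fixed = TRUE), use.names = FALSE)
  f <- unique(f[nzchar(f)])
  paste(f, collapse = ",")
}

has_flag <- function(flags, flag) {
  vapply(
    strsplit(flags, ",", fixed = TRUE),
    function(f) flag %in% f,
    logical(1)
  )
}
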