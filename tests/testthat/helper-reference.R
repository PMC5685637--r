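# Naive, loop-based reference implementations used as independent oracles.
# They share no code with the package internals: plain per-position /
# per-window loops, and an explicitly written percentile formula.

ref_quantile <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}

# Truncated-Gaussian smoothing by an explicit per-position loop with
# per-source edge renormalization.
ref_smooth <- function(v, sigma = 50, mass = 0.995) {
  h <- ceiling(qnorm((1 + mass) / 2) * sigma)
  w <- dnorm(-h:h, sd = sigma)
  w <- w / sum(w)
  n <- length(v)
  y <- numeric(n)
  for (p in seq_len(n)) {
    if (v[p] == 0) next
    lo <- max(1, p - h)
    hi <- min(n, p + h)
    kw <- w[(lo - p + h + 1):(hi - p + h + 1)]
    y[lo:hi] <- y[lo:hi] + v[p] * kw / sum(kw)
  }
  y
}

# Per-window RMSD of unit-area-rescaled curves, naive loop.
ref_shape_diff <- function(a, b, window = 150, step = 5) {
  n <- length(a)
  wstart <- seq(1, n - window + 1, by = step)
  anchors <- wstart + window %/% 2
  rmsd <- numeric(length(wstart))
  zero <- logical(length(wstart))
  for (k in seq_along(wstart)) {
    ia <- wstart[k]:(wstart[k] + window - 1)
    wa <- a[ia]
    wb <- b[ia]
    if (sum(wa) == 0 || sum(wb) == 0) {
      zero[k] <- TRUE
      rmsd[k] <- 0
    } else {
      rmsd[k] <- sqrt(mean((wa / sum(wa) - wb / sum(wb))^2))
    }
  }
  list(anchors = anchors, rmsd = rmsd, zero = zero)
}

# Local maxima by brute-force enumeration over every index.
ref_peaks <- function(rmsd) {
  n <- length(rmsd)
  peaks <- integer(0)
  k <- 2
  while (k <= n - 1) {
    j <- k
    while (j < n && rmsd[j + 1] == rmsd[k]) j <- j + 1
    if (j < n && k > 1 && rmsd[k] > rmsd[k - 1] && rmsd[k] > rmsd[j + 1]) {
      peaks <- c(peaks, floor((k + j) / 2))
    }
    k <- j + 1
  }
  peaks
}

# Contig boundaries by a naive outward walk.
ref_contig <- function(v, p, thr) {
  n <- length(v)
  s <- p
  while (s > 1 && v[s - 1] >= thr) s <- s - 1
  e <- p
  while (e < n && v[e + 1] >= thr) e <- e + 1
  clamp5 <- s == 1 && v[1] >= thr
  clamp3 <- e == n && v[n] >= thr
  list(start = s, end = e, avg = mean(v[s:e]), clamp5 = clamp5,
       clamp3 = clamp3)
}

# Fixed-point pairwise merging in an arbitrary processing order.
ref_merge <- function(df, v, max_gap = 1000, max_fold = 3,
                      order_fun = identity) {
  repeat {
    k <- nrow(df)
    merged <- FALSE
    idx <- order_fun(seq_len(k))
    for (i in idx) {
      for (j in idx) {
        if (i >= j) next
        if (abs(df$start[i] - df$start[j]) >= max_gap) next
        lo <- min(df$avg[i], df$avg[j])
        hi <- max(df$avg[i], df$avg[j])
        if (lo <= 0 || hi / lo >= max_fold) next
        s <- min(df$start[i], df$start[j])
        e <- max(df$end[i], df$end[j])
        df <- rbind(
          data.frame(start = s, end = e, avg = mean(v[s:e])),
          df[-c(i, j), c("start", "end", "avg")]
        )
        merged <- TRUE
        break
      }
      if (merged) break
    }
    if (!merged) break
  }
  df[order(df$start), , drop = FALSE]
}

# Exhaustive PWM scoring over all offsets and both strands.
ref_scan_best <- function(seq, motif) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  chars <- strsplit(toupper(seq), "")[[1]]
  L <- motif$length
  n <- length(chars)
  out <- data.frame(offset = integer(), strand = character(),
                    score = numeric())
  for (i in seq_len(n - L + 1)) {
    for (st in c("+", "-")) {
      word <- chars[i:(i + L - 1)]
      if (st == "-") word <- rev(unname(comp[word]))
      s <- 0
      for (j in seq_len(L)) {
        s <- s + if (word[j] %in% rownames(motif$mat)) {
          motif$mat[word[j], j]
        } else {
          min(motif$mat[, j])
        }
      }
      out <- rbind(out, data.frame(offset = i, strand = st, score = s,
                                   stringsAsFactors = FALSE))
    }
  }
  out
}
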