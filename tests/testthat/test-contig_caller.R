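# Build a shape_diff_track directly from an RMSD series so peak logic can
# be tested in isolation.
fake_diff <- function(rmsd, step = 5L, window = 150L) {
  n <- length(rmsd)
  anchors <- as.integer(window %/% 2 + 1L + step * (seq_len(n) - 1L))
  structure(
    list(
      layout = genome_layout(c(chrI = max(anchors) + window)),
      window = window, step = step,
      data = list(chrI = list(
        anchors = anchors, rmsd = rmsd,
        zero = rep(FALSE, n), masked = rep(FALSE, n)
      )),
      samples = c(ctrl = "c", test = "t")
    ),
    class = "shape_diff_track"
  )
}

test_that("peak finding returns strict local maxima with plateau collapse", {
  p <- find_peaks(fake_diff(c(0, 1, 3, 1, 0)))
  expect_equal(p$index, 3L)
  expect_equal(p$rmsd, 3)

  expect_equal(nrow(find_peaks(fake_diff(c(1, 2, 3, 4, 5)))), 0L)

  p2 <- find_peaks(fake_diff(c(0, 2, 2, 2, 0)))
  expect_equal(p2$index, 3L)

  # plateaus ramping into a higher value are not peaks
  expect_equal(nrow(find_peaks(fake_diff(c(0, 2, 2, 3, 0)))), 1L)
  expect_equal(find_peaks(fake_diff(c(0, 2, 2, 3, 0)))$index, 4L)

  # series boundaries never yield peaks
  expect_equal(nrow(find_peaks(fake_diff(c(5, 1, 1, 1, 4)))), 0L)
})

test_that("peak finding matches brute-force enumeration on random series", {
  set.seed(77)
  for (i in 1:20) {
    r <- round(runif(sample(10:60, 1)) * 8) / 2 # many ties/plateaus
    got <- find_peaks(fake_diff(r))$index
    expect_identical(got, as.integer(ref_peaks(r)), label = paste("case", i))
  }
})

test_that("TES classification is orientation-aware", {
  # 1 kb sequence, test coverage high left of 500, low right of it
  v <- c(rep(10, 500), rep(2, 500))
  tr <- vec_track(v)
  pk <- data.frame(seqname = "chrI", index = 1L, pos = 500L, rmsd = 1,
                   stringsAsFactors = FALSE)

  plus_gene <- one_gene_annot(start = 100L, end = 900L, strand = "+")
  cp <- classify_tes(pk, tr, plus_gene, flank = 150L)
  expect_true(cp$tes_like)        # more coverage 5' than 3' on + strand
  expect_equal(cp$strand_source, "gene")

  minus_gene <- one_gene_annot(start = 100L, end = 900L, strand = "-")
  cm <- classify_tes(pk, tr, minus_gene, flank = 150L)
  expect_false(cm$tes_like)       # same profile flips on the - strand

  # mirror profile on + strand is a TSS candidate
  cr <- classify_tes(pk, vec_track(rev(v)), plus_gene, flank = 150L)
  expect_false(cr$tes_like)

  # no overlapping gene: retained in the TSS-like orientation, flagged
  cu <- classify_tes(pk, tr, empty_annot(), flank = 150L)
  expect_false(cu$tes_like)
  expect_equal(cu$strand, "-")
  expect_equal(cu$strand_source, "inferred")
})

test_that("percentile thresholds use linear interpolation on the stated pools", {
  expect_equal(pctile(1:100, 0.5), 50.5)
  expect_equal(pctile(1:100, 0.95), 95.05)
  expect_equal(pctile(rep(7, 10), c(0.5, 0.9, 0.95)), rep(7, 3))

  set.seed(13)
  pool <- runif(501) * 10
  for (p in c(0.5, 0.9, 0.95)) {
    expect_equal(pctile(pool, p), ref_quantile(pool, p), tolerance = 1e-12)
  }
  # translation equivariance
  expect_equal(pctile(pool + 3.2, 0.9), pctile(pool, 0.9) + 3.2,
               tolerance = 1e-12)

  set.seed(14)
  a <- vec_track(random_cov(600) + 1)
  b <- vec_track(random_cov(600) + 1)
  d <- shape_difference(a, b)
  thr <- compute_thresholds(a, b, d)
  expect_equal(thr$rmsd_median, ref_quantile(d$data$chrI$rmsd, 0.5),
               tolerance = 1e-12)
  expect_equal(thr$cov_p95,
               ref_quantile(a$values$chrI + b$values$chrI, 0.95),
               tolerance = 1e-12)
  expect_equal(thr$diff_p90,
               ref_quantile(b$values$chrI - a$values$chrI, 0.9),
               tolerance = 1e-12)
  expect_true(thr$cov_median <= thr$cov_p95)
  empty_diff <- structure(
    list(layout = a$layout, window = 150L, step = 5L,
         data = list(chrI = list(anchors = integer(0), rmsd = numeric(0),
                                 zero = logical(0), masked = logical(0))),
         samples = c(ctrl = "c", test = "t")),
    class = "shape_diff_track"
  )
  expect_error(compute_thresholds(a, b, empty_diff), "empty")
})

test_that("the three filtering criteria are strict at their boundaries", {
  thr <- structure(
    list(rmsd_median = 0.5, cov_median = 10, cov_p95 = 20, diff_p90 = 3),
    class = "threshold_set"
  )
  mk_tracks <- function(cov_ctrl, cov_test) {
    list(ctrl = vec_track(rep(cov_ctrl, 9)),
         test = vec_track(rep(cov_test, 9)))
  }
  mk_peak <- function(rmsd) {
    data.frame(seqname = "chrI", index = 1L, pos = 5L, rmsd = rmsd,
               tes_like = FALSE, stringsAsFactors = FALSE)
  }

  # RMSD exactly at the median fails criterion 1 ("larger than median")
  tt <- mk_tracks(6, 9) # cov_sum 15 in band, diff 3... choose diff > 3
  tt <- mk_tracks(5.5, 9.5) # sum 15, diff 4 > 3
  f <- filter_candidates(mk_peak(0.5), thr, tt$ctrl, tt$test)
  expect_false(f$pass_rmsd)
  expect_false(f$keep)
  f <- filter_candidates(mk_peak(0.5 + 1e-9), thr, tt$ctrl, tt$test)
  expect_true(f$pass_rmsd && f$keep)

  # coverage sum at either band edge fails criterion 2 (strictly between)
  at_median <- mk_tracks(3, 7)     # sum 10 == median
  f <- filter_candidates(mk_peak(1), thr, at_median$ctrl, at_median$test)
  expect_false(f$pass_cov)
  at_p95 <- mk_tracks(8, 12)       # sum 20 == p95
  f <- filter_candidates(mk_peak(1), thr, at_p95$ctrl, at_p95$test)
  expect_false(f$pass_cov)
  above_p95 <- mk_tracks(9, 13)    # sum 22 > p95
  f <- filter_candidates(mk_peak(1), thr, above_p95$ctrl, above_p95$test)
  expect_false(f$pass_cov && f$keep)

  # signal difference exactly at p90 fails criterion 3 (strict)
  at_p90 <- mk_tracks(6, 9)        # sum 15 ok, diff 3 == p90
  f <- filter_candidates(mk_peak(1), thr, at_p90$ctrl, at_p90$test)
  expect_true(f$pass_rmsd && f$pass_cov)
  expect_false(f$pass_diff)
  expect_false(f$keep)

  # TES-like peaks never survive
  pk <- mk_peak(1)
  pk$tes_like <- TRUE
  f <- filter_candidates(pk, thr, tt$ctrl, tt$test)
  expect_false(f$keep)
})

test_that("contig boundaries stop at the first sub-threshold base", {
  # profile ..0,0,5,5,5,0,0.. with p90 = 1 -> exactly the three 5s
  ctrl <- vec_track(rep(0, 9))
  test <- vec_track(c(0, 0, 0, 5, 5, 5, 0, 0, 0))
  thr <- structure(list(diff_p90 = 1), class = "threshold_set")
  pk <- data.frame(seqname = "chrI", index = 1L, pos = 5L, rmsd = 1,
                   strand = "+", strand_source = "gene", keep = TRUE,
                   stringsAsFactors = FALSE)
  ct <- build_contigs(pk, ctrl, test, thr, sample = "s")
  expect_equal(ct$start, 4L)
  expect_equal(ct$end, 6L)
  expect_equal(ct$avg_diff, 5)
  expect_equal(ct$size, 3L)
  expect_equal(score_and_rank(ct)$score, 15)
  expect_equal(ct$tss, 4L)

  # constant-difference contig: averaged difference equals that constant
  test2 <- vec_track(c(0, 0, 2, 2, 2, 2, 2, 0, 0))
  pk$pos <- 5L
  ct2 <- build_contigs(pk, ctrl, test2, thr, sample = "s")
  expect_equal(ct2$avg_diff, 2)

  # peak at the sequence start clamps and flags
  test3 <- vec_track(c(5, 5, 5, 0, 0, 0, 0, 0, 0))
  pk3 <- pk
  pk3$pos <- 1L
  ct3 <- build_contigs(pk3, ctrl, test3, thr, sample = "s")
  expect_equal(ct3$start, 1L)
  expect_true(has_flag(ct3$flags, "clamped5"))

  # degenerate single-base contig retained but flagged
  test4 <- vec_track(c(0, 0, 0, 0, 5, 0, 0, 0, 0))
  ct4 <- build_contigs(pk, ctrl, test4, thr, sample = "s")
  expect_equal(ct4$size, 1L)
  expect_true(has_flag(ct4$flags, "degenerate"))
})

test_that("contig boundaries match the naive walk on random profiles", {
  set.seed(99)
  ctrl <- vec_track(numeric(800))
  for (i in 1:10) {
    v <- pmax(0, round(rnorm(800, 1, 2), 2))
    test <- vec_track(v)
    thr_v <- ref_quantile(v, 0.9)
    thr <- structure(list(diff_p90 = thr_v), class = "threshold_set")
    ps <- which(v > thr_v)
    ps <- ps[ps > 1 & ps < 800]
    if (!length(ps)) next
    pk <- data.frame(
      seqname = "chrI", index = seq_along(ps), pos = as.integer(ps),
      rmsd = 1, strand = "+", strand_source = "gene", keep = TRUE,
      stringsAsFactors = FALSE
    )
    ct <- build_contigs(pk, ctrl, test, thr, sample = "s")
    for (r in seq_len(nrow(ct))) {
      ref <- ref_contig(v, ps[r], thr_v)
      expect_equal(ct$start[r], ref$start)
      expect_equal(ct$end[r], ref$end)
      expect_equal(ct$avg_diff[r], ref$avg, tolerance = 1e-12)
    }
  }
})

test_that("raising the contig threshold never lengthens a contig", {
  set.seed(101)
  v <- pmax(0, round(rnorm(500, 2, 2), 2))
  ctrl <- vec_track(numeric(500))
  test <- vec_track(v)
  p <- which.max(v)
  pk <- data.frame(seqname = "chrI", index = 1L, pos = as.integer(p),
                   rmsd = 1, strand = "+", strand_source = "gene",
                   keep = TRUE, stringsAsFactors = FALSE)
  sizes <- sapply(c(0.5, 1, 2, 3), function(t) {
    thr <- structure(list(diff_p90 = t), class = "threshold_set")
    build_contigs(pk, ctrl, test, thr, sample = "s")$size
  })
  expect_true(all(diff(sizes) <= 0))
})

mk_contig_df <- function(starts, ends, avgs, strand = "+") {
  data.frame(
    seqname = "chrI", start = as.integer(starts), end = as.integer(ends),
    tss = as.integer(starts), strand = strand, strand_source = "gene",
    avg_diff = avgs, size = as.integer(ends - starts + 1L), sample = "s",
    flags = "", stringsAsFactors = FALSE
  )
}

test_that("contig merging applies the proximity and fold rules strictly", {
  n <- 3000L
  mk_tr <- function(v) vec_track(v)
  # two contigs: starts 100 and 900 (delta 800), avg 2 and 5 (ratio 2.5)
  v <- numeric(n)
  v[100:400] <- 2
  v[900:1200] <- 5
  ctrl <- mk_tr(numeric(n))
  test <- mk_tr(v)
  m <- merge_contigs(mk_contig_df(c(100, 900), c(400, 1200), c(2, 5)),
                     ctrl, test)
  expect_equal(nrow(m), 1L)
  expect_equal(m$start, 100L)
  expect_equal(m$end, 1200L)
  expect_equal(m$avg_diff, mean(v[100:1200]), tolerance = 1e-12)
  expect_true(has_flag(m$flags, "merged"))

  # ratio 3.5 fails the 3-fold rule
  v2 <- numeric(n)
  v2[100:400] <- 2
  v2[900:1200] <- 7
  m2 <- merge_contigs(mk_contig_df(c(100, 900), c(400, 1200), c(2, 7)),
                      ctrl, mk_tr(v2))
  expect_equal(nrow(m2), 2L)

  # delta 5' of exactly 1000 fails the strict "< 1 kb" rule
  v3 <- numeric(n)
  v3[100:400] <- 2
  v3[1100:1400] <- 2
  m3 <- merge_contigs(mk_contig_df(c(100, 1100), c(400, 1400), c(2, 2)),
                      ctrl, mk_tr(v3))
  expect_equal(nrow(m3), 2L)
  m4 <- merge_contigs(mk_contig_df(c(100, 1099), c(400, 1400), c(2, 2)),
                      ctrl, mk_tr(v3))
  expect_equal(nrow(m4), 1L)
})

test_that("merging reaches an order-independent fixed point", {
  set.seed(55)
  n <- 6000L
  for (rep_i in 1:5) {
    k <- sample(3:7, 1)
    starts <- sort(sample(seq(1, n - 400, by = 50), k))
    ends <- starts + sample(50:350, k, replace = TRUE)
    v <- numeric(n)
    avgs <- numeric(k)
    for (i in seq_len(k)) {
      avgs[i] <- sample(1:6, 1)
      v[starts[i]:ends[i]] <- avgs[i]
    }
    ctrl <- vec_track(numeric(n))
    test <- vec_track(v)
    got <- merge_contigs(mk_contig_df(starts, ends, avgs), ctrl, test)
    got <- got[order(got$start), ]
    ref1 <- ref_merge(data.frame(start = starts, end = ends, avg = avgs), v)
    ref2 <- ref_merge(data.frame(start = starts, end = ends, avg = avgs), v,
                      order_fun = rev)
    expect_equal(got$start, ref1$start)
    expect_equal(got$end, ref1$end)
    expect_equal(ref1$start, ref2$start)
    expect_equal(ref1$end, ref2$end)
  }
})

test_that("ranking orders by score with deterministic tie-breaks", {
  df <- mk_contig_df(c(500, 100, 300), c(599, 199, 399), c(1, 3, 2))
  df$avg_diff <- c(10, 30, 20) / 100
  r <- score_and_rank(df)
  expect_equal(r$score, r$avg_diff * r$size)
  expect_equal(r$start[r$rank], c(100L, 300L, 500L))

  # equal scores: 5'-most coordinate wins
  df2 <- mk_contig_df(c(700, 200), c(799, 299), c(2, 2))
  r2 <- score_and_rank(df2)
  expect_equal(r2$start[r2$rank == 1L], 200L)
})
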