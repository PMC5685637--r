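toy_counts <- function() {
  # consensus GCAT
  rbind(
    A = c(0, 0, 12, 0),
    C = c(0, 12, 0, 0),
    G = c(12, 0, 0, 0),
    T = c(0, 0, 0, 12)
  )
}

test_that("PWM loading builds log-odds with correct score bounds", {
  m <- load_pwm(write_pfm(toy_counts(), "TOY"))
  expect_equal(m$name, "TOY")
  expect_equal(m$length, 4L)
  expect_equal(m$consensus, "GCAT")
  expect_equal(m$min_score, sum(apply(m$mat, 2, min)))
  expect_equal(m$max_score, sum(apply(m$mat, 2, max)))
  # direct log-odds oracle for one cell: p = (12 + .25)/(12 + 1), bg 1/4
  expect_equal(unname(m$mat["G", 1]), log((12.25 / 13) / 0.25),
               tolerance = 1e-12)
  expect_equal(unname(m$mat["A", 1]), log((0.25 / 13) / 0.25),
               tolerance = 1e-12)

  # degenerate (all-equal columns) motifs are refused at load
  flat <- matrix(3, 4, 5, dimnames = list(c("A", "C", "G", "T"), NULL))
  expect_error(load_pwm(write_pfm(flat)), "degenerate")
  # malformed: not 4 rows
  bad <- write_tmp(c(">X", "A [ 1 2 ]", "C [ 1 2 ]", "G [ 1 2 ]"))
  expect_error(load_pwm(bad), "4 matrix rows")
})

test_that("scanning finds consensus at relative score 1 and nothing at 0", {
  m <- load_pwm(write_pfm(toy_counts()))
  hits <- scan_motif("TTGCATTT", m)
  expect_equal(nrow(hits[hits$strand == "+", ]), 1L)
  expect_equal(hits$offset[hits$strand == "+"], 3L)
  expect_equal(hits$rel_score[hits$strand == "+"], 1, tolerance = 1e-12)

  # reverse-complement of the consensus hits on the minus strand
  hits_rc <- scan_motif("TTATGCTT", m)
  expect_equal(hits_rc$strand, "-")
  expect_equal(hits_rc$offset, 3L)
  expect_equal(hits_rc$rel_score, 1, tolerance = 1e-12)

  # anti-consensus scores relative 0 on the forward strand
  anti <- paste(c("C", "G", "T", "G"), collapse = "") # worst at each column
  all_sc <- attr(scan_motif(anti, m, threshold = 1.01), "best")
  expect_true(all_sc < 1)

  expect_warning(empty <- scan_motif("GC", m), "shorter")
  expect_equal(nrow(empty), 0L)
})

test_that("scan equals exhaustive brute-force scoring on random sequences", {
  set.seed(202)
  m <- load_pwm(write_pfm(matrix(sample(0:9, 24, TRUE), 4,
                                 dimnames = list(c("A", "C", "G", "T"), NULL))))
  for (i in 1:5) {
    s <- paste(sample(c("A", "C", "G", "T", "N"), 40, TRUE,
                      prob = c(.24, .24, .24, .24, .04)), collapse = "")
    got <- scan_motif(s, m, threshold = -Inf)
    ref <- ref_scan_best(s, m)
    got <- got[order(got$offset, got$strand), ]
    ref <- ref[order(ref$offset, ref$strand), ]
    expect_equal(got$score, ref$score, tolerance = 1e-12)
    expect_equal(got$offset, ref$offset)
    expect_equal(got$strand, ref$strand)
  }
})

test_that("scanning is reverse-complement symmetric", {
  set.seed(203)
  m <- load_pwm(write_pfm(toy_counts()))
  for (i in 1:5) {
    s <- paste(sample(c("A", "C", "G", "T"), 60, TRUE), collapse = "")
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    a <- scan_motif(s, m, threshold = -Inf)
    b <- scan_motif(rc, m, threshold = -Inf)
    expect_equal(sort(a$score), sort(b$score), tolerance = 1e-12)
  }
})

test_that("relative score ignores per-column constants; threshold is strict", {
  base <- matrix(c(0, 1, 2, 4,
                   3, 0, 1, 2,
                   0, 0, 0, 0,
                   1, 2, 3, 0), 4, byrow = TRUE,
                 dimnames = list(c("A", "C", "G", "T"), NULL))
  m1 <- motif_model(base)
  m2 <- motif_model(sweep(base, 2, c(5, -2, 0.5, 1), "+"))
  s <- "ACGTACGTACG"
  h1 <- scan_motif(s, m1, threshold = -Inf)
  h2 <- scan_motif(s, m2, threshold = -Inf)
  expect_equal(h1$rel_score, h2$rel_score, tolerance = 1e-12)

  # a site at exactly the threshold fraction is not a hit
  # (C scores 17/20 = 0.85 forward; its reverse complement G scores 0.5)
  mt <- motif_model(rbind(A = 20, C = 17, G = 10, T = 0))
  expect_equal(nrow(scan_motif("C", mt, threshold = 0.85)), 0L) # rel = 0.85
  expect_equal(nrow(scan_motif("A", mt, threshold = 0.85)), 1L) # rel = 1
  expect_equal(scan_motif("G", mt, threshold = -Inf)$rel_score[1], 0.5)
})

test_that("upstream flagging anchors at the 3' end of the TSS range", {
  m <- load_pwm(write_pfm(toy_counts()))
  n <- 2000L
  chars <- rep("T", n)
  annot <- one_gene_annot(start = 1001L, end = 1900L, strand = "+")
  # call at +535±11 -> anchor offset 546 -> genomic anchor 1546;
  # window is [1246, 1545]; plant the motif at its center
  chars[1400:1403] <- c("G", "C", "A", "T")
  genome <- Biostrings::DNAStringSet(c(chrI = paste(chars, collapse = "")))
  call <- data.frame(
    gene_id = "G1", seqname = "chrI", host_strand = "+",
    orf_start = 1001L, orf_end = 1900L, tss = 1536L, tss_range = 11L,
    offset = 535L, stringsAsFactors = FALSE
  )
  fl <- flag_upstream_sites(call, genome, m, window = 300L, prefix = "mse")
  expect_true(fl$mse_hit)

  # motif just outside the window (301 nt upstream of the anchor) is missed
  chars2 <- rep("T", n)
  chars2[1242:1245] <- c("G", "C", "A", "T") # window starts at 1246
  genome2 <- Biostrings::DNAStringSet(c(chrI = paste(chars2, collapse = "")))
  fl2 <- flag_upstream_sites(call, genome2, m, window = 300L, prefix = "mse")
  expect_false(fl2$mse_hit)
  # ... and the same motif one base later is caught
  chars3 <- rep("T", n)
  chars3[1246:1249] <- c("G", "C", "A", "T")
  genome3 <- Biostrings::DNAStringSet(c(chrI = paste(chars3, collapse = "")))
  expect_true(flag_upstream_sites(call, genome3, m, window = 300L,
                                  prefix = "mse")$mse_hit)
})

test_that("exact enrichment reproduces hand-enumerated hypergeometrics", {
  # table [[3,1],[1,3]]: p = 34/70 by exhaustive enumeration
  e <- exact_enrichment(3, 4, 1, 4)
  expect_equal(e$p, 34 / 70, tolerance = 1e-12)

  # identical proportions -> p = 1
  expect_equal(exact_enrichment(2, 4, 2, 4)$p, 1)

  # invalid margins error
  expect_error(exact_enrichment(5, 4, 1, 4), "margins")
  expect_error(exact_enrichment(-1, 4, 1, 4), "non-negative")

  # agrees with the independent base-R implementation on random tables
  set.seed(303)
  for (i in 1:25) {
    n <- sample(2:12, 1)
    N <- sample(2:40, 1)
    k <- sample(0:n, 1)
    K <- sample(0:N, 1)
    e <- exact_enrichment(k, n, K, N)
    ft <- fisher.test(matrix(c(k, n - k, K, N - K), 2, byrow = TRUE))
    expect_equal(e$p, ft$p.value, tolerance = 1e-9,
                 label = sprintf("k=%d n=%d K=%d N=%d", k, n, K, N))
  }
})

test_that("over-representation p is monotone in the hit count", {
  ps <- sapply(0:6, function(k) exact_enrichment(k, 6, 3, 10)$p_over)
  expect_true(all(diff(ps) < 0))
})
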