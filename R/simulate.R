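# Synthetic genomes, annotations and coverage tracks with known ground
# truth: genes with basal transcription in the control, subsets gaining an
# internally initiated transcript in the test samples, TES-shift decoys,
# masked high-signal contaminant features, and per-base count noise.

#' Simulation specification
#'
#' Defines the study conditions of a synthetic dataset. Defaults describe a
#' ~1 Mb genome of 200 well-spaced genes with long-tailed basal expression,
#' 20 of them gaining a mid-ORF internal TSS in every test sample, with
#' negative-binomial count noise.
#'
#' @param seed RNG seed; fixed seed implies byte-identical outputs.
#' @param chrom_count,genes_per_chrom genome shape (default 4 x 50 genes).
#' @param gene_length,intergenic_gap uniform integer bounds in nt (defaults
#'   1000-3000 and 2000-3000; wide spacing keeps adjacent-gene bleed-through
#'   out of the picture by construction).
#' @param chrom_margin gene-free margin at each chromosome end (nt).
#' @param basal_meanlog,basal_sdlog lognormal basal depth across genes
#'   (default median 30, sdlog 1: the long-tailed expression distribution
#'   typical of RNA-seq).
#' @param background_depth mean depth of pervasive background signal.
#' @param induced_count genes gaining an internal TSS in test samples.
#' @param induced_basal uniform bounds of induced genes' basal depth
#'   (default 20-50: the mid-expression band the coverage-sum filter
#'   targets).
#' @param induced_fold uniform bounds of the induction fold (> 1; default
#'   4-5).
#' @param tss_frac internal TSS position as a fraction of ORF length
#'   (default 0.3-0.7, which respects the 75-nt internality margin for all
#'   gene lengths).
#' @param decoy_count,decoy_frac TES-decoy genes: in test samples they lose
#'   coverage 3' of a point at `decoy_frac` of their length.
#' @param test_samples number of test samples (default 3).
#' @param tss_jitter per-sample, per-gene uniform jitter of the induced
#'   plateau start in nt (default 5), exercising the TSS-range logic.
#' @param noise `"nb"` (negative binomial), `"poisson"`, or `"none"`
#'   (exact means).
#' @param nb_size negative-binomial size (dispersion) parameter.
#' @param motif consensus sequence planted 5' of each internal TSS
#'   (transcription-strand-aware).
#' @param motif_gap distance between the planted motif's 3' end and the TSS
#'   (default 120 nt, a mid-promoter position).
#' @param excluded_count,excluded_length,excluded_depth high-signal decoy
#'   features (rRNA-like) masked by the exclusion BED.
#' @return a `sim_spec` object.
#' @export
sim_spec <- function(seed = 1L, chrom_count = 4L, genes_per_chrom = 50L,
                     gene_length = c(1000L, 3000L),
                     intergenic_gap = c(2000L, 3000L), chrom_margin = 3000L,
                     basal_meanlog = log(30), basal_sdlog = 1,
                     background_depth = 2, induced_count = 20L,
                     induced_basal = c(20, 50), induced_fold = c(4, 5),
                     tss_frac = c(0.3, 0.7), decoy_count = 0L,
                     decoy_frac = c(0.4, 0.7), test_samples = 3L,
                     tss_jitter = 5L, noise = c("nb", "poisson", "none"),
                     nb_size = 10, motif = "GCACAAAAT", motif_gap = 120L,
                     excluded_count = 2L, excluded_length = 500L,
                     excluded_depth = 5000) {
  noise <- match.arg(noise)
  problems <- character(0)
  n_genes <- chrom_count * genes_per_chrom
  if (induced_count + decoy_count > n_genes) {
    problems <- c(problems, "induced_count + decoy_count exceeds gene count")
  }
  if (any(induced_fold <= 1)) {
    problems <- c(problems, "induced_fold must be > 1")
  }
  if (tss_frac[1] * gene_length[1] < 75 + tss_jitter) {
    problems <- c(problems, "tss_frac/gene_length violate the 75-nt margin")
  }
  if ((1 - tss_frac[2]) * gene_length[1] < 75 + tss_jitter) {
    problems <- c(problems, "tss_frac upper bound violates the 75-nt margin")
  }
  if (tss_frac[1] * gene_length[1] <= motif_gap + nchar(motif)) {
    problems <- c(problems, "no room for the planted motif inside the ORF")
  }
  if (test_samples < 1) problems <- c(problems, "need >= 1 test sample")
  if (length(problems)) {
    stop("invalid sim_spec: ", paste(problems, collapse = "; "))
  }
  structure(
    list(
      seed = as.integer(seed), chrom_count = as.integer(chrom_count),
      genes_per_chrom = as.integer(genes_per_chrom),
      gene_length = as.integer(gene_length),
      intergenic_gap = as.integer(intergenic_gap),
      chrom_margin = as.integer(chrom_margin),
      basal_meanlog = basal_meanlog, basal_sdlog = basal_sdlog,
      background_depth = background_depth,
      induced_count = as.integer(induced_count),
      induced_basal = induced_basal, induced_fold = induced_fold,
      tss_frac = tss_frac, decoy_count = as.integer(decoy_count),
      decoy_frac = decoy_frac, test_samples = as.integer(test_samples),
      tss_jitter = as.integer(tss_jitter), noise = noise, nb_size = nb_size,
      motif = toupper(motif), motif_gap = as.integer(motif_gap),
      excluded_count = as.integer(excluded_count),
      excluded_length = as.integer(excluded_length),
      excluded_depth = excluded_depth
    ),
    class = "sim_spec"
  )
}

with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

draw_counts <- function(mu, spec) {
  switch(
    spec$noise,
    nb = stats::rnbinom(length(mu), size = spec$nb_size, mu = mu),
    poisson = stats::rpois(length(mu), mu),
    none = mu
  )
}

#' Generate a synthetic dataset with ground truth
#'
#' Writes genome FASTA, GFF3 annotation, exclusion BED, control bedGraph,
#' one bedGraph per test sample, and the truth table (TSV + JSON) into
#' `dir`. Control coverage is a per-gene plateau of basal depth over a low
#' background; each test sample adds, for induced genes, a plateau of
#' `basal * (fold - 1)` from the (jittered) planted internal TSS to the
#' gene's 3' end; TES-decoy genes lose their basal coverage 3' of the
#' planted end site. The motif consensus is written into the genome just
#' upstream of each planted TSS. Deterministic given the spec seed.
#'
#' @param spec a [sim_spec()].
#' @param dir output directory (created if needed).
#' @return list with `dir`, `paths` (named file paths), `truth` (data
#'   frame), `layout`, `spec`.
#' @export
simulate_dataset <- function(spec, dir = tempfile("itss_sim_")) {
  stopifnot(inherits(spec, "sim_spec"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  with_seed(spec$seed, {
    n_genes <- spec$chrom_count * spec$genes_per_chrom
    chroms <- sprintf("chr%s", utils::as.roman(seq_len(spec$chrom_count)))

    gene_rows <- list()
    chr_lens <- integer(spec$chrom_count)
    gid <- 0L
    for (ci in seq_len(spec$chrom_count)) {
      pos <- spec$chrom_margin + 1L
      for (g in seq_len(spec$genes_per_chrom)) {
        gid <- gid + 1L
        len <- sample(spec$gene_length[1]:spec$gene_length[2], 1L)
        gene_rows[[gid]] <- data.frame(
          gene_id = sprintf("G%04d", gid),
          gene_name = sprintf("SYN%d", gid),
          seqname = chroms[ci], start = pos, end = pos + len - 1L,
          length = len,
          strand = sample(c("+", "-"), 1L), stringsAsFactors = FALSE
        )
        pos <- pos + len - 1L +
          sample(spec$intergenic_gap[1]:spec$intergenic_gap[2], 1L)
      }
      chr_lens[ci] <- pos + spec$chrom_margin
    }
    genes <- do.call(rbind, gene_rows)
    layout <- genome_layout(stats::setNames(chr_lens, chroms))

    genes$basal <- stats::rlnorm(n_genes, spec$basal_meanlog, spec$basal_sdlog)
    induced <- sample.int(n_genes, spec$induced_count)
    decoys <- if (spec$decoy_count > 0L) {
      sample(setdiff(seq_len(n_genes), induced), spec$decoy_count)
    } else {
      integer(0)
    }
    genes$induced <- seq_len(n_genes) %in% induced
    genes$decoy <- seq_len(n_genes) %in% decoys
    genes$basal[induced] <- stats::runif(
      spec$induced_count, spec$induced_basal[1], spec$induced_basal[2]
    )
    genes$fold <- NA_real_
    genes$fold[induced] <- stats::runif(
      spec$induced_count, spec$induced_fold[1], spec$induced_fold[2]
    )
    genes$tss <- NA_integer_
    frac <- stats::runif(spec$induced_count, spec$tss_frac[1], spec$tss_frac[2])
    genes$tss[induced] <- ifelse(
      genes$strand[induced] == "+",
      genes$start[induced] + as.integer(round_half_up(frac * (genes$length[induced] - 1L))),
      genes$end[induced] - as.integer(round_half_up(frac * (genes$length[induced] - 1L)))
    )
    genes$tes_pos <- NA_integer_
    if (length(decoys)) {
      dfr <- stats::runif(spec$decoy_count, spec$decoy_frac[1],
                          spec$decoy_frac[2])
      genes$tes_pos[decoys] <- ifelse(
        genes$strand[decoys] == "+",
        genes$start[decoys] + as.integer(round_half_up(dfr * (genes$length[decoys] - 1L))),
        genes$end[decoys] - as.integer(round_half_up(dfr * (genes$length[decoys] - 1L)))
      )
    }

    # Genome with the motif consensus planted upstream of each planted TSS.
    seqs <- lapply(chr_lens, function(n) {
      sample(c("A", "C", "G", "T"), n, replace = TRUE)
    })
    names(seqs) <- chroms
    mot <- strsplit(spec$motif, "")[[1]]
    mot_rc <- rev(c(A = "T", C = "G", G = "C", T = "A")[mot])
    genes$motif_start <- NA_integer_
    for (i in induced) {
      sq <- genes$seqname[i]
      t <- genes$tss[i]
      if (genes$strand[i] == "+") {
        s <- t - spec$motif_gap - length(mot) + 1L
        seqs[[sq]][s:(s + length(mot) - 1L)] <- mot
      } else {
        s <- t + spec$motif_gap
        seqs[[sq]][s:(s + length(mot) - 1L)] <- mot_rc
      }
      genes$motif_start[i] <- s
    }
    genome <- Biostrings::DNAStringSet(vapply(seqs, paste, "", collapse = ""))

    # Masked high-signal decoy features in the gene-free chromosome-end
    # margins.
    excl <- NULL
    if (spec$excluded_count > 0L) {
      ci <- rep(seq_len(spec$chrom_count),
                length.out = spec$excluded_count)
      s <- chr_lens[ci] - spec$chrom_margin + 500L
      excl <- data.frame(
        seqname = chroms[ci], start = as.integer(s),
        end = as.integer(s + spec$excluded_length - 1L),
        stringsAsFactors = FALSE
      )
    }

    # Mean-depth vectors, then per-sample counts.
    mu_ctrl <- lapply(chr_lens, function(n) rep(spec$background_depth, n))
    names(mu_ctrl) <- chroms
    for (i in seq_len(n_genes)) {
      sq <- genes$seqname[i]
      mu_ctrl[[sq]][genes$start[i]:genes$end[i]] <-
        mu_ctrl[[sq]][genes$start[i]:genes$end[i]] + genes$basal[i]
    }
    if (!is.null(excl)) {
      for (i in seq_len(nrow(excl))) {
        sq <- excl$seqname[i]
        mu_ctrl[[sq]][excl$start[i]:excl$end[i]] <-
          mu_ctrl[[sq]][excl$start[i]:excl$end[i]] + spec$excluded_depth
      }
    }

    paths <- list(
      genome = file.path(dir, "genome.fa"),
      annotation = file.path(dir, "genes.gff3"),
      exclusions = file.path(dir, "exclude.bed"),
      control = file.path(dir, "control.bedGraph"),
      tests = file.path(dir, sprintf("test_%d.bedGraph",
                                     seq_len(spec$test_samples))),
      truth_tsv = file.path(dir, "truth.tsv"),
      truth_json = file.path(dir, "truth.json")
    )

    ctrl_counts <- lapply(mu_ctrl, function(mu) draw_counts(mu, spec))
    write_bedgraph(
      coverage_track(ctrl_counts, layout, sample = "control"),
      paths$control
    )

    for (s_i in seq_len(spec$test_samples)) {
      mu <- mu_ctrl
      for (i in induced) {
        sq <- genes$seqname[i]
        jit <- if (spec$tss_jitter > 0L) {
          sample((-spec$tss_jitter):spec$tss_jitter, 1L)
        } else {
          0L
        }
        t <- genes$tss[i] + jit
        extra <- genes$basal[i] * (genes$fold[i] - 1)
        reg <- if (genes$strand[i] == "+") t:genes$end[i] else genes$start[i]:t
        mu[[sq]][reg] <- mu[[sq]][reg] + extra
      }
      for (i in decoys) {
        sq <- genes$seqname[i]
        reg <- if (genes$strand[i] == "+") {
          genes$tes_pos[i]:genes$end[i]
        } else {
          genes$start[i]:genes$tes_pos[i]
        }
        mu[[sq]][reg] <- pmax(0, mu[[sq]][reg] - genes$basal[i])
      }
      counts <- lapply(mu, function(m) draw_counts(m, spec))
      write_bedgraph(
        coverage_track(counts, layout, sample = sprintf("test_%d", s_i)),
        paths$tests[s_i]
      )
    }

    Biostrings::writeXStringSet(genome, paths$genome)
    write_gff3(genes, paths$annotation, layout)
    if (!is.null(excl)) {
      write_bed3(excl, paths$exclusions)
    } else {
      writeLines(character(0), paths$exclusions)
    }
    utils::write.table(genes, paths$truth_tsv, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    jsonlite::write_json(genes, paths$truth_json, dataframe = "rows",
                         na = "null")

    list(dir = dir, paths = paths, truth = genes, layout = layout,
         spec = spec)
  })
}

#' Score internal-TSS calls against simulation truth
#'
#' A call is a true positive iff its host gene was induced and its
#' consensus TSS lies within `tolerance` nt of the planted TSS. Precision
#' is over calls, recall over planted genes; with zero calls precision is
#' reported as 1 with a `vacuous` flag.
#'
#' @param calls an `internal_tss_calls` data frame.
#' @param truth the `truth` data frame from [simulate_dataset()].
#' @param tolerance positional tolerance in nt (default 100).
#' @return list: `precision`, `recall`, `mean_abs_error`, `tp`, `n_calls`,
#'   `n_planted`, `vacuous_precision`.
#' @export
score_against_truth <- function(calls, truth, tolerance = 100) {
  planted <- truth[truth$induced, , drop = FALSE]
  n_calls <- nrow(calls)
  if (n_calls) {
    m <- match(calls$gene_id, truth$gene_id)
    tp <- !is.na(m) & truth$induced[m] &
      abs(calls$tss - truth$tss[m]) <= tolerance
    err <- abs(calls$tss - truth$tss[m])[tp]
  } else {
    tp <- logical(0)
    err <- numeric(0)
  }
  recall <- if (nrow(planted)) {
    length(unique(calls$gene_id[tp])) / nrow(planted)
  } else {
    NA_real_
  }
  list(
    precision = if (n_calls) sum(tp) / n_calls else 1,
    recall = recall,
    mean_abs_error = if (length(err)) mean(err) else NA_real_,
    tp = sum(tp), n_calls = n_calls, n_planted = nrow(planted),
    vacuous_precision = n_calls == 0L
  )
}
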