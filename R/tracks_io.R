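# On-disk formats: bedGraph, GFF3, BED, FASTA.

# Split raw lines into whitespace-delimited field matrix, reporting the
# 1-based file line number of the first malformed line.
split_fields <- function(lines, line_no, n_fields, what) {
  flds <- strsplit(trimws(lines), "[ \t]+")
  nf <- lengths(flds)
  bad <- which(nf < n_fields)
  if (length(bad)) {
    stop(
      what, " parse error at line ", line_no[bad[1]], ": expected at least ",
      n_fields, " fields, found ", nf[bad[1]]
    )
  }
  matrix(
    unlist(lapply(flds, `[`, seq_len(n_fields)), use.names = FALSE),
    ncol = n_fields, byrow = TRUE
  )
}

num_field <- function(x, line_no, what, field) {
  suppressWarnings(v <- as.numeric(x))
  bad <- which(is.na(v) & !is.na(x))
  if (length(bad)) {
    stop(
      what, " parse error at line ", line_no[bad[1]],
      ": non-numeric ", field, " '", x[bad[1]], "'"
    )
  }
  v
}

#' Read a bedGraph coverage file
#'
#' Reads a 4-column bedGraph (0-based, half-open intervals) into a per-base
#' [coverage_track()]. Positions not covered by any interval get value 0;
#' overlapping intervals are an error, as are intervals outside the layout.
#'
#' @param path bedGraph file.
#' @param layout a [genome_layout()] giving the coordinate space.
#' @param sample sample label (defaults to the file name).
#' @return a `coverage_track`.
#' @export
read_bedgraph <- function(path, layout,
                          sample = sub("\\.[^.]*$", "", basename(path))) {
  lines <- readLines(path)
  line_no <- seq_along(lines)
  keep <- nzchar(trimws(lines)) & !grepl("^(#|track\\b|browser\\b)", lines)
  lines <- lines[keep]
  line_no <- line_no[keep]

  vals <- lapply(layout$lengths, function(n) numeric(n))

  if (length(lines)) {
    m <- split_fields(lines, line_no, 4L, "bedGraph")
    chrom <- m[, 1]
    start0 <- num_field(m[, 2], line_no, "bedGraph", "start")
    end0 <- num_field(m[, 3], line_no, "bedGraph", "end")
    value <- num_field(m[, 4], line_no, "bedGraph", "value")

    unknown <- which(!chrom %in% seq_names(layout))
    if (length(unknown)) {
      stop(
        "bedGraph line ", line_no[unknown[1]], ": unknown sequence '",
        chrom[unknown[1]], "'"
      )
    }
    bad <- which(start0 < 0 | end0 <= start0 |
                   start0 != floor(start0) | end0 != floor(end0))
    if (length(bad)) {
      stop(
        "bedGraph line ", line_no[bad[1]], ": invalid interval [",
        start0[bad[1]], ", ", end0[bad[1]], ")"
      )
    }
    over_end <- which(end0 > as.numeric(layout$lengths[chrom]))
    if (length(over_end)) {
      stop(
        "bedGraph line ", line_no[over_end[1]], ": interval end ",
        end0[over_end[1]], " beyond length of ", chrom[over_end[1]]
      )
    }
    if (any(!is.finite(value)) || any(value < 0)) {
      stop("bedGraph: coverage values must be finite and >= 0")
    }

    for (sq in unique(chrom)) {
      i <- which(chrom == sq)
      o <- i[order(start0[i])]
      st <- start0[o]
      en <- end0[o]
      ovl <- which(st[-1] < en[-length(en)])
      if (length(ovl)) {
        stop(
          "bedGraph: overlapping intervals on ", sq, " (line ",
          line_no[o[ovl[1] + 1L]], ")"
        )
      }
      n <- seq_len_of(layout, sq)
      gaps <- st - c(0, en[-length(en)])
      lens <- as.integer(rbind(gaps, en - st))
      vls <- as.numeric(rbind(0, value[o]))
      tail_gap <- n - en[length(en)]
      if (tail_gap > 0) {
        lens <- c(lens, as.integer(tail_gap))
        vls <- c(vls, 0)
      }
      nz <- lens > 0L
      vals[[sq]] <- inverse.rle(list(lengths = lens[nz], values = vls[nz]))
    }
  }
  coverage_track(vals, layout, sample = sample)
}

#' Write a coverage track as bedGraph
#'
#' Run-length encodes the per-base values; zero runs are omitted so that
#' `read_bedgraph(write_bedgraph(x))` reproduces the values exactly.
#'
#' @param track a `coverage_track` (or smoothed track).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (sq in names(track$values)) {
    r <- rle(track$values[[sq]])
    ends <- cumsum(r$lengths)
    starts0 <- ends - r$lengths
    nz <- r$values != 0
    if (any(nz)) {
      writeLines(sprintf(
        "%s\t%d\t%d\t%s",
        sq, starts0[nz], ends[nz], sprintf("%.17g", r$values[nz])
      ), con)
    }
  }
  invisible(path)
}

#' Read gene annotation from GFF3
#'
#' Extracts features of one type (genes by default) with their ID, span,
#' and strand. Coordinates are kept 1-based inclusive, the GFF3 convention.
#'
#' @param path GFF3 file.
#' @param feature_type feature type (column 3) to extract.
#' @param layout optional [genome_layout()]; if given, features on unknown
#'   sequences or beyond sequence ends are an error.
#' @return a `gene_annotation` data frame with columns `gene_id`, `seqname`,
#'   `start`, `end`, `strand`, `gene_name`.
#' @export
read_gff3 <- function(path, feature_type = "gene", layout = NULL) {
  lines <- readLines(path)
  line_no <- seq_along(lines)
  keep <- nzchar(trimws(lines)) & !startsWith(lines, "#")
  lines <- lines[keep]
  line_no <- line_no[keep]

  out <- data.frame(
    gene_id = character(), seqname = character(), start = integer(),
    end = integer(), strand = character(), gene_name = character(),
    stringsAsFactors = FALSE
  )
  if (length(lines)) {
    flds <- strsplit(lines, "\t", fixed = TRUE)
    nf <- lengths(flds)
    bad <- which(nf != 9L)
    if (length(bad)) {
      stop("GFF3 parse error at line ", line_no[bad[1]], ": expected 9 fields")
    }
    m <- matrix(unlist(flds, use.names = FALSE), ncol = 9L, byrow = TRUE)
    sel <- m[, 3] == feature_type
    m <- m[sel, , drop = FALSE]
    line_no <- line_no[sel]
    if (nrow(m)) {
      start <- num_field(m[, 4], line_no, "GFF3", "start")
      end <- num_field(m[, 5], line_no, "GFF3", "end")
      strand <- m[, 7]
      bad <- which(!strand %in% c("+", "-"))
      if (length(bad)) {
        stop(
          "GFF3 line ", line_no[bad[1]], ": unknown strand '",
          strand[bad[1]], "'"
        )
      }
      bad <- which(start > end | start < 1)
      if (length(bad)) {
        stop("GFF3 line ", line_no[bad[1]], ": invalid feature span")
      }
      attr9 <- m[, 9]
      idm <- regmatches(attr9, regexpr("(?:^|;)\\s*ID=[^;]+", attr9))
      has_id <- grepl("(?:^|;)\\s*ID=[^;]+", attr9)
      if (any(!has_id)) {
        stop(
          "GFF3 line ", line_no[which(!has_id)[1]],
          ": feature has no ID attribute"
        )
      }
      gene_id <- sub("^;?\\s*ID=", "", idm)
      dup <- which(duplicated(gene_id))
      if (length(dup)) {
        stop(
          "GFF3 line ", line_no[dup[1]], ": duplicate ID '",
          gene_id[dup[1]], "'"
        )
      }
      nm <- rep(NA_character_, nrow(m))
      has_nm <- grepl("(?:^|;)\\s*Name=[^;]+", attr9)
      nm[has_nm] <- sub(
        "^;?\\s*Name=", "",
        regmatches(attr9, regexpr("(?:^|;)\\s*Name=[^;]+", attr9))
      )
      if (!is.null(layout)) {
        unknown <- which(!m[, 1] %in% seq_names(layout))
        if (length(unknown)) {
          stop(
            "GFF3 line ", line_no[unknown[1]], ": unknown sequence '",
            m[unknown[1], 1], "'"
          )
        }
        over <- which(end > as.numeric(layout$lengths[m[, 1]]))
        if (length(over)) {
          stop("GFF3 line ", line_no[over[1]], ": feature beyond sequence end")
        }
      }
      out <- data.frame(
        gene_id = gene_id, seqname = m[, 1],
        start = as.integer(start), end = as.integer(end),
        strand = strand, gene_name = nm, stringsAsFactors = FALSE
      )
    }
  }
  class(out) <- c("gene_annotation", "data.frame")
  out
}

#' Write gene annotation as GFF3
#' @param annot a `gene_annotation` data frame.
#' @param path output file.
#' @param layout optional layout for `##sequence-region` headers.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(annot, path, layout = NULL) {
  hdr <- "##gff-version 3"
  if (!is.null(layout)) {
    hdr <- c(hdr, sprintf(
      "##sequence-region %s 1 %d", seq_names(layout), layout$lengths
    ))
  }
  attrs <- ifelse(
    is.na(annot$gene_name),
    sprintf("ID=%s", annot$gene_id),
    sprintf("ID=%s;Name=%s", annot$gene_id, annot$gene_name)
  )
  body <- sprintf(
    "%s\titss\tgene\t%d\t%d\t.\t%s\t.\t%s",
    annot$seqname, annot$start, annot$end, annot$strand, attrs
  )
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read an exclusion BED file
#'
#' BED intervals (0-based, half-open) naming regions to mask from coverage:
#' contaminant features such as rDNA, tRNA genes, mitochondrial DNA.
#'
#' @param path BED file (3+ columns).
#' @param layout a [genome_layout()]; intervals must lie within it.
#' @return an `exclusion_set` data frame with 1-based inclusive `start`/`end`.
#' @export
read_exclusions <- function(path, layout) {
  lines <- readLines(path)
  line_no <- seq_along(lines)
  keep <- nzchar(trimws(lines)) & !grepl("^(#|track\\b|browser\\b)", lines)
  lines <- lines[keep]
  line_no <- line_no[keep]
  out <- data.frame(
    seqname = character(), start = integer(), end = integer(),
    stringsAsFactors = FALSE
  )
  if (length(lines)) {
    m <- split_fields(lines, line_no, 3L, "BED")
    start0 <- num_field(m[, 2], line_no, "BED", "start")
    end0 <- num_field(m[, 3], line_no, "BED", "end")
    unknown <- which(!m[, 1] %in% seq_names(layout))
    if (length(unknown)) {
      stop(
        "BED line ", line_no[unknown[1]], ": unknown sequence '",
        m[unknown[1], 1], "'"
      )
    }
    bad <- which(start0 < 0 | end0 <= start0 |
                   end0 > as.numeric(layout$lengths[m[, 1]]))
    if (length(bad)) {
      stop("BED line ", line_no[bad[1]], ": interval outside layout bounds")
    }
    out <- data.frame(
      seqname = m[, 1], start = as.integer(start0 + 1),
      end = as.integer(end0), stringsAsFactors = FALSE
    )
  }
  class(out) <- c("exclusion_set", "data.frame")
  out
}

#' Write intervals as BED (3-column)
#' @param df data frame with `seqname`, `start`, `end` (1-based inclusive).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_bed3 <- function(df, path) {
  writeLines(sprintf("%s\t%d\t%d", df$seqname, df$start - 1L, df$end), path)
  invisible(path)
}

#' Read a genome FASTA
#' @param path FASTA file.
#' @return a `Biostrings::DNAStringSet` with names trimmed at the first space.
#' @export
read_genome <- function(path) {
  g <- Biostrings::readDNAStringSet(path)
  names(g) <- sub("\\s.*$", "", names(g))
  g
}

#' Layout of a genome FASTA
#' @param genome a `DNAStringSet`.
#' @return a [genome_layout()].
#' @export
layout_from_genome <- function(genome) {
  genome_layout(stats::setNames(Biostrings::width(genome), names(genome)))
}

#' Extract the sequence immediately upstream of an anchor position
#'
#' Returns the `length` nt 5' of `anchor` on the given strand (the anchor
#' base itself is not included); minus-strand sequences are
#' reverse-complemented. Windows running past a sequence end are truncated
#' with a warning and flagged rather than dropped.
#'
#' @param genome a `DNAStringSet`.
#' @param seqname sequence name.
#' @param anchor 1-based anchor position (must lie inside the sequence).
#' @param strand `"+"` or `"-"`.
#' @param length window length in nt (default 300).
#' @return list with `sequence` (character), `truncated`, `seqname`,
#'   `start`, `end`, `strand`.
#' @export
extract_upstream <- function(genome, seqname, anchor, strand, length = 300L) {
  if (!seqname %in% names(genome)) stop("unknown sequence: ", seqname)
  n <- Biostrings::width(genome[seqname])
  if (anchor < 1 || anchor > n) {
    stop("anchor ", anchor, " outside sequence ", seqname, " (1..", n, ")")
  }
  stopifnot(strand %in% c("+", "-"), length >= 1)
  if (strand == "+") {
    s <- anchor - length
    e <- anchor - 1L
  } else {
    s <- anchor + 1L
    e <- anchor + length
  }
  s2 <- max(1L, s)
  e2 <- min(n, e)
  truncated <- (s2 != s) || (e2 != e)
  if (truncated) {
    warning(
      "upstream window truncated at ", seqname, " end (",
      max(0L, e2 - s2 + 1L), " of ", length, " nt)"
    )
  }
  if (e2 < s2) {
    sq <- ""
  } else {
    x <- Biostrings::subseq(genome[[seqname]], start = s2, end = e2)
    if (strand == "-") x <- Biostrings::reverseComplement(x)
    sq <- as.character(x)
  }
  list(
    sequence = sq, truncated = truncated, seqname = seqname,
    start = if (e2 < s2) NA_integer_ else s2,
    end = if (e2 < s2) NA_integer_ else e2, strand = strand
  )
}
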