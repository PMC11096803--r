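RBS_MOTIFS <- list(
  "6-mer" = "AGGAGG",
  "5-mer" = c("AGGAG", "GGAGG"),
  "4-mer" = c("AGGA", "GGAG", "GAGG")
)

#' Annotated genome segment
#'
#' Container for one nucleotide segment with its CDS/ORF annotations.
#' Coordinates are stored 0-based half-open internally; all file interfaces
#' (GFF3) use 1-based inclusive coordinates. Minus-strand ORFs are
#' reverse-complemented into plus orientation at construction time (with a
#' warning), so downstream windowing always reads the annotation strand.
#'
#' @param segment_id unique segment identifier.
#' @param sequence nucleotide sequence, 5' to 3' (character; IUPAC DNA).
#' @param orfs data frame with columns \code{orf_id}, \code{start},
#'   \code{end} (0-based half-open), \code{strand} (\code{"+"}/\code{"-"}).
#' @param dataset_label grouping label for frequency tables (e.g.
#'   \code{"Picobirnavirus Segment 1"}).
#' @return object of class \code{annotated_segment}.
#' @export
annotated_segment <- function(segment_id, sequence, orfs, dataset_label) {
  sequence <- toupper(sequence)
  if (!grepl("^[ACGTRYSWKMBDHVN]*$", sequence))
    stopf("segment %s: sequence contains non-IUPAC characters", segment_id)
  stopifnot(is.data.frame(orfs),
            all(c("orf_id", "start", "end", "strand") %in% names(orfs)))
  L <- nchar(sequence)
  if (nrow(orfs) > 0L) {
    if (any(orfs$start < 0L | orfs$end > L | orfs$start >= orfs$end))
      stopf("segment %s: ORF coordinates out of bounds", segment_id)
    if (anyDuplicated(orfs$orf_id))
      stopf("segment %s: duplicate orf_id", segment_id)
    if (any(orfs$strand == "-")) {
      warnf("segment %s: minus-strand ORF(s) reverse-complemented into plus orientation",
            segment_id)
      sequence_rc <- revcomp_dna(sequence)
      for (i in which(orfs$strand == "-")) {
        s <- orfs$start[i]; e <- orfs$end[i]
        orfs$start[i] <- L - e; orfs$end[i] <- L - s
        orfs$strand[i] <- "+"
      }
      # segments mixing strands are not supported; a minus-strand annotation
      # flips the whole segment
      if (!all(orfs$strand == "+"))
        stopf("segment %s: mixed-strand ORFs unsupported", segment_id)
      sequence <- sequence_rc
    }
  }
  orfs <- orfs[order(orfs$start), , drop = FALSE]
  rownames(orfs) <- NULL
  structure(list(segment_id = segment_id, sequence = sequence,
                 orfs = orfs, dataset_label = dataset_label),
            class = "annotated_segment")
}

revcomp_dna <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Read annotated segments from FASTA + GFF3
#'
#' CDS features (GFF3 \code{type == "CDS"}) define the ORFs; the first codon
#' of each CDS is taken as the start codon without requiring ATG (alternative
#' genetic codes occur in these virus families).
#'
#' @param fasta_path FASTA file of segment sequences.
#' @param gff_path GFF3 file whose seqnames match the FASTA headers.
#' @param dataset_label label applied to all segments in the file.
#' @return list of \code{\link{annotated_segment}} objects.
#' @export
read_segments <- function(fasta_path, gff_path, dataset_label) {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  gff <- rtracklayer::import(gff_path, format = "gff3")
  gff <- gff[gff$type == "CDS"]
  out <- list()
  for (sid in names(seqs)) {
    g <- gff[as.character(GenomicRanges::seqnames(gff)) == sid]
    ids <- g$ID
    if (is.null(ids) || anyNA(ids)) ids <- paste0(sid, "_cds", seq_along(g))
    orfs <- data.frame(
      orf_id = as.character(ids),
      start = GenomicRanges::start(g) - 1L,   # 1-based inclusive -> 0-based half-open
      end = GenomicRanges::end(g),
      strand = as.character(GenomicRanges::strand(g)),
      stringsAsFactors = FALSE)
    orfs$strand[orfs$strand == "*"] <- "+"
    out[[length(out) + 1L]] <-
      annotated_segment(sid, as.character(seqs[[sid]]), orfs, dataset_label)
  }
  out
}

#' Write annotated segments to FASTA + GFF3
#'
#' @param segments list of \code{\link{annotated_segment}} objects.
#' @param fasta_path,gff_path output paths.
#' @return invisibly, the two paths.
#' @export
write_segments <- function(segments, fasta_path, gff_path) {
  seqs <- Biostrings::DNAStringSet(vapply(segments, `[[`, "", "sequence"))
  names(seqs) <- vapply(segments, `[[`, "", "segment_id")
  Biostrings::writeXStringSet(seqs, fasta_path)
  rows <- do.call(rbind, lapply(segments, function(s) {
    if (nrow(s$orfs) == 0L) return(NULL)
    cbind(segment_id = s$segment_id, s$orfs)
  }))
  gr <- GenomicRanges::GRanges(
    seqnames = factor(rows$segment_id, levels = names(seqs)),
    ranges = IRanges::IRanges(start = rows$start + 1L, end = rows$end),
    strand = rows$strand,
    seqlengths = stats::setNames(Biostrings::width(seqs), names(seqs)))
  gr$type <- "CDS"
  gr$ID <- rows$orf_id
  gr$phase <- 0L
  rtracklayer::export(gr, gff_path, format = "gff3")
  invisible(c(fasta = fasta_path, gff = gff_path))
}

#' Keep segments with a full upstream window before their first ORF
#'
#' A segment is retained only when its 5'-most ORF has at least
#' \code{min_utr} nucleotides of untranslated region before the start codon,
#' so the full scan window exists. Segments with no annotated ORFs are
#' dropped with a warning.
#'
#' @param segments list of \code{\link{annotated_segment}} objects.
#' @param min_utr minimum 5' UTR length (default 24).
#' @return the filtered list.
#' @export
filter_segments <- function(segments, min_utr = 24L) {
  keep <- vapply(segments, function(s) {
    if (nrow(s$orfs) == 0L) {
      warnf("segment %s has no annotated ORFs; dropped", s$segment_id)
      return(FALSE)
    }
    min(s$orfs$start) >= min_utr
  }, TRUE)
  segments[keep]
}

#' Extract the upstream window of one ORF
#'
#' Returns the \code{window} nucleotides immediately preceding the first base
#' of the ORF's start codon (the codon itself is excluded). For non-first
#' ORFs with fewer than \code{window} nucleotides available the window is
#' shortened to what exists and flagged via the \code{"truncated"} attribute.
#'
#' @param segment an \code{\link{annotated_segment}}.
#' @param orf_id which ORF.
#' @param window window length (default 24).
#' @return character string of length at most \code{window}.
#' @export
extract_upstream <- function(segment, orf_id, window = 24L) {
  i <- match(orf_id, segment$orfs$orf_id)
  if (is.na(i)) stopf("segment %s: unknown orf_id '%s'", segment$segment_id, orf_id)
  s <- segment$orfs$start[i]
  from <- max(0L, s - window)
  w <- substr(segment$sequence, from + 1L, s)
  attr(w, "truncated") <- (s - from) < window
  w
}

#' Classify a window by its longest Shine-Dalgarno motif
#'
#' Searches the window for the full AGGAGG hexamer, then the 5-mers AGGAG and
#' GGAGG, then the 4-mers AGGA, GGAG and GAGG; the longest class with a match
#' wins, so classes are mutually exclusive and their counts are additive.
#' Matching is exact (ambiguity codes never match) and must lie wholly inside
#' the window. The leftmost match of the winning class is reported.
#'
#' @param window a DNA string (typically 24 nt).
#' @param orf_id optional identifier copied into the result.
#' @return list of class \code{motif_hit}: \code{orf_id}, \code{motif_class}
#'   (\code{"6-mer"}, \code{"5-mer"}, \code{"4-mer"} or \code{"none"}),
#'   \code{motif} (matched string or \code{NA}), \code{offset} (0-based
#'   position of the match in the window, or \code{NA}).
#' @export
classify_window <- function(window, orf_id = NA_character_) {
  window <- toupper(window)
  for (cls in names(RBS_MOTIFS)) {
    hits <- vapply(RBS_MOTIFS[[cls]],
                   function(m) regexpr(m, window, fixed = TRUE)[[1]], 0L)
    hits <- hits[hits > 0L]
    if (length(hits) > 0L) {
      best <- which.min(hits)
      return(structure(list(orf_id = orf_id, motif_class = cls,
                            motif = names(hits)[best],
                            offset = unname(hits[best]) - 1L),
                       class = "motif_hit"))
    }
  }
  structure(list(orf_id = orf_id, motif_class = "none",
                 motif = NA_character_, offset = NA_integer_),
            class = "motif_hit")
}

#' Scan all ORFs of a segment set
#'
#' @param segments list of \code{\link{annotated_segment}} objects (already
#'   filtered with \code{\link{filter_segments}}).
#' @param window window length (default 24).
#' @return data frame with one row per ORF: \code{dataset_label},
#'   \code{segment_id}, \code{orf_id}, \code{motif_class}, \code{motif},
#'   \code{offset}, \code{window}.
#' @export
scan_segments <- function(segments, window = 24L) {
  rows <- list()
  for (s in segments) {
    for (i in seq_len(nrow(s$orfs))) {
      w <- extract_upstream(s, s$orfs$orf_id[i], window)
      hit <- classify_window(w, s$orfs$orf_id[i])
      rows[[length(rows) + 1L]] <- data.frame(
        dataset_label = s$dataset_label, segment_id = s$segment_id,
        orf_id = hit$orf_id, motif_class = hit$motif_class,
        motif = hit$motif %||% NA_character_,
        offset = hit$offset %||% NA_integer_,
        window = as.character(w), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Per-dataset RBS motif frequency table
#'
#' Aggregates the per-ORF motif classes into counts and percentages per
#' dataset label, mirroring the usual published layout: sequences, ORFs,
#' total ORFs with any motif, then the mutually exclusive 4-mer / 5-mer /
#' 6-mer classes. Percentages are 100 * count / n_orfs rounded half-up to one
#' decimal.
#'
#' @param segments list of \code{\link{annotated_segment}} objects.
#' @param window window length (default 24).
#' @return object of class \code{rbs_frequency_table}: a data frame with
#'   columns \code{dataset_label}, \code{n_sequences}, \code{n_orfs},
#'   \code{n_total}, \code{pct_total}, \code{n_4mer}, \code{pct_4mer},
#'   \code{n_5mer}, \code{pct_5mer}, \code{n_6mer}, \code{pct_6mer}, plus the
#'   per-ORF scan in attribute \code{"hits"}.
#' @export
frequency_table <- function(segments, window = 24L) {
  hits <- scan_segments(segments, window)
  labs <- unique(vapply(segments, `[[`, "", "dataset_label"))
  rows <- lapply(labs, function(lab) {
    segs <- segments[vapply(segments, function(s) s$dataset_label == lab, TRUE)]
    h <- hits[hits$dataset_label == lab, , drop = FALSE]
    n_orfs <- nrow(h)
    if (n_orfs == 0L) warnf("dataset '%s' has no ORFs", lab)
    cnt <- function(cls) sum(h$motif_class == cls)
    n4 <- cnt("4-mer"); n5 <- cnt("5-mer"); n6 <- cnt("6-mer")
    ntot <- n4 + n5 + n6
    pct <- function(k) if (n_orfs == 0L) NA_real_ else round_half_up(100 * k / n_orfs, 1)
    data.frame(dataset_label = lab, n_sequences = length(segs),
               n_orfs = n_orfs,
               n_total = ntot, pct_total = pct(ntot),
               n_4mer = n4, pct_4mer = pct(n4),
               n_5mer = n5, pct_5mer = pct(n5),
               n_6mer = n6, pct_6mer = pct(n6),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, hits = hits, class = c("rbs_frequency_table", "data.frame"))
}

#' @export
print.rbs_frequency_table <- function(x, ...) {
  df <- as.data.frame(x)
  cat("RBS motif frequencies (percent of annotated ORFs, half-up to 1 dp):\n")
  for (i in seq_len(nrow(df))) {
    cat(sprintf("  %-28s seqs %4d  ORFs %4d | any %4d (%.1f) | 4-mer %4d (%.1f) | 5-mer %4d (%.1f) | 6-mer %4d (%.1f)\n",
                df$dataset_label[i], df$n_sequences[i], df$n_orfs[i],
                df$n_total[i], df$pct_total[i], df$n_4mer[i], df$pct_4mer[i],
                df$n_5mer[i], df$pct_5mer[i], df$n_6mer[i], df$pct_6mer[i]))
  }
  invisible(x)
}
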