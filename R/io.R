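## Readers and writers for the plain-text formats the pipeline touches.
## Internal convention: all coordinates 0-based half-open; 1-based inclusive
## inputs (show-coords, VCF, RepeatMasker .out) are converted at the boundary.

#' Read per-individual contigs from FASTA
#'
#' Headers must follow \code{IndividualXYZ_I}: the individual id is everything
#' before the last underscore, so individual ids may themselves contain
#' underscores. Sequences are uppercased.
#'
#' @param path FASTA file.
#' @return A \code{\linkS4class{ContigSet}}.
#' @export
#' @examples
#' f <- tempfile(fileext = ".fa")
#' writeLines(c(">SweGen0010_1572", "acgt"), f)
#' cs <- readContigFasta(f)
#' individualIds(cs)  # "SweGen0010"
readContigFasta <- function(path) {
  stopifnot(file.exists(path))
  seqs <- Biostrings::readDNAStringSet(path)
  if (length(seqs) == 0L) return(ContigSet(Biostrings::DNAStringSet()))
  ## keep only the first whitespace-delimited token of each header
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  if (any(Biostrings::width(seqs) == 0L))
    stop("empty sequence for record(s): ",
         paste(names(seqs)[Biostrings::width(seqs) == 0L], collapse = ", "))
  bad <- !grepl("_", names(seqs), fixed = TRUE)
  if (any(bad))
    stop("malformed header (no underscore) in record(s): ",
         paste(names(seqs)[bad], collapse = ", "))
  ContigSet(Biostrings::DNAStringSet(toupper(as.character(seqs))))
}

#' Write contigs to FASTA
#'
#' @param contigs A \code{ContigSet}.
#' @param path Output file.
#' @return \code{path}, invisibly.
#' @export
writeContigFasta <- function(contigs, path) {
  Biostrings::writeXStringSet(contigSequences(contigs), path, width = 80L)
  invisible(path)
}

#' Read a show-coords alignment table
#'
#' Parses the headerless tab-separated dialect produced by
#' \command{show-coords -H -T -c}: columns S1 E1 S2 E2 LEN1 LEN2 \%IDY \%COVR
#' \%COVQ TAGR TAGQ, where S1/E1 are 1-based inclusive target coordinates and
#' S2/E2 query coordinates. Rows with S1 > E1 are minus-strand hits and are
#' reported with swapped, ascending target coordinates. All coordinates are
#' converted to 0-based half-open.
#'
#' @param path Tab-separated file, no header.
#' @return data.frame of alignment hits: query_id, target_id, query_start,
#'   query_end, target_start, target_end, strand, identity_pct,
#'   query_cov_pct, target_cov_pct.
#' @export
readCoordsTable <- function(path) {
  stopifnot(file.exists(path))
  empty <- data.frame(query_id = character(0), target_id = character(0),
                      query_start = integer(0), query_end = integer(0),
                      target_start = integer(0), target_end = integer(0),
                      strand = character(0), identity_pct = numeric(0),
                      query_cov_pct = numeric(0), target_cov_pct = numeric(0),
                      stringsAsFactors = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) return(empty)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != 11L))
    stop("wrong column count (expected 11) at line ", which(nf != 11L)[1])
  m <- do.call(rbind, parts)
  s1 <- as.integer(m[, 1]); e1 <- as.integer(m[, 2])
  s2 <- as.integer(m[, 3]); e2 <- as.integer(m[, 4])
  minus <- s1 > e1
  ts <- ifelse(minus, e1, s1); te <- ifelse(minus, s1, e1)
  ## query coordinates may also arrive reversed on minus-strand rows
  qs <- pmin(s2, e2); qe <- pmax(s2, e2)
  data.frame(query_id = m[, 11], target_id = m[, 10],
             query_start = qs - 1L, query_end = qe,
             target_start = ts - 1L, target_end = te,
             strand = ifelse(minus, "-", "+"),
             identity_pct = as.numeric(m[, 7]),
             query_cov_pct = as.numeric(m[, 9]),
             target_cov_pct = as.numeric(m[, 8]),
             stringsAsFactors = FALSE)
}

#' Write alignment hits as a show-coords table
#'
#' Inverse of \code{\link{readCoordsTable}} for canonical (plus-strand
#' untouched, minus-strand re-reversed) rows.
#'
#' @param hits data.frame as returned by \code{readCoordsTable}.
#' @param path Output file.
#' @return \code{path}, invisibly.
#' @export
writeCoordsTable <- function(hits, path) {
  minus <- hits$strand == "-"
  s1 <- ifelse(minus, hits$target_end, hits$target_start + 1L)
  e1 <- ifelse(minus, hits$target_start + 1L, hits$target_end)
  lines <- paste(s1, e1, hits$query_start + 1L, hits$query_end,
                 abs(hits$target_end - hits$target_start),
                 hits$query_end - hits$query_start,
                 formatC(hits$identity_pct, format = "f", digits = 2),
                 formatC(hits$target_cov_pct, format = "f", digits = 2),
                 formatC(hits$query_cov_pct, format = "f", digits = 2),
                 hits$target_id, hits$query_id, sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

## Map a RepeatMasker class/family string onto the fixed ten-class vocabulary.
mapRepeatClass <- function(x) {
  out <- rep("Other", length(x))
  out[grepl("^LINE", x)] <- "LINE"
  out[grepl("^SINE", x)] <- "SINE"
  out[grepl("^LTR", x)] <- "LTR"
  out[grepl("^DNA", x)] <- "DNA"
  out[grepl("^Simple_repeat", x)] <- "Simple_repeat"
  out[grepl("^Satellite", x)] <- "Satellite"
  out[grepl("RNA", x)] <- "RNA"
  out[grepl("^Low_complexity", x)] <- "Low_complexity"
  out
}

#' Parse RepeatMasker .out annotations
#'
#' Reads the standard \file{.out} layout (three header lines, then
#' whitespace-separated columns) and returns per-sequence annotations over the
#' fixed repeat-class vocabulary. Overlapping annotations are resolved in
#' favour of the row with the higher Smith-Waterman score (ties: the earlier
#' row); unannotated bases are implicit \code{"Unmasked"}.
#'
#' @param path RepeatMasker \file{.out} file.
#' @param seqLengths Named integer vector of sequence lengths; every annotated
#'   sequence id must be present.
#' @return Named list (one element per name in \code{seqLengths}): data.frame
#'   with 0-based half-open \code{start}, \code{end} and \code{class} of the
#'   resolved, non-overlapping annotated intervals.
#' @export
readRepeatMaskerOut <- function(path, seqLengths) {
  stopifnot(file.exists(path), !is.null(names(seqLengths)))
  lines <- readLines(path)
  if (length(lines) >= 1L && grepl("^\\s*SW", lines[1]))
    lines <- lines[-seq_len(min(3L, length(lines)))]
  lines <- lines[nzchar(trimws(lines))]
  ann <- lapply(names(seqLengths), function(x) {
    data.frame(start = integer(0), end = integer(0), class = character(0),
               stringsAsFactors = FALSE)
  })
  names(ann) <- names(seqLengths)
  if (length(lines) == 0L) return(ann)
  parts <- strsplit(trimws(lines), "\\s+")
  score <- vapply(parts, function(p) as.numeric(p[1]), 0)
  seqid <- vapply(parts, function(p) p[5], "")
  qbeg <- vapply(parts, function(p) as.integer(p[6]), 0L)
  qend <- vapply(parts, function(p) as.integer(p[7]), 0L)
  cls <- mapRepeatClass(vapply(parts, function(p) p[11], ""))
  unknown <- setdiff(unique(seqid), names(seqLengths))
  if (length(unknown) > 0L)
    stop("annotated sequence absent from seq_lengths: ",
         paste(unknown, collapse = ", "))
  for (id in unique(seqid)) {
    sel <- which(seqid == id)
    ann[[id]] <- resolveRepeatOverlaps(
      data.frame(start = qbeg[sel] - 1L, end = qend[sel], class = cls[sel],
                 score = score[sel], stringsAsFactors = FALSE),
      seqLengths[[id]])
  }
  ann
}

## Resolve overlapping scored intervals on one sequence: per base, the
## highest-scoring interval wins; ties go to the earlier row. Returns merged
## runs as a data.frame(start, end, class), clipped to [0, seqLen).
resolveRepeatOverlaps <- function(df, seqLen) {
  if (nrow(df) == 0L)
    return(data.frame(start = integer(0), end = integer(0),
                      class = character(0), stringsAsFactors = FALSE))
  df$start <- pmax(df$start, 0L)
  df$end <- pmin(df$end, seqLen)
  df <- df[df$start < df$end, , drop = FALSE]
  if (nrow(df) == 0L)
    return(data.frame(start = integer(0), end = integer(0),
                      class = character(0), stringsAsFactors = FALSE))
  ## paint bases in increasing (score, reverse row order) so the winner is
  ## painted last
  o <- order(df$score, -seq_len(nrow(df)))
  owner <- rep(NA_character_, seqLen)
  for (i in o) owner[seq(df$start[i] + 1L, df$end[i])] <- df$class[i]
  r <- rle(ifelse(is.na(owner), "", owner))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- r$values != ""
  data.frame(start = as.integer(starts[keep]), end = as.integer(ends[keep]),
             class = r$values[keep], stringsAsFactors = FALSE)
}

#' Read / write BED4 intervals
#'
#' BED is natively 0-based half-open, matching the internal convention.
#' The fourth column (name) is kept as the interval label; reading a BED3
#' file yields empty labels. Round-trips are lossless.
#'
#' @param path BED file.
#' @return A \code{\link[GenomicRanges]{GRanges}} with a \code{label}
#'   metadata column. Note the \code{GRanges} display is 1-based; use
#'   \code{writeBedFile} to emit BED coordinates again.
#' @export
#' @examples
#' f <- tempfile(fileext = ".bed")
#' writeLines("chr1\t10\t20\tgene", f)
#' readBedFile(f)
readBedFile <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L)
    return(GenomicRanges::GRanges(label = character(0)))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 3L)) stop("fewer than 3 BED columns at line ", which(nf < 3L)[1])
  chrom <- vapply(parts, `[`, "", 1L)
  start <- suppressWarnings(as.integer(vapply(parts, `[`, "", 2L)))
  end <- suppressWarnings(as.integer(vapply(parts, `[`, "", 3L)))
  if (anyNA(start) || anyNA(end))
    stop("non-integer BED coordinates at line ",
         which(is.na(start) | is.na(end))[1])
  bad <- start < 0L | start >= end
  if (any(bad))
    stop("invalid interval (start < 0 or start >= end) at line ", which(bad)[1])
  label <- ifelse(nf >= 4L, vapply(parts, `[`, "", 4L), "")
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start + 1L, end),
                         label = label)
}

#' @rdname readBedFile
#' @param gr A \code{GRanges} (a \code{label} metadata column is written as
#'   the BED name column when present).
#' @export
writeBedFile <- function(gr, path) {
  lab <- if ("label" %in% colnames(S4Vectors::mcols(gr)))
    S4Vectors::mcols(gr)$label else NULL
  start0 <- GenomicRanges::start(gr) - 1L
  end0 <- GenomicRanges::end(gr)
  lines <- if (is.null(lab))
    paste(as.character(GenomicRanges::seqnames(gr)), start0, end0, sep = "\t")
  else
    paste(as.character(GenomicRanges::seqnames(gr)), start0, end0, lab,
          sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

#' Read deletion records from a minimal SV VCF
#'
#' Accepts VCF 4.x with symbolic \code{<DEL>} records carrying \code{END}
#' and/or \code{SVLEN} in INFO and \code{GT} as the first FORMAT key. POS is
#' treated as the first deleted base: a record with POS=101, END=200 becomes
#' the 0-based half-open interval [100, 200). Filtering on FILTER/SVTYPE is a
#' later step (\code{\link{filterDeletions}}); all records are returned.
#'
#' @param path VCF file (one sample column).
#' @param individual Individual id to attach; defaults to the VCF sample name.
#' @return data.frame: individual, chrom, start, end, filter_status, svtype,
#'   genotype (hom_ref / het / hom_alt / missing).
#' @export
readDeletionVcf <- function(path, individual = NULL) {
  stopifnot(file.exists(path))
  v <- suppressWarnings(VariantAnnotation::readVcf(path))
  n <- length(v)
  if (is.null(individual)) {
    sn <- colnames(v)
    individual <- if (length(sn) >= 1L) sn[1] else NA_character_
  }
  if (n == 0L)
    return(data.frame(individual = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      filter_status = character(0), svtype = character(0),
                      genotype = character(0), stringsAsFactors = FALSE))
  rr <- SummarizedExperiment::rowRanges(v)
  pos <- GenomicRanges::start(rr)
  info <- VariantAnnotation::info(v)
  endv <- if ("END" %in% colnames(info)) as.integer(unlist2int(info$END, n))
          else rep(NA_integer_, n)
  svlen <- if ("SVLEN" %in% colnames(info)) as.integer(unlist2int(info$SVLEN, n))
           else rep(NA_integer_, n)
  svtype <- if ("SVTYPE" %in% colnames(info))
    as.character(unlist2chr(info$SVTYPE, n)) else rep(NA_character_, n)
  alt <- vapply(seq_len(n), function(i)
    paste(as.character(VariantAnnotation::alt(v)[[i]]), collapse = ","), "")
  svtype <- ifelse(!is.na(svtype), svtype,
                   ifelse(alt == "<DEL>", "DEL", "other"))
  svtype <- ifelse(svtype == "DEL", "DEL", "other")
  end0 <- ifelse(!is.na(endv), endv, pos - 1L + abs(svlen))
  isDel <- svtype == "DEL"
  if (any(isDel & is.na(end0)))
    stop("DEL record with neither END nor SVLEN at ",
         names(v)[which(isDel & is.na(end0))[1]])
  gt <- VariantAnnotation::geno(v)$GT
  gt <- if (is.null(gt)) rep("./.", n) else as.character(gt[, 1])
  gmap <- c("0/0" = "hom_ref", "0|0" = "hom_ref",
            "0/1" = "het", "1/0" = "het", "0|1" = "het", "1|0" = "het",
            "1/1" = "hom_alt", "1|1" = "hom_alt")
  genotype <- ifelse(gt %in% names(gmap), gmap[gt], "missing")
  data.frame(individual = individual,
             chrom = as.character(GenomicRanges::seqnames(rr)),
             start = pos - 1L, end = as.integer(end0),
             filter_status = as.character(rr$FILTER), svtype = svtype,
             genotype = unname(genotype), stringsAsFactors = FALSE)
}

## Collapse VariantAnnotation's List-typed INFO columns to one value per row.
unlist2int <- function(x, n) {
  if (is.integer(x) || is.numeric(x)) return(as.integer(x))
  vapply(seq_len(n), function(i) {
    xi <- x[[i]]
    if (length(xi) == 0L) NA_integer_ else as.integer(xi[1])
  }, 0L)
}
unlist2chr <- function(x, n) {
  if (is.character(x)) return(x)
  vapply(seq_len(n), function(i) {
    xi <- x[[i]]
    if (length(xi) == 0L) NA_character_ else as.character(xi[1])
  }, "")
}

#' Write deletion records as a minimal SV VCF
#'
#' Inverse of \code{\link{readDeletionVcf}} for one individual.
#'
#' @param records data.frame with columns chrom, start, end, filter_status,
#'   svtype, genotype (as produced by the simulator or the reader).
#' @param path Output file.
#' @param sample Sample name for the header column.
#' @return \code{path}, invisibly.
#' @export
writeDeletionVcf <- function(records, path, sample = "S1") {
  hdr <- c("##fileformat=VCFv4.2",
           "##INFO=<ID=END,Number=1,Type=Integer,Description=\"End position of the variant\">",
           "##INFO=<ID=SVLEN,Number=1,Type=Integer,Description=\"Length of the variant\">",
           "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"Type of structural variant\">",
           "##ALT=<ID=DEL,Description=\"Deletion\">",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t",
                  sample))
  gmap <- c(hom_ref = "0/0", het = "0/1", hom_alt = "1/1", missing = "./.")
  if (nrow(records) > 0L) {
    svtype <- ifelse(records$svtype == "DEL", "DEL", records$svtype)
    alt <- ifelse(svtype == "DEL", "<DEL>", paste0("<", svtype, ">"))
    rows <- paste(records$chrom, records$start + 1L,
                  paste0("sv", seq_len(nrow(records))), "N", alt, ".",
                  records$filter_status,
                  paste0("END=", records$end, ";SVTYPE=", svtype,
                         ";SVLEN=", -(records$end - records$start)),
                  "GT", gmap[records$genotype], sep = "\t")
    writeLines(c(hdr, rows), path)
  } else writeLines(hdr, path)
  invisible(path)
}

#' Read SAM-flag records from SAM text
#'
#' Extracts (read_id, flag, target_id) from every alignment line of a SAM
#' text file; header lines (starting with \code{@}) are skipped and no flag
#' filtering is applied here (see \code{\link{countReads}}). The target id is
#' \code{NA} for records with the unmapped bit (0x4) set.
#'
#' @param path SAM text file.
#' @return data.frame: read_id, flag (integer), target_id.
#' @export
readSamFlags <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "@")]
  if (length(lines) == 0L)
    return(data.frame(read_id = character(0), flag = integer(0),
                      target_id = character(0), stringsAsFactors = FALSE))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) < 3L))
    stop("SAM alignment line with fewer than 3 fields at line ",
         which(lengths(parts) < 3L)[1])
  flag <- suppressWarnings(as.integer(vapply(parts, `[`, "", 2L)))
  if (anyNA(flag))
    stop("non-integer SAM flag at alignment line ", which(is.na(flag))[1])
  target <- vapply(parts, `[`, "", 3L)
  target[bitwAnd(flag, 4L) != 0L | target == "*"] <- NA_character_
  data.frame(read_id = vapply(parts, `[`, "", 1L), flag = flag,
             target_id = target, stringsAsFactors = FALSE)
}

#' Write SAM-flag records as SAM text
#'
#' Minimal SAM emission (unaligned coordinates), sufficient for flag-filtered
#' read counting; the complement of \code{\link{readSamFlags}}.
#'
#' @param records data.frame with read_id, flag, target_id.
#' @param path Output file.
#' @param targets optional character vector of target names for \code{@SQ}
#'   header lines.
#' @return \code{path}, invisibly.
#' @export
writeSamFlags <- function(records, path, targets = NULL) {
  hdr <- "@HD\tVN:1.6\tSO:unsorted"
  if (!is.null(targets) && length(targets) > 0L)
    hdr <- c(hdr, paste0("@SQ\tSN:", targets, "\tLN:1000"))
  tid <- ifelse(is.na(records$target_id), "*", records$target_id)
  rows <- paste(records$read_id, records$flag, tid, "1", "0", "*", "*", "0",
                "0", "*", "*", sep = "\t")
  writeLines(c(hdr, rows), path)
  invisible(path)
}
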