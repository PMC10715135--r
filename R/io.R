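# Readers and writers for the standard formats: SAM/BAM alignments (via
# Rsamtools / GenomicAlignments), a flat TSV alignment fixture format,
# per-strand BEDGraph 5' profiles (via rtracklayer) and decay count tables.

ALIGN_TSV_COLS <- c("reference", "leftmost", "rightmost", "strand",
                    "is_paired", "is_read2", "is_unique")

#' Read alignment records from SAM, BAM or the TSV fixture format
#'
#' SAM/BAM records are parsed with GenomicAlignments, so `leftmost` /
#' `rightmost` span the aligned bases only (CIGAR-aware: deletions and
#' skips extend the span, soft clips do not). Unmapped records are
#' excluded. Flag bits are mapped to `is_paired` (0x1), `is_read2` (0x80)
#' and `is_unique` (negation of the secondary bit 0x100).
#'
#' The TSV fixture format is a plain tab-separated table with a header row
#' of `reference`, `leftmost`, `rightmost`, `strand`, `is_paired`,
#' `is_read2`, `is_unique`.
#'
#' @param path file path; format inferred from the extension unless given.
#' @param format `"auto"`, `"sam"`, `"bam"` or `"tsv"`.
#' @return data.frame of alignment records.
#' @export
read_alignments <- function(path, format = c("auto", "sam", "bam", "tsv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)),
                     sam = "sam", bam = "bam", tsv = "tsv", txt = "tsv",
                     stop_input("cannot infer alignment format from: ", path))
  }
  if (!file.exists(path)) stop_input("no such alignment file: ", path)
  if (format == "tsv") {
    rec <- utils::read.delim(path, stringsAsFactors = FALSE)
    if (!all(ALIGN_TSV_COLS %in% names(rec)))
      stop_input(path, ": TSV fixture needs columns ",
                 paste(ALIGN_TSV_COLS, collapse = ", "))
    for (col in c("is_paired", "is_read2", "is_unique"))
      rec[[col]] <- as.logical(rec[[col]])
    return(validate_alignments(rec))
  }
  bam <- if (format == "sam") {
    Rsamtools::asBam(path, tempfile(fileext = ".bam"), overwrite = TRUE,
                     indexDestination = TRUE)
  } else {
    path
  }
  param <- Rsamtools::ScanBamParam(
    what = "flag",
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE))
  ga <- GenomicAlignments::readGAlignments(bam, param = param)
  gadf <- as.data.frame(ga)
  flag <- S4Vectors::mcols(ga)$flag
  rec <- data.frame(
    reference = as.character(gadf$seqnames),
    leftmost = gadf$start,
    rightmost = gadf$end,
    strand = as.character(gadf$strand),
    is_paired = bitwAnd(flag, 1L) > 0L,
    is_read2 = bitwAnd(flag, 128L) > 0L,
    is_unique = bitwAnd(flag, 256L) == 0L,
    stringsAsFactors = FALSE)
  validate_alignments(rec)
}

#' Write alignment records as a minimal SAM file
#'
#' Emits a coordinate-unsorted SAM with an `@SQ` header per reference,
#' all-match CIGARs over the aligned span and flag bits encoding
#' strand/pairing/read-2/uniqueness, sufficient to round-trip through
#' [read_alignments()]. Paired mates are linked by the `qname` column when
#' present.
#'
#' @param records alignment records (optionally with a `qname` column).
#' @param path output path (`.sam`).
#' @param references named vector of reference lengths for the header;
#'   defaults to the maximum `rightmost` per reference.
#' @return `path`, invisibly.
#' @export
write_sam <- function(records, path, references = NULL) {
  validate_alignments(records)
  if (is.null(references)) {
    refs <- sort(unique(records$reference))
    references <- stats::setNames(
      vapply(refs, function(r) max(records$rightmost[records$reference == r]),
             numeric(1)), refs)
  }
  qname <- records$qname %||% sprintf("read%06d", seq_len(nrow(records)))
  flag <- rep(0L, nrow(records))
  flag <- flag + ifelse(records$is_paired, 1L + 2L, 0L)
  flag <- flag + ifelse(records$is_paired & records$is_read2, 128L, 0L)
  flag <- flag + ifelse(records$is_paired & !records$is_read2, 64L, 0L)
  flag <- flag + ifelse(records$strand == "-", 16L, 0L)
  # mates of a stranded pair sit on opposite strands
  flag <- flag + ifelse(records$is_paired & records$strand == "+", 32L, 0L)
  flag <- flag + ifelse(records$is_unique, 0L, 256L)
  mapq <- ifelse(records$is_unique, 50L, 0L)
  cigar <- paste0(records$rightmost - records$leftmost + 1L, "M")
  rnext <- ifelse(records$is_paired, "=", "*")
  pnext <- rep(0L, nrow(records))
  if (any(records$is_paired) && !is.null(records$qname)) {
    mate <- match(paste(qname, !records$is_read2),
                  paste(qname, records$is_read2))
    pnext <- ifelse(records$is_paired & !is.na(mate),
                    records$leftmost[mate], 0L)
  }
  header <- c("@HD\tVN:1.6\tSO:unsorted",
              sprintf("@SQ\tSN:%s\tLN:%d",
                      names(references), as.integer(references)))
  body <- paste(qname, flag, records$reference, records$leftmost, mapq,
                cigar, rnext, pnext, 0L, "*", "*", sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Write alignment records in the TSV fixture format
#'
#' @param records alignment records.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_alignments_tsv <- function(records, path) {
  validate_alignments(records)
  utils::write.table(records[, ALIGN_TSV_COLS], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a 5' profile as per-strand BEDGraph tracks
#'
#' One BEDGraph file per strand (`<prefix>_fwd.bedgraph`,
#' `<prefix>_rev.bedgraph`; unstranded profiles write a single
#' `<prefix>.bedgraph`). Coordinates are converted from the profile's
#' 1-based inclusive convention to BEDGraph's 0-based half-open intervals
#' by the rtracklayer exporter.
#'
#' @param profile a [five_prime_profile()].
#' @param prefix output path prefix.
#' @return character vector of the files written, invisibly.
#' @export
write_profile_bedgraph <- function(profile, prefix) {
  stopifnot(inherits(profile, "five_prime_profile"))
  strands <- if (all(profile$counts$strand == "*")) {
    c("*" = paste0(prefix, ".bedgraph"))
  } else {
    c("+" = paste0(prefix, "_fwd.bedgraph"),
      "-" = paste0(prefix, "_rev.bedgraph"))
  }
  seqlen <- profile$references
  for (s in names(strands)) {
    cts <- profile$counts[profile$counts$strand == s, , drop = FALSE]
    gr <- GenomicRanges::GRanges(
      seqnames = factor(cts$reference, levels = names(seqlen)),
      ranges = IRanges::IRanges(start = cts$pos, width = 1L),
      score = cts$count,
      seqlengths = seqlen)
    rtracklayer::export(gr, strands[[s]], format = "bedGraph")
  }
  invisible(unname(strands))
}

#' Read per-strand BEDGraph tracks back into a 5' profile
#'
#' Intervals wider than one base (adjacent equal-count runs merged by the
#' writer) are expanded back to per-position counts.
#'
#' @param forward path of the forward-strand (or unstranded) BEDGraph.
#' @param reverse path of the reverse-strand BEDGraph, or `NULL` for an
#'   unstranded profile.
#' @param references optional named vector of reference lengths.
#' @return a [five_prime_profile()].
#' @export
read_profile_bedgraph <- function(forward, reverse = NULL,
                                  references = NULL) {
  read_one <- function(path, strand) {
    gr <- as.data.frame(rtracklayer::import(path, format = "bedGraph"))
    if (!nrow(gr)) return(empty_profile_counts(strand))
    pos <- unlist(mapply(seq.int, gr$start, gr$end, SIMPLIFY = FALSE))
    data.frame(reference = rep(as.character(gr$seqnames), gr$width),
               strand = strand,
               pos = as.integer(pos),
               count = rep(as.integer(gr$score), gr$width),
               stringsAsFactors = FALSE)
  }
  counts <- if (is.null(reverse)) {
    read_one(forward, "*")
  } else {
    rbind(read_one(forward, "+"), read_one(reverse, "-"))
  }
  five_prime_profile(counts, references = references)
}

#' Read a rifampicin-chase count table
#'
#' Expects a TSV with columns `gene`, `length_bp` and one count column per
#' time point whose header encodes the time in minutes (`t0`, `t1`, `t3`,
#' `t9` or plain numbers).
#'
#' @param path TSV path.
#' @return list with `counts` (the data.frame) and `times` (numeric
#'   minutes parsed from the header).
#' @export
read_counts_tsv <- function(path) {
  counts <- utils::read.delim(path, stringsAsFactors = FALSE,
                              check.names = FALSE)
  if (!all(c("gene", "length_bp") %in% names(counts)))
    stop_input(path, ": needs 'gene' and 'length_bp' columns")
  time_cols <- setdiff(names(counts), c("gene", "length_bp"))
  times <- suppressWarnings(as.numeric(sub("^[tT]_?", "", time_cols)))
  if (any(is.na(times)))
    stop_input(path, ": cannot parse time points from columns: ",
               paste(time_cols[is.na(times)], collapse = ", "))
  list(counts = counts, times = times)
}

empty_profile_counts <- function(strand = character()) {
  data.frame(reference = character(), strand = strand[0],
             pos = integer(), count = integer(), stringsAsFactors = FALSE)
}

# flat key = value config writer/reader for scenario fixtures
write_flat_config <- function(x, path) {
  vals <- vapply(x, function(v) paste(format(v, digits = 15), collapse = ","),
                 character(1))
  writeLines(paste0(names(x), " = ", vals), path)
  invisible(path)
}
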