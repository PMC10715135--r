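#' Construct a 5' profile
#'
#' A 5' profile stores, per (reference, strand, position), how many
#' sequenced fragments have their 5' end at that position. Zero-count
#' positions are never stored; `total_reads` always equals the sum of the
#' stored counts.
#'
#' @param counts data.frame with columns `reference` (character), `strand`
#'   (`"+"`, `"-"` or `"*"`), `pos` (1-based integer) and `count`
#'   (non-negative integer). Zero-count rows are dropped; duplicate
#'   positions are summed.
#' @param references named integer vector of reference sequence lengths
#'   defining the profile's reference space (used for merge compatibility
#'   checks and BEDGraph headers). Defaults to the references present.
#' @return an object of class `five_prime_profile`.
#' @export
five_prime_profile <- function(counts = data.frame(reference = character(),
                                                   strand = character(),
                                                   pos = integer(),
                                                   count = integer()),
                               references = NULL) {
  need <- c("reference", "strand", "pos", "count")
  if (!all(need %in% names(counts)))
    stop_input("counts needs columns: ", paste(need, collapse = ", "))
  counts <- counts[, need, drop = FALSE]
  counts$reference <- as.character(counts$reference)
  counts$strand <- as.character(counts$strand)
  counts$pos <- as.integer(counts$pos)
  counts$count <- as.integer(counts$count)
  if (any(counts$count < 0L)) stop_input("negative counts")
  if (any(counts$pos < 1L)) stop_input("positions must be >= 1")
  if (!all(counts$strand %in% c("+", "-", "*")))
    stop_input("strand must be one of '+', '-', '*'")
  counts <- counts[counts$count > 0L, , drop = FALSE]
  # collapse duplicates
  key <- paste(counts$reference, counts$strand, counts$pos, sep = "\r")
  if (anyDuplicated(key)) {
    first <- !duplicated(key)
    tot <- rowsum(counts$count, key, reorder = FALSE)
    counts <- counts[first, , drop = FALSE]
    counts$count <- as.integer(tot[match(key[first], rownames(tot)), 1L])
  }
  counts <- order_positions(counts)
  rownames(counts) <- NULL
  if (is.null(references)) {
    refs <- sort(unique(counts$reference))
    references <- stats::setNames(
      vapply(refs, function(r) {
        if (!length(counts$pos[counts$reference == r])) 0L
        else max(counts$pos[counts$reference == r])
      }, integer(1)), refs)
  }
  structure(list(counts = counts,
                 total_reads = sum(counts$count),
                 references = references),
            class = "five_prime_profile")
}

#' @export
print.five_prime_profile <- function(x, ...) {
  cat(sprintf("5' profile: %d positions, %d reads, references: %s\n",
              nrow(x$counts), x$total_reads,
              paste(names(x$references), collapse = ", ")))
  if (nrow(x$counts)) print(utils::head(x$counts, 6L))
  invisible(x)
}

# validate a data.frame of alignment records
validate_alignments <- function(records) {
  need <- c("reference", "leftmost", "rightmost", "strand",
            "is_paired", "is_read2", "is_unique")
  if (!all(need %in% names(records)))
    stop_input("alignment records need columns: ", paste(need, collapse = ", "))
  if (any(records$leftmost > records$rightmost))
    stop_input("leftmost > rightmost in alignment records")
  if (any(records$leftmost < 1L)) stop_input("alignment positions must be >= 1")
  if (!all(records$strand %in% c("+", "-")))
    stop_input("alignment strand must be '+' or '-'")
  invisible(records)
}

#' Filter alignment records down to those carrying fragment 5' ends
#'
#' In a paired-end stranded library only read 2 starts at the 5' end of the
#' sequenced fragment, so the paired layout keeps read-2 records (whether or
#' not the mate aligned) and drops everything else. In a single-end library
#' every read starts at the fragment 5' end, so all records are kept.
#' Non-uniquely aligned records are always removed.
#'
#' @param records alignment records (see [read_alignments()] for columns).
#' @param layout `"paired"` or `"single"`.
#' @return the filtered records.
#' @export
select_informative_reads <- function(records, layout = c("paired", "single")) {
  layout <- match.arg(layout)
  validate_alignments(records)
  records <- records[records$is_unique, , drop = FALSE]
  if (layout == "paired") {
    if (nrow(records) > 0L && !any(records$is_read2))
      warning("paired layout but no read-2 records found; ",
              "is this library really paired-end?", call. = FALSE)
    records <- records[records$is_read2, , drop = FALSE]
  }
  rownames(records) <- NULL
  records
}

#' 5' genomic position of aligned records
#'
#' On the forward strand the fragment 5' end is the leftmost aligned base;
#' on the reverse strand it is the rightmost aligned base. Both refer to the
#' aligned span, so soft-clipped bases are excluded (the span comes from the
#' CIGAR walk when records are read from SAM/BAM).
#'
#' @param records alignment records.
#' @return data.frame with columns `reference`, `strand`, `pos`.
#' @export
five_prime_position <- function(records) {
  validate_alignments(records)
  data.frame(reference = as.character(records$reference),
             strand = as.character(records$strand),
             pos = ifelse(records$strand == "+",
                          records$leftmost, records$rightmost),
             stringsAsFactors = FALSE)
}

#' Undersample libraries to a common depth
#'
#' Equalizes sequencing depth across libraries before profile comparison:
#' the target is `floor(fraction * min(library sizes))` and every library is
#' reduced to exactly that many records by uniform sampling without
#' replacement. Each library draws from its own child RNG stream derived
#' from the pipeline seed and the library name ([derive_seed()]), so the
#' subsample of one library does not depend on which other libraries are
#' present.
#'
#' @param libraries named list of alignment-record data.frames (names
#'   default to `lib1`, `lib2`, ...).
#' @param fraction target depth as a fraction of the smallest library
#'   (default 0.9).
#' @param seed pipeline-level integer seed.
#' @return list of subsampled record data.frames, same names and order.
#' @export
undersample <- function(libraries, fraction = 0.9, seed = 1) {
  if (!length(libraries)) stop_input("no libraries given")
  if (fraction <= 0 || fraction > 1) stop_input("fraction must be in (0, 1]")
  if (is.null(names(libraries)) || any(!nzchar(names(libraries))))
    names(libraries) <- paste0("lib", seq_along(libraries))
  sizes <- vapply(libraries, nrow, integer(1))
  if (any(sizes == 0L)) stop_input("all libraries must be non-empty")
  target <- floor(fraction * min(sizes))
  if (target < 1L)
    stop_input("degenerate depth: undersampling target is 0 records")
  out <- lapply(names(libraries), function(nm) {
    lib <- libraries[[nm]]
    idx <- with_seed(derive_seed(seed, nm),
                     sample.int(nrow(lib), target, replace = FALSE))
    res <- lib[idx, , drop = FALSE]
    rownames(res) <- NULL
    res
  })
  names(out) <- names(libraries)
  out
}

#' Accumulate a 5' profile from filtered alignment records
#'
#' Counts how many records place their fragment 5' end
#' ([five_prime_position()]) at each (reference, strand, position).
#'
#' @param records alignment records, already filtered
#'   ([select_informative_reads()]).
#' @param references optional named vector of reference lengths to declare
#'   the profile's reference space.
#' @return a [five_prime_profile()] with `total_reads = nrow(records)`.
#' @export
build_profile <- function(records, references = NULL) {
  if (nrow(records) == 0L) {
    return(five_prime_profile(references = references))
  }
  fp <- five_prime_position(records)
  key <- paste(fp$reference, fp$strand, fp$pos, sep = "\r")
  first <- !duplicated(key)
  idx <- match(key, key[first])
  counts <- data.frame(reference = fp$reference[first],
                       strand = fp$strand[first],
                       pos = as.integer(fp$pos[first]),
                       count = tabulate(idx, nbins = sum(first)),
                       stringsAsFactors = FALSE)
  five_prime_profile(counts, references = references)
}

#' Merge replicate 5' profiles into one per-strain profile
#'
#' Position-wise sum of counts across replicates; `total_reads` is the sum
#' of the replicate totals. All profiles must declare the same reference
#' space.
#'
#' @param profiles list of [five_prime_profile()] objects (length >= 1).
#' @return a single merged `five_prime_profile`.
#' @export
merge_replicates <- function(profiles) {
  if (!length(profiles)) stop_input("no profiles to merge")
  ok <- vapply(profiles, inherits, logical(1), "five_prime_profile")
  if (!all(ok)) stop_input("all inputs must be five_prime_profile objects")
  refsets <- lapply(profiles, function(p) sort(names(p$references)))
  if (length(unique(vapply(refsets, paste, character(1), collapse = ","))) > 1L)
    stop_input("profiles cover different reference spaces: ",
               paste(unique(unlist(refsets)), collapse = ", "))
  refs <- profiles[[1L]]$references
  for (p in profiles[-1L])
    refs[names(p$references)] <- pmax(refs[names(p$references)],
                                      p$references)
  all_counts <- do.call(rbind, lapply(profiles, `[[`, "counts"))
  five_prime_profile(all_counts, references = refs)
}

#' Collapse the strands of a profile
#'
#' Re-accumulates counts ignoring strand (all positions get strand `"*"`).
#' Provided for the alternative reading in which the per-position proportion
#' is computed on unstranded coverage.
#'
#' @param profile a [five_prime_profile()].
#' @return an unstranded `five_prime_profile`.
#' @export
collapse_strands <- function(profile) {
  stopifnot(inherits(profile, "five_prime_profile"))
  counts <- profile$counts
  counts$strand <- "*"
  five_prime_profile(counts, references = profile$references)
}
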