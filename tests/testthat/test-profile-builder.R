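test_that("informative-read filter keeps paired and unpaired R2, drops the rest", {
  lib <- rbind(
    make_records(leftmost = 10, is_paired = TRUE, is_read2 = FALSE),  # R1
    make_records(leftmost = 20, is_paired = TRUE, is_read2 = TRUE),   # R2 paired
    make_records(leftmost = 30, is_paired = FALSE, is_read2 = TRUE),  # R2 unpaired mate
    make_records(leftmost = 40, is_paired = TRUE, is_read2 = TRUE,
                 is_unique = FALSE))                                  # multimapped R2
  kept <- select_informative_reads(lib, "paired")
  expect_equal(kept$leftmost, c(20L, 30L))
  expect_true(all(kept$is_read2))
})

test_that("single-end layout keeps all unique records", {
  lib <- make_records(leftmost = seq(10, 50, 10))
  expect_equal(nrow(select_informative_reads(lib, "single")), 5)
  lib$is_unique[2] <- FALSE
  expect_equal(nrow(select_informative_reads(lib, "single")), 4)
})

test_that("empty streams pass through and suspicious libraries warn", {
  empty <- make_records(leftmost = integer(0))
  expect_equal(nrow(select_informative_reads(empty, "paired")), 0)
  no_r2 <- make_records(leftmost = c(1, 2), is_paired = TRUE)
  expect_warning(out <- select_informative_reads(no_r2, "paired"),
                 "no read-2")
  expect_equal(nrow(out), 0)
})

test_that("fragment 5' end is leftmost on + and rightmost on -", {
  fp <- five_prime_position(rbind(
    make_records(leftmost = 101, rightmost = 150, strand = "+"),
    make_records(leftmost = 101, rightmost = 150, strand = "-")))
  expect_equal(fp$pos, c(101, 150))
})

test_that("SAM parsing walks the CIGAR: deletions extend the aligned span", {
  sam <- tempfile(fileext = ".sam")
  writeLines(c(
    "@HD\tVN:1.6\tSO:unsorted",
    "@SQ\tSN:chr\tLN:1000",
    # 30M10D21M spans 61 reference bases: 200..260, minus strand
    "r1\t16\tchr\t200\t50\t30M10D21M\t*\t0\t0\t*\t*",
    # soft clips do not extend the span
    "r2\t0\tchr\t300\t50\t5S45M\t*\t0\t0\t*\t*"), sam)
  rec <- read_alignments(sam)
  rec <- rec[order(rec$leftmost), ]
  expect_equal(rec$rightmost, c(260L, 344L))
  expect_equal(five_prime_position(rec)$pos, c(260L, 300L))
})

test_that("undersampling hits the exact floor target in every library", {
  libs <- lapply(c(1000, 1200, 900, 1500), function(n)
    make_records(leftmost = seq_len(n)))
  out <- undersample(libs, fraction = 0.9, seed = 1)
  expect_equal(vapply(out, nrow, integer(1)), rep(810L, 4),
               ignore_attr = TRUE)
  # fraction 1: smallest library is a permutation of itself
  out2 <- undersample(libs[c(3, 1)], fraction = 1, seed = 1)
  expect_equal(sort(out2[[1]]$leftmost), seq_len(900))
  expect_error(undersample(list(make_records(leftmost = 1:3)), fraction = 0.1),
               "degenerate depth")
})

test_that("undersampling is a without-replacement subsample, seed-sensitive", {
  lib <- make_records(leftmost = rep(1:5, each = 4)) # 20 records, ties
  s1 <- undersample(list(a = lib), fraction = 0.5, seed = 1)[[1]]
  expect_equal(nrow(s1), 10)
  expect_true(all(table(s1$leftmost) <= table(lib$leftmost)[names(table(s1$leftmost))]))
  expect_identical(s1, undersample(list(a = lib), fraction = 0.5, seed = 1)[[1]])
  big <- make_records(leftmost = seq_len(5000))
  d1 <- undersample(list(a = big), fraction = 0.5, seed = 1)[[1]]
  d2 <- undersample(list(a = big), fraction = 0.5, seed = 2)[[1]]
  expect_false(identical(sort(d1$leftmost), sort(d2$leftmost)))
  # child streams keyed by library name: other libraries do not perturb a draw
  alone <- undersample(list(a = big), fraction = 0.5, seed = 9)[[1]]
  with_b <- undersample(list(a = big, b = big), fraction = 0.5, seed = 9)$a
  expect_identical(alone, with_b)
})

test_that("profiles accumulate 5' starts and never cross strands", {
  recs <- rbind(make_records(leftmost = 100, strand = "+"),
                make_records(leftmost = 100, strand = "+"),
                make_records(leftmost = 201, rightmost = 250, strand = "-"))
  p <- build_profile(recs)
  expect_equal(p$total_reads, 3)
  expect_equal(p$counts$count[p$counts$strand == "+"], 2)
  expect_equal(p$counts$pos[p$counts$strand == "-"], 250)
  # same position, opposite strands stay separate
  two <- rbind(make_records(leftmost = 7, rightmost = 7, strand = "+"),
               make_records(leftmost = 7, rightmost = 7, strand = "-"))
  expect_equal(nrow(build_profile(two)$counts), 2)
  empty <- build_profile(make_records(leftmost = integer(0)))
  expect_equal(empty$total_reads, 0)
})

test_that("replicate merging sums position-wise and is order-invariant", {
  a <- profile_from(1, 2)
  b <- profile_from(c(1, 2), c(3, 1))
  m <- merge_replicates(list(a, b))
  expect_equal(m$counts$count, c(5L, 1L))
  expect_equal(m$total_reads, 6)
  expect_identical(merge_replicates(list(a)), a)
  c3 <- profile_from(c(2, 9), c(4, 2))
  perms <- list(c(1,2,3), c(1,3,2), c(2,1,3), c(2,3,1), c(3,1,2), c(3,2,1))
  merged <- lapply(perms, function(p) merge_replicates(list(a, b, c3)[p]))
  for (m2 in merged[-1]) expect_identical(m2, merged[[1]])
  bad <- profile_from(1, 1, references = c(other = 500L))
  expect_error(merge_replicates(list(a, bad)), "reference spaces")
})

test_that("merged totals conserve post-undersampling library sizes", {
  sc <- small_scenario(seed = 5)
  aln <- generate_alignments(sc, 50, paired = FALSE)
  libs <- undersample(aln$mutant, fraction = 0.9, seed = 1)
  profs <- lapply(libs, function(l)
    build_profile(select_informative_reads(l, "single")))
  merged <- merge_replicates(profs)
  expect_equal(merged$total_reads, sum(vapply(libs, nrow, integer(1))))
  # undersampling never creates positions absent from the input
  full <- merge_replicates(lapply(aln$mutant, function(l)
    build_profile(select_informative_reads(l, "single"))))
  key <- function(p) paste(p$counts$strand, p$counts$pos)
  expect_true(all(key(merged) %in% key(full)))
})

test_that("alignment and profile files round-trip through SAM, TSV and BEDGraph", {
  sc <- small_scenario(seed = 8)
  aln <- generate_alignments(sc, 50, paired = TRUE)
  rec <- aln$wt[[1]]
  refs <- c(synthetic_genome = sc$genome_length)
  canon <- function(d) {
    d <- d[, c("reference", "leftmost", "rightmost", "strand",
               "is_paired", "is_read2", "is_unique")]
    d <- d[do.call(order, d), ]
    rownames(d) <- NULL
    d
  }
  sam <- tempfile(fileext = ".sam")
  write_sam(rec, sam, references = refs)
  expect_identical(canon(read_alignments(sam)), canon(rec))
  tsv <- tempfile(fileext = ".tsv")
  write_alignments_tsv(rec, tsv)
  expect_identical(canon(read_alignments(tsv)), canon(rec))
  prof <- build_profile(select_informative_reads(rec, "paired"),
                        references = refs)
  paths <- write_profile_bedgraph(prof, tempfile())
  back <- read_profile_bedgraph(paths[1], paths[2], references = refs)
  expect_identical(back$counts, prof$counts)
})
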