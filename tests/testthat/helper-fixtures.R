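# fixtures built in code: alignment-record constructors and small scenarios

make_records <- function(reference = "chr", leftmost, rightmost = leftmost + 49L,
                         strand = "+", is_paired = FALSE, is_read2 = FALSE,
                         is_unique = TRUE) {
  n <- length(leftmost)
  rl <- function(x) if (length(x) == n) x else rep(x, length.out = n)
  data.frame(reference = rl(reference),
             leftmost = as.integer(leftmost),
             rightmost = as.integer(rightmost),
             strand = rl(strand),
             is_paired = rl(is_paired), is_read2 = rl(is_read2),
             is_unique = rl(is_unique),
             stringsAsFactors = FALSE)
}

profile_from <- function(pos, count, strand = "+", reference = "chr",
                         references = c(chr = 1000L)) {
  five_prime_profile(
    data.frame(reference = reference, strand = strand,
               pos = as.integer(pos), count = as.integer(count),
               stringsAsFactors = FALSE),
    references = references)
}

# proportion field assembled directly from integer count pairs
field_from_counts <- function(m, w) {
  stopifnot(length(m) == length(w), all(m + w >= 1))
  f <- data.frame(reference = "chr", strand = "+", pos = seq_along(m),
                  mutant = as.integer(m), wt = as.integer(w),
                  stringsAsFactors = FALSE)
  f$p <- f$mutant / (f$mutant + f$wt)
  class(f) <- c("proportion_field", "data.frame")
  f
}

small_scenario <- function(seed = 1, n_exclusive_sites = 0, ...) {
  fragmentation_scenario(genome_length = 50000, n_shared_sites = 2000,
                         lambda_shared = 0.5, n_exclusive_sites = n_exclusive_sites,
                         lambda_exclusive = 1, n_replicates_per_strain = 2,
                         seed = seed, ...)
}

# Planted-excess alignment fixture with mass-balanced libraries: every
# library is padded to a common size with reads at one fixed position, so
# depth equalization is a symmetric ~10% thinning (the regime of real
# libraries, whose total mass is comparable between strains) rather than an
# asymmetric one driven by the planted reads themselves.
balanced_excess_alignments <- function(scenario, read_length = 50) {
  aln <- generate_alignments(scenario, read_length = read_length,
                             paired = FALSE)
  sizes <- vapply(c(aln$mutant, aln$wt), nrow, integer(1))
  target <- max(sizes) + 1L
  ballast <- function(n) {
    make_records(reference = "synthetic_genome", leftmost = rep(1L, n),
                 rightmost = rep(as.integer(read_length), n))
  }
  pad <- function(lib) rbind(lib[, names(ballast(0))],
                             ballast(target - nrow(lib)))
  list(mutant = lapply(aln$mutant, pad), wt = lapply(aln$wt, pad))
}

merged_strain_profiles <- function(scenario) {
  prof <- generate_profiles(scenario)
  list(mutant = merge_replicates(prof$mutant),
       wt = merge_replicates(prof$wt))
}
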