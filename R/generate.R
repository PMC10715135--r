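# Synthetic-data generators. All are deterministic given the scenario seed
# and restore the caller's RNG state.

SYNTH_REF <- "synthetic_genome"

# Sample site coordinates for a scenario: shared sites first, then
# exclusive sites, disjoint within each strand. Called under with_seed().
sample_sites <- function(scenario) {
  n_tot <- scenario$n_shared_sites + scenario$n_exclusive_sites
  strand <- sample(c("+", "-"), n_tot, replace = TRUE,
                   prob = c(scenario$strand_fraction,
                            1 - scenario$strand_fraction))
  pos <- integer(n_tot)
  for (s in c("+", "-")) {
    k <- sum(strand == s)
    if (k > scenario$genome_length)
      stop_input("site count exceeds available positions on strand ", s,
                 ": ", k, " > ", scenario$genome_length)
    if (k > 0L)
      pos[strand == s] <- sample.int(scenario$genome_length, k,
                                     replace = FALSE)
  }
  data.frame(pos = pos, strand = strand,
             type = rep(c("shared", "exclusive"),
                        c(scenario$n_shared_sites,
                          scenario$n_exclusive_sites)),
             stringsAsFactors = FALSE)
}

site_profile <- function(sites, counts, genome_length) {
  keep <- counts > 0L
  five_prime_profile(
    data.frame(reference = SYNTH_REF,
               strand = sites$strand[keep],
               pos = sites$pos[keep],
               count = counts[keep],
               stringsAsFactors = FALSE),
    references = stats::setNames(genome_length, SYNTH_REF))
}

#' Generate synthetic replicate 5' profiles for two strains
#'
#' Draws cleavage-site coordinates once, then per-replicate Poisson counts:
#' shared sites get independent counts in every replicate of both strains;
#' exclusive sites get counts in the mutant replicates only. Replicates and
#' strains are exchangeable at shared sites, so any strain-exclusive
#' positions among them arise purely from Poisson zeros — the background
#' that the excess statistic compares the planted signal against.
#'
#' @param scenario a [fragmentation_scenario()].
#' @return a list with elements `mutant` and `wt` (each a list of
#'   [five_prime_profile()] objects, one per replicate) and `sites`, the
#'   planted site table (`pos`, `strand`, `type`).
#' @export
generate_profiles <- function(scenario) {
  stopifnot(inherits(scenario, "fragmentation_scenario"))
  with_seed(scenario$seed, {
    sites <- sample_sites(scenario)
    shared <- sites$type == "shared"
    reps <- scenario$n_replicates_per_strain
    draw_strain <- function(is_mutant) {
      lapply(seq_len(reps), function(r) {
        counts <- integer(nrow(sites))
        counts[shared] <- stats::rpois(sum(shared), scenario$lambda_shared)
        if (is_mutant && any(!shared))
          counts[!shared] <- stats::rpois(sum(!shared),
                                          scenario$lambda_exclusive)
        site_profile(sites, counts, scenario$genome_length)
      })
    }
    # fixed draw order: wt replicates first, then mutant replicates
    wt <- draw_strain(FALSE)
    mutant <- draw_strain(TRUE)
    list(mutant = mutant, wt = wt, sites = sites)
  })
}

#' Generate synthetic alignment records matching [generate_profiles()]
#'
#' Expands the per-replicate site counts drawn under the scenario seed into
#' alignment records whose informative-read 5' positions reproduce the
#' generated profiles exactly: filtering with [select_informative_reads()]
#' and accumulating with [build_profile()] is the identity round trip back
#' to [generate_profiles()] output.
#'
#' In paired mode each fragment emits a read-2 record carrying the 5' end
#' plus a read-1 mate on the opposite strand at the fragment's far end
#' (fragment length `2 * read_length`), so half of all records are
#' non-informative and must be removed by the read-2 filter. In single mode
#' every record is informative. Coordinates are clamped to the genome so a
#' clamped mate never moves the 5' position itself.
#'
#' @param scenario a [fragmentation_scenario()].
#' @param read_length read length in bp (>= 1).
#' @param paired emit R1/R2 pairs (`TRUE`) or single-end records.
#' @return list with `mutant` and `wt`, each a list of per-replicate
#'   alignment-record data.frames, plus `sites` as in [generate_profiles()].
#' @export
generate_alignments <- function(scenario, read_length = 50, paired = TRUE) {
  stopifnot(inherits(scenario, "fragmentation_scenario"))
  read_length <- as.integer(read_length)
  if (read_length < 1L) stop_input("read_length must be >= 1")
  prof <- generate_profiles(scenario)
  g <- scenario$genome_length
  frag_len <- 2L * read_length
  expand <- function(profile, strain, rep_i) {
    cts <- profile$counts
    if (!nrow(cts)) {
      return(empty_records(qname = TRUE))
    }
    p <- rep(cts$pos, cts$count)
    s <- rep(cts$strand, cts$count)
    n <- length(p)
    qname <- sprintf("%s_rep%d_frag%06d", strain, rep_i, seq_len(n))
    fwd <- s == "+"
    # read 2 carries the fragment 5' end
    r2_left <- ifelse(fwd, p, pmax(1L, p - read_length + 1L))
    r2_right <- ifelse(fwd, pmin(g, p + read_length - 1L), p)
    r2 <- data.frame(reference = SYNTH_REF,
                     leftmost = as.integer(r2_left),
                     rightmost = as.integer(r2_right),
                     strand = s,
                     is_paired = paired,
                     is_read2 = paired,
                     is_unique = TRUE,
                     qname = qname,
                     stringsAsFactors = FALSE)
    if (!paired) {
      return(r2)
    }
    # read 1 sits at the far (3') end of the fragment, opposite strand
    m_left <- ifelse(fwd, p + frag_len - read_length, p - frag_len + 1L)
    m_left <- pmax(1L, pmin(m_left, g))
    m_right <- pmin(g, m_left + read_length - 1L)
    r1 <- data.frame(reference = SYNTH_REF,
                     leftmost = as.integer(m_left),
                     rightmost = as.integer(m_right),
                     strand = ifelse(fwd, "-", "+"),
                     is_paired = TRUE,
                     is_read2 = FALSE,
                     is_unique = TRUE,
                     qname = qname,
                     stringsAsFactors = FALSE)
    out <- rbind(r2, r1)
    rownames(out) <- NULL
    out
  }
  list(mutant = lapply(seq_along(prof$mutant), function(i)
         expand(prof$mutant[[i]], "mutant", i)),
       wt = lapply(seq_along(prof$wt), function(i)
         expand(prof$wt[[i]], "wt", i)),
       sites = prof$sites)
}

empty_records <- function(qname = FALSE) {
  df <- data.frame(reference = character(), leftmost = integer(),
                   rightmost = integer(), strand = character(),
                   is_paired = logical(), is_read2 = logical(),
                   is_unique = logical(), stringsAsFactors = FALSE)
  if (qname) df$qname <- character()
  df
}

#' Generate a synthetic rifampicin-chase decay series
#'
#' `level(t) = initial_level * 2^(-t / true_half_life) * exp(e_t)` with
#' `e_t ~ N(0, sqrt(log(1 + cv^2)))`, i.e. multiplicative log-normal noise
#' with the scenario's coefficient of variation (median-unbiased).
#'
#' @param scenario a [decay_scenario()].
#' @param gene identifier stored on the series.
#' @return a [decay_series()] with normalization `"relative"`.
#' @export
generate_decay_series <- function(scenario, gene = "synthetic") {
  stopifnot(inherits(scenario, "decay_scenario"))
  t <- scenario$time_points
  base <- scenario$initial_level * 2^(-t / scenario$true_half_life)
  if (scenario$noise_cv > 0) {
    sdlog <- sqrt(log(1 + scenario$noise_cv^2))
    eps <- with_seed(scenario$seed, stats::rnorm(length(t), 0, sdlog))
    base <- base * exp(eps)
  }
  decay_series(gene = gene, time_points = t, levels = base,
               normalization = "relative")
}
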