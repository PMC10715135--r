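#' Per-position proportion of mutant 5' counts
#'
#' For every genomic position covered in at least one strain computes
#' `P = mutant / (mutant + wt)` from the merged, depth-equalized 5'
#' profiles. `P = 1` marks positions seen only in the mutant (candidate
#' decay intermediates), `P = 0` positions seen only in the wild type
#' (background fragmentation), and `P = 0.5` equal counts.
#'
#' @param mutant,wt merged [five_prime_profile()] objects over the same
#'   reference space.
#' @param collapse_strands if `TRUE`, strands are collapsed before the
#'   proportion is computed ([collapse_strands()]).
#' @return an object of class `proportion_field`: a data.frame with columns
#'   `reference`, `strand`, `pos`, `mutant`, `wt`, `p`.
#' @export
compute_proportions <- function(mutant, wt, collapse_strands = FALSE) {
  stopifnot(inherits(mutant, "five_prime_profile"),
            inherits(wt, "five_prime_profile"))
  if (collapse_strands) {
    mutant <- collapse_strands(mutant)
    wt <- collapse_strands(wt)
  }
  if (mutant$total_reads + wt$total_reads == 0L)
    stop_input("both profiles are empty; proportion field undefined")
  mc <- mutant$counts
  wc <- wt$counts
  mkey <- paste(mc$reference, mc$strand, mc$pos, sep = "\r")
  wkey <- paste(wc$reference, wc$strand, wc$pos, sep = "\r")
  keys <- unique(c(mkey, wkey))
  mi <- match(keys, mkey)
  wi <- match(keys, wkey)
  src <- ifelse(is.na(mi), wi + nrow(mc), mi) # row index into rbind(mc, wc)
  both <- rbind(mc[, c("reference", "strand", "pos")],
                wc[, c("reference", "strand", "pos")])
  m <- ifelse(is.na(mi), 0L, mc$count[mi])
  w <- ifelse(is.na(wi), 0L, wc$count[wi])
  field <- data.frame(reference = both$reference[src],
                      strand = both$strand[src],
                      pos = both$pos[src],
                      mutant = as.integer(m),
                      wt = as.integer(w),
                      stringsAsFactors = FALSE)
  field$p <- field$mutant / (field$mutant + field$wt)
  field <- order_positions(field)
  rownames(field) <- NULL
  class(field) <- c("proportion_field", "data.frame")
  field
}

#' Histogram of the proportion field
#'
#' Counts of the two biologically relevant singleton classes, `P = 0`
#' (wild-type exclusive) and `P = 1` (mutant exclusive), plus 99 equal-width
#' bins over the open interval (0, 1) holding the background positions seen
#' in both strains.
#'
#' Membership of P = 0 and P = 1 is exact because those values arise only
#' from an integer zero numerator or zero complement. Interior bin
#' assignment is done in integer arithmetic (`99 * mutant` against
#' `mutant + wt`): values strictly inside a bin follow the usual floor rule;
#' the rare values landing exactly on a bin edge are assigned toward the
#' center bin, which makes the histogram exactly mirror-symmetric under a
#' strain swap (`P -> 1 - P` maps bin j to bin 100 - j).
#'
#' @param field a [compute_proportions()] result.
#' @return an object of class `excess_histogram`: list with `n0`, `n1`,
#'   `interior_bin_counts` (length 99), `breaks` (bin edges) and
#'   `n_positions`.
#' @export
proportion_histogram <- function(field) {
  stopifnot(inherits(field, "proportion_field"))
  if (!nrow(field)) stop_input("empty proportion field")
  m <- field$mutant
  w <- field$wt
  n0 <- sum(m == 0L)
  n1 <- sum(w == 0L)
  interior <- m > 0L & w > 0L
  mi <- as.double(m[interior])
  den <- mi + as.double(w[interior])
  num <- 99 * mi
  k <- num %/% den
  on_edge <- (num %% den) == 0
  idx <- k + 1 - (on_edge & 2 * mi > den) # edge values go toward the center
  counts <- tabulate(as.integer(idx), nbins = 99L)
  structure(list(n0 = n0, n1 = n1,
                 interior_bin_counts = counts,
                 breaks = seq(0, 1, length.out = 100L),
                 n_positions = nrow(field)),
            class = "excess_histogram")
}

#' Percent excess of mutant-exclusive over wild-type-exclusive positions
#'
#' `100 * (n1 / n0 - 1)`: the headline fragmentation-excess statistic (78
#' means 78 percent more mutant-exclusive than wild-type-exclusive
#' positions). Returns `Inf` when `n0 = 0` (infinite excess).
#'
#' @param n0 count of P = 0 positions.
#' @param n1 count of P = 1 positions.
#' @return percent excess.
#' @export
excess_ratio <- function(n0, n1) {
  if (n0 < 0 || n1 < 0) stop_input("counts must be non-negative")
  if (n0 == 0) return(Inf)
  100 * (n1 / n0 - 1)
}

#' Pooled background standard deviation of the interior histogram
#'
#' The Gaussian background model pools its noise from all P except the two
#' target classes: the sample standard deviation (denominator N - 1) of the
#' 99 interior bin counts, zero-count bins included.
#'
#' @param hist an [proportion_histogram()] result.
#' @return non-negative standard deviation, on the count scale.
#' @export
pooled_background_sd <- function(hist) {
  stopifnot(inherits(hist, "excess_histogram"))
  # sort first so the floating-point sum is permutation-invariant: a strain
  # swap mirrors the bin vector and must leave sigma bit-identical
  stats::sd(sort(hist$interior_bin_counts))
}

#' Bayesian error rate for the two exclusive-position counts
#'
#' Equal-prior, equal-variance two-class Gaussian decision: treating the two
#' extreme bin counts as draws from Gaussians with common standard deviation
#' `sigma`, the misclassification probability of the Bayes rule is
#' `BER = pnorm(-|n1 - n0| / (2 * sigma))`. `BER = 0.5` means the two
#' classes are indistinguishable; small BER means the separation is large
#' relative to the background bin-count noise.
#'
#' @param n0,n1 exclusive-position counts.
#' @param sigma pooled background SD ([pooled_background_sd()]). `sigma = 0`
#'   degenerates to 0 if the counts differ and 0.5 otherwise.
#' @return BER in \[0, 0.5\].
#' @export
bayes_error_rate <- function(n0, n1, sigma) {
  if (n0 < 0 || n1 < 0 || sigma < 0)
    stop_input("n0, n1 and sigma must be non-negative")
  if (sigma == 0) return(if (n0 == n1) 0.5 else 0)
  stats::pnorm(-abs(n1 - n0) / (2 * sigma))
}

#' Significance decision on a Bayesian error rate
#'
#' @param ber Bayesian error rate in \[0, 0.5\].
#' @param alpha decision threshold (default 0.01); significance requires
#'   `ber < alpha` strictly.
#' @return logical.
#' @export
decide_significance <- function(ber, alpha = 0.01) {
  if (ber < 0 || ber > 0.5) stop_input("ber must be in [0, 0.5]")
  if (alpha <= 0 || alpha >= 0.5) stop_input("alpha must be in (0, 0.5)")
  ber < alpha
}

#' Upper-tail hypergeometric overlap probability
#'
#' Probability of observing at least `overlap` common elements between a set
#' of `size_a` and a set of `size_b` drawn from a universe of `universe`
#' elements, under the hypergeometric null (drawing `size_b` elements
#' without replacement from a population containing `size_a` successes).
#'
#' @param size_a,size_b set sizes.
#' @param overlap observed intersection size.
#' @param universe population size.
#' @return `P(X >= overlap)`.
#' @export
hypergeometric_overlap <- function(size_a, size_b, overlap, universe) {
  if (any(c(size_a, size_b, overlap, universe) < 0))
    stop_input("all arguments must be non-negative")
  if (size_a > universe || size_b > universe)
    stop_input("set sizes cannot exceed the universe")
  if (overlap > min(size_a, size_b))
    stop_input("overlap cannot exceed the smaller set")
  stats::phyper(overlap - 1, size_a, universe - size_a, size_b,
                lower.tail = FALSE)
}

#' Fragmentation-excess test on two merged 5' profiles
#'
#' Runs the full statistic on depth-equalized, replicate-merged profiles:
#' proportion field, histogram, exclusive-position counts, pooled background
#' SD, Bayesian error rate and the significance decision.
#'
#' @param mutant,wt merged [five_prime_profile()] objects.
#' @param alpha BER significance threshold (default 0.01).
#' @param collapse_strands compute P on unstranded coverage.
#' @return an object of class `ber_result`: list with `n0`, `n1`,
#'   `excess_percent`, `sigma`, `ber`, `significant`, `alpha`, plus the
#'   `histogram` and the proportion `field`.
#' @export
fragmentation_excess <- function(mutant, wt, alpha = 0.01,
                                 collapse_strands = FALSE) {
  field <- compute_proportions(mutant, wt,
                               collapse_strands = collapse_strands)
  hist <- proportion_histogram(field)
  sigma <- pooled_background_sd(hist)
  ber <- bayes_error_rate(hist$n0, hist$n1, sigma)
  structure(list(n0 = hist$n0,
                 n1 = hist$n1,
                 excess_percent = excess_ratio(hist$n0, hist$n1),
                 sigma = sigma,
                 ber = ber,
                 significant = decide_significance(ber, alpha),
                 alpha = alpha,
                 histogram = hist,
                 field = field),
            class = "ber_result")
}

#' @export
print.ber_result <- function(x, ...) {
  cat("Fragmentation-excess test (5' profile proportion statistic)\n")
  cat(sprintf("  P = 0 (wt-exclusive) positions:     n0 = %d\n", x$n0))
  cat(sprintf("  P = 1 (mutant-exclusive) positions: n1 = %d\n", x$n1))
  cat(sprintf("  excess: %.1f%%  background sigma: %.2f\n",
              x$excess_percent, x$sigma))
  cat(sprintf("  BER = %.3g  ->  %s (alpha = %g)\n", x$ber,
              if (x$significant) "SIGNIFICANT excess" else "not significant",
              x$alpha))
  invisible(x)
}
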