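#' Define a synthetic fragmentation scenario
#'
#' A fragmentation scenario describes the generative model behind synthetic
#' 5' profiles: a set of cleavage sites shared by both strains, whose
#' per-replicate 5'-start counts are Poisson, plus an optional set of
#' mutant-exclusive sites standing in for RNA decay intermediates that the
#' mutant fails to clear. Strain-exclusive positions (count zero in one
#' strain) arise from Poisson sampling alone at shared sites, which is what
#' creates the background of P = 0 and P = 1 positions against which a
#' planted excess is judged.
#'
#' The defaults describe the null background regime used throughout the
#' package's self-tests: a 2 Mb genome carrying 20,000 shared sites at a
#' merged per-strain site rate of 0.9 (3 replicates x lambda 0.3), which
#' yields on the order of 5,000 strain-exclusive positions per strain from
#' sampling noise alone. Use [calibrate_excess_scenario()] to plant an
#' excess of a given size on top of this background.
#'
#' @param genome_length genome size in bp (sites live on both strands).
#' @param n_shared_sites number of cleavage sites present in both strains.
#' @param lambda_shared Poisson mean 5'-start count per shared site per
#'   replicate.
#' @param n_exclusive_sites number of mutant-only decay-intermediate sites.
#' @param lambda_exclusive Poisson mean count per exclusive site per mutant
#'   replicate.
#' @param n_replicates_per_strain replicate libraries per strain.
#' @param strand_fraction expected fraction of sites on the forward strand.
#' @param seed integer seed; all generators consuming the scenario are
#'   deterministic given the scenario (including this seed).
#' @return an object of class `fragmentation_scenario`.
#' @seealso [generate_profiles()], [generate_alignments()],
#'   [calibrate_excess_scenario()]
#' @export
fragmentation_scenario <- function(genome_length = 2e6,
                                   n_shared_sites = 20000,
                                   lambda_shared = 0.3,
                                   n_exclusive_sites = 0,
                                   lambda_exclusive = 1,
                                   n_replicates_per_strain = 3,
                                   strand_fraction = 0.5,
                                   seed = 1) {
  genome_length <- as.integer(genome_length)
  n_shared_sites <- as.integer(n_shared_sites)
  n_exclusive_sites <- as.integer(n_exclusive_sites)
  n_replicates_per_strain <- as.integer(n_replicates_per_strain)
  if (genome_length < 1L) stop_input("genome_length must be positive")
  if (n_shared_sites < 1L) stop_input("need at least one shared site")
  if (n_exclusive_sites < 0L) stop_input("n_exclusive_sites must be >= 0")
  if (lambda_shared <= 0 || lambda_exclusive <= 0)
    stop_input("Poisson rates must be positive")
  if (n_replicates_per_strain < 1L) stop_input("need >= 1 replicate per strain")
  if (strand_fraction < 0 || strand_fraction > 1)
    stop_input("strand_fraction must be in [0, 1]")
  if (n_shared_sites + n_exclusive_sites > 2 * genome_length)
    stop_input("site count exceeds available (strand, position) slots: ",
               n_shared_sites + n_exclusive_sites, " > ", 2 * genome_length)
  structure(
    list(genome_length = genome_length,
         n_shared_sites = n_shared_sites,
         lambda_shared = lambda_shared,
         n_exclusive_sites = n_exclusive_sites,
         lambda_exclusive = lambda_exclusive,
         n_replicates_per_strain = n_replicates_per_strain,
         strand_fraction = strand_fraction,
         seed = as.integer(seed)),
    class = "fragmentation_scenario")
}

#' @export
print.fragmentation_scenario <- function(x, ...) {
  cat("Fragmentation scenario\n")
  cat(sprintf("  genome: %d bp; %d shared sites (lambda %.3g),",
              x$genome_length, x$n_shared_sites, x$lambda_shared),
      sprintf("%d exclusive sites (lambda %.3g)\n",
              x$n_exclusive_sites, x$lambda_exclusive))
  cat(sprintf("  %d replicates/strain, strand fraction %.2f, seed %d\n",
              x$n_replicates_per_strain, x$strand_fraction, x$seed))
  invisible(x)
}

#' Calibrate the planted excess of a scenario to a target n1/n0 ratio
#'
#' Chooses the number of mutant-exclusive sites so that, in expectation, the
#' merged-profile count of mutant-exclusive positions (P = 1) is
#' `target_ratio` times the count of wild-type-exclusive positions (P = 0).
#' With `R` replicates and shared-site rate `lambda_s`, a shared site is
#' exclusive to one given strain with probability
#' `p01 = exp(-L) * (1 - exp(-L))`, `L = R * lambda_s`, and a planted
#' exclusive site registers at all with probability
#' `1 - exp(-R * lambda_e)`; the calibrated count is
#' `(target_ratio - 1) * n_shared * p01 / (1 - exp(-R * lambda_e))`.
#'
#' @param scenario a [fragmentation_scenario()] supplying the background.
#' @param target_ratio desired expected ratio of P = 1 to P = 0 positions
#'   (1.78 reproduces a 78 percent excess regime).
#' @return the scenario with `n_exclusive_sites` replaced.
#' @export
calibrate_excess_scenario <- function(scenario, target_ratio = 1.78) {
  stopifnot(inherits(scenario, "fragmentation_scenario"))
  if (target_ratio < 1) stop_input("target_ratio must be >= 1")
  r <- scenario$n_replicates_per_strain
  l <- r * scenario$lambda_shared
  p01 <- exp(-l) * (1 - exp(-l))
  p_seen <- 1 - exp(-r * scenario$lambda_exclusive)
  n_excl <- as.integer(round(
    (target_ratio - 1) * scenario$n_shared_sites * p01 / p_seen))
  scenario$n_exclusive_sites <- n_excl
  if (scenario$n_shared_sites + n_excl > 2 * scenario$genome_length)
    stop_input("calibrated site count exceeds the genome's site space")
  scenario
}

#' Define a synthetic rifampicin-chase decay scenario
#'
#' Describes one transcript decaying exponentially after transcription
#' shut-off: `level(t) = initial_level * 2^(-t / true_half_life) * exp(e_t)`
#' with `e_t` zero-median Gaussian on the log scale, scaled so the
#' multiplicative noise has the stated coefficient of variation. The default
#' sampling grid is 0, 1, 3 and 9 minutes after rifampicin addition.
#'
#' @param true_half_life half-life in minutes; `Inf` gives a non-decaying
#'   (rate 0) transcript.
#' @param time_points sampling times in minutes, ascending, starting at 0.
#' @param initial_level abundance at time 0 (arbitrary units).
#' @param noise_cv coefficient of variation of the multiplicative log-normal
#'   noise; 0 gives a noiseless series.
#' @param seed integer seed.
#' @return an object of class `decay_scenario`.
#' @export
decay_scenario <- function(true_half_life = 4,
                           time_points = c(0, 1, 3, 9),
                           initial_level = 100,
                           noise_cv = 0.1,
                           seed = 1) {
  if (!(is.numeric(true_half_life) && true_half_life > 0))
    stop_input("true_half_life must be positive (Inf allowed)")
  if (length(time_points) < 2L || is.unsorted(time_points, strictly = TRUE) ||
      time_points[1L] != 0)
    stop_input("time_points must be strictly ascending and start at 0")
  if (initial_level <= 0) stop_input("initial_level must be positive")
  if (noise_cv < 0) stop_input("noise_cv must be >= 0")
  structure(
    list(true_half_life = true_half_life,
         time_points = as.numeric(time_points),
         initial_level = initial_level,
         noise_cv = noise_cv,
         seed = as.integer(seed)),
    class = "decay_scenario")
}
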