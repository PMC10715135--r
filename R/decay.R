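#' Reads per kilobase per million mapped reads
#'
#' @param reads read count for the gene (vectorized).
#' @param gene_length_bp gene length in bp (>= 1).
#' @param total_mapped total mapped reads in the library (>= 1).
#' @return RPKM value(s).
#' @export
rpkm <- function(reads, gene_length_bp, total_mapped) {
  if (any(gene_length_bp < 1)) stop_input("gene_length_bp must be >= 1")
  if (any(total_mapped < 1)) stop_input("total_mapped must be >= 1")
  if (any(reads < 0)) stop_input("reads must be non-negative")
  reads / (gene_length_bp / 1e3) / (total_mapped / 1e6)
}

#' Construct a decay time series
#'
#' @param gene gene identifier.
#' @param time_points sampling times (minutes), ascending, starting at 0.
#' @param levels abundances at each time point (RPKM, mRNA fraction,
#'   ddCt-relative or arbitrary relative units).
#' @param normalization one of `"rpkm"`, `"fraction"`, `"ddct"`,
#'   `"relative"`.
#' @return an object of class `decay_series`.
#' @export
decay_series <- function(gene, time_points, levels,
                         normalization = c("rpkm", "fraction", "ddct",
                                           "relative")) {
  normalization <- match.arg(normalization)
  if (length(time_points) != length(levels))
    stop_input("time_points and levels must have equal length")
  if (length(time_points) < 2L || is.unsorted(time_points, strictly = TRUE) ||
      time_points[1L] != 0)
    stop_input("time_points must be strictly ascending and start at 0")
  structure(list(gene = as.character(gene),
                 time_points = as.numeric(time_points),
                 levels = as.numeric(levels),
                 normalization = normalization),
            class = "decay_series")
}

#' Fit a first-order exponential decay and report the half-life
#'
#' Ordinary least squares of `log(level)` on time with a free intercept;
#' the decay rate is minus the slope and the half-life `log(2) / rate`.
#' The sampling grid bounds what is measurable: with points at 0/1/3/9 min,
#' transcripts faster than ~1 min or slower than ~15 min are not reliably
#' quantified, so estimates outside `(min_half_life, max_half_life)` are
#' flagged `too_fast` / `too_stable` (strictly outside; estimates exactly at
#' a bound keep status `ok`). A non-positive fitted rate is `too_stable`
#' with half-life `NA`.
#'
#' Non-positive levels cannot enter the log fit; they are dropped with a
#' warning and at least 3 usable points are required.
#'
#' @param series a [decay_series()].
#' @param min_half_life,max_half_life calculability bounds in minutes
#'   (defaults 1 and 15).
#' @return an object of class `half_life_estimate`: list with `gene`,
#'   `rate_k` (1/min), `half_life` (min, `NA` when not calculable from a
#'   non-positive rate), `fit_r2` and `status` (`ok`, `too_fast`,
#'   `too_stable`).
#' @export
fit_exponential_decay <- function(series, min_half_life = 1,
                                  max_half_life = 15) {
  stopifnot(inherits(series, "decay_series"))
  t <- series$time_points
  y <- series$levels
  usable <- is.finite(y) & y > 0
  if (any(!usable)) {
    warning(sprintf("%s: dropped %d non-positive level(s) before log fit",
                    series$gene, sum(!usable)), call. = FALSE)
    t <- t[usable]
    y <- y[usable]
  }
  if (length(y) < 3L)
    stop_input(series$gene, ": fewer than 3 usable time points")
  fit <- stats::lm(log(y) ~ t)
  slope <- unname(stats::coef(fit)[2L])
  rate_k <- -slope
  r2 <- suppressWarnings(summary(fit)$r.squared)
  if (!is.finite(r2)) r2 <- NA_real_ # constant series: R^2 undefined
  if (rate_k <= 0) {
    half_life <- NA_real_
    status <- "too_stable"
  } else {
    half_life <- log(2) / rate_k
    # relative guard so a half-life computed exactly at a bound is not
    # pushed over it by floating-point rounding of the log-linear fit
    eps <- 1e-9
    status <- if (half_life > max_half_life * (1 + eps)) "too_stable"
              else if (half_life < min_half_life * (1 - eps)) "too_fast"
              else "ok"
  }
  structure(list(gene = series$gene, rate_k = rate_k,
                 half_life = half_life, fit_r2 = r2, status = status),
            class = "half_life_estimate")
}

#' @export
print.half_life_estimate <- function(x, ...) {
  hl <- if (is.na(x$half_life)) "not calculable"
        else sprintf("%.3g min", x$half_life)
  cat(sprintf("%s: half-life %s (k = %.4g /min, R2 = %s, status %s)\n",
              x$gene, hl, x$rate_k,
              if (is.na(x$fit_r2)) "NA" else sprintf("%.3f", x$fit_r2),
              x$status))
  invisible(x)
}

#' Bulk mRNA fraction series
#'
#' Divides mRNA-assigned reads by total reads at each time point; the
#' resulting fraction series is fit with [fit_exponential_decay()] to give
#' the bulk mRNA half-life.
#'
#' @param mrna_reads mRNA read counts per time point.
#' @param total_reads total read counts per time point (>= mrna_reads).
#' @param time_points sampling times (minutes).
#' @return a [decay_series()] with normalization `"fraction"`.
#' @export
bulk_mrna_fraction <- function(mrna_reads, total_reads,
                               time_points = c(0, 1, 3, 9)) {
  if (length(mrna_reads) != length(total_reads))
    stop_input("mrna_reads and total_reads must have equal length")
  if (any(total_reads <= 0)) stop_input("total_reads must be positive")
  if (any(mrna_reads > total_reads))
    stop_input("mrna_reads cannot exceed total_reads")
  decay_series(gene = "bulk", time_points = time_points,
               levels = mrna_reads / total_reads,
               normalization = "fraction")
}

#' Welch two-sample t-test (unequal variances)
#'
#' Two-tailed t-test with the Welch-Satterthwaite degrees of freedom. When
#' both groups are constant the statistic is degenerate: equal means give
#' `p = 1` by convention, unequal means `p = 0`.
#'
#' @param group_a,group_b numeric vectors (each length >= 2).
#' @return list with `t`, `df` and `p_two_sided`.
#' @export
welch_t_test <- function(group_a, group_b) {
  if (length(group_a) < 2L || length(group_b) < 2L)
    stop_input("each group needs at least 2 values")
  va <- stats::var(group_a)
  vb <- stats::var(group_b)
  if (va == 0 && vb == 0) {
    df <- length(group_a) + length(group_b) - 2
    if (mean(group_a) == mean(group_b))
      return(list(t = 0, df = df, p_two_sided = 1))
    return(list(t = sign(mean(group_a) - mean(group_b)) * Inf,
                df = df, p_two_sided = 0))
  }
  res <- stats::t.test(group_a, group_b, var.equal = FALSE)
  list(t = unname(res$statistic), df = unname(res$parameter),
       p_two_sided = res$p.value)
}

#' Relative expression ratio by the 2^-ddCt method
#'
#' qPCR quantification of a target gene against an internal reference gene,
#' relative to the time-zero sample:
#' `2^-[(Ct_target,t - Ct_ref,t) - (Ct_target,t0 - Ct_ref,t0)]`.
#'
#' @param ct_target_t,ct_ref_t Ct values of target and reference gene at
#'   time t.
#' @param ct_target_t0,ct_ref_t0 Ct values at the reference time point.
#' @return expression ratio (vectorized).
#' @export
ddct_ratio <- function(ct_target_t, ct_ref_t, ct_target_t0, ct_ref_t0) {
  if (!all(is.finite(c(ct_target_t, ct_ref_t, ct_target_t0, ct_ref_t0))))
    stop_input("Ct values must be finite")
  2^-((ct_target_t - ct_ref_t) - (ct_target_t0 - ct_ref_t0))
}

#' Per-gene half-life table from a count matrix
#'
#' Converts a gene x time-point count table to RPKM series and fits each
#' gene with [fit_exponential_decay()]. Genes whose series cannot be fit
#' (fewer than 3 positive levels) are reported with status
#' `insufficient_data` rather than dropped.
#'
#' @param counts data.frame with columns `gene`, `length_bp` and one count
#'   column per time point (see [read_counts_tsv()]).
#' @param times numeric time points (minutes) matching the count columns.
#' @param total_mapped total mapped reads per time point for the RPKM
#'   denominator; defaults to the column sums of the count columns.
#' @param min_half_life,max_half_life calculability bounds (minutes).
#' @return data.frame: `gene`, `rate_k`, `half_life`, `r2`, `status`.
#' @export
fit_half_lives <- function(counts, times, total_mapped = NULL,
                           min_half_life = 1, max_half_life = 15) {
  if (!all(c("gene", "length_bp") %in% names(counts)))
    stop_input("counts needs 'gene' and 'length_bp' columns")
  cnt <- as.matrix(counts[, setdiff(names(counts), c("gene", "length_bp")),
                          drop = FALSE])
  if (ncol(cnt) != length(times))
    stop_input("number of count columns (", ncol(cnt),
               ") does not match times (", length(times), ")")
  if (is.null(total_mapped)) total_mapped <- colSums(cnt)
  rows <- lapply(seq_len(nrow(cnt)), function(i) {
    lv <- rpkm(cnt[i, ], counts$length_bp[i], total_mapped)
    est <- tryCatch(
      suppressWarnings(fit_exponential_decay(
        decay_series(counts$gene[i], times, lv, normalization = "rpkm"),
        min_half_life, max_half_life)),
      error = function(e) list(gene = counts$gene[i], rate_k = NA_real_,
                               half_life = NA_real_, fit_r2 = NA_real_,
                               status = "insufficient_data"))
    data.frame(gene = est$gene, rate_k = est$rate_k,
               half_life = est$half_life, r2 = est$fit_r2,
               status = est$status, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
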