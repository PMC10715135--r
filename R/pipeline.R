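# End-to-end orchestration: fragmentation-excess runs, decay runs and
# synthetic-fixture generation, with reproducible artifacts.

as_record_list <- function(x, strain) {
  if (is.data.frame(x)) x <- list(x)
  out <- lapply(x, function(el) {
    if (is.character(el)) read_alignments(el) else validate_alignments(el)
  })
  names(out) <- sprintf("%s_%d", strain, seq_along(out))
  out
}

#' Run the fragmentation-excess pipeline on alignment libraries
#'
#' Executes the full chain: uniqueness filtering, depth equalization by
#' undersampling across all libraries of both strains, fragment-5'-end
#' (read-2) filtering, per-library 5' profiles, replicate merging per
#' strain, the per-position proportion field, its histogram, and the
#' Bayesian error rate decision. Identical inputs, parameters and seed give
#' byte-identical outputs.
#'
#' Library sizes for the undersampling target are taken after the
#' uniqueness filter but before the read-2 filter (the read-2 filter then
#' runs on the subsampled records); set `size_after_r2 = TRUE` for the
#' alternative ordering.
#'
#' @param mutant,wt replicate libraries per strain: a list of alignment
#'   record data.frames and/or file paths (SAM/BAM/TSV), or a single one.
#' @param layout `"paired"` or `"single"` (applies to all libraries).
#' @param fraction undersampling depth as a fraction of the smallest
#'   library (default 0.9).
#' @param seed pipeline seed; per-library subsampling streams are derived
#'   from it ([derive_seed()]).
#' @param alpha BER significance threshold.
#' @param collapse_strands compute P on unstranded coverage.
#' @param size_after_r2 size libraries for undersampling after the read-2
#'   filter instead of before.
#' @param output_dir if non-`NULL`, artifacts are written there: per-strain
#'   per-strand BEDGraph profiles, `histogram.tsv`, `result.json` and
#'   `manifest.json`.
#' @return a `ber_result` (see [fragmentation_excess()]).
#' @export
run_fragexcess <- function(mutant, wt, layout = c("paired", "single"),
                           fraction = 0.9, seed = 1, alpha = 0.01,
                           collapse_strands = FALSE, size_after_r2 = FALSE,
                           output_dir = NULL) {
  layout <- match.arg(layout)
  if (fraction <= 0 || fraction > 1) stop_input("fraction must be in (0, 1]")
  if (alpha <= 0 || alpha >= 0.5) stop_input("alpha must be in (0, 0.5)")
  libs <- c(as_record_list(mutant, "mutant"), as_record_list(wt, "wt"))
  # uniqueness filter precedes library sizing
  libs <- lapply(libs, function(l) l[l$is_unique, , drop = FALSE])
  if (size_after_r2)
    libs <- lapply(libs, select_informative_reads, layout = layout)
  sizes_in <- vapply(libs, nrow, integer(1))
  message("library sizes (unique reads): ",
          paste(sprintf("%s=%d", names(sizes_in), sizes_in), collapse = " "))
  libs <- undersample(libs, fraction = fraction, seed = seed)
  if (!size_after_r2)
    libs <- lapply(libs, select_informative_reads, layout = layout)
  refspace <- reference_space(libs)
  profiles <- lapply(libs, build_profile, references = refspace)
  is_mut <- grepl("^mutant_", names(profiles))
  merged_mut <- merge_replicates(profiles[is_mut])
  merged_wt <- merge_replicates(profiles[!is_mut])
  result <- fragmentation_excess(merged_mut, merged_wt, alpha = alpha,
                                 collapse_strands = collapse_strands)
  message(sprintf("n0 = %d, n1 = %d, sigma = %.4f, BER = %.6g",
                  result$n0, result$n1, result$sigma, result$ber))
  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    write_profile_bedgraph(merged_mut, file.path(output_dir, "mutant"))
    write_profile_bedgraph(merged_wt, file.path(output_dir, "wt"))
    write_histogram_tsv(result$histogram,
                        file.path(output_dir, "histogram.tsv"))
    res <- result[c("n0", "n1", "excess_percent", "sigma", "ber",
                    "significant", "alpha")]
    res$seed <- seed
    res$fraction <- fraction
    jsonlite::write_json(res, file.path(output_dir, "result.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    manifest <- list(
      tool = "fragexcess", version = pkg_version(),
      subcommand = "fragexcess",
      libraries = as.list(sizes_in),
      layout = layout, fraction = fraction, seed = seed, alpha = alpha,
      collapse_strands = collapse_strands, size_after_r2 = size_after_r2,
      undersample_target = floor(fraction * min(sizes_in)))
    jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  result
}

reference_space <- function(libs) {
  recs <- do.call(rbind, lapply(libs, function(l)
    l[, c("reference", "rightmost")]))
  refs <- sort(unique(recs$reference))
  stats::setNames(vapply(refs, function(r)
    as.integer(max(recs$rightmost[recs$reference == r])), integer(1)), refs)
}

write_histogram_tsv <- function(hist, path) {
  stopifnot(inherits(hist, "excess_histogram"))
  lo <- hist$breaks[-length(hist$breaks)]
  hi <- hist$breaks[-1L]
  df <- data.frame(bin_low = c(0, lo, 1),
                   bin_high = c(0, hi, 1),
                   count = c(hist$n0, hist$interior_bin_counts, hist$n1))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# proportion-field histogram",
               "# first and last rows are the exact singleton classes P=0 and P=1"),
             con)
  utils::write.table(format(df, digits = 15, trim = TRUE, scientific = FALSE),
                     con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

pkg_version <- function() {
  as.character(utils::packageVersion("fragexcess"))
}

#' Run the rifampicin-chase decay pipeline
#'
#' Per replicate library, converts counts to RPKM and fits every gene's
#' half-life; when both strains have at least two replicates, per-gene
#' half-lives are compared across strains with Welch's unequal-variance
#' t-test and Benjamini-Hochberg adjustment. If per-time-point totals are
#' supplied, the bulk mRNA fraction series is fit per replicate and the
#' bulk half-lives compared between strains the same way.
#'
#' Half-life fits use a plain log-linear least-squares decay model with a
#' free intercept (stated in the output header); genes with insufficient
#' usable points are reported with a status, never dropped silently.
#'
#' @param mutant,wt replicate count tables per strain: a list of
#'   data.frames (columns `gene`, `length_bp`, one per time point) and/or
#'   TSV paths ([read_counts_tsv()]), or a single one.
#' @param times numeric time points in minutes; if `NULL`, parsed from the
#'   first TSV path given.
#' @param mutant_totals,wt_totals optional lists (one vector per replicate)
#'   of total mapped reads per time point; used as the RPKM denominator and
#'   for the bulk mRNA fraction. When absent the RPKM denominator falls
#'   back to the per-time-point mRNA column sums, which deflates apparent
#'   decay rates as the mRNA pool itself shrinks after rifampicin.
#' @param min_half_life,max_half_life calculability bounds (minutes).
#' @param output_dir if non-`NULL`, writes `halflife_<strain>_rep<i>.tsv`,
#'   `comparison.tsv` and `manifest.json`.
#' @return list with `per_replicate` (list of per-gene tables),
#'   `comparison` (per-gene Welch table with `p_adj`, or `NULL`) and
#'   `bulk` (per-strain bulk half-lives and their Welch test, or `NULL`).
#' @export
run_decay <- function(mutant, wt = NULL, times = NULL,
                      mutant_totals = NULL, wt_totals = NULL,
                      min_half_life = 1, max_half_life = 15,
                      output_dir = NULL) {
  load_strain <- function(x) {
    if (is.null(x)) return(NULL)
    if (is.data.frame(x) || is.character(x) && length(x) == 1L &&
        !is.list(x)) x <- list(x)
    lapply(x, function(el) {
      if (is.character(el)) {
        parsed <- read_counts_tsv(el)
        if (is.null(times)) times <<- parsed$times
        parsed$counts
      } else el
    })
  }
  mutant <- load_strain(mutant)
  wt <- load_strain(wt)
  if (is.null(times)) stop_input("time points not given and not parseable")
  fit_all <- function(tabs, strain, totals) {
    out <- lapply(seq_along(tabs), function(i)
      fit_half_lives(tabs[[i]], times,
                     total_mapped = if (is.null(totals)) NULL
                                    else totals[[i]],
                     min_half_life = min_half_life,
                     max_half_life = max_half_life))
    names(out) <- sprintf("%s_rep%d", strain, seq_along(tabs))
    out
  }
  fits <- fit_all(mutant, "mutant", mutant_totals)
  if (!is.null(wt)) fits <- c(fits, fit_all(wt, "wt", wt_totals))
  comparison <- NULL
  if (!is.null(wt) && length(mutant) >= 2L && length(wt) >= 2L)
    comparison <- compare_half_lives(fits[grepl("^mutant_", names(fits))],
                                     fits[grepl("^wt_", names(fits))])
  bulk <- NULL
  if (!is.null(mutant_totals)) {
    bulk_hl <- function(tabs, totals) {
      vapply(seq_along(tabs), function(i) {
        cnt <- as.matrix(tabs[[i]][, setdiff(names(tabs[[i]]),
                                             c("gene", "length_bp"))])
        series <- bulk_mrna_fraction(colSums(cnt), totals[[i]], times)
        est <- suppressWarnings(
          fit_exponential_decay(series, min_half_life, max_half_life))
        est$half_life
      }, numeric(1))
    }
    bulk <- list(mutant = bulk_hl(mutant, mutant_totals))
    if (!is.null(wt) && !is.null(wt_totals)) {
      bulk$wt <- bulk_hl(wt, wt_totals)
      if (length(bulk$mutant) >= 2L && length(bulk$wt) >= 2L &&
          !anyNA(c(bulk$mutant, bulk$wt)))
        bulk$welch <- welch_t_test(bulk$mutant, bulk$wt)
    }
  }
  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    hdr <- paste0("# half-lives from a log-linear exponential fit",
                  " (free intercept); bounds (",
                  min_half_life, ", ", max_half_life, ") min")
    for (nm in names(fits)) {
      p <- file.path(output_dir, paste0("halflife_", nm, ".tsv"))
      con <- file(p, "w"); writeLines(hdr, con)
      utils::write.table(fits[[nm]], con, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      close(con)
    }
    if (!is.null(comparison)) {
      p <- file.path(output_dir, "comparison.tsv")
      con <- file(p, "w"); writeLines(hdr, con)
      utils::write.table(comparison, con, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      close(con)
    }
    jsonlite::write_json(
      list(tool = "fragexcess", version = pkg_version(),
           subcommand = "decay", times = times,
           replicates = names(fits),
           bounds = c(min_half_life, max_half_life)),
      file.path(output_dir, "manifest.json"),
      auto_unbox = TRUE, pretty = TRUE)
  }
  list(per_replicate = fits, comparison = comparison, bulk = bulk)
}

#' Compare per-gene half-lives between strains across replicates
#'
#' Welch's t-test on the per-replicate half-life estimates of each gene
#' (genes need >= 2 usable estimates per strain), with Benjamini-Hochberg
#' adjustment across genes.
#'
#' @param fits_a,fits_b lists of per-gene fit tables ([fit_half_lives()]),
#'   one per replicate.
#' @return data.frame: `gene`, mean half-life per group, `t`, `df`, `p`,
#'   `p_adj`, `n_a`, `n_b`.
#' @export
compare_half_lives <- function(fits_a, fits_b) {
  pull <- function(fits, gene) {
    v <- vapply(fits, function(f) {
      i <- match(gene, f$gene)
      if (is.na(i) || f$status[i] != "ok") NA_real_ else f$half_life[i]
    }, numeric(1))
    v[!is.na(v)]
  }
  genes <- sort(unique(unlist(lapply(c(fits_a, fits_b), `[[`, "gene"))))
  rows <- lapply(genes, function(g) {
    a <- pull(fits_a, g)
    b <- pull(fits_b, g)
    if (length(a) < 2L || length(b) < 2L)
      return(data.frame(gene = g, half_life_a = mean(a), half_life_b = mean(b),
                        t = NA_real_, df = NA_real_, p = NA_real_,
                        n_a = length(a), n_b = length(b)))
    w <- welch_t_test(a, b)
    data.frame(gene = g, half_life_a = mean(a), half_life_b = mean(b),
               t = w$t, df = w$df, p = w$p_two_sided,
               n_a = length(a), n_b = length(b))
  })
  out <- do.call(rbind, rows)
  out$p_adj <- stats::p.adjust(out$p, method = "BH")
  rownames(out) <- NULL
  out
}

#' Write a synthetic fixture set to disk
#'
#' Generates alignments and profiles for a scenario and writes SAM files
#' (one per strain per replicate), per-strand BEDGraph profiles of the
#' per-strain merged truth, the planted site table and the scenario as a
#' flat key-value config.
#'
#' @param scenario a [fragmentation_scenario()].
#' @param output_dir directory to write into (created if needed).
#' @param read_length,paired passed to [generate_alignments()].
#' @return list of written paths, invisibly.
#' @export
run_simulate <- function(scenario, output_dir, read_length = 50,
                         paired = TRUE) {
  stopifnot(inherits(scenario, "fragmentation_scenario"))
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  aln <- generate_alignments(scenario, read_length = read_length,
                             paired = paired)
  prof <- generate_profiles(scenario)
  refs <- stats::setNames(scenario$genome_length, SYNTH_REF)
  paths <- character()
  for (strain in c("mutant", "wt")) {
    for (i in seq_along(aln[[strain]])) {
      p <- file.path(output_dir, sprintf("%s_rep%d.sam", strain, i))
      write_sam(aln[[strain]][[i]], p, references = refs)
      paths <- c(paths, p)
    }
    merged <- merge_replicates(prof[[strain]])
    paths <- c(paths, write_profile_bedgraph(
      merged, file.path(output_dir, paste0(strain, "_merged"))))
  }
  sites_path <- file.path(output_dir, "planted_sites.tsv")
  utils::write.table(prof$sites, sites_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  cfg_path <- file.path(output_dir, "scenario.cfg")
  write_flat_config(unclass(scenario), cfg_path)
  invisible(c(paths, sites_path, cfg_path))
}
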