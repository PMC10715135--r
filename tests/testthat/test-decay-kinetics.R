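test_that("rpkm is the standard reads / kb / million normalization", {
  expect_equal(rpkm(10, 500, 1e6), 20)
  expect_equal(rpkm(0, 500, 1e6), 0)
  expect_equal(rpkm(20, 500, 2e6), rpkm(10, 500, 1e6)) # scale invariance
  expect_error(rpkm(1, 0, 1e6), "length")
  expect_error(rpkm(1, 500, 0), "total_mapped")
})

test_that("exponential fits recover exact half-lives on noiseless series", {
  s <- decay_series("g", c(0, 1, 2), c(1, 0.5, 0.25))
  est <- fit_exponential_decay(s)
  expect_equal(est$half_life, 1)
  expect_equal(est$fit_r2, 1)
  expect_equal(est$status, "ok")
  s4 <- generate_decay_series(decay_scenario(true_half_life = 4, noise_cv = 0))
  est4 <- fit_exponential_decay(s4)
  expect_equal(est4$half_life, 4, tolerance = 1e-12)
  # invariant to multiplicative rescaling of the series
  s4b <- decay_series("g", s4$time_points, s4$levels * 1e3)
  expect_equal(fit_exponential_decay(s4b)$half_life, est4$half_life)
})

test_that("calculability bounds flag too-fast and too-stable transcripts", {
  grid <- c(0, 1, 3, 9)
  mk <- function(hl) decay_series("g", grid, 2^(-grid / hl))
  expect_equal(fit_exponential_decay(mk(16))$status, "too_stable")
  expect_equal(fit_exponential_decay(mk(0.5))$status, "too_fast")
  # bounds are strict: estimates exactly at a bound stay calculable
  expect_equal(fit_exponential_decay(mk(15))$status, "ok")
  expect_equal(fit_exponential_decay(mk(1))$status, "ok")
  const <- fit_exponential_decay(decay_series("g", grid, rep(5, 4)))
  expect_equal(const$status, "too_stable")
  expect_true(is.na(const$half_life))
  rising <- fit_exponential_decay(decay_series("g", grid, c(1, 2, 4, 8)))
  expect_equal(rising$status, "too_stable")
})

test_that("non-positive levels are dropped with a warning, not fatal unless <3 remain", {
  s <- decay_series("g", c(0, 1, 2, 3), c(1, 0.5, 0, 0.125))
  expect_warning(est <- fit_exponential_decay(s), "non-positive")
  expect_equal(est$half_life, 1, tolerance = 1e-9)
  bad <- decay_series("g", c(0, 1, 2), c(1, 0, 0))
  expect_error(suppressWarnings(fit_exponential_decay(bad)),
               "fewer than 3")
})

test_that("bulk mRNA fraction feeds the bulk half-life fit", {
  s <- bulk_mrna_fraction(c(500, 250, 125), c(1000, 1000, 1000),
                          time_points = c(0, 1, 2))
  expect_equal(s$levels, c(0.5, 0.25, 0.125))
  expect_equal(fit_exponential_decay(s)$half_life, 1)
  all_mrna <- bulk_mrna_fraction(c(10, 10, 10), c(10, 10, 10), c(0, 1, 2))
  expect_equal(fit_exponential_decay(all_mrna)$status, "too_stable")
  expect_error(bulk_mrna_fraction(c(5, 5), c(4, 5), c(0, 1)), "exceed")
})

test_that("Welch test matches the textbook statistic and its symmetries", {
  w <- welch_t_test(c(1, 2, 3), c(2, 3, 4))
  expect_equal(w$t, -1.2247, tolerance = 1e-4)
  expect_equal(w$df, 4)
  expect_equal(w$p_two_sided, 0.287, tolerance = 1e-2)
  # hand computation: t = (m1-m2)/sqrt(s1^2/n1 + s2^2/n2)
  expect_equal(w$t, (2 - 3) / sqrt(1 / 3 + 1 / 3))
  sw <- welch_t_test(c(2, 3, 4), c(1, 2, 3))
  expect_equal(sw$t, -w$t)
  expect_equal(sw$p_two_sided, w$p_two_sided)
  same <- welch_t_test(c(5, 5), c(5, 5))
  expect_equal(same$t, 0)
  expect_equal(same$p_two_sided, 1)
  # equal variances and sizes: Welch equals the pooled-variance test
  a <- c(1, 2, 3, 4); b <- c(2, 3, 4, 5)
  pooled <- t.test(a, b, var.equal = TRUE)
  we <- welch_t_test(a, b)
  expect_equal(we$t, unname(pooled$statistic))
  expect_equal(we$df, unname(pooled$parameter))
  expect_equal(we$p_two_sided, pooled$p.value)
})

test_that("ddCt ratios follow 2^-ddCt against reference gene and t0", {
  expect_equal(ddct_ratio(22, 15, 20, 15), 0.25)
  expect_equal(ddct_ratio(18, 18, 18, 18), 1)
  expect_equal(ddct_ratio(21.3, 15.2, 19.8, 15.0), 2^-1.3)
  expect_equal(log2(ddct_ratio(21.3, 15.2, 19.8, 15.0)), -1.3) # log2 oracle
  expect_error(ddct_ratio(NA, 1, 1, 1), "finite")
})

test_that("per-gene half-life tables keep unfittable genes with a status", {
  grid <- c(0, 1, 3, 9)
  counts <- data.frame(gene = c("fast", "slow", "dead"),
                       length_bp = c(900, 1200, 500),
                       t0 = c(8000, 4000, 10),
                       t1 = c(5000, 3500, 0),
                       t3 = c(2000, 2800, 0),
                       t9 = c(200, 1200, 0))
  tab <- suppressWarnings(
    fit_half_lives(counts, grid, total_mapped = rep(1e6, 4)))
  expect_equal(nrow(tab), 3)
  expect_equal(tab$status[tab$gene == "dead"], "insufficient_data")
  expect_true(all(c("rate_k", "half_life", "r2", "status") %in% names(tab)))
})

test_that("strain comparison adjusts per-gene Welch p-values monotonically", {
  grid <- c(0, 1, 3, 9)
  mk_rep <- function(hl_a, hl_b, noise_seed) {
    set.seed(noise_seed)
    lv <- function(hl) round(1e4 * 2^(-grid / hl) * exp(rnorm(4, 0, 0.05)))
    a <- lv(hl_a); b <- lv(hl_b)
    data.frame(gene = c("g1", "g2"), length_bp = c(1000, 1000),
               t0 = c(a[1], b[1]), t1 = c(a[2], b[2]),
               t3 = c(a[3], b[3]), t9 = c(a[4], b[4]))
  }
  mut <- lapply(1:3, function(s) mk_rep(6, 2, s))
  wt <- lapply(1:3, function(s) mk_rep(3, 2, 10 + s))
  res <- run_decay(mut, wt, times = grid)
  cmp <- res$comparison
  expect_equal(sort(cmp$gene), c("g1", "g2"))
  expect_true(all(cmp$p_adj >= cmp$p, na.rm = TRUE))
  ord <- order(cmp$p)
  expect_true(all(diff(cmp$p_adj[ord]) >= -1e-12, na.rm = TRUE))
})
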