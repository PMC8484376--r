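test_that("per-variant Fst matches hand-evaluated cases", {
  tab <- counts_table(
    pos = c(1000, 2000, 3000, 4000),
    a_ref = c(20, 30, 8, 30), a_alt = c(20, 0, 32, 0),
    b_ref = c(30, 0, 32, 30), b_alt = c(30, 30, 8, 0)
  )
  res <- variant_fst(tab, "poolA", "poolB")
  # identical frequencies: fst = 0
  expect_equal(res$fst[1], 0)
  # fixed difference: pi_within = 0, pi_between = 1, fst = 1
  expect_equal(res$pi_within[2], 0)
  expect_equal(res$pi_between[2], 1)
  expect_equal(res$fst[2], 1)
  # p = 0.8 vs 0.2: independent per-term recomputation
  p1 <- 32 / 40; p2 <- 8 / 40
  piw <- (2 * p1 * (1 - p1) + 2 * p2 * (1 - p2)) / 2
  pib <- p1 * (1 - p2) + p2 * (1 - p1)
  expect_equal(piw, 0.32)
  expect_equal(pib, 0.68)
  expect_equal(res$fst[3], (pib - piw) / pib)
  expect_equal(res$fst[3], 9 / 17)
  # both pools fixed for ref: pi_between = 0, flagged undefined
  expect_true(res$undefined[4])
  expect_true(is.na(res$fst[4]))
  expect_error(variant_fst(tab, "poolA", "nope"), "unknown pool")
})

test_that("Fst never exceeds 1 and is 0 only at equal frequencies", {
  withr::with_seed(1, {
    tab <- counts_table(
      pos = seq_len(500) * 100,
      a_ref = rpois(500, 20), a_alt = rpois(500, 20),
      b_ref = rpois(500, 20), b_alt = rpois(500, 20)
    )
  })
  res <- variant_fst(tab, "poolA", "poolB")
  ok <- !res$undefined
  expect_true(all(res$fst[ok] <= 1))
  expect_equal(res$fst[ok] == 0, (res$p1 == res$p2)[ok])
})

test_that("window means equal the arithmetic-mean oracle", {
  # 30 variants at 1 kb spacing, values 0..29, one 30 kb window
  tab <- tibble::tibble(chrom = "chrS", pos = seq_len(30) * 1000 - 500,
                        val = 0:29)
  w <- window_scan(tab, "val", window_bp = 30000, min_variants = 1)
  expect_equal(nrow(w), 1)
  expect_equal(w$stat, 14.5)
  expect_equal(w$n_variants, 30L)
  expect_equal(w$end - w$start, 30000)
  # a single variant is its own window mean
  one <- window_scan(tibble::tibble(chrom = "c", pos = 123456, val = 7.5),
                     "val", min_variants = 1)
  expect_equal(one$stat, 7.5)
  # min_variants filter drops a 9-variant window
  nine <- tibble::tibble(chrom = "c", pos = seq_len(9) * 1000, val = 1)
  expect_equal(nrow(window_scan(nine, "val", min_variants = 10)), 0)
  expect_error(window_scan(nine, "val", window_bp = 0), "positive")
})

test_that("windowed means match brute force on random multi-chromosome input", {
  withr::with_seed(7, {
    df <- tibble::tibble(
      chrom = sample(c("c1", "c2"), 2000, replace = TRUE),
      pos = sample.int(3e6, 2000),
      val = rnorm(2000)
    )
  })
  for (step in c(30000, 10000)) {
    got <- window_scan(df, "val", window_bp = 30000, step_bp = step,
                       min_variants = 5)
    want <- oracle_window_means(df, "val", 30000, step, 5)
    expect_equal(nrow(got), nrow(want))
    expect_lt(max(abs(got$stat - want$stat)), 1e-12)
    expect_identical(got$n_variants, want$n_variants)
  }
})

test_that("window Z scores are standardized and hand-checkable", {
  w <- tibble::tibble(chrom = "c", start = c(0, 3, 6) * 1e4,
                      end = c(3, 6, 9) * 1e4, n_variants = 10L,
                      stat = c(0.1, 0.2, 0.3))
  z <- zscore_windows(w, tail = "upper")
  expect_equal(z$z, c(-1, 0, 1))           # sample sd = 0.1
  expect_equal(z$z[2], 0)                  # at the genome-wide mean
  withr::with_seed(2, {
    big <- tibble::tibble(chrom = "c", start = seq(0, 299) * 3e4,
                          end = seq(1, 300) * 3e4, n_variants = 10L,
                          stat = rnorm(300))
  })
  zb <- zscore_windows(big, tail = "lower")
  expect_lt(abs(mean(zb$z)), 1e-9)
  expect_lt(abs(sd(zb$z) - 1), 1e-9)
  expect_error(zscore_windows(w[1, ]), "two")
  w0 <- w; w0$stat <- 1
  expect_error(zscore_windows(w0), "variance")
})

test_that("the fixed Z cutoff flags windows at or below -4.70", {
  # engineer a window whose standardized score is exactly -4.71 / -4.69
  base <- c(seq(-1.5, 1.5, length.out = 60))
  make <- function(target_z) {
    f <- function(v0) {
      s <- c(base, v0)
      (v0 - mean(s)) / sd(s) - target_z
    }
    v0 <- stats::uniroot(f, c(-50, 0))$root
    tibble::tibble(chrom = "c", start = seq_along(c(base, v0)) * 3e4 - 3e4,
                   end = seq_along(c(base, v0)) * 3e4, n_variants = 10L,
                   stat = c(base, v0))
  }
  low <- zscore_windows(make(-4.71), tail = "lower")
  expect_true(low$significant_fixed[61])
  high <- zscore_windows(make(-4.69), tail = "lower")
  expect_false(high$significant_fixed[61])
})

test_that("pooled heterozygosity matches the closed form and its bounds", {
  # one balanced variant attains the analytic maximum 0.5
  one <- counts_table(pos = 15000, a_ref = 10, a_alt = 0, b_ref = 0, b_alt = 10)
  hw <- hp_windows(one, window_bp = 30000, min_variants = 1)
  expect_equal(hw$stat, 0.5)
  # two variants (30,10) and (20,20): Hp = 2*50*30/80^2
  two <- counts_table(pos = c(10000, 20000), a_ref = c(30, 20),
                      a_alt = c(10, 0), b_ref = c(0, 0), b_alt = c(0, 20))
  hw2 <- hp_windows(two, window_bp = 30000, min_variants = 1)
  expect_equal(hw2$sum_nmaj, 50)
  expect_equal(hw2$sum_nmin, 30)
  expect_equal(hw2$stat, 2 * 50 * 30 / 80^2)
  expect_equal(hw2$stat, 0.46875)
  # the literal printed numerator variant
  lit <- hp_windows(two, window_bp = 30000, min_variants = 1,
                    literal_numerator = TRUE)
  expect_equal(lit$stat, 2 * 30 / 80^2)
  # monomorphic windows give Hp = 0
  mono <- counts_table(pos = c(10000, 20000), a_ref = c(30, 25),
                       a_alt = c(0, 0), b_ref = c(10, 15), b_alt = c(0, 0))
  expect_equal(hp_windows(mono, window_bp = 30000, min_variants = 1)$stat, 0)
})

test_that("Hp stays in [0, 0.5], attaining 0.5 only at balanced counts", {
  b <- simulate_breed_pools(4, tibble::tibble(chrom = "c", length_bp = 2e6),
                            variant_spacing = 500, seed = 31)
  hw <- hp_windows(b)
  expect_true(all(hw$stat >= 0 & hw$stat <= 0.5))
  at_max <- hw$stat == 0.5
  expect_equal(at_max, hw$sum_nmaj == hw$sum_nmin)
  # brute-force recomputation per window
  mm <- major_minor_counts(b)
  for (i in unique(round(seq(1, nrow(hw), length.out = 10)))) {
    inside <- mm$pos > hw$start[i] & mm$pos <= hw$end[i]
    maj <- sum(mm$nmaj[inside]); mn <- sum(mm$nmin[inside])
    expect_equal(hw$stat[i], 2 * maj * mn / (maj + mn)^2, tolerance = 1e-12)
  }
})

test_that("Hp is invariant to breed labels and to which allele is ref", {
  b <- simulate_breed_pools(3, tibble::tibble(chrom = "c", length_bp = 1e6),
                            seed = 17)
  shuffled <- b[, c("chrom", "pos", "ref", "alt",
                    "breed3_ref", "breed3_alt", "breed1_ref", "breed1_alt",
                    "breed2_ref", "breed2_alt")]
  expect_equal(hp_windows(b)$stat, hp_windows(shuffled)$stat)
  # swapping ref/alt counts everywhere leaves the major/minor split unchanged
  swapped <- b
  for (p in pool_names(b)) {
    swapped[[paste0(p, "_ref")]] <- b[[paste0(p, "_alt")]]
    swapped[[paste0(p, "_alt")]] <- b[[paste0(p, "_ref")]]
  }
  expect_equal(hp_windows(b)$stat, hp_windows(swapped)$stat)
})

test_that("degenerate all-fixed input fails cleanly in the Hp scan", {
  fixed <- counts_table(pos = seq_len(100) * 1000,
                        a_ref = rep(30, 100), a_alt = rep(0, 100),
                        b_ref = rep(30, 100), b_alt = rep(0, 100))
  expect_error(hp_scan(fixed, min_variants = 1), "variance")
  expect_error(hp_scan(fixed[, 1:6], min_variants = 1), "two breed")
})
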