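toy_filter <- function(...) {
  marker_filter(region = list(chrom = "chrS", start = 1, end = 3e6), ...)
}

test_that("hard filters apply depth and frequency rules exactly", {
  # frequencies A: .5 .5 .9 .45 .05 .55 / B: .1 .3 .1 .15 .1 0, all depth 40
  tab <- counts_table(
    pos = c(1, 2, 3, 4, 5, 6) * 250000,
    a_ref = c(20, 20, 4, 22, 38, 18), a_alt = c(20, 20, 36, 18, 2, 22),
    b_ref = c(36, 28, 36, 34, 36, 40), b_alt = c(4, 12, 4, 6, 4, 0)
  )
  sel <- select_markers(tab, toy_filter(), "poolA", "poolB", seed = 1)
  expect_equal(attr(sel, "attrition")[["frequency"]], 3)
  expect_setequal(sel$pos, c(1, 4, 6) * 250000)
  # depth below 20 reads in either pool excludes regardless of frequency
  low <- tab
  low$poolA_ref[1] <- 10; low$poolA_alt[1] <- 9   # depth 19, freq 0.47
  sel2 <- select_markers(low, toy_filter(), "poolA", "poolB", seed = 1)
  expect_false(250000 %in% sel2$pos)
  # borderline pass: 0.45 vs 0.15 at depth 40/40
  expect_true(1000000 %in% sel$pos)
})

test_that("Fst mode replaces the frequency windows", {
  tab <- counts_table(
    pos = c(250000, 500000),
    a_ref = c(4, 30), a_alt = c(36, 10),    # p1 = .9, .25
    b_ref = c(36, 25), b_alt = c(4, 15)     # p2 = .1, .375
  )
  sel <- select_markers(tab, toy_filter(min_fst = 0.35), "poolA", "poolB")
  expect_equal(sel$pos, 250000)   # fst(.9,.1) = 9/17 > .35; fst(.25,.375) small
})

test_that("spacing thinning is seeded, in range, and idempotent", {
  withr::with_seed(5, {
    n <- 400
    tab <- counts_table(
      pos = sort(sample.int(3e6, n)),
      a_ref = rep(20, n), a_alt = rep(20, n),
      b_ref = rep(36, n), b_alt = rep(4, n)
    )
  })
  f <- toy_filter(spacing_range = c(189000, 322000))
  sel <- select_markers(tab, f, "poolA", "poolB", seed = 3)
  gaps <- diff(sel$pos)
  over <- attr(sel, "oversized_gaps")
  expect_equal(sum(gaps > 322000), over)
  expect_true(all(gaps >= 189000))
  expect_identical(sel$pos,
                   select_markers(tab, f, "poolA", "poolB", seed = 3)$pos)
  # applied to its own output the same set comes back (spacing satisfied)
  again <- select_markers(sel, f, "poolA", "poolB", seed = 99)
  expect_equal(again$pos, sel$pos)
})

test_that("an empty candidate set reports per-filter attrition", {
  tab <- counts_table(pos = 250000, a_ref = 40, a_alt = 0, b_ref = 40,
                      b_alt = 0)
  expect_error(select_markers(tab, toy_filter(), "poolA", "poolB"),
               "region=1.*depth=1.*frequency=0")
})

test_that("genotype coding matches a direct dosage lookup", {
  cfg <- small_config(n_bc = 60)
  ped <- simulate_cross(cfg, markers = marker_map_for(cfg, 5e5), seed = 8)
  gm <- build_genotype_matrix(ped)
  bc <- bc_individuals(ped)
  cols <- match(bc$id, colnames(ped$hap_m))
  dosage <- ped$hap_m[, cols] + ped$hap_p[, cols]
  lookup <- c("HOM_WT", "HET", "HOM_FAY")
  expect_identical(as.vector(gm$codes), lookup[as.vector(dosage) + 1L])
  # a backcross to the wild-type line cannot be homozygous founder-line
  expect_false("HOM_FAY" %in% gm$codes)
})

test_that("missing genotypes are coded and all-missing columns retained", {
  dosage <- matrix(c(0L, 1L, NA, NA, NA, NA), nrow = 3,
                   dimnames = list(NULL, c("i1", "i2")))
  gm <- build_genotype_matrix(
    dosage = dosage,
    marker_table = tibble::tibble(chrom = "c", pos = c(1, 2, 3) * 1e5)
  )
  expect_identical(gm$codes[, "i2"], rep("MISSING", 3))
  expect_identical(gm$codes[, "i1"], c("HOM_WT", "HET", "MISSING"))
})

test_that("non-recombining interval follows hand-enumerated events", {
  # 5 markers x 4 birds; one event between m2/m3, one between m4/m5
  dosage <- rbind(
    c(1L, 0L, 1L, 0L),   # m1
    c(1L, 0L, 1L, 0L),   # m2
    c(1L, 0L, 0L, 0L),   # m3  (bird 3 recombined in m2-m3)
    c(1L, 0L, 0L, 0L),   # m4
    c(1L, 1L, 0L, 0L)    # m5  (bird 2 recombined in m4-m5)
  )
  colnames(dosage) <- paste0("b", 1:4)
  gm <- build_genotype_matrix(
    dosage = dosage,
    marker_table = tibble::tibble(chrom = "c", pos = (1:5) * 1e5)
  )
  iv <- find_nonrecombining_interval(gm, anchor_pos = 3e5)
  expect_equal(c(iv$first_marker, iv$last_marker), c(3, 4))
  expect_equal(c(iv$start, iv$end), c(3e5, 4e5))
  expect_equal(c(iv$border_start, iv$border_end), c(2e5, 5e5))
  expect_equal(iv$n_recombinants_at_borders, c(1L, 1L))
  # single-marker chromosome: the interval is that marker
  one <- build_genotype_matrix(
    dosage = dosage[1, , drop = FALSE],
    marker_table = tibble::tibble(chrom = "c", pos = 1e5)
  )
  iv1 <- find_nonrecombining_interval(one, anchor_pos = 1e5)
  expect_equal(c(iv1$start, iv1$end), c(1e5, 1e5))
  # every adjacent pair recombinant: anchor marker alone
  zig <- build_genotype_matrix(
    dosage = rbind(c(1L, 0L), c(0L, 1L), c(1L, 0L)),
    marker_table = tibble::tibble(chrom = "c", pos = (1:3) * 1e5)
  )
  ivz <- find_nonrecombining_interval(zig, anchor_pos = 2e5)
  expect_equal(c(ivz$first_marker, ivz$last_marker), c(2, 2))
})

test_that("the anchor requires perfect carrier association", {
  dosage <- rbind(c(1L, 0L, 1L), c(1L, 1L, 0L))
  colnames(dosage) <- paste0("b", 1:3)
  gm <- build_genotype_matrix(
    dosage = dosage,
    marker_table = tibble::tibble(chrom = "c", pos = c(1e5, 2e5))
  )
  expect_error(find_nonrecombining_interval(gm, carriers = c(TRUE, TRUE, TRUE)),
               "best candidates")
  iv <- find_nonrecombining_interval(gm, carriers = c(TRUE, FALSE, TRUE))
  expect_equal(iv$anchor, 1)
})

test_that("reported intervals contain no simulated crossover", {
  cfg <- small_config(
    n_bc = 150,
    cold_region = list(chrom = "chrS", start = 9e6, end = 11e6,
                       rate_cm_mb = 0.01)
  )
  ped <- simulate_cross(cfg, markers = marker_map_for(cfg, 2e5), seed = 19)
  gm <- build_genotype_matrix(ped)
  iv <- find_nonrecombining_interval(
    gm, carriers = bc_individuals(ped)$causal_carrier)
  # oracle: recompute adjacent-pair events from the crossover log parity
  pos <- gm$markers$pos
  expect_gt(iv$last_marker, iv$first_marker)
  gaps <- iv$first_marker:(iv$last_marker - 1)
  for (xo in ped$crossovers) {
    if (nrow(xo) == 0) next
    for (g in gaps) {
      n_in_gap <- sum(xo$pos > pos[g] & xo$pos <= pos[g + 1])
      expect_true(n_in_gap %% 2 == 0)
    }
  }
})

test_that("a cold region is recovered as a non-recombining interval", {
  hits <- 0
  for (seed in 1:20) {
    cfg <- small_config(
      length_bp = 5e6, n_bc = 365, causal_pos = 2.5e6, modifier_pos = 4.9e6,
      cold_region = list(chrom = "chrS", start = 2e6, end = 3e6,
                         rate_cm_mb = 0.001)
    )
    ped <- simulate_cross(cfg, markers = marker_map_for(cfg, 1e5), seed = seed)
    gm <- build_genotype_matrix(ped)
    iv <- find_nonrecombining_interval(
      gm, carriers = bc_individuals(ped)$causal_carrier)
    if (iv$start <= 2e6 && iv$end >= 3e6) hits <- hits + 1
  }
  expect_gte(hits, 19)
})

test_that("pool states classify fixed and segregating variants", {
  expect_equal(classify_pool_state(40, 0), "FIXED_REF")
  expect_equal(classify_pool_state(0, 35), "FIXED_ALT")
  expect_equal(classify_pool_state(18, 22), "SEGREGATING")   # 0.55
  expect_equal(classify_pool_state(0, 0), "MISSING")
  expect_equal(classify_pool_state(c(40, 0), c(0, 35)),
               c("FIXED_REF", "FIXED_ALT"))
  tab <- counts_table(pos = c(1000, 6000, 20000),
                      a_ref = c(40, 0, 18), a_alt = c(0, 35, 22),
                      b_ref = c(1, 39, 0), b_alt = c(39, 1, 0))
  st <- pool_state_matrix(tab, anchor = list(chrom = "chrS", start = 5000,
                                             end = 7000), flank = 5000)
  expect_equal(st$pos, c(1000, 6000))
  expect_equal(st$poolA, c("FIXED_REF", "FIXED_ALT"))
  expect_equal(st$poolB, c("FIXED_ALT", "FIXED_REF"))
})
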