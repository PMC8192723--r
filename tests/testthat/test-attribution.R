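test_that("the 2x2 endpoint-presence rule labels the toy scenario", {
  bundle <- toy_attribution_bundle()
  om <- attribute_origin(bundle$table, bundle$metadata)
  expect_equal(unclass(om)[["A"]], "RESIDENT_ONLY")
  expect_equal(unclass(om)[["B"]], "INVADER_ONLY")
  expect_equal(unclass(om)[["C"]], "SHARED")
  expect_equal(unclass(om)[["D"]], "NEITHER")
  # every ASV gets exactly one label
  expect_setequal(names(om), colnames(bundle$table))

  # missing pure treatment is a configuration error
  meta_no_hp <- bundle$metadata[bundle$metadata$treatment != "HP", ]
  tab_no_hp <- asv_table(unclass(bundle$table)[meta_no_hp$sample_id, ])
  expect_error(attribute_origin(tab_no_hp, meta_no_hp), "invader treatment")
})

test_that("presence threshold and endpoint-week selection are honoured", {
  bundle <- toy_attribution_bundle()
  # with a high presence threshold, C's 15-25 reads in HP vanish -> C
  # becomes resident-only
  om <- attribute_origin(bundle$table, bundle$metadata,
                         presence_threshold = 29)
  expect_equal(unclass(om)[["C"]], "RESIDENT_ONLY")

  # ancestral (earlier-week) pure samples must be ignored
  counts <- rbind(unclass(bundle$table),
                  LP_0 = c(0L, 999L, 0L, 0L))  # ancestral LP carrying B
  meta <- sample_metadata(rownames(counts),
                          c("LP", "LP", "HP", "HP", "D10", "LP"),
                          c(1, 2, 1, 2, 1, 3), c(8, 8, 8, 8, 8, 0))
  om2 <- attribute_origin(asv_table(counts), meta)
  expect_equal(unclass(om2)[["B"]], "INVADER_ONLY")
})

test_that("invasion metrics match hand arithmetic and flag degeneracies", {
  counts <- rbind(s1 = c(A = 50L, B = 30L, C = 20L))
  tab <- asv_table(counts)
  om <- structure(c(A = "RESIDENT_ONLY", B = "INVADER_ONLY", C = "SHARED"),
                  class = "origin_map")
  m <- invasion_metrics(tab, om)
  expect_equal(m$invader_read_fraction, 30 / 80)
  expect_equal(m$worst_case_read_fraction, 30 / 100)
  expect_equal(m$attributable_read_fraction, 0.80)
  expect_equal(m$invader_asv_fraction, 1 / 2)
  expect_equal(m$invader_asv_count, 1L)
  expect_false(m$undefined)

  # only resident ASVs -> invader fractions are exactly 0
  m0 <- invasion_metrics(tab, structure(
    c(A = "RESIDENT_ONLY", B = "RESIDENT_ONLY", C = "RESIDENT_ONLY"),
    class = "origin_map"))
  expect_equal(m0$invader_read_fraction, 0)

  # only shared ASVs -> undefined, carried as missing
  mu <- invasion_metrics(tab, structure(
    c(A = "SHARED", B = "SHARED", C = "NEITHER"), class = "origin_map"))
  expect_true(mu$undefined)
  expect_true(is.na(mu$invader_read_fraction))
})

test_that("metrics respect their structural invariants on synthetic data", {
  s <- cached_study(1)
  om <- attribute_origin(s$table, s$metadata)
  invaded <- s$metadata$sample_id[!s$metadata$treatment %in% c("LP", "HP")]
  m <- invasion_metrics(s$table, om, samples = invaded)
  ok <- !is.na(m$invader_read_fraction)
  # monotone denominators
  expect_true(all(m$worst_case_read_fraction[ok] <=
                    m$invader_read_fraction[ok] + 1e-12))
  expect_true(all(m$worst_case_asv_fraction[ok] <=
                    m$invader_asv_fraction[ok] + 1e-12))
  expect_true(all(m$invader_asv_count <= rowSums(s$table[invaded, ] > 0)))

  # permutation symmetry: swapping the pure labels maps x -> 1 - x
  om_swap <- attribute_origin(s$table, s$metadata,
                              resident_label = "HP", invader_label = "LP")
  m_swap <- invasion_metrics(s$table, om_swap, samples = invaded)
  expect_equal(m_swap$invader_read_fraction[ok],
               1 - m$invader_read_fraction[ok], tolerance = 1e-12)
})

test_that("dose effect test reduces to t-test for two balanced groups", {
  set.seed(7)
  metrics <- data.frame(
    sample_id = paste0("s", 1:10),
    invader_read_fraction = c(rnorm(5, 0.4, 0.05), rnorm(5, 0.6, 0.05)))
  class(metrics) <- c("invasion_metrics", "data.frame")
  meta <- sample_metadata(paste0("s", 1:10), rep(c("D10", "D1"), each = 5),
                          rep(1:5, 2), rep(8, 10))
  res <- dose_effect_test(metrics, meta, "read_fraction")
  tt <- t.test(invader_read_fraction ~ treatment,
               merge(metrics, meta), var.equal = TRUE)
  expect_equal(res$F, unname(tt$statistic^2), tolerance = 1e-10)
  expect_equal(res$p, tt$p.value, tolerance = 1e-10)

  expect_error(dose_effect_test(metrics[1:5, ], meta, "read_fraction"),
               ">= 2 dose groups")
})

test_that("dose effect test holds its size under the null", {
  set.seed(123)
  reps <- 1000
  meta <- sample_metadata(paste0("s", 1:20),
                          rep(c("D10", "D1", "D0.1", "D0.01"), each = 5),
                          rep(1:5, 4), rep(8, 20))
  rej <- 0
  for (i in seq_len(reps)) {
    metrics <- data.frame(sample_id = paste0("s", 1:20),
                          invader_read_fraction = rnorm(20))
    class(metrics) <- c("invasion_metrics", "data.frame")
    if (dose_effect_test(metrics, meta, "read_fraction")$p < 0.05)
      rej <- rej + 1
  }
  expect_gte(rej / reps, 0.03)
  expect_lte(rej / reps, 0.07)
})

test_that("scoring against truth separates inversions from detection loss", {
  # construct a truth and a map with one detection-induced misattribution
  truth <- structure(list(
    origin = c(a = "LP_only", b = "HP_only", c = "shared", d = "shared"),
    key_taxa = character(0)), class = "sim_truth")
  om <- structure(c(a = "RESIDENT_ONLY", b = "INVADER_ONLY",
                    c = "SHARED", d = "RESIDENT_ONLY"),
                  class = "origin_map")
  sc <- score_against_truth(om, truth)
  expect_equal(sc$n_inversions, 0L)
  expect_equal(sc$n_detection_misattributions, 1L)

  om_bad <- structure(c(a = "INVADER_ONLY", b = "RESIDENT_ONLY",
                        c = "SHARED", d = "SHARED"), class = "origin_map")
  expect_equal(score_against_truth(om_bad, truth)$n_inversions, 2L)
})
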