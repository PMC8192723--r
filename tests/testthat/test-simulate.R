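test_that("volumetric mixing follows hand arithmetic and domain checks", {
  expect_equal(mix_profiles(c(1, 0), c(0, 1), 0.5), c(0.5, 0.5))
  expect_equal(mix_profiles(c(0.8, 0.2, 0), c(0, 0.5, 0.5), 0.1),
               c(0.72, 0.23, 0.05))
  # dose -> 0 limit approaches the resident profile
  expect_equal(mix_profiles(c(0.8, 0.2), c(0.5, 0.5), 1e-12),
               c(0.8, 0.2), tolerance = 1e-10)
  expect_error(mix_profiles(c(1, 0), c(0, 1), 0), "dose")
  expect_error(mix_profiles(c(1, 0), c(0, 1), 1), "dose")
})

test_that("source generation respects the configured support structure", {
  cfg <- sim_config(n_shared = 0, n_lp_unique = 2, n_hp_unique = 2,
                    n_key_taxa = 0, key_abundance = NA,
                    dominant_abundance = 0, seed = 1)
  set.seed(1)
  src <- generate_sources(cfg)
  expect_equal(sum(src$lp > 0 & src$hp > 0), 0)  # disjoint support
  expect_equal(sum(src$lp), 1)
  expect_equal(sum(src$hp), 1)

  cfg2 <- sim_config(seed = 2)
  set.seed(2)
  src2 <- generate_sources(cfg2)
  expect_equal(sum(src2$lp > 0), cfg2$n_shared + cfg2$n_lp_unique)
  expect_equal(sum(src2$hp > 0), cfg2$n_shared + cfg2$n_hp_unique)
  expect_true(all(src2$truth$key_taxa %in%
                    names(src2$truth$origin)[src2$truth$origin == "HP_only"]))
  # origin partition is exhaustive and exclusive
  expect_setequal(unique(src2$truth$origin),
                  c("shared", "LP_only", "HP_only"))

  # sigma -> 0 degenerate lognormal: all free abundances equal
  cfg3 <- sim_config(abundance_sigma = 1e-9, n_key_taxa = 0,
                     key_abundance = NA, dominant_abundance = 0, seed = 3)
  set.seed(3)
  src3 <- generate_sources(cfg3)
  nz <- src3$lp[src3$lp > 0]
  expect_lt(diff(range(nz)) / mean(nz), 1e-6)
})

test_that("transfer dynamics honours its neutral and degenerate limits", {
  cfg <- sim_config(invader_fitness_s = 0, bottleneck_N = Inf,
                    allee_fc = 0, allee_fc_all = 0, seed = 1)
  set.seed(1)
  src <- generate_sources(cfg)
  mixed <- mix_profiles(src$lp, src$hp, 0.01)
  out <- transfer_dynamics(mixed, src$truth, cfg, 5)
  expect_equal(out, mixed, tolerance = 1e-12)  # neutral deterministic limit

  # single taxon at frequency 1 stays at 1, selection or not
  cfg2 <- sim_config(seed = 1)
  one <- stats::setNames(c(1), names(src$lp)[1])
  expect_equal(unname(transfer_dynamics(one, src$truth, cfg2, 3)), 1)
  one_hp <- stats::setNames(c(1),
    names(src$truth$origin)[src$truth$origin == "HP_only"][1])
  expect_equal(unname(transfer_dynamics(one_hp, src$truth, cfg2, 3)), 1)
})

test_that("neutral single-transfer extinction matches the closed form", {
  # P(extinct) = (1 - f)^N for a neutral taxon at frequency f
  f <- 1e-4; N <- 1e4; reps <- 3000
  cfg <- sim_config(invader_fitness_s = 0, bottleneck_N = N,
                    allee_fc = 0, allee_fc_all = 0, seed = 1)
  truth <- structure(list(origin = c(rare = "LP_only", common = "LP_only"),
                          key_taxa = character(0)), class = "sim_truth")
  profile <- c(rare = f, common = 1 - f)
  set.seed(42)
  extinct <- sum(vapply(seq_len(reps), function(i)
    transfer_dynamics(profile, truth, cfg, 1)[["rare"]] == 0, logical(1)))
  p_hat <- extinct / reps
  p_true <- (1 - f)^N
  se <- sqrt(p_true * (1 - p_true) / reps)
  expect_lt(abs(p_hat - p_true), 4 * se)
})

test_that("read sampling conserves depth and has multinomial spread", {
  p <- c(a = 1, b = 0, c = 0)
  set.seed(1)
  expect_equal(sample_reads(p, 100), c(a = 100L, b = 0L, c = 0L))
  r <- sample_reads(c(a = 0.5, b = 0.5), 1e6)
  expect_equal(sum(r), 1e6)
  expect_lt(abs(r[["a"]] - 5e5), 3 * sqrt(1e6 * 0.25))
})

test_that("gas series follows the piecewise key-taxon gate", {
  cfg <- sim_config(gas_base_rate = 10, gas_boost_rate = 30,
                    gas_lag_weeks = 4, gas_noise_sd = 0,
                    n_key_taxa = 1, key_taxa_k = 1, seed = 1)
  truth <- structure(list(origin = c(k1 = "HP_only", x = "LP_only"),
                          key_taxa = "k1"), class = "sim_truth")
  # key taxa present: 6 base weeks then 2 boosted weeks
  g <- sim_gas_series(c(k1 = 0.2, x = 0.8), truth, cfg, invasion_week = 2,
                      n_weeks = 8, pure = "no", backlog = FALSE)
  expect_equal(g$cumulative_gas_ml[8], 6 * 10 + 2 * 30)
  # key taxa absent: base rate throughout
  g0 <- sim_gas_series(c(k1 = 0, x = 1), truth, cfg, 2, 8, pure = "no")
  expect_equal(g0$cumulative_gas_ml[8], 8 * 10)
  # lag 0, invasion at week 0: boosted throughout
  cfg0 <- sim_config(gas_base_rate = 10, gas_boost_rate = 30,
                     gas_lag_weeks = 0, gas_noise_sd = 0,
                     n_key_taxa = 1, key_taxa_k = 1, seed = 1)
  gb <- sim_gas_series(c(k1 = 0.2, x = 0.8), truth, cfg0, 0, 8, pure = "no")
  expect_equal(gb$cumulative_gas_ml[8], 8 * 30)
  # pure HP ignores the gate; backlog release catches an invaded
  # community up to the pure-HP total
  gh <- sim_gas_series(c(k1 = 0, x = 1), truth, cfg, 2, 8, pure = "HP")
  expect_equal(gh$cumulative_gas_ml[8], 8 * 30)
  gc <- sim_gas_series(c(k1 = 0.2, x = 0.8), truth, cfg, 2, 8,
                       pure = "no", backlog = TRUE)
  expect_equal(gc$cumulative_gas_ml[8], 8 * 30)
})

test_that("full study has the experimental design and is reproducible", {
  s <- cached_study(1)
  expect_equal(nrow(s$table), 29)  # one HP sample lost
  expect_equal(sort(unique(s$metadata$treatment)),
               sort(c("LP", "HP", "D10", "D1", "D0.1", "D0.01")))
  expect_equal(sum(s$metadata$treatment == "HP"), 4)
  expect_s3_class(s$tree, "phylo")
  expect_true(all(colnames(s$table) %in% s$tree$tip.label))
  expect_equal(nrow(validate_bundle(s$table, s$metadata, s$tree, s$gas)), 0)
  depths <- rowSums(s$table)
  expect_true(all(depths >= 350000 & depths <= 500000))

  cfg_full <- sim_config(seed = 1, drop_hp_sample = FALSE)
  expect_equal(nrow(simulate_study(cfg_full)$table), 30)

  s2 <- simulate_study(sim_config(seed = 1))
  expect_identical(unclass(s$table)[, ], unclass(s2$table)[, ])
  expect_identical(s$gas$cumulative_gas_ml, s2$gas$cumulative_gas_ml)
  expect_identical(ape::write.tree(s$tree), ape::write.tree(s2$tree))
})

test_that("per-sample substreams are stable under design changes", {
  # dropping doses from the design must not perturb the samples that remain
  cfg_all <- tiny_config(seed = 9)
  cfg_two <- tiny_config(seed = 9, doses = c(0.1, 0.01))
  s_all <- simulate_study(cfg_all)
  s_two <- simulate_study(cfg_two)
  shared_samples <- intersect(rownames(s_all$table), rownames(s_two$table))
  expect_gt(length(shared_samples), 0)
  expect_identical(unclass(s_all$table)[shared_samples, ],
                   unclass(s_two$table)[shared_samples, ])
})

test_that("truth JSON round trips", {
  s <- cached_study(1)
  path <- withr::local_tempfile(fileext = ".json")
  write_truth(s$truth, path)
  back <- read_truth(path)
  expect_identical(back$origin, s$truth$origin)
  expect_identical(back$key_taxa, s$truth$key_taxa)
  expect_equal(back$dose, s$truth$dose)
})
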