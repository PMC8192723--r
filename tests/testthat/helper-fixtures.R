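# Shared fixtures. The 20 default-configuration synthetic studies used by
# the acceptance suite are expensive enough to build once and cache.

.study_cache <- new.env(parent = emptyenv())

cached_study <- function(seed) {
  key <- paste0("study_", seed)
  if (is.null(.study_cache[[key]]))
    .study_cache[[key]] <- simulate_study(sim_config(seed = seed))
  .study_cache[[key]]
}

# a small, fast configuration for pipeline-level tests
tiny_config <- function(seed = 1L, ...) {
  sim_config(n_shared = 40, n_lp_unique = 15, n_hp_unique = 15,
             bottleneck_N = 1e4, read_depth = c(5000, 8000),
             n_key_taxa = 2, key_taxa_k = 1, seed = seed, ...)
}

# hand-built toy attribution scenario:
# pure LP endpoints support {A, C}; pure HP endpoints support {B, C};
# the invaded sample has reads on {A, B, C, D}
toy_attribution_bundle <- function() {
  asvs <- c("A", "B", "C", "D")
  counts <- rbind(
    LP_1 = c(50, 0, 30, 0),
    LP_2 = c(40, 0, 20, 0),
    HP_1 = c(0, 60, 25, 0),
    HP_2 = c(0, 55, 15, 0),
    D10_1 = c(50, 30, 20, 5))
  colnames(counts) <- asvs
  meta <- sample_metadata(rownames(counts),
                          c("LP", "LP", "HP", "HP", "D10"),
                          c(1, 2, 1, 2, 1), rep(8, 5))
  list(table = asv_table(counts), metadata = meta)
}

# the 4-leaf worked tree used across UniFrac examples
toy_tree <- function() ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
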