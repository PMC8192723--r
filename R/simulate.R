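#' @keywords internal
#' Stable substream seed from a root seed and a label
#'
#' Deterministic hash of (seed, label) so that adding samples to a design
#' never perturbs the random stream of existing ones. Kept below 2^31.
substream_seed <- function(seed, label) {
  codes <- utf8ToInt(label)
  h <- (as.double(seed) %% 2147483647) + 1
  for (c in codes) h <- (h * 31 + c) %% 2147483629
  as.integer(h %% 2147483647)
}

with_substream <- function(seed, label, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(substream_seed(seed, label))
  expr
}

#' Generate the two source community profiles and the ground truth
#'
#' Relative abundances of each source's taxa are drawn lognormal(0,
#' `abundance_sigma`) and normalised. Shared ASVs are nonzero in both
#' sources, unique ASVs in exactly one. Key taxa (the taxa that carry the
#' biogas boost) are HP-unique: either planted at `key_abundance` each, or
#' sampled among the HP-unique taxa, optionally weighted toward rare ones.
#'
#' @param config a [sim_config()].
#' @return list with `lp`, `hp` (named relative-abundance vectors over the
#'   union of all ASV ids, each summing to 1) and `truth` (class
#'   `"sim_truth"`: per-ASV `origin` in `LP_only`/`HP_only`/`shared`,
#'   `key_taxa` ids, and slots the study simulator fills in).
#' @export
generate_sources <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n_all <- config$n_shared + config$n_lp_unique + config$n_hp_unique
  ids <- sprintf("ASV_%04d", seq_len(n_all))
  origin <- rep(c("shared", "LP_only", "HP_only"),
                c(config$n_shared, config$n_lp_unique, config$n_hp_unique))
  names(origin) <- ids
  shared <- ids[origin == "shared"]
  lp_unique <- ids[origin == "LP_only"]
  hp_unique <- ids[origin == "HP_only"]

  draw <- function(k) stats::rlnorm(k, 0, config$abundance_sigma)

  lp <- stats::setNames(numeric(n_all), ids)
  lp_taxa <- c(shared, lp_unique)
  lp[lp_taxa] <- draw(length(lp_taxa))
  lp <- lp / sum(lp)

  hp <- stats::setNames(numeric(n_all), ids)
  if (config$n_key_taxa > 0 && !is.na(config$key_abundance)) {
    key <- utils::tail(hp_unique, config$n_key_taxa)
    key_mass <- config$n_key_taxa * config$key_abundance
    # in its home community the invader guild sits at its niche carrying
    # capacity, so the HP-unique mass is pinned at x_max (when finite)
    guild_mass <- if (is.finite(config$x_max)) config$x_max else
      length(hp_unique) / (config$n_shared + length(hp_unique))
    if (guild_mass <= key_mass)
      stop("x_max must exceed n_key_taxa * key_abundance")
    nonkey <- setdiff(hp_unique, key)
    dom <- character(0)
    dom_mass <- 0
    if (config$dominant_abundance > 0 && length(nonkey) > 0) {
      dom <- nonkey[1]
      dom_mass <- config$dominant_abundance
      nonkey <- nonkey[-1]
    }
    if (guild_mass <= key_mass + dom_mass)
      stop("x_max must exceed the planted key + dominant mass")
    hp[nonkey] <- draw(length(nonkey))
    hp[nonkey] <- hp[nonkey] / sum(hp[nonkey]) *
      (guild_mass - key_mass - dom_mass)
    hp[shared] <- draw(length(shared))
    hp[shared] <- hp[shared] / sum(hp[shared]) * (1 - guild_mass)
    hp[key] <- config$key_abundance
    hp[dom] <- dom_mass
  } else {
    hp_taxa <- c(shared, hp_unique)
    hp[hp_taxa] <- draw(length(hp_taxa))
    hp <- hp / sum(hp)
    key <- character(0)
    if (config$n_key_taxa > 0) {
      w <- if (isTRUE(config$key_bias_rare)) 1 / hp[hp_unique] else
        rep(1, length(hp_unique))
      key <- sample(hp_unique, config$n_key_taxa, prob = w / sum(w))
    }
  }
  truth <- structure(list(origin = origin, key_taxa = key,
                          dose = NULL, invader_trajectory = NULL),
                     class = "sim_truth")
  list(lp = lp, hp = hp, truth = truth)
}

#' Volumetric mixing of two community profiles
#'
#' @param lp_profile,hp_profile relative-abundance vectors over the same
#'   taxa (each summing to 1).
#' @param dose invader volume fraction, in (0,1).
#' @return `(1 - dose) * lp + dose * hp`.
#' @export
mix_profiles <- function(lp_profile, hp_profile, dose) {
  if (!is.numeric(dose) || length(dose) != 1 || dose <= 0 || dose >= 1)
    stop("dose must be a single number in (0, 1)")
  stopifnot(length(lp_profile) == length(hp_profile))
  (1 - dose) * lp_profile + dose * hp_profile
}

#' Weekly serial-transfer dynamics with selection and bottlenecks
#'
#' Iterates `n_transfers` of: growth (fitness-weighted frequency update)
#' followed by a multinomial bottleneck of `bottleneck_N` cells. HP-unique
#' taxa carry a weekly growth advantage `s` that fades as their summed
#' frequency `X` fills the invader niche (`w = 1 + s * max(0, 1 -
#' X/x_max)`); invader taxa whose own frequency is below their critical
#' frequency (`allee_fc` for key taxa, `allee_fc_all` for the rest of the
#' guild) instead get absolute fitness `allee_sub_w` (positive frequency
#' dependence / priority effect).
#' Taxa hitting frequency 0 stay 0 (no migration). With `bottleneck_N =
#' Inf` the bottleneck is skipped (deterministic limit).
#'
#' @param profile named relative-abundance vector summing to 1.
#' @param truth `sim_truth` from [generate_sources()] (supplies origins and
#'   key-taxon ids).
#' @param config a [sim_config()].
#' @param n_transfers number of weekly transfers to iterate.
#' @param trace if `TRUE`, also return the invader (HP-unique) total
#'   frequency after every transfer.
#' @return the endpoint relative-abundance vector; with `trace = TRUE`, a
#'   list `(profile, invader_fraction)`.
#' @export
transfer_dynamics <- function(profile, truth, config, n_transfers,
                              trace = FALSE) {
  stopifnot(abs(sum(profile) - 1) < 1e-8)
  hp_only <- names(profile) %in% names(truth$origin)[truth$origin == "HP_only"]
  is_key <- names(profile) %in% truth$key_taxa
  s <- config$invader_fitness_s
  traj <- numeric(n_transfers)
  p <- profile
  for (t in seq_len(n_transfers)) {
    w <- rep(1, length(p))
    if (any(hp_only) && s != 0) {
      # weekly batch growth of the invader guild, truncated at its niche:
      # the guild multiplier m gives post-growth frequency
      # m*X / (m*X + 1 - X); m_fill is the value that lands exactly on
      # x_max, so growth stops when the niche resource is exhausted and an
      # over-filled guild (X > x_max) starves back down — the niche is a
      # two-sided attractor and every dose converges to the same invader
      # mass
      X <- sum(p[hp_only])
      m <- 1 + s
      if (is.finite(config$x_max) && X > 0 && X < 1 - 1e-12) {
        m_fill <- (config$x_max * (1 - X)) / (X * (1 - config$x_max))
        m <- min(m, m_fill)
      }
      w[hp_only] <- m
    }
    if (config$allee_fc_all > 0)
      w[hp_only & !is_key & p < config$allee_fc_all & p > 0] <-
        config$allee_sub_w
    if (config$allee_fc > 0 && any(is_key))
      w[is_key & p < config$allee_fc & p > 0] <- config$allee_sub_w
    q <- p * w
    q <- q / sum(q)
    if (is.finite(config$bottleneck_N)) {
      counts <- stats::rmultinom(1, config$bottleneck_N, q)[, 1]
      p <- counts / config$bottleneck_N
    } else {
      p <- q
    }
    if (trace) traj[t] <- sum(p[hp_only])
  }
  if (trace) list(profile = p, invader_fraction = traj) else p
}

#' Sequencing-depth read sampling
#'
#' @param profile relative-abundance vector summing to 1.
#' @param depth total reads to draw.
#' @return integer count vector (same names), summing to `depth`.
#' @export
sample_reads <- function(profile, depth) {
  stopifnot(abs(sum(profile) - 1) < 1e-8, depth >= 1)
  counts <- stats::rmultinom(1, depth, profile)[, 1]
  stats::setNames(as.integer(counts), names(profile))
}

#' Key-taxon-gated weekly biogas series for one fermenter
#'
#' Weekly production runs at `gas_base_rate`; from week `invasion_week +
#' gas_lag_weeks + 1` onward it switches to `gas_boost_rate` iff at least
#' `key_taxa_k` of the key taxa are present (nonzero) in the endpoint
#' community profile. Pure HP fermenters produce at the boosted rate
#' throughout. With `backlog = TRUE` the switch also releases the substrate
#' backlog of the base-rate weeks, spread uniformly over the remaining
#' weeks (catch-up kinetics). Gaussian noise (`noise_sd`) perturbs weekly
#' increments, truncated at 0 so the cumulative series stays
#' non-decreasing.
#'
#' @param endpoint_profile the fermenter's endpoint relative abundances.
#' @param truth `sim_truth` carrying `key_taxa`.
#' @param config a [sim_config()] (rates, lag, `key_taxa_k`).
#' @param invasion_week week at whose end invasion happened (pure
#'   communities: any value with `pure != "no"`).
#' @param n_weeks total weeks measured.
#' @param pure `"no"` for invaded fermenters, `"LP"` or `"HP"` for pure.
#' @param backlog enable catch-up release on switching.
#' @param noise_sd weekly-increment noise, mL.
#' @param sample_id id used in the returned frame.
#' @return a [gas_series_frame()] with weeks `1..n_weeks`.
#' @export
sim_gas_series <- function(endpoint_profile, truth, config, invasion_week,
                           n_weeks, pure = c("no", "LP", "HP"),
                           backlog = FALSE, noise_sd = 0,
                           sample_id = "sample") {
  pure <- match.arg(pure)
  base <- config$gas_base_rate
  boost <- config$gas_boost_rate
  rates <- rep(base, n_weeks)
  if (pure == "HP") {
    rates[] <- boost
  } else if (pure == "no") {
    n_key_present <- sum(endpoint_profile[truth$key_taxa] > 0, na.rm = TRUE)
    if (n_key_present >= config$key_taxa_k && config$key_taxa_k >= 0 &&
        length(truth$key_taxa) > 0) {
      onset <- invasion_week + config$gas_lag_weeks  # boosted weeks: onset+1..
      if (onset < n_weeks) {
        boosted <- seq(onset + 1L, n_weeks)
        rates[boosted] <- boost
        if (backlog) {
          deficit <- (boost - base) * onset
          rates[boosted] <- rates[boosted] + deficit / length(boosted)
        }
      }
    }
  }
  if (noise_sd > 0)
    rates <- pmax(0, rates + stats::rnorm(n_weeks, 0, noise_sd))
  gas_series_frame(rep(sample_id, n_weeks), seq_len(n_weeks), cumsum(rates))
}

#' Simulate a complete invasion study
#'
#' Produces the full dataset of the default design: pure LP and pure HP
#' replicates (optionally dropping one HP sample, mirroring a failed
#' sequencing run) and `replicates` fermenters per invasion dose. Every
#' fermenter runs `n_transfers_pre` weekly transfers from its source
#' profile; invaded fermenters are then mixed volumetrically with the
#' pre-adapted HP replicate-1 community and run `n_transfers_post` further
#' transfers under selection. Endpoint communities are read-sampled at
#' 350-500k reads, a coalescent tree with exponential branch lengths is
#' simulated over all ASVs, and weekly gas follows the key-taxon gate.
#' Every random stream derives from `config$seed` via stable per-sample
#' substreams, so the output is fully reproducible and adding samples
#' never perturbs existing ones.
#'
#' @param config a [sim_config()].
#' @return list of class `"sim_study"`: `table` ([asv_table()]),
#'   `metadata`, `tree` (`phylo`), `gas` ([gas_series_frame()]), `truth`
#'   (`sim_truth` with per-sample `dose` and invader-fraction
#'   trajectories), and `config`.
#' @export
simulate_study <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  src <- with_substream(config$seed, "sources", generate_sources(config))
  truth <- src$truth
  n_weeks <- config$n_transfers_pre + config$n_transfers_post
  invasion_week <- config$n_transfers_pre

  # pre-adapted HP replicate 1: the inoculum for every invasion
  hp_inoculum <- with_substream(config$seed, "inoculum:HP:1",
    transfer_dynamics(src$hp, truth, jitter_niche(config),
                      config$n_transfers_pre))

  dose_labels <- dose_treatment_label(config$doses)
  design <- rbind(
    data.frame(treatment = "LP", replicate = seq_len(config$replicates),
               dose = NA_real_),
    data.frame(treatment = "HP",
               replicate = seq_len(config$replicates -
                                     as.integer(isTRUE(config$drop_hp_sample))),
               dose = NA_real_),
    do.call(rbind, lapply(seq_along(config$doses), function(i)
      data.frame(treatment = dose_labels[i],
                 replicate = seq_len(config$replicates),
                 dose = config$doses[i]))))
  design$sample_id <- paste(design$treatment, design$replicate, sep = "_")

  n_taxa <- length(src$lp)
  counts <- matrix(0L, nrow(design), n_taxa,
                   dimnames = list(design$sample_id, names(src$lp)))
  endpoints <- matrix(0, nrow(design), n_taxa,
                      dimnames = list(design$sample_id, names(src$lp)))
  trajectories <- list()
  gas_rows <- vector("list", nrow(design))

  for (i in seq_len(nrow(design))) {
    row <- design[i, ]
    with_substream(config$seed, paste0("sample:", row$sample_id), {
      cfg_rep <- jitter_niche(config)
      if (row$treatment %in% c("LP", "HP")) {
        start <- if (row$treatment == "LP") src$lp else src$hp
        res <- transfer_dynamics(start, truth, cfg_rep, n_weeks, trace = TRUE)
      } else {
        pre <- transfer_dynamics(src$lp, truth, cfg_rep,
                                 config$n_transfers_pre)
        mixed <- mix_profiles(pre, hp_inoculum, row$dose)
        res <- transfer_dynamics(mixed, truth, cfg_rep,
                                 config$n_transfers_post, trace = TRUE)
      }
      endpoint <- res$profile
      trajectories[[row$sample_id]] <- res$invader_fraction
      depth <- round(stats::runif(1, config$read_depth[1],
                                  config$read_depth[2]))
      counts[i, ] <- sample_reads(endpoint, depth)
      endpoints[i, ] <- endpoint
      pure <- if (row$treatment %in% c("LP", "HP")) row$treatment else "no"
      gas_rows[[i]] <- sim_gas_series(
        endpoint, truth, config, invasion_week, n_weeks, pure = pure,
        backlog = config$backlog_release, noise_sd = config$gas_noise_sd,
        sample_id = row$sample_id)
    })
  }

  tree <- with_substream(config$seed, "tree", {
    tr <- ape::rcoal(n_taxa, tip.label = names(src$lp))
    tr$edge.length <- stats::rexp(nrow(tr$edge))
    tr
  })

  truth$dose <- stats::setNames(design$dose, design$sample_id)
  truth$invader_trajectory <- trajectories
  gas <- do.call(rbind, gas_rows)
  class(gas) <- c("gas_series", "data.frame")

  structure(list(
    table = asv_table(counts),
    metadata = sample_metadata(design$sample_id, design$treatment,
                               design$replicate, rep(n_weeks, nrow(design))),
    tree = tree, gas = gas, truth = truth, config = config,
    endpoint_profiles = endpoints, lp_source = src$lp, hp_source = src$hp),
    class = "sim_study")
}

# bottle-level environmental draw of the niche size (uses current stream)
jitter_niche <- function(config) {
  if (config$x_max_rep_sd <= 0 || !is.finite(config$x_max)) return(config)
  config$x_max <- config$x_max * exp(stats::rnorm(1, 0, config$x_max_rep_sd))
  config
}

dose_treatment_label <- function(doses) {
  lab <- paste0("D", vapply(doses * 100, function(d)
    format(d, scientific = FALSE, trim = TRUE, drop0trailing = TRUE),
    character(1)))
  known <- treatment_levels()
  bad <- setdiff(lab, known)
  if (length(bad))
    stop("dose(s) outside the supported treatment label set: ",
         paste(bad, collapse = ", "))
  lab
}

#' @export
print.sim_study <- function(x, ...) {
  cat("Synthetic invasion study\n")
  print(x$table)
  cat(sprintf("  truth: %d LP-only, %d HP-only, %d shared ASVs; %d key taxa\n",
              sum(x$truth$origin == "LP_only"),
              sum(x$truth$origin == "HP_only"),
              sum(x$truth$origin == "shared"), length(x$truth$key_taxa)))
  invisible(x)
}

#' Write / read the simulator ground truth as JSON
#'
#' The oracle file for validating attribution on synthetic data.
#'
#' @param truth a `sim_truth`.
#' @param path JSON path.
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(list(
    origin = as.list(truth$origin),
    key_taxa = truth$key_taxa,
    dose = as.list(truth$dose)), path, auto_unbox = TRUE, digits = NA,
    na = "null", null = "null")
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  x <- jsonlite::read_json(path)
  structure(list(
    origin = unlist(x$origin),
    key_taxa = as.character(unlist(x$key_taxa)),
    dose = unlist(lapply(x$dose, function(d) if (is.null(d)) NA_real_ else d)),
    invader_trajectory = NULL), class = "sim_truth")
}
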