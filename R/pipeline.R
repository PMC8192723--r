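#' Run the full invasion analysis end to end
#'
#' Orchestrates the pipeline in study order — simulate (or load), validate,
#' attribute origins, invasion statistics, alpha/beta diversity with
#' PERMANOVA, the tipping-point screen, and gas dose-response and
#' many-to-one contrasts — optionally writing every artifact plus a
#' checksummed manifest into an output directory. Rerunning with the same
#' configuration and seed reproduces the report exactly.
#'
#' @param config a [sim_config()]; drives the simulator and seeds every
#'   stochastic stage (permutations, Monte-Carlo Dunnett).
#' @param out_dir optional directory for artifacts; created if missing.
#' @param real_data optional list with elements `table`, `metadata`,
#'   `tree`, `gas` — skips simulation and analyses user data (no ground
#'   truth, so truth scoring is omitted).
#' @param n_permutations PERMANOVA permutations.
#' @return list of class `"run_report"` with per-stage results.
#' @export
run_study <- function(config = sim_config(), out_dir = NULL,
                      real_data = NULL, n_permutations = 999) {
  artifacts <- character(0)
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  emit <- function(name, writer) {
    if (is.null(out_dir)) return(invisible(NULL))
    path <- file.path(out_dir, name)
    writer(path)
    artifacts[[length(artifacts) + 1L]] <<- path
    invisible(path)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      if (!is.null(out_dir)) write_manifest(artifacts, out_dir)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }

  study <- stage("data", {
    if (is.null(real_data)) {
      s <- simulate_study(config)
      emit("asv_table.tsv", function(p) write_asv_table(s$table, p))
      emit("metadata.tsv", function(p) write_sample_metadata(s$metadata, p))
      emit("tree.nwk", function(p) write_newick(s$tree, p))
      emit("gas.csv", function(p) write_gas_series(s$gas, p))
      emit("truth.json", function(p) write_truth(s$truth, p))
      s
    } else {
      need <- c("table", "metadata", "tree", "gas")
      miss <- setdiff(need, names(real_data))
      if (length(miss))
        stop("real_data missing element(s): ", paste(miss, collapse = ", "))
      c(real_data, list(truth = NULL, config = config))
    }
  })
  stage("validate", {
    report <- validate_bundle(study$table, study$metadata, study$tree,
                              study$gas)
    if (nrow(report) > 0)
      stop("inconsistent bundle:\n",
           paste(report$message, collapse = "\n"))
  })

  invaded <- study$metadata$sample_id[
    !study$metadata$treatment %in% c("LP", "HP")]
  attribution <- stage("attribution", {
    origins <- attribute_origin(study$table, study$metadata)
    metrics <- invasion_metrics(study$table, origins, samples = invaded)
    tests <- lapply(c("read_fraction", "asv_fraction", "asv_count"),
                    function(r) dose_effect_test(metrics, study$metadata,
                                                 response = r))
    names(tests) <- c("read_fraction", "asv_fraction", "asv_count")
    score <- if (!is.null(study$truth))
      score_against_truth(origins, study$truth) else NULL
    emit("origins.tsv", function(p) utils::write.table(
      data.frame(asv_id = names(origins), label = unclass(origins)),
      p, sep = "\t", quote = FALSE, row.names = FALSE))
    emit("invasion_metrics.tsv", function(p) utils::write.table(
      as.data.frame(metrics), p, sep = "\t", quote = FALSE,
      row.names = FALSE))
    list(origins = origins, metrics = metrics, dose_tests = tests,
         truth_score = score)
  })

  diversity <- stage("diversity", {
    alpha <- alpha_diversity(study$table)
    d_uw <- unifrac_matrix(study$table, study$tree, "unweighted")
    d_w <- unifrac_matrix(study$table, study$tree, "weighted")
    grp <- study$metadata$treatment[match(rownames(study$table),
                                          study$metadata$sample_id)]
    perm_uw <- permanova(d_uw, grp, n_permutations,
                         seed = substream_seed(config$seed, "permanova:uw"))
    perm_w <- permanova(d_w, grp, n_permutations,
                        seed = substream_seed(config$seed, "permanova:w"))
    pw_w <- pairwise_permanova(d_w, grp, n_permutations,
                               seed = substream_seed(config$seed,
                                                     "pairwise:w"))
    emit("alpha_diversity.tsv", function(p) utils::write.table(
      alpha, p, sep = "\t", quote = FALSE, row.names = FALSE))
    emit("unifrac_unweighted.tsv", function(p) utils::write.table(
      as.data.frame(unclass(d_uw)), p, sep = "\t", quote = FALSE))
    emit("unifrac_weighted.tsv", function(p) utils::write.table(
      as.data.frame(unclass(d_w)), p, sep = "\t", quote = FALSE))
    list(alpha = alpha, unifrac_unweighted = d_uw, unifrac_weighted = d_w,
         permanova_unweighted = perm_uw, permanova_weighted = perm_w,
         pairwise_weighted = pw_w)
  })

  screen <- stage("screen", {
    sc <- screen_taxa(study$table, study$metadata)
    emit("screen_hits.tsv", function(p) utils::write.table(
      data.frame(asv_id = sc$stage1,
                 stage = ifelse(sc$stage1 %in% sc$stage2, 2L, 1L),
                 sc$prevalence, check.names = FALSE),
      p, sep = "\t", quote = FALSE, row.names = FALSE))
    sc
  })

  gas <- stage("gas", {
    summ <- summarize_gas(study$gas, study$metadata)
    trend <- dose_trend(summ)
    vs_hp <- many_to_one(summ, "HP",
                         seed = substream_seed(config$seed, "dunnett:HP"))
    vs_lp <- many_to_one(summ, "LP",
                         seed = substream_seed(config$seed, "dunnett:LP"))
    emit("gas_report.tsv", function(p) utils::write.table(
      rbind(as.data.frame(vs_hp), as.data.frame(vs_lp)),
      p, sep = "\t", quote = FALSE, row.names = FALSE))
    list(summary = summ, trend = trend, vs_hp = vs_hp, vs_lp = vs_lp)
  })

  report <- structure(list(
    config = config,
    seed = config$seed,
    version = as.character(utils::packageVersion("commvade")),
    attribution = attribution, diversity = diversity,
    screen = screen, gas = gas,
    data = study), class = "run_report")

  if (!is.null(out_dir)) {
    emit("config.yaml", function(p) yaml::write_yaml(
      unclass(config)[!vapply(unclass(config), is.null, logical(1))], p))
    emit("report.json", function(p) write_report_json(report, p))
    write_manifest(artifacts, out_dir)
  }
  report
}

write_manifest <- function(paths, out_dir) {
  rel <- basename(unlist(paths))
  sums <- unname(tools::md5sum(unlist(paths)))
  jsonlite::write_json(
    list(files = stats::setNames(as.list(sums), rel)),
    file.path(out_dir, "manifest.json"), auto_unbox = TRUE)
  invisible(NULL)
}

write_report_json <- function(report, path) {
  tests <- report$attribution$dose_tests
  out <- list(
    seed = report$seed,
    version = report$version,
    dose_effect = lapply(tests, function(t)
      list(F = t$F, df = t$df, p = t$p)),
    permanova = list(
      weighted = report$diversity$permanova_weighted[
        c("pseudo_F", "R2", "p_perm", "df_between", "df_within")],
      unweighted = report$diversity$permanova_unweighted[
        c("pseudo_F", "R2", "p_perm", "df_between", "df_within")]),
    screen = list(stage1 = report$screen$stage1,
                  stage2 = report$screen$stage2),
    gas = list(
      trend = report$gas$trend$log10,
      vs_hp = as.data.frame(report$gas$vs_hp),
      vs_lp = as.data.frame(report$gas$vs_lp)))
  if (!is.null(report$attribution$truth_score))
    out$truth_score <- list(
      n_inversions = report$attribution$truth_score$n_inversions,
      n_detection_misattributions =
        report$attribution$truth_score$n_detection_misattributions)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}

#' @export
print.run_report <- function(x, ...) {
  cat("commvade run report (seed", x$seed, ")\n\n")
  print(x$attribution$dose_tests$read_fraction)
  print(x$attribution$dose_tests$asv_count)
  if (!is.null(x$attribution$truth_score)) print(x$attribution$truth_score)
  cat("\nWeighted UniFrac "); print(x$diversity$permanova_weighted)
  cat("Unweighted UniFrac "); print(x$diversity$permanova_unweighted)
  cat("\n"); print(x$screen)
  cat("\n"); print(x$gas$trend)
  print(x$gas$vs_hp); print(x$gas$vs_lp)
  invisible(x)
}
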