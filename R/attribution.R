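#' Attribute ASV origin from pure-community endpoints
#'
#' The core classification rule of the pipeline: an ASV is "present in" a
#' pure community iff its count exceeds `presence_threshold` in at least
#' one endpoint replicate of that treatment. ASVs present in exactly one
#' pure community are attributed to it (`RESIDENT_ONLY` /
#' `INVADER_ONLY`); ASVs present in both are `SHARED` and ASVs present in
#' neither are `NEITHER` — both are unattributable and excluded from the
#' invasion statistics. Only endpoint pure-community samples (maximum
#' `week` by default) enter the rule, never ancestral inocula.
#'
#' @param table an [asv_table()].
#' @param metadata a [sample_metadata()] frame covering the table.
#' @param resident_label,invader_label treatment labels of the pure
#'   resident and invader communities (default `LP`, `HP`).
#' @param week_final the endpoint week; defaults to the maximum week among
#'   the pure-community samples.
#' @param presence_threshold reads strictly above this count as presence
#'   (default 0, i.e. any read).
#' @return named character vector over all table ASVs, values in
#'   `RESIDENT_ONLY`, `INVADER_ONLY`, `SHARED`, `NEITHER`; class
#'   `"origin_map"`, with the endpoint sample ids used kept as attributes.
#' @export
attribute_origin <- function(table, metadata, resident_label = "LP",
                             invader_label = "HP", week_final = NULL,
                             presence_threshold = 0) {
  stopifnot(inherits(table, "asv_table"))
  meta <- metadata[match(rownames(table), metadata$sample_id), ]
  if (anyNA(meta$sample_id))
    stop("metadata does not cover every table sample")
  pure <- meta$treatment %in% c(resident_label, invader_label)
  if (is.null(week_final)) week_final <- max(meta$week[pure])
  res_samples <- meta$sample_id[meta$treatment == resident_label &
                                  meta$week == week_final]
  inv_samples <- meta$sample_id[meta$treatment == invader_label &
                                  meta$week == week_final]
  if (length(res_samples) == 0)
    stop("no endpoint samples for resident treatment '", resident_label, "'")
  if (length(inv_samples) == 0)
    stop("no endpoint samples for invader treatment '", invader_label, "'")

  in_res <- apply(table[res_samples, , drop = FALSE] > presence_threshold,
                  2, any)
  in_inv <- apply(table[inv_samples, , drop = FALSE] > presence_threshold,
                  2, any)
  label <- ifelse(in_res & in_inv, "SHARED",
           ifelse(in_res, "RESIDENT_ONLY",
           ifelse(in_inv, "INVADER_ONLY", "NEITHER")))
  structure(stats::setNames(label, colnames(table)),
            resident_samples = res_samples, invader_samples = inv_samples,
            resident_label = resident_label, invader_label = invader_label,
            presence_threshold = presence_threshold,
            class = "origin_map")
}

#' Per-sample invasion-success statistics
#'
#' Headline fractions use the attributable (known-origin) reads/ASVs as
#' denominator, following the invader abundance/diversity definitions;
#' worst-case fractions instead divide the invader numerators by the full
#' sample totals, the bound obtained if every unattributed read or ASV
#' actually originated from the resident community. Samples with zero
#' attributable reads get `NA` fractions (flagged, never 0).
#'
#' @param table an [asv_table()].
#' @param origin_map an [attribute_origin()] result covering the table's
#'   ASVs.
#' @param samples sample ids to evaluate (default: all rows of `table`).
#' @return data.frame (class `"invasion_metrics"`), one row per sample:
#'   `invader_read_fraction`, `invader_asv_fraction`,
#'   `attributable_read_fraction`, `attributable_asv_fraction`,
#'   `worst_case_read_fraction`, `worst_case_asv_fraction`,
#'   `invader_asv_count`, `undefined`.
#' @export
invasion_metrics <- function(table, origin_map,
                             samples = rownames(table)) {
  stopifnot(inherits(table, "asv_table"))
  miss <- setdiff(colnames(table), names(origin_map))
  if (length(miss))
    stop("origin map does not cover ASV(s): ",
         paste(utils::head(miss, 5), collapse = ", "))
  lab <- origin_map[colnames(table)]
  inv <- lab == "INVADER_ONLY"
  res <- lab == "RESIDENT_ONLY"
  out <- lapply(samples, function(sid) {
    x <- as.numeric(table[sid, ])
    present <- x > 0
    total_reads <- sum(x)
    total_asvs <- sum(present)
    inv_reads <- sum(x[inv])
    res_reads <- sum(x[res])
    inv_asvs <- sum(present & inv)
    res_asvs <- sum(present & res)
    attr_reads <- inv_reads + res_reads
    attr_asvs <- inv_asvs + res_asvs
    undefined <- attr_reads == 0
    data.frame(
      sample_id = sid,
      invader_read_fraction = if (undefined) NA_real_ else
        inv_reads / attr_reads,
      invader_asv_fraction = if (attr_asvs == 0) NA_real_ else
        inv_asvs / attr_asvs,
      attributable_read_fraction = attr_reads / total_reads,
      attributable_asv_fraction = if (total_asvs == 0) NA_real_ else
        attr_asvs / total_asvs,
      worst_case_read_fraction = inv_reads / total_reads,
      worst_case_asv_fraction = if (total_asvs == 0) NA_real_ else
        inv_asvs / total_asvs,
      invader_asv_count = inv_asvs,
      undefined = undefined,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  class(out) <- c("invasion_metrics", "data.frame")
  out
}

#' Test whether an invasion statistic varies with propagule pressure
#'
#' One-way fixed-effects linear model of the chosen response on dose
#' treatment as a categorical predictor, reporting the full-vs-null F test
#' and Tukey-adjusted post-hoc pairwise contrasts. Samples with undefined
#' (missing) metrics are dropped listwise, with the count reported.
#'
#' @param metrics an [invasion_metrics()] frame.
#' @param metadata a [sample_metadata()] frame.
#' @param response one of `"read_fraction"`, `"asv_fraction"`,
#'   `"asv_count"`.
#' @param treatments treatment labels to include (default: the dose
#'   treatments present).
#' @return list of class `"dose_effect_test"`: `F`, `df`, `p`, `anova`,
#'   `pairwise` (TukeyHSD table), `n_dropped`.
#' @export
dose_effect_test <- function(metrics, metadata,
                             response = c("read_fraction", "asv_fraction",
                                          "asv_count"),
                             treatments = NULL) {
  response <- match.arg(response)
  col <- switch(response,
                read_fraction = "invader_read_fraction",
                asv_fraction = "invader_asv_fraction",
                asv_count = "invader_asv_count")
  df <- merge(as.data.frame(metrics),
              as.data.frame(metadata)[, c("sample_id", "treatment")],
              by = "sample_id")
  if (is.null(treatments))
    treatments <- intersect(c("D10", "D1", "D0.1", "D0.01"),
                            unique(df$treatment))
  df <- df[df$treatment %in% treatments, ]
  n0 <- nrow(df)
  df <- df[!is.na(df[[col]]), ]
  n_dropped <- n0 - nrow(df)
  tab <- table(df$treatment)
  if (length(tab) < 2 || any(tab < 2))
    stop("dose_effect_test needs >= 2 dose groups with >= 2 replicates each")
  df$treatment <- factor(df$treatment, levels = treatments)
  fit <- stats::aov(df[[col]] ~ treatment, data = df)
  an <- stats::anova(fit)
  structure(list(response = response,
                 F = an[1, "F value"], p = an[1, "Pr(>F)"],
                 df = c(an[1, "Df"], an[2, "Df"]),
                 anova = an,
                 pairwise = stats::TukeyHSD(fit)$treatment,
                 n_dropped = n_dropped),
            class = "dose_effect_test")
}

#' @export
print.dose_effect_test <- function(x, ...) {
  cat(sprintf("Dose effect on invader %s: F(%d,%d) = %.4g, p = %.4g\n",
              x$response, x$df[1], x$df[2], x$F, x$p))
  if (x$n_dropped > 0)
    cat(sprintf("  (%d sample(s) with undefined metrics dropped)\n",
                x$n_dropped))
  invisible(x)
}

#' Score an origin map against simulator ground truth
#'
#' Cross-tabulates assigned labels against true origins and separates
#' true label inversions (assigned invader with true resident origin, or
#' vice versa — the failure mode the attribution rule must never show)
#' from detection-induced misattributions (truth-shared ASVs assigned to
#' one side because they went extinct in the other pure community's
#' endpoints).
#'
#' @param origin_map an [attribute_origin()] result.
#' @param truth a `sim_truth`.
#' @return list of class `"attribution_score"`: `confusion` (assigned x
#'   true table), `n_inversions`, `n_detection_misattributions`.
#' @export
score_against_truth <- function(origin_map, truth) {
  ids <- intersect(names(origin_map), names(truth$origin))
  assigned <- factor(unclass(origin_map)[ids],
                     levels = c("RESIDENT_ONLY", "INVADER_ONLY",
                                "SHARED", "NEITHER"))
  true <- factor(truth$origin[ids],
                 levels = c("LP_only", "HP_only", "shared"))
  confusion <- table(assigned = assigned, true = true)
  n_inversions <- confusion["RESIDENT_ONLY", "HP_only"] +
    confusion["INVADER_ONLY", "LP_only"]
  n_detect <- confusion["RESIDENT_ONLY", "shared"] +
    confusion["INVADER_ONLY", "shared"]
  structure(list(confusion = confusion,
                 n_inversions = as.integer(n_inversions),
                 n_detection_misattributions = as.integer(n_detect)),
            class = "attribution_score")
}

#' @export
print.attribution_score <- function(x, ...) {
  cat("Attribution vs. ground truth\n")
  print(x$confusion)
  cat(sprintf("label inversions: %d; detection-induced misattributions: %d\n",
              x$n_inversions, x$n_detection_misattributions))
  invisible(x)
}
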