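#' Configuration of the tipping-point taxon screen
#'
#' @param high_treatments treatments above the functional tipping point
#'   (default the 10 and 1 percent doses).
#' @param low_treatments treatments below it (default 0.1 and 0.01
#'   percent).
#' @param prevalence_min stage-2 keeps ASVs detected in strictly more than
#'   this fraction of each high treatment's replicates.
#' @param presence_threshold reads strictly above this count as presence.
#' @param high_conjunction stage-1 presence rule across high treatments:
#'   `TRUE` (default) requires presence in every high treatment, `FALSE`
#'   in at least one.
#' @param prevalence_pooled apply the stage-2 prevalence rule to the
#'   pooled high-treatment replicates instead of per treatment.
#' @return list of class `"screen_config"`.
#' @export
screen_config <- function(high_treatments = c("D10", "D1"),
                          low_treatments = c("D0.1", "D0.01"),
                          prevalence_min = 0.5,
                          presence_threshold = 0,
                          high_conjunction = TRUE,
                          prevalence_pooled = FALSE) {
  if (length(intersect(high_treatments, low_treatments)))
    stop("high and low treatment sets must be disjoint")
  if (!length(high_treatments) || !length(low_treatments))
    stop("high and low treatment sets must be non-empty")
  stopifnot(prevalence_min >= 0, prevalence_min <= 1)
  structure(list(high_treatments = high_treatments,
                 low_treatments = low_treatments,
                 prevalence_min = prevalence_min,
                 presence_threshold = presence_threshold,
                 high_conjunction = high_conjunction,
                 prevalence_pooled = prevalence_pooled),
            class = "screen_config")
}

screen_presence <- function(table, metadata, treatment, config) {
  ids <- metadata$sample_id[metadata$treatment == treatment]
  if (!length(ids))
    stop("treatment '", treatment, "' has no samples in metadata")
  table[ids, , drop = FALSE] > config$presence_threshold
}

#' Stage-1 tipping-point screen
#'
#' ASVs present (in at least one replicate) in the high-dose treatments but
#' absent from every replicate of every low-dose treatment — the
#' candidates for taxa whose presence tracks the functional tipping point.
#' "Present in the high treatments" is a conjunction by default (present
#' in each); a flag switches to the union reading.
#'
#' @param table an [asv_table()].
#' @param metadata a [sample_metadata()] frame.
#' @param config a [screen_config()].
#' @return lexicographically ordered character vector of ASV ids.
#' @export
tipping_point_asvs <- function(table, metadata, config = screen_config()) {
  stopifnot(inherits(table, "asv_table"))
  high_hit <- vapply(config$high_treatments, function(tr)
    apply(screen_presence(table, metadata, tr, config), 2, any),
    logical(ncol(table)))
  in_high <- if (config$high_conjunction) apply(high_hit, 1, all)
             else apply(high_hit, 1, any)
  low_hit <- vapply(config$low_treatments, function(tr)
    apply(screen_presence(table, metadata, tr, config), 2, any),
    logical(ncol(table)))
  in_low <- apply(low_hit, 1, any)
  sort(colnames(table)[in_high & !in_low])
}

#' Stage-2 prevalence refinement
#'
#' Keeps stage-1 hits detected in strictly more than `prevalence_min` of
#' the replicates within each high treatment separately (or pooled, by
#' flag).
#'
#' @param table an [asv_table()].
#' @param metadata a [sample_metadata()] frame.
#' @param stage1_hits ASV ids from [tipping_point_asvs()].
#' @param config a [screen_config()].
#' @return lexicographically ordered subset of `stage1_hits`.
#' @export
prevalence_refine <- function(table, metadata, stage1_hits,
                              config = screen_config()) {
  stopifnot(all(stage1_hits %in% colnames(table)))
  if (!length(stage1_hits)) return(character(0))
  if (config$prevalence_pooled) {
    pres <- do.call(rbind, lapply(config$high_treatments, function(tr)
      screen_presence(table, metadata, tr, config)))
    prev <- colMeans(pres[, stage1_hits, drop = FALSE])
    keep <- prev > config$prevalence_min
  } else {
    keep <- rep(TRUE, length(stage1_hits))
    for (tr in config$high_treatments) {
      pres <- screen_presence(table, metadata, tr, config)
      prev <- colMeans(pres[, stage1_hits, drop = FALSE])
      keep <- keep & (prev > config$prevalence_min)
    }
  }
  sort(stage1_hits[keep])
}

#' Run the full two-stage screen
#'
#' @inheritParams tipping_point_asvs
#' @return list of class `"taxa_screen"`: `stage1`, `stage2`, and a
#'   per-ASV prevalence table for the high treatments.
#' @export
screen_taxa <- function(table, metadata, config = screen_config()) {
  stage1 <- tipping_point_asvs(table, metadata, config)
  stage2 <- prevalence_refine(table, metadata, stage1, config)
  prev <- if (length(stage1)) {
    do.call(cbind, lapply(config$high_treatments, function(tr) {
      pres <- screen_presence(table, metadata, tr, config)
      colMeans(pres[, stage1, drop = FALSE])
    }))
  } else matrix(numeric(0), 0, length(config$high_treatments))
  colnames(prev) <- config$high_treatments
  structure(list(stage1 = stage1, stage2 = stage2, prevalence = prev,
                 config = config), class = "taxa_screen")
}

#' @export
print.taxa_screen <- function(x, ...) {
  cat(sprintf("Tipping-point screen: %d stage-1 hits, %d after prevalence refinement (> %.0f%% of %s replicates)\n",
              length(x$stage1), length(x$stage2),
              100 * x$config$prevalence_min,
              paste(x$config$high_treatments, collapse = " and ")))
  if (length(x$stage2))
    cat("stage-2:", paste(x$stage2, collapse = ", "), "\n")
  invisible(x)
}
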