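#' Construct an ASV count table
#'
#' The central object of the pipeline: a samples x ASVs matrix of
#' non-negative integer read counts. Counts are never rarefied anywhere in
#' the package; relative abundances are derived on the fly where a method
#' needs them.
#'
#' @param counts numeric matrix, samples in rows, ASVs in columns. Values
#'   must be non-negative and integral (a numeric that is exactly integral is
#'   coerced; `3.5` is an error).
#' @param sample_ids,asv_ids character vectors of unique identifiers;
#'   default to the dimnames of `counts`.
#' @return an `asv_table`: an integer matrix with class `"asv_table"`,
#'   rownames = sample ids, colnames = ASV ids.
#' @examples
#' tab <- asv_table(matrix(c(5, 0, 0, 7), 2, 2,
#'   dimnames = list(c("s1", "s2"), c("a", "b"))))
#' rowSums(tab)
#' @export
asv_table <- function(counts, sample_ids = rownames(counts),
                      asv_ids = colnames(counts)) {
  if (!is.matrix(counts)) counts <- as.matrix(counts)
  if (is.null(sample_ids) || is.null(asv_ids))
    stop("sample_ids and asv_ids are required (as arguments or dimnames)")
  if (length(sample_ids) != nrow(counts) || length(asv_ids) != ncol(counts))
    stop("id lengths do not match the count matrix dimensions")
  sample_ids <- as.character(sample_ids)
  asv_ids <- as.character(asv_ids)
  if (anyDuplicated(sample_ids))
    stop("duplicate sample ids: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  if (anyDuplicated(asv_ids))
    stop("duplicate ASV ids: ",
         paste(unique(asv_ids[duplicated(asv_ids)]), collapse = ", "))
  if (anyNA(counts) || !is.numeric(counts))
    stop("counts must be numeric with no missing values")
  if (any(counts < 0)) stop("counts must be non-negative")
  if (any(abs(counts - round(counts)) > 1e-8))
    stop("non-integer count encountered; read counts must be integral")
  zero <- rowSums(counts) == 0
  if (any(zero))
    stop("sample(s) with zero total reads: ",
         paste(sample_ids[zero], collapse = ", "))
  storage.mode(counts) <- "integer"
  dimnames(counts) <- list(sample_ids, asv_ids)
  class(counts) <- c("asv_table", class(counts))
  counts
}

#' @export
print.asv_table <- function(x, ...) {
  cat(sprintf("ASV count table: %d samples x %d ASVs, %s total reads\n",
              nrow(x), ncol(x), format(sum(as.numeric(x)), big.mark = ",")))
  cat("samples:", paste(utils::head(rownames(x), 6), collapse = ", "),
      if (nrow(x) > 6) "..." else "", "\n")
  invisible(x)
}

#' Relative abundances of an ASV table
#'
#' @param table an [asv_table()].
#' @return numeric matrix of the same shape; each row sums to 1.
#' @export
relative_abundance <- function(table) {
  stopifnot(inherits(table, "asv_table"))
  sweep(unclass(table), 1, rowSums(table), "/")
}

#' Sample metadata constructor
#'
#' @param sample_id character ids, one per sample.
#' @param treatment treatment labels, each one of `LP`, `HP`, `D10`, `D1`,
#'   `D0.1`, `D0.01` (pure low producer, pure high producer, and the four
#'   invasion doses as percent by volume).
#' @param replicate positive integer replicate index within treatment.
#' @param week non-negative integer sampling week.
#' @return data.frame with class `"sample_metadata"`.
#' @export
sample_metadata <- function(sample_id, treatment, replicate, week) {
  sample_id <- as.character(sample_id)
  treatment <- as.character(treatment)
  bad <- setdiff(unique(treatment), treatment_levels())
  if (length(bad))
    stop("unknown treatment label(s): ", paste(bad, collapse = ", "),
         " (allowed: ", paste(treatment_levels(), collapse = ", "), ")")
  replicate <- as.integer(replicate)
  week <- as.integer(week)
  if (anyDuplicated(sample_id))
    stop("duplicate sample ids in metadata")
  if (any(replicate < 1L)) stop("replicate must be a positive integer")
  if (any(week < 0L)) stop("week must be non-negative")
  out <- data.frame(sample_id = sample_id, treatment = treatment,
                    replicate = replicate, week = week,
                    stringsAsFactors = FALSE)
  class(out) <- c("sample_metadata", "data.frame")
  out
}

#' Allowed treatment labels
#'
#' @return character vector: pure communities then doses, high to low.
#' @export
treatment_levels <- function() c("LP", "HP", "D10", "D1", "D0.1", "D0.01")

#' Map dose treatments to volume fractions
#'
#' @param treatment character vector of treatment labels.
#' @return numeric vector: volume fraction for dose treatments, `NA` for
#'   pure communities.
#' @export
treatment_dose <- function(treatment) {
  map <- c(D10 = 0.1, D1 = 0.01, `D0.1` = 0.001, `D0.01` = 1e-4,
           LP = NA_real_, HP = NA_real_)
  unname(map[as.character(treatment)])
}

#' Gas series constructor
#'
#' Long-format weekly cumulative CO2-stripped biogas per fermenter.
#'
#' @param sample_id character ids (repeated across weeks).
#' @param week integer week of measurement.
#' @param cumulative_gas_ml non-negative cumulative volume, mL; must be
#'   non-decreasing in week within each sample.
#' @return data.frame with class `"gas_series"`.
#' @export
gas_series_frame <- function(sample_id, week, cumulative_gas_ml) {
  out <- data.frame(sample_id = as.character(sample_id),
                    week = as.integer(week),
                    cumulative_gas_ml = as.numeric(cumulative_gas_ml),
                    stringsAsFactors = FALSE)
  if (any(out$cumulative_gas_ml < 0)) stop("cumulative gas must be >= 0")
  out <- out[order(out$sample_id, out$week), , drop = FALSE]
  rownames(out) <- NULL
  for (sid in unique(out$sample_id)) {
    g <- out$cumulative_gas_ml[out$sample_id == sid]
    if (is.unsorted(g)) {
      wk <- out$week[out$sample_id == sid][which(diff(g) < 0)[1] + 1L]
      stop(sprintf("cumulative gas decreases for sample %s at week %d",
                   sid, wk))
    }
  }
  class(out) <- c("gas_series", "data.frame")
  out
}
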