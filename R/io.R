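#' Read an ASV count table from TSV or BIOM
#'
#' TSV dialect: samples in rows, ASVs in columns, first header cell
#' `sample_id`. The transposed orientation is auto-detected only when the
#' first header cell is `asv_id`; any other first header is rejected, so a
#' silently transposed table can never slip through. BIOM files (the
#' "sample by observation" convention) are read through the biomformat
#' package.
#'
#' @param path file path.
#' @param format `"tsv"` or `"biom"`.
#' @return an [asv_table()].
#' @export
read_asv_table <- function(path, format = c("tsv", "biom")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "biom") {
    if (!requireNamespace("biomformat", quietly = TRUE))
      stop("reading BIOM requires the biomformat package")
    b <- biomformat::read_biom(path)
    m <- as.matrix(biomformat::biom_data(b))  # observations x samples
    return(asv_table(t(m)))
  }
  header <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1]]
  if (length(header) < 2L)
    stop("format error: expected a tab-delimited table with >= 2 columns")
  first <- header[1]
  if (!first %in% c("sample_id", "asv_id"))
    stop("format error: first header cell must be 'sample_id' ",
         "(samples in rows) or 'asv_id' (transposed); got '", first, "'")
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE,
                          colClasses = c("character"))
  ids <- df[[1]]
  num <- as.matrix(df[, -1, drop = FALSE])
  suppressWarnings(storage.mode(num) <- "numeric")
  if (anyNA(num))
    stop("format error: non-numeric count in ", basename(path))
  if (any(abs(num - round(num)) > 1e-8))
    stop("format error: non-integer count in ", basename(path))
  rownames(num) <- ids
  if (first == "asv_id") num <- t(num)
  asv_table(num)
}

#' Write an ASV count table as TSV
#'
#' @param table an [asv_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_asv_table <- function(table, path) {
  stopifnot(inherits(table, "asv_table"))
  df <- data.frame(sample_id = rownames(table), unclass(table),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read sample metadata from TSV
#'
#' Expects exactly the columns `sample_id`, `treatment`, `replicate`,
#' `week`.
#'
#' @param path file path.
#' @return a [sample_metadata()] data frame.
#' @export
read_sample_metadata <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  need <- c("sample_id", "treatment", "replicate", "week")
  if (!setequal(names(df), need))
    stop("metadata must have exactly the columns ",
         paste(need, collapse = ", "))
  sample_metadata(df$sample_id, df$treatment, df$replicate, df$week)
}

#' @rdname read_sample_metadata
#' @param metadata a [sample_metadata()] frame.
#' @export
write_sample_metadata <- function(metadata, path) {
  utils::write.table(as.data.frame(metadata), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a rooted phylogeny from Newick
#'
#' Thin wrapper over [ape::read.tree()] adding the validation the pipeline
#' relies on: unique leaf labels and non-negative branch lengths. The tree's
#' branch-length units are irrelevant to UniFrac ratios.
#'
#' @param path file path containing a single Newick string.
#' @return an [ape::read.tree()] `phylo` object.
#' @export
read_newick <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tree <- tryCatch(ape::read.tree(path),
                   error = function(e) stop("Newick parse error: ",
                                            conditionMessage(e)))
  if (is.null(tree)) stop("Newick parse error: could not parse ", path)
  validate_phylo(tree)
}

#' @rdname read_newick
#' @param tree a `phylo` object.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path, digits = 15)
  invisible(path)
}

validate_phylo <- function(tree) {
  if (!inherits(tree, "phylo")) stop("not a phylo object")
  if (anyDuplicated(tree$tip.label))
    stop("duplicate leaf labels in tree")
  if (is.null(tree$edge.length))
    stop("tree has no branch lengths")
  if (any(tree$edge.length < 0))
    stop("negative branch length in tree")
  tree
}

#' Read/write a weekly cumulative gas series (long CSV)
#'
#' Columns: `sample_id`, `week`, `cumulative_gas_ml`. Missing weeks are not
#' interpolated anywhere in the pipeline; analyses use observed weeks only.
#'
#' @param path file path.
#' @return a [gas_series_frame()].
#' @export
read_gas_series <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "week", "cumulative_gas_ml")
  if (!all(need %in% names(df)))
    stop("gas CSV must have columns ", paste(need, collapse = ", "))
  gas_series_frame(df$sample_id, df$week, df$cumulative_gas_ml)
}

#' @rdname read_gas_series
#' @param gas a [gas_series_frame()].
#' @export
write_gas_series <- function(gas, path) {
  utils::write.csv(as.data.frame(gas), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Cross-validate a study bundle
#'
#' Checks the joint consistency of count table, metadata, and (optionally)
#' tree and gas series. Findings are returned, never thrown: an empty report
#' means the bundle is consistent.
#'
#' @param table an [asv_table()].
#' @param metadata a [sample_metadata()] frame.
#' @param tree optional `phylo` covering every ASV observed with nonzero
#'   count.
#' @param gas optional [gas_series_frame()].
#' @return data.frame (class `"bundle_report"`) with columns `component`
#'   and `message`, one row per violation.
#' @export
validate_bundle <- function(table, metadata, tree = NULL, gas = NULL) {
  findings <- list()
  note <- function(component, message)
    findings[[length(findings) + 1L]] <<- data.frame(
      component = component, message = message, stringsAsFactors = FALSE)

  missing_meta <- setdiff(rownames(table), metadata$sample_id)
  for (s in missing_meta)
    note("metadata", sprintf("sample '%s' in table has no metadata row", s))
  dup <- metadata$sample_id[duplicated(metadata$sample_id)]
  for (s in unique(dup))
    note("metadata", sprintf("sample '%s' has multiple metadata rows", s))

  if (!is.null(tree)) {
    observed <- colnames(table)[colSums(table) > 0]
    absent <- setdiff(observed, tree$tip.label)
    for (a in absent)
      note("tree", sprintf("ASV '%s' observed in table but not a tree leaf", a))
  }
  if (!is.null(gas)) {
    unknown <- setdiff(unique(gas$sample_id), metadata$sample_id)
    for (s in unknown)
      note("gas", sprintf("gas series sample '%s' has no metadata row", s))
  }
  report <- if (length(findings)) do.call(rbind, findings) else
    data.frame(component = character(), message = character(),
               stringsAsFactors = FALSE)
  class(report) <- c("bundle_report", "data.frame")
  report
}

#' @export
print.bundle_report <- function(x, ...) {
  if (nrow(x) == 0L) {
    cat("Bundle consistent: no violations.\n")
  } else {
    cat(sprintf("Bundle report: %d violation(s)\n", nrow(x)))
    for (i in seq_len(nrow(x)))
      cat(sprintf("  [%s] %s\n", x$component[i], x$message[i]))
  }
  invisible(x)
}
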