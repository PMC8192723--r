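#' ASV richness of a sample
#'
#' @param sample numeric count (or abundance) vector.
#' @return number of taxa with value > 0.
#' @export
richness <- function(sample) sum(sample > 0)

#' Pielou evenness of a sample
#'
#' Shannon entropy of the nonzero relative abundances divided by its
#' maximum `ln(S)`. Undefined for fewer than two taxa (`ln 1 = 0`);
#' returns `NA` with a warning.
#'
#' @param sample numeric count (or abundance) vector.
#' @return evenness in `[0, 1]`, or `NA` if richness < 2.
#' @export
pielou <- function(sample) {
  p <- sample[sample > 0]
  s <- length(p)
  if (s < 2) {
    warning("Pielou evenness undefined for richness < 2")
    return(NA_real_)
  }
  p <- p / sum(p)
  -sum(p * log(p)) / log(s)
}

#' Per-sample alpha diversity of a count table
#'
#' @param table an [asv_table()].
#' @return data.frame: `sample_id`, `richness`, `pielou`.
#' @export
alpha_diversity <- function(table) {
  stopifnot(inherits(table, "asv_table"))
  data.frame(
    sample_id = rownames(table),
    richness = apply(table, 1, richness),
    pielou = suppressWarnings(apply(table, 1, pielou)),
    stringsAsFactors = FALSE, row.names = NULL)
}

# Per-branch descendant leaf masses, one postorder pass.
# Returns list(lengths = edge lengths, mass = edges x samples matrix of
# summed leaf values beneath each edge's child).
branch_masses <- function(tree, values) {
  # values: samples x leaves (named columns)
  miss <- colnames(values)[colSums(values != 0) > 0]
  miss <- setdiff(miss, tree$tip.label)
  if (length(miss))
    stop("ASV(s) present but not tree leaves: ",
         paste(utils::head(miss, 5), collapse = ", "))
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  n_samp <- nrow(values)
  node_mass <- matrix(0, n_node, n_samp)
  idx <- match(tree$tip.label, colnames(values))
  found <- !is.na(idx)
  node_mass[which(found), ] <- t(values[, idx[found], drop = FALSE])
  tr <- stats::reorder(tree, "postorder")
  for (i in seq_len(nrow(tr$edge))) {
    e <- tr$edge[i, ]
    node_mass[e[1], ] <- node_mass[e[1], ] + node_mass[e[2], ]
  }
  list(lengths = tr$edge.length,
       mass = node_mass[tr$edge[, 2], , drop = FALSE])
}

#' UniFrac distance between two communities
#'
#' First-principles implementation over a rooted tree with branch lengths,
#' computed in a single postorder traversal. Unweighted: a branch is
#' covered by a sample iff at least one leaf beneath it is present; the
#' distance is the length covered by exactly one sample divided by the
#' length covered by at least one. Weighted: branch lengths weight the
#' absolute difference in the summed relative abundance beneath each
#' branch; the normalised variant (default) divides by the
#' abundance-weighted total `sum(b * (P_a + P_b))`, bounding it to
#' `[0, 1]`.
#'
#' @param sample_a,sample_b named count vectors (names = ASV ids).
#' @param tree rooted `phylo` with branch lengths; every present ASV must
#'   be a leaf.
#' @param method `"unweighted"` or `"weighted"`.
#' @param normalized normalise the weighted variant (ignored for
#'   unweighted).
#' @return a single distance.
#' @export
unifrac_pair <- function(sample_a, sample_b, tree,
                         method = c("unweighted", "weighted"),
                         normalized = TRUE) {
  method <- match.arg(method)
  ids <- union(names(sample_a), names(sample_b))
  m <- matrix(0, 2, length(ids), dimnames = list(c("a", "b"), ids))
  m["a", names(sample_a)] <- sample_a
  m["b", names(sample_b)] <- sample_b
  unifrac_matrix_values(m, tree, method, normalized)[1, 2]
}

unifrac_matrix_values <- function(values, tree, method, normalized) {
  n <- nrow(values)
  if (method == "weighted") {
    rs <- rowSums(values)
    if (any(rs == 0)) stop("empty sample in weighted UniFrac")
    values <- values / rs
  } else {
    values <- (values > 0) * 1
  }
  bm <- branch_masses(tree, values)
  len <- bm$lengths
  d <- matrix(0, n, n, dimnames = list(rownames(values), rownames(values)))
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
    pa <- bm$mass[, i]; pb <- bm$mass[, j]
    if (method == "unweighted") {
      ca <- pa > 0; cb <- pb > 0
      denom <- sum(len[ca | cb])
      dij <- if (denom == 0) 0 else sum(len[xor(ca, cb)]) / denom
    } else {
      raw <- sum(len * abs(pa - pb))
      dij <- if (normalized) {
        denom <- sum(len * (pa + pb))
        if (denom == 0) 0 else raw / denom
      } else raw
    }
    d[i, j] <- d[j, i] <- dij
  }
  d
}

#' All-pairs UniFrac distance matrix for a count table
#'
#' Counts are converted to relative abundances on the fly for the weighted
#' variant (the pipeline never rarefies).
#'
#' @param table an [asv_table()].
#' @inheritParams unifrac_pair
#' @return symmetric matrix (class `"dist_matrix"`) over samples.
#' @export
unifrac_matrix <- function(table, tree,
                           method = c("unweighted", "weighted"),
                           normalized = TRUE) {
  stopifnot(inherits(table, "asv_table"))
  method <- match.arg(method)
  d <- unifrac_matrix_values(unclass(table) * 1.0, tree, method, normalized)
  class(d) <- c("dist_matrix", class(d))
  d
}

#' Distance-based permutational MANOVA (one-way)
#'
#' Partitions the squared inter-point distances: `SS_total = sum_{i<j}
#' d_ij^2 / N`, `SS_within = sum_g sum_{i<j in g} d_ij^2 / n_g`,
#' `SS_between = SS_total - SS_within`; `pseudo-F = (SS_between / (a-1)) /
#' (SS_within / (N-a))`. Significance by whole-label permutation with the
#' add-one estimator `p = (1 + #{F* >= F}) / (1 + n_permutations)` (ties
#' count as extreme), so p is never exactly 0 and its floor is
#' `1/(n_permutations + 1)`.
#'
#' @param dist symmetric distance matrix (or `dist`) over samples.
#' @param groups group labels, one per sample.
#' @param n_permutations number of label permutations (>= 99).
#' @param seed optional integer seed for the permutation stream.
#' @return list of class `"permanova"`: `pseudo_F`, `R2`, `p_perm`,
#'   `df_between`, `df_within`, `n_permutations`, `seed`, `degenerate`.
#' @export
permanova <- function(dist, groups, n_permutations = 999, seed = NULL) {
  d <- as.matrix(dist)
  n <- nrow(d)
  groups <- as.character(groups)
  stopifnot(length(groups) == n, n_permutations >= 99)
  tab <- table(groups)
  if (length(tab) < 2) stop("permanova needs >= 2 groups")
  if (any(tab == 0)) stop("empty group")
  if (all(d == 0)) {
    out <- list(pseudo_F = NA_real_, R2 = NA_real_, p_perm = NA_real_,
                df_between = length(tab) - 1L, df_within = n - length(tab),
                n_permutations = n_permutations, seed = seed,
                degenerate = TRUE)
    class(out) <- "permanova"
    return(out)
  }
  d2 <- d^2
  a <- length(tab)
  ss_total <- sum(d2[upper.tri(d2)]) / n
  f_stat <- function(g) {
    ss_within <- 0
    for (lev in unique(g)) {
      idx <- which(g == lev)
      if (length(idx) > 1)
        ss_within <- ss_within +
          sum(d2[idx, idx][upper.tri(d2[idx, idx])]) / length(idx)
    }
    ss_between <- ss_total - ss_within
    if (ss_within <= 0) return(Inf)
    (ss_between / (a - 1)) / (ss_within / (n - a))
  }
  f_obs <- f_stat(groups)
  ssw <- 0
  for (lev in unique(groups)) {
    idx <- which(groups == lev)
    if (length(idx) > 1)
      ssw <- ssw + sum(d2[idx, idx][upper.tri(d2[idx, idx])]) / length(idx)
  }
  r2 <- (ss_total - ssw) / ss_total
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit(if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
  }
  n_extreme <- 0L
  for (k in seq_len(n_permutations)) {
    fp <- f_stat(sample(groups))
    if (fp >= f_obs) n_extreme <- n_extreme + 1L
  }
  out <- list(pseudo_F = f_obs, R2 = r2,
              p_perm = (1 + n_extreme) / (1 + n_permutations),
              df_between = a - 1L, df_within = n - a,
              n_permutations = n_permutations, seed = seed,
              degenerate = FALSE)
  class(out) <- "permanova"
  out
}

#' @export
print.permanova <- function(x, ...) {
  if (isTRUE(x$degenerate)) {
    cat("PERMANOVA: degenerate (all distances zero); no test.\n")
    return(invisible(x))
  }
  cat(sprintf("PERMANOVA: pseudo-F(%d,%d) = %.3f, R2 = %.3f, p = %.4g (%d permutations)\n",
              x$df_between, x$df_within, x$pseudo_F, x$R2, x$p_perm,
              x$n_permutations))
  invisible(x)
}

#' Pairwise PERMANOVA over all unordered group pairs
#'
#' @inheritParams permanova
#' @param adjust multiplicity adjustment: `"bonferroni"` (default, the
#'   convention for pairwise PERMANOVA) or `"holm"`.
#' @return data.frame (class `"pairwise_permanova"`): one row per pair
#'   with pseudo-F, R2, raw and adjusted p.
#' @export
pairwise_permanova <- function(dist, groups, n_permutations = 999,
                               seed = NULL, adjust = c("bonferroni", "holm")) {
  adjust <- match.arg(adjust)
  d <- as.matrix(dist)
  groups <- as.character(groups)
  levs <- unique(groups)
  pairs <- utils::combn(levs, 2, simplify = FALSE)
  rows <- lapply(seq_along(pairs), function(k) {
    pr <- pairs[[k]]
    idx <- groups %in% pr
    sub_seed <- if (is.null(seed)) NULL else substream_seed(seed, paste(pr, collapse = ":"))
    res <- permanova(d[idx, idx], groups[idx], n_permutations, sub_seed)
    data.frame(group1 = pr[1], group2 = pr[2],
               pseudo_F = res$pseudo_F, R2 = res$R2, p_raw = res$p_perm,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- stats::p.adjust(out$p_raw, method = adjust)
  attr(out, "adjust") <- adjust
  class(out) <- c("pairwise_permanova", "data.frame")
  out
}
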