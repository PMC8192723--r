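# Independent oracles used to cross-check the package's own
# implementations. These deliberately take naive routes (per-edge clade
# extraction, exhaustive enumeration) so they share no code with the
# traversal-based implementations they validate.

# tips descending from a node (naive, via ape::extract.clade)
oracle_desc_tips <- function(tree, node) {
  n_tip <- length(tree$tip.label)
  if (node <= n_tip) return(tree$tip.label[node])
  ape::extract.clade(tree, node)$tip.label
}

# brute-force UniFrac by explicit branch-by-branch enumeration
oracle_unifrac <- function(a, b, tree, method = "unweighted",
                           normalized = TRUE) {
  ids <- union(names(a), names(b))
  av <- stats::setNames(numeric(length(ids)), ids); av[names(a)] <- a
  bv <- stats::setNames(numeric(length(ids)), ids); bv[names(b)] <- b
  if (method == "weighted") {
    av <- av / sum(av); bv <- bv / sum(bv)
  }
  num <- 0; den <- 0
  for (i in seq_len(nrow(tree$edge))) {
    tips <- oracle_desc_tips(tree, tree$edge[i, 2])
    len <- tree$edge.length[i]
    pa <- sum(av[intersect(tips, names(av))])
    pb <- sum(bv[intersect(tips, names(bv))])
    if (method == "unweighted") {
      ca <- pa > 0; cb <- pb > 0
      if (xor(ca, cb)) num <- num + len
      if (ca || cb) den <- den + len
    } else {
      num <- num + len * abs(pa - pb)
      den <- den + len * (pa + pb)
    }
  }
  if (method == "unweighted") {
    if (den == 0) 0 else num / den
  } else if (normalized) {
    if (den == 0) 0 else num / den
  } else num
}

# exhaustive PERMANOVA p for two groups of equal size (all label splits)
oracle_permanova_exhaustive <- function(d, groups) {
  d <- as.matrix(d)
  n <- nrow(d)
  levs <- unique(groups)
  stopifnot(length(levs) == 2)
  n1 <- sum(groups == levs[1])
  d2 <- d^2
  fstat <- function(g) {
    ss_tot <- sum(d2[upper.tri(d2)]) / n
    ssw <- 0
    for (lev in unique(g)) {
      idx <- which(g == lev)
      if (length(idx) > 1)
        ssw <- ssw + sum(d2[idx, idx][upper.tri(d2[idx, idx])]) / length(idx)
    }
    a <- length(unique(g))
    if (ss_tot - ssw <= 0 && ssw == 0) return(NA_real_)
    if (ssw == 0) return(Inf)
    ((ss_tot - ssw) / (a - 1)) / (ssw / (n - a))
  }
  f_obs <- fstat(groups)
  combos <- utils::combn(n, n1)
  fs <- apply(combos, 2, function(idx) {
    g <- rep(levs[2], n); g[idx] <- levs[1]
    fstat(g)
  })
  mean(fs >= f_obs)
}

# random table + coalescent tree instance for property tests
random_unifrac_instance <- function(n_leaves = 16, n_samples = 2) {
  tree <- ape::rcoal(n_leaves, tip.label = sprintf("t%02d", seq_len(n_leaves)))
  tree$edge.length <- stats::rexp(nrow(tree$edge))
  counts <- matrix(stats::rpois(n_samples * n_leaves, 3),
                   n_samples, n_leaves,
                   dimnames = list(sprintf("s%d", seq_len(n_samples)),
                                   tree$tip.label))
  # guarantee nonzero rows
  for (i in seq_len(n_samples))
    if (sum(counts[i, ]) == 0) counts[i, sample.int(n_leaves, 1)] <- 1L
  list(tree = tree, table = asv_table(counts))
}
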