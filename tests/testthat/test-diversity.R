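test_that("richness and Pielou evenness match direct formula evaluation", {
  expect_equal(richness(c(5, 0, 7)), 2)
  expect_equal(richness(c(0, 0, 0)), 0)
  expect_equal(pielou(rep(10, 7)), 1)
  # counts (75, 25): H' = -(0.75 ln 0.75 + 0.25 ln 0.25) = 0.5623,
  # J = H' / ln 2 = 0.8113
  expect_equal(pielou(c(75, 25)) * log(2), 0.5623, tolerance = 1e-4)
  expect_equal(pielou(c(75, 25)), 0.8113, tolerance = 1e-4)
  expect_warning(j <- pielou(c(10, 0)), "undefined")
  expect_true(is.na(j))

  set.seed(3)
  m <- matrix(rpois(40, 2), 4, 10,
              dimnames = list(paste0("s", 1:4), paste0("a", 1:10)))
  m[, 1] <- m[, 1] + 1L
  tab <- asv_table(m)
  alpha <- alpha_diversity(tab)
  expect_equal(alpha$richness, unname(apply(m, 1, function(x) sum(x > 0))))
  brute_h <- apply(m, 1, function(x) {
    p <- x[x > 0] / sum(x)
    -sum(p * log(p)) / log(length(p))
  })
  expect_equal(alpha$pielou, unname(brute_h))
})

test_that("unweighted UniFrac reproduces branch-by-branch enumeration", {
  tree <- toy_tree()
  a <- c(A = 1, B = 1); b <- c(C = 1, D = 1)
  expect_equal(unifrac_pair(a, b, tree, "unweighted"), 1)
  # a = {A,B}, b = {A,C}: unique {B, C, CD} = 3 of covered 5
  expect_equal(unifrac_pair(c(A = 1, B = 1), c(A = 1, C = 1), tree,
                            "unweighted"), 0.6)
  expect_equal(unifrac_pair(a, a, tree, "unweighted"), 0)
})

test_that("weighted UniFrac matches its worked examples", {
  tree <- toy_tree()
  # a = all A, b = all C: branches A, AB, C, CD each contribute 1
  expect_equal(unifrac_pair(c(A = 1), c(C = 1), tree, "weighted",
                            normalized = FALSE), 4)
  expect_equal(unifrac_pair(c(A = 1), c(C = 1), tree, "weighted",
                            normalized = TRUE), 1)
  expect_equal(unifrac_pair(c(A = 2, B = 2), c(A = 1, B = 1), tree,
                            "weighted"), 0)

  # star tree: raw weighted UniFrac is the L1 distance
  star <- ape::read.tree(text = "(A:1,B:1,C:1);")
  p <- c(A = 0.5, B = 0.3, C = 0.2); q <- c(A = 0.1, B = 0.1, C = 0.8)
  expect_equal(unifrac_pair(p, q, star, "weighted", normalized = FALSE),
               sum(abs(p - q)))
})

test_that("UniFrac errors when a present ASV is not a tree leaf", {
  tree <- toy_tree()
  expect_error(unifrac_pair(c(A = 1, Z = 1), c(C = 1), tree), "Z")
})

test_that("UniFrac obeys metric axioms and presence invariance", {
  set.seed(21)
  for (i in 1:25) {
    inst <- random_unifrac_instance(n_leaves = 10, n_samples = 3)
    for (method in c("unweighted", "weighted")) {
      d <- unifrac_matrix(inst$table, inst$tree, method)
      expect_equal(unclass(d), t(unclass(d)), tolerance = 1e-12)
      expect_true(all(diag(d) == 0))
      expect_true(all(d >= -1e-12 & d <= 1 + 1e-12))
    }
    # unweighted depends only on presence: doubling counts changes nothing
    tab2 <- asv_table(unclass(inst$table) * 2L)
    expect_equal(unclass(unifrac_matrix(inst$table, inst$tree, "unweighted")),
                 unclass(unifrac_matrix(tab2, inst$tree, "unweighted")),
                 tolerance = 1e-12)
  }
})

test_that("UniFrac agrees with an independent reference implementation", {
  skip_if_not_installed("phyloseq")
  set.seed(31)
  for (i in 1:5) {
    inst <- random_unifrac_instance(n_leaves = 12, n_samples = 3)
    ps <- phyloseq::phyloseq(
      phyloseq::otu_table(t(unclass(inst$table)), taxa_are_rows = TRUE),
      phyloseq::phy_tree(inst$tree))
    ref_u <- as.matrix(phyloseq::UniFrac(ps, weighted = FALSE))
    mine_u <- unclass(unifrac_matrix(inst$table, inst$tree, "unweighted"))
    expect_equal(mine_u[rownames(ref_u), colnames(ref_u)], ref_u,
                 tolerance = 1e-9, ignore_attr = TRUE)
    ref_w <- as.matrix(phyloseq::UniFrac(ps, weighted = TRUE,
                                         normalized = FALSE))
    mine_w <- unclass(unifrac_matrix(inst$table, inst$tree, "weighted",
                                     normalized = FALSE))
    expect_equal(mine_w[rownames(ref_w), colnames(ref_w)], ref_w,
                 tolerance = 1e-9, ignore_attr = TRUE)
  }
})

test_that("permanova matches its variance partition and vegan's adonis2", {
  skip_if_not_installed("vegan")
  set.seed(41)
  x <- matrix(rnorm(36), 12, 3)
  x[7:12, ] <- x[7:12, ] + 1.5
  groups <- rep(c("g1", "g2"), each = 6)
  d <- as.matrix(dist(x))
  res <- permanova(d, groups, n_permutations = 999, seed = 5)
  ref <- vegan::adonis2(as.dist(d) ~ g, data = data.frame(g = groups),
                        permutations = 999)
  expect_equal(res$pseudo_F, ref$F[1], tolerance = 1e-10)
  expect_equal(res$R2, ref$R2[1], tolerance = 1e-10)
  expect_equal(res$df_between, ref$Df[1])
  expect_equal(res$df_within, ref$Df[2])
  # both permutation p-values estimate the same tail probability
  expect_lt(abs(res$p_perm - ref$`Pr(>F)`[1]), 0.05)
})

test_that("permanova p-values honour floor, seed, and relabeling", {
  set.seed(43)
  d <- as.matrix(dist(matrix(rnorm(24), 8, 3)))
  groups <- rep(c("a", "b"), each = 4)
  r1 <- permanova(d, groups, 99, seed = 1)
  r2 <- permanova(d, groups, 99, seed = 1)
  expect_identical(r1$p_perm, r2$p_perm)
  expect_gte(r1$p_perm, 1 / 100)
  expect_true(r1$R2 >= 0 && r1$R2 <= 1)

  # permuting sample order together with labels leaves F unchanged
  perm <- sample(8)
  r3 <- permanova(d[perm, perm], groups[perm], 99, seed = 1)
  expect_equal(r1$pseudo_F, r3$pseudo_F, tolerance = 1e-12)

  # coincident groups separated by a gap: infinite F, floor p
  d0 <- matrix(1, 6, 6) - diag(1, 6)
  d0[1:3, 1:3] <- 0; d0[4:6, 4:6] <- 0
  # ties (permutations recreating the same partition) count as extreme,
  # so p is the share of partition-preserving relabelings, not 1/(B+1)
  r4 <- permanova(d0, rep(c("a", "b"), each = 3), 99, seed = 2)
  expect_true(is.infinite(r4$pseudo_F))
  expect_lte(r4$p_perm, 0.25)

  # all-zero distances: degenerate, no test
  r5 <- permanova(matrix(0, 6, 6), rep(c("a", "b"), each = 3), 99)
  expect_true(r5$degenerate)
  expect_true(is.na(r5$p_perm))
})

test_that("pairwise permanova enumerates pairs and adjusts p-values", {
  set.seed(47)
  x <- matrix(rnorm(36), 12, 3)
  groups <- rep(c("a", "b", "c"), each = 4)
  d <- as.matrix(dist(x))
  pw <- pairwise_permanova(d, groups, 99, seed = 3)
  expect_equal(nrow(pw), choose(3, 2))
  expect_equal(pw$p_adjusted, pmin(1, pw$p_raw * 3))
  hol <- pairwise_permanova(d, groups, 99, seed = 3, adjust = "holm")
  expect_equal(hol$p_adjusted, p.adjust(hol$p_raw, "holm"))

  # three identical groups: all adjusted p ~ 1
  xx <- matrix(rep(rnorm(4 * 3), 3), 12, 3, byrow = FALSE)
  dd <- as.matrix(dist(rbind(xx[1:4, ], xx[1:4, ], xx[1:4, ])))
  pw0 <- pairwise_permanova(dd, groups, 99, seed = 4)
  expect_true(all(pw0$p_adjusted > 0.9 | is.na(pw0$p_adjusted)))
})
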