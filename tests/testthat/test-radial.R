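# Minimal single-chromosome fixture: genes placed in explicit bins with
# an explicit metric over those bins.
manual_fixture <- function(tss, class_label, de_flag, D, res = 250000) {
  n_bins <- nrow(D)
  genes <- gene_table(sprintf("g%02d", seq_along(tss)), "chr1", tss,
                      class_label = class_label, de_flag = de_flag)
  bins <- make_bins(c(chr1 = n_bins * res), res)
  binning <- assign_spatial_bins(genes, bins, res)
  list(genes = genes, binning = binning, D = D)
}

test_that("three co-binned class genes give sigma_R(0) = 3/(4*pi)", {
  D <- matrix(0, 1, 1)
  fx <- manual_fixture(c(0, 1000, 2000), "A", TRUE, D)
  rp <- radial_distribution(fx$genes, fx$binning, fx$D, "A", "A",
                            delta_r = 1, n_shells = 3)
  expect_equal(rp$sigma_R[1], 3 / (4 * pi))
  expect_equal(rp$sigma_R[2:3], c(0, 0))
})

test_that("an out-of-range counted group yields an all-zero profile", {
  D <- matrix(c(0, 50, 50, 0), 2)
  fx <- manual_fixture(c(0, 1000, 250000), c("A", "A", "B"),
                       TRUE, D)
  rp <- radial_distribution(fx$genes, fx$binning, fx$D, "A", "B",
                            delta_r = 1, n_shells = 5)
  expect_equal(rp$sigma_R, rep(0, 5))
})

test_that("infinite distances never contribute to any shell", {
  D <- matrix(c(0, Inf, Inf, 0), 2)
  fx <- manual_fixture(c(0, 250000), "A", TRUE, D)
  rp <- radial_distribution(fx$genes, fx$binning, fx$D, "A", "A",
                            delta_r = 10, n_shells = 4)
  expect_equal(rp$sigma_R, rep(0, 4))
})

test_that("radial profiles match a brute-force oracle on random fixtures", {
  set.seed(91)
  for (rep in 1:6) {
    fx <- random_fixture(n_genes = sample(100:300, 1))
    dr <- quantile(fx$D[upper.tri(fx$D)], 0.1)
    classes <- sort(unique(na.omit(fx$genes$class_label)))
    a <- classes[1]
    for (cnt in c("ALL", "DE", classes)) {
      rp <- radial_distribution(fx$genes, fx$binning, fx$D, a, cnt,
                                delta_r = dr, n_shells = 6)
      expect_equal(rp$sigma_R,
                   oracle_radial(fx$genes, fx$binning$bin, fx$D, a, cnt,
                                 dr, 6),
                   tolerance = 1e-12)
    }
  }
})

test_that("class profiles satisfy the exact partition identity", {
  set.seed(101)
  fx <- random_fixture(n_genes = 200, n_classes = 4)
  dr <- quantile(fx$D[upper.tri(fx$D)], 0.1)
  classes <- sort(unique(na.omit(fx$genes$class_label)))
  nd <- sum(fx$genes$de_flag)
  for (a in classes) {
    sD <- radial_distribution(fx$genes, fx$binning, fx$D, a, "DE",
                              delta_r = dr, n_shells = 5)$sigma_R
    lhs <- 0
    for (b in classes) {
      nb <- sum(fx$genes$class_label == b, na.rm = TRUE) - (a == b)
      lhs <- lhs + nb * radial_distribution(fx$genes, fx$binning, fx$D, a, b,
                                            delta_r = dr,
                                            n_shells = 5)$sigma_R
    }
    expect_equal(lhs, (nd - 1) * sD, tolerance = 1e-12)
  }
})

test_that("sigma_R is invariant under bin relabeling and within-bin gene order", {
  set.seed(111)
  fx <- random_fixture(n_genes = 150, n_chrom = 1)
  dr <- quantile(fx$D[upper.tri(fx$D)], 0.1)
  a <- sort(unique(na.omit(fx$genes$class_label)))[1]
  ref <- radial_distribution(fx$genes, fx$binning, fx$D, a, a,
                             delta_r = dr, n_shells = 5)$sigma_R

  # shuffle gene rows (including within-bin order)
  perm <- sample(nrow(fx$genes))
  g2 <- validate_gene_table(as.data.frame(fx$genes)[perm, ])
  b2 <- fx$binning
  b2$bin <- fx$binning$bin[perm]
  b2$gene_id <- g2$gene_id
  expect_equal(radial_distribution(g2, b2, fx$D, a, a, delta_r = dr,
                                   n_shells = 5)$sigma_R, ref)

  # relabel bin indices by a permutation applied consistently to D
  nb <- nrow(fx$D)
  bperm <- sample(nb)
  D2 <- fx$D[bperm, bperm]
  b3 <- fx$binning
  b3$bin <- match(fx$binning$bin, bperm)
  expect_equal(radial_distribution(fx$genes, b3, D2, a, a, delta_r = dr,
                                   n_shells = 5)$sigma_R, ref)
})

test_that("first-shell ratios self-normalize and flag zero denominators", {
  set.seed(121)
  fx <- random_fixture(n_genes = 150)
  dr <- quantile(fx$D[upper.tri(fx$D)], 0.1)
  a <- sort(unique(na.omit(fx$genes$class_label)))[1]
  sA <- radial_distribution(fx$genes, fx$binning, fx$D, a, "ALL",
                            delta_r = dr, n_shells = 1)
  expect_equal(sA$sigma_R[1] / sA$sigma_R[1], 1)

  rm <- first_shell_ratios(fx$genes, fx$binning, fx$D, dr)
  expect_true(all(is.finite(rm$ratios)))
  expect_true(all(rm$ratios >= 0))

  # isolated genes (all pairwise distances infinite) have zero all-gene
  # first-shell density: ratios flagged undefined, not silently zero
  D <- matrix(Inf, 4, 4); diag(D) <- 0
  iso <- manual_fixture(c(0, 250000, 500000, 750000),
                        c("A", "A", "B", "B"), TRUE, D)
  expect_warning(expect_warning(
    rz <- first_shell_ratios(iso$genes, iso$binning, iso$D, delta_r = 1),
    "zero"), "zero")
  expect_true(all(is.na(rz$ratios)))
})

test_that("first-shell linear offsets separate cis pairs from trans pairs", {
  # two class genes in one bin, 50 kb apart
  D <- matrix(0, 1, 1)
  fx <- manual_fixture(c(0, 50000), "A", TRUE, D)
  fs <- first_shell_linear_distances(fx$genes, fx$binning, fx$D, "A",
                                     delta_r = 1)
  expect_equal(fs$offsets, 50000)
  expect_equal(fs$n_trans, 0L)

  # planted long-range pair: TSS 50 Mb apart, bins adjacent in space
  sizes <- c(chr1 = 51e6)
  genes <- gene_table(c("a", "b"), "chr1", c(0, 50e6), class_label = "A",
                      de_flag = TRUE)
  bins <- make_bins(sizes, 250000)
  binning <- assign_spatial_bins(genes, bins, 250000)
  nb <- nrow(bins)
  D2 <- matrix(100, nb, nb)
  diag(D2) <- 0
  D2[binning$bin[1], binning$bin[2]] <- D2[binning$bin[2], binning$bin[1]] <- 0.5
  fs2 <- first_shell_linear_distances(genes, binning, D2, "A", delta_r = 1)
  expect_equal(fs2$offsets, 5e7)

  # trans pair
  genes3 <- gene_table(c("a", "b"), c("chr1", "chr2"), c(0, 0),
                       class_label = "A", de_flag = TRUE)
  bins3 <- make_bins(c(chr1 = 250000, chr2 = 250000), 250000)
  binning3 <- assign_spatial_bins(genes3, bins3, 250000)
  D3 <- matrix(c(0, 0.5, 0.5, 0), 2)
  fs3 <- first_shell_linear_distances(genes3, binning3, D3, "A", delta_r = 1)
  expect_equal(length(fs3$offsets), 0L)
  expect_equal(fs3$n_trans, 1L)

  # all pairs beyond the first shell: empty distribution
  fs4 <- first_shell_linear_distances(genes3, binning3, D3, "A",
                                      delta_r = 0.1)
  expect_equal(length(fs4$offsets), 0L)
  expect_equal(fs4$n_trans, 0L)
})

test_that("cis-only counting drops trans-chromosomal pairs", {
  genes <- gene_table(c("a", "b", "c"), c("chr1", "chr2", "chr1"),
                      c(0, 0, 250000), class_label = "A", de_flag = TRUE)
  bins <- make_bins(c(chr1 = 500000, chr2 = 250000), 250000)
  binning <- assign_spatial_bins(genes, bins, 250000)
  D <- matrix(0.2, 3, 3); diag(D) <- 0
  full <- radial_distribution(genes, binning, D, "A", "A", delta_r = 1,
                              n_shells = 1)
  cis <- radial_distribution(genes, binning, D, "A", "A", delta_r = 1,
                             n_shells = 1, cis_only = TRUE)
  expect_true(cis$mean_count[1] < full$mean_count[1])
  expect_equal(full$mean_count[1], 2)
  expect_equal(cis$mean_count[1], 2 / 3)
})
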