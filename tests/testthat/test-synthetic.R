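test_that("simulated genomes honor the configured bookkeeping", {
  cfg <- synthetic_config(n_chrom = 1, chrom_length = 10e6, n_genes = 100,
                          de_fraction = 0.5, n_classes = 2, seed = 1)
  g <- simulate_genome(cfg)
  cs <- class_sizes(g)
  expect_equal(cs$n, 100L)
  expect_equal(cs$n_de, 50L)
  expect_equal(unname(cs$class_sizes), c(25L, 25L))
  expect_error(synthetic_config(n_classes = 2,
                                class_proportions = c(0.5, 0.6)))
  expect_error(class_counts(synthetic_config(n_genes = 10, de_fraction = 0.1,
                                             n_classes = 4)),
               "infeasible")
})

test_that("every stage is reproducible from the configuration seed", {
  cfg <- synthetic_config(n_genes = 120, seed = 33)
  expect_identical(simulate_genome(cfg), simulate_genome(cfg))
  g <- simulate_genome(cfg)
  s1 <- simulate_structure(g, cfg)
  s2 <- simulate_structure(g, cfg)
  expect_identical(s1$coords, s2$coords)
  expect_identical(structure_to_contacts(s1, cfg)$counts,
                   structure_to_contacts(s1, cfg)$counts)
})

test_that("unclumped class placement is uniform along the chromosome", {
  # with linear_clump_rate = 0, class-gene TSS are iid uniform on [0, L)
  cfg <- synthetic_config(n_chrom = 1, chrom_length = 10e6, n_genes = 60,
                          de_fraction = 0.5, n_classes = 2,
                          linear_clump_rate = 0)
  set.seed(191)
  pos <- unlist(lapply(1:100, function(r) {
    g <- simulate_genome(cfg)
    g$tss[!is.na(g$class_label) & g$class_label == "C1"] / cfg$chrom_length
  }))
  ks <- suppressWarnings(ks.test(pos, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("clumped placement concentrates same-class neighbours", {
  set.seed(201)
  near <- function(cfg) {
    g <- simulate_genome(cfg)
    tss <- sort(g$tss[!is.na(g$class_label) & g$class_label == "C1"])
    mean(diff(tss) <= 250000)
  }
  cfg0 <- synthetic_config(n_chrom = 1, chrom_length = 20e6, n_genes = 200,
                           de_fraction = 0.5, n_classes = 2,
                           linear_clump_rate = 0)
  cfg5 <- synthetic_config(n_chrom = 1, chrom_length = 20e6, n_genes = 200,
                           de_fraction = 0.5, n_classes = 2,
                           linear_clump_rate = 5)
  expect_gt(mean(replicate(10, near(cfg5))), mean(replicate(10, near(cfg0))))
})

test_that("anchor pull displaces only class-gene bins and collapses at 1", {
  cfg0 <- synthetic_config(n_genes = 200, anchor_pull = 0, seed = 77)
  cfg8 <- synthetic_config(n_genes = 200, anchor_pull = 0.8, seed = 77)
  g <- simulate_genome(cfg0)
  s0 <- simulate_structure(g, cfg0)
  s8 <- simulate_structure(g, cfg8)
  binning <- assign_spatial_bins(g, s0$bins, cfg0$resolution)
  class_bins <- unique(binning$bin[!is.na(g$class_label)])
  moved <- which(rowSums(abs(s0$coords - s8$coords)) > 1e-12)
  expect_setequal(moved, class_bins)

  # pull = 1 collapses a single-class bin set onto its anchor
  cfg1 <- synthetic_config(n_chrom = 1, chrom_length = 5e6, n_genes = 20,
                           de_fraction = 1, n_classes = 1, anchor_pull = 1,
                           seed = 5)
  g1 <- simulate_genome(cfg1)
  s1 <- simulate_structure(g1, cfg1)
  b1 <- assign_spatial_bins(g1, s1$bins, cfg1$resolution)
  occupied <- unique(b1$bin)
  d <- as.matrix(dist(s1$coords[occupied, , drop = FALSE]))
  expect_equal(max(d), 0)
})

test_that("mean intra-class distance shrinks as the pull strengthens", {
  pulls <- c(0, 0.2, 0.4, 0.6, 0.8)
  set.seed(211)
  means <- sapply(pulls, function(p) {
    mean(replicate(8, {
      cfg <- synthetic_config(n_genes = 200, anchor_pull = p)
      g <- simulate_genome(cfg)
      s <- simulate_structure(g, cfg)
      b <- assign_spatial_bins(g, s$bins, cfg$resolution)
      cb <- unique(b$bin[!is.na(g$class_label) & g$class_label == "C1"])
      mean(dist(s$coords[cb, , drop = FALSE]))
    }))
  })
  expect_true(all(diff(means) < 0))
})

test_that("noiseless contacts follow the distance-decay law and invert exactly", {
  cfg <- synthetic_config(n_chrom = 1, chrom_length = 1e6, n_genes = 4,
                          de_fraction = 1, n_classes = 1,
                          sequencing_depth = 1, seed = 3)
  u <- WALK_STEP_SD * sqrt(3)
  coords <- structure(list(coords = cbind(c(0, 2 * u, 5 * u, 9 * u), 0, 0),
                           bins = make_bins(c(chr1 = 1e6), 250000),
                           anchors = NULL, step = WALK_STEP_SD),
                      class = "bin_coordinates")
  cm <- structure_to_contacts(coords, cfg, noiseless = TRUE)
  expect_equal(cm$counts[1, 2], 1 / 2)  # lambda = depth * (d/u)^-1
  expect_equal(cm$counts[1, 3], 1 / 5)
  expect_equal(cm$counts[3, 4], 1 / 4)

  # round trip on a convex chain: reconstructed distances are the true
  # distances in contact units
  D <- distances_from_contacts(cm, gamma = 1)
  true_d <- as.matrix(dist(coords$coords)) / u
  expect_equal(D, true_d, tolerance = 1e-12, ignore_attr = TRUE)

  # Poisson mode is seed-reproducible
  c1 <- structure_to_contacts(coords, cfg)
  c2 <- structure_to_contacts(coords, cfg)
  expect_identical(c1$counts, c2$counts)
  expect_true(all(c1$counts == floor(c1$counts)))
})

test_that("coincident bins receive the capped intensity, not infinity", {
  cfg <- synthetic_config(sequencing_depth = 7, seed = 4)
  coords <- structure(list(coords = rbind(c(.5, .5, .5), c(.5, .5, .5)),
                           bins = make_bins(c(chr1 = 500000), 250000),
                           anchors = NULL, step = WALK_STEP_SD),
                      class = "bin_coordinates")
  cm <- structure_to_contacts(coords, cfg, noiseless = TRUE)
  expect_equal(cm$counts[1, 2], 7)
})

test_that("synthetic datasets round-trip through plain-text files", {
  sim <- simulate_dataset("null", seed = 8)
  dir <- withr::local_tempdir()
  write_dataset(sim, dir)
  genes <- read_gene_table(file.path(dir, "genes.tsv"), "tsv")
  expect_equal(as.data.frame(genes), as.data.frame(sim$genes))
  cm <- read_contact_map(file.path(dir, "contacts.coo.tsv"),
                         file.path(dir, "bins.bed"), "coo")
  expect_equal(cm$counts, sim$contacts$counts)
})
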