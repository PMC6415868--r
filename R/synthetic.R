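# Per-axis step SD of the polymer random walk, chosen so that a 20-Mb
# chromosome (80 bins at 250 kb) has an RMS end-to-end distance of about
# half the unit cube edge: sd * sqrt(3 * 80) = 0.5.
WALK_STEP_SD <- 0.5 / sqrt(3 * 80)

#' Configuration for the synthetic co-clustering generator
#'
#' Defines a synthetic study: a genome of `n_chrom` chromosomes of
#' `chrom_length` bp carrying `n_genes` genes, of which a `de_fraction`
#' are differentially expressed and partitioned into `n_classes`
#' co-regulation classes. Two planting mechanisms create the two
#' clustering phenotypes the statistics are designed to separate:
#' `linear_clump_rate` clumps same-class genes within 250-kb sequence
#' windows (sequence-driven clustering, visible in both the linear and
#' radial functions), and `anchor_pull` pulls the 3D positions of bins
#' containing same-class genes toward a class-specific spatial anchor
#' (3D-driven clustering, visible only radially). Contacts decay with
#' spatial distance with exponent `contact_decay_gamma` and are observed
#' with Poisson noise at `sequencing_depth`.
#'
#' @param n_chrom number of chromosomes.
#' @param chrom_length chromosome length in bp.
#' @param n_genes total genes.
#' @param de_fraction fraction of genes flagged DE, in (0, 1].
#' @param n_classes number of gene classes partitioning the DE genes.
#' @param class_proportions simplex vector of class proportions
#'   (default equal).
#' @param linear_clump_rate mean number of extra same-class genes
#'   recruited into a 250-kb window around each class seed locus
#'   (0 = uniform placement).
#' @param anchor_pull planting strength in [0, 1]: bins containing
#'   class genes move this fraction of the way to their class anchor.
#' @param contact_decay_gamma distance-decay exponent of contacts.
#' @param sequencing_depth expected contact count for bins one polymer
#'   step apart (the Poisson intensity cap).
#' @param resolution spatial bin size in bp (default 250000).
#' @param seed integer seed governing all stages of the run.
#' @return a validated `synthetic_config` list.
#' @export
synthetic_config <- function(n_chrom = 2L, chrom_length = 20e6,
                             n_genes = 400L, de_fraction = 0.4,
                             n_classes = 4L, class_proportions = NULL,
                             linear_clump_rate = 0, anchor_pull = 0,
                             contact_decay_gamma = 1,
                             sequencing_depth = 200,
                             resolution = 250000, seed = NULL) {
  if (is.null(class_proportions)) {
    class_proportions <- rep(1 / n_classes, n_classes)
  }
  stopifnot(n_chrom >= 1L, chrom_length > 0, n_genes >= 1L,
            de_fraction > 0, de_fraction <= 1,
            n_classes >= 1L, length(class_proportions) == n_classes,
            abs(sum(class_proportions) - 1) < 1e-8,
            all(class_proportions > 0),
            linear_clump_rate >= 0,
            anchor_pull >= 0, anchor_pull <= 1,
            contact_decay_gamma > 0, sequencing_depth > 0,
            resolution > 0)
  structure(list(n_chrom = as.integer(n_chrom), chrom_length = chrom_length,
                 n_genes = as.integer(n_genes), de_fraction = de_fraction,
                 n_classes = as.integer(n_classes),
                 class_proportions = class_proportions,
                 linear_clump_rate = linear_clump_rate,
                 anchor_pull = anchor_pull,
                 contact_decay_gamma = contact_decay_gamma,
                 sequencing_depth = sequencing_depth,
                 resolution = resolution, seed = seed),
            class = "synthetic_config")
}

#' Chromosome sizes of a synthetic configuration
#' @param cfg a [synthetic_config()].
#' @return named vector of chromosome lengths.
#' @export
synthetic_chrom_sizes <- function(cfg) {
  stats::setNames(rep(cfg$chrom_length, cfg$n_chrom),
                  paste0("chr", seq_len(cfg$n_chrom)))
}

# Largest-remainder apportionment of n_de among classes.
class_counts <- function(cfg) {
  n_de <- round(cfg$de_fraction * cfg$n_genes)
  raw <- cfg$class_proportions * n_de
  sizes <- floor(raw)
  rem <- n_de - sum(sizes)
  if (rem > 0) {
    give <- order(raw - sizes, decreasing = TRUE)[seq_len(rem)]
    sizes[give] <- sizes[give] + 1
  }
  if (any(sizes == 0)) stop("infeasible class proportions: class of size 0")
  as.integer(sizes)
}

#' Simulate a gene table with planted class structure
#'
#' Places `n_genes` genes on the synthetic genome. Unclassed genes are
#' uniform over the genome. Class genes are placed by a Neyman-Scott
#' cluster process when `linear_clump_rate > 0`: each cluster starts at
#' a uniformly placed seed gene joined by a geometrically distributed
#' number (mean `linear_clump_rate`) of same-class genes within the
#' following 250-kb window; at rate 0 this degenerates to uniform
#' placement. A `de_fraction` of genes are flagged DE and the DE genes
#' are partitioned into classes `C1..CK` by `class_proportions`.
#'
#' @param cfg a [synthetic_config()]; if `cfg$seed` is set, the RNG is
#'   seeded with it (this stage uses the seed unchanged).
#' @return a [gene_table()] sorted by chromosome and TSS.
#' @export
simulate_genome <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  sizes <- class_counts(cfg)
  n_de <- sum(sizes)
  n_plain <- cfg$n_genes - n_de
  if (n_plain < 0) stop("more DE genes than genes")
  chroms <- paste0("chr", seq_len(cfg$n_chrom))
  L <- cfg$chrom_length
  window <- 250000

  place_uniform <- function(k) {
    data.frame(chrom = sample(chroms, k, replace = TRUE),
               tss = floor(stats::runif(k, 0, L)),
               stringsAsFactors = FALSE)
  }
  place_class <- function(k) {
    if (cfg$linear_clump_rate == 0) return(place_uniform(k))
    out <- vector("list", 0L)
    left <- k
    while (left > 0L) {
      extra <- stats::rgeom(1L, 1 / (1 + cfg$linear_clump_rate))
      m <- min(1L + extra, left)
      ch <- sample(chroms, 1L)
      seed_pos <- floor(stats::runif(1L, 0, L))
      pos <- c(seed_pos,
               pmin(seed_pos + floor(stats::runif(m - 1L, 0, window)), L - 1))
      out[[length(out) + 1L]] <- data.frame(chrom = ch, tss = pos,
                                            stringsAsFactors = FALSE)
      left <- left - m
    }
    do.call(rbind, out)
  }

  parts <- list()
  if (n_plain > 0L) {
    p <- place_uniform(n_plain)
    p$class_label <- NA_character_
    p$de_flag <- FALSE
    parts[[length(parts) + 1L]] <- p
  }
  for (k in seq_len(cfg$n_classes)) {
    p <- place_class(sizes[k])
    p$class_label <- paste0("C", k)
    p$de_flag <- TRUE
    parts[[length(parts) + 1L]] <- p
  }
  df <- do.call(rbind, parts)
  df <- df[order(match(df$chrom, chroms), df$tss), , drop = FALSE]
  gene_table(sprintf("g%04d", seq_len(nrow(df))), df$chrom, df$tss,
             strand = sample(c("+", "-"), nrow(df), replace = TRUE),
             class_label = df$class_label, de_flag = df$de_flag,
             chrom_sizes = synthetic_chrom_sizes(cfg))
}

reflect_unit <- function(x) {
  x <- abs(x) %% 2
  ifelse(x > 1, 2 - x, x)
}

#' Simulate 3D bin coordinates with planted class co-localization
#'
#' Lays each chromosome as a 3D Gaussian-step random walk confined to
#' the unit cube (nucleus volume V = 1) by reflection, with the step SD
#' fixed so a 20-Mb chromosome spans about half the cube. Each class is
#' assigned a uniform random anchor point; every bin containing genes of
#' a class is then displaced a fraction `anchor_pull` of the way toward
#' its anchor (bins hosting several classes move toward the mean of
#' their anchors). `anchor_pull = 0` leaves the walk untouched;
#' `anchor_pull = 1` collapses each single-class bin set onto its
#' anchor.
#'
#' @param genes a [gene_table()] from [simulate_genome()].
#' @param cfg a [synthetic_config()]; if `cfg$seed` is set, the RNG is
#'   seeded with `cfg$seed + 1` (stage offset keeps the stages
#'   individually reproducible under one configuration seed).
#' @return a `bin_coordinates` list: `coords` (n_bins x 3 matrix),
#'   `bins`, `anchors`, `step` (per-axis step SD).
#' @export
simulate_structure <- function(genes, cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed + 1L)
  bins <- make_bins(synthetic_chrom_sizes(cfg), cfg$resolution)
  nb <- nrow(bins)
  coords <- matrix(NA_real_, nb, 3L)
  for (ch in unique(bins$chrom)) {
    rows <- which(bins$chrom == ch)
    n <- length(rows)
    steps <- matrix(stats::rnorm((n - 1L) * 3L, sd = WALK_STEP_SD),
                    n - 1L, 3L)
    walk <- apply(rbind(matrix(stats::runif(3L), 1L, 3L), steps), 2L, cumsum)
    coords[rows, ] <- reflect_unit(walk)
  }
  anchors <- matrix(stats::runif(cfg$n_classes * 3L), cfg$n_classes, 3L,
                    dimnames = list(paste0("C", seq_len(cfg$n_classes)), NULL))
  if (cfg$anchor_pull > 0) {
    binning <- assign_spatial_bins(genes, bins, cfg$resolution)
    lab <- genes$class_label
    for (b in unique(binning$bin[!is.na(lab) & !is.na(binning$bin)])) {
      cl <- unique(lab[!is.na(lab) & binning$bin == b])
      cl <- cl[!is.na(cl)]
      if (length(cl) == 0L) next
      target <- colMeans(anchors[cl, , drop = FALSE])
      coords[b, ] <- (1 - cfg$anchor_pull) * coords[b, ] +
        cfg$anchor_pull * target
    }
  }
  structure(list(coords = coords, bins = bins, anchors = anchors,
                 step = WALK_STEP_SD),
            class = "bin_coordinates")
}

#' Convert latent bin coordinates into a Hi-C contact map
#'
#' The expected contact between two bins decays with their spatial
#' distance: `lambda_ij = depth * (d_ij / u)^(-gamma)`, where `u` is the
#' RMS length of one polymer step (the generator's contact distance
#' unit) and `depth` caps the intensity for pairs closer than one step
#' (including coincident bins, which get the cap rather than an infinite
#' rate). Observed counts are Poisson draws around `lambda` (or exactly
#' `lambda` in noiseless mode, which exists for exact oracle checks);
#' the matrix is symmetric with a zero diagonal.
#'
#' @param coords a `bin_coordinates` from [simulate_structure()].
#' @param cfg a [synthetic_config()]; if `cfg$seed` is set, the RNG is
#'   seeded with `cfg$seed + 2` (stage offset).
#' @param noiseless if `TRUE`, return the expected counts.
#' @return a [contact_map()].
#' @export
structure_to_contacts <- function(coords, cfg, noiseless = FALSE) {
  stopifnot(inherits(coords, "bin_coordinates"),
            inherits(cfg, "synthetic_config"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed + 2L)
  d <- as.matrix(stats::dist(coords$coords))
  u <- coords$step * sqrt(3)  # RMS displacement of one walk step
  lambda <- cfg$sequencing_depth * pmin((d / u)^(-cfg$contact_decay_gamma),
                                        1, na.rm = FALSE)
  lambda[d < u] <- cfg$sequencing_depth
  diag(lambda) <- 0
  if (noiseless) {
    counts <- lambda
  } else {
    counts <- matrix(0, nrow(d), ncol(d))
    up <- upper.tri(d)
    counts[up] <- stats::rpois(sum(up), lambda[up])
    counts <- counts + t(counts)
  }
  contact_map(counts, coords$bins, cfg$resolution)
}

#' Named preset configurations
#'
#' Four study scenarios used throughout the package's validation:
#' `"null"` (no planted structure), `"strong"` (3D anchor pull 0.8, the
#' planted analogue of a strongly spatially co-clustered class),
#' `"sequence_only"` (heavy linear clumping, no 3D pull — clustering
#' driven purely by sequence proximity), and `"mixed"` (both
#' mechanisms, moderate). All share 2 chromosomes x 20 Mb, 400 genes,
#' 40% DE, 4 equal classes, decay exponent 1, depth 200.
#'
#' @param preset one of `"null"`, `"strong"`, `"sequence_only"`,
#'   `"mixed"`.
#' @param seed integer seed.
#' @return a [synthetic_config()].
#' @export
preset_config <- function(preset = c("null", "strong", "sequence_only",
                                     "mixed"), seed = NULL) {
  preset <- match.arg(preset)
  base <- list(seed = seed)
  args <- switch(preset,
    null = list(),
    strong = list(anchor_pull = 0.8),
    sequence_only = list(linear_clump_rate = 5),
    mixed = list(anchor_pull = 0.5, linear_clump_rate = 2))
  do.call(synthetic_config, c(base, args))
}

#' Simulate a complete synthetic dataset
#'
#' Runs genome, structure and contact simulation under one configuration
#' seed and returns everything needed for an end-to-end analysis,
#' including the latent coordinates for oracle checks.
#'
#' @param cfg a [synthetic_config()], or a preset name for
#'   [preset_config()].
#' @param seed integer seed (used when `cfg` is a preset name, or to
#'   override `cfg$seed`).
#' @param noiseless passed to [structure_to_contacts()].
#' @return list with `genes`, `coords`, `contacts`, `binning`, `cfg`.
#' @export
simulate_dataset <- function(cfg, seed = NULL, noiseless = FALSE) {
  if (is.character(cfg)) cfg <- preset_config(cfg, seed = seed)
  if (!is.null(seed)) cfg$seed <- seed
  genes <- simulate_genome(cfg)
  coords <- simulate_structure(genes, cfg)
  contacts <- structure_to_contacts(coords, cfg, noiseless = noiseless)
  binning <- assign_spatial_bins(genes, contacts)
  list(genes = genes, coords = coords, contacts = contacts,
       binning = binning, cfg = cfg)
}

#' Write a synthetic dataset to plain-text files
#'
#' Writes the gene TSV, bin BED, contact COO triplets and the true bin
#' coordinates (for oracle tests) into a directory.
#'
#' @param sim result of [simulate_dataset()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_gene_table(sim$genes, file.path(dir, "genes.tsv"))
  write_contact_map(sim$contacts, file.path(dir, "contacts.coo.tsv"),
                    file.path(dir, "bins.bed"))
  coords <- data.frame(bin = seq_len(nrow(sim$coords$coords)) - 1L,
                       sim$coords$coords)
  names(coords) <- c("bin", "x", "y", "z")
  utils::write.table(coords, file.path(dir, "coords.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}
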