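# Independent brute-force oracles and random-fixture builders.
# The oracles deliberately re-derive every quantity from the interval
# definitions with explicit loops, sharing no code with the package
# implementation.

# Linear distribution functions by explicit interval membership:
# pair i collects offsets in [i*dl, (i+1)*dl) or [-(i+1)*dl, -i*dl).
oracle_linear <- function(genes, alpha, delta_l, i_max) {
  tagged <- which(!is.na(genes$class_label) & genes$class_label == alpha)
  in_class <- !is.na(genes$class_label) & genes$class_label == alpha
  acc <- matrix(0, i_max, 3)
  for (x in tagged) {
    for (j in seq_len(nrow(genes))) {
      if (j == x || genes$chrom[j] != genes$chrom[x]) next
      o <- genes$tss[j] - genes$tss[x]
      for (i in 0:(i_max - 1)) {
        hit <- (o >= i * delta_l && o < (i + 1) * delta_l) ||
          (o >= -(i + 1) * delta_l && o < -i * delta_l)
        if (hit) {
          if (in_class[j]) acc[i + 1, 1] <- acc[i + 1, 1] + 1
          acc[i + 1, 2] <- acc[i + 1, 2] + 1
          if (genes$de_flag[j]) acc[i + 1, 3] <- acc[i + 1, 3] + 1
        }
      }
    }
  }
  m <- acc / length(tagged)
  data.frame(i = 0:(i_max - 1),
             sigma_L = m[, 1] / (length(tagged) - 1),
             sigma_LA = m[, 2] / (nrow(genes) - 1),
             sigma_LD = m[, 3] / (sum(genes$de_flag) - 1))
}

# Radial distribution by explicit tagged-gene x counted-gene x shell loops.
oracle_radial <- function(genes, bin, D, alpha, counted, delta_r, n_shells) {
  tagged <- which(!is.na(genes$class_label) & genes$class_label == alpha)
  cnt <- if (identical(counted, "ALL")) {
    seq_len(nrow(genes))
  } else if (identical(counted, "DE")) {
    which(genes$de_flag)
  } else {
    which(!is.na(genes$class_label) & genes$class_label == counted)
  }
  norm <- if (identical(counted, "ALL")) {
    nrow(genes) - 1
  } else if (identical(counted, "DE") || identical(counted, alpha)) {
    length(cnt) - 1
  } else {
    length(cnt)
  }
  counts <- matrix(0, length(tagged), n_shells)
  for (t in seq_along(tagged)) {
    x <- tagged[t]
    for (j in cnt) {
      if (j == x) next  # tagged gene never counts itself
      d <- D[bin[x], bin[j]]
      if (!is.finite(d)) next
      for (i in 0:(n_shells - 1)) {
        if (d >= i * delta_r && d < (i + 1) * delta_r) {
          counts[t, i + 1] <- counts[t, i + 1] + 1
        }
      }
    }
  }
  V <- (4 * pi / 3) * ((((1:n_shells)) * delta_r)^3 -
                         ((0:(n_shells - 1)) * delta_r)^3)
  colMeans(counts) / (norm * V)
}

# All-pairs shortest paths by the Floyd-Warshall recursion.
floyd_warshall <- function(adj) {
  n <- nrow(adj)
  D <- matrix(Inf, n, n)
  D[adj > 0] <- adj[adj > 0]
  diag(D) <- 0
  for (k in 1:n) for (i in 1:n) for (j in 1:n) {
    if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
  }
  D
}

# Random gene table + bins + Euclidean distance matrix, built directly
# (not via the package generator). Classes partition the DE genes.
random_fixture <- function(n_genes = 120, n_chrom = 2, chrom_len = 5e6,
                           n_classes = 3, de_frac = 0.5, res = 250000) {
  sizes <- stats::setNames(rep(chrom_len, n_chrom),
                           paste0("chr", seq_len(n_chrom)))
  chrom <- sample(names(sizes), n_genes, replace = TRUE)
  tss <- floor(runif(n_genes, 0, chrom_len))
  n_de <- max(n_classes * 2, round(de_frac * n_genes))
  de <- rep(FALSE, n_genes)
  de[sample(n_genes, n_de)] <- TRUE
  lab <- rep(NA_character_, n_genes)
  lab[de] <- paste0("K", sample(rep_len(seq_len(n_classes), n_de)))
  genes <- gene_table(sprintf("g%03d", 1:n_genes), chrom, tss,
                      class_label = lab, de_flag = de)
  bins <- make_bins(sizes, res)
  coords <- matrix(runif(nrow(bins) * 3), ncol = 3)
  D <- as.matrix(dist(coords))
  binning <- assign_spatial_bins(genes, bins, res)
  list(genes = genes, bins = bins, D = D, binning = binning,
       coords = coords)
}

# Random sparse symmetric direct-distance graph as a contact map.
random_contact_map <- function(n = 20, p_edge = 0.3, res = 1000) {
  m <- matrix(0, n, n)
  up <- which(upper.tri(m))
  on <- up[runif(length(up)) < p_edge]
  m[on] <- runif(length(on), 0.5, 5)
  m <- m + t(m)
  if (all(m == 0)) m[1, 2] <- m[2, 1] <- 1  # guarantee an edge
  bins <- make_bins(c(chr1 = n * res), res)
  contact_map(m, bins, res)
}
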