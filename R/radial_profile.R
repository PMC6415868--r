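#' Spherical shell volumes
#'
#' Shell `i` is the half-open distance interval `[i*dr, (i+1)*dr)`; its
#' volume is `(4*pi/3) * (((i+1)*dr)^3 - (i*dr)^3)`, with the nucleus
#' volume convention V = 1 (distances are expressed in units where the
#' nucleus has unit volume, or any fixed unit — the volume convention
#' cancels from enrichment ratios).
#'
#' @param n_shells number of shells.
#' @param delta_r shell thickness.
#' @return numeric vector of shell volumes, strictly increasing.
#' @export
shell_volumes <- function(n_shells, delta_r) {
  delta_r <- unname(delta_r)
  i <- seq_len(n_shells) - 1
  (4 * pi / 3) * (((i + 1) * delta_r)^3 - (i * delta_r)^3)
}

# Resolve a counted-group spec ("ALL", "DE", or a class label) to gene
# indices within `genes`.
counted_group <- function(genes, counted) {
  if (identical(counted, "ALL")) {
    seq_len(nrow(genes))
  } else if (identical(counted, "DE")) {
    which(genes$de_flag)
  } else {
    which(!is.na(genes$class_label) & genes$class_label == counted)
  }
}

#' Radial distribution function of a gene group around a tagged class
#'
#' For every class-`alpha` gene taken as the tagged gene, the sphere
#' centred on the tagged gene's genomic bin is divided into concentric
#' shells of thickness `delta_r` in the spatial distance matrix `D`. The
#' number of counted-group genes whose bins fall in shell `i` (distance
#' in `[i*dr, (i+1)*dr)`; genes sharing the tagged bin are at distance 0,
#' hence in shell 0) is divided by the group size and the shell volume,
#' and averaged over all tagged genes:
#'
#' \deqn{\sigma^R_{\alpha\beta}(i) = \left\langle \frac{n_{\beta i}}
#'   {N_\beta \; V_i / V} \right\rangle_\alpha, \quad V = 1}
#'
#' When the counted group contains the tagged gene itself (counted =
#' same class, `"ALL"`, or `"DE"`), the tagged gene is excluded from the
#' shell-0 count, and for the same-class case also from the normalizer
#' (`N_alpha - 1`); the controls use `N - 1` and `N_D - 1`. Pairs at
#' infinite distance (disconnected components) never fall in any shell.
#'
#' Genes whose bins are absent from `D` (e.g. filtered chromosomes) are
#' dropped from both the tagged and counted sets with a message;
#' normalizers refer to the retained genes. Multiple tagged genes in one
#' bin are each used independently: the average is over genes, not bins.
#'
#' @param genes a [gene_table()].
#' @param binning a `spatial_binning` from [assign_spatial_bins()].
#' @param D spatial distance matrix over the binning's bins.
#' @param alpha tagged class label.
#' @param counted `"ALL"`, `"DE"`, or a class label (use `alpha` itself
#'   for the intra-class function).
#' @param delta_r shell thickness, same unit as `D`.
#' @param n_shells number of shells (default 10).
#' @param cis_only if `TRUE`, only same-chromosome gene pairs are
#'   counted; default counts genome-wide.
#' @return a `radial_profile` data frame with columns `shell`,
#'   `sigma_R`, `mean_count`, `shell_volume`; attributes `alpha`,
#'   `counted`, `normalizer`, `delta_r`.
#' @export
radial_distribution <- function(genes, binning, D, alpha,
                                counted = "ALL", delta_r,
                                n_shells = 10L, cis_only = FALSE) {
  stopifnot(delta_r > 0, n_shells >= 1L)
  valid <- !is.na(binning$bin)
  n_dropped <- sum(!valid)
  if (n_dropped > 0L) {
    message(n_dropped, " gene(s) without a bin in the distance matrix dropped")
  }
  g <- genes[valid, , drop = FALSE]
  bin <- binning$bin[valid]
  tagged <- which(!is.na(g$class_label) & g$class_label == alpha)
  if (length(tagged) == 0L) stop("no tagged genes in class ", alpha)
  cnt <- counted_group(g, counted)
  self_in_group <- identical(counted, "ALL") ||
    (identical(counted, "DE")) || identical(counted, alpha)
  norm <- if (identical(counted, alpha)) {
    length(cnt) - 1L
  } else if (identical(counted, "ALL")) {
    nrow(g) - 1L
  } else if (identical(counted, "DE")) {
    length(cnt) - 1L
  } else {
    length(cnt)
  }
  if (norm <= 0L) stop("normalizer not positive for counted group ", counted)

  counts <- matrix(0, nrow = length(tagged), ncol = n_shells)
  for (t in seq_along(tagged)) {
    x <- tagged[t]
    d <- D[bin[x], bin[cnt]]
    if (cis_only) d[g$chrom[cnt] != g$chrom[x]] <- Inf
    sh <- floor(d / delta_r)
    sh[!is.finite(sh) | sh >= n_shells] <- NA
    counts[t, ] <- tabulate(sh + 1L, nbins = n_shells)
    if (self_in_group && (x %in% cnt)) {
      counts[t, 1L] <- counts[t, 1L] - 1L  # tagged gene is at distance 0
    }
  }
  V <- shell_volumes(n_shells, delta_r)
  mean_count <- colMeans(counts)
  out <- data.frame(shell = seq_len(n_shells) - 1L,
                    sigma_R = mean_count / (norm * V),
                    mean_count = mean_count,
                    shell_volume = V)
  attr(out, "alpha") <- alpha
  attr(out, "counted") <- counted
  attr(out, "normalizer") <- norm
  attr(out, "delta_r") <- delta_r
  class(out) <- c("radial_profile", "data.frame")
  out
}

#' First-shell enrichment ratio matrix across classes
#'
#' Computes, for every ordered pair of classes (tagged `alpha`, counted
#' `beta`), the first-shell enrichment ratio
#' \eqn{\sigma^R_{\alpha\beta}(0) / \sigma^{RA}_\alpha(0)} — the density
#' of class-`beta` genes in the first spatial shell around tagged
#' class-`alpha` genes, relative to the density of all genes there.
#' Values above 1 on the diagonal indicate intra-class spatial
#' co-clustering beyond the all-gene background; off-diagonal entries
#' measure inter-class co-clustering. A per-class DE-control column
#' \eqn{\sigma^{RD}_\alpha(0)/\sigma^{RA}_\alpha(0)} is also returned.
#'
#' @inheritParams radial_distribution
#' @param classes class labels to include (default: all declared
#'   classes, sorted).
#' @return a `ratio_matrix`: list with `ratios` (K x K matrix, rows =
#'   tagged class, cols = counted class), `de_ratio` (named vector),
#'   `sigma0` (first-shell sigma values used), `delta_r`. A zero
#'   all-gene denominator yields `NA` entries with a warning.
#' @export
first_shell_ratios <- function(genes, binning, D, delta_r,
                               classes = NULL, cis_only = FALSE) {
  if (is.null(classes)) {
    classes <- sort(unique(genes$class_label[!is.na(genes$class_label)]))
  }
  K <- length(classes)
  ratios <- matrix(NA_real_, K, K, dimnames = list(classes, classes))
  de_ratio <- stats::setNames(rep(NA_real_, K), classes)
  sigma0 <- list()
  for (a in classes) {
    sA <- radial_distribution(genes, binning, D, a, "ALL", delta_r,
                              n_shells = 1L, cis_only = cis_only)$sigma_R[1L]
    sD <- radial_distribution(genes, binning, D, a, "DE", delta_r,
                              n_shells = 1L, cis_only = cis_only)$sigma_R[1L]
    sB <- vapply(classes, function(b) {
      radial_distribution(genes, binning, D, a, b, delta_r,
                          n_shells = 1L, cis_only = cis_only)$sigma_R[1L]
    }, numeric(1))
    if (sA > 0) {
      ratios[a, ] <- sB / sA
      de_ratio[a] <- sD / sA
    } else {
      warning("all-gene first-shell density is zero for tagged class ", a,
              "; ratios undefined")
    }
    sigma0[[a]] <- c(all = sA, de = sD, sB)
  }
  structure(list(ratios = ratios, de_ratio = de_ratio, sigma0 = sigma0,
                 delta_r = delta_r),
            class = "ratio_matrix")
}

#' Linear genomic offsets between first-shell same-class gene pairs
#'
#' For each unordered pair of class-`alpha` genes whose bins lie within
#' the first spatial shell of each other (distance < `delta_r`), records
#' the absolute genomic TSS offset when the genes share a chromosome, or
#' counts the pair as trans-chromosomal otherwise. Large offsets reveal
#' class members that are far apart along the sequence yet spatially
#' close.
#'
#' @inheritParams radial_distribution
#' @return list with `offsets` (numeric vector of bp offsets, one per
#'   cis pair) and `n_trans` (count of trans-chromosomal first-shell
#'   pairs).
#' @export
first_shell_linear_distances <- function(genes, binning, D, alpha, delta_r) {
  stopifnot(delta_r > 0)
  valid <- !is.na(binning$bin)
  g <- genes[valid, , drop = FALSE]
  bin <- binning$bin[valid]
  idx <- which(!is.na(g$class_label) & g$class_label == alpha)
  offsets <- numeric(0)
  n_trans <- 0L
  if (length(idx) >= 2L) {
    pairs <- utils::combn(idx, 2L)
    d <- D[cbind(bin[pairs[1L, ]], bin[pairs[2L, ]])]
    close <- is.finite(d) & d < delta_r
    p1 <- pairs[1L, close]
    p2 <- pairs[2L, close]
    cis <- g$chrom[p1] == g$chrom[p2]
    offsets <- abs(g$tss[p1[cis]] - g$tss[p2[cis]])
    n_trans <- sum(!cis)
  }
  list(offsets = offsets, n_trans = n_trans)
}
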