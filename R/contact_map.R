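#' Construct a Hi-C contact map
#'
#' A contact map is a symmetric non-negative bin-by-bin matrix of contact
#' frequencies together with the genomic coordinates of its bins. Bins
#' must tile each chromosome contiguously at the declared resolution
#' (the last bin of a chromosome may be short). The diagonal is ignored
#' by all downstream operations.
#'
#' @param counts symmetric non-negative numeric matrix (dense, or a
#'   `Matrix` sparse matrix which is densified).
#' @param bins data frame with columns `chrom`, `start`, `end`
#'   (0-based half-open), one row per matrix row/column, in matrix order.
#' @param resolution bin size in bp; inferred from the bins if omitted.
#' @return a `contact_map` object (list with `counts`, `bins`,
#'   `resolution`).
#' @export
contact_map <- function(counts, bins, resolution = NULL) {
  counts <- as.matrix(counts)
  if (nrow(counts) != ncol(counts)) stop("counts must be square")
  if (nrow(counts) != nrow(bins)) stop("counts dimension must match bins")
  if (any(counts < 0)) stop("contact counts must be non-negative")
  if (max(abs(counts - t(counts))) > 1e-8 * max(1, max(abs(counts)))) {
    stop("contact matrix must be symmetric")
  }
  counts <- (counts + t(counts)) / 2
  bins <- data.frame(chrom = as.character(bins$chrom),
                     start = as.numeric(bins$start),
                     end = as.numeric(bins$end),
                     stringsAsFactors = FALSE)
  if (is.null(resolution)) resolution <- max(bins$end - bins$start)
  check_bin_tiling(bins, resolution)
  structure(list(counts = counts, bins = bins, resolution = resolution),
            class = "contact_map")
}

check_bin_tiling <- function(bins, resolution) {
  for (ch in unique(bins$chrom)) {
    b <- bins[bins$chrom == ch, , drop = FALSE]
    b <- b[order(b$start), , drop = FALSE]
    k <- seq_len(nrow(b)) - 1
    if (any(b$start != k * resolution)) {
      stop("bins on ", ch, " do not tile contiguously at resolution ",
           resolution)
    }
    if (any(b$end[-nrow(b)] != b$start[-1])) {
      stop("bins on ", ch, " have gaps or overlaps")
    }
  }
  invisible(TRUE)
}

#' Build genomic bins tiling chromosomes at a fixed resolution
#'
#' @param chrom_sizes named numeric vector or two-column data frame of
#'   chromosome lengths (bp).
#' @param resolution bin size in bp.
#' @return data frame with `chrom`, `start`, `end` (0-based half-open);
#'   the last bin of a chromosome may be short.
#' @export
make_bins <- function(chrom_sizes, resolution) {
  stopifnot(resolution > 0)
  sizes <- as_chrom_sizes(chrom_sizes)
  out <- lapply(names(sizes), function(ch) {
    n <- ceiling(sizes[[ch]] / resolution)
    start <- (seq_len(n) - 1) * resolution
    data.frame(chrom = ch, start = start,
               end = pmin(start + resolution, sizes[[ch]]),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Read a contact map from COO triplets or a dense matrix
#'
#' The COO format is three tab-separated columns
#' `bin_i<TAB>bin_j<TAB>count` with 0-based bin indices referring to the
#' companion bin BED file (chrom, start, end; 0-based half-open). Entries
#' are mirrored to enforce symmetry; duplicated (i, j) entries are summed.
#' The dense format is a whitespace-separated square matrix.
#'
#' @param path path to the contact file.
#' @param bins_path path to the bin BED file.
#' @param format `"coo"` or `"dense"`.
#' @param resolution optional bin size in bp (inferred if omitted).
#' @return a [contact_map()].
#' @export
read_contact_map <- function(path, bins_path, format = c("coo", "dense"),
                             resolution = NULL) {
  format <- match.arg(format)
  bins <- read_bins_bed(bins_path)
  n <- nrow(bins)
  if (format == "coo") {
    coo <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)
    i <- as.integer(coo[[1L]]) + 1L
    j <- as.integer(coo[[2L]]) + 1L
    x <- as.numeric(coo[[3L]])
    if (any(i < 1L | i > n | j < 1L | j > n)) {
      stop("COO bin index out of range of the bin table")
    }
    m <- as.matrix(Matrix::sparseMatrix(i = i, j = j, x = x, dims = c(n, n)))
    m <- pmax(m, t(m))  # mirror: an entry given on one side defines both
  } else {
    m <- as.matrix(utils::read.table(path))
    dimnames(m) <- NULL
  }
  contact_map(m, bins, resolution = resolution)
}

#' Read a bin BED file (chrom, start, end)
#'
#' @param path path to a BED3 file.
#' @return data frame with `chrom`, `start`, `end` (0-based half-open).
#' @export
read_bins_bed <- function(path) {
  df <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)
  data.frame(chrom = as.character(df[[1L]]), start = as.numeric(df[[2L]]),
             end = as.numeric(df[[3L]]), stringsAsFactors = FALSE)
}

#' Write a contact map as COO triplets plus a bin BED
#'
#' Only the upper triangle (i <= j) of non-zero entries is written, with
#' 0-based bin indices.
#'
#' @param cm a [contact_map()].
#' @param path output path for the COO TSV.
#' @param bins_path output path for the bin BED.
#' @return `path`, invisibly.
#' @export
write_contact_map <- function(cm, path, bins_path) {
  idx <- which(upper.tri(cm$counts, diag = TRUE) & cm$counts > 0,
               arr.ind = TRUE)
  coo <- data.frame(i = idx[, 1L] - 1L, j = idx[, 2L] - 1L,
                    x = cm$counts[idx])
  utils::write.table(coo, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  bed <- cm$bins
  bed$start <- format(bed$start, scientific = FALSE, trim = TRUE)
  bed$end <- format(bed$end, scientific = FALSE, trim = TRUE)
  utils::write.table(bed, bins_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Assign genes to fixed-size genomic bins by TSS
#'
#' A gene with TSS `t` on chromosome `c` maps to bin `floor(t /
#' resolution)` of `c` (half-open bins `[k*res, (k+1)*res)`), i.e. the
#' bin containing its TSS. Genes on chromosomes absent from the bin
#' table are excluded from spatial operations (bin index `NA`) with a
#' warning; they remain available for linear-profile operations.
#'
#' @param genes a [gene_table()].
#' @param bins bin table (data frame `chrom`, `start`, `end`) or a
#'   [contact_map()] whose bins are used.
#' @param resolution bin size in bp; inferred from the bins if omitted.
#' @return a `spatial_binning`: list with `bin` (integer row index into
#'   `bins` per gene, `NA` when unmapped), `bins`, `resolution`,
#'   `gene_id`.
#' @export
assign_spatial_bins <- function(genes, bins, resolution = NULL) {
  if (inherits(bins, "contact_map")) {
    if (is.null(resolution)) resolution <- bins$resolution
    bins <- bins$bins
  }
  if (is.null(resolution)) resolution <- max(bins$end - bins$start)
  stopifnot(resolution > 0)
  ord <- order(match(bins$chrom, unique(bins$chrom)), bins$start)
  if (any(ord != seq_along(ord))) stop("bin table must be sorted by chrom, start")
  offset <- c(0, cumsum(table(factor(bins$chrom, levels = unique(bins$chrom)))))
  names(offset) <- c(unique(bins$chrom), "_end")
  nb <- table(factor(bins$chrom, levels = unique(bins$chrom)))
  k <- genes$tss %/% resolution
  idx <- rep(NA_integer_, nrow(genes))
  known <- genes$chrom %in% names(nb)
  inrange <- known & k < as.numeric(nb[genes$chrom])
  idx[inrange] <- as.integer(offset[genes$chrom[inrange]] + k[inrange] + 1)
  dropped <- sum(!inrange)
  if (dropped > 0L) {
    warning(dropped, " gene(s) on chromosomes/positions absent from the bin ",
            "table; excluded from spatial operations")
  }
  structure(list(bin = idx, bins = bins, resolution = resolution,
                 gene_id = genes$gene_id),
            class = "spatial_binning")
}

#' Genome-wide gene occupancy of fixed-size bins
#'
#' Tiles the genome into bins of `bin_size` (default 1 Mb, the scale of
#' topologically associating domains) and summarises how genes and DE
#' genes pack into them: a joint histogram over (genes per bin, DE genes
#' per bin), the fraction of gene-free bins, and the cumulative share of
#' all genes found in the densest top fraction of bins.
#'
#' @param genes a [gene_table()]; must be non-empty.
#' @param chrom_sizes chromosome lengths (named vector or data frame).
#' @param bin_size bin size in bp (default 1e6).
#' @param top_fracs fractions of densest bins at which cumulative gene
#'   shares are reported.
#' @return list with `histogram` (matrix, rows = genes per bin, cols =
#'   DE genes per bin, cells = number of bins), `gene_free_fraction`,
#'   `top_share` (named numeric), `n_bins`, `bin_size`.
#' @export
occupancy_summary <- function(genes, chrom_sizes, bin_size = 1e6,
                              top_fracs = c(0.01, 0.05, 0.1, 0.2)) {
  if (nrow(genes) == 0L) stop("empty gene table")
  sizes <- as_chrom_sizes(chrom_sizes)
  unknown <- !(genes$chrom %in% names(sizes))
  if (any(unknown)) {
    warning(sum(unknown), " gene(s) on chromosomes without declared sizes ",
            "excluded from the occupancy summary")
    genes <- genes[!unknown, , drop = FALSE]
    if (nrow(genes) == 0L) stop("no genes on declared chromosomes")
  }
  bins <- make_bins(sizes, bin_size)
  binning <- assign_spatial_bins(genes, bins, bin_size)
  nb <- nrow(bins)
  g <- tabulate(binning$bin, nbins = nb)
  d <- tabulate(binning$bin[genes$de_flag], nbins = nb)
  hist <- table(factor(g, levels = 0:max(g)), factor(d, levels = 0:max(d)))
  hist <- unclass(hist)
  ord <- order(g, decreasing = TRUE)
  cum <- cumsum(g[ord]) / sum(g)
  top_share <- vapply(top_fracs, function(f) cum[max(1L, ceiling(f * nb))],
                      numeric(1))
  names(top_share) <- paste0("top_", top_fracs * 100, "pct")
  list(histogram = hist,
       gene_free_fraction = mean(g == 0),
       top_share = top_share,
       n_bins = nb, bin_size = bin_size)
}
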