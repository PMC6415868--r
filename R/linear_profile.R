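#' Pair-of-bins index for a signed TSS offset
#'
#' The sequence flanking a tagged TSS is divided into pairs of bins of
#' width `delta_l`: pair `i` covers offsets `[i*dl, (i+1)*dl)` downstream
#' and `[-(i+1)*dl, -i*dl)` upstream. The intervals are half-open so the
#' pairs partition all offsets: an offset of 0 (co-located TSS) belongs
#' to pair 0 and no offset is counted twice.
#'
#' @param offset numeric vector of signed TSS offsets (bp).
#' @param delta_l bin width (bp).
#' @return integer vector of pair indices (0-based).
#' @keywords internal
linear_pair_index <- function(offset, delta_l) {
  ifelse(offset >= 0, offset %/% delta_l, ceiling(-offset / delta_l) - 1)
}

#' Averaged linear distribution function of a gene class
#'
#' For every class-`alpha` gene taken in turn as the tagged gene, counts
#' how many genes of a given group have their TSS in the `i`-th pair of
#' `delta_l`-wide bins flanking the tagged TSS (same chromosome only; the
#' tagged gene itself is excluded, so pair 0 counts co-located and
#' near-TSS neighbours but never the gene itself). Averaging the counts
#' over all tagged genes and normalising by the group size minus self
#' gives the linear distribution function:
#'
#' \deqn{\sigma^L_\alpha(i) = \langle n_{i\alpha} + n_{-i\alpha}
#'   \rangle_\alpha / (N_\alpha - 1)}
#'
#' and analogously the all-gene control \eqn{\sigma^{LA}_\alpha(i) =
#' \langle n_i + n_{-i}\rangle_\alpha / (N - 1)} and the DE-gene control
#' \eqn{\sigma^{LD}_\alpha(i) = \langle n_{iD} + n_{-iD}\rangle_\alpha /
#' (N_D - 1)}. If class membership carried no information about linear
#' position, all three would agree within statistical error; an excess of
#' \eqn{\sigma^L} over the controls at small `i` indicates clustering of
#' the class along the sequence.
#'
#' No edge correction is applied near chromosome ends: bins extending
#' past an end simply contain fewer genes, identically for the class and
#' both controls.
#'
#' @param genes a [gene_table()].
#' @param alpha class label of the tagged class (needs at least 2
#'   members).
#' @param delta_l flanking bin width in bp (default 125000).
#' @param i_max number of bin pairs computed (indices `0 .. i_max - 1`;
#'   default 40, i.e. +/- 5 Mb at the default width).
#' @return a `linear_profile` data frame with columns `i`, `sigma_L`,
#'   `sigma_LA`, `sigma_LD` and the raw mean counts `n_class`, `n_all`,
#'   `n_de`; attributes carry `alpha`, `delta_l` and the normalizers.
#' @export
linear_distribution <- function(genes, alpha, delta_l = 125000, i_max = 40L) {
  stopifnot(delta_l > 0, i_max >= 1L)
  tagged <- which(!is.na(genes$class_label) & genes$class_label == alpha)
  n_alpha <- length(tagged)
  if (n_alpha < 2L) stop("class too small for sigma^L: N_alpha = ", n_alpha)
  n <- nrow(genes)
  n_de <- sum(genes$de_flag)
  if (n < 2L || n_de < 2L) stop("need at least 2 genes and 2 DE genes")

  is_class <- !is.na(genes$class_label) & genes$class_label == alpha
  acc <- matrix(0, nrow = i_max, ncol = 3L)  # class, all, de
  for (x in tagged) {
    same <- which(genes$chrom == genes$chrom[x])
    same <- same[same != x]
    if (length(same) == 0L) next
    idx <- linear_pair_index(genes$tss[same] - genes$tss[x], delta_l)
    keep <- idx < i_max
    idx <- idx[keep] + 1L
    same <- same[keep]
    if (length(same) == 0L) next
    acc[, 1L] <- acc[, 1L] + tabulate(idx[is_class[same]], nbins = i_max)
    acc[, 2L] <- acc[, 2L] + tabulate(idx, nbins = i_max)
    acc[, 3L] <- acc[, 3L] + tabulate(idx[genes$de_flag[same]], nbins = i_max)
  }
  mean_counts <- acc / n_alpha
  out <- data.frame(
    i = seq_len(i_max) - 1L,
    sigma_L = mean_counts[, 1L] / (n_alpha - 1),
    sigma_LA = mean_counts[, 2L] / (n - 1),
    sigma_LD = mean_counts[, 3L] / (n_de - 1),
    n_class = mean_counts[, 1L],
    n_all = mean_counts[, 2L],
    n_de = mean_counts[, 3L]
  )
  attr(out, "alpha") <- alpha
  attr(out, "delta_l") <- delta_l
  attr(out, "normalizers") <- c(class = n_alpha - 1, all = n - 1, de = n_de - 1)
  class(out) <- c("linear_profile", "data.frame")
  out
}
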