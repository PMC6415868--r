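# Gene-level first-shell machinery shared by the permutation test.
#
# P[x, y] is TRUE when the bins of genes x and y are within delta_r
# (finite distance); P[x, x] is TRUE (distance 0) and self terms are
# subtracted where the estimator excludes the tagged gene.
first_shell_adjacency <- function(bin, D, delta_r) {
  d <- D[bin, bin, drop = FALSE]
  is.finite(d) & d < delta_r
}

diag_first_shell_ratio <- function(P, row_all, tagged_idx, n_genes, v0) {
  nt <- length(tagged_idx)
  num <- (sum(P[tagged_idx, tagged_idx]) - nt) / nt / ((nt - 1) * v0)
  den <- mean(row_all[tagged_idx]) / ((n_genes - 1) * v0)
  num / den
}

#' Permutation test for intra-class first-shell enrichment
#'
#' Tests whether the observed diagonal first-shell enrichment ratio
#' \eqn{\sigma^R_{\alpha\alpha}(0)/\sigma^{RA}_\alpha(0)} of class
#' `alpha` exceeds what class labels carry by chance. The null is
#' generated by uniformly permuting class labels among the DE genes
#' (preserving every class size, the DE set, and all gene positions and
#' bins) and recomputing the ratio; the competing hypothesis is
#' class-specific clustering beyond generic DE-gene clustering, which is
#' why labels move only within the DE set. The test is one-sided
#' (enrichment), with the add-one estimator
#' `p = (1 + #(null >= observed)) / (B + 1)` so `p` is never zero.
#'
#' @inheritParams radial_distribution
#' @param B number of permutations (at least 19; default 999).
#' @param seed optional integer seed for reproducibility.
#' @return a `permutation_test` list: `alpha`, `observed`, `null`
#'   (length-`B` vector), `p`, `B`, `seed`.
#' @export
permutation_test_first_shell <- function(genes, binning, D, alpha, delta_r,
                                         B = 999L, seed = NULL) {
  if (B < 19L) stop("B < 19: p-value resolution too coarse")
  if (!is.null(seed)) set.seed(seed)
  valid <- !is.na(binning$bin)
  g <- genes[valid, , drop = FALSE]
  bin <- binning$bin[valid]
  labels <- g$class_label
  de_idx <- which(g$de_flag)
  tagged <- which(!is.na(labels) & labels == alpha)
  if (length(tagged) < 2L) stop("class too small for the permutation test")

  P <- first_shell_adjacency(bin, D, delta_r)
  row_all <- rowSums(P) - 1  # all-gene first-shell count per gene, self excluded
  v0 <- shell_volumes(1L, delta_r)
  n <- nrow(g)
  size_check <- sort(table(labels[de_idx], useNA = "ifany"))

  observed <- diag_first_shell_ratio(P, row_all, tagged, n, v0)
  null <- vapply(seq_len(B), function(b) {
    perm <- labels
    perm[de_idx] <- sample(labels[de_idx])
    stopifnot(identical(sort(table(perm[de_idx], useNA = "ifany")), size_check))
    diag_first_shell_ratio(P, row_all,
                           which(!is.na(perm) & perm == alpha), n, v0)
  }, numeric(1))
  p <- (1 + sum(null >= observed)) / (B + 1)
  structure(list(alpha = alpha, observed = observed, null = null,
                 p = p, B = B, seed = seed),
            class = "permutation_test")
}

#' Merge fine gene classes into coarser classes
#'
#' Relabels classed genes according to a fine-to-merged mapping,
#' emulating the situation where an upstream clustering resolves only
#' mixtures of finer co-regulation classes. Merging classes that
#' co-cluster at different spatial anchors dilutes the diagonal
#' first-shell enrichment of the merged class toward 1.
#'
#' @param genes a [gene_table()].
#' @param mapping named character vector: `names(mapping)` are the fine
#'   class labels, values the merged labels. Every fine label present in
#'   `genes` must be mapped.
#' @return a relabeled [gene_table()].
#' @export
merge_classes <- function(genes, mapping) {
  fine <- unique(genes$class_label[!is.na(genes$class_label)])
  unmapped <- setdiff(fine, names(mapping))
  if (length(unmapped) > 0L) {
    stop("unmapped class label(s): ", paste(unmapped, collapse = ", "))
  }
  lab <- genes$class_label
  has <- !is.na(lab)
  lab[has] <- unname(mapping[lab[has]])
  genes$class_label <- lab
  validate_gene_table(as.data.frame(genes))
}

#' Benjamini-Hochberg adjustment for per-class p-values
#'
#' Step-up false discovery rate adjustment across the tested classes
#' (via [stats::p.adjust()]), with input validation: p-values must lie in
#' (0, 1], as produced by the add-one permutation estimator.
#'
#' @param pvalues numeric vector of p-values in (0, 1].
#' @return adjusted p-values, same length and names.
#' @export
bh_adjust <- function(pvalues) {
  if (any(!is.finite(pvalues)) || any(pvalues <= 0) || any(pvalues > 1)) {
    stop("p-values must lie in (0, 1]")
  }
  stats::p.adjust(pvalues, method = "BH")
}

#' Full co-clustering analysis of a gene table and contact map
#'
#' Convenience wrapper running the whole pipeline: contact inversion and
#' shortest-path completion, shell-width selection, first-shell
#' enrichment ratios for every class, per-class permutation tests, and
#' BH adjustment.
#'
#' @param genes a [gene_table()].
#' @param cm a [contact_map()].
#' @param gamma contact inversion exponent.
#' @param delta_r shell width; default picks
#'   [default_shell_width()] on the reconstructed distances.
#' @param B permutations per class.
#' @param seed integer seed for the permutation tests.
#' @return list with `D`, `delta_r`, `binning`, `ratios` (a
#'   `ratio_matrix`), `tests` (per-class `permutation_test`s), and
#'   `p_adjusted`.
#' @export
analyze_coclustering <- function(genes, cm, gamma = 1, delta_r = NULL,
                                 B = 999L, seed = NULL) {
  D <- distances_from_contacts(cm, gamma = gamma)
  if (is.null(delta_r)) delta_r <- default_shell_width(D)
  binning <- assign_spatial_bins(genes, cm)
  ratios <- first_shell_ratios(genes, binning, D, delta_r)
  classes <- rownames(ratios$ratios)
  tests <- lapply(seq_along(classes), function(k) {
    permutation_test_first_shell(genes, binning, D, classes[k], delta_r,
                                 B = B,
                                 seed = if (is.null(seed)) NULL else seed + k)
  })
  names(tests) <- classes
  p <- vapply(tests, `[[`, numeric(1), "p")
  list(D = D, delta_r = delta_r, binning = binning, ratios = ratios,
       tests = tests, p_adjusted = bh_adjust(p))
}
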