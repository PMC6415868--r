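#' Construct a validated gene table
#'
#' A gene table locates every gene by the strand-resolved transcription
#' start site (TSS) and carries two orthogonal annotations: a `de_flag`
#' marking differentially expressed (DE) genes, and an optional
#' `class_label` assigning a gene to a co-regulation class (e.g. a class
#' exported from an HMM/DREM clustering of expression trajectories).
#' Class labels are only allowed on DE genes: the classes partition a
#' subset of the DE genes, and the unlabeled remainder participates only
#' in the all-gene (and, if DE, the DE-gene) controls.
#'
#' Coordinates are 0-based bp throughout (BED dialect).
#'
#' @param gene_id character, unique gene identifiers.
#' @param chrom character, chromosome names.
#' @param tss non-negative integer TSS positions (0-based bp).
#' @param strand one of `"+"`, `"-"`, `"*"` per gene (`"*"` = unknown).
#' @param class_label optional class labels; `NA` or `""` means unlabeled.
#' @param de_flag logical DE indicator.
#' @param chrom_sizes optional named vector or two-column data frame
#'   (`chrom`, `length`); when supplied, TSS positions are checked to lie
#'   within the declared chromosome lengths.
#' @return A `gene_table`: a data frame with columns `gene_id`, `chrom`,
#'   `tss`, `strand`, `class_label`, `de_flag`.
#' @examples
#' gene_table(c("g1", "g2"), "chr1", c(100, 900), c("+", "-"),
#'            class_label = c("C1", NA), de_flag = c(TRUE, FALSE))
#' @export
gene_table <- function(gene_id, chrom, tss, strand = "*",
                       class_label = NA_character_, de_flag = FALSE,
                       chrom_sizes = NULL) {
  n <- length(gene_id)
  df <- data.frame(
    gene_id = as.character(gene_id),
    chrom = as.character(rep_len(chrom, n)),
    tss = as.numeric(rep_len(tss, n)),
    strand = as.character(rep_len(strand, n)),
    class_label = as.character(rep_len(class_label, n)),
    de_flag = as.logical(rep_len(de_flag, n)),
    stringsAsFactors = FALSE
  )
  df$class_label[!is.na(df$class_label) & df$class_label == ""] <- NA_character_
  validate_gene_table(df, chrom_sizes = chrom_sizes)
}

#' Validate a gene table
#'
#' Enforces the gene-table invariants: unique gene ids, non-negative
#' integral TSS, valid strand codes, and the class/DE consistency rule
#' (every classed gene must be flagged DE).
#'
#' @param df a data frame with gene-table columns.
#' @param chrom_sizes optional chromosome lengths (see [gene_table()]).
#' @return `df` with class `gene_table`, invisibly checked.
#' @export
validate_gene_table <- function(df, chrom_sizes = NULL) {
  required <- c("gene_id", "chrom", "tss", "strand", "class_label", "de_flag")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    stop("gene table is missing columns: ", paste(missing, collapse = ", "))
  }
  dup <- unique(df$gene_id[duplicated(df$gene_id)])
  if (length(dup) > 0L) {
    stop("duplicate gene_id: ", paste(dup, collapse = ", "))
  }
  if (any(is.na(df$tss)) || any(df$tss < 0) || any(df$tss != floor(df$tss))) {
    stop("tss must be non-negative integers (0-based bp)")
  }
  if (!all(df$strand %in% c("+", "-", "*"))) {
    stop("strand must be one of '+', '-', '*'")
  }
  bad <- !is.na(df$class_label) & !df$de_flag
  if (any(bad)) {
    stop("classed gene(s) with de_flag = FALSE: ",
         paste(df$gene_id[bad], collapse = ", "))
  }
  if (!is.null(chrom_sizes)) {
    sizes <- as_chrom_sizes(chrom_sizes)
    len <- sizes[df$chrom]
    over <- !is.na(len) & df$tss >= len
    if (any(over)) {
      stop("tss beyond declared chromosome length for: ",
           paste(df$gene_id[over], collapse = ", "))
    }
  }
  class(df) <- c("gene_table", "data.frame")
  df
}

as_chrom_sizes <- function(x) {
  if (is.data.frame(x)) {
    stats::setNames(as.numeric(x[[2L]]), as.character(x[[1L]]))
  } else {
    stats::setNames(as.numeric(x), names(x))
  }
}

#' Read a gene table from TSV or BED6
#'
#' The TSV format carries all fields directly (columns `gene_id`,
#' `chrom`, `tss`, `strand`, optionally `class_label` and `de_flag` in
#' 0/1 or TRUE/FALSE). A BED6 file supplies coordinates only; the TSS is
#' resolved from the strand (`start` for `+`, `end` for `-`, both in the
#' BED 0-based half-open convention), and class labels and DE flags come
#' from a companion class table (TSV with columns `gene_id`,
#' `class_label`, `de_flag`). Genes absent from the class table are
#' unlabeled and not DE.
#'
#' @param path path to the gene file.
#' @param format `"tsv"` or `"bed6"`.
#' @param class_table optional path to a class-assignment TSV (required
#'   information for BED6 inputs carrying classes).
#' @param chrom_sizes optional chromosome sizes for range checking.
#' @return a [gene_table()].
#' @export
read_gene_table <- function(path, format = c("tsv", "bed6"),
                            class_table = NULL, chrom_sizes = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "tsv") {
    df <- utils::read.delim(path, stringsAsFactors = FALSE)
    if (is.null(df$class_label)) df$class_label <- NA_character_
    if (is.null(df$de_flag)) df$de_flag <- FALSE
    df$class_label <- as.character(df$class_label)
    de <- df$de_flag
    if (!is.logical(de)) de <- as.integer(de) != 0L
    gt <- gene_table(df$gene_id, df$chrom, df$tss, df$strand,
                     df$class_label, de, chrom_sizes = chrom_sizes)
  } else {
    gr <- rtracklayer::import(path, format = "BED")
    strand <- as.character(GenomicRanges::strand(gr))
    # GRanges are 1-based closed; BED start = start(gr) - 1, BED end = end(gr)
    tss <- ifelse(strand == "-", GenomicRanges::end(gr),
                  GenomicRanges::start(gr) - 1L)
    ids <- gr$name
    lab <- rep(NA_character_, length(gr))
    de <- rep(FALSE, length(gr))
    if (!is.null(class_table)) {
      ct <- utils::read.delim(class_table, stringsAsFactors = FALSE)
      ct$class_label <- as.character(ct$class_label)
      ct$class_label[!is.na(ct$class_label) & ct$class_label == ""] <- NA_character_
      m <- match(ids, ct$gene_id)
      hit <- !is.na(m)
      lab[hit] <- ct$class_label[m[hit]]
      def <- ct$de_flag
      if (!is.logical(def)) def <- as.integer(def) != 0L
      de[hit] <- def[m[hit]]
    }
    gt <- gene_table(ids, as.character(GenomicRanges::seqnames(gr)), tss,
                     ifelse(strand %in% c("+", "-"), strand, "*"),
                     lab, de, chrom_sizes = chrom_sizes)
  }
  gt
}

#' Write a gene table as TSV
#'
#' Inverse of [read_gene_table()] for the TSV format: unlabeled genes get
#' an empty `class_label`, and `de_flag` is written as 0/1.
#'
#' @param genes a [gene_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gene_table <- function(genes, path) {
  out <- as.data.frame(genes)
  out$class_label[is.na(out$class_label)] <- ""
  out$de_flag <- as.integer(out$de_flag)
  out$tss <- format(out$tss, scientific = FALSE, trim = TRUE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Class, DE and total gene counts
#'
#' @param genes a [gene_table()].
#' @return list with `n` (total genes), `n_de` (DE genes), and
#'   `class_sizes` (named vector of per-class counts).
#' @export
class_sizes <- function(genes) {
  tab <- table(genes$class_label[!is.na(genes$class_label)])
  list(n = nrow(genes), n_de = sum(genes$de_flag),
       class_sizes = stats::setNames(as.integer(tab), names(tab)))
}

#' Read a chromosome sizes file
#'
#' Two tab-separated columns, `chrom` and `length` (bp), no header.
#'
#' @param path path to the sizes file.
#' @return named numeric vector of chromosome lengths.
#' @export
read_chrom_sizes <- function(path) {
  df <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)
  stats::setNames(as.numeric(df[[2L]]), as.character(df[[1L]]))
}
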