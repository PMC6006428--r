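## Gene co-expression pipeline: normalization, significance-masked
## correlation matrices, clustering-based ordering, and module density
## comparison.

#' Normalize an expression matrix
#'
#' Three inspectable stages, applied in order:
#' \enumerate{
#'   \item `log2(x + 1)` (the +1 accommodates genes with zero counts);
#'   \item quantile normalization fitting all samples to a single
#'     distribution (each sample's sorted values are replaced by the
#'     cross-sample mean of order statistics, ties receiving the mean
#'     of their tied targets; delegated to
#'     `limma::normalizeQuantiles`);
#'   \item subtraction of the quantile-normalized gene mean across all
#'     samples.
#' }
#'
#' @param mat genes x samples matrix of non-negative FPKM-like values.
#' @param stages character vector of stages to apply, in order, from
#'   `c("log", "quantile", "center")`.
#' @return normalized matrix (same dimnames).
#' @export
normalize_expression <- function(mat,
                                 stages = c("log", "quantile", "center")) {
  stopifnot(is.matrix(mat))
  stages <- match.arg(stages, c("log", "quantile", "center"),
                      several.ok = TRUE)
  if ("log" %in% stages && any(mat < 0))
    stop("expression values must be non-negative before log2(x + 1)")
  out <- mat
  for (s in stages) {
    out <- switch(s,
      log = log2(out + 1),
      quantile = {
        q <- limma::normalizeQuantiles(out, ties = TRUE)
        dimnames(q) <- dimnames(out)
        q
      },
      center = out - rowMeans(out))
  }
  out
}

#' Pearson correlation matrix with significance mask
#'
#' Pairwise gene-gene Pearson correlation across samples with
#' two-sided p-values from the exact t-transform
#' `t = r sqrt(n-2) / sqrt(1-r^2)`; entries with `p > p_threshold` are
#' masked (`NA` in `masked`).  Constant (zero-variance) genes have
#' undefined correlations: their pairs are masked and the genes
#' reported.
#'
#' @param mat normalized genes x samples matrix (>= 3 samples).
#' @param p_threshold significance threshold for the mask (default
#'   0.01).
#' @return list of class `correlation_matrix`: `pcc` (full matrix),
#'   `p` (p-values, 0 on the diagonal), `masked` (PCC with
#'   non-significant entries `NA`), `constant_genes`.
#' @export
pcc_matrix <- function(mat, p_threshold = 0.01) {
  stopifnot(is.matrix(mat))
  n <- ncol(mat)
  if (n < 3) stop("need at least 3 samples")
  sds <- apply(mat, 1, stats::sd)
  const <- rownames(mat)[sds == 0]
  r <- suppressWarnings(stats::cor(t(mat)))
  tstat <- r * sqrt(n - 2) / sqrt(pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  diag(p) <- 0
  masked <- r
  masked[p > p_threshold] <- NA
  bad <- sds == 0
  masked[bad, ] <- NA; masked[, bad] <- NA
  diag(masked) <- 1
  structure(list(pcc = r, p = p, masked = masked,
                 constant_genes = const,
                 p_threshold = p_threshold),
            class = "correlation_matrix")
}

#' Order genes by hierarchical clustering of correlations
#'
#' Agglomerative clustering with complete linkage on the distance
#' `1 - PCC`; returns the dendrogram leaf order.  `hclust` ties are
#' broken by its deterministic row order, so the ordering is
#' reproducible for a given input.
#'
#' @param corr a `correlation_matrix` from [pcc_matrix()] or a square
#'   PCC matrix.
#' @return integer vector: leaf order of the genes.
#' @export
order_by_clustering <- function(corr) {
  r <- if (inherits(corr, "correlation_matrix")) corr$pcc else corr
  stopifnot(is.matrix(r), nrow(r) == ncol(r))
  if (all(!is.finite(r))) stop("correlation matrix contains no finite values")
  if (nrow(r) == 1) return(1L)
  d <- stats::as.dist(1 - r)
  if (any(!is.finite(d))) stop("cannot cluster a fully masked matrix")
  stats::hclust(d, method = "complete")$order
}

#' Within- and between-set PCC distributions
#'
#' Collects the PCC values inside each gene set, between each pair of
#' sets, and between each set and the background; summarises each
#' collection with a kernel density (normal-reference bandwidth) and
#' reports the separation between sets as differences of within-set
#' median PCCs.
#'
#' @param corr a `correlation_matrix` or square PCC matrix with gene
#'   dimnames.
#' @param gene_sets named list of character vectors (each >= 2 genes,
#'   subsets of the matrix genes).
#' @return list with `within` (named list of PCC vectors), `between`
#'   (named list for each set pair), `densities` (stats::density
#'   objects, NULL for empty collections), `within_medians`, and
#'   `separation` (matrix of pairwise within-median differences).
#' @export
module_pcc_density <- function(corr, gene_sets) {
  r <- if (inherits(corr, "correlation_matrix")) corr$pcc else corr
  genes <- rownames(r)
  for (nm in names(gene_sets)) {
    gs <- gene_sets[[nm]]
    if (length(gs) < 2) stop("gene set '", nm, "' has fewer than 2 genes")
    if (!all(gs %in% genes))
      stop("gene set '", nm, "' contains genes absent from the matrix")
  }
  off_diag <- function(m) m[upper.tri(m)]
  within <- lapply(gene_sets, function(gs) off_diag(r[gs, gs, drop = FALSE]))
  between <- list()
  nms <- names(gene_sets)
  if (length(nms) >= 2) {
    for (i in seq_along(nms)) for (j in seq_along(nms)) {
      if (j <= i) next
      key <- paste(nms[i], nms[j], sep = ":")
      between[[key]] <-
        as.numeric(r[gene_sets[[nms[i]]], gene_sets[[nms[j]]]])
    }
  }
  all_sets <- unlist(gene_sets)
  bg <- setdiff(genes, all_sets)
  if (length(bg) >= 1)
    for (nm in nms)
      between[[paste(nm, "background", sep = ":")]] <-
        as.numeric(r[gene_sets[[nm]], bg, drop = FALSE])
  dens <- lapply(c(within, between), function(v)
    if (length(v) >= 2) stats::density(v, bw = "nrd0") else NULL)
  wm <- vapply(within, stats::median, 0)
  sep <- outer(wm, wm, `-`)
  list(within = within, between = between, densities = dens,
       within_medians = wm, separation = sep)
}

#' Read/write expression matrices as TSV (genes in rows)
#' @param mat genes x samples matrix.
#' @param path file path.
#' @return `read_expression` returns a matrix.
#' @export
write_expression <- function(mat, path) {
  utils::write.table(mat, path, sep = "\t", quote = FALSE,
                     col.names = NA)
  invisible(path)
}

#' @rdname write_expression
#' @export
read_expression <- function(path) {
  as.matrix(utils::read.delim(path, row.names = 1, check.names = FALSE))
}
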