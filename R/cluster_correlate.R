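#' Hierarchical clustering of samples on enrichment scores
#'
#' Agglomerative clustering of samples using the Euclidean distance between
#' their ES profiles over a chosen signature subset (typically the
#' disease-vs-healthy enriched set). Complete linkage by default; the
#' linkage is a presentation choice, so it is configurable.
#'
#' @param es signatures x samples ES matrix.
#' @param signature_subset ids of the rows to cluster on (default: all).
#' @param linkage "complete" (default), "average", or "ward.D2".
#' @param k number(s) of flat clusters to cut (default 2).
#' @param annotations optional data.frame with a `sample` column plus
#'   grouping columns (e.g. disease, group, timepoint) used for the
#'   per-cluster composition table.
#' @return object of class `cluster_result`: list with `hclust`, `labels`
#'   (matrix samples x length(k)), `k`, and `composition` (NULL without
#'   annotations).
#' @export
hcluster <- function(es, signature_subset = rownames(es),
                     linkage = c("complete", "average", "ward.D2"),
                     k = 2L, annotations = NULL) {
  stopifnot(is.matrix(es))
  linkage <- match.arg(linkage)
  signature_subset <- unique(as.character(signature_subset))
  if (!length(signature_subset)) stop("signature subset is empty")
  miss <- setdiff(signature_subset, rownames(es))
  if (length(miss)) stop("unknown signature(s): ", paste(miss, collapse = ", "))
  if (ncol(es) < 2L) stop("need at least 2 samples to cluster")
  sub <- es[signature_subset, , drop = FALSE]
  hc <- stats::hclust(stats::dist(t(sub), method = "euclidean"),
                      method = linkage)
  labels <- vapply(k, function(kk) stats::cutree(hc, k = kk),
                   integer(ncol(sub)))
  labels <- matrix(labels, ncol = length(k),
                   dimnames = list(colnames(sub), paste0("k", k)))
  comp <- NULL
  if (!is.null(annotations)) {
    stopifnot("sample" %in% names(annotations))
    ann <- annotations[match(colnames(sub), annotations$sample), , drop = FALSE]
    grp <- interaction(ann[setdiff(names(ann), "sample")], drop = TRUE)
    comp <- table(cluster = labels[, 1L], group = grp)
  }
  structure(list(hclust = hc, labels = labels, k = k, composition = comp),
            class = "cluster_result")
}

#' Cluster purity against a reference labeling
#'
#' For each flat cluster, the majority reference label and the fraction of
#' members carrying it; plus the member-weighted overall purity. Quantifies
#' statements like "one cluster is almost entirely healthy controls and
#' post-treatment responders".
#'
#' @param labels integer cluster assignments named by sample (e.g. one
#'   column of a `cluster_result`'s `labels`), or a `cluster_result`
#'   (first k used).
#' @param reference character reference labels, named by sample or parallel.
#' @return list with `per_cluster` data.frame (cluster, n, majority,
#'   purity) and `overall` weighted purity.
#' @export
cluster_purity <- function(labels, reference) {
  if (inherits(labels, "cluster_result"))
    labels <- stats::setNames(labels$labels[, 1L],
                              rownames(labels$labels))
  if (!is.null(names(labels)) && !is.null(names(reference)))
    reference <- reference[names(labels)]
  stopifnot(length(labels) == length(reference))
  tab <- table(cluster = labels, ref = as.character(reference))
  maj <- colnames(tab)[apply(tab, 1L, which.max)]
  n <- rowSums(tab)
  pur <- apply(tab, 1L, max) / n
  list(per_cluster = data.frame(cluster = rownames(tab), n = as.integer(n),
                                majority = maj, purity = as.numeric(pur),
                                stringsAsFactors = FALSE, row.names = NULL),
       overall = sum(pur * n) / sum(n))
}

#' Pairwise Pearson correlation between signature enrichment profiles
#'
#' Correlates ES rows across samples for every pair in `set_a` x `set_b`,
#' with the two-sided p-value from the t transform of r, and (when a
#' library is supplied) the gene-composition overlap of the pair — high ES
#' correlation with near-zero gene overlap is the signal that two cell-type
#' programs co-occur rather than share genes. P-values are reported
#' unadjusted.
#'
#' @param es signatures x samples ES matrix (>= 3 samples).
#' @param set_a,set_b signature id vectors (rows of `es`).
#' @param lib optional [signature_library()] for overlap counts.
#' @return data.frame with columns sig_a, sig_b, r, p, n, n_overlap_genes.
#'   Zero-variance rows give NA correlations with a warning.
#' @export
signature_correlations <- function(es, set_a, set_b, lib = NULL) {
  stopifnot(is.matrix(es), ncol(es) >= 3L)
  set_a <- as.character(set_a); set_b <- as.character(set_b)
  miss <- setdiff(c(set_a, set_b), rownames(es))
  if (length(miss)) stop("unknown signature(s): ", paste(miss, collapse = ", "))
  n <- ncol(es)
  grid <- expand.grid(sig_a = set_a, sig_b = set_b,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  r <- p <- numeric(nrow(grid)); ovl <- rep(NA_integer_, nrow(grid))
  warned <- FALSE
  for (i in seq_len(nrow(grid))) {
    x <- es[grid$sig_a[i], ]; y <- es[grid$sig_b[i], ]
    if (stats::sd(x) == 0 || stats::sd(y) == 0) {
      r[i] <- NA_real_; p[i] <- NA_real_; warned <- TRUE
    } else {
      r[i] <- stats::cor(x, y)
      tstat <- r[i] * sqrt((n - 2) / max(1 - r[i]^2, .Machine$double.eps))
      p[i] <- 2 * stats::pt(abs(tstat), n - 2, lower.tail = FALSE)
    }
    if (!is.null(lib))
      ovl[i] <- length(intersect(lib$sets[[grid$sig_a[i]]],
                                 lib$sets[[grid$sig_b[i]]]))
  }
  if (warned) warning("zero-variance ES row(s): correlation reported as NA")
  data.frame(grid, r = r, p = p, n = n, n_overlap_genes = ovl,
             stringsAsFactors = FALSE)
}

#' Export a clustering tree in Newick format
#'
#' @param result a `cluster_result` (or an `hclust`).
#' @param path output path.
#' @return `path`, invisibly. Requires the `ape` package.
#' @export
export_newick <- function(result, path) {
  hc <- if (inherits(result, "cluster_result")) result$hclust else result
  if (!requireNamespace("ape", quietly = TRUE))
    stop("Newick export requires the 'ape' package")
  ape::write.tree(ape::as.phylo(hc), file = path)
  invisible(path)
}
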