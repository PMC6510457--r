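#' Kernel-CDF expression statistic
#'
#' First stage of the single-sample enrichment engine. For each gene i the
#' expression profile across the cohort is smoothed with a Gaussian kernel
#' CDF and each sample's value is replaced by its estimated cumulative
#' probability:
#'
#'   z_ij = (1/n) * sum_k Phi((x_ij - x_ik) / h_i),  h_i = s_i / 4
#'
#' where s_i is the gene's sample standard deviation. The statistic is
#' invariant to per-gene positive affine transforms of the input (location
#' shifts cancel; positive scaling cancels through h_i), which is what makes
#' downstream scores comparable across genes measured on different dynamic
#' ranges. Zero-variance genes are uninformative and are assigned z = 0.5
#' everywhere, with a warning.
#'
#' @param expr numeric genes x samples matrix (log2 intensities) with >= 3
#'   columns.
#' @return matrix of the same shape with entries in (0, 1).
#' @export
kcdf_transform <- function(expr) {
  stopifnot(is.matrix(expr), is.numeric(expr))
  if (anyNA(expr)) stop("expression matrix contains missing values")
  n <- ncol(expr)
  if (n < 3L) stop("kernel CDF estimation needs at least 3 samples")
  mu <- rowMeans(expr)
  s <- sqrt(rowSums((expr - mu)^2) / (n - 1L))
  h <- s / 4
  z <- matrix(0.5, nrow(expr), n, dimnames = dimnames(expr))
  zv <- h == 0
  if (any(zv))
    warning(sum(zv), " zero-variance gene(s) assigned z = 0.5")
  for (i in which(!zv)) {
    xi <- expr[i, ]
    z[i, ] <- rowMeans(stats::pnorm(outer(xi, xi, "-") / h[i]))
  }
  z
}

#' Symmetric rank statistic
#'
#' Second stage: within each sample, genes are ranked by decreasing KCDF
#' statistic (ties broken stably by gene index) and the rank is folded
#' around the middle of the list,
#'
#'   r_ij = | p/2 - rank_ij |,  p = number of genes,
#'
#' so that extreme genes (highest- and lowest-expressed) get large weights
#' and mid-list genes get weights near zero.
#'
#' @param z genes x samples matrix from [kcdf_transform()] (finite).
#' @return matrix of folded ranks, same shape as `z`.
#' @export
rank_statistic <- function(z) {
  stopifnot(is.matrix(z), all(is.finite(z)))
  p <- nrow(z)
  rk <- apply_sample_ranks(z)
  r <- abs(p / 2 - rk)
  dimnames(r) <- dimnames(z)
  r
}

## Per-sample rank of each gene under decreasing z, stable in gene index.
apply_sample_ranks <- function(z) {
  p <- nrow(z)
  out <- matrix(0L, p, ncol(z))
  for (j in seq_len(ncol(z))) {
    ord <- order(-z[, j], seq_len(p))  # radix: deterministic ties
    out[ord, j] <- seq_len(p)
  }
  out
}

#' Enrichment-score random walk for one sample
#'
#' Third stage: a weighted Kolmogorov-Smirnov-like walk down the sample's
#' ranked gene list. Steps on in-set genes rise by that gene's folded rank
#' raised to `tau` (normalized by the in-set total); steps on out-of-set
#' genes fall by 1/(p - k). The score is the maximum positive deviation
#' plus the maximum negative deviation of the walk ("max-diff" statistic),
#' which lies in \[-1, 1\] and is near 0 for a set scattered uniformly
#' through the list.
#'
#' @param r numeric vector of folded rank statistics for one sample
#'   (gene order = row order of the matrix).
#' @param ord integer permutation giving the sample's genes in decreasing
#'   expression-statistic order (`ord[1]` = top gene).
#' @param geneset integer indices (into `r`) of the signature's genes.
#' @param tau weight exponent on the folded rank (default 1).
#' @return ES scalar in \[-1, 1\].
#' @export
walk_es <- function(r, ord, geneset, tau = 1) {
  p <- length(r)
  k <- length(geneset)
  if (k < 1L || k >= p)
    stop("gene set must be a non-empty strict subset of the universe")
  inset <- logical(p)
  inset[geneset] <- TRUE
  inset <- inset[ord]
  w <- (r[ord]^tau) * inset
  if (sum(w) == 0) w <- as.numeric(inset)  # all set genes folded to rank 0
  cdf_in <- cumsum(w) / sum(w)
  cdf_out <- cumsum(!inset) / (p - k)
  d <- cdf_in - cdf_out
  max(c(d, 0)) + min(c(d, 0))
}

#' Single-sample gene-set enrichment scores
#'
#' Full engine: kernel-CDF transform, per-sample symmetric rank statistic,
#' and the weighted random walk, applied to every signature x sample pair.
#' Scores are cohort-relative (the KCDF pools across all supplied samples),
#' so samples that must be comparable should be scored in a single call;
#' scoring a validation cohort separately is the "independent validation"
#' mode.
#'
#' @param expr numeric genes x samples matrix (log2 scale) with rownames
#'   (gene symbols, unique) and colnames (sample ids, unique); >= 3 samples.
#' @param lib a [signature_library()].
#' @param min_size,max_size signature size bounds applied after intersecting
#'   each signature with the expression matrix's gene universe (defaults
#'   5 and 500). Out-of-bounds signatures are dropped with a warning.
#' @param tau random-walk weight exponent (default 1).
#' @return signatures x samples numeric matrix of enrichment scores in
#'   \[-1, 1\], with an attribute `"params"` recording the engine settings.
#' @examples
#' set.seed(1)
#' x <- matrix(rnorm(200, 7, 1), 20, 10,
#'             dimnames = list(paste0("G", 1:20), paste0("S", 1:10)))
#' lib <- signature_library(list(setA.UP = paste0("G", 1:6)))
#' es <- gsva_scores(x, lib)
#' range(es)
#' @export
gsva_scores <- function(expr, lib, min_size = 5L, max_size = 500L, tau = 1) {
  stopifnot(is.matrix(expr), inherits(lib, "signature_library"))
  if (is.null(rownames(expr)) || is.null(colnames(expr)))
    stop("expression matrix needs gene rownames and sample colnames")
  if (anyDuplicated(rownames(expr))) stop("duplicate gene ids")
  if (anyDuplicated(colnames(expr))) stop("duplicate sample ids")
  genes <- toupper(rownames(expr))
  idx <- lapply(lib$sets, function(g) which(genes %in% g))
  sizes <- lengths(idx)
  keep <- sizes >= min_size & sizes <= max_size & sizes < nrow(expr)
  if (any(!keep))
    warning("dropping ", sum(!keep), " signature(s) outside size bounds [",
            min_size, ", ", max_size, "] after universe intersection: ",
            paste(names(idx)[!keep], collapse = ", "))
  idx <- idx[keep]
  if (!length(idx))
    stop("no signature survives intersection with the gene universe")
  z <- kcdf_transform(expr)
  r <- rank_statistic(z)
  p <- nrow(expr)
  es <- matrix(NA_real_, length(idx), ncol(expr),
               dimnames = list(names(idx), colnames(expr)))
  for (j in seq_len(ncol(expr))) {
    ordj <- order(-z[, j], seq_len(p))
    rj <- r[, j]
    for (s in seq_along(idx))
      es[s, j] <- walk_es(rj, ordj, idx[[s]], tau = tau)
  }
  attr(es, "params") <- list(kcdf = "Gaussian", bandwidth = "sd/4",
                             tau = tau, es_mode = "maxdiff",
                             min_size = min_size, max_size = max_size)
  es
}

#' Write / read an enrichment-score matrix as TSV with a JSON sidecar
#'
#' The engine parameters travel with the scores in `<path>.params.json` so a
#' stored matrix is self-describing.
#'
#' @param es matrix from [gsva_scores()].
#' @param path TSV output path.
#' @return `path` invisibly (writer); the ES matrix with its `"params"`
#'   attribute restored (reader).
#' @export
write_es_matrix <- function(es, path) {
  df <- data.frame(signature = rownames(es), es, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  params <- attr(es, "params")
  if (!is.null(params))
    jsonlite::write_json(params, paste0(path, ".params.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_es_matrix
#' @export
read_es_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  es <- as.matrix(df[, -1L, drop = FALSE])
  rownames(es) <- df[[1L]]
  sidecar <- paste0(path, ".params.json")
  if (file.exists(sidecar))
    attr(es, "params") <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  es
}
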