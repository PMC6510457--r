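#' Selection criteria for differential enrichment
#'
#' The dual threshold under which a signature counts as differentially
#' enriched between two groups: the difference in mean enrichment score
#' must be at least `min_delta` AND the t-test significance must be at
#' most `alpha`. Significance defaults to the Benjamini-Hochberg adjusted
#' p-value; set `use_adjusted = FALSE` to threshold the raw p instead
#' (both readings are defensible from the published description, so the
#' choice is carried in the criteria object and logged in outputs).
#'
#' @param min_delta minimum |difference in mean ES| (default 0.2).
#' @param alpha significance cutoff, inclusive (default 0.05).
#' @param direction which sign of delta qualifies: "up" (group A above
#'   group B), "down", or "both" (default "up", matching the upregulated
#'   signature selection used for the disease-activity score).
#' @param use_adjusted threshold the BH-adjusted p (default TRUE).
#' @return object of class `selection_criteria`.
#' @export
selection_criteria <- function(min_delta = 0.2, alpha = 0.05,
                               direction = c("up", "down", "both"),
                               use_adjusted = TRUE) {
  stopifnot(alpha > 0, alpha < 1, min_delta >= 0)
  structure(list(min_delta = min_delta, alpha = alpha,
                 direction = match.arg(direction), adjust = "BH",
                 use_adjusted = isTRUE(use_adjusted)),
            class = "selection_criteria")
}

#' Compare enrichment scores between two sample groups
#'
#' Per-signature two-sample comparison of ES: pooled-variance t-test
#' (the two-level reduction of a general linear model), or a paired t-test
#' when `paired = TRUE` and `subject` links the samples (the within-subject
#' post-treatment vs baseline design). P-values are BH-adjusted across the
#' signatures tested in this one comparison.
#'
#' @param es signatures x samples ES matrix.
#' @param labels character/factor of group labels, either named by sample id
#'   or parallel to `colnames(es)`.
#' @param group_a,group_b the two labels to compare; `delta` = mean(A) -
#'   mean(B), so put the case group first and the reference second.
#' @param paired use a paired t-test (default FALSE).
#' @param subject subject ids parallel to `labels`; required when `paired`.
#' @return a data.frame of class `differential_result` with one row per
#'   signature: mean_a, mean_b, delta, t, df, p_raw, p_adj; comparison
#'   metadata in attributes.
#' @export
compare_groups <- function(es, labels, group_a, group_b,
                           paired = FALSE, subject = NULL) {
  stopifnot(is.matrix(es))
  labels <- align_labels(labels, colnames(es))
  known <- unique(labels)
  if (!group_a %in% known) stop("unknown group label: ", group_a)
  if (!group_b %in% known) stop("unknown group label: ", group_b)
  ia <- which(labels == group_a); ib <- which(labels == group_b)
  if (length(ia) < 2L || length(ib) < 2L)
    stop("each group needs at least 2 samples (",
         group_a, ": ", length(ia), ", ", group_b, ": ", length(ib), ")")
  a <- es[, ia, drop = FALSE]; b <- es[, ib, drop = FALSE]
  if (paired) {
    if (is.null(subject)) stop("paired comparison needs subject ids")
    subject <- align_labels(subject, colnames(es))
    sa <- subject[ia]; sb <- subject[ib]
    common <- intersect(sa, sb)
    if (length(common) < 2L) stop("fewer than 2 complete subject pairs")
    d <- a[, match(common, sa), drop = FALSE] -
         b[, match(common, sb), drop = FALSE]
    nd <- ncol(d)
    md <- rowMeans(d)
    sd_d <- sqrt(rowSums((d - md)^2) / (nd - 1L))
    t <- md / (sd_d / sqrt(nd))
    t[sd_d == 0 & md == 0] <- 0
    df <- nd - 1L
    p <- 2 * stats::pt(abs(t), df, lower.tail = FALSE)
    res <- data.frame(signature = rownames(es), mean_a = rowMeans(a),
                      mean_b = rowMeans(b), delta = md, t = t, df = df,
                      p_raw = p, stringsAsFactors = FALSE, row.names = NULL)
  } else {
    tt <- row_t_pooled(a, b)
    res <- data.frame(signature = rownames(es), mean_a = rowMeans(a),
                      mean_b = rowMeans(b), delta = tt$delta, t = tt$t,
                      df = tt$df, p_raw = tt$p, stringsAsFactors = FALSE,
                      row.names = NULL)
  }
  res$p_adj <- stats::p.adjust(res$p_raw, method = "BH")
  attr(res, "comparison") <- list(group_a = group_a, group_b = group_b,
                                  n_a = length(ia), n_b = length(ib),
                                  paired = paired)
  class(res) <- c("differential_result", class(res))
  res
}

align_labels <- function(labels, ids) {
  labels <- as.character(labels)
  if (!is.null(names(labels))) {
    if (!all(ids %in% names(labels)))
      stop("labels missing for sample(s): ",
           paste(setdiff(ids, names(labels)), collapse = ", "))
    labels <- labels[ids]
  } else if (length(labels) != length(ids)) {
    stop("labels must be named by sample id or match the column count")
  }
  unname(labels)
}

#' Select differentially enriched signatures
#'
#' Applies [selection_criteria()] to a [compare_groups()] result. Both
#' boundaries are inclusive: delta exactly at `min_delta` and significance
#' exactly at `alpha` qualify.
#'
#' @param res a `differential_result`.
#' @param crit a [selection_criteria()] (default: the standard thresholds).
#' @return character vector of selected signature ids, in the result's
#'   row order; the criteria used are attached as attribute `"criteria"`.
#' @export
select_enriched <- function(res, crit = selection_criteria()) {
  stopifnot(inherits(res, "differential_result"),
            inherits(crit, "selection_criteria"))
  p <- if (crit$use_adjusted) res$p_adj else res$p_raw
  ok <- !is.na(p) & p <= crit$alpha & abs(res$delta) >= crit$min_delta
  ok <- ok & switch(crit$direction,
                    up = res$delta > 0,
                    down = res$delta < 0,
                    both = TRUE)
  out <- res$signature[ok]
  attr(out, "criteria") <- crit
  out
}

#' Two-set Venn partition
#'
#' @param set_a,set_b character vectors of signature ids.
#' @return list with counts `only_a`, `shared`, `only_b` and the member
#'   vectors `members_only_a`, `members_shared`, `members_only_b`.
#' @export
venn_counts <- function(set_a, set_b) {
  set_a <- unique(as.character(set_a)); set_b <- unique(as.character(set_b))
  sh <- intersect(set_a, set_b)
  oa <- setdiff(set_a, set_b); ob <- setdiff(set_b, set_a)
  list(only_a = length(oa), shared = length(sh), only_b = length(ob),
       members_only_a = oa, members_shared = sh, members_only_b = ob)
}

#' Write a differential result as TSV
#'
#' @param res a `differential_result`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_differential_result <- function(res, path) {
  utils::write.table(as.data.frame(res), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
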