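#' Baseline differential-enrichment workflow
#'
#' The first analysis arm: score the whole cohort once, then compare each
#' disease's baseline samples (responders and non-responders together)
#' against the healthy volunteers, select the upregulated signatures per
#' disease, and intersect across diseases to obtain the shared
#' disease-activity set that feeds the molecular score.
#'
#' @param expr genes x samples log2 expression matrix.
#' @param annotations data.frame with columns sample, disease, group
#'   (NHV/R/NR), timepoint (BL/PT), optional subject.
#' @param lib a [signature_library()].
#' @param crit a [selection_criteria()] (default: delta >= 0.2,
#'   BH-adjusted p <= 0.05, upregulated).
#' @param es optional precomputed ES matrix (skips [gsva_scores()]).
#' @param outdir optional directory; when given, per-comparison TSVs, the
#'   selected-set JSON, and a run manifest are written there.
#' @param ... passed to [gsva_scores()].
#' @return list with `es`, `results` (named list of `differential_result`,
#'   one per disease, comparisons named like "CD_BL_vs_NHV"), `selected`
#'   (named list of id vectors), and `shared` (the intersection).
#' @export
run_baseline <- function(expr, annotations, lib,
                         crit = selection_criteria(), es = NULL,
                         outdir = NULL, ...) {
  check_annotations(annotations)
  nhv <- annotations$sample[annotations$group == "NHV"]
  if (!length(nhv)) stop("no NHV samples in annotations")
  diseases <- setdiff(unique(annotations$disease), "none")
  if (!length(diseases)) stop("no disease samples in annotations")
  if (is.null(es)) es <- gsva_scores(expr, lib, ...)

  labels <- stats::setNames(
    ifelse(annotations$group == "NHV", "NHV",
           paste(annotations$disease, annotations$timepoint, sep = "_")),
    annotations$sample)
  results <- list(); selected <- list()
  for (dis in diseases) {
    cmp <- paste0(dis, "_BL_vs_NHV")
    if (!any(labels == paste0(dis, "_BL")))
      stop("no baseline samples for disease ", dis)
    res <- compare_groups(es, labels, paste0(dis, "_BL"), "NHV")
    results[[cmp]] <- res
    selected[[cmp]] <- as.character(select_enriched(res, crit))
  }
  shared <- Reduce(intersect, selected)
  out <- list(es = es, results = results, selected = selected,
              shared = shared, criteria = crit)
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    write_es_matrix(es, file.path(outdir, "es_matrix.tsv"))
    for (cmp in names(results))
      write_differential_result(results[[cmp]],
                                file.path(outdir, paste0(cmp, ".tsv")))
    jsonlite::write_json(c(selected, list(shared = shared)),
                         file.path(outdir, "selected_sets.json"),
                         pretty = TRUE)
    write_manifest(outdir, list(step = "baseline",
                                criteria = unclass(crit),
                                n_samples = ncol(es),
                                n_signatures = nrow(es),
                                comparisons = names(results)))
  }
  out
}

#' Score-and-classify workflow
#'
#' Second arm: compute the molecular disease-activity score over a selected
#' signature set, scan classification thresholds on the baseline
#' responder/non-responder samples, and report confusion metrics at the
#' chosen (or overridden) threshold.
#'
#' @param es signatures x samples ES matrix.
#' @param annotations as in [run_baseline()].
#' @param signature_set selected signature ids (non-empty).
#' @param threshold optional fixed cutoff; by default the threshold is
#'   chosen by `criterion` on the baseline patient samples.
#' @param criterion passed to [choose_threshold()].
#' @param outdir optional output directory (score TSV, metrics JSON,
#'   threshold-scan TSV, manifest).
#' @return list with `imds` (the `imds_result`), `threshold`, `predicted`
#'   (baseline patient classes), `metrics` (sensitivity/specificity/table),
#'   and `scan` (NULL when `threshold` was supplied).
#' @export
run_score <- function(es, annotations, signature_set, threshold = NULL,
                      criterion = "max_specificity_first", outdir = NULL) {
  check_annotations(annotations)
  if (!length(signature_set)) stop("signature set is empty")
  nhv <- annotations$sample[annotations$group == "NHV"]
  if (!length(nhv)) stop("no NHV samples for score centering")
  imds <- compute_imds(es, signature_set, nhv_ids = nhv)

  bl <- annotations[annotations$group %in% c("R", "NR") &
                    annotations$timepoint == "BL", ]
  lab <- stats::setNames(bl$group, bl$sample)
  sc <- imds$scores[bl$sample]
  scan <- NULL
  if (is.null(threshold)) {
    pick <- choose_threshold(sc, lab, criterion = criterion)
    threshold <- pick$threshold
    scan <- pick$scan
  }
  predicted <- classify_imds(sc, threshold = threshold)
  metrics <- confusion_metrics(predicted, lab)
  out <- list(imds = imds, threshold = threshold, predicted = predicted,
              metrics = metrics, scan = scan)
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(
      data.frame(sample = names(imds$scores), score = imds$scores,
                 row.names = NULL),
      file.path(outdir, "imds_scores.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(scan))
      utils::write.table(scan, file.path(outdir, "threshold_scan.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(
      list(threshold = threshold, sensitivity = metrics$sensitivity,
           specificity = metrics$specificity,
           confusion = as.data.frame(metrics$table),
           n_signatures = length(imds$signature_set)),
      file.path(outdir, "imds_metrics.json"), auto_unbox = TRUE,
      pretty = TRUE)
    write_manifest(outdir, list(step = "score", threshold = threshold,
                                criterion = criterion,
                                n_signatures = length(imds$signature_set)))
  }
  out
}

check_annotations <- function(ann) {
  stopifnot(is.data.frame(ann))
  need <- c("sample", "disease", "group", "timepoint")
  miss <- setdiff(need, names(ann))
  if (length(miss))
    stop("annotations missing column(s): ", paste(miss, collapse = ", "))
  bad <- setdiff(unique(ann$group), c("NHV", "R", "NR"))
  if (length(bad)) stop("unknown group label(s): ", paste(bad, collapse = ", "))
  invisible(ann)
}

## Reproducibility manifest: package version, settings, and a config hash,
## so any output directory records how to regenerate itself.
write_manifest <- function(outdir, config) {
  manifest <- list(
    package = "imdscore",
    version = as.character(utils::packageVersion("imdscore")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    timestamp_utc = format(Sys.time(), "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
    config = config,
    config_hash = config_hash(config))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

#' Deterministic hash of a configuration object
#'
#' Serializes the config to canonical JSON and folds the bytes through a
#' small polynomial rolling hash; identical configurations yield identical
#' hashes on every platform, so reruns can be compared by manifest.
#'
#' @param config any jsonlite-serializable object.
#' @return 8-hex-digit character hash.
#' @export
config_hash <- function(config) {
  bytes <- utf8ToInt(as.character(jsonlite::toJSON(config, auto_unbox = TRUE,
                                                   digits = NA)))
  h <- 17
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}
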