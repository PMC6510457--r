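#' Design of a synthetic IBD expression cohort
#'
#' Encodes, as generative assumptions, the structure the analysis expects
#' of a real anti-TNF cohort: two diseases sharing a common set of truly
#' dysregulated signatures; non-responders more dysregulated than
#' responders at baseline; responders reverting to the healthy state after
#' treatment; non-responders molecularly unchanged by treatment. Effects
#' are additive shifts on the log2 scale with independent Gaussian noise —
#' no gene-gene correlation beyond co-shifting within a signature, which is
#' all the downstream pipeline assumes.
#'
#' @param n_genes size of the gene universe (default 2000).
#' @param n_per_group samples per (disease x response x timepoint) cell and
#'   per NHV reference (default 12).
#' @param diseases disease arms (default c("CD", "UC")).
#' @param timepoints sampling timepoints (default c("BL", "PT")); restrict
#'   to "BL" for baseline-only cohorts.
#' @param n_signatures total signatures in the emitted library (default
#'   100); the first `n_true` are truly dysregulated, the rest null.
#' @param n_true truly dysregulated, disease-shared signatures (default 10).
#' @param signature_size genes per signature, drawn without replacement and
#'   disjoint across signatures (default 20; requires
#'   `n_signatures * signature_size <= n_genes`, so null signatures are
#'   exactly null).
#' @param delta_r log2 shift of true-signature genes in responders at
#'   baseline (default 0.8).
#' @param delta_nr shift in non-responders at baseline (default 1.6; must
#'   be >= `delta_r`).
#' @param delta_r_pt responder post-treatment shift (default 0: reversion
#'   to health).
#' @param delta_nr_pt non-responder post-treatment shift (default =
#'   `delta_nr`: no change).
#' @param noise_sd per-gene Gaussian noise sd on the log2 scale
#'   (default 0.5).
#' @param baseline_mean,baseline_mean_sd distribution of per-gene baseline
#'   means, Normal(7, 1.5) by default — a typical log2 microarray
#'   intensity range.
#' @param seed RNG seed; generation is fully reproducible from it.
#' @return object of class `cohort_design` (a validated list).
#' @export
cohort_design <- function(n_genes = 2000L, n_per_group = 12L,
                          diseases = c("CD", "UC"),
                          timepoints = c("BL", "PT"),
                          n_signatures = 100L, n_true = 10L,
                          signature_size = 20L,
                          delta_r = 0.8, delta_nr = 1.6,
                          delta_r_pt = 0, delta_nr_pt = delta_nr,
                          noise_sd = 0.5,
                          baseline_mean = 7, baseline_mean_sd = 1.5,
                          seed = 20190101L) {
  design <- structure(as.list(environment()), class = "cohort_design")
  validate_design(design)
  design
}

validate_design <- function(d) {
  stopifnot(d$n_genes >= 1L, d$n_per_group >= 2L,
            length(d$diseases) >= 1L,
            all(d$timepoints %in% c("BL", "PT")), "BL" %in% d$timepoints,
            d$n_true >= 0L, d$n_true <= d$n_signatures,
            d$signature_size >= 1L,
            d$noise_sd > 0, d$delta_r >= 0, d$delta_nr >= d$delta_r)
  if (d$n_signatures * d$signature_size > d$n_genes)
    stop("signatures do not fit in the gene universe without reuse: need ",
         d$n_signatures * d$signature_size, " genes, have ", d$n_genes)
  invisible(d)
}

#' The canonical synthetic cohort design
#'
#' 2000 genes; 12 samples per cell for NHV and each disease x response x
#' timepoint; 10 true + 90 null signatures of 20 genes; responder baseline
#' shift 0.8 and non-responder 1.6 log2 units; noise sd 0.5; fixed seed.
#' Serves as the package's standard test fixture.
#'
#' @return a [cohort_design()].
#' @export
default_design <- function() cohort_design()

#' Simulate an expression cohort with planted ground truth
#'
#' Generates a log2 expression matrix, sample annotation table, signature
#' library, and the ground truth needed to verify every downstream stage.
#' Gene blocks are disjoint across signatures; true-signature genes are
#' shifted by the group's delta in the appropriate patient samples, in
#' both disease arms (the truly dysregulated biology is disease-shared).
#' Deterministic given `design$seed` (Mersenne-Twister / inversion).
#'
#' @param design a [cohort_design()].
#' @return object of class `synthetic_cohort`: list with `expr` (genes x
#'   samples matrix), `annotations` (data.frame: sample, disease, group,
#'   timepoint, subject), `library` (a [signature_library()]), `truth`
#'   (list: true_ids, null_ids, gene assignment, per-cell deltas), and the
#'   `design`.
#' @examples
#' cohort <- simulate_cohort(cohort_design(n_genes = 200, n_per_group = 3,
#'                                         n_signatures = 10, n_true = 2,
#'                                         diseases = "CD", seed = 7L))
#' dim(cohort$expr)
#' @export
simulate_cohort <- function(design = default_design()) {
  stopifnot(inherits(design, "cohort_design"))
  validate_design(design)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(design$seed, kind = "Mersenne-Twister", normal.kind = "Inversion")

  genes <- sprintf("G%05d", seq_len(design$n_genes))
  mu <- stats::rnorm(design$n_genes, design$baseline_mean,
                     design$baseline_mean_sd)

  ## disjoint gene blocks -> null signatures share no genes with true ones
  perm <- sample.int(design$n_genes)
  ids <- c(sprintf("colon.inflamed%02d.HS.IVV.UP", seq_len(design$n_true)),
           sprintf("colon.null%02d.HS.IVV.UP",
                   seq_len(design$n_signatures - design$n_true)))
  sets <- lapply(seq_len(design$n_signatures), function(s) {
    genes[perm[((s - 1L) * design$signature_size + 1L):
               (s * design$signature_size)]]
  })
  names(sets) <- ids
  lib <- signature_library(sets)
  true_ids <- ids[seq_len(design$n_true)]

  ## sample sheet: one shared NHV arm + disease x response x timepoint cells
  sheet <- data.frame(sample = sprintf("NHV_%02d", seq_len(design$n_per_group)),
                      disease = "none", group = "NHV", timepoint = "BL",
                      subject = sprintf("NHV_%02d", seq_len(design$n_per_group)),
                      stringsAsFactors = FALSE)
  for (dis in design$diseases)
    for (resp in c("R", "NR"))
      for (tp in design$timepoints) {
        subj <- sprintf("%s_%s_%02d", dis, resp, seq_len(design$n_per_group))
        sheet <- rbind(sheet, data.frame(
          sample = paste0(subj, "_", tp), disease = dis, group = resp,
          timepoint = tp, subject = subj, stringsAsFactors = FALSE))
      }

  deltas <- c(R.BL = design$delta_r, R.PT = design$delta_r_pt,
              NR.BL = design$delta_nr, NR.PT = design$delta_nr_pt)
  expr <- matrix(stats::rnorm(design$n_genes * nrow(sheet), mu,
                              design$noise_sd),
                 nrow = design$n_genes,
                 dimnames = list(genes, sheet$sample))
  true_gene_idx <- match(unlist(sets[true_ids], use.names = FALSE), genes)
  for (j in seq_len(nrow(sheet))) {
    if (sheet$group[j] == "NHV") next
    d <- deltas[[paste(sheet$group[j], sheet$timepoint[j], sep = ".")]]
    if (d != 0) expr[true_gene_idx, j] <- expr[true_gene_idx, j] + d
  }

  structure(list(expr = expr, annotations = sheet, library = lib,
                 truth = list(true_ids = true_ids,
                              null_ids = setdiff(ids, true_ids),
                              true_gene_idx = true_gene_idx,
                              deltas = deltas),
                 design = design),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf(paste0("synthetic_cohort: %d genes x %d samples, ",
                     "%d signatures (%d true)\n"),
              nrow(x$expr), ncol(x$expr), length(x$library),
              length(x$truth$true_ids)))
  print(table(x$annotations$disease, paste(x$annotations$group,
                                           x$annotations$timepoint)))
  invisible(x)
}

#' Write a synthetic cohort in the real-data input formats
#'
#' Emits the same TSV/GMT files the real-data path reads (expression TSV
#' with a `gene` column, annotation TSV, GMT library, design JSON), so
#' synthetic and real runs are interchangeable.
#'
#' @param cohort a `synthetic_cohort`.
#' @param dir output directory (created if needed).
#' @return named vector of written paths, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(expression = file.path(dir, "expression.tsv"),
             annotations = file.path(dir, "annotations.tsv"),
             gmt = file.path(dir, "signatures.gmt"),
             design = file.path(dir, "design.json"),
             truth = file.path(dir, "truth.json"))
  utils::write.table(data.frame(gene = rownames(cohort$expr), cohort$expr,
                                check.names = FALSE),
                     paths["expression"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(cohort$annotations, paths["annotations"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_gmt(cohort$library, paths["gmt"])
  jsonlite::write_json(unclass(cohort$design), paths["design"],
                       auto_unbox = TRUE, pretty = TRUE)
  jsonlite::write_json(cohort$truth[c("true_ids", "null_ids", "deltas")],
                       paths["truth"], auto_unbox = FALSE, pretty = TRUE)
  invisible(paths)
}

#' Read an expression matrix and annotation table from TSV
#'
#' @param expression_path TSV with a `gene` first column and one column per
#'   sample (log2 scale).
#' @param annotation_path TSV with at least columns sample, disease, group,
#'   timepoint (optional subject).
#' @return list with `expr` (matrix) and `annotations` (data.frame).
#' @export
read_cohort <- function(expression_path, annotation_path) {
  df <- utils::read.delim(expression_path, check.names = FALSE)
  expr <- as.matrix(df[, -1L, drop = FALSE])
  rownames(expr) <- df[[1L]]
  ann <- utils::read.delim(annotation_path, stringsAsFactors = FALSE)
  need <- c("sample", "disease", "group", "timepoint")
  miss <- setdiff(need, names(ann))
  if (length(miss))
    stop("annotation table missing column(s): ", paste(miss, collapse = ", "))
  if (!all(colnames(expr) %in% ann$sample))
    stop("annotation table missing sample(s) present in expression matrix")
  list(expr = expr, annotations = ann)
}
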