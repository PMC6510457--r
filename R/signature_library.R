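#' Gene-signature libraries
#'
#' A signature library is an ordered, named collection of gene sets, each with
#' optional naming-convention metadata (tissue/cell, condition, organism,
#' experimental setting, direction of regulation). It is the unit of biology
#' the enrichment engine scores: one enrichment score per signature per sample.
#'
#' @param sets named list of character vectors of gene symbols. Names are the
#'   signature ids and must be unique.
#' @param meta optional data.frame of per-signature metadata with an `id`
#'   column matching `names(sets)`. A `direction` column ("UP"/"DOWN") is
#'   required by scoring helpers that care about orientation; if absent it is
#'   parsed from a trailing `.UP`/`.DOWN` (or `_UP`/`_DOWN`) token in the id.
#' @return an object of class `signature_library`.
#' @examples
#' lib <- signature_library(list(
#'   "Tcell.activated.HS.IVS.UP" = c("CD3E", "CD2", "IL2RA", "CTLA4", "ICOS"),
#'   "Neutrophil.activated.HS.IVS.UP" = c("FCGR3B", "CXCR2", "S100A8",
#'                                        "S100A9", "MPO")
#' ))
#' length(lib)
#' @export
signature_library <- function(sets, meta = NULL) {
  stopifnot(is.list(sets))
  if (length(sets)) {
    if (is.null(names(sets)) || anyNA(names(sets)) || any(names(sets) == ""))
      stop("every signature must have a non-empty id")
    dup <- names(sets)[duplicated(names(sets))]
    if (length(dup))
      stop("duplicate signature id(s): ", paste(unique(dup), collapse = ", "))
  }
  sets <- lapply(sets, function(g) {
    g <- unique(toupper(as.character(g)))
    g <- g[!is.na(g) & nzchar(g)]
    if (!length(g)) stop("signature with no genes after normalization")
    g
  })
  if (is.null(meta)) {
    meta <- data.frame(id = names(sets) %||% character(0),
                       description = rep("", length(sets)),
                       stringsAsFactors = FALSE)
  } else {
    stopifnot(is.data.frame(meta), "id" %in% names(meta))
    meta <- meta[match(names(sets), meta$id), , drop = FALSE]
    rownames(meta) <- NULL
  }
  if (!"direction" %in% names(meta))
    meta$direction <- parse_direction(meta$id)
  meta$n_genes <- lengths(sets)[match(meta$id, names(sets))]
  structure(list(sets = sets, meta = meta), class = "signature_library")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## Trailing UP/DOWN token of a signature id (the library naming convention
## puts direction last); NA when the id carries none.
parse_direction <- function(ids) {
  out <- rep(NA_character_, length(ids))
  out[grepl("[._]UP$", ids, ignore.case = TRUE)] <- "UP"
  out[grepl("[._](DOWN|DN)$", ids, ignore.case = TRUE)] <- "DOWN"
  out
}

#' @export
length.signature_library <- function(x) length(x$sets)

#' @export
names.signature_library <- function(x) names(x$sets)

#' @export
`[.signature_library` <- function(x, i) {
  ids <- names(x$sets)[if (is.character(i)) match(i, names(x$sets)) else i]
  if (anyNA(ids)) stop("unknown signature id in subset")
  signature_library(x$sets[ids], x$meta[match(ids, x$meta$id), , drop = FALSE])
}

#' @export
print.signature_library <- function(x, ...) {
  cat(sprintf("signature_library with %d signature(s), %d unique gene(s)\n",
              length(x), length(unique(unlist(x$sets, use.names = FALSE)))))
  if (length(x)) {
    show <- utils::head(x$meta[, c("id", "n_genes", "direction")], 6L)
    print(show, row.names = FALSE)
    if (length(x) > 6L) cat(sprintf("... and %d more\n", length(x) - 6L))
  }
  invisible(x)
}

#' Read a gene-set library from a GMT file
#'
#' Standard GMT dialect: one signature per tab-separated line, fields are
#' id, description, then one gene symbol per field. Symbols are uppercased
#' and deduplicated; signature order in the file is preserved.
#'
#' @param path path to a GMT file.
#' @param alias_map optional data.frame with columns `old` and `new` used to
#'   update outdated gene symbols at load (a reproducible, offline stand-in
#'   for symbol-checking services). Applied before deduplication.
#' @return a [signature_library()].
#' @export
read_gmt <- function(path, alias_map = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines))
    return(signature_library(stats::setNames(list(), character(0))))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L))
    stop("GMT line ", which(nf < 3L)[1L],
         " has fewer than 3 tab-separated fields")
  ids <- vapply(fields, `[[`, "", 1L)
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stop("duplicate signature id(s) in GMT: ",
         paste(unique(dup), collapse = ", "))
  desc <- vapply(fields, `[[`, "", 2L)
  sets <- lapply(fields, function(f) toupper(f[-(1:2)]))
  if (!is.null(alias_map)) {
    stopifnot(all(c("old", "new") %in% names(alias_map)))
    old <- toupper(alias_map$old); new <- toupper(alias_map$new)
    sets <- lapply(sets, function(g) {
      hit <- match(g, old)
      g[!is.na(hit)] <- new[hit[!is.na(hit)]]
      g
    })
  }
  signature_library(stats::setNames(sets, ids),
                    data.frame(id = ids, description = desc,
                               stringsAsFactors = FALSE))
}

#' Write a signature library to a GMT file
#'
#' @param lib a [signature_library()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(lib, path) {
  stopifnot(inherits(lib, "signature_library"))
  desc <- lib$meta$description %||% rep("", length(lib))
  desc[is.na(desc)] <- ""
  lines <- vapply(seq_along(lib$sets), function(i) {
    paste(c(names(lib$sets)[i], desc[i], lib$sets[[i]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Drop signatures below a minimum size
#'
#' Small gene sets yield unstable enrichment scores; the library-construction
#' rule discards sets of fewer than 5 genes. Idempotent; order preserved.
#'
#' @param lib a [signature_library()].
#' @param min_genes minimum retained size (default 5).
#' @return the filtered library. Removed ids are reported via [message()].
#' @export
filter_min_genes <- function(lib, min_genes = 5L) {
  stopifnot(inherits(lib, "signature_library"), min_genes >= 1L)
  keep <- lengths(lib$sets) >= min_genes
  if (any(!keep))
    message("filter_min_genes: removed ",
            paste(names(lib$sets)[!keep], collapse = ", "))
  if (all(keep)) return(lib)
  lib[which(keep)]
}

#' Split mixed-direction signatures into UP and DOWN halves
#'
#' Signatures assembled from differential-expression results contain genes
#' regulated in both directions; scoring requires single-direction sets.
#' Each mixed signature is split into an `<id>.UP` and `<id>.DOWN` signature
#' and the minimum-size filter is re-applied to the halves.
#'
#' @param lib a [signature_library()].
#' @param directions named list keyed by signature id; each element a
#'   character vector ("up"/"down", case-insensitive) parallel to that
#'   signature's genes. Signatures whose id already carries an UP/DOWN
#'   suffix pass through unchanged and need no entry.
#' @param min_genes size filter applied after splitting (default 5).
#' @return a [signature_library()] in which every signature is
#'   single-direction.
#' @export
split_directions <- function(lib, directions = list(), min_genes = 5L) {
  stopifnot(inherits(lib, "signature_library"))
  out <- list(); rows <- list()
  for (i in seq_along(lib$sets)) {
    id <- names(lib$sets)[i]
    if (!is.na(lib$meta$direction[i])) {
      out[[id]] <- lib$sets[[i]]
      rows[[id]] <- lib$meta[i, c("id", "description", "direction")]
      next
    }
    dir <- directions[[id]]
    if (is.null(dir))
      stop("signature '", id, "' has no direction information")
    dir <- toupper(dir)
    if (length(dir) != length(lib$sets[[i]]) ||
        !all(dir %in% c("UP", "DOWN")))
      stop("invalid per-gene directions for signature '", id, "'")
    for (d in c("UP", "DOWN")) {
      g <- lib$sets[[i]][dir == d]
      if (length(g) >= min_genes) {
        nid <- paste0(id, ".", d)
        out[[nid]] <- g
        rows[[nid]] <- data.frame(id = nid,
                                  description = lib$meta$description[i],
                                  direction = d, stringsAsFactors = FALSE)
      } else if (length(g)) {
        message("split_directions: dropped ", id, ".", d,
                " (", length(g), " gene(s) < ", min_genes, ")")
      }
    }
  }
  meta <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  signature_library(out, meta)
}

#' Derive an UP/DOWN signature pair from a two-group comparison
#'
#' Per-gene pooled-variance two-sample t-test on log2 expression with
#' Benjamini-Hochberg FDR across all genes; genes pass with
#' |log2 fold change| >= log2(`fc_threshold`) and FDR < `fdr_threshold`.
#' The minimum-size filter is applied to each half.
#'
#' @param expr numeric genes x samples matrix of log2 expression with
#'   rownames (gene symbols) and colnames (sample ids).
#' @param groups two-level factor (or character) over columns of `expr`;
#'   fold change is level 2 minus level 1 (case vs control when control is
#'   the first level).
#' @param fc_threshold natural-scale fold-change threshold (default 2).
#' @param fdr_threshold BH-FDR cutoff (default 0.05).
#' @param min_genes minimum signature size (default 5).
#' @param id id stem for the derived signatures (suffixes `.UP`, `.DOWN`).
#' @return list with `up` and `down` gene-symbol vectors (empty when the
#'   half fails `min_genes`), the full per-gene `stats` table, and `library`,
#'   a [signature_library()] holding the surviving halves.
#' @export
derive_signature_from_de <- function(expr, groups, fc_threshold = 2,
                                     fdr_threshold = 0.05, min_genes = 5L,
                                     id = "derived") {
  stopifnot(is.matrix(expr), !is.null(rownames(expr)))
  groups <- as.factor(groups)
  if (nlevels(droplevels(groups)) != 2L)
    stop("`groups` must have exactly two levels")
  groups <- droplevels(groups)
  if (any(table(groups) < 2L))
    stop("need at least 2 samples per group for a variance estimate")
  ctl <- expr[, groups == levels(groups)[1L], drop = FALSE]
  cas <- expr[, groups == levels(groups)[2L], drop = FALSE]
  tt <- row_t_pooled(cas, ctl)
  lfc <- tt$delta
  fdr <- stats::p.adjust(tt$p, method = "BH")
  stats_tab <- data.frame(gene = rownames(expr), log2fc = lfc, t = tt$t,
                          p = tt$p, fdr = fdr, stringsAsFactors = FALSE,
                          row.names = NULL)
  lt <- log2(fc_threshold)
  up <- rownames(expr)[lfc >= lt & fdr < fdr_threshold]
  down <- rownames(expr)[lfc <= -lt & fdr < fdr_threshold]
  if (length(up) < min_genes) up <- character(0)
  if (length(down) < min_genes) down <- character(0)
  sets <- list()
  if (length(up)) sets[[paste0(id, ".UP")]] <- up
  if (length(down)) sets[[paste0(id, ".DOWN")]] <- down
  list(up = up, down = down, stats = stats_tab,
       library = signature_library(sets))
}

## Row-wise pooled-variance two-sample t; returns delta (mean A - mean B),
## t, df, p (two-sided). Used by DE derivation and ES group comparison.
row_t_pooled <- function(a, b) {
  na <- ncol(a); nb <- ncol(b)
  ma <- rowMeans(a); mb <- rowMeans(b)
  va <- rowSums((a - ma)^2) / (na - 1L)
  vb <- rowSums((b - mb)^2) / (nb - 1L)
  sp2 <- ((na - 1L) * va + (nb - 1L) * vb) / (na + nb - 2L)
  se <- sqrt(sp2 * (1 / na + 1 / nb))
  t <- (ma - mb) / se
  t[se == 0 & ma == mb] <- 0  # identical constant rows: no evidence
  df <- na + nb - 2L
  p <- 2 * stats::pt(abs(t), df, lower.tail = FALSE)
  p[is.nan(p)] <- NA_real_
  list(delta = ma - mb, t = t, df = df, p = p)
}

#' Pairwise gene-overlap audit of a signature library
#'
#' Quantifies redundancy between signatures: for every unordered pair the
#' overlap fraction is |A intersect B| / min(|A|, |B|) (flags containment,
#' the redundancy that would bias an additive score) or the Jaccard index.
#' Pairs at or above `threshold` are listed.
#'
#' @param lib a [signature_library()] with >= 2 signatures.
#' @param threshold listing cutoff on the overlap fraction (default 0.20).
#' @param method `"min"` (default) or `"jaccard"`.
#' @return list with `n_pairs` (= m(m-1)/2), `n_over`, and `pairs_over`,
#'   a data.frame of (id_a, id_b, overlap, fraction) sorted by fraction.
#' @export
overlap_summary <- function(lib, threshold = 0.20,
                            method = c("min", "jaccard")) {
  stopifnot(inherits(lib, "signature_library"), length(lib) >= 2L)
  method <- match.arg(method)
  m <- length(lib)
  ids <- names(lib$sets)
  pairs <- utils::combn(m, 2L)
  frac <- numeric(ncol(pairs)); ov <- integer(ncol(pairs))
  for (k in seq_len(ncol(pairs))) {
    a <- lib$sets[[pairs[1L, k]]]; b <- lib$sets[[pairs[2L, k]]]
    ov[k] <- length(intersect(a, b))
    denom <- if (method == "min") min(length(a), length(b))
             else length(union(a, b))
    frac[k] <- ov[k] / denom
  }
  sel <- which(frac >= threshold)
  sel <- sel[order(-frac[sel])]
  list(n_pairs = ncol(pairs), n_over = length(sel),
       pairs_over = data.frame(id_a = ids[pairs[1L, sel]],
                               id_b = ids[pairs[2L, sel]],
                               overlap = ov[sel], fraction = frac[sel],
                               stringsAsFactors = FALSE, row.names = NULL))
}

#' Audit a signature library
#'
#' One-stop summary used to sanity-check a library against its published
#' description: signature count, pairwise-comparison count, unique-gene
#' total, size distribution, and the high-overlap pair list.
#'
#' @inheritParams overlap_summary
#' @return list with `n_signatures`, `n_pairs`, `n_unique_genes`,
#'   `size_range`, and the [overlap_summary()] result.
#' @export
audit_library <- function(lib, threshold = 0.20, method = c("min", "jaccard")) {
  ov <- if (length(lib) >= 2L) overlap_summary(lib, threshold, method)
        else list(n_pairs = 0L, n_over = 0L, pairs_over = NULL)
  list(n_signatures = length(lib),
       n_pairs = ov$n_pairs,
       n_unique_genes = length(unique(unlist(lib$sets, use.names = FALSE))),
       size_range = if (length(lib)) range(lengths(lib$sets)) else c(NA, NA),
       overlap = ov)
}
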