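test_that("read_gmt parses, normalizes, and round-trips", {
  # 103-line file -> 103 signatures, order preserved
  sets <- lapply(1:103, function(i) sprintf("GENE%d_%d", i, 1:10))
  names(sets) <- sprintf("sig%03d.UP", 1:103)
  path <- write_temp_gmt(sets)
  lib <- read_gmt(path)
  expect_s3_class(lib, "signature_library")
  expect_length(lib, 103)
  expect_identical(names(lib), names(sets))

  # case folding and deduplication
  f <- tempfile(); writeLines("sigA\tdesc\tTNF\ttnf", f)
  expect_identical(read_gmt(f)$sets$sigA, "TNF")

  # empty file -> empty library
  f2 <- tempfile(); writeLines(character(0), f2)
  expect_length(read_gmt(f2), 0)

  # round trip
  out <- tempfile(fileext = ".gmt")
  write_gmt(lib, out)
  lib2 <- read_gmt(out)
  expect_identical(lib2$sets, lib$sets)
  expect_identical(lib2$meta$direction, lib$meta$direction)
})

test_that("read_gmt rejects malformed input with informative errors", {
  f <- tempfile(); writeLines(c("a\td\tG1", "a\td\tG2"), f)
  expect_error(read_gmt(f), "duplicate.*a")
  f2 <- tempfile(); writeLines(c("ok\td\tG1", "short\tonlydesc"), f2)
  expect_error(read_gmt(f2), "line 2")
  expect_error(read_gmt(tempfile()), "not found")
})

test_that("read_gmt applies a user alias map at load", {
  f <- tempfile(); writeLines("s\td\tOLDSYM\tKEEP", f)
  lib <- read_gmt(f, alias_map = data.frame(old = "OLDSYM", new = "NEWSYM"))
  expect_setequal(lib$sets$s, c("NEWSYM", "KEEP"))
})

test_that("filter_min_genes enforces the size rule and is idempotent", {
  lib <- signature_library(list(four.UP = sprintf("A%d", 1:4),
                                five.UP = sprintf("B%d", 1:5),
                                six.UP = sprintf("C%d", 1:6)))
  expect_message(f1 <- filter_min_genes(lib), "four.UP")
  expect_identical(names(f1), c("five.UP", "six.UP"))  # 5 is the boundary
  expect_identical(filter_min_genes(f1)$sets, f1$sets) # idempotent
  # all-large library passes unchanged
  expect_identical(filter_min_genes(lib, min_genes = 1)$sets, lib$sets)
})

test_that("split_directions yields single-direction sets and re-filters", {
  mixed <- signature_library(list(sigM = sprintf("G%d", 1:13)))
  dirs <- list(sigM = c(rep("up", 6), rep("down", 7)))
  out <- split_directions(mixed, dirs)
  expect_identical(names(out), c("sigM.UP", "sigM.DOWN"))
  expect_identical(lengths(out$sets), c(sigM.UP = 6L, sigM.DOWN = 7L))
  expect_identical(out$meta$direction, c("UP", "DOWN"))

  # undersized half discarded after the split
  dirs2 <- list(sigM = c(rep("up", 6), rep("down", 4), rep("up", 3)))
  expect_message(out2 <- split_directions(mixed, dirs2), "sigM.DOWN")
  expect_identical(names(out2), "sigM.UP")

  # already single-direction -> identity
  single <- signature_library(list(a.UP = sprintf("G%d", 1:8)))
  expect_identical(split_directions(single)$sets, single$sets)

  # no direction information -> error
  expect_error(split_directions(mixed), "direction")
})

test_that("derive_signature_from_de applies both thresholds", {
  set.seed(42)
  p <- 200; n <- 5
  expr <- matrix(rnorm(p * 2 * n, 7, 0.1), p, 2 * n,
                 dimnames = list(sprintf("G%03d", 1:p),
                                 sprintf("S%02d", 1:(2 * n))))
  groups <- rep(c("ctl", "case"), each = n)
  groups <- factor(groups, levels = c("ctl", "case"))
  planted <- sprintf("G%03d", 1:10)
  expr[planted, groups == "case"] <- expr[planted, groups == "case"] + 2

  res <- derive_signature_from_de(expr, groups, id = "toy")
  expect_setequal(res$up, planted)
  expect_length(res$down, 0)
  expect_identical(names(res$library), "toy.UP")

  # oracle: per-gene closed-form pooled t matches stats::t.test
  g <- planted[1]
  tt <- t.test(expr[g, groups == "case"], expr[g, groups == "ctl"],
               var.equal = TRUE)
  row <- res$stats[res$stats$gene == g, ]
  expect_equal(row$t, unname(tt$statistic), tolerance = 1e-12)
  expect_equal(row$p, tt$p.value, tolerance = 1e-12)

  # identical group means -> nothing selected
  expr0 <- matrix(rnorm(p * 2 * n, 7, 0.1), p, 2 * n,
                  dimnames = dimnames(expr))
  res0 <- derive_signature_from_de(expr0, groups)
  expect_length(res0$up, 0); expect_length(res0$down, 0)

  # sub-threshold fold change excluded despite tiny p
  expr19 <- expr0
  expr19[planted, groups == "case"] <- expr19[planted, groups == "case"] +
    log2(1.9)
  res19 <- derive_signature_from_de(expr19, groups)
  expect_length(res19$up, 0)
  expect_true(all(res19$stats[res19$stats$gene %in% planted, "fdr"] < 0.05))

  # one sample per group -> no variance estimate
  expect_error(derive_signature_from_de(expr[, c(1, 6)],
                                        factor(c("ctl", "case"))),
               "at least 2")
})

test_that("overlap_summary counts pairs and fractions correctly", {
  # worked example: |A∩B| / min(|A|,|B|) = 2/5
  lib <- signature_library(list(A.UP = c("a", "b", "c", "d", "e"),
                                B.UP = c("a", "b", "v", "w", "x", "y", "z")))
  ov <- overlap_summary(lib, threshold = 0.2)
  expect_identical(ov$n_pairs, 1L)
  expect_equal(ov$pairs_over$fraction, 0.4)

  # identical signatures: fraction 1, listed
  lib2 <- signature_library(list(A.UP = letters[1:6], B.UP = letters[1:6]))
  expect_equal(overlap_summary(lib2)$pairs_over$fraction, 1)

  # jaccard denominator option
  expect_equal(overlap_summary(lib, method = "jaccard",
                               threshold = 0)$pairs_over$fraction, 2 / 10)

  # pair count is m(m-1)/2 and fractions stay in [0,1] for random libraries
  for (m in c(2, 5, 17)) {
    rl <- random_library(sprintf("G%03d", 1:60), m, 8, seed = m)
    o <- overlap_summary(rl, threshold = 0)
    expect_identical(o$n_pairs, as.integer(m * (m - 1) / 2))
    expect_true(all(o$pairs_over$fraction >= 0 & o$pairs_over$fraction <= 1))
  }
  # symmetry: reversing library order gives the same fractions per pair
  rl <- random_library(sprintf("G%03d", 1:40), 6, 10, seed = 99)
  rev_lib <- rl[rev(seq_len(6))]
  key <- function(o) {
    k <- apply(o$pairs_over[, c("id_a", "id_b")], 1, function(x)
      paste(sort(x), collapse = "|"))
    stats::setNames(o$pairs_over$fraction, k)[order(k)]
  }
  expect_equal(key(overlap_summary(rl, 0)), key(overlap_summary(rev_lib, 0)))
})

test_that("audit_library summarizes counts and unique genes", {
  lib <- signature_library(list(a.UP = letters[1:5], b.UP = letters[4:9],
                                c.UP = letters[8:13]))
  a <- audit_library(lib)
  expect_identical(a$n_signatures, 3L)
  expect_identical(a$n_pairs, 3L)
  expect_identical(a$n_unique_genes, 13L)
})
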