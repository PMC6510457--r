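# Shared fixtures, computed once per test run. The default cohort takes a
# few seconds to score, so it is memoized for all tests that need it.

.fixtures <- new.env(parent = emptyenv())

default_fixture <- function() {
  if (is.null(.fixtures$default)) {
    cohort <- simulate_cohort(default_design())
    es <- gsva_scores(cohort$expr, cohort$library)
    baseline <- run_baseline(cohort$expr, cohort$annotations,
                             cohort$library, es = es)
    .fixtures$default <- list(cohort = cohort, es = es, baseline = baseline)
  }
  .fixtures$default
}

# Small random expression matrix with unique gene/sample names.
random_expr <- function(p, n, seed) {
  set.seed(seed)
  matrix(rnorm(p * n, 7, 1), p, n,
         dimnames = list(sprintf("G%03d", seq_len(p)),
                         sprintf("S%02d", seq_len(n))))
}

# Library of m single-direction signatures over the given gene universe.
random_library <- function(genes, m, size, seed) {
  set.seed(seed)
  sets <- lapply(seq_len(m), function(i) sample(genes, size))
  names(sets) <- sprintf("sig%03d.UP", seq_len(m))
  signature_library(sets)
}

write_temp_gmt <- function(sets, file = tempfile(fileext = ".gmt")) {
  writeLines(vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], "desc", sets[[i]]), collapse = "\t")
  }, ""), file)
  file
}
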