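# Independent brute-force reimplementation of the enrichment engine,
# written straight from the formulas with explicit loops. Deliberately
# shares no code with the package internals; used as the oracle for
# equivalence tests on small instances.

oracle_gsva <- function(expr, sets, tau = 1) {
  p <- nrow(expr); n <- ncol(expr)
  z <- matrix(NA_real_, p, n)
  for (i in seq_len(p)) {
    s <- stats::sd(expr[i, ])
    for (j in seq_len(n)) {
      z[i, j] <- if (s == 0) 0.5 else {
        acc <- 0
        for (k in seq_len(n))
          acc <- acc + stats::pnorm((expr[i, j] - expr[i, k]) / (s / 4))
        acc / n
      }
    }
  }
  es <- matrix(NA_real_, length(sets), n,
               dimnames = list(names(sets), colnames(expr)))
  for (j in seq_len(n)) {
    ord <- order(-z[, j], seq_len(p))
    rnk <- integer(p); rnk[ord] <- seq_len(p)
    r <- abs(p / 2 - rnk)
    for (s in seq_along(sets)) {
      idx <- which(rownames(expr) %in% toupper(sets[[s]]))
      k <- length(idx)
      den_in <- sum(r[idx]^tau)
      vin <- 0; vout <- 0; vmax <- 0; vmin <- 0
      for (g in seq_len(p)) {
        gene <- ord[g]
        if (gene %in% idx) vin <- vin + r[gene]^tau / den_in
        else vout <- vout + 1 / (p - k)
        d <- vin - vout
        if (d > vmax) vmax <- d
        if (d < vmin) vmin <- d
      }
      es[s, j] <- vmax + vmin
    }
  }
  es
}

# Exhaustive threshold scan: every value strictly between two consecutive
# observed scores behaves identically, so trying all midpoints is complete.
oracle_best_threshold <- function(scores, labels) {
  u <- sort(unique(scores))
  cand <- c(u[1] - 1, (u[-1] + u[-length(u)]) / 2, u[length(u)] + 1)
  best <- NULL
  for (th in cand) {
    pred <- ifelse(scores < th, "responder-like", "nonresponder-like")
    sens <- mean(pred[labels == "R"] == "responder-like")
    spec <- mean(pred[labels == "NR"] == "nonresponder-like")
    if (spec == 1 && (is.null(best) || sens > best$sens))
      best <- list(th = th, sens = sens, spec = spec)
  }
  best
}
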