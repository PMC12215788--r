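# Independent oracles used across tests. These deliberately avoid the
# package's own code paths (and stats::cor / stats::p.adjust) so that
# agreement is informative.

oracle_pearson <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n
  my <- sum(y) / n
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

oracle_fisher_z <- function(r) 0.5 * log((1 + r) / (1 - r))

# Step-down Holm adjustment, written out longhand.
oracle_holm <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  running_max <- 0
  for (i in seq_len(m)) {
    val <- min(1, (m - i + 1) * p[o[i]])
    running_max <- max(running_max, val)
    adj[o[i]] <- running_max
  }
  adj
}

# Step-up Benjamini-Hochberg adjustment, written out longhand.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p, decreasing = TRUE)
  adj <- numeric(m)
  running_min <- Inf
  for (i in seq_len(m)) {
    rank <- m - i + 1
    val <- min(1, m * p[o[i]] / rank)
    running_min <- min(running_min, val)
    adj[o[i]] <- running_min
  }
  adj
}

# Brute-force dyadic ISC: explicit double loop over subject pairs.
oracle_dyadic_isc <- function(panel) {
  out <- list()
  for (v in unique(panel$video)) {
    pv <- panel[panel$video == v, ]
    subjects <- sort(unique(pv$subject))
    if (length(subjects) < 2) next
    for (i in seq_along(subjects)) {
      for (j in seq_along(subjects)) {
        if (i >= j) next
        for (rg in sort(unique(pv$region))) {
          xi <- pv$value[pv$subject == subjects[i] & pv$region == rg]
          xi <- xi[order(pv$timepoint[pv$subject == subjects[i] &
                                        pv$region == rg])]
          xj <- pv$value[pv$subject == subjects[j] & pv$region == rg]
          xj <- xj[order(pv$timepoint[pv$subject == subjects[j] &
                                        pv$region == rg])]
          out[[length(out) + 1]] <- data.frame(
            subject_a = subjects[i], subject_b = subjects[j], video = v,
            region = rg, r = oracle_pearson(xi, xj),
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  do.call(rbind, out)
}
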