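# Independent oracles and fixture generators used across the suite.

# textbook Pearson correlation, written out long-hand
brute_pearson <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n
  my <- sum(y) / n
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# brute-force UPGMA: clusters kept as member index sets; at every step all
# inter-cluster distances are recomputed from the ORIGINAL matrix as the
# plain mean over member pairs, then the global minimum is merged.
upgma_oracle <- function(d) {
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  heights <- numeric(0)
  compositions <- list()
  while (length(clusters) > 1L) {
    k <- length(clusters)
    best <- Inf; bi <- bj <- 0L
    for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
      dij <- mean(d[clusters[[i]], clusters[[j]]])
      if (dij < best) { best <- dij; bi <- i; bj <- j }
    }
    merged <- sort(c(clusters[[bi]], clusters[[bj]]))
    heights <- c(heights, best)
    compositions[[length(compositions) + 1L]] <- merged
    clusters <- c(clusters[-c(bi, bj)], list(merged))
  }
  list(heights = heights, compositions = compositions)
}

# member sets (sorted leaf indices) per merge of a pm_dendrogram
dend_compositions <- function(dend) {
  members <- vector("list", nrow(dend$merge))
  for (m in seq_len(nrow(dend$merge))) {
    kids <- lapply(dend$merge[m, ], function(node)
      if (node < 0L) -node else members[[node]])
    members[[m]] <- sort(c(kids[[1L]], kids[[2L]]))
  }
  members
}

# random distance matrix from Euclidean distances of random points
# (symmetric, zero diagonal, ties have probability zero)
rand_dist <- function(n) {
  pts <- matrix(rnorm(n * 3L), n)
  d <- as.matrix(dist(pts))
  dimnames(d) <- list(paste0("s", seq_len(n)), paste0("s", seq_len(n)))
  d
}

# random kinetic curve on a 0.25 h grid: noisy saturating ramp
rand_curve <- function(n = 385L, id = "X") {
  t <- seq(0, by = 0.25, length.out = n)
  base <- 60 * (1 - exp(-t / runif(1, 5, 30)))
  pm_series(id, "cond", 1L, t, pmax(base + rnorm(n, 0, 3), 0))
}

# noiseless logistic mean curve, restated from first principles
logistic_mu <- function(t, A, rate, t_m, b = 0, theta = 1, delta = 0) {
  b + theta * A / (1 + exp(-rate * (t - t_m - delta)))
}

# minimal TreeView-compatible GTR reader: returns per-merge member sets
# (leaf names) and similarities
parse_gtr <- function(path, leaf_names) {
  lines <- readLines(path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  members <- list()
  sims <- numeric(0)
  resolve <- function(tok) {
    if (grepl("^GENE[0-9]+X$", tok)) {
      idx <- as.integer(sub("X$", "", sub("^GENE", "", tok))) + 1L
      leaf_names[idx]
    } else {
      idx <- as.integer(sub("X$", "", sub("^NODE", "", tok)))
      members[[idx]]
    }
  }
  for (p in parts) {
    stopifnot(length(p) == 4L, grepl("^NODE[0-9]+X$", p[1L]))
    idx <- as.integer(sub("X$", "", sub("^NODE", "", p[1L])))
    members[[idx]] <- sort(c(resolve(p[2L]), resolve(p[3L])))
    sims[idx] <- as.numeric(p[4L])
  }
  list(members = members, similarities = sims)
}

# write a small delimited file and return its path
write_fixture <- function(lines, ext = ".tsv") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}
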