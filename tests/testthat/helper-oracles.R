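# Independent oracles used across the suite. These deliberately use naive
# algorithms (pair counting, permutation enumeration, transitive closure)
# so they stay independent of the package's implementations.

# AUROC by exhaustive pair counting, ties = 1/2
oracle_auc <- function(values, labels, positive) {
  pos <- values[labels == positive]
  neg <- values[labels != positive]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  tot / (length(pos) * length(neg))
}

# BH by the textbook recipe: sort ascending, scale by m/rank, cumulative
# min from the bottom via an explicit loop, map back.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  sorted <- m / seq_len(m) * p[o]
  if (m >= 2)
    for (i in (m - 1):1) sorted[i] <- min(sorted[i], sorted[i + 1])
  adj <- numeric(m)
  adj[o] <- pmin(1, sorted)
  adj
}

# DBSCAN by transitive closure of the core-core adjacency matrix
oracle_dbscan <- function(coords, eps, min_pts) {
  d <- as.matrix(dist(coords))
  nb <- d <= eps
  core <- rowSums(nb) >= min_pts
  n <- nrow(d)
  reach <- nb & outer(core, core, "&")
  diag(reach) <- core
  for (k in seq_len(n)) reach <- reach | (reach %*% reach) > 0
  labels <- integer(n)
  cl <- 0L
  for (i in seq_len(n)) {
    if (!core[i] || labels[i] != 0) next
    cl <- cl + 1L
    labels[reach[i, ] & core] <- cl
  }
  for (i in which(!core)) {
    cand <- which(nb[i, ] & core)
    if (length(cand)) labels[i] <- labels[cand[which.min(d[i, cand])]]
  }
  labels
}

# best label alignment by enumerating all permutations (small k only)
oracle_align_overlap <- function(tab) {
  k <- max(dim(tab))
  pad <- matrix(0, k, k)
  pad[seq_len(nrow(tab)), seq_len(ncol(tab))] <- tab
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (rest in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
    out
  }
  best <- -Inf
  for (p in perms(seq_len(k)))
    best <- max(best, sum(pad[cbind(seq_len(k), p)]))
  best
}

# running-sum enrichment score by an explicit per-gene loop
oracle_es <- function(stats, set, weight = 1) {
  o <- order(stats, decreasing = TRUE)
  s <- stats[o]
  hit <- names(s) %in% set
  tot <- sum(abs(s[hit])^weight)
  run <- 0; best <- 0
  miss <- 1 / (length(s) - sum(hit))
  for (i in seq_along(s)) {
    run <- run + if (hit[i]) abs(s[[i]])^weight / tot else -miss
    if (abs(run) > abs(best)) best <- run
  }
  unname(best)
}

# two equally sized gaussian blobs in 2-D, far apart
make_blobs <- function(n_per = 10, sep = 20, sd = 0.3, seed = 1) {
  set.seed(seed)
  coords <- rbind(
    cbind(rnorm(n_per, 0, sd), rnorm(n_per, 0, sd)),
    cbind(rnorm(n_per, sep, sd), rnorm(n_per, 0, sd)))
  list(coords = coords, labels = rep(1:2, each = n_per))
}

# small two-class expression matrix with clean separation
make_two_class_expr <- function(n_genes = 120, n_per = 15, delta = 4,
                                seed = 1) {
  set.seed(seed)
  n <- 2 * n_per
  x <- matrix(rnorm(n_genes * n, 8, 1), n_genes, n,
              dimnames = list(sprintf("g%03d", 1:n_genes),
                              sprintf("s%02d", 1:n)))
  de <- seq_len(n_genes %/% 3)
  x[de, seq_len(n_per)] <- x[de, seq_len(n_per)] + delta
  list(expr = x, labels = rep(c("chRCC", "RO"), each = n_per), de = de)
}
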