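#' UMAP parameter set for the ensemble
#'
#' Defaults are the grid-search winners used throughout: 20 neighbors,
#' min_dist 0.01, 1000 random genes per iteration, Manhattan metric.
#'
#' @param n_neighbors local neighborhood size (>= 2).
#' @param min_dist minimum embedding distance (>= 0).
#' @param gene_count number of genes sampled per iteration.
#' @param metric one of `"manhattan"`, `"euclidean"`, `"cosine"`.
#' @return a named list of class `umap_params`.
#' @export
umap_params <- function(n_neighbors = 20, min_dist = 0.01, gene_count = 1000,
                        metric = c("manhattan", "euclidean", "cosine")) {
  metric <- match.arg(metric)
  stopifnot(n_neighbors >= 2, min_dist >= 0, gene_count >= 1)
  structure(list(n_neighbors = n_neighbors, min_dist = min_dist,
                 gene_count = gene_count, metric = metric),
            class = "umap_params")
}

#' Embed samples in two dimensions
#'
#' Projects the samples of a (gene-subset) expression matrix into a 2-D
#' embedding that preserves local neighborhood structure, using a UMAP
#' implementation behind the contract. Deterministic given `seed`
#' (single-threaded optimization).
#'
#' @param expr matrix, genes x samples; samples become the embedded points.
#' @param params a [umap_params()] list.
#' @param seed integer seed.
#' @return numeric matrix, samples x 2, rownames = sample ids.
#' @export
embed_2d <- function(expr, params = umap_params(), seed = 1) {
  n <- ncol(expr)
  if (n < params$n_neighbors + 1)
    stop("need at least n_neighbors + 1 = ", params$n_neighbors + 1,
         " samples, got ", n)
  set.seed(seed)
  co <- uwot::umap(t(expr), n_neighbors = params$n_neighbors,
                   min_dist = params$min_dist, metric = params$metric,
                   n_components = 2, n_threads = 1, n_sgd_threads = 0,
                   verbose = FALSE)
  rownames(co) <- colnames(expr)
  colnames(co) <- c("UMAP1", "UMAP2")
  co
}

#' Cluster separation score
#'
#' Mean pairwise distance between cluster centroids divided by the mean
#' within-cluster distance to centroid (floored at 1e-8); larger is better.
#' Noise points (label 0) are ignored. Invariant to rigid motions of the
#' coordinates.
#'
#' @param coords points x dims matrix.
#' @param labels integer labels, 0 = noise.
#' @return positive scalar.
#' @export
separation_score <- function(coords, labels) {
  keep <- labels != 0
  coords <- as.matrix(coords)[keep, , drop = FALSE]
  labels <- labels[keep]
  ids <- sort(unique(labels))
  if (length(ids) < 2)
    stop("separation score undefined for fewer than 2 clusters",
         call. = FALSE)
  cent <- t(vapply(ids, function(l) colMeans(coords[labels == l, , drop = FALSE]),
                   numeric(ncol(coords))))
  inter <- mean(stats::dist(cent))
  intra <- mean(sqrt(rowSums((coords - cent[match(labels, ids), , drop = FALSE])^2)))
  inter / max(intra, 1e-8)
}

#' Grid search over embedding hyperparameters
#'
#' Evaluates every combination of the supplied grids once (one embedding
#' per combination, common derived seed), clusters each embedding, and
#' ranks combinations by [separation_score()]. Combinations yielding fewer
#' than two clusters score `NA` and sort last.
#'
#' @param expr gene-level matrix (genes x samples).
#' @param gene_counts,n_neighbors,min_dists,metrics grid vectors.
#' @param eps DBSCAN radius, or `"elbow"` to pick it per embedding.
#' @param min_pts DBSCAN minimum neighborhood size.
#' @param seed master seed.
#' @return list: `best` ([umap_params()] of the top combination) and
#'   `table` (one row per combination with its score, ranked).
#' @export
grid_search <- function(expr,
                        gene_counts = c(25, 250, 1000, 5000, 10000),
                        n_neighbors = c(5, 10, 20, 50),
                        min_dists = c(0.01, 0.1, 0.2, 0.5, 0.99),
                        metrics = c("cosine", "manhattan", "euclidean"),
                        eps = "elbow", min_pts = 5, seed = 1) {
  gene_counts <- gene_counts[gene_counts <= nrow(expr)]
  if (!length(gene_counts)) stop("all gene_counts exceed the gene universe")
  grid <- expand.grid(gene_count = gene_counts, n_neighbors = n_neighbors,
                      min_dist = min_dists, metric = metrics,
                      stringsAsFactors = FALSE)
  subsets <- lapply(stats::setNames(gene_counts, gene_counts), function(gc) {
    set.seed(derive_seed(seed, paste0("grid-genes:", gc)))
    sample.int(nrow(expr), gc)
  })
  embed_seed <- derive_seed(seed, "grid-embed")
  grid$score <- vapply(seq_len(nrow(grid)), function(i) {
    g <- grid[i, ]
    sub <- expr[subsets[[as.character(g$gene_count)]], , drop = FALSE]
    p <- umap_params(g$n_neighbors, g$min_dist, g$gene_count, g$metric)
    co <- tryCatch(embed_2d(sub, p, seed = embed_seed),
                   error = function(e) NULL)
    if (is.null(co)) return(NA_real_)
    e <- if (identical(eps, "elbow")) choose_eps_elbow(co, min_pts) else eps
    tryCatch(separation_score(co, cluster_density(co, e, min_pts)),
             error = function(e) NA_real_)
  }, numeric(1))
  grid <- grid[order(-grid$score, na.last = TRUE), ]
  rownames(grid) <- NULL
  b <- grid[1, ]
  list(best = umap_params(b$n_neighbors, b$min_dist, b$gene_count, b$metric),
       table = grid)
}

#' Align cluster labels to a reference partition
#'
#' Maps the clusters of `labels` onto the groups of `reference` by solving
#' the assignment problem on their contingency table (maximum total
#' overlap, Hungarian algorithm). Clusters with no overlap with any
#' reference group — or beyond the reference's group count — receive fresh
#' ids above the reference range. Noise (0) passes through unmapped.
#'
#' @param reference integer labels of the reference partition (0 = noise).
#' @param labels integer labels to relabel (same samples, same order).
#' @return integer labels expressed in the reference's group ids.
#' @export
align_labels <- function(reference, labels) {
  stopifnot(length(reference) == length(labels))
  reference <- as.integer(reference)
  labels <- as.integer(labels)
  out <- integer(length(labels))
  rids <- sort(setdiff(unique(reference), 0L))
  lids <- sort(setdiff(unique(labels), 0L))
  if (!length(lids)) return(out)
  if (!length(rids)) { # nothing to align to: keep labels as fresh ids
    out[labels != 0] <- labels[labels != 0]
    return(out)
  }
  keep <- reference != 0 & labels != 0
  ov <- matrix(0, length(lids), length(rids),
               dimnames = list(lids, rids))
  if (any(keep)) {
    tab <- table(factor(labels[keep], levels = lids),
                 factor(reference[keep], levels = rids))
    ov[] <- as.numeric(tab)
  }
  k <- max(dim(ov))
  pad <- matrix(0, k, k)
  pad[seq_len(nrow(ov)), seq_len(ncol(ov))] <- ov
  sol <- clue::solve_LSAP(pad, maximum = TRUE)
  fresh <- max(rids)
  map <- integer(length(lids))
  storage.mode(fresh) <- "integer"
  for (i in seq_along(lids)) {
    j <- sol[i]
    if (j <= length(rids) && ov[i, j] > 0) {
      map[i] <- rids[j]
    } else {
      fresh <- fresh + 1L
      map[i] <- fresh
    }
  }
  out[labels != 0] <- map[match(labels[labels != 0], lids)]
  out
}

#' Ensemble configuration
#'
#' @param n_iterations number of random-gene-subset iterations.
#' @param threshold plurality-vote consensus threshold; a sample needs this
#'   support fraction (inclusive) to be assigned, otherwise it is
#'   "ambiguous". Must exceed 0.5.
#' @param seed master seed for the whole ensemble.
#' @param strict_denominator if `TRUE`, support is counted over all
#'   iterations; by default iterations where the sample fell out as noise
#'   are removed from its denominator.
#' @return a named list of class `ensemble_config`.
#' @export
ensemble_config <- function(n_iterations = 1000, threshold = 0.70, seed = 1,
                            strict_denominator = FALSE) {
  stopifnot(n_iterations >= 1, threshold > 0.5, threshold <= 1)
  structure(list(n_iterations = n_iterations, threshold = threshold,
                 seed = seed, strict_denominator = strict_denominator),
            class = "ensemble_config")
}

#' Iterated density-based embedding consensus (DBU)
#'
#' The core classifier: each iteration draws `gene_count` genes uniformly
#' without replacement, embeds the samples in 2-D, density-clusters the
#' embedding, and aligns the resulting clusters to a reference partition
#' (the first iteration producing >= 2 clusters). Final per-sample groups
#' come from plurality voting: the modal aligned group, assigned only when
#' its support reaches the consensus threshold, otherwise "ambiguous".
#' Iterations where a sample fell out as noise are excluded from that
#' sample's denominator (see [ensemble_config()]).
#'
#' @param expr gene-level log2 matrix (genes x samples), batch-corrected.
#' @param params [umap_params()].
#' @param dbscan list with `eps` (number or `"elbow"`) and `min_pts`.
#' @param config [ensemble_config()].
#' @return object of class `dbu_consensus`: `assignment` (named character,
#'   group id or `"ambiguous"`), `support` (named numeric), `iterations`
#'   (iteration x sample aligned label matrix, 0 = noise), `coclust`
#'   (sample x sample co-clustering frequency, unit diagonal), plus the
#'   configuration used.
#' @export
run_ensemble <- function(expr, params = umap_params(),
                         dbscan = list(eps = "elbow", min_pts = 5),
                         config = ensemble_config()) {
  validate_expression(expr)
  ng <- nrow(expr); n <- ncol(expr)
  if (params$gene_count > ng)
    stop("gene_count (", params$gene_count, ") exceeds available genes (", ng, ")")
  iters <- config$n_iterations
  raw <- matrix(0L, iters, n, dimnames = list(NULL, colnames(expr)))
  eps_used <- numeric(iters)
  for (i in seq_len(iters)) {
    si <- derive_seed(config$seed, paste0("iter", i))
    set.seed(si)
    gidx <- sample.int(ng, params$gene_count)
    co <- embed_2d(expr[gidx, , drop = FALSE], params, seed = si)
    e <- if (identical(dbscan$eps, "elbow"))
      choose_eps_elbow(co, dbscan$min_pts) else dbscan$eps
    eps_used[i] <- e
    raw[i, ] <- cluster_density(co, e, dbscan$min_pts)
  }
  ncl <- apply(raw, 1, function(l) length(setdiff(unique(l), 0L)))
  ref_i <- which(ncl >= 2)[1]
  if (is.na(ref_i))
    stop("no structure found: every iteration produced < 2 clusters")
  reference <- raw[ref_i, ]
  aligned <- t(apply(raw, 1, function(l) align_labels(reference, l)))
  colnames(aligned) <- colnames(expr)

  vote <- .vote_consensus(aligned, config$threshold,
                          config$strict_denominator)
  assignment <- vote$assignment
  support <- vote$support

  nz <- aligned != 0L
  both <- crossprod(nz) # iterations where both samples were non-noise
  together <- matrix(0, n, n)
  for (g in sort(setdiff(unique(as.vector(aligned)), 0L))) {
    ind <- aligned == g
    together <- together + crossprod(ind)
  }
  coclust <- ifelse(both > 0, together / both, 0)
  diag(coclust) <- 1
  dimnames(coclust) <- list(colnames(expr), colnames(expr))

  structure(list(assignment = assignment, support = support,
                 iterations = aligned, coclust = coclust,
                 threshold = config$threshold, n_iterations = iters,
                 eps = eps_used, params = params, reference_iteration = ref_i),
            class = "dbu_consensus")
}

# Plurality voting over an aligned iteration x sample label matrix.
# Support = modal-group count / iterations where the sample was not noise
# (or / all iterations when strict). The threshold is inclusive (>=).
.vote_consensus <- function(aligned, threshold, strict = FALSE) {
  n <- ncol(aligned)
  iters <- nrow(aligned)
  support <- numeric(n); assignment <- character(n)
  for (j in seq_len(n)) {
    counted <- aligned[aligned[, j] != 0L, j]
    if (!length(counted)) {
      support[j] <- 0; assignment[j] <- "ambiguous"; next
    }
    tab <- table(counted)
    modal <- names(tab)[which.max(tab)] # ties: smallest group id
    denom <- if (strict) iters else length(counted)
    support[j] <- max(tab) / denom
    assignment[j] <- if (support[j] >= threshold) modal else "ambiguous"
  }
  names(support) <- names(assignment) <- colnames(aligned)
  list(assignment = assignment, support = support)
}

#' @export
print.dbu_consensus <- function(x, ...) {
  tab <- table(x$assignment)
  cat("DBU consensus over", x$n_iterations, "iterations (threshold",
      x$threshold, ")\n")
  for (g in names(tab)) cat("  ", g, ":", tab[[g]], "samples\n")
  cat("  median support:", round(stats::median(x$support), 3), "\n")
  invisible(x)
}

#' Concordance of consensus groups with histology
#'
#' Tumor samples only (normal kidney excluded): consensus groups are mapped
#' to histology labels by majority composition, and accuracy is the
#' fraction of non-ambiguous tumor samples whose mapped label matches their
#' histology. Ambiguous samples are reported separately, together with the
#' accuracy when they are counted in the denominator.
#'
#' @param consensus a `dbu_consensus`.
#' @param pheno phenotype table.
#' @return list: `accuracy`, `accuracy_with_ambiguous`, `ambiguous_rate`,
#'   `confusion` (histology x predicted), `mapping` (group -> histology),
#'   `per_class` (sensitivity/specificity per histology).
#' @export
concordance <- function(consensus, pheno) {
  validate_phenotype(pheno)
  ph <- pheno[match(names(consensus$assignment), pheno$sample), ]
  tumor <- ph$histology %in% c("chRCC", "RO")
  truth <- ph$histology[tumor]
  pred_g <- consensus$assignment[tumor]
  groups <- setdiff(unique(pred_g), "ambiguous")
  if (!length(groups)) stop("all tumor samples are ambiguous")
  mapping <- vapply(groups, function(g) {
    tab <- sort(table(truth[pred_g == g]), decreasing = TRUE)
    names(tab)[1]
  }, character(1))
  pred <- ifelse(pred_g == "ambiguous", "ambiguous", mapping[pred_g])
  ok <- pred != "ambiguous"
  accuracy <- mean(pred[ok] == truth[ok])
  confusion <- table(histology = truth,
                     predicted = factor(pred, levels = c(sort(unique(mapping)),
                                                         "ambiguous")))
  per_class <- lapply(unique(truth), function(h) {
    tp <- sum(truth == h & pred == h)
    fn <- sum(truth == h & pred != h)
    fp <- sum(truth != h & pred == h)
    tn <- sum(truth != h & pred != h)
    c(sensitivity = tp / (tp + fn), specificity = tn / (tn + fp))
  })
  names(per_class) <- unique(truth)
  list(accuracy = accuracy,
       accuracy_with_ambiguous = sum(pred[ok] == truth[ok]) / length(truth),
       ambiguous_rate = mean(!ok),
       confusion = confusion, mapping = mapping, per_class = per_class)
}

#' Average-linkage hierarchical clustering on correlation distance
#'
#' Clusters sample profiles (typically restricted to a signature) with
#' distance `1 - Pearson correlation` and average linkage; the 2-group cut
#' is returned alongside the dendrogram.
#'
#' @param expr matrix, genes x samples (>= 2 samples).
#' @return list: `hclust` object, `labels` (2-cut integer labels).
#' @export
hierarchical_cluster <- function(expr) {
  validate_expression(expr)
  if (ncol(expr) < 2) stop("need at least 2 samples")
  sds <- apply(expr, 2, stats::sd)
  if (any(sds < 1e-12))
    stop("constant sample profile(s), correlation undefined: ",
         paste(colnames(expr)[sds < 1e-12], collapse = ", "))
  d <- stats::as.dist(1 - stats::cor(expr))
  hc <- stats::hclust(d, method = "average")
  list(hclust = hc, labels = stats::cutree(hc, k = 2))
}
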