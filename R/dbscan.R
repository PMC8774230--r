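#' Density-based clustering with noise (DBSCAN semantics)
#'
#' Standard density clustering on 2-D (or any-dimensional) coordinates:
#' a core point has at least `min_pts` neighbors within `eps` (itself
#' included); clusters are the connected components of core points under
#' the eps-neighborhood graph; non-core points within eps of a core point
#' join the cluster of their nearest such core (border points); everything
#' else is noise (label 0). Cluster ids are renumbered by first member
#' index, so the labelling is stable and permutation of point order only
#' renames clusters.
#'
#' @param coords numeric matrix, points x dimensions.
#' @param eps neighborhood radius (> 0).
#' @param min_pts minimum neighborhood size for a core point (>= 1).
#' @return integer vector of cluster labels; 0 marks noise.
#' @export
cluster_density <- function(coords, eps, min_pts) {
  coords <- as.matrix(coords)
  stopifnot(all(is.finite(coords)), eps > 0, min_pts >= 1)
  n <- nrow(coords)
  d <- as.matrix(stats::dist(coords))
  nb <- d <= eps
  core <- rowSums(nb) >= min_pts
  labels <- integer(n)
  cl <- 0L
  for (i in seq_len(n)) {
    if (!core[i] || labels[i] != 0L) next
    cl <- cl + 1L
    queue <- i
    labels[i] <- cl
    while (length(queue)) {
      p <- queue[1]; queue <- queue[-1]
      reach <- which(nb[p, ] & core & labels == 0L)
      labels[reach] <- cl
      queue <- c(queue, reach)
    }
  }
  border <- which(!core & labels == 0L)
  for (i in border) {
    cand <- which(nb[i, ] & core)
    if (length(cand))
      labels[i] <- labels[cand[which.min(d[i, cand])]]
  }
  labels
}

#' Choose eps from the k-distance elbow
#'
#' Sorts each point's distance to its `min_pts`-th nearest neighbor in
#' ascending order and returns the distance at the knee of that curve,
#' located as the point of maximum perpendicular distance to the chord
#' joining the curve's endpoints — the programmatic version of reading an
#' elbow plot.
#'
#' @param coords numeric matrix, points x dimensions.
#' @param min_pts neighborhood size (the k of the k-distance curve).
#' @return a single eps value.
#' @export
choose_eps_elbow <- function(coords, min_pts) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  if (n < min_pts + 1)
    stop("need at least min_pts + 1 points for the k-distance curve")
  d <- as.matrix(stats::dist(coords))
  # distance to the min_pts-th nearest *other* point (sorted row includes self at 0)
  kdist <- apply(d, 1, function(row) sort(row)[min_pts + 1])
  y <- sort(kdist)
  if (max(y) < .Machine$double.eps)
    stop("all points identical; k-distance curve is degenerate")
  x <- seq_along(y)
  x1 <- x[1]; y1 <- y[1]; x2 <- x[n]; y2 <- y[n]
  denom <- sqrt((x2 - x1)^2 + (y2 - y1)^2)
  perp <- abs((y2 - y1) * x - (x2 - x1) * y + x2 * y1 - y2 * x1) / denom
  y[which.max(perp)]
}
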