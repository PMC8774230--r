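#' Weighted running-sum enrichment score
#'
#' Walks the ranking (statistic descending); each set member adds
#' `|stat|^weight` normalized by the set's total, each non-member subtracts
#' `1/(N - m)`. The enrichment score is the running-sum extremum of largest
#' magnitude. `weight = 0` reduces to the classic Kolmogorov-Smirnov walk.
#'
#' @param stats named numeric vector of ranking statistics (any order; it
#'   is sorted descending internally, ties kept in input order).
#' @param set character vector of member gene ids.
#' @param weight exponent on `|stat|` for member increments (default 1).
#' @return list: `es`, `running` (full running sum, one value per gene),
#'   `hits` (positions of members in the ranking).
#' @export
enrichment_score <- function(stats, set, weight = 1) {
  stopifnot(!is.null(names(stats)), !anyDuplicated(names(stats)))
  o <- order(stats, decreasing = TRUE)
  s <- stats[o]
  hit <- names(s) %in% set
  m <- sum(hit)
  if (m == 0) stop("no set members in the ranked universe")
  N <- length(s)
  w <- abs(s)^weight
  tot <- sum(w[hit])
  inc <- if (tot > 0) w / tot else rep(1 / m, N)
  step <- ifelse(hit, inc, if (N > m) -1 / (N - m) else 0)
  running <- cumsum(step)
  es <- running[which.max(abs(running))]
  list(es = unname(es), running = stats::setNames(running, names(s)),
       hits = which(hit))
}

# ES from hit positions in a pre-sorted ranking; O(m log m) per call.
# absw = |stat|^weight aligned with the descending ranking.
.es_from_positions <- function(pos, absw, N) {
  m <- length(pos)
  pos <- sort(pos)
  w <- absw[pos]
  tot <- sum(w)
  w <- if (tot > 0) w / tot else rep(1 / m, m)
  miss <- if (N > m) 1 / (N - m) else 0
  cw <- cumsum(w)
  j <- seq_len(m)
  after <- cw - (pos - j) * miss        # running sum just after each hit
  before <- after - w                   # just before each hit
  cand <- c(after, before)
  unname(cand[which.max(abs(cand))])
}

#' Preranked gene-set enrichment with a permutation null
#'
#' For each gene set (restricted to the ranked universe and within the size
#' bounds) the enrichment score is compared against a null built by
#' permuting gene labels of the ranking statistic — equivalently, drawing
#' random sets of the same size. The permutation p-value is one-sided on
#' the observed sign with the +1 correction; NES normalizes the observed ES
#' by the mean magnitude of same-sign null scores; BH adjustment is applied
#' across sets. Deterministic given `seed`.
#'
#' @param stats named numeric ranking statistic (e.g. signed moderated t).
#' @param collection named list of gene sets (see [read_gmt()]).
#' @param n_perm number of permutations (>= 100).
#' @param seed integer seed.
#' @param min_size,max_size set-size bounds after restriction to the
#'   universe; out-of-bounds sets are excluded with a message.
#' @param weight member increment exponent, as in [enrichment_score()].
#' @return data.frame: `set`, `size`, `es`, `nes`, `p`, `adj_p`, one row
#'   per retained set.
#' @export
preranked_gsea <- function(stats, collection, n_perm = 1000, seed = 1,
                           min_size = 5, max_size = 500, weight = 1) {
  stopifnot(n_perm >= 100, is.list(collection), !is.null(names(collection)))
  o <- order(stats, decreasing = TRUE)
  s <- stats[o]
  N <- length(s)
  absw <- abs(s)^weight
  idx_of <- stats::setNames(seq_len(N), names(s))

  sizes <- vapply(collection, function(g) sum(g %in% names(s)), integer(1))
  keep <- sizes >= min_size & sizes <= max_size
  if (any(!keep))
    message("excluding ", sum(!keep), " set(s) outside size bounds [",
            min_size, ", ", max_size, "]: ",
            paste(utils::head(names(collection)[!keep], 5), collapse = ", "),
            if (sum(!keep) > 5) ", ...")
  collection <- collection[keep]
  if (!length(collection)) stop("no gene sets left after size filtering")

  set.seed(derive_seed(seed, "gsea"))
  rows <- lapply(names(collection), function(nm) {
    members <- intersect(collection[[nm]], names(s))
    m <- length(members)
    es <- .es_from_positions(idx_of[members], absw, N)
    perm <- vapply(seq_len(n_perm), function(i)
      .es_from_positions(sample.int(N, m), absw, N), numeric(1))
    same <- sign(perm) == sign(es)
    p <- (1 + sum(same & abs(perm) >= abs(es))) / (1 + sum(same))
    nes <- if (any(same)) es / mean(abs(perm[same])) else NA_real_
    data.frame(set = nm, size = m, es = es, nes = nes, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$adj_p <- bh_adjust(out$p)
  rownames(out) <- NULL
  out
}

#' Ranking statistic from a DGE result
#'
#' @param dge a `dge_result`; the signed moderated t is the ranking metric.
#' @return named numeric vector sorted descending.
#' @export
rank_from_dge <- function(dge) {
  stopifnot(inherits(dge, "dge_result"))
  s <- stats::setNames(dge$table$t, dge$table$gene)
  sort(s, decreasing = TRUE)
}
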