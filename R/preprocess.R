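#' Score probes by specificity, coverage and robustness
#'
#' Each annotated probe gets a total score that is the product of three
#' components, each penalizing one probe failure mode:
#' \describe{
#'   \item{specificity}{1 / (number of genes the probe maps to) — penalizes
#'     cross-mapping probes.}
#'   \item{coverage}{fraction of samples with intensity above the study-wide
#'     25th percentile — penalizes low-signal probes.}
#'   \item{robustness}{mean intensity / (SD + 0.01) — penalizes noisy
#'     probes.}
#' }
#' Probes absent from the annotation are dropped with a warning.
#'
#' @param expr probe-level log2 matrix (probes x samples).
#' @param annotation data.frame with columns `probe`, `gene` (multi-mapping
#'   probes occupy several rows).
#' @return data.frame with one row per (probe, gene) pair: `probe`, `gene`,
#'   `specificity`, `coverage`, `robustness`, `total`.
#' @export
score_probes <- function(expr, annotation) {
  validate_expression(expr, "probe matrix")
  stopifnot(all(c("probe", "gene") %in% names(annotation)))
  unann <- setdiff(rownames(expr), annotation$probe)
  if (length(unann)) {
    warning("excluding ", length(unann), " unannotated probe(s): ",
            paste(utils::head(unann, 5), collapse = ", "),
            if (length(unann) > 5) ", ...")
    expr <- expr[setdiff(rownames(expr), unann), , drop = FALSE]
  }
  ann <- annotation[annotation$probe %in% rownames(expr), , drop = FALSE]
  q25 <- stats::quantile(expr, 0.25, names = FALSE)
  cov <- rowMeans(expr > q25)
  mu <- rowMeans(expr)
  sdv <- sqrt(.row_vars(expr))
  rob <- mu / (sdv + 0.01)
  ngenes <- table(ann$probe)
  spec <- 1 / as.numeric(ngenes[ann$probe])
  out <- data.frame(probe = ann$probe, gene = ann$gene,
                    specificity = spec,
                    coverage = cov[ann$probe],
                    robustness = rob[ann$probe],
                    stringsAsFactors = FALSE)
  out$total <- out$specificity * out$coverage * out$robustness
  rownames(out) <- NULL
  out
}

#' Collapse probes to genes by the highest-scoring probe
#'
#' For each gene, the probe with the largest total score wins and its row of
#' expression values becomes the gene's row; exact score ties go to the
#' lexicographically smallest probe id, making the result independent of
#' probe and sample order.
#'
#' @param scores output of [score_probes()].
#' @param expr probe-level matrix the scores were computed on.
#' @return gene-level matrix (genes x samples), rows ordered by gene id.
#' @export
select_best_probes <- function(scores, expr) {
  stopifnot(all(scores$probe %in% rownames(expr)))
  sc <- scores[order(scores$gene, -scores$total, scores$probe), ]
  win <- sc[!duplicated(sc$gene), ]
  out <- expr[win$probe, , drop = FALSE]
  rownames(out) <- win$gene
  out[order(rownames(out)), , drop = FALSE]
}

#' Detect and apply log2 scale
#'
#' Heuristic: log2-scale expression summaries rarely exceed ~20, raw
#' intensities are in the hundreds. If the 99th percentile exceeds 30 the
#' matrix is treated as raw scale and `log2(x + 1)` is applied; otherwise it
#' is returned unchanged. Idempotent by construction.
#'
#' @param expr numeric matrix.
#' @return the matrix on log2 scale, with attribute `scale` set to
#'   `"log2"` and `log_applied` recording whether a transform happened.
#' @export
detect_log_scale <- function(expr) {
  validate_expression(expr)
  q99 <- stats::quantile(expr, 0.99, names = FALSE)
  applied <- FALSE
  if (q99 > 30) {
    if (any(expr < 0))
      stop("raw-scale matrix (99th percentile ", round(q99, 1),
           " > 30) contains negative values; cannot log-transform")
    expr <- log2(expr + 1)
    applied <- TRUE
  }
  attr(expr, "scale") <- "log2"
  attr(expr, "log_applied") <- applied
  expr
}

#' Merge gene-level studies on their common genes
#'
#' @param tables named list of gene-level matrices (genes x samples); names
#'   are the batch ids.
#' @return list with `expr` (common genes x all samples) and `batch`
#'   (character vector, one entry per column).
#' @export
merge_studies <- function(tables) {
  stopifnot(is.list(tables), length(tables) >= 2, !is.null(names(tables)))
  common <- Reduce(intersect, lapply(tables, rownames))
  if (length(common) == 0)
    stop("no genes are shared by all studies; cannot merge")
  common <- sort(common)
  expr <- do.call(cbind, lapply(tables, function(m) m[common, , drop = FALSE]))
  batch <- rep(names(tables), vapply(tables, ncol, integer(1)))
  validate_expression(expr, "merged matrix")
  list(expr = expr, batch = batch)
}

#' PCA batch audit
#'
#' Standardizes genes, computes principal components of the samples, and
#' reports how much of the PC1-2 variation is explained by batch membership
#' versus histology (one-way R-squared on the 2-D coordinates). In the
#' multi-study world this package emulates, batch R2 exceeds histology R2
#' before batch correction and the order reverses afterwards.
#'
#' @param expr gene-level log2 matrix (genes x samples).
#' @param pheno phenotype table covering the samples.
#' @param k number of PCs to return coordinates for.
#' @return list: `coords` (samples x k), `var_explained`, `r2_batch`,
#'   `r2_histology`, `degenerate` flag.
#' @export
pca_batch_report <- function(expr, pheno, k = 5) {
  validate_expression(expr)
  validate_phenotype(pheno, expr)
  if (ncol(expr) < 3) stop("need at least 3 samples for a PCA audit")
  pheno <- pheno[match(colnames(expr), pheno$sample), ]
  v <- .row_vars(expr)
  if (all(v < 1e-24)) {
    co <- matrix(0, ncol(expr), k,
                 dimnames = list(colnames(expr), paste0("PC", seq_len(k))))
    return(list(coords = co, var_explained = rep(0, k),
                r2_batch = 0, r2_histology = 0, degenerate = TRUE))
  }
  z <- (expr[v > 1e-24, , drop = FALSE] - rowMeans(expr[v > 1e-24, , drop = FALSE])) /
    sqrt(v[v > 1e-24])
  pc <- stats::prcomp(t(z), center = TRUE, scale. = FALSE)
  k <- min(k, ncol(pc$x))
  coords <- pc$x[, seq_len(k), drop = FALSE]
  r2 <- function(groups) {
    g <- as.factor(groups)
    if (nlevels(g) < 2) return(0)
    xy <- coords[, 1:min(2, k), drop = FALSE]
    centered <- scale(xy, scale = FALSE)
    tot <- sum(centered^2)
    if (tot < 1e-24) return(0)
    within <- sum(vapply(levels(g), function(l) {
      sub <- xy[g == l, , drop = FALSE]
      sum(scale(sub, scale = FALSE)^2)
    }, numeric(1)))
    max(0, min(1, 1 - within / tot))
  }
  list(coords = coords,
       var_explained = (pc$sdev^2 / sum(pc$sdev^2))[seq_len(k)],
       r2_batch = r2(pheno$batch),
       r2_histology = r2(pheno$histology),
       degenerate = FALSE)
}
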