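#' Moderated two-group t-test with variance shrinkage
#'
#' Per-gene pooled variances are shrunk toward a common prior estimated by
#' moment-matching the distribution of log sample variances (the classic
#' empirical-Bayes scheme: a scaled inverse-chi-square prior with `d0`
#' degrees of freedom and location `s0^2`, recovered by digamma/trigamma
#' inversion). The moderated statistic uses the posterior variance
#' `(d0 s0^2 + d s_g^2) / (d0 + d)` on `d0 + d` degrees of freedom.
#'
#' @param expr gene-level log2 matrix (genes x samples).
#' @param labels character vector of group labels per sample.
#' @param groups the two labels to contrast, in `c(numerator, denominator)`
#'   order; log2 fold change is `mean(groups[1]) - mean(groups[2])`.
#'   Defaults to the sorted unique labels.
#' @param d0 prior degrees of freedom; `NULL` (default) estimates them,
#'   `0` gives the ordinary two-sample t exactly, `Inf` shrinks every gene
#'   to the common prior variance.
#' @return object of class `dge_result`: `table` (gene, group means, `lfc`,
#'   linear `fc` = 2^|lfc|, `direction`, moderated `t`, `df`, `p`, `adj_p`),
#'   hyperparameters `d0` and `s0_2`, and the contrasted `groups`.
#' @export
moderated_t_test <- function(expr, labels, groups = NULL, d0 = NULL) {
  validate_expression(expr)
  stopifnot(length(labels) == ncol(expr))
  if (is.null(groups)) groups <- sort(unique(labels))
  stopifnot(length(groups) == 2, all(groups %in% labels))
  i1 <- labels == groups[1]; i2 <- labels == groups[2]
  n1 <- sum(i1); n2 <- sum(i2)
  if (n1 < 2 || n2 < 2) stop("need >= 2 samples in each group")
  m1 <- rowMeans(expr[, i1, drop = FALSE])
  m2 <- rowMeans(expr[, i2, drop = FALSE])
  v1 <- .row_vars(expr[, i1, drop = FALSE])
  v2 <- .row_vars(expr[, i2, drop = FALSE])
  d <- n1 + n2 - 2
  s2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / d
  if (all(s2 < .Machine$double.eps))
    stop("all genes have zero variance; nothing to test")
  diff <- m1 - m2

  if (nrow(expr) == 1 && is.null(d0)) {
    warning("single gene: no shrinkage target, falling back to ordinary t")
    d0 <- 0
  }
  s0_2 <- NA_real_
  if (is.null(d0)) {
    ok <- s2 > .Machine$double.eps
    e <- log(s2[ok]) - digamma(d / 2) + log(d / 2)
    ev <- stats::var(e) - trigamma(d / 2)
    if (is.finite(ev) && ev > 0) {
      d0 <- 2 * .trigamma_inverse(ev)
      s0_2 <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
    } else {
      d0 <- Inf
      s0_2 <- exp(mean(e))
    }
  } else if (d0 > 0) {
    ok <- s2 > .Machine$double.eps
    e <- log(s2[ok]) - digamma(d / 2) + log(d / 2)
    s0_2 <- if (is.finite(d0))
      exp(mean(e) + digamma(d0 / 2) - log(d0 / 2)) else exp(mean(e))
  }
  s2_post <- if (d0 == 0) s2
  else if (is.infinite(d0)) rep(s0_2, length(s2))
  else (d0 * s0_2 + d * s2) / (d0 + d)
  tstat <- diff / sqrt(s2_post * (1 / n1 + 1 / n2))
  df_total <- d0 + d
  p <- 2 * stats::pt(-abs(tstat), df = df_total)
  tab <- data.frame(gene = rownames(expr), mean1 = m1, mean2 = m2,
                    lfc = diff, fc = 2^abs(diff),
                    direction = ifelse(diff >= 0, groups[1], groups[2]),
                    t = tstat, df = df_total, p = p,
                    adj_p = bh_adjust(p),
                    stringsAsFactors = FALSE, row.names = NULL)
  names(tab)[2:3] <- paste0("mean_", groups)
  structure(list(table = tab, d0 = d0, s0_2 = s0_2, groups = groups,
                 n = c(n1, n2)),
            class = "dge_result")
}

# Newton inversion of the trigamma function (solve trigamma(x) = y, y > 0)
.trigamma_inverse <- function(y) {
  if (y >= 1e7) return(1 / sqrt(y))
  if (y <= 1e-6) return(1 / y)
  x <- 0.5 + 1 / y
  for (i in 1:50) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, deriv = 2)
    x <- x + dif
    if (abs(dif / x) < 1e-10) break
  }
  x
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return adjusted p-values (monotone, capped at 1), same order as input.
#' @export
bh_adjust <- function(p) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1]")
  n <- length(p)
  if (n <= 1) return(p)
  o <- order(p, decreasing = TRUE)
  i <- n:1
  adj <- numeric(n)
  adj[o] <- pmin(1, cummin(n / i * p[o]))
  adj
}

#' Rank-based AUROC (Mann-Whitney)
#'
#' Probability that a random positive-class value ranks above a random
#' negative-class value, with ties counted one half — identical to
#' exhaustive pair counting.
#'
#' @param values numeric vector.
#' @param labels class labels.
#' @param positive the positive class label.
#' @return AUROC in `[0, 1]`.
#' @export
roc_auc <- function(values, labels, positive) {
  pos <- labels == positive
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0)
    stop("both classes must be present (positive n=", n1, ", negative n=", n0, ")")
  r <- rank(values)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Sensitivity / specificity / accuracy at one cutpoint
#'
#' Predicts positive when `value >= cutpoint` (the positive class is the
#' high-expression class throughout the package). Accuracy is the
#' class-size-weighted identity `(sens * n_pos + spec * n_neg) / n` — i.e.
#' plain accuracy; when sensitivity equals specificity it equals both,
#' whatever the class sizes.
#'
#' @param values numeric vector.
#' @param labels class labels.
#' @param cutpoint threshold.
#' @param positive positive class label.
#' @return named vector: sensitivity, specificity, accuracy, youden.
#' @export
cutpoint_metrics <- function(values, labels, cutpoint, positive) {
  pos <- labels == positive
  stopifnot(any(pos), any(!pos))
  sens <- mean(values[pos] >= cutpoint)
  spec <- mean(values[!pos] < cutpoint)
  acc <- (sens * sum(pos) + spec * sum(!pos)) / length(values)
  c(sensitivity = sens, specificity = spec, accuracy = acc,
    youden = sens + spec - 1)
}

#' Percentile-cutpoint ROC profile for one gene
#'
#' Evaluates sensitivity, specificity and accuracy at the 1st..99th
#' percentiles of the pooled values, with the positive class taken as the
#' class with the higher mean (so "positive" means high expression). The
#' optimum cutpoint maximizes accuracy; ties are broken by larger Youden's
#' J, then by the smaller cutpoint.
#'
#' @param values numeric vector (one gene across samples).
#' @param labels class labels (exactly two).
#' @param positive optional positive class; default = higher-mean class.
#' @return list of class `roc_profile`: `auroc`, `positive`, `negative`,
#'   `table` (percentile, cutpoint, sensitivity, specificity, accuracy),
#'   `optimum` (percentile, cutpoint + metrics), `degenerate` flag.
#' @export
percentile_profile <- function(values, labels, positive = NULL) {
  classes <- sort(unique(labels))
  stopifnot(length(classes) == 2, length(values) >= 5)
  if (is.null(positive)) {
    mns <- tapply(values, labels, mean)
    positive <- names(mns)[which.max(mns)]
  }
  negative <- setdiff(classes, positive)
  if (stats::sd(values) < 1e-12) {
    return(structure(list(auroc = 0.5, positive = positive,
                          negative = negative, table = NULL, optimum = NULL,
                          degenerate = TRUE),
                     class = "roc_profile"))
  }
  auroc <- roc_auc(values, labels, positive)
  pctl <- 1:99
  cuts <- stats::quantile(values, pctl / 100, names = FALSE)
  pos <- labels == positive
  npos <- sum(pos); nneg <- sum(!pos); n <- length(values)
  sens <- vapply(cuts, function(t) mean(values[pos] >= t), numeric(1))
  spec <- vapply(cuts, function(t) mean(values[!pos] < t), numeric(1))
  acc <- (sens * npos + spec * nneg) / n
  youden <- sens + spec - 1
  ord <- order(-acc, -youden, cuts)
  b <- ord[1]
  structure(list(
    auroc = auroc, positive = positive, negative = negative,
    table = data.frame(percentile = pctl, cutpoint = cuts, sensitivity = sens,
                       specificity = spec, accuracy = acc),
    optimum = list(percentile = pctl[b], cutpoint = cuts[b],
                   sensitivity = sens[b], specificity = spec[b],
                   accuracy = acc[b], youden = youden[b]),
    degenerate = FALSE), class = "roc_profile")
}

#' Percentile profiles for every gene of a matrix
#'
#' @param expr gene-level matrix (genes x samples).
#' @param labels class labels per sample (exactly two classes).
#' @return named list of [percentile_profile()] results.
#' @export
profile_genes <- function(expr, labels) {
  validate_expression(expr)
  out <- lapply(seq_len(nrow(expr)),
                function(i) percentile_profile(expr[i, ], labels))
  names(out) <- rownames(expr)
  out
}
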