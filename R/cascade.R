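#' Staged ROC signature selection (COGS-style cascade)
#'
#' Applies the nested candidate filters in their canonical order —
#' significant DE (BH-adjusted p), minimum linear fold change, minimum
#' AUROC, then the joint sensitivity/specificity/AUROC/accuracy screen —
#' and ranks the survivors by a weighted priority score combining
#' (z-scored) log2 fold change, the breadth of percentile cutpoints at
#' which accuracy exceeds the accuracy threshold, and an optional
#' user-supplied relevance weight standing in for literature-based
#' prioritization. The top `k` survivors form the signature.
#'
#' @param dge a `dge_result` from [moderated_t_test()].
#' @param profiles list from [profile_genes()] on the same genes.
#' @param k signature size (default 30).
#' @param fc_min,auc_min,sens_min,spec_min,auc2_min,acc_min,adjp_max stage
#'   thresholds; defaults follow the published cascade
#'   (|FC| >= 2, AUROC >= 0.9, sens > 0.91, spec > 0.91, AUROC > 0.92,
#'   accuracy > 0.92, adjusted p < 0.05).
#' @param weights named numeric weights `c(fc=, breadth=, relevance=)`. If
#'   all are zero, ranking falls back to AUROC (descending) then adjusted p
#'   (ascending), then gene id.
#' @param relevance optional named numeric vector of per-gene relevance
#'   scores (default 0).
#' @return list of class `cogs_cascade`: `stages` (named list of gene-id
#'   vectors, nested), `counts`, `signature` (data.frame with gene,
#'   optimum cutpoint, accuracy, sensitivity, specificity, AUROC, linear
#'   fold change, adjusted p, direction and priority score).
#' @export
run_cascade <- function(dge, profiles, k = 30,
                        fc_min = 2, auc_min = 0.9,
                        sens_min = 0.91, spec_min = 0.91,
                        auc2_min = 0.92, acc_min = 0.92, adjp_max = 0.05,
                        weights = c(fc = 1, breadth = 1, relevance = 1),
                        relevance = NULL) {
  stopifnot(inherits(dge, "dge_result"))
  tab <- dge$table
  stopifnot(all(tab$gene %in% names(profiles)))
  profiles <- profiles[tab$gene]
  auroc <- vapply(profiles, `[[`, numeric(1), "auroc")
  degen <- vapply(profiles, `[[`, logical(1), "degenerate")
  getopt <- function(p, f) if (p$degenerate) NA_real_ else p$optimum[[f]]
  sens <- vapply(profiles, getopt, numeric(1), "sensitivity")
  spec <- vapply(profiles, getopt, numeric(1), "specificity")
  acc <- vapply(profiles, getopt, numeric(1), "accuracy")
  cut <- vapply(profiles, getopt, numeric(1), "cutpoint")
  breadth <- vapply(profiles, function(p) {
    if (p$degenerate) 0L else sum(p$table$accuracy > acc_min)
  }, integer(1))
  rel <- rep(0, nrow(tab))
  names(rel) <- tab$gene
  if (!is.null(relevance)) {
    common <- intersect(names(relevance), tab$gene)
    rel[common] <- relevance[common]
  }

  s_all <- tab$gene
  s_de <- tab$gene[tab$adj_p < adjp_max]
  s_fc <- intersect(s_de, tab$gene[tab$fc >= fc_min])
  s_auc <- intersect(s_fc, tab$gene[!degen & auroc >= auc_min])
  joint <- !degen & !is.na(sens) & sens > sens_min & spec > spec_min &
    auroc > auc2_min & acc > acc_min
  s_joint <- intersect(s_auc, tab$gene[joint])

  idx <- match(s_joint, tab$gene)
  if (all(weights == 0)) {
    ord <- order(-auroc[idx], tab$adj_p[idx], tab$gene[idx])
  } else {
    z <- function(x) if (length(x) > 1 && stats::sd(x) > 0)
      (x - mean(x)) / stats::sd(x) else rep(0, length(x))
    score <- weights[["fc"]] * z(abs(tab$lfc[idx])) +
      weights[["breadth"]] * z(breadth[idx]) +
      weights[["relevance"]] * rel[idx]
    ord <- order(-score, -auroc[idx], tab$adj_p[idx], tab$gene[idx])
  }
  if (length(s_joint) < k)
    warning("only ", length(s_joint), " genes survive the cascade; ",
            "returning all of them")
  take <- idx[ord][seq_len(min(k, length(s_joint)))]
  priority <- if (all(weights == 0)) rep(NA_real_, length(take)) else {
    z <- function(x) if (length(x) > 1 && stats::sd(x) > 0)
      (x - mean(x)) / stats::sd(x) else rep(0, length(x))
    sc <- weights[["fc"]] * z(abs(tab$lfc[idx])) +
      weights[["breadth"]] * z(breadth[idx]) +
      weights[["relevance"]] * rel[idx]
    sc[match(take, idx)]
  }
  signature <- data.frame(
    gene = tab$gene[take],
    optimum_cutpoint = cut[take],
    accuracy = acc[take],
    sensitivity = sens[take],
    specificity = spec[take],
    auroc = auroc[take],
    fc = tab$fc[take],
    adj_p = tab$adj_p[take],
    direction = tab$direction[take],
    positive_class = vapply(profiles[take], `[[`, character(1), "positive"),
    negative_class = vapply(profiles[take], `[[`, character(1), "negative"),
    priority = priority,
    stringsAsFactors = FALSE, row.names = NULL)
  structure(list(
    stages = list(all = s_all, significant = s_de, fold_change = s_fc,
                  auroc = s_auc, joint = s_joint,
                  signature = signature$gene),
    counts = c(all = length(s_all), significant = length(s_de),
               fold_change = length(s_fc), auroc = length(s_auc),
               joint = length(s_joint), signature = nrow(signature)),
    thresholds = list(fc_min = fc_min, auc_min = auc_min, sens_min = sens_min,
                      spec_min = spec_min, auc2_min = auc2_min,
                      acc_min = acc_min, adjp_max = adjp_max, k = k),
    signature = signature), class = "cogs_cascade")
}

#' Apply a signature to a new expression matrix
#'
#' Restricts the matrix to the signature genes and casts one cutpoint vote
#' per gene per sample: a sample's value at or above the gene's optimum
#' cutpoint votes for the gene's positive (high-expression) class,
#' otherwise for the negative class. The per-sample majority of votes is
#' reported alongside the restricted matrix, which feeds the clustering
#' route ([hierarchical_cluster()]).
#'
#' @param expr gene-level matrix of the new dataset (genes x samples).
#' @param signature signature data.frame (from [run_cascade()]`$signature`
#'   or [read_signature()]).
#' @return list: `matrix` (restricted expression), `calls` (gene x sample
#'   class votes), `votes` (per sample: predicted class, fraction of votes),
#'   `missing` (signature genes absent from the matrix).
#' @export
evaluate_signature <- function(expr, signature) {
  validate_expression(expr)
  need <- c("gene", "optimum_cutpoint", "positive_class", "negative_class")
  stopifnot(all(need %in% names(signature)))
  missing <- setdiff(signature$gene, rownames(expr))
  if (length(missing) > 0.5 * nrow(signature))
    stop("fewer than 50% of signature genes present; missing: ",
         paste(missing, collapse = ", "))
  sig <- signature[!signature$gene %in% missing, , drop = FALSE]
  m <- expr[sig$gene, , drop = FALSE]
  calls <- matrix(NA_character_, nrow(m), ncol(m), dimnames = dimnames(m))
  for (i in seq_len(nrow(m)))
    calls[i, ] <- ifelse(m[i, ] >= sig$optimum_cutpoint[i],
                         sig$positive_class[i], sig$negative_class[i])
  classes <- sort(unique(c(sig$positive_class, sig$negative_class)))
  votes <- data.frame(sample = colnames(m), stringsAsFactors = FALSE)
  counts <- vapply(classes, function(cl) colSums(calls == cl),
                   numeric(ncol(m)))
  if (is.null(dim(counts))) counts <- matrix(counts, nrow = 1,
                                             dimnames = list(NULL, classes))
  top <- apply(counts, 1, which.max)
  maxed <- counts[cbind(seq_len(nrow(counts)), top)]
  tie <- rowSums(counts == maxed) > 1
  votes$predicted <- ifelse(tie, "ambiguous", classes[top])
  votes$support <- maxed / nrow(m)
  list(matrix = m, calls = calls, votes = votes, missing = missing)
}
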