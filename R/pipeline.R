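#' Preprocess a multi-study probe-level bundle
#'
#' Per batch: log-scale detection, probe scoring and best-probe collapse to
#' gene level; then merge on common genes, audit batches by PCA, apply the
#' empirical-Bayes batch correction (histology as covariate by default) and
#' audit again.
#'
#' @param bundle list with `expr`, `pheno`, `annotation` as produced by
#'   [generate_study()] (or assembled from the readers).
#' @param use_covariates protect histology signal during batch correction.
#' @return list: `expr` (corrected gene x sample matrix), `batch`, `pheno`,
#'   `audit_pre`, `audit_post`.
#' @export
preprocess_bundle <- function(bundle, use_covariates = TRUE) {
  pheno <- validate_phenotype(bundle$pheno, bundle$expr)
  batches <- unique(pheno$batch)
  gene_tables <- lapply(batches, function(b) {
    cols <- pheno$sample[pheno$batch == b]
    e <- detect_log_scale(bundle$expr[, cols, drop = FALSE])
    sc <- score_probes(e, bundle$annotation)
    select_best_probes(sc, e)
  })
  names(gene_tables) <- batches
  merged <- merge_studies(gene_tables)
  ph <- pheno[match(colnames(merged$expr), pheno$sample), ]
  audit_pre <- pca_batch_report(merged$expr, ph)
  corrected <- combat_adjust(merged$expr, merged$batch,
                             covariates = if (use_covariates) ph$histology)
  audit_post <- pca_batch_report(corrected, ph)
  list(expr = corrected, batch = merged$batch, pheno = ph,
       audit_pre = audit_pre, audit_post = audit_post)
}

#' Gene sets for exercising enrichment on synthetic truth
#'
#' Builds a small GMT-style collection from a generated bundle: the planted
#' chRCC-high and RO-high gene sets, the tumor-vs-normal set, and random
#' null sets drawn from the gene universe.
#'
#' @param truth `truth` element of a generated bundle.
#' @param universe character vector of gene ids available post-merge.
#' @param n_random number of random null sets.
#' @param set_size size of each random set.
#' @param seed integer seed.
#' @return named list of gene-id vectors.
#' @export
synthetic_gene_sets <- function(truth, universe, n_random = 20,
                                set_size = 50, seed = 1) {
  de <- truth$de_genes
  sets <- list(
    planted_chRCC_high = intersect(de$gene[de$lfc > 0], universe),
    planted_RO_high = intersect(de$gene[de$lfc < 0], universe),
    planted_tumor_vs_normal = intersect(truth$tumor_genes, universe)
  )
  set.seed(derive_seed(seed, "genesets"))
  for (i in seq_len(n_random))
    sets[[sprintf("random_%02d", i)]] <- sample(universe, set_size)
  sets[vapply(sets, length, integer(1)) > 0]
}

#' Run the full discovery analysis on a synthetic bundle
#'
#' Generation (unless a bundle is supplied), preprocessing, the DBU
#' consensus ensemble, concordance with histology, moderated-t differential
#' expression between the tumor classes, percentile ROC profiling, the
#' signature cascade and preranked enrichment. One master seed drives every
#' stage through [derive_seed()].
#'
#' @param seed master seed.
#' @param bundle optional pre-generated bundle; default
#'   [generate_discovery_surrogate()] on the same seed.
#' @param n_iterations ensemble iterations (desk-scale default 100).
#' @param n_perm enrichment permutations.
#' @param k signature size.
#' @param gene_sets optional collection; default [synthetic_gene_sets()].
#' @return list with all intermediate results: `bundle`, `prep`,
#'   `consensus`, `concordance`, `dge`, `profiles`, `cascade`, `gsea`.
#' @export
run_discovery_pipeline <- function(seed, bundle = NULL, n_iterations = 100,
                                   n_perm = 500, k = 30, gene_sets = NULL) {
  if (is.null(bundle)) bundle <- generate_discovery_surrogate(seed)
  prep <- preprocess_bundle(bundle)
  cons <- run_ensemble(prep$expr,
                       params = umap_params(),
                       dbscan = list(eps = "elbow", min_pts = 5),
                       config = ensemble_config(n_iterations = n_iterations,
                                                seed = derive_seed(seed, "dbu")))
  conc <- concordance(cons, prep$pheno)
  tumor <- prep$pheno$histology %in% c("chRCC", "RO")
  texpr <- prep$expr[, prep$pheno$sample[tumor], drop = FALSE]
  tlab <- prep$pheno$histology[tumor]
  dge <- moderated_t_test(texpr, tlab, groups = c("chRCC", "RO"))
  profiles <- profile_genes(texpr, tlab)
  cascade <- run_cascade(dge, profiles, k = k)
  if (is.null(gene_sets))
    gene_sets <- synthetic_gene_sets(bundle$truth, rownames(prep$expr),
                                     seed = derive_seed(seed, "sets"))
  gsea <- preranked_gsea(rank_from_dge(dge), gene_sets, n_perm = n_perm,
                         seed = derive_seed(seed, "gsea-stage"))
  list(bundle = bundle, prep = prep, consensus = cons, concordance = conc,
       dge = dge, profiles = profiles, cascade = cascade, gsea = gsea)
}
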