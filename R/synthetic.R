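#' Describe a multi-study synthetic expression design
#'
#' A study design states the world the generator emulates: per-batch sample
#' composition, gene and probe counts, the fraction of genes differentially
#' expressed between the two tumor classes, the linear-scale fold-change
#' range those genes span, batch location/scale effect magnitudes, residual
#' noise, and the platform (log2 microarray intensities or RNA-seq log-CPM).
#'
#' Defaults mirror the discovery meta-dataset this package targets: five
#' microarray batches totalling 53 chRCC, 36 RO and 17 normal kidney
#' samples; ~300 planted chRCC-vs-RO genes with linear fold changes between
#' 2 and 56; log2 baselines around 8.
#'
#' @param studies named list; each element is `c(chRCC = , RO = , N = )`
#'   counts for one batch, optionally with a `platform` attribute overriding
#'   the design-wide platform.
#' @param n_genes number of genes.
#' @param probes_per_gene integer range `c(min, max)` of probes per gene.
#' @param frac_de fraction of genes differentially expressed between chRCC
#'   and RO (an equally sized disjoint set separates tumors from normal).
#' @param fc_range linear-scale fold-change bounds, lower bound >= 1.
#' @param batch_loc_sd SD (log2 units) of per-batch per-gene additive shifts.
#' @param batch_scale_shape shape of the unit-mean inverse-gamma from which
#'   per-batch per-gene residual variance multipliers are drawn.
#' @param noise_sd residual SD (log2 units) per sample.
#' @param platform `"array_log2"` or `"rnaseq_logcpm"`.
#' @return a `study_design` list.
#' @export
study_design <- function(studies,
                         n_genes = 3000,
                         probes_per_gene = c(1, 3),
                         frac_de = 0.10,
                         fc_range = c(2, 56),
                         batch_loc_sd = 1.0,
                         batch_scale_shape = 25,
                         noise_sd = 1.0,
                         platform = c("array_log2", "rnaseq_logcpm")) {
  platform <- match.arg(platform)
  stopifnot(is.list(studies), length(studies) >= 1, !is.null(names(studies)))
  for (nm in names(studies)) {
    s <- studies[[nm]]
    if (!all(c("chRCC", "RO", "N") %in% names(s)) || any(s[.class_names] < 0))
      stop("study '", nm, "' needs non-negative counts named chRCC, RO, N")
    if (sum(s[.class_names]) == 0)
      stop("study '", nm, "' has zero samples")
  }
  if (length(fc_range) != 2 || fc_range[1] > fc_range[2])
    stop("fc_range must be an increasing pair")
  if (fc_range[1] < 1) stop("fc_range lower bound must be >= 1")
  if (frac_de < 0 || frac_de > 1) stop("frac_de must lie in [0, 1]")
  stopifnot(n_genes >= 1, length(probes_per_gene) == 2,
            probes_per_gene[1] >= 1, probes_per_gene[1] <= probes_per_gene[2],
            batch_loc_sd >= 0, batch_scale_shape > 2, noise_sd >= 0)
  structure(list(studies = studies, n_genes = n_genes,
                 probes_per_gene = probes_per_gene, frac_de = frac_de,
                 fc_range = fc_range, batch_loc_sd = batch_loc_sd,
                 batch_scale_shape = batch_scale_shape, noise_sd = noise_sd,
                 platform = platform),
            class = "study_design")
}

.class_names <- c("chRCC", "RO", "N")

# Table-composition of the discovery meta-dataset (chRCC/RO/N per batch).
.discovery_studies <- list(
  GSE11024 = c(chRCC = 6,  RO = 7,  N = 12),
  GSE11151 = c(chRCC = 4,  RO = 4,  N = 5),
  GSE19982 = c(chRCC = 15, RO = 15, N = 0),
  GSE8271  = c(chRCC = 10, RO = 10, N = 0),
  GSE2109  = c(chRCC = 18, RO = 0,  N = 0)
)

#' Generate a multi-study synthetic expression bundle
#'
#' Draws per-gene log2 baselines Normal(8, 1.5^2), plants signed fold
#' changes for a chRCC-vs-RO gene set and a disjoint tumor-vs-normal gene
#' set (linear FC uniform on `fc_range`, split half up/half down), applies
#' per-batch additive location shifts and multiplicative residual scale
#' factors, and expands every gene into 1..`probes_per_gene[2]` probes: one
#' faithful probe plus degraded extras (low signal, inflated noise, or
#' cross-mapped annotation). The `rnaseq_logcpm` platform converts the
#' latent log2 means into negative-binomial counts and returns log2-CPM.
#'
#' Gene-level truth (baselines, DE gene identity, fold changes) depends only
#' on `seed`, `n_genes`, `frac_de` and `fc_range`, so discovery and
#' validation bundles generated from the same seed share their planted
#' biology.
#'
#' @param design a [study_design()].
#' @param seed integer master seed; all randomness derives from it.
#' @return list with `expr` (probe x sample log2 matrix), `pheno`
#'   (sample/histology/batch data.frame), `annotation` (probe/gene map) and
#'   `truth` (planted ground truth, see Details).
#' @details `truth` contains `de_genes` (data.frame of planted chRCC-vs-RO
#'   genes with signed log2 fold change and population AUROC implied by the
#'   noise model), `offsets` (per-class per-gene mean shifts), `tumor_genes`
#'   (tumor-vs-normal set), `batch_effects` (per-batch location/scale),
#'   `good_probe` (gene -> faithful probe) and the design parameters.
#' @export
generate_study <- function(design, seed) {
  stopifnot(inherits(design, "study_design"))
  ng <- design$n_genes
  genes <- sprintf("g%04d", seq_len(ng))

  ## -- gene-level world (independent of study composition / probe layout)
  set.seed(derive_seed(seed, "genes"))
  mu <- stats::rnorm(ng, 8, 1.5)
  names(mu) <- genes
  n_de <- round(design$frac_de * ng)
  off <- matrix(0, ng, 3, dimnames = list(genes, .class_names))
  de_idx <- integer(0); tum_idx <- integer(0)
  lfc_cr <- numeric(0)
  if (n_de > 0) {
    pick <- sample.int(ng, min(2 * n_de, ng))
    de_idx <- pick[seq_len(n_de)]
    tum_idx <- pick[setdiff(seq_along(pick), seq_len(n_de))]
    fc <- stats::runif(n_de, design$fc_range[1], design$fc_range[2])
    sgn <- rep(c(1, -1), length.out = n_de)
    lfc_cr <- sgn * log2(fc) # chRCC minus RO
    off[de_idx, "chRCC"] <- lfc_cr / 2
    off[de_idx, "RO"] <- -lfc_cr / 2
    if (length(tum_idx)) {
      fc_t <- stats::runif(length(tum_idx), design$fc_range[1], design$fc_range[2])
      sgn_t <- rep(c(1, -1), length.out = length(tum_idx))
      off[tum_idx, "chRCC"] <- off[tum_idx, "chRCC"] + sgn_t * log2(fc_t)
      off[tum_idx, "RO"] <- off[tum_idx, "RO"] + sgn_t * log2(fc_t)
    }
  }

  ## -- probe layout
  set.seed(derive_seed(seed, "probes"))
  pmin_ <- design$probes_per_gene[1]; pmax_ <- design$probes_per_gene[2]
  nprobes <- if (pmax_ > pmin_)
    sample(pmin_:pmax_, ng, replace = TRUE) else rep(pmin_, ng)
  modes <- c("lowsignal", "noisy", "crossmap")
  probe_rows <- vector("list", ng)
  for (g in seq_len(ng)) {
    k <- nprobes[g]
    ids <- sprintf("%s_p%d", genes[g], seq_len(k))
    mode <- c("faithful", if (k > 1) sample(modes, k - 1, replace = TRUE))
    partner <- rep(NA_integer_, k)
    cm <- mode == "crossmap"
    if (any(cm))
      partner[cm] <- sample(setdiff(seq_len(ng), g), sum(cm), replace = TRUE)
    probe_rows[[g]] <- data.frame(probe = ids, gene = genes[g], gidx = g,
                                  mode = mode, partner = partner,
                                  stringsAsFactors = FALSE)
  }
  probes <- do.call(rbind, probe_rows)
  np <- nrow(probes)

  ## -- per-batch effects and sample values
  batches <- names(design$studies)
  batch_fx <- list()
  expr_cols <- list(); pheno_rows <- list()
  for (b in batches) {
    set.seed(derive_seed(seed, paste0("batch:", b)))
    gamma <- stats::rnorm(ng, 0, design$batch_loc_sd)
    a <- design$batch_scale_shape
    delta2 <- if (is.finite(a))
      (a - 1) / stats::rgamma(ng, shape = a, rate = 1) # InvGamma mean 1
    else rep(1, ng) # shape = Inf: no scale effects
    names(gamma) <- names(delta2) <- genes
    batch_fx[[b]] <- list(location = gamma, scale = delta2)

    counts <- design$studies[[b]][.class_names]
    plat <- attr(design$studies[[b]], "platform")
    if (is.null(plat)) plat <- design$platform
    cls <- rep(.class_names, counts)
    ids <- sprintf("%s_s%02d", b, seq_along(cls))
    ns <- length(cls)

    set.seed(derive_seed(seed, paste0("study:", b)))
    # latent gene signal per sample (no residual noise yet)
    sig <- mu + gamma + off[, cls, drop = FALSE] # ng x ns via recycling
    dim(sig) <- c(ng, ns)
    sdv <- design$noise_sd * sqrt(delta2)
    pm <- matrix(NA_real_, np, ns, dimnames = list(probes$probe, ids))
    noise <- matrix(stats::rnorm(np * ns), np, ns) * sdv[probes$gidx]
    base_sig <- sig[probes$gidx, , drop = FALSE]
    cross <- probes$mode == "crossmap"
    if (any(cross)) {
      base_sig[cross, ] <- 0.5 * sig[probes$gidx[cross], , drop = FALSE] +
        0.5 * sig[probes$partner[cross], , drop = FALSE]
      # hybridizing two transcripts is noisier, not cleaner
      noise[cross, ] <- noise[cross, , drop = FALSE] * 2
    }
    base_sig[probes$mode == "lowsignal", ] <-
      base_sig[probes$mode == "lowsignal", , drop = FALSE] - 4
    noise[probes$mode == "noisy", ] <-
      noise[probes$mode == "noisy", , drop = FALSE] * 3
    pm[] <- base_sig + noise
    if (plat == "rnaseq_logcpm") {
      lam <- pmin(2^pm, 1e9)
      cnt <- matrix(stats::rnbinom(np * ns, mu = lam, size = 1 / 0.15), np, ns)
      libsize <- colSums(cnt)
      pm <- log2(t(t(cnt + 0.5) / (libsize + 1)) * 1e6)
      dimnames(pm) <- list(probes$probe, ids)
    }
    expr_cols[[b]] <- pm
    pheno_rows[[b]] <- data.frame(sample = ids, histology = cls, batch = b,
                                  stringsAsFactors = FALSE)
  }
  expr <- do.call(cbind, expr_cols)
  pheno <- do.call(rbind, pheno_rows)
  rownames(pheno) <- NULL

  ann_extra <- probes[probes$mode == "crossmap", c("probe", "partner")]
  annotation <- rbind(
    data.frame(probe = probes$probe, gene = probes$gene,
               stringsAsFactors = FALSE),
    if (nrow(ann_extra))
      data.frame(probe = ann_extra$probe, gene = genes[ann_extra$partner],
                 stringsAsFactors = FALSE)
  )
  annotation <- annotation[order(annotation$probe, annotation$gene), ]
  rownames(annotation) <- NULL

  auroc_pop <- if (n_de > 0)
    stats::pnorm(abs(lfc_cr) / (design$noise_sd * sqrt(2))) else numeric(0)
  truth <- list(
    de_genes = data.frame(gene = genes[de_idx], lfc = lfc_cr,
                          fc = 2^abs(lfc_cr), auroc_pop = auroc_pop,
                          stringsAsFactors = FALSE),
    tumor_genes = genes[tum_idx],
    offsets = off,
    baseline = mu,
    batch_effects = batch_fx,
    good_probe = stats::setNames(sprintf("%s_p1", genes), genes),
    noise_sd = design$noise_sd,
    design = design
  )
  list(expr = expr, pheno = pheno, annotation = annotation, truth = truth)
}

#' Discovery surrogate: five microarray batches, 53 chRCC / 36 RO / 17 N
#'
#' Emulates the five-study discovery meta-dataset (106 arrays) with the
#' default planted world: ~300 chRCC-vs-RO genes at linear fold changes
#' 2-56, per-batch location/scale shifts, multi-probe genes.
#'
#' @param seed master seed.
#' @param ... overrides passed to [study_design()].
#' @return see [generate_study()].
#' @export
generate_discovery_surrogate <- function(seed, ...) {
  generate_study(study_design(.discovery_studies, ...), seed)
}

#' Validation surrogate: one microarray batch (9 chRCC, 9 RO) plus one
#' RNA-seq log-CPM batch (65 chRCC)
#'
#' Shares planted gene-level truth with [generate_discovery_surrogate()]
#' when called with the same seed, so a signature learned on the discovery
#' bundle can be evaluated here. Platform location/scale differences are
#' present before batch correction.
#'
#' @param seed master seed.
#' @param ... overrides passed to [study_design()].
#' @return see [generate_study()].
#' @export
generate_validation_surrogate <- function(seed, ...) {
  arr <- c(chRCC = 9, RO = 9, N = 0)
  seq_ <- c(chRCC = 65, RO = 0, N = 0)
  attr(arr, "platform") <- "array_log2"
  attr(seq_, "platform") <- "rnaseq_logcpm"
  design <- study_design(list(VALARR = arr, VALSEQ = seq_),
                         probes_per_gene = c(1, 1), ...)
  generate_study(design, seed)
}

#' Write a generated bundle to a directory
#'
#' Expression TSV, phenotype CSV, annotation TSV and truth JSON in the
#' dialects of the package's readers.
#'
#' @param bundle output of [generate_study()].
#' @param dir destination directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_expression(bundle$expr, file.path(dir, "expression.tsv"))
  write_phenotype(bundle$pheno, file.path(dir, "phenotype.csv"))
  write_annotation(bundle$annotation, file.path(dir, "annotation.tsv"))
  tr <- bundle$truth
  tr$design <- unclass(tr$design)
  tr$offsets <- NULL # large and reconstructible; keep the serialized truth light
  jsonlite::write_json(tr, file.path(dir, "truth.json"), digits = NA,
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}
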