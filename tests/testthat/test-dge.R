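test_that("moderated t matches its limits and the limma oracle", {
  tc <- make_two_class_expr(n_genes = 300, n_per = 10, delta = 2, seed = 13)

  # d0 = 0: ordinary two-sample t exactly
  d0fit <- moderated_t_test(tc$expr, tc$labels, groups = c("chRCC", "RO"),
                            d0 = 0)
  tt <- apply(tc$expr, 1, function(v)
    stats::t.test(v[tc$labels == "chRCC"], v[tc$labels == "RO"],
                  var.equal = TRUE)$statistic)
  expect_equal(unname(d0fit$table$t), unname(tt), tolerance = 1e-10)

  # d0 -> Inf on equal true variances: approximately the common-variance t
  fitInf <- moderated_t_test(tc$expr, tc$labels, groups = c("chRCC", "RO"),
                             d0 = Inf)
  s2 <- fitInf$s0_2
  tcommon <- (rowMeans(tc$expr[, tc$labels == "chRCC"]) -
                rowMeans(tc$expr[, tc$labels == "RO"])) /
    sqrt(s2 * (2 / 10))
  expect_equal(fitInf$table$t, unname(tcommon), tolerance = 1e-10)
  # estimated d0 is large when variances are truly equal
  est <- moderated_t_test(tc$expr, tc$labels, groups = c("chRCC", "RO"))
  expect_gt(est$d0, 5)
  expect_equal(est$table$t, unname(tcommon), tolerance = 0.15)

  # independent oracle: limma's eBayes, on data with genuinely
  # heterogeneous gene variances so the prior df is finite
  skip_if_not_installed("limma")
  set.seed(55)
  ng <- 400; n <- 24
  sd_g <- sqrt(4 / rchisq(ng, 4))
  x <- matrix(rnorm(ng * n), ng, n) * sd_g + 8
  dimnames(x) <- list(paste0("g", 1:ng), paste0("s", 1:n))
  lab <- rep(c("A", "B"), each = 12)
  mine <- moderated_t_test(x, lab, groups = c("A", "B"))
  fit <- limma::eBayes(limma::lmFit(x, cbind(1, lab == "A")))
  expect_equal(mine$d0, fit$df.prior, tolerance = 1e-8)
  expect_equal(mine$s0_2, fit$s2.prior, tolerance = 1e-8)
  expect_equal(unname(mine$table$t), unname(fit$t[, 2]), tolerance = 1e-10)
  expect_equal(unname(mine$table$p), unname(fit$p.value[, 2]),
               tolerance = 1e-10)
})

test_that("moderated t is monotone in the gene variance", {
  set.seed(14)
  n_per <- 8
  base <- c(rep(1, n_per), rep(0, n_per)) # fixed mean difference 1
  sds <- seq(0.2, 3, length.out = 50)
  noise <- matrix(rnorm(50 * 2 * n_per), 50)
  x <- sweep(noise, 1, sds, "*") + rep(base, each = 50)
  # force identical group means and fixed difference across genes
  x <- x - rowMeans(x[, 1:n_per]) + 1
  x[, (n_per + 1):(2 * n_per)] <-
    x[, (n_per + 1):(2 * n_per), drop = FALSE] -
    rowMeans(x[, (n_per + 1):(2 * n_per), drop = FALSE])
  dimnames(x) <- list(paste0("g", 1:50), paste0("s", 1:16))
  fit <- moderated_t_test(x, rep(c("A", "B"), each = n_per),
                          groups = c("A", "B"))
  v <- .rowvars <- apply(x, 1, var)
  ord <- order(v)
  expect_true(all(diff(abs(fit$table$t[ord])) <= 1e-12))
})

test_that("single gene falls back to ordinary t with a warning", {
  x <- matrix(rnorm(10, 8), 1, 10,
              dimnames = list("g1", paste0("s", 1:10)))
  lab <- rep(c("A", "B"), each = 5)
  expect_warning(fit <- moderated_t_test(x, lab, groups = c("A", "B")),
                 "single gene")
  expect_equal(fit$d0, 0)
})

test_that("BH adjustment equals the brute-force step-up", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(c(0.005, 0.1, 0.9)), c(0.015, 0.15, 0.9))
  expect_equal(bh_adjust(0.37), 0.37)
  expect_error(bh_adjust(c(0.1, 1.2)), "\\[0, 1\\]")
  set.seed(15)
  for (i in 1:50) {
    p <- round(runif(sample(1:40, 1)), sample(1:4, 1))
    expect_identical(bh_adjust(p), oracle_bh(p))
    expect_equal(bh_adjust(p), p.adjust(p, "BH"))
  }
})

test_that("AUROC equals exhaustive pair counting", {
  expect_equal(roc_auc(c(1, 2, 10, 11), rep(c("n", "p"), each = 2), "p"), 1)
  expect_equal(roc_auc(c(3, 5, 1, 2, 4), c("p", "p", "n", "n", "n"), "p"),
               5 / 6)
  expect_equal(roc_auc(rep(7, 10), rep(c("p", "n"), 5), "p"), 0.5)
  expect_error(roc_auc(1:3, rep("p", 3), "p"), "both classes")
  set.seed(16)
  for (i in 1:60) {
    n <- sample(4:30, 1)
    v <- sample(1:10, n, replace = TRUE) # heavy ties
    lab <- c("p", "n", sample(c("p", "n"), n - 2, replace = TRUE))
    expect_equal(roc_auc(v, lab, "p"), oracle_auc(v, lab, "p"))
  }
})

test_that("percentile profile finds the documented optimum", {
  vals <- c(4, 6, 1, 3, 5)
  labs <- c("p", "p", "n", "n", "n")
  pr <- percentile_profile(vals, labs, positive = "p")
  # brute force over all thresholds: accuracy peaks at 0.8, attained for
  # cutpoints in (3, 4] (Youden 2/3) and (5, 6] (Youden 1/2); the Youden
  # tie-break then the smaller-cutpoint rule put the optimum in (3, 4]
  expect_equal(pr$optimum$accuracy, 0.8)
  expect_gt(pr$optimum$cutpoint, 3)
  expect_lte(pr$optimum$cutpoint, 4)
  expect_equal(pr$optimum$youden, 2 / 3, tolerance = 1e-12)
  # argmax contract: optimum accuracy >= accuracy at every percentile
  expect_true(all(pr$optimum$accuracy >= pr$table$accuracy))
  # sens = spec  =>  accuracy equals both for any class weighting
  for (split in list(c(50, 100), c(100, 50), c(200, 50))) {
    vpos <- c(rep(10, round(0.94 * split[1])),
              rep(0, round(0.06 * split[1])))
    vneg <- c(rep(0, round(0.94 * split[2])),
              rep(10, round(0.06 * split[2])))
    m <- cutpoint_metrics(c(vpos, vneg),
                          rep(c("p", "n"), c(split[1], split[2])),
                          cutpoint = 5, positive = "p")
    expect_equal(unname(m["sensitivity"]), 0.94)
    expect_equal(unname(m["specificity"]), 0.94)
    expect_equal(unname(m["accuracy"]), 0.94)
  }
  # perfectly separated gene: all three metrics 1 at the optimum
  sep <- percentile_profile(c(1, 1, 2, 9, 9, 10), rep(c("n", "p"), each = 3))
  expect_equal(sep$optimum$accuracy, 1)
  expect_equal(sep$optimum$sensitivity, 1)
  expect_equal(sep$optimum$specificity, 1)
  expect_equal(sep$auroc, 1)
  # positive class defaults to the higher-mean class
  expect_identical(sep$positive, "p")
  # constant gene flagged degenerate
  flat <- percentile_profile(rep(5, 8), rep(c("p", "n"), 4))
  expect_true(flat$degenerate)
  expect_equal(flat$auroc, 0.5)
})

test_that("the selection cascade nests, ranks and recovers truth", {
  tc <- make_two_class_expr(n_genes = 200, n_per = 20, delta = 5, seed = 17)
  dge <- moderated_t_test(tc$expr, tc$labels, groups = c("chRCC", "RO"))
  prof <- profile_genes(tc$expr, tc$labels)
  casc <- run_cascade(dge, prof, k = 30)
  st <- casc$stages
  expect_true(all(st$significant %in% st$all))
  expect_true(all(st$fold_change %in% st$significant))
  expect_true(all(st$auroc %in% st$fold_change))
  expect_true(all(st$joint %in% st$auroc))
  expect_true(all(st$signature %in% st$joint))
  expect_equal(nrow(casc$signature), 30)
  # planted genes dominate the signature
  planted <- rownames(tc$expr)[tc$de]
  expect_gte(mean(casc$signature$gene %in% planted), 0.9)
  # k larger than the survivor count returns everything with a warning
  expect_warning(big <- run_cascade(dge, prof, k = 5000), "survive")
  expect_equal(nrow(big$signature), length(st$joint))
  # all-zero weights: AUROC then adjusted p ordering
  casc0 <- run_cascade(dge, prof, k = 30,
                       weights = c(fc = 0, breadth = 0, relevance = 0))
  idx <- match(casc0$signature$gene, dge$table$gene)
  key <- order(-casc0$signature$auroc, dge$table$adj_p[idx],
               casc0$signature$gene)
  expect_identical(key, seq_len(30))
})

test_that("signatures apply to new data through cutpoint votes", {
  tc <- make_two_class_expr(n_genes = 200, n_per = 20, delta = 5, seed = 18)
  dge <- moderated_t_test(tc$expr, tc$labels, groups = c("chRCC", "RO"))
  prof <- profile_genes(tc$expr, tc$labels)
  sig <- run_cascade(dge, prof, k = 20)$signature
  # fresh data from the same world
  tc2 <- make_two_class_expr(n_genes = 200, n_per = 15, delta = 5, seed = 99)
  ev <- evaluate_signature(tc2$expr, sig)
  expect_gte(mean(ev$votes$predicted == tc2$labels), 0.95)
  # single-gene signature: votes equal that gene's cutpoint calls
  one <- evaluate_signature(tc2$expr, sig[1, ])
  calls <- ifelse(tc2$expr[sig$gene[1], ] >= sig$optimum_cutpoint[1],
                  sig$positive_class[1], sig$negative_class[1])
  expect_identical(unname(one$votes$predicted), unname(calls))
  # absent genes: listed, and a <50% overlap is an error naming them
  sig_bad <- sig
  sig_bad$gene <- paste0("missing", seq_len(nrow(sig_bad)))
  expect_error(evaluate_signature(tc2$expr, sig_bad), "missing1")
})
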