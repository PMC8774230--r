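test_that("embedding satisfies its shape/determinism/separation contract", {
  tc <- make_two_class_expr(n_genes = 100, n_per = 25, delta = 6)
  p <- umap_params(n_neighbors = 10, gene_count = 100)
  co <- embed_2d(tc$expr, p, seed = 5)
  expect_equal(dim(co), c(50, 2))
  expect_true(all(is.finite(co)))
  expect_identical(rownames(co), colnames(tc$expr))
  expect_identical(co, embed_2d(tc$expr, p, seed = 5))
  labs <- rep(1:2, each = 25)
  expect_gt(separation_score(co, labs), 1)
  expect_error(embed_2d(tc$expr[, 1:8], p), "n_neighbors")
})

test_that("density clustering matches the transitive-closure oracle", {
  bl <- make_blobs(n_per = 10, sep = 20, sd = 0.3)
  got <- cluster_density(bl$coords, eps = 2, min_pts = 5)
  expect_equal(length(unique(got[got != 0])), 2)
  expect_equal(sum(got == 0), 0)
  # random geometries vs oracle (agreement up to label renaming)
  for (s in 1:15) {
    set.seed(s)
    pts <- matrix(rnorm(60, sd = 2), 30, 2)
    eps <- runif(1, 0.5, 2)
    mp <- sample(2:5, 1)
    a <- cluster_density(pts, eps, mp)
    b <- oracle_dbscan(pts, eps, mp)
    expect_identical(a == 0, b == 0)
    for (cl in setdiff(unique(a), 0))
      expect_length(unique(b[a == cl]), 1)
  }
  # no core points -> all noise
  iso <- matrix(c(0, 0, 10, 0, 0, 10, 10, 10), 4, 2, byrow = TRUE)
  expect_equal(cluster_density(iso, eps = 2, min_pts = 5), rep(0L, 4))
  # permutation equivariance
  set.seed(8)
  pts <- rbind(matrix(rnorm(30, 0, .4), 15, 2),
               matrix(rnorm(30, 8, .4), 15, 2))
  perm <- sample(30)
  l1 <- cluster_density(pts, 2, 5)
  l2 <- cluster_density(pts[perm, ], 2, 5)
  expect_identical(l1[perm] == 0, l2 == 0)
  tab <- table(l1[perm], l2)
  expect_true(all(rowSums(tab > 0) <= 1))
})

test_that("elbow eps lands between the intra and inter blob scales", {
  bl <- make_blobs(n_per = 10, sep = 20, sd = 0.3)
  eps <- choose_eps_elbow(bl$coords, min_pts = 5)
  expect_gt(eps, max(dist(bl$coords[1:10, ])) * 0.99 * 0) # positive
  expect_lt(eps, 10)
  expect_gt(eps, 0.05)
  # uniform grid: eps on the order of the spacing
  gr <- as.matrix(expand.grid(1:6, 1:6))
  eg <- choose_eps_elbow(gr, min_pts = 3)
  expect_gt(eg, 0.5); expect_lt(eg, 5)
  expect_error(choose_eps_elbow(matrix(1, 10, 2), 3), "degenerate")
})

test_that("separation score behaves like an inter/intra ratio", {
  # two point masses: intra floor kicks in, score huge
  pm <- rbind(matrix(c(0, 0), 6, 2, byrow = TRUE),
              matrix(c(5, 0), 6, 2, byrow = TRUE))
  s <- separation_score(pm, rep(1:2, each = 6))
  expect_gt(s, 1e6)
  # true labels beat random labels on separable blobs
  bl <- make_blobs(n_per = 15, sep = 10, sd = 0.5, seed = 3)
  set.seed(4)
  s_true <- separation_score(bl$coords, bl$labels)
  s_rand <- separation_score(bl$coords, sample(bl$labels))
  expect_gt(s_true, s_rand)
  # isometry invariance
  th <- 0.7
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  moved <- bl$coords %*% R + 3
  expect_equal(separation_score(moved, bl$labels), s_true, tolerance = 1e-9)
  expect_error(separation_score(bl$coords, rep(1, 30)), "fewer than 2")
})

test_that("grid search enumerates the full grid and returns the argmax", {
  tc <- make_two_class_expr(n_genes = 150, n_per = 12, delta = 5)
  gs <- grid_search(tc$expr, gene_counts = c(50, 150),
                    n_neighbors = c(5, 10), min_dists = c(0.01, 0.5),
                    metrics = c("manhattan", "euclidean"), seed = 2)
  expect_equal(nrow(gs$table), 2 * 2 * 2 * 2)
  best <- gs$table$score[1]
  expect_true(all(is.na(gs$table$score[-1]) |
                    gs$table$score[-1] <= best))
  expect_s3_class(gs$best, "umap_params")
})

test_that("label alignment solves the assignment problem", {
  # permuted labels are recovered exactly
  ref <- c(1, 1, 1, 2, 2, 3, 3, 3)
  swapped <- c(3, 3, 3, 1, 1, 2, 2, 2) # 1->3, 2->1, 3->2
  expect_identical(align_labels(ref, swapped), as.integer(ref))

  # 3x3 contingency [[10,0,1],[0,9,0],[2,0,8]]: diagonal mapping, overlap 27
  ref3 <- c(rep(1, 12), rep(2, 9), rep(3, 9))
  lab3 <- c(rep(1, 10), rep(3, 2), rep(2, 9), rep(1, 1), rep(3, 8))
  tab <- table(lab3, ref3)
  expect_equal(unname(oracle_align_overlap(tab)), 27)
  aligned <- align_labels(ref3, lab3)
  keep <- aligned != 0
  expect_equal(sum(aligned[keep] == ref3[keep]), 27)

  # alignment is invariant to arbitrary relabelling of its input
  relab <- c(5, 9, 7)[lab3]
  expect_identical(align_labels(ref3, relab), aligned)

  # extra cluster beyond the reference gets a fresh id
  ref4 <- c(1, 1, 2, 2, 0, 0)
  lab4 <- c(1, 1, 2, 2, 3, 3)
  out <- align_labels(ref4, lab4)
  expect_identical(out[1:4], c(1L, 1L, 2L, 2L))
  expect_true(all(out[5:6] > 2))

  # noise passes through
  expect_equal(align_labels(c(1, 1, 0), c(2, 2, 0)), c(1L, 1L, 0L))

  # random cases: total overlap equals the brute-force optimum
  for (s in 1:10) {
    set.seed(s)
    r <- sample(1:3, 40, replace = TRUE)
    l <- sample(1:4, 40, replace = TRUE)
    al <- align_labels(r, l)
    expect_equal(sum(al == r & al != 0), oracle_align_overlap(table(l, r)))
  }
})

test_that("plurality voting honors the inclusive 70% threshold", {
  # 7 of 10 counted iterations -> assigned at exactly 0.70
  aligned <- matrix(c(rep(1L, 7), rep(2L, 3)), 10, 1,
                    dimnames = list(NULL, "s1"))
  v <- dbucogs:::.vote_consensus(aligned, threshold = 0.70)
  expect_identical(unname(v$assignment), "1")
  expect_equal(unname(v$support), 0.7)
  # 69% -> ambiguous (69 of 100)
  aligned2 <- matrix(c(rep(1L, 69), rep(2L, 31)), 100, 1,
                     dimnames = list(NULL, "s1"))
  v2 <- dbucogs:::.vote_consensus(aligned2, threshold = 0.70)
  expect_identical(unname(v2$assignment), "ambiguous")
  # noise iterations leave the denominator unless strict
  aligned3 <- matrix(c(rep(1L, 6), rep(0L, 4)), 10, 1,
                     dimnames = list(NULL, "s1"))
  expect_identical(
    unname(dbucogs:::.vote_consensus(aligned3, 0.70)$assignment), "1")
  expect_identical(
    unname(dbucogs:::.vote_consensus(aligned3, 0.70,
                                     strict = TRUE)$assignment), "ambiguous")
})

test_that("the ensemble recovers planted structure deterministically", {
  tc <- make_two_class_expr(n_genes = 200, n_per = 20, delta = 6, seed = 9)
  cfg <- ensemble_config(n_iterations = 8, seed = 77)
  p <- umap_params(n_neighbors = 10, gene_count = 80)
  cons <- run_ensemble(tc$expr, p, list(eps = "elbow", min_pts = 5), cfg)
  expect_s3_class(cons, "dbu_consensus")
  expect_identical(cons,
                   run_ensemble(tc$expr, p, list(eps = "elbow", min_pts = 5),
                                cfg))
  # support invariants hold on every run
  expect_true(all(cons$support >= 0 & cons$support <= 1))
  assigned <- cons$assignment != "ambiguous"
  expect_true(all(cons$support[assigned] >= cons$threshold))
  # unanimity on clean data: everything assigned with support 1
  expect_true(all(cons$support == 1))
  expect_true(all(assigned))
  # co-clustering matrix: symmetric, unit diagonal, in [0,1]
  expect_equal(cons$coclust, t(cons$coclust))
  expect_equal(unname(diag(cons$coclust)), rep(1, 40))
  expect_true(all(cons$coclust >= 0 & cons$coclust <= 1))
  # the two planted classes never co-cluster here
  expect_lt(max(cons$coclust[1:20, 21:40]), 0.5)
  expect_error(run_ensemble(tc$expr, umap_params(gene_count = 10000)),
               "gene_count")
})

test_that("concordance maps groups to histology and scores accuracy", {
  # perfect 53/36 recovery
  ph <- data.frame(sample = sprintf("s%03d", 1:89),
                   histology = rep(c("chRCC", "RO"), c(53, 36)),
                   batch = "A")
  mk <- function(assign) structure(list(assignment = assign),
                                   class = "dbu_consensus")
  a <- setNames(rep(c("1", "2"), c(53, 36)), ph$sample)
  expect_equal(concordance(mk(a), ph)$accuracy, 1.0)
  # swapping group ids changes nothing
  a2 <- setNames(rep(c("2", "1"), c(53, 36)), ph$sample)
  expect_equal(concordance(mk(a2), ph)$accuracy, 1.0)
  # 87 of 89 concordant
  a3 <- a; a3[1:2] <- "2"
  cc <- concordance(mk(a3), ph)
  expect_equal(cc$accuracy, 87 / 89, tolerance = 1e-12)
  expect_equal(round(cc$accuracy, 4), 0.9775)
  # ambiguous samples are excluded from accuracy but reported
  a4 <- a; a4[1:9] <- "ambiguous"
  cc4 <- concordance(mk(a4), ph)
  expect_equal(cc4$accuracy, 1.0)
  expect_equal(cc4$ambiguous_rate, 9 / 89)
})

test_that("hierarchical clustering uses correlation distance and 2-cuts", {
  set.seed(6)
  x <- matrix(rnorm(200, 8), 20, 10,
              dimnames = list(paste0("g", 1:20), paste0("s", 1:10)))
  x[, 6:10] <- x[, 6:10] + rep(c(4, -4), each = 10)
  x[, 2] <- x[, 1] # duplicated sample
  hc <- hierarchical_cluster(x)
  expect_equal(min(hc$hclust$height), 0, tolerance = 1e-12)
  first <- hc$hclust$merge[1, ]
  expect_setequal(abs(first), c(1, 2))
  expect_equal(length(unique(hc$labels)), 2)
  # sample-order invariance of the 2-cut partition
  perm <- sample(10)
  hc2 <- hierarchical_cluster(x[, perm])
  tab <- table(hc$labels[perm], hc2$labels)
  expect_true(all(rowSums(tab > 0) == 1))
  # constant profile rejected by name
  bad <- x; bad[, 3] <- 7
  expect_error(hierarchical_cluster(bad), "s3")
})
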