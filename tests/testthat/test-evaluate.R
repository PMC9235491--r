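# Region aggregation, ROC, DE baselines, probes, enrichment.

test_that("region aggregation sums mapped types and renormalizes", {
  map <- c(t1 = "A", t2 = "A", t3 = "B", t4 = "B")
  p <- setNames(c(0.1, 0.2, 0.3, 0.4), names(map))
  expect_equal(aggregate_to_regions(p, map), c(A = 0.3, B = 0.7))

  map3 <- c(t1 = "A", t2 = "A", t3 = "B")  # t4 unmapped
  expect_equal(aggregate_to_regions(p, map3), c(A = 0.5, B = 0.5))

  ident <- c(t1 = "r1", t2 = "r2", t3 = "r3", t4 = "r4")
  expect_equal(unname(aggregate_to_regions(p, ident)), unname(p))

  only_unmapped <- setNames(c(0, 0, 0, 1), names(map))
  expect_error(aggregate_to_regions(only_unmapped, map3), "unmapped")
})

test_that("aggregation conserves mapped mass before renormalization", {
  set.seed(60)
  map <- c(t1 = "A", t2 = "A", t3 = "B", t4 = "C")  # t5 unmapped
  for (rep in 1:10) {
    p <- as.numeric(random_simplex(1, 5))
    names(p) <- paste0("t", 1:5)
    agg <- aggregate_to_regions(p, map)
    mapped_mass <- sum(p[names(map)])
    expect_equal(sum(agg) * mapped_mass, mapped_mass, tolerance = 1e-12)
    expect_equal(unname(agg["A"]) * mapped_mass, p[["t1"]] + p[["t2"]],
                 tolerance = 1e-12)
  }
})

test_that("gene-level predictions are elementwise means on the simplex", {
  tb <- tibble::tibble(gene = c("g1", "g1", "g2"),
                       A = c(1, 0, 0.5), B = c(0, 1, 0.5))
  out <- gene_level_prediction(tb)
  expect_equal(out$A[out$gene == "g1"], 0.5)
  expect_equal(out$A[out$gene == "g2"], 0.5)   # single image: identity
  expect_equal(out$A + out$B, rep(1, 2))
  rep3 <- tibble::tibble(gene = "g", A = rep(0.2, 3), B = rep(0.8, 3))
  expect_equal(gene_level_prediction(rep3)$B, 0.8)
  expect_error(gene_level_prediction(tb[0, ]), "no image")
})

test_that("ROC recovers perfect separation and chance behavior", {
  scores <- tibble::tibble(gene = paste0("g", 1:6),
                           A = c(0.9, 0.8, 0.7, 0.2, 0.1, 0.3),
                           B = c(0.1, 0.2, 0.3, 0.8, 0.9, 0.7))
  truth <- tibble::tibble(gene = paste0("g", 1:6),
                          region = rep(c("A", "B"), each = 3))
  roc <- ovr_roc(scores, truth)
  expect_equal(roc$auc$auc, c(1, 1))

  set.seed(61)
  n <- 2000L
  rnd <- tibble::tibble(gene = paste0("g", 1:n), A = runif(n), B = runif(n))
  rtruth <- tibble::tibble(gene = rnd$gene,
                           region = sample(c("A", "B"), n, replace = TRUE))
  rroc <- ovr_roc(rnd, rtruth)
  expect_true(all(abs(rroc$auc$auc - 0.5) < 0.05))
})

test_that("AUC with ties equals the pair-counting oracle", {
  # 4-gene toy case with one tied score
  s <- c(0.9, 0.5, 0.5, 0.1)
  lab <- c(TRUE, TRUE, FALSE, FALSE)
  scores <- tibble::tibble(gene = paste0("g", 1:4), A = s)
  truth <- tibble::tibble(gene = scores$gene,
                          region = ifelse(lab, "A", "other"))
  roc <- ovr_roc(scores, truth)
  expect_equal(roc$auc$auc, oracle_auc_paircount(s, lab))  # 0.875
  expect_equal(roc$auc$auc, 0.875)

  set.seed(62)
  for (rep in 1:10) {
    s2 <- sample(seq(0, 1, by = 0.25), 8, replace = TRUE)
    l2 <- sample(c(TRUE, FALSE), 8, replace = TRUE)
    if (sum(l2) == 0 || sum(!l2) == 0) next
    sc <- tibble::tibble(gene = paste0("g", 1:8), A = s2)
    tr <- tibble::tibble(gene = sc$gene, region = ifelse(l2, "A", "z"))
    expect_equal(ovr_roc(sc, tr)$auc$auc, oracle_auc_paircount(s2, l2))
  }
})

test_that("AUC is invariant under strictly monotone score transforms", {
  set.seed(63)
  s <- rnorm(30)
  lab <- sample(c(TRUE, FALSE), 30, replace = TRUE, prob = c(0.4, 0.6))
  sc1 <- tibble::tibble(gene = paste0("g", 1:30), A = s)
  sc2 <- tibble::tibble(gene = sc1$gene, A = exp(2 * s) + 5)
  tr <- tibble::tibble(gene = sc1$gene, region = ifelse(lab, "A", "z"))
  expect_equal(ovr_roc(sc1, tr)$auc$auc, ovr_roc(sc2, tr)$auc$auc)
})

test_that("degenerate label sets skip the region with a warning", {
  sc <- tibble::tibble(gene = paste0("g", 1:3), A = c(1, 2, 3))
  tr <- tibble::tibble(gene = sc$gene, region = "A")
  expect_warning(roc <- ovr_roc(sc, tr), "skipped")
  expect_equal(nrow(roc$auc), 0L)
})

test_that("Welch t on a 6-value fixture matches the closed form", {
  x <- c(10.2, 9.8, 10.5)   # type-k cells
  y <- c(1.1, 0.7, 1.6)     # the rest
  X <- matrix(c(x, y), ncol = 1)
  expr <- expression_dataset(X, rep(c("k", "rest"), each = 3), "g1")
  stat <- ovr_de_statistics(expr, "t_test")
  expect_equal(stat["g1", "k"], oracle_welch_t(x, y), tolerance = 1e-9)
  expect_equal(stat["g1", "rest"], -stat["g1", "k"], tolerance = 1e-9)
  expect_equal(stat["g1", "k"], unname(t.test(x, y)$statistic),
               tolerance = 1e-9)
})

test_that("constant genes score zero in both tests", {
  X <- cbind(rep(5, 8), rnorm(8))
  expr <- expression_dataset(X, rep(c("a", "b"), each = 4), c("flat", "var"))
  tt <- suppressWarnings(ovr_de_statistics(expr, "t_test"))
  expect_equal(unname(tt["flat", ]), c(0, 0))
  wz <- ovr_de_statistics(expr, "wilcoxon")
  expect_equal(unname(wz["flat", ]), c(0, 0))
})

test_that("a strongly marker-like gene is maximal in its own type", {
  set.seed(64)
  types <- rep(c("a", "b", "c"), each = 10)
  x <- ifelse(types == "b", 10, 0) + rnorm(30, sd = 0.01)
  expr <- expression_dataset(cbind(g = x), types, "g")
  for (m in c("t_test", "wilcoxon")) {
    stat <- ovr_de_statistics(expr, m)
    expect_equal(colnames(stat)[which.max(stat["g", ])], "b")
  }
})

test_that("wilcoxon z matches the normal approximation with tie correction", {
  set.seed(65)
  x <- c(1, 2, 2, 3, 5, 5, 5, 8)
  types <- c("a", "a", "a", "a", "b", "b", "b", "b")
  expr <- expression_dataset(cbind(g = x), types, "g")
  z <- ovr_de_statistics(expr, "wilcoxon")["g", "a"]
  # independent computation from first principles
  r <- rank(x)
  U <- sum(r[types == "a"]) - 4 * 5 / 2
  ties <- table(x)
  sig2 <- (4 * 4 / 12) * ((8 + 1) - sum(ties^3 - ties) / (8 * 7))
  expect_equal(z, (U - 8) / sqrt(sig2), tolerance = 1e-12)
})

test_that("region scores take the max statistic over mapped types", {
  stat_expr <- expression_dataset(
    cbind(g1 = c(10, 10, 0, 0, 0, 0) + rnorm(6, sd = 0.01)),
    c("t1", "t1", "t2", "t2", "t3", "t3"), "g1"
  )
  map <- c(t1 = "A", t2 = "A", t3 = "B")
  sc <- de_baseline_scores(stat_expr, "t_test", map)
  st <- ovr_de_statistics(stat_expr, "t_test")
  expect_equal(sc$A, max(st["g1", c("t1", "t2")]))
  expect_equal(sc$B, st[["g1", "t3"]])
})

test_that("donor probe recovers an explicit donor code and not noise", {
  set.seed(66)
  donors <- rep(paste0("d", 1:4), each = 30)
  H <- diag(4)[rep(1:4, each = 30), ] + matrix(rnorm(480, sd = 0.05),
                                               ncol = 4)
  expect_gte(donor_probe(H, donors, seed = 1), 0.99)

  noise <- matrix(rnorm(2000 * 8), 2000, 8)
  nd <- rep(paste0("d", 1:4), each = 500)
  acc <- donor_probe(noise, nd, seed = 1)
  expect_lt(abs(acc - 0.25), 0.04)

  expect_error(donor_probe(H, rep("d1", 120)), "2 classes")
  expect_error(linear_probe(H[1:8, ], c(rep("a", 6), "b", "b"), folds = 5L),
               "fewer folds")
})

test_that("hypergeometric enrichment matches closed forms and the pmf oracle", {
  universe <- paste0("g", 1:10)
  annotated <- universe[1:5]
  cluster <- universe[1:4]
  expect_equal(cluster_enrichment(cluster, annotated, universe), 5 / 210,
               tolerance = 1e-12)
  # empty overlap: upper tail from 0 is exactly 1
  expect_equal(cluster_enrichment(universe[6:7], annotated, universe), 1)
  expect_error(cluster_enrichment(c("zz"), annotated, universe), "subset")

  set.seed(67)
  for (rep in 1:50) {
    N <- sample(20:200, 1)
    uni <- paste0("u", seq_len(N))
    ann <- sample(uni, sample(1:(N - 1), 1))
    clu <- sample(uni, sample(1:(N - 1), 1))
    k <- length(intersect(clu, ann))
    expect_equal(cluster_enrichment(clu, ann, uni),
                 oracle_hyper_upper(k, length(ann), N, length(clu)),
                 tolerance = 1e-12)
  }
})

test_that("BH adjustment is applied across an enrichment table", {
  p <- c(0.001, 0.01, 0.04, 0.2)
  expect_equal(adjust_enrichment(p), p.adjust(p, "BH"))
})
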