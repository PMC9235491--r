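# Specificity vectors and the soft-label linear classifier.

test_that("mean expression by type matches hand-computed averages", {
  # 3 cells (2 of type A, 1 of type B) x 2 genes
  X <- matrix(c(2, 4, 6,
                1, 3, 5), ncol = 2,
              dimnames = list(NULL, NULL))
  expr <- expression_dataset(X, c("A", "A", "B"), c("g1", "g2"))
  m <- mean_expression_by_type(expr)
  expect_equal(m["g1", "A"], 3)   # mean of 2, 4
  expect_equal(m["g1", "B"], 6)
  expect_equal(m["g2", "A"], 2)   # mean of 1, 3
  expect_equal(m["g2", "B"], 5)

  const <- expression_dataset(matrix(7, 4, 2), c("A", "A", "B", "B"),
                              c("g1", "g2"))
  expect_true(all(mean_expression_by_type(const) == 7))
})

test_that("a cell type with zero cells is reported by name", {
  X <- matrix(1, 2, 1)
  expect_error(expression_dataset(X, c("A", NA), "g1"), "labeled")
})

test_that("specificity vectors are simplex-normalized rows", {
  m <- rbind(g1 = c(1, 1, 1, 1), g2 = c(2, 1, 1, 0), g3 = c(0, 0, 5, 0))
  y <- suppressWarnings(build_specificity(m))
  expect_equal(unname(y["g1", ]), rep(0.25, 4))
  expect_equal(unname(y["g2", ]), c(0.5, 0.25, 0.25, 0))
  expect_equal(unname(y["g3", ]), c(0, 0, 1, 0))  # one-hot fixed point
  expect_equal(rowSums(y), setNames(rep(1, 3), rownames(y)), tolerance = 1e-9)
})

test_that("all-zero expression rows are dropped with a warning", {
  m <- rbind(g1 = c(1, 2), g2 = c(0, 0))
  expect_warning(y <- build_specificity(m), "all-zero")
  expect_equal(rownames(y), "g1")
  expect_equal(attr(y, "dropped"), "g2")
})

test_that("K = 1 gives an exactly zero loss for any weights", {
  H <- matrix(rnorm(10 * 3), 10, 3)
  Y <- matrix(1, 10, 1)
  clf <- fit_soft_label_classifier(H, Y, epochs = 5L)
  expect_equal(tail(clf$loss_history, 1L), 0)
})

test_that("loss at zero weights with uniform targets is exactly N log K", {
  set.seed(50)
  N <- 17L; D <- 6L; K <- 5L
  H <- matrix(rnorm(N * D), N, D)
  A <- matrix(0, D, K)
  Y <- matrix(1 / K, N, K)
  expect_equal(ihcontrast:::soft_label_loss(H, A, Y), N * log(K))
})

test_that("analytic gradient matches central finite differences", {
  set.seed(51)
  H <- matrix(rnorm(8 * 4), 8, 4)
  Y <- random_simplex(8, 3)
  A <- matrix(rnorm(12, sd = 0.5), 4, 3)
  expect_equal(ihcontrast:::soft_label_grad(H, A, Y),
               oracle_fd_grad(H, A, Y), tolerance = 1e-6)
})

test_that("separable one-hot targets are fit to near-perfect accuracy", {
  set.seed(52)
  n <- 60L
  H <- rbind(cbind(rnorm(n, 3), rnorm(n, 0)),
             cbind(rnorm(n, -3), rnorm(n, 0)))
  Y <- rbind(matrix(rep(c(1, 0), each = n), ncol = 2),
             matrix(rep(c(0, 1), each = n), ncol = 2))
  clf <- fit_soft_label_classifier(H, Y, epochs = 300L)
  acc <- mean(max.col(predict_cell_types(H, clf)) == max.col(Y))
  expect_gte(acc, 0.99)
  # training loss near-monotone: final far below initial
  expect_lt(tail(clf$loss_history, 1), clf$loss_history[1] / 2)
})

test_that("predictions live on the simplex and are shift-invariant", {
  set.seed(53)
  H <- matrix(rnorm(20 * 5), 20, 5)
  A <- matrix(rnorm(5 * 4), 5, 4)
  P <- predict_cell_types(H, A)
  expect_equal(rowSums(P), rep(1, 20), tolerance = 1e-6)
  expect_true(all(P > 0))
  expect_equal(predict_cell_types(H, A),
               predict_cell_types(H, A + 100), tolerance = 1e-9)
  expect_equal(unname(predict_cell_types(matrix(rnorm(5), 1),
                                         matrix(0, 5, 4))[1, ]),
               rep(0.25, 4))
})

test_that("planted types are recovered from noisy one-hot embeddings", {
  set.seed(54)
  K <- 4L; n_per <- 40L
  types <- rep(seq_len(K), each = n_per)
  H <- diag(K)[types, ] + matrix(rnorm(K * n_per * K, sd = 0.1), ncol = K)
  Y <- diag(K)[types, ]
  tr_idx <- unlist(lapply(split(seq_along(types), types), head, 30L))
  clf <- fit_soft_label_classifier(H[tr_idx, ], Y[tr_idx, ], epochs = 300L)
  held <- setdiff(seq_along(types), tr_idx)
  acc <- mean(max.col(predict_cell_types(H[held, ], clf)) == types[held])
  expect_gte(acc, 0.9)
})

test_that("target matching drops unmatched and held-out genes", {
  emb <- tibble::tibble(image_id = paste0("i", 1:4),
                        gene = c("g1", "g1", "g2", "g3"),
                        donor = "d1", e1 = rnorm(4), e2 = rnorm(4))
  spec <- rbind(g1 = c(0.5, 0.5), g2 = c(1, 0))
  colnames(spec) <- c("A", "B")
  expect_message(tr <- match_specificity_targets(emb, spec), "dropped")
  expect_equal(tr$genes, c("g1", "g1", "g2"))
  expect_equal(nrow(tr$H), 3L)
  tr2 <- suppressMessages(match_specificity_targets(emb, spec,
                                                    holdout_genes = "g2"))
  expect_equal(tr2$genes, c("g1", "g1"))
})

test_that("expression MTX triplet round-trips through the reader", {
  fx <- cached_fixture("tiny")
  expr <- read_expression_mtx(fx$paths$expr)
  expect_equal(expr$gene_names, fx$expr$gene_names)
  expect_equal(expr$cell_types, fx$expr$cell_types)
  expect_equal(as.matrix(expr$matrix), unname(fx$expr$matrix),
               tolerance = 1e-6, ignore_attr = TRUE)
  expect_error(read_expression_mtx(tempdir()), "missing expression")
})
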