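# Cross-modal label transfer: per-gene cell-type specificity vectors from a
# labeled expression matrix, and the soft-label linear classifier that maps
# image embeddings h to predicted cell-type probabilities.
#
# The specificity vector of gene g is its mean expression per cell type,
# normalized onto the K-simplex. The classifier minimizes the soft-label
# cross-entropy  -sum_i y_{g(i)}' log softmax(h_i' A)  over A in R^{D x K}
# (no intercept), by Adam on the analytic gradient H' (softmax(H A) - Y).

#' Construct an expression dataset
#'
#' @param matrix cells x genes matrix of non-negative expression values
#'   (dense or `Matrix` sparse). Values are used exactly as provided: any
#'   normalization or log transform is the caller's upstream choice.
#' @param cell_types per-cell label, length `nrow(matrix)`.
#' @param gene_names unique per-column identifiers, length `ncol(matrix)`.
#' @return an `expression_dataset` list.
#' @export
expression_dataset <- function(matrix, cell_types, gene_names) {
  if (length(cell_types) != nrow(matrix)) {
    stopf("cell_types length %d != number of cells %d",
          length(cell_types), nrow(matrix))
  }
  if (length(gene_names) != ncol(matrix)) {
    stopf("gene_names length %d != number of genes %d",
          length(gene_names), ncol(matrix))
  }
  if (anyDuplicated(gene_names)) stopf("gene names must be unique")
  if (anyNA(cell_types)) stopf("every cell must be labeled")
  colnames(matrix) <- gene_names
  structure(list(matrix = matrix, cell_types = as.character(cell_types),
                 gene_names = as.character(gene_names)),
            class = "expression_dataset")
}

#' Read an MTX-triplet expression dataset
#'
#' Expects `matrix.mtx` (cells x genes or genes x cells, oriented by matching
#' the side lengths against the annotation files), `genes.tsv` (one gene per
#' line), `barcodes.tsv`, and `cell_types.tsv` (barcode TAB label, with or
#' without header).
#'
#' @param dir directory holding the four files.
#' @return an [expression_dataset()].
#' @export
read_expression_mtx <- function(dir) {
  need <- c("matrix.mtx", "genes.tsv", "barcodes.tsv", "cell_types.tsv")
  paths <- file.path(dir, need)
  miss <- need[!file.exists(paths)]
  if (length(miss) > 0) stopf("missing expression file(s): %s",
                              paste(miss, collapse = ", "))
  m <- Matrix::readMM(paths[1])
  genes <- readLines(paths[2])
  barcodes <- readLines(paths[3])
  if (nrow(m) == length(genes) && ncol(m) == length(barcodes)) {
    m <- Matrix::t(m)  # stored genes x cells; we use cells x genes
  } else if (!(nrow(m) == length(barcodes) && ncol(m) == length(genes))) {
    stopf("matrix dimensions %dx%d match neither genes (%d) nor barcodes (%d)",
          nrow(m), ncol(m), length(genes), length(barcodes))
  }
  ct <- readr::read_tsv(paths[4], col_names = c("barcode", "cell_type"),
                        show_col_types = FALSE, progress = FALSE)
  if (identical(unname(unlist(ct[1, ])), c("barcode", "cell_type"))) {
    ct <- ct[-1, ]
  }
  lab <- setNames(ct$cell_type, ct$barcode)[barcodes]
  if (anyNA(lab)) stopf("cell_types.tsv lacks labels for %d barcode(s)",
                        sum(is.na(lab)))
  expression_dataset(m, unname(lab), genes)
}

#' Mean expression per cell type
#'
#' @param expr an [expression_dataset()]; every cell type must have at least
#'   one cell.
#' @return genes x K numeric matrix; entry (g, k) is the arithmetic mean of
#'   gene g across the cells labeled k. Columns are sorted type names.
#' @export
mean_expression_by_type <- function(expr) {
  stopifnot(inherits(expr, "expression_dataset"))
  types <- sort(unique(expr$cell_types))
  counts <- table(factor(expr$cell_types, levels = types))
  if (any(counts == 0)) {
    stopf("cell type with zero cells: %s",
          paste(names(counts)[counts == 0], collapse = ", "))
  }
  ind <- Matrix::sparseMatrix(
    i = seq_along(expr$cell_types),
    j = match(expr$cell_types, types),
    x = 1, dims = c(length(expr$cell_types), length(types))
  )
  ind <- ind %*% Matrix::Diagonal(x = 1 / as.numeric(counts))
  means <- as.matrix(Matrix::t(ind) %*% expr$matrix)   # K x genes
  out <- t(means)
  dimnames(out) <- list(expr$gene_names, types)
  out
}

#' Normalize per-gene mean expression onto the simplex
#'
#' Each row of the mean-expression matrix is divided by its sum, producing a
#' specificity vector on the K-simplex. Genes with all-zero rows carry no
#' label signal and are dropped with a warning.
#'
#' @param mean_matrix genes x K non-negative matrix from
#'   [mean_expression_by_type()] (a single named vector is treated as one
#'   row).
#' @return genes x K matrix whose rows are non-negative and sum to 1; dropped
#'   genes are recorded in the `dropped` attribute.
#' @export
build_specificity <- function(mean_matrix) {
  if (is.null(dim(mean_matrix))) mean_matrix <- t(as.matrix(mean_matrix))
  if (any(mean_matrix < 0)) stopf("mean expression must be non-negative")
  rs <- rowSums(mean_matrix)
  zero <- rs == 0
  if (any(zero)) {
    warnf("dropping %d gene(s) with all-zero expression", sum(zero))
  }
  out <- mean_matrix[!zero, , drop = FALSE] / rs[!zero]
  attr(out, "dropped") <- rownames(mean_matrix)[zero] %||% which(zero)
  out
}

# Soft-label cross-entropy and its analytic gradient.
soft_label_loss <- function(H, A, Y) {
  P <- softmax_rows(H %*% A)
  -sum(Y * log(pmax(P, 1e-300)))
}

soft_label_grad <- function(H, A, Y) {
  P <- softmax_rows(H %*% A)
  t(H) %*% (P - Y)
}

#' Fit the soft-label linear classifier
#'
#' Minimizes `-sum_i y_i' log softmax(h_i' A)` over the `D x K` weight matrix
#' `A` (no intercept) with Adam on the analytic gradient
#' `H' (softmax(HA) - Y)`. Defaults follow the reference setup: learning rate
#' 0.01 for 1000 epochs (full-batch).
#'
#' @param H `N x D` embedding matrix (finite values).
#' @param Y `N x K` soft-target matrix; every row on the simplex. Targets are
#'   assigned per image from the specificity vector of that image's gene.
#' @param learning_rate Adam step size.
#' @param epochs full-batch gradient steps.
#' @return an `ihc_classifier` with weights `A` (`D x K`, column names taken
#'   from `Y`) and `loss_history`.
#' @export
fit_soft_label_classifier <- function(H, Y, learning_rate = 0.01,
                                      epochs = 1000L) {
  H <- as.matrix(H); Y <- as.matrix(Y)
  if (nrow(H) != nrow(Y)) stopf("H has %d rows but Y has %d", nrow(H), nrow(Y))
  assert_finite(H, "embeddings H")
  if (any(Y < 0) || any(abs(rowSums(Y) - 1) > 1e-6)) {
    stopf("every row of Y must lie on the simplex")
  }
  D <- ncol(H); K <- ncol(Y)
  A <- matrix(0, D, K)
  state <- adam_init(list(A = A))
  history <- numeric(epochs)
  for (t in seq_len(epochs)) {
    g <- soft_label_grad(H, A, Y)
    upd <- adam_step(list(A = A), list(A = g), state, learning_rate, t)
    A <- upd$p$A
    state <- upd$s
    history[t] <- soft_label_loss(H, A, Y)
  }
  colnames(A) <- colnames(Y)
  structure(list(A = A, loss_history = history, n_train = nrow(H)),
            class = "ihc_classifier")
}

#' Predict cell-type probabilities from embeddings
#'
#' @param H `N x D` embedding matrix (or a single D-vector).
#' @param classifier an `ihc_classifier` (or a bare `D x K` weight matrix).
#' @return `N x K` matrix of softmax probabilities; each row positive,
#'   summing to 1.
#' @export
predict_cell_types <- function(H, classifier) {
  A <- if (inherits(classifier, "ihc_classifier")) classifier$A else classifier
  if (is.null(dim(H))) H <- matrix(H, nrow = 1L)
  P <- softmax_rows(as.matrix(H) %*% A)
  colnames(P) <- colnames(A)
  P
}

#' Per-image specificity targets for classifier training
#'
#' Joins image embeddings to per-gene specificity vectors by exact
#' (case-sensitive) gene name, dropping images of genes absent from the
#' specificity matrix and, optionally, of held-out genes.
#'
#' @param embeddings tibble from [embed_corpus()].
#' @param specificity genes x K matrix from [build_specificity()].
#' @param holdout_genes character vector of genes to exclude from training
#'   (e.g. an evaluation marker list).
#' @return list with `H` (matched embedding matrix), `Y` (matched targets),
#'   `genes` (per-row gene), `n_dropped` (images without a specificity row).
#' @export
match_specificity_targets <- function(embeddings, specificity,
                                      holdout_genes = character(0)) {
  keep <- embeddings$gene %in% rownames(specificity) &
    !(embeddings$gene %in% holdout_genes)
  n_dropped <- sum(!keep & !(embeddings$gene %in% holdout_genes))
  if (n_dropped > 0) {
    message(sprintf("%d image(s) dropped: gene not in specificity matrix",
                    n_dropped))
  }
  emb <- embeddings[keep, , drop = FALSE]
  list(H = embedding_matrix(emb),
       Y = specificity[emb$gene, , drop = FALSE],
       genes = emb$gene, n_dropped = n_dropped)
}

#' @export
print.ihc_classifier <- function(x, ...) {
  cat(sprintf("<ihc_classifier> D=%d, K=%d, trained on %d images, loss %.4f\n",
              nrow(x$A), ncol(x$A), x$n_train, tail(x$loss_history, 1L)))
  invisible(x)
}

#' @export
tidy.ihc_classifier <- function(x, ...) {
  A <- x$A
  if (is.null(colnames(A))) colnames(A) <- paste0("k", seq_len(ncol(A)))
  as_tibble(A) |>
    mutate(dimension = seq_len(nrow(A)), .before = 1L) |>
    tidyr::pivot_longer(-"dimension", names_to = "cell_type",
                        values_to = "weight")
}

#' @export
glance.ihc_classifier <- function(x, ...) {
  tibble(n_train = x$n_train, d = nrow(x$A), k = ncol(x$A),
         epochs = length(x$loss_history),
         final_loss = tail(x$loss_history, 1L))
}
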