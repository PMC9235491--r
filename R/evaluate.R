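# Region-level evaluation battery: cell-type -> region aggregation,
# gene-level averaging, one-vs-rest ROC, transcriptomic differential-
# expression baselines (max over the region's cell types), the donor-
# invariance probe, and hypergeometric cluster enrichment.

#' Read a cell-type to region map
#'
#' @param path TSV with columns `cell_type`, `region`. Types absent from the
#'   file are unmapped (their probability mass is renormalized away during
#'   aggregation, the treatment given to types such as leukocytes and
#'   fibroblasts that span regions).
#' @return named character vector `cell_type -> region`.
#' @export
read_region_map <- function(path) {
  tb <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("cell_type", "region") %in% names(tb))) {
    stopf("region map must have columns cell_type, region")
  }
  if (anyDuplicated(tb$cell_type)) {
    stopf("each cell type must map to exactly one region")
  }
  setNames(tb$region, tb$cell_type)
}

#' Aggregate cell-type probabilities to anatomical regions
#'
#' Region r receives the summed probability of all cell types mapped to it;
#' the result is renormalized to sum 1 (a no-op unless unmapped types carry
#' mass).
#'
#' @param cell_probs simplex vector named by cell type, or an `N x K` matrix
#'   with cell-type column names (rows on the simplex).
#' @param region_map named character vector from [read_region_map()] (or a
#'   data frame with `cell_type`, `region`).
#' @return matrix `N x R` (or vector for vector input) on the simplex;
#'   columns are sorted region names.
#' @export
aggregate_to_regions <- function(cell_probs, region_map) {
  if (is.data.frame(region_map)) {
    region_map <- setNames(region_map$region, region_map$cell_type)
  }
  vec_in <- is.null(dim(cell_probs))
  P <- if (vec_in) t(as.matrix(cell_probs)) else as.matrix(cell_probs)
  if (is.null(colnames(P))) stopf("cell_probs must carry cell-type names")
  regions <- sort(unique(unname(region_map)))
  Agg <- matrix(0, nrow(P), length(regions),
                dimnames = list(rownames(P), regions))
  mapped <- intersect(colnames(P), names(region_map))
  for (ct in mapped) {
    r <- region_map[[ct]]
    Agg[, r] <- Agg[, r] + P[, ct]
  }
  tot <- rowSums(Agg)
  if (any(tot <= 0)) {
    stopf("all probability mass on unmapped cell types for %d row(s)",
          sum(tot <= 0))
  }
  Agg <- Agg / tot
  if (vec_in) Agg[1, ] else Agg
}

#' Average per-image region vectors into gene-level predictions
#'
#' Ground truth is defined per gene, not per image, so the per-image region
#' probability vectors of each gene are averaged elementwise (the mean of
#' simplex vectors stays on the simplex).
#'
#' @param image_regions tibble with a `gene` column and one numeric column
#'   per region (one row per image).
#' @return tibble with one row per gene and the same region columns.
#' @export
gene_level_prediction <- function(image_regions) {
  if (nrow(image_regions) == 0L) stopf("no image-level predictions supplied")
  image_regions |>
    group_by(.data$gene) |>
    summarise(across(dplyr::where(is.numeric), mean), .groups = "drop")
}

#' One-versus-rest ROC per region
#'
#' For each region r, genes labeled r are positives and all other labeled
#' genes negatives; the region-r score column is the predictor. Curves and
#' AUC come from the empirical ROC with thresholds at distinct score values,
#' so the AUC equals the Mann-Whitney pair-counting value (ties contribute
#' one half).
#'
#' @param scores tibble with `gene` plus one numeric score column per region.
#' @param truth tibble with `gene`, `region` (one label per gene).
#' @return an `ihc_roc` list: `auc` tibble (`region`, `auc`, `n_pos`,
#'   `n_neg`) and `curves` tibble (`region`, `fpr`, `tpr`). Regions with no
#'   positives or no negatives are skipped with a warning.
#' @export
ovr_roc <- function(scores, truth) {
  stopifnot(is.data.frame(scores), all(c("gene", "region") %in% names(truth)))
  scores <- scores[scores$gene %in% truth$gene, , drop = FALSE]
  lab <- setNames(truth$region, truth$gene)[scores$gene]
  regions <- setdiff(names(scores), "gene")
  aucs <- list(); curves <- list()
  for (r in regions) {
    y <- lab == r
    if (sum(y) == 0L || sum(!y) == 0L) {
      warnf("region '%s' lacks positives or negatives; skipped", r)
      next
    }
    rr <- pROC::roc(response = y, predictor = scores[[r]],
                    levels = c(FALSE, TRUE), direction = "<", quiet = TRUE)
    aucs[[r]] <- tibble(region = r, auc = as.numeric(pROC::auc(rr)),
                        n_pos = sum(y), n_neg = sum(!y))
    curves[[r]] <- tibble(region = r,
                          fpr = rev(1 - rr$specificities),
                          tpr = rev(rr$sensitivities))
  }
  structure(list(auc = bind_rows(aucs), curves = bind_rows(curves)),
            class = "ihc_roc")
}

#' @export
print.ihc_roc <- function(x, ...) {
  cat("<ihc_roc> one-vs-rest region AUC\n")
  print(x$auc)
  invisible(x)
}

#' @export
autoplot.ihc_roc <- function(object, ...) {
  ggplot(object$curves, aes(x = .data$fpr, y = .data$tpr,
                            colour = .data$region)) +
    geom_path() +
    geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                colour = "grey60") +
    labs(x = "false positive rate", y = "true positive rate",
         colour = "region") +
    theme_minimal()
}

#' One-versus-rest differential-expression statistics per cell type
#'
#' For each gene and cell type, compares the type's cells against all other
#' cells: Welch's unequal-variance t statistic, or the rank-sum statistic
#' standardized to a z score with tie correction. Genes that are constant
#' within the comparison (zero variance / all ties) score 0 -- no evidence of
#' specificity.
#'
#' @param expr an [expression_dataset()]; each cell type and its complement
#'   must contain at least 2 cells.
#' @param method `"t_test"` (Welch) or `"wilcoxon"` (normal-approximated z).
#' @return genes x K numeric matrix of statistics.
#' @export
ovr_de_statistics <- function(expr, method = c("t_test", "wilcoxon")) {
  method <- match.arg(method)
  X <- as.matrix(expr$matrix)
  types <- sort(unique(expr$cell_types))
  n <- nrow(X)
  out <- matrix(0, ncol(X), length(types),
                dimnames = list(expr$gene_names, types))
  if (method == "wilcoxon") ranks <- apply(X, 2L, rank)
  for (j in seq_along(types)) {
    g1 <- expr$cell_types == types[j]
    n1 <- sum(g1); n2 <- n - n1
    if (n1 < 2L || n2 < 2L) {
      stopf("cell type '%s' or its complement has fewer than 2 cells",
            types[j])
    }
    if (method == "t_test") {
      m1 <- colMeans(X[g1, , drop = FALSE])
      m2 <- colMeans(X[!g1, , drop = FALSE])
      v1 <- (colSums(X[g1, , drop = FALSE]^2) - n1 * m1^2) / (n1 - 1)
      v2 <- (colSums(X[!g1, , drop = FALSE]^2) - n2 * m2^2) / (n2 - 1)
      v1 <- pmax(v1, 0); v2 <- pmax(v2, 0)
      se <- sqrt(v1 / n1 + v2 / n2)
      tt <- ifelse(se > 0, (m1 - m2) / se, 0)
      if (any(se == 0)) {
        warnf("%d gene(s) with zero variance in '%s' comparison scored 0",
              sum(se == 0), types[j])
      }
      out[, j] <- tt
    } else {
      U <- colSums(ranks[g1, , drop = FALSE]) - n1 * (n1 + 1) / 2
      tiecor <- vapply(seq_len(ncol(X)), function(g) {
        tt <- table(X[, g])
        sum(tt^3 - tt)
      }, numeric(1))
      sig2 <- (n1 * n2 / 12) * ((n + 1) - tiecor / (n * (n - 1)))
      z <- ifelse(sig2 > 0, (U - n1 * n2 / 2) / sqrt(sig2), 0)
      out[, j] <- z
    }
  }
  out
}

#' Transcriptomic baseline scores per region
#'
#' Converts per-cell-type one-vs-rest statistics into per-region specificity
#' scores by taking, for each gene, the maximum statistic over the cell types
#' mapped to each region.
#'
#' @param expr an [expression_dataset()].
#' @param method `"t_test"` or `"wilcoxon"` (see [ovr_de_statistics()]).
#' @param region_map named character vector `cell_type -> region`.
#' @return tibble with `gene` and one score column per region, ready for
#'   [ovr_roc()].
#' @export
de_baseline_scores <- function(expr, method = c("t_test", "wilcoxon"),
                               region_map) {
  stat <- ovr_de_statistics(expr, method)
  if (is.data.frame(region_map)) {
    region_map <- setNames(region_map$region, region_map$cell_type)
  }
  regions <- sort(unique(unname(region_map)))
  out <- matrix(-Inf, nrow(stat), length(regions),
                dimnames = list(rownames(stat), regions))
  for (ct in intersect(colnames(stat), names(region_map))) {
    r <- region_map[[ct]]
    out[, r] <- pmax(out[, r], stat[, ct])
  }
  bind_cols(tibble(gene = rownames(stat)),
            as_tibble(out, .name_repair = "minimal"))
}

#' Cross-validated linear probe accuracy
#'
#' Stratified k-fold cross-validation of a multinomial logistic regression
#' predicting a label from embeddings; used both as the donor-invariance
#' probe (lower accuracy = more donor-invariant representation) and as the
#' planted-class probe on synthetic corpora.
#'
#' @param H `N x D` embedding matrix.
#' @param labels length-N class labels; at least 2 classes, each with at
#'   least `folds` members.
#' @param folds number of CV folds (default 5).
#' @param seed RNG seed for the fold assignment.
#' @param decay weak L2 penalty passed to [nnet::multinom()] (numerical
#'   stabilizer, not a tuned regularizer).
#' @return mean held-out accuracy in `[0, 1]`.
#' @export
linear_probe <- function(H, labels, folds = 5L, seed = 1L, decay = 1e-4) {
  H <- as.matrix(H)
  labels <- as.character(labels)
  if (length(unique(labels)) < 2L) {
    stopf("linear probe needs at least 2 classes; got %d",
          length(unique(labels)))
  }
  cnt <- table(labels)
  if (any(cnt < folds)) {
    stopf("class '%s' has %d < folds = %d samples; use fewer folds",
          names(cnt)[which.min(cnt)], min(cnt), folds)
  }
  set.seed(seed)
  fold <- integer(length(labels))
  for (cl in names(cnt)) {
    idx <- sample(which(labels == cl))
    fold[idx] <- rep_len(seq_len(folds), length(idx))
  }
  df <- data.frame(y = factor(labels), H)
  acc <- numeric(folds)
  for (f in seq_len(folds)) {
    te <- fold == f
    fit <- nnet::multinom(y ~ ., data = df[!te, , drop = FALSE],
                          trace = FALSE, decay = decay, maxit = 200L,
                          MaxNWts = (ncol(H) + 1L) * length(cnt) + 10L)
    pred <- predict(fit, newdata = df[te, , drop = FALSE], type = "class")
    acc[f] <- mean(pred == df$y[te])
  }
  mean(acc)
}

#' Donor-invariance probe
#'
#' Fivefold cross-validated accuracy of a multinomial logistic regression
#' predicting the tissue donor from the embedding. The donor-masked negative
#' sampling is designed to push this toward chance.
#'
#' @inheritParams linear_probe
#' @param donors length-N donor labels.
#' @return mean held-out accuracy.
#' @export
donor_probe <- function(H, donors, folds = 5L, seed = 1L) {
  linear_probe(H, donors, folds = folds, seed = seed)
}

#' Hypergeometric cluster enrichment
#'
#' Upper-tail probability that a cluster of genes contains at least the
#' observed number of annotated genes when drawn from the universe at
#' random: `P(X >= k)` for `X ~ Hypergeometric(N = |universe|,
#' K = |annotated|, n = |cluster|)`, `k = |cluster & annotated|`.
#'
#' @param cluster,annotated,universe character vectors of gene identifiers;
#'   `cluster` and `annotated` must be subsets of `universe`.
#' @return the raw upper-tail p-value (exactly 1 when the overlap is empty).
#' @export
cluster_enrichment <- function(cluster, annotated, universe) {
  cluster <- unique(cluster); annotated <- unique(annotated)
  universe <- unique(universe)
  if (!all(cluster %in% universe)) stopf("cluster is not a subset of universe")
  if (!all(annotated %in% universe)) {
    stopf("annotated set is not a subset of universe")
  }
  k <- length(intersect(cluster, annotated))
  phyper(k - 1, length(annotated), length(universe) - length(annotated),
         length(cluster), lower.tail = FALSE)
}

#' Benjamini-Hochberg adjustment for enrichment tables
#'
#' Convenience wrapper: raw p-values are reported by default; this adds an
#' adjusted column across a table of cluster x annotation tests.
#'
#' @param p numeric vector of raw p-values.
#' @return vector of BH-adjusted values.
#' @export
adjust_enrichment <- function(p) stats::p.adjust(p, method = "BH")
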