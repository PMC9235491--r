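# Gene-grouped, donor-masked contrastive learning.
#
# Positives: two images of the same nominal target gene (pooled across
# antibodies and donors), each independently augmented. Negatives: the other
# batch members' second views. In donor-masked mode, negatives from donors
# other than the anchor's are masked out of the denominator and the surviving
# same-donor terms are re-weighted by B / B_i, with
# B_i = sum_k 1[d_i = d_k] (the self term counts). This steers the encoder to
# pull apart images that cluster merely by tissue donor, while the uniform
# mode is the standard NT-Xent denominator over all batch members.

#' Contrastive training configuration
#'
#' Defaults follow the reference training setup: temperature 1.0, embedding
#' dimension 128, batches of 150 gene pairs, Adam with learning rate 5e-4 for
#' 1000 epochs.
#'
#' @param batch_size number of genes (positive pairs) per minibatch; >= 2.
#' @param temperature softmax temperature tau > 0.
#' @param epochs training epochs; one epoch visits about one batch per
#'   `floor(n_genes / batch_size)` (at least one batch).
#' @param learning_rate Adam step size.
#' @param embedding_dim embedding dimension D.
#' @param channels per-block channel counts of the default CNN backbone.
#' @param negative_mode `"donor_masked"` (mask negatives from other donors and
#'   reweight by B/B_i) or `"uniform"` (standard NT-Xent denominator).
#' @param donor_mask_source which donor label the mask compares against the
#'   anchor's: `"first_view"` (the literal algorithm; donors of the first-drawn
#'   records) or `"negative_view"` (donors of the second views actually used
#'   as negatives).
#' @param count_self logical; whether B_i counts the anchor itself (the
#'   printed summation does). `FALSE` uses the "number of negatives" reading.
#' @param symmetrize logical; average the loss over both view directions
#'   (SimCLR-style) instead of the one-directional form.
#' @param seed master seed; fans out to named substreams for initialization,
#'   gene sampling and augmentation.
#' @return a `contrastive_config` list.
#' @export
contrastive_config <- function(batch_size = 150L, temperature = 1.0,
                               epochs = 1000L, learning_rate = 5e-4,
                               embedding_dim = 128L,
                               channels = c(8L, 16L, 32L, 32L),
                               negative_mode = c("donor_masked", "uniform"),
                               donor_mask_source = c("first_view",
                                                     "negative_view"),
                               count_self = TRUE, symmetrize = FALSE,
                               seed = 1L) {
  stopifnot(batch_size >= 2L, temperature > 0, epochs >= 1L,
            learning_rate > 0, embedding_dim >= 1L)
  structure(
    list(batch_size = as.integer(batch_size), temperature = temperature,
         epochs = as.integer(epochs), learning_rate = learning_rate,
         embedding_dim = as.integer(embedding_dim),
         channels = as.integer(channels),
         negative_mode = match.arg(negative_mode),
         donor_mask_source = match.arg(donor_mask_source),
         count_self = isTRUE(count_self), symmetrize = isTRUE(symmetrize),
         seed = as.integer(seed)),
    class = "contrastive_config"
  )
}

#' Sample a positive pair of images for a gene
#'
#' Draws two records uniformly without replacement from the gene's
#' equivalence class (all images whose antibody nominally targets that gene).
#' A singleton class returns the same record twice; the two views then differ
#' only by augmentation.
#'
#' @param corpus an `ihc_corpus`.
#' @param gene gene name present in the corpus.
#' @return integer vector of two record indices.
#' @export
sample_positive_pair <- function(corpus, gene) {
  cls <- corpus$gene_partition[[gene]]
  if (is.null(cls)) stopf("gene '%s' not present in corpus", gene)
  if (length(cls) == 1L) return(c(cls, cls))
  cls[sample.int(length(cls), 2L)]
}

#' Assemble a minibatch of augmented positive pairs
#'
#' Samples `batch_size` genes uniformly without replacement (falling back to
#' sampling with replacement, with a warning, when the corpus has fewer
#' genes), draws a positive pair per gene, and augments each member
#' independently.
#'
#' @param corpus an `ihc_corpus` (non-empty).
#' @param config a [contrastive_config()].
#' @param aug an [augment_config()].
#' @param cache optional environment memoising decoded images.
#' @return a `pair_batch`: list with 4-d arrays `views_a`, `views_b`
#'   (`crop x crop x 3 x B`), character `donors`, `donors_b`, `genes`.
#' @export
make_batch <- function(corpus, config, aug, cache = NULL) {
  genes <- names(corpus$gene_partition)
  if (length(genes) == 0L) stopf("cannot sample a batch from an empty corpus")
  B <- config$batch_size
  if (length(genes) >= B) {
    gsel <- sample(genes, B)
  } else {
    warnf("corpus has %d genes < batch_size %d; sampling with replacement",
          length(genes), B)
    gsel <- sample(genes, B, replace = TRUE)
  }
  cs <- aug$crop_size
  va <- array(0, c(cs, cs, 3L, B))
  vb <- array(0, c(cs, cs, 3L, B))
  donors <- character(B); donors_b <- character(B)
  for (i in seq_len(B)) {
    pr <- sample_positive_pair(corpus, gsel[i])
    donors[i] <- corpus$records$donor[pr[1]]
    donors_b[i] <- corpus$records$donor[pr[2]]
    va[, , , i] <- augment_image(load_corpus_image(corpus, pr[1], cache), aug)
    vb[, , , i] <- augment_image(load_corpus_image(corpus, pr[2], cache), aug)
  }
  structure(list(views_a = va, views_b = vb, donors = donors,
                 donors_b = donors_b, genes = gsel),
            class = "pair_batch")
}

#' Pairwise cosine similarity
#'
#' @param Z,Zp numeric matrices `B x D` with no zero rows.
#' @return `B x B` matrix with `S[i, j]` the cosine similarity of `Z[i, ]`
#'   and `Zp[j, ]`; entries in `[-1, 1]`.
#' @export
pairwise_similarity <- function(Z, Zp) {
  nz <- sqrt(rowSums(Z^2)); np <- sqrt(rowSums(Zp^2))
  if (any(nz == 0) || any(np == 0)) stopf("zero-norm row in similarity input")
  (Z / nz) %*% t(Zp / np)
}

#' Donor-masked contrastive loss
#'
#' Per-sample loss for anchor i over the similarity matrix `S` (rows: first
#' views, columns: second views):
#' \deqn{l_i = -\log \frac{e^{s_{ii}/\tau}}{e^{s_{ii}/\tau} +
#'   (B/B_i) \sum_{k \ne i} 1[d_i = d_k]\, e^{s_{ik}/\tau}}}
#' with \eqn{B_i = \sum_{k=1}^B 1[d_i = d_k]} (the self term counts, so
#' \eqn{B_i \ge 1}). Uniform mode drops the indicator and the \eqn{B/B_i}
#' factor (the standard NT-Xent denominator). Computed by log-sum-exp with
#' the maximum subtracted. A sample whose donor is unique in the batch has no
#' surviving negatives and contributes exactly 0.
#'
#' @param S `B x B` similarity matrix.
#' @param donors length-B donor labels of the first views.
#' @param tau temperature, > 0.
#' @param mode `"donor_masked"` or `"uniform"`.
#' @param donors_b donor labels of the second views; only consulted when
#'   `mask_source = "negative_view"`.
#' @param mask_source which labels the indicator compares to the anchor's
#'   donor (see [contrastive_config()]).
#' @param count_self whether B_i includes the anchor.
#' @return list with `total` (mean of per-sample losses) and `per_sample`
#'   (length B, all >= 0 in the default self-counting form).
#' @export
masked_contrastive_loss <- function(S, donors, tau = 1.0,
                                    mode = c("donor_masked", "uniform"),
                                    donors_b = NULL,
                                    mask_source = c("first_view",
                                                    "negative_view"),
                                    count_self = TRUE) {
  mode <- match.arg(mode)
  mask_source <- match.arg(mask_source)
  r <- contrastive_loss_grad(S, donors, tau, mode, donors_b, mask_source,
                             count_self, want_grad = FALSE)
  list(total = r$total, per_sample = r$per_sample)
}

# Loss plus (optionally) dL/dS for training. Weight matrix formulation:
# den_i = sum_k w_ik exp(s_ik / tau), w_ii = 1, w_ik = (B/B_i) * mask.
contrastive_loss_grad <- function(S, donors, tau, mode, donors_b = NULL,
                                  mask_source = "first_view",
                                  count_self = TRUE, want_grad = TRUE) {
  if (tau <= 0) stopf("temperature must be positive")
  B <- nrow(S)
  if (length(donors) != B) stopf("donors must have length nrow(S)")
  assert_finite(S, "similarity matrix")
  if (mode == "uniform") {
    Wmat <- matrix(1, B, B)
  } else {
    dmask <- if (mask_source == "negative_view") {
      if (is.null(donors_b)) stopf("donors_b required for negative_view mask")
      donors_b
    } else donors
    M <- outer(donors, dmask, `==`) * 1
    cnt <- if (count_self) {
      # B_i per the printed summation: self included via the first-view labels
      rowSums(outer(donors, donors, `==`))
    } else {
      pmax(rowSums(M) - (mask_source == "first_view"), 1)
    }
    Wmat <- M * (B / cnt)
  }
  diag(Wmat) <- 1
  A <- S / tau + log(Wmat * (Wmat > 0) + (Wmat <= 0))  # log w; -Inf where w=0
  A[Wmat <= 0] <- -Inf
  m <- apply(A, 1L, max)
  E <- exp(A - m)
  den <- rowSums(E)
  li <- m + log(den) - diag(S) / tau
  total <- mean(li)
  out <- list(total = total, per_sample = li)
  if (want_grad) {
    P <- E / den                      # softmax over weighted terms, row-wise
    G <- P / tau
    diag(G) <- diag(G) - 1 / tau
    out$grad <- G / B                 # d(total)/dS
  }
  out
}

#' Train the contrastive encoder
#'
#' Runs the gene-grouped, donor-masked objective: per batch, sample genes,
#' draw and augment positive pairs, embed both views, project to the unit
#' sphere, form pairwise cosine similarities, and take an Adam step on the
#' (masked) contrastive loss. The projection head is used only here;
#' [embed_corpus()] returns the pre-projection embeddings h.
#'
#' @param corpus a (quality-filtered) `ihc_corpus`.
#' @param config a [contrastive_config()].
#' @param aug an [augment_config()].
#' @param verbose print the epoch loss every 50 epochs.
#' @return an `ihc_encoder` with `loss_history` (one mean loss per epoch).
#' @export
train_contrastive <- function(corpus, config = contrastive_config(),
                              aug = augment_config(), verbose = FALSE) {
  stopifnot(inherits(corpus, "ihc_corpus"))
  n_genes <- length(corpus$gene_partition)
  if (n_genes == 0L) stopf("cannot train on an empty corpus")
  B <- min(config$batch_size, max(n_genes, 2L))
  cfg <- config
  cfg$batch_size <- B
  set.seed(derive_seed(config$seed, "init"))
  enc <- init_encoder(crop_size = aug$crop_size, channels = config$channels,
                      embedding_dim = config$embedding_dim)
  state <- adam_init(enc$params)
  cache <- new.env(parent = emptyenv())
  batches_per_epoch <- max(1L, n_genes %/% B)
  set.seed(derive_seed(config$seed, "train"))
  history <- numeric(config$epochs)
  t <- 0L
  for (ep in seq_len(config$epochs)) {
    ep_loss <- 0
    for (bi in seq_len(batches_per_epoch)) {
      batch <- suppressWarnings(make_batch(corpus, cfg, aug, cache))
      r <- contrastive_step(enc, batch, cfg)
      if (!is.finite(r$loss)) {
        stopf("non-finite contrastive loss at epoch %d, batch %d", ep, bi)
      }
      enc <- r$enc
      t <- t + 1L
      upd <- adam_step(enc$params, r$grads, state, cfg$learning_rate, t)
      enc$params <- upd$p
      state <- upd$s
      ep_loss <- ep_loss + r$loss
    }
    history[ep] <- ep_loss / batches_per_epoch
    if (verbose && ep %% 50L == 0L) {
      message(sprintf("epoch %d  loss %.4f", ep, history[ep]))
    }
  }
  enc$loss_history <- history
  enc$trained <- TRUE
  enc$config <- cfg
  enc
}

# One forward/backward pass over a pair batch; returns loss and param grads.
contrastive_step <- function(enc, batch, cfg) {
  fa <- encoder_forward(enc, batch$views_a, keep_cache = TRUE)
  fb <- encoder_forward(enc, batch$views_b, keep_cache = TRUE)
  enc <- update_bn_stats(enc, fa)
  enc <- update_bn_stats(enc, fb)
  pa <- project_forward(enc, fa$H)
  pb <- project_forward(enc, fb$H)
  S <- pa$Z %*% t(pb$Z)   # rows already unit-norm
  lr1 <- contrastive_loss_grad(S, batch$donors, cfg$temperature,
                               cfg$negative_mode, batch$donors_b,
                               cfg$donor_mask_source, cfg$count_self)
  if (cfg$symmetrize) {
    lr2 <- contrastive_loss_grad(t(S), batch$donors_b, cfg$temperature,
                                 cfg$negative_mode, batch$donors,
                                 cfg$donor_mask_source, cfg$count_self)
    loss <- (lr1$total + lr2$total) / 2
    dS <- (lr1$grad + t(lr2$grad)) / 2
  } else {
    loss <- lr1$total
    dS <- lr1$grad
  }
  dZa <- dS %*% pb$Z
  dZb <- t(dS) %*% pa$Z
  ba <- project_backward(enc, pa, dZa)
  bb <- project_backward(enc, pb, dZb)
  ga <- encoder_backward(enc, fa, ba$dH)
  gb <- encoder_backward(enc, fb, bb$dH)
  grads <- ga
  for (l in seq_along(ga$conv)) {
    for (fld in names(ga$conv[[l]])) {
      grads$conv[[l]][[fld]] <- ga$conv[[l]][[fld]] + gb$conv[[l]][[fld]]
    }
  }
  grads$fc$W <- ga$fc$W + gb$fc$W
  grads$fc$b <- ga$fc$b + gb$fc$b
  grads$proj <- list(W = ba$dW + bb$dW, b = ba$db + bb$db)
  list(loss = loss, grads = grads, enc = enc)
}

#' Embed every image of a corpus
#'
#' Deterministic inference: each image is center-cropped to the encoder's
#' input size (no stochastic augmentation) and mapped to its embedding h.
#' Records whose image cannot be decoded are collected and reported in the
#' `failed` attribute; the run continues.
#'
#' @param corpus an `ihc_corpus`.
#' @param encoder a (trained) `ihc_encoder`.
#' @param batch_size images per forward pass.
#' @return tibble with `image_id`, `gene`, `donor` and `e1 ... eD` embedding
#'   columns, one row per record in record order. Use [embedding_matrix()] to
#'   extract the numeric `N x D` matrix.
#' @export
embed_corpus <- function(corpus, encoder, batch_size = 64L) {
  stopifnot(inherits(corpus, "ihc_corpus"), inherits(encoder, "ihc_encoder"))
  n <- nrow(corpus$records)
  D <- encoder$embedding_dim
  H <- matrix(NA_real_, n, D)
  cs <- encoder$crop_size
  failed <- character(0)
  idx <- seq_len(n)
  for (start in seq(1L, n, by = batch_size)) {
    ii <- idx[start:min(start + batch_size - 1L, n)]
    X <- array(0, c(cs, cs, 3L, length(ii)))
    ok <- logical(length(ii))
    for (j in seq_along(ii)) {
      img <- tryCatch(load_corpus_image(corpus, ii[j]), error = function(e) e)
      if (inherits(img, "error")) {
        failed <- c(failed, corpus$records$image_id[ii[j]])
        next
      }
      X[, , , j] <- center_crop(img, cs)
      ok[j] <- TRUE
    }
    if (any(ok)) {
      Hb <- encoder_forward(enc = encoder, X = X[, , , ok, drop = FALSE])$H
      H[ii[ok], ] <- Hb
    }
  }
  if (length(failed) > 0) {
    warnf("failed to decode %d image(s): %s", length(failed),
          paste(head(failed, 3L), collapse = ", "))
  }
  out <- dplyr::bind_cols(
    corpus$records[, c("image_id", "gene", "donor")],
    as_tibble(H, .name_repair = ~ paste0("e", seq_len(D)))
  )
  attr(out, "failed") <- failed
  out
}

#' Extract the numeric embedding matrix from an embedding tibble
#'
#' @param embeddings a tibble from [embed_corpus()] (or any tibble with
#'   `e1 ... eD` columns).
#' @return numeric matrix `N x D` with `image_id` rownames when present.
#' @export
embedding_matrix <- function(embeddings) {
  cols <- grep("^e[0-9]+$", names(embeddings), value = TRUE)
  cols <- cols[order(as.integer(sub("^e", "", cols)))]
  H <- as.matrix(embeddings[, cols])
  if ("image_id" %in% names(embeddings)) rownames(H) <- embeddings$image_id
  H
}

center_crop <- function(img, cs) {
  d <- dim(img)
  if (d[1] < cs || d[2] < cs) {
    stopf("image (%dx%d) smaller than crop size %d", d[1], d[2], cs)
  }
  oy <- (d[1] - cs) %/% 2L
  ox <- (d[2] - cs) %/% 2L
  img[(oy + 1L):(oy + cs), (ox + 1L):(ox + cs), , drop = FALSE]
}

#' @export
print.ihc_encoder <- function(x, ...) {
  cat(sprintf(
    "<ihc_encoder> %s, crop %d, D=%d, blocks [%s]%s\n",
    if (x$trained) "trained" else "untrained", x$crop_size, x$embedding_dim,
    paste(x$channels, collapse = ","),
    if (length(x$loss_history))
      sprintf(", final loss %.4f", tail(x$loss_history, 1L)) else ""
  ))
  invisible(x)
}

#' @export
glance.ihc_encoder <- function(x, ...) {
  tibble(
    trained = x$trained,
    epochs = length(x$loss_history),
    embedding_dim = x$embedding_dim,
    crop_size = x$crop_size,
    final_loss = if (length(x$loss_history)) tail(x$loss_history, 1L)
                 else NA_real_
  )
}

#' @export
autoplot.ihc_encoder <- function(object, ...) {
  df <- tibble(epoch = seq_along(object$loss_history),
               loss = object$loss_history)
  ggplot(df, aes(x = .data$epoch, y = .data$loss)) +
    geom_line() +
    labs(x = "epoch", y = "mean contrastive loss") +
    theme_minimal()
}
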