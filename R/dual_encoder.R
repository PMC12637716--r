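#' Paired multiome cell
#'
#' One cell measured in both modalities: an ATAC token set and an RNA
#' expression vector (normalized counts), plus an optional cell-type label.
#'
#' @param atac a `token_sequence`.
#' @param rna numeric gene-expression vector.
#' @param cell_id identifier (defaults to the ATAC cell id).
#' @param label optional cell-type label.
#' @return A `paired_multiome_cell`.
#' @export
paired_multiome_cell <- function(atac, rna, cell_id = atac$cell_id, label = NULL) {
  stopifnot(inherits(atac, "token_sequence"), is.numeric(rna))
  structure(list(atac = atac, rna = as.numeric(rna),
                 cell_id = as.character(cell_id), label = label),
            class = "paired_multiome_cell")
}

#' Bundled expression encoder
#'
#' A small feed-forward encoder mapping a gene-expression vector to an
#' embedding (one ReLU hidden layer). It stands behind the same interface a
#' larger pretrained transcriptome encoder would: any object with `params`,
#' `dims`, and `n_layers` fields compatible with the internal dense-layer
#' forward/backward can be plugged into [train_dual_encoder()].
#'
#' @param n_genes input gene count.
#' @param hidden_dim hidden width.
#' @param out_dim embedding dimension (the shared projection dimension).
#' @param seed initialization seed.
#' @return An `rna_encoder`.
#' @export
rna_encoder <- function(n_genes, hidden_dim = 64L, out_dim = 32L, seed = 0L) {
  dims <- c(n_genes, hidden_dim, out_dim)
  structure(list(params = init_mlp_params(dims, seed = seed, prefix = "rna"),
                 dims = dims, n_layers = 2L, prefix = "rna"),
            class = "rna_encoder")
}

#' Symmetric contrastive (InfoNCE) alignment loss
#'
#' CLIP-style objective on a batch of paired projections: the scaled
#' cosine-similarity matrix of L2-normalized rows is scored by softmax
#' cross-entropy against the diagonal, averaged over the ATAC-to-RNA and
#' RNA-to-ATAC directions. With all projections identical (uniform
#' similarities) the loss is `log(batch_size)`.
#'
#' @param atac_proj,rna_proj row-aligned (row i = same cell) L2-normalized
#'   projection matrices.
#' @param temperature softmax temperature (similarities divided by it).
#' @return scalar loss.
#' @export
craft_loss <- function(atac_proj, rna_proj, temperature = 0.07) {
  stopifnot(all(dim(atac_proj) == dim(rna_proj)), temperature > 0)
  B <- nrow(atac_proj)
  if (B < 2L) stop("craft_loss: contrastive loss needs a batch of >= 2",
                   call. = FALSE)
  logits <- tcrossprod(atac_proj, rna_proj) / temperature
  ce_rows <- -mean(log(clip_prob(diag(softmax_rows(logits)), 1e-300)))
  ce_cols <- -mean(log(clip_prob(diag(softmax_rows(t(logits))), 1e-300)))
  (ce_rows + ce_cols) / 2
}

l2_normalize_rows <- function(X) {
  r <- sqrt(rowSums(X * X))
  r[r == 0] <- 1
  list(Z = X / r, r = r)
}

l2_normalize_bwd <- function(dZ, Z, r) {
  (dZ - Z * rowSums(dZ * Z)) / r
}

#' Dual-encoder training configuration
#'
#' Defaults follow the published recipe for contrastive RNA-ATAC alignment:
#' 15 epochs under a linear learning-rate schedule with peak rate 5e-5 and a
#' learnable temperature initialized at 0.07.
#'
#' @param shared_dim shared projection dimension.
#' @param temperature_init initial softmax temperature (learnable).
#' @param epochs training epochs (default 15).
#' @param lr peak learning rate (default 5e-5).
#' @param weight_decay decoupled weight decay.
#' @param batch_size cells per contrastive batch (>= 2).
#' @param holdout_frac held-out fraction for retrieval monitoring.
#' @param seed RNG seed.
#' @return A `craft_config`.
#' @export
craft_config <- function(shared_dim = 32L, temperature_init = 0.07,
                         epochs = 15L, lr = 5e-5, weight_decay = 0.01,
                         batch_size = 32L, holdout_frac = 0.2, seed = 0L) {
  stopifnot(temperature_init > 0, batch_size >= 2L, epochs >= 0)
  structure(list(shared_dim = as.integer(shared_dim),
                 temperature_init = temperature_init,
                 epochs = as.integer(epochs), lr = lr,
                 weight_decay = weight_decay,
                 batch_size = as.integer(batch_size),
                 holdout_frac = holdout_frac, seed = as.integer(seed)),
            class = "craft_config")
}

dual_project_atac <- function(joint, token_list) {
  fw <- transformer_forward(joint$atac_model$params, joint$atac_model$config,
                            token_list)
  emb <- matrix(0, length(token_list), joint$atac_model$config$d_model)
  for (i in seq_along(fw$rows)) {
    idx <- fw$rows[[i]]
    if (length(idx)) emb[i, ] <- colMeans(fw$H[idx, , drop = FALSE])
  }
  l2_normalize_rows(add_bias(emb %*% joint$proj_W, joint$proj_b))$Z
}

dual_project_rna <- function(joint, X) {
  l2_normalize_rows(mlp_forward(joint$rna$params, X, joint$rna$n_layers,
                                prefix = joint$rna$prefix)$Y)$Z
}

#' Embed cells into the shared latent space
#'
#' @param joint a trained `dual_encoder_model`.
#' @param cells for the ATAC side, a list of `token_sequence` (or
#'   `paired_multiome_cell`); for the RNA side, a cells x genes matrix or a
#'   list of `paired_multiome_cell`.
#' @return cells x shared_dim matrix of L2-normalized embeddings.
#' @export
dual_embed_atac <- function(joint, cells) {
  stopifnot(inherits(joint, "dual_encoder_model"))
  if (length(cells) && inherits(cells[[1L]], "paired_multiome_cell"))
    cells <- lapply(cells, `[[`, "atac")
  dual_project_atac(joint, as_token_list(cells))
}

#' @rdname dual_embed_atac
#' @export
dual_embed_rna <- function(joint, cells) {
  stopifnot(inherits(joint, "dual_encoder_model"))
  X <- if (is.matrix(cells)) cells else
    do.call(rbind, lapply(cells, `[[`, "rna"))
  if (ncol(X) != joint$rna$dims[1L]) {
    stop(sprintf("dual_embed_rna: %d gene(s) but encoder expects %d",
                 ncol(X), joint$rna$dims[1L]), call. = FALSE)
  }
  dual_project_rna(joint, X)
}

retrieval_accuracy <- function(joint, paired, labels) {
  Za <- dual_embed_atac(joint, paired)
  Zr <- dual_embed_rna(joint, paired)
  sim <- tcrossprod(Za, Zr)
  hit <- vapply(seq_len(nrow(sim)), function(i)
    labels[which.max(sim[i, ])] == labels[i], logical(1))
  mean(hit)
}

#' Train a CLIP-style ATAC/RNA dual encoder
#'
#' Jointly trains the ATAC transformer tower (mean-pooled cell embedding
#' followed by a linear projection) and a pluggable expression encoder, both
#' L2-normalized into a shared space, with the symmetric contrastive loss of
#' [craft_loss()] and a learnable temperature. The learning rate decays
#' linearly from its peak to zero over training. Per-epoch loss and held-out
#' top-1 cross-modal cell-type retrieval accuracy are recorded.
#'
#' @param atac_model an `atac_model` (pretrained or fresh).
#' @param rna_enc an `rna_encoder` (or compatible pluggable encoder).
#' @param paired list of `paired_multiome_cell` with labels.
#' @param cfg a `craft_config`.
#' @return list with `model` (a `dual_encoder_model`), `history`, and
#'   `holdout` indices.
#' @export
train_dual_encoder <- function(atac_model, rna_enc, paired,
                               cfg = craft_config()) {
  stopifnot(inherits(atac_model, "atac_model"), inherits(rna_enc, "rna_encoder"),
            length(paired) >= 2L)
  n_genes <- length(paired[[1L]]$rna)
  if (n_genes != rna_enc$dims[1L]) {
    stop(sprintf("train_dual_encoder: cells have %d gene(s), encoder expects %d",
                 n_genes, rna_enc$dims[1L]), call. = FALSE)
  }
  if (rna_enc$dims[length(rna_enc$dims)] != cfg$shared_dim) {
    stop("train_dual_encoder: rna encoder output dim must equal shared_dim",
         call. = FALSE)
  }
  mcfg <- atac_model$config
  tl <- lapply(paired, function(pc) pc$atac$tokens)
  Xrna <- do.call(rbind, lapply(paired, `[[`, "rna"))
  labels <- vapply(paired, function(pc) as.character(pc$label %||% NA_character_),
                   character(1))
  with_local_seed(cfg$seed, {
    ap <- atac_model$params
    hp <- list(proj_W = matrix(stats::rnorm(mcfg$d_model * cfg$shared_dim,
                                            sd = 0.02),
                               mcfg$d_model, cfg$shared_dim),
               proj_b = rep(0, cfg$shared_dim),
               log_scale = log(1 / cfg$temperature_init))
    rp <- rna_enc$params
    opt_a <- adamw_init(ap); opt_h <- adamw_init(hp); opt_r <- adamw_init(rp)
    n <- length(paired)
    n_hold <- floor(cfg$holdout_frac * n)
    hold <- if (n_hold > 0) sample.int(n, n_hold) else integer(0)
    tr <- setdiff(seq_len(n), hold)
    make_joint <- function() {
      structure(list(atac_model = structure(list(config = mcfg, params = ap),
                                            class = "atac_model"),
                     proj_W = hp$proj_W, proj_b = hp$proj_b,
                     log_scale = hp$log_scale,
                     rna = list(params = rp, dims = rna_enc$dims,
                                n_layers = rna_enc$n_layers,
                                prefix = rna_enc$prefix),
                     config = cfg),
                class = "dual_encoder_model")
    }
    n_steps <- max(1L, cfg$epochs * ceiling(length(tr) / cfg$batch_size))
    step <- 0L
    history <- data.frame(epoch = integer(), loss = numeric(),
                          holdout_retrieval = numeric())
    for (ep in seq_len(cfg$epochs)) {
      ord <- sample(tr)
      batches <- split(ord, ceiling(seq_along(ord) / cfg$batch_size))
      batches <- batches[lengths(batches) >= 2L]
      ep_loss <- numeric(length(batches))
      for (bi in seq_along(batches)) {
        b <- batches[[bi]]
        B <- length(b)
        step <- step + 1L
        lr_t <- cfg$lr * (1 - (step - 1) / n_steps)
        # ATAC tower forward
        fw <- transformer_forward(ap, mcfg, tl[b], train = TRUE,
                                  want_cache = TRUE)
        Pa <- matrix(0, B, mcfg$d_model)
        for (i in seq_len(B)) {
          idx <- fw$rows[[i]]
          if (length(idx)) Pa[i, ] <- colMeans(fw$H[idx, , drop = FALSE])
        }
        Ua <- add_bias(Pa %*% hp$proj_W, hp$proj_b)
        na <- l2_normalize_rows(Ua); Za <- na$Z
        # RNA tower forward
        rfw <- mlp_forward(rp, Xrna[b, , drop = FALSE], rna_enc$n_layers,
                           prefix = rna_enc$prefix, want_cache = TRUE)
        nr <- l2_normalize_rows(rfw$Y); Zr <- nr$Z
        scale <- exp(hp$log_scale)
        sim <- tcrossprod(Za, Zr)
        logits <- sim * scale
        Pr <- softmax_rows(logits)
        Pc <- t(softmax_rows(t(logits)))
        I <- diag(B)
        loss <- -(mean(log(clip_prob(diag(Pr), 1e-300))) +
                    mean(log(clip_prob(diag(Pc), 1e-300)))) / 2
        if (!is.finite(loss)) stop("train_dual_encoder: loss diverged",
                                   call. = FALSE)
        dlogits <- ((Pr - I) + (Pc - I)) / (2 * B)
        g_log_scale <- sum(dlogits * sim) * scale
        dZa <- (dlogits %*% Zr) * scale
        dZr <- (t(dlogits) %*% Za) * scale
        dUa <- l2_normalize_bwd(dZa, Za, na$r)
        dUr <- l2_normalize_bwd(dZr, Zr, nr$r)
        g_h <- list(proj_W = crossprod(Pa, dUa), proj_b = colSums(dUa),
                    log_scale = g_log_scale)
        dPa <- dUa %*% t(hp$proj_W)
        dH <- matrix(0, nrow(fw$H), mcfg$d_model)
        for (i in seq_len(B)) {
          idx <- fw$rows[[i]]
          if (length(idx)) {
            dH[idx, ] <- matrix(dPa[i, ] / length(idx), length(idx),
                                mcfg$d_model, byrow = TRUE)
          }
        }
        g_a <- transformer_backward(ap, mcfg, fw, dH)
        g_r <- mlp_backward(rp, rfw, dUr, rna_enc$n_layers,
                            prefix = rna_enc$prefix)
        g_r$dX <- NULL
        ua <- adamw_step(ap, g_a, opt_a, lr = lr_t,
                         weight_decay = cfg$weight_decay)
        ap <- ua$params; opt_a <- ua$state
        uh <- adamw_step(hp, g_h, opt_h, lr = lr_t, weight_decay = 0)
        hp <- uh$params; opt_h <- uh$state
        ur <- adamw_step(rp, g_r, opt_r, lr = lr_t,
                         weight_decay = cfg$weight_decay)
        rp <- ur$params; opt_r <- ur$state
        ep_loss[bi] <- loss
      }
      acc <- if (length(hold) && !anyNA(labels[hold])) {
        retrieval_accuracy(make_joint(), paired[hold], labels[hold])
      } else NA_real_
      history <- rbind(history, data.frame(epoch = ep, loss = mean(ep_loss),
                                           holdout_retrieval = acc))
    }
    list(model = make_joint(), history = history, holdout = hold)
  })
}

# ---- RNA decoder ---------------------------------------------------------

#' Train an RNA expression decoder
#'
#' Learns to predict a cell's RNA expression profile from its ATAC-derived
#' embedding: a fully connected layer with ReLU maps the embedding to a
#' latent space, and a one-hidden-layer decoder maps the latent vector to
#' the gene-expression vector. Trained by mean-squared error with AdamW;
#' held-out per-cell Spearman correlation between observed and predicted
#' expression is reported.
#'
#' @param source a trained `dual_encoder_model` (shared-space ATAC
#'   embeddings), an `atac_model` (mean-pooled embeddings), or a
#'   precomputed cells x dim embedding matrix.
#' @param paired list of `paired_multiome_cell`.
#' @param latent_dim latent dimension of the encoder stage.
#' @param hidden_dim hidden width of the decoder stage.
#' @param epochs,lr,batch_size,seed optimizer settings.
#' @param holdout_frac held-out fraction for Spearman monitoring.
#' @return list with `decoder` (an `rna_decoder`), `history`,
#'   `holdout_spearman` (per held-out cell), and `holdout` indices.
#' @export
train_rna_decoder <- function(source, paired, latent_dim = 16L,
                              hidden_dim = 64L, epochs = 200L, lr = 1e-3,
                              batch_size = 64L, holdout_frac = 0.2, seed = 0L) {
  Emb <- decoder_input_embeddings(source, paired)
  Y <- do.call(rbind, lapply(paired, `[[`, "rna"))
  n_genes <- ncol(Y)
  dims <- c(ncol(Emb), latent_dim, hidden_dim, n_genes)
  with_local_seed(seed, {
    dp <- init_mlp_params(dims, seed = stats::runif(1) * 1e6, prefix = "dec")
    opt <- adamw_init(dp)
    n <- nrow(Emb)
    n_hold <- floor(holdout_frac * n)
    hold <- if (n_hold > 0) sample.int(n, n_hold) else integer(0)
    tr <- setdiff(seq_len(n), hold)
    history <- data.frame(epoch = integer(), train_mse = numeric())
    for (ep in seq_len(epochs)) {
      ord <- sample(tr)
      batches <- split(ord, ceiling(seq_along(ord) / batch_size))
      mse <- numeric(length(batches))
      for (bi in seq_along(batches)) {
        b <- batches[[bi]]
        fwd <- mlp_forward(dp, Emb[b, , drop = FALSE], 3L, prefix = "dec",
                           want_cache = TRUE)
        resid <- fwd$Y - Y[b, , drop = FALSE]
        mse[bi] <- mean(resid^2)
        g <- mlp_backward(dp, fwd, 2 * resid / length(resid), 3L, prefix = "dec")
        g$dX <- NULL
        upd <- adamw_step(dp, g, opt, lr = lr, weight_decay = 0)
        dp <- upd$params; opt <- upd$state
      }
      history <- rbind(history, data.frame(epoch = ep, train_mse = mean(mse)))
    }
    decoder <- structure(list(params = dp, dims = dims, n_layers = 3L),
                         class = "rna_decoder")
    sp <- if (length(hold)) {
      pred <- impute_expression(decoder, Emb[hold, , drop = FALSE])
      vapply(seq_along(hold), function(i) {
        s <- try(spearman_rho(Y[hold[i], ], pred[i, ]), silent = TRUE)
        if (inherits(s, "try-error")) NA_real_ else s
      }, numeric(1))
    } else numeric(0)
    list(decoder = decoder, history = history, holdout_spearman = sp,
         holdout = hold)
  })
}

decoder_input_embeddings <- function(source, paired) {
  if (is.matrix(source)) {
    stopifnot(nrow(source) == length(paired))
    source
  } else if (inherits(source, "dual_encoder_model")) {
    dual_embed_atac(source, paired)
  } else if (inherits(source, "atac_model")) {
    cell_embedding(encode(source, lapply(paired, `[[`, "atac")))
  } else {
    stop("train_rna_decoder: unsupported embedding source", call. = FALSE)
  }
}

#' Impute RNA expression from an ATAC embedding
#'
#' @param decoder an `rna_decoder`.
#' @param embedding a single embedding vector or a cells x dim matrix.
#' @return predicted expression (vector, or cells x genes matrix).
#' @export
impute_expression <- function(decoder, embedding) {
  stopifnot(inherits(decoder, "rna_decoder"))
  vec <- is.null(dim(embedding))
  X <- if (vec) matrix(embedding, 1L) else embedding
  if (ncol(X) != decoder$dims[1L]) {
    stop(sprintf("impute_expression: embedding dim %d but decoder expects %d",
                 ncol(X), decoder$dims[1L]), call. = FALSE)
  }
  Y <- mlp_forward(decoder$params, X, decoder$n_layers, prefix = "dec")$Y
  if (vec) drop(Y) else Y
}
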