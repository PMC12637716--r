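#' ELECTRA-style corruption of a token sequence
#'
#' Each position is independently flagged for replacement with probability
#' `p`; flagged positions receive an id drawn uniformly from `[0, V)`. The
#' replacement label `delta` follows the draw, not the outcome: a
#' replacement that happens to collide with the original id (probability
#' 1/V) is still labeled replaced, exactly as the detection loss uses it.
#'
#' @param tokens integer vector of 0-based token ids (or a `token_sequence`).
#' @param p replacement probability in `[0, 1]` (default 0.45).
#' @param vocab_size vocabulary size V.
#' @param seed optional seed; when given the draw is reproducible and the
#'   caller's RNG state is untouched.
#' @return list with `original`, `corrupted` (integer id vectors) and
#'   `delta` (0/1 replacement indicators).
#' @export
corrupt_tokens <- function(tokens, p = 0.45, vocab_size, seed = NULL) {
  if (inherits(tokens, "token_sequence")) tokens <- tokens$tokens
  stopifnot(p >= 0, p <= 1, vocab_size >= 1L)
  draw <- function() corrupt_vec(as.integer(tokens), p, as.integer(vocab_size))
  if (is.null(seed)) draw() else with_local_seed(seed, draw())
}

# corruption using the current RNG stream (pretrain's inner loop)
corrupt_vec <- function(tokens, p, V) {
  n <- length(tokens)
  delta <- if (n) as.integer(stats::runif(n) < p) else integer(0)
  corrupted <- tokens
  k <- which(delta == 1L)
  if (length(k)) corrupted[k] <- sample.int(V, length(k), replace = TRUE) - 1L
  list(original = tokens, corrupted = corrupted, delta = delta)
}

#' Replaced-token-detection loss
#'
#' Binary cross-entropy of the per-position replacement probabilities
#' against the replacement indicators: mean over a cell's positions, then
#' mean over cells. Probabilities are clamped away from 0 and 1 for
#' numerical safety. With `y_hat = 0.5` everywhere the loss is `log(2)`.
#'
#' @param y_hat numeric vector of probabilities.
#' @param delta 0/1 indicators, same length.
#' @param cells optional list of index vectors grouping positions into
#'   cells; by default all positions form one group.
#' @return scalar loss.
#' @export
rtd_loss <- function(y_hat, delta, cells = NULL) {
  stopifnot(length(y_hat) == length(delta))
  y <- clip_prob(y_hat)
  ll <- -(delta * log(y) + (1 - delta) * log(1 - y))
  if (is.null(cells)) return(mean(ll))
  per_cell <- vapply(cells, function(idx)
    if (length(idx)) mean(ll[idx]) else NA_real_, numeric(1))
  mean(per_cell, na.rm = TRUE)
}

auroc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  if (!length(pos) || !length(neg)) return(NA_real_)
  r <- rank(c(pos, neg), ties.method = "average")
  (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (as.numeric(length(pos)) * length(neg))
}

#' Pretraining configuration
#'
#' @param replace_prob token replacement rate p (default 0.45).
#' @param lr AdamW learning rate.
#' @param weight_decay decoupled weight decay on 2-D weights.
#' @param batch_size cells per minibatch.
#' @param epochs training epochs.
#' @param holdout_frac fraction of cells held out for monitoring.
#' @param seed seed for shuffling, corruption, and the holdout split.
#' @return A `pretrain_config`.
#' @export
pretrain_config <- function(replace_prob = 0.45, lr = 1e-3, weight_decay = 0.01,
                            batch_size = 32L, epochs = 5L, holdout_frac = 0.1,
                            seed = 0L) {
  stopifnot(replace_prob >= 0, replace_prob <= 1, lr > 0, epochs >= 0,
            batch_size >= 1, holdout_frac >= 0, holdout_frac < 1)
  structure(list(replace_prob = replace_prob, lr = lr,
                 weight_decay = weight_decay, batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), holdout_frac = holdout_frac,
                 seed = as.integer(seed)),
            class = "pretrain_config")
}

# forward + RTD loss + gradients for one corrupted minibatch
rtd_batch_step <- function(params, cfg, corrupted_list, deltas, train = TRUE) {
  fw <- transformer_forward(params, cfg, corrupted_list, train = train,
                            want_cache = TRUE)
  s <- drop(fw$H %*% params$rtd_w) + params$rtd_b
  y <- clip_prob(sigmoid(s))
  delta <- unlist(deltas, use.names = FALSE)
  nonempty <- sum(lengths(corrupted_list) > 0L)
  w <- numeric(length(s))
  for (ci in seq_along(fw$rows)) {
    idx <- fw$rows[[ci]]
    if (length(idx)) w[idx] <- 1 / (length(idx) * nonempty)
  }
  loss <- sum(w * -(delta * log(y) + (1 - delta) * log(1 - y)))
  ds <- w * (y - delta)
  g <- transformer_backward(params, cfg, fw, outer(ds, params$rtd_w))
  g$rtd_w <- drop(crossprod(fw$H, ds))
  g$rtd_b <- sum(ds)
  list(loss = loss, grads = g)
}

eval_rtd <- function(model, token_list, p) {
  corr <- lapply(token_list, corrupt_vec, p = p, V = model$config$vocab_size)
  fw <- transformer_forward(model$params, model$config,
                            lapply(corr, `[[`, "corrupted"))
  y <- sigmoid(drop(fw$H %*% model$params$rtd_w) + model$params$rtd_b)
  delta <- unlist(lapply(corr, `[[`, "delta"), use.names = FALSE)
  list(loss = rtd_loss(y, delta, cells = fw$rows),
       auroc = auroc(y, delta))
}

#' Pretrain with replaced-token detection
#'
#' ELECTRA-style self-supervised pretraining: every minibatch is corrupted
#' by uniform token replacement at rate `replace_prob` and the model is
#' trained to classify each position as replaced or original
#' (single-network detection; there is no generator model because the
#' corruption distribution is uniform). AdamW, seeded shuffling, per-epoch
#' held-out loss and replacement-detection AUROC.
#'
#' @param model an `atac_model`.
#' @param cells list of `token_sequence` (or integer id vectors).
#' @param cfg a `pretrain_config`.
#' @param checkpoint_dir optional directory; a checkpoint is written per epoch.
#' @return list with `model`, `history` (epoch 0 = untrained evaluation), and
#'   `holdout` (indices of held-out cells).
#' @export
pretrain <- function(model, cells, cfg = pretrain_config(),
                     checkpoint_dir = NULL) {
  stopifnot(inherits(model, "atac_model"), inherits(cfg, "pretrain_config"))
  tl <- as_token_list(cells)
  if (length(tl) == 0L) stop("pretrain: empty corpus", call. = FALSE)
  mcfg <- model$config
  params <- model$params
  with_local_seed(cfg$seed, {
    n <- length(tl)
    n_hold <- floor(cfg$holdout_frac * n)
    hold <- if (n_hold > 0) sample.int(n, n_hold) else integer(0)
    train_idx <- setdiff(seq_len(n), hold)
    opt <- adamw_init(params)
    history <- data.frame(epoch = integer(), train_loss = numeric(),
                          holdout_loss = numeric(), holdout_auroc = numeric())
    log_row <- function(epoch, train_loss) {
      ev <- if (length(hold)) {
        eval_rtd(structure(list(config = mcfg, params = params),
                           class = "atac_model"), tl[hold], cfg$replace_prob)
      } else list(loss = NA_real_, auroc = NA_real_)
      rbind(history, data.frame(epoch = epoch, train_loss = train_loss,
                                holdout_loss = ev$loss, holdout_auroc = ev$auroc))
    }
    history <- log_row(0L, NA_real_)
    for (ep in seq_len(cfg$epochs)) {
      ord <- sample(train_idx)
      batches <- split(ord, ceiling(seq_along(ord) / cfg$batch_size))
      ep_losses <- numeric(length(batches))
      for (bi in seq_along(batches)) {
        b <- batches[[bi]]
        corr <- lapply(tl[b], corrupt_vec, p = cfg$replace_prob,
                       V = mcfg$vocab_size)
        st <- rtd_batch_step(params, mcfg,
                             lapply(corr, `[[`, "corrupted"),
                             lapply(corr, `[[`, "delta"))
        if (!is.finite(st$loss)) {
          stop(sprintf("pretrain: loss diverged (%.3g) at epoch %d batch %d",
                       st$loss, ep, bi), call. = FALSE)
        }
        upd <- adamw_step(params, st$grads, opt, lr = cfg$lr,
                          weight_decay = cfg$weight_decay)
        params <- upd$params; opt <- upd$state
        ep_losses[bi] <- st$loss
      }
      history <- log_row(ep, mean(ep_losses))
      if (!is.null(checkpoint_dir)) {
        dir.create(checkpoint_dir, showWarnings = FALSE, recursive = TRUE)
        save_model(structure(list(config = mcfg, params = params),
                             class = "atac_model"),
                   file.path(checkpoint_dir, sprintf("epoch%03d.rds", ep)))
      }
    }
    list(model = structure(list(config = mcfg, params = params),
                           class = "atac_model"),
         history = history, holdout = hold)
  })
}

# ---- triplet fine-tuning -------------------------------------------------

pnorm_dist <- function(x, p = 2) {
  if (p == 2) sqrt(sum(x * x)) else sum(abs(x)^p)^(1 / p)
}

#' Triplet margin loss
#'
#' `L = max(d(a, p) - d(a, n) + margin, 0)` with `d` the p-norm distance,
#' averaged over triplets. Defaults margin = 1.0, p = 2. With
#' `a == p == n` both distance terms cancel and the loss equals the margin.
#'
#' @param emb_a,emb_p,emb_n anchor / positive / negative embeddings: equal
#'   length vectors, or matrices with one triplet per row.
#' @param margin hinge margin (default 1.0).
#' @param p_norm norm order (default 2).
#' @return scalar batch-mean loss.
#' @export
triplet_loss <- function(emb_a, emb_p, emb_n, margin = 1.0, p_norm = 2) {
  if (is.null(dim(emb_a))) {
    emb_a <- matrix(emb_a, 1L); emb_p <- matrix(emb_p, 1L)
    emb_n <- matrix(emb_n, 1L)
  }
  stopifnot(all(dim(emb_a) == dim(emb_p)), all(dim(emb_a) == dim(emb_n)))
  per <- vapply(seq_len(nrow(emb_a)), function(i) {
    dap <- pnorm_dist(emb_a[i, ] - emb_p[i, ], p_norm)
    dan <- pnorm_dist(emb_a[i, ] - emb_n[i, ], p_norm)
    max(dap - dan + margin, 0)
  }, numeric(1))
  mean(per)
}

# gradient of the p-norm distance ||x||_p wrt x (0 at x = 0)
pnorm_dist_grad <- function(x, p = 2) {
  d <- pnorm_dist(x, p)
  if (d == 0) return(x * 0)
  if (p == 2) x / d else sign(x) * abs(x)^(p - 1) / d^(p - 1)
}

#' Fine-tune with triplet loss on cell-type labels
#'
#' Mines uniform random (anchor, positive, negative) triplets within each
#' minibatch — anchor and positive share a cell-type label, the negative has
#' a different one — pools cell embeddings, and minimizes the triplet margin
#' loss with AdamW. Labels with fewer than two cells are excluded from
#' anchor/positive mining with a warning.
#'
#' @param model an `atac_model`.
#' @param cells list of `token_sequence`.
#' @param labels cell-type label per cell.
#' @param margin hinge margin (default 1.0).
#' @param p_norm distance norm order (default 2).
#' @param epochs fine-tuning epochs.
#' @param triplets_per_epoch triplets mined per epoch (default: one per cell).
#' @param batch_size triplets per optimization step.
#' @param lr AdamW learning rate.
#' @param weight_decay decoupled weight decay.
#' @param seed RNG seed for mining and shuffling.
#' @return list with `model` and `history` (per-epoch mean loss).
#' @export
finetune_triplet <- function(model, cells, labels, margin = 1.0, p_norm = 2,
                             epochs = 3L, triplets_per_epoch = length(cells),
                             batch_size = 16L, lr = 1e-4, weight_decay = 0.01,
                             seed = 0L) {
  stopifnot(inherits(model, "atac_model"), length(cells) == length(labels))
  tl <- as_token_list(cells)
  labels <- as.character(labels)
  tab <- table(labels)
  usable <- names(tab)[tab >= 2L]
  if (length(usable) < length(tab)) {
    warning(sprintf("finetune_triplet: excluding label(s) with < 2 cells from anchor/positive mining: %s",
                    paste(setdiff(names(tab), usable), collapse = ", ")))
  }
  if (length(usable) < 1L || length(unique(labels)) < 2L) {
    stop("finetune_triplet: need >= 2 distinct labels, at least one with >= 2 cells",
         call. = FALSE)
  }
  by_label <- split(seq_along(labels), labels)
  mcfg <- model$config
  params <- model$params
  with_local_seed(seed, {
    opt <- adamw_init(params)
    history <- data.frame(epoch = integer(), loss = numeric())
    for (ep in seq_len(epochs)) {
      trips <- t(vapply(seq_len(triplets_per_epoch), function(i) {
        la <- sample(usable, 1L)
        ap <- sample(by_label[[la]], 2L)
        ln <- sample(setdiff(names(by_label), la), 1L)
        c(ap, sample(by_label[[ln]], 1L))
      }, integer(3L)))
      batches <- split(seq_len(nrow(trips)), ceiling(seq_len(nrow(trips)) / batch_size))
      ep_loss <- numeric(length(batches))
      for (bi in seq_along(batches)) {
        tb <- trips[batches[[bi]], , drop = FALSE]
        ucells <- sort(unique(as.vector(tb)))
        fw <- transformer_forward(params, mcfg, tl[ucells], train = TRUE,
                                  want_cache = TRUE)
        emb <- matrix(0, length(ucells), mcfg$d_model)
        for (i in seq_along(ucells)) {
          idx <- fw$rows[[i]]
          if (length(idx)) emb[i, ] <- colMeans(fw$H[idx, , drop = FALSE])
        }
        pos_of <- match(as.vector(tb), ucells)
        dim(pos_of) <- dim(tb)
        demb <- matrix(0, length(ucells), mcfg$d_model)
        losses <- numeric(nrow(tb))
        for (ti in seq_len(nrow(tb))) {
          a <- emb[pos_of[ti, 1L], ]; p <- emb[pos_of[ti, 2L], ]
          nv <- emb[pos_of[ti, 3L], ]
          dap <- pnorm_dist(a - p, p_norm); dan <- pnorm_dist(a - nv, p_norm)
          losses[ti] <- max(dap - dan + margin, 0)
          if (losses[ti] > 0) {
            gp <- pnorm_dist_grad(a - p, p_norm)
            gn <- pnorm_dist_grad(a - nv, p_norm)
            sc <- 1 / nrow(tb)
            demb[pos_of[ti, 1L], ] <- demb[pos_of[ti, 1L], ] + sc * (gp - gn)
            demb[pos_of[ti, 2L], ] <- demb[pos_of[ti, 2L], ] - sc * gp
            demb[pos_of[ti, 3L], ] <- demb[pos_of[ti, 3L], ] + sc * gn
          }
        }
        dH <- matrix(0, nrow(fw$H), mcfg$d_model)
        for (i in seq_along(ucells)) {
          idx <- fw$rows[[i]]
          if (length(idx)) {
            dH[idx, ] <- matrix(demb[i, ] / length(idx), length(idx),
                                mcfg$d_model, byrow = TRUE)
          }
        }
        grads <- transformer_backward(params, mcfg, fw, dH)
        upd <- adamw_step(params, grads, opt, lr = lr,
                          weight_decay = weight_decay)
        params <- upd$params; opt <- upd$state
        ep_loss[bi] <- mean(losses)
      }
      history <- rbind(history, data.frame(epoch = ep, loss = mean(ep_loss)))
    }
    list(model = structure(list(config = mcfg, params = params),
                           class = "atac_model"),
         history = history)
  })
}
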