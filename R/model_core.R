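#' Model configuration
#'
#' Hyperparameters of the region-set transformer encoder. The encoder is
#' deliberately free of positional encodings: a cell is an unordered set of
#' region tokens, so per-token outputs must be permutation-equivariant and
#' pooled cell embeddings permutation-invariant. Desk-scale defaults
#' (`d_model = 64`, 4 layers, 4 heads, context 256) are small presets for
#' laptop-scale experiments; `max_context = 8192` mirrors atlas-scale use.
#'
#' @param vocab_size number of vocabulary regions V (one PAD id is reserved
#'   internally at id V, after the region ids).
#' @param d_model embedding dimension (divisible by `n_heads`).
#' @param n_layers number of stacked encoder layers.
#' @param n_heads attention heads.
#' @param ffn_dim feed-forward hidden width (default `4 * d_model`).
#' @param dropout dropout rate on the residual branches during training.
#' @param max_context context window C used by the default tokenizer policy.
#' @return A `model_config`.
#' @export
model_config <- function(vocab_size, d_model = 64L, n_layers = 4L, n_heads = 4L,
                         ffn_dim = 4L * d_model, dropout = 0, max_context = 256L) {
  stopifnot(vocab_size >= 1L, d_model >= 1L, n_layers >= 1L, n_heads >= 1L,
            ffn_dim >= 1L, d_model %% n_heads == 0L, max_context >= 1L,
            dropout >= 0, dropout < 1)
  structure(list(vocab_size = as.integer(vocab_size),
                 d_model = as.integer(d_model),
                 n_layers = as.integer(n_layers),
                 n_heads = as.integer(n_heads),
                 ffn_dim = as.integer(ffn_dim),
                 dropout = dropout,
                 max_context = as.integer(max_context)),
            class = "model_config")
}

#' Initialize a region-set transformer model
#'
#' Token embedding table (plus one reserved PAD row), pre-normalization
#' transformer encoder layers (multi-head self-attention and GELU
#' feed-forward, residual connections, final layer norm), and a
#' replaced-token-detection head. The head is zero-initialized so an
#' untrained model predicts replacement probability exactly 0.5.
#'
#' @param config a `model_config`.
#' @param seed integer seed for weight initialization.
#' @return An `atac_model` (list with `config` and `params`).
#' @export
init_model <- function(config, seed = 0L) {
  stopifnot(inherits(config, "model_config"))
  structure(list(config = config,
                 params = init_encoder_params(config, seed = seed)),
            class = "atac_model")
}

#' @export
print.atac_model <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(paste0("region-set transformer: V=%d, d_model=%d, %d layer(s), ",
                     "%d head(s), %s parameter(s)\n"),
              cfg$vocab_size, cfg$d_model, cfg$n_layers, cfg$n_heads,
              format(n_parameters(x), big.mark = ",")))
  invisible(x)
}

#' Number of trainable parameters
#' @param model an `atac_model`.
#' @return integer count over all weights and biases.
#' @export
n_parameters <- function(model) {
  sum(vapply(model$params, length, numeric(1)))
}

as_token_list <- function(cells) {
  if (inherits(cells, "token_sequence")) cells <- list(cells)
  lapply(cells, function(x) {
    if (inherits(x, "token_sequence")) x$tokens else as.integer(x)
  })
}

cell_ids_of <- function(cells) {
  if (inherits(cells, "token_sequence")) cells <- list(cells)
  vapply(seq_along(cells), function(i) {
    x <- cells[[i]]
    if (inherits(x, "token_sequence")) x$cell_id
    else names(cells)[i] %||% sprintf("cell%d", i)
  }, character(1L))
}

#' Encode a batch of cells
#'
#' Runs the transformer forward pass in evaluation mode (no dropout) and
#' returns the final-layer contextual embedding of every token. Cells are
#' processed as ragged sequences: padding positions are never materialized,
#' which realizes the contract that PAD carries no gradient and is excluded
#' from pooling and loss. An optional context policy is applied first.
#'
#' @param model an `atac_model`.
#' @param cells a list of `token_sequence` (or bare integer id vectors).
#' @param policy optional `context_policy` applied per cell before encoding.
#' @return An `encoded_batch`: list with `H` (total-tokens x d_model matrix of
#'   contextual embeddings), `rows` (per-cell row indices into `H`),
#'   `token_ids` (0-based), `cell_ids`, `lens`.
#' @export
encode <- function(model, cells, policy = NULL) {
  stopifnot(inherits(model, "atac_model"))
  ids <- cell_ids_of(cells)
  tl <- as_token_list(cells)
  if (!is.null(policy)) {
    tl <- lapply(seq_along(tl), function(i)
      apply_context_policy(token_sequence(ids[i], tl[[i]]), policy)$tokens)
  }
  if (any(lengths(tl) == 0L)) {
    warning("encode: batch contains empty cell(s); their pooled embedding is the zero vector")
  }
  fw <- transformer_forward(model$params, model$config, tl,
                            train = FALSE, want_cache = FALSE)
  structure(list(H = fw$H, rows = fw$rows, token_ids = fw$ids,
                 cell_ids = ids, lens = fw$lens,
                 d_model = model$config$d_model),
            class = "encoded_batch")
}

#' Replaced-token-detection probabilities
#'
#' Per-position probability that the token was replaced:
#' `y_hat_j = sigmoid(w_o . h_j + b)` on the final contextual embeddings.
#'
#' @param model an `atac_model`.
#' @param encoded an `encoded_batch` from [encode()].
#' @return numeric vector of probabilities in (0, 1), one per token position
#'   (aligned with `encoded$token_ids`).
#' @export
rtd_probabilities <- function(model, encoded) {
  stopifnot(inherits(encoded, "encoded_batch"))
  sigmoid(drop(encoded$H %*% model$params$rtd_w) + model$params$rtd_b)
}

#' Mean-pooled cell embeddings
#'
#' The cell embedding is the arithmetic mean of the cell's non-pad
#' contextual token embeddings. Empty cells yield the zero vector (with a
#' warning at encode time).
#'
#' @param encoded an `encoded_batch`.
#' @return matrix (cells x d_model), rownames = cell ids.
#' @export
cell_embedding <- function(encoded) {
  stopifnot(inherits(encoded, "encoded_batch"))
  out <- matrix(0, length(encoded$rows), encoded$d_model)
  for (i in seq_along(encoded$rows)) {
    idx <- encoded$rows[[i]]
    if (length(idx)) {
      out[i, ] <- colMeans(encoded$H[idx, , drop = FALSE])
    }
  }
  rownames(out) <- encoded$cell_ids
  out
}

#' Contextualized region embeddings for one cell
#'
#' Exposes the per-token final-layer embeddings, before pooling, paired with
#' their vocabulary ids. The same vocabulary id embedded in different cells
#' generally yields different vectors: the representation is
#' context-dependent.
#'
#' @param model an `atac_model`.
#' @param cell a `token_sequence` (or integer id vector).
#' @return list with `token_ids` (0-based integer vector) and `embeddings`
#'   (k x d_model matrix, row j for token j).
#' @export
contextual_region_embeddings <- function(model, cell) {
  enc <- encode(model, list(cell))
  list(token_ids = enc$token_ids, embeddings = enc$H)
}

#' Save / load a model checkpoint
#'
#' Single-file container holding the config and all weights, plus a sidecar
#' human-readable key-value config when `config_path` is given.
#'
#' @param model an `atac_model`.
#' @param path checkpoint path (.rds).
#' @param config_path optional path for a plain-text key=value config dump.
#' @export
save_model <- function(model, path, config_path = NULL) {
  saveRDS(model, path)
  if (!is.null(config_path)) {
    writeLines(sprintf("%s=%s", names(model$config),
                       vapply(model$config, format, character(1L))),
               config_path)
  }
  invisible(path)
}

#' @rdname save_model
#' @return `load_model`: the restored `atac_model`.
#' @export
load_model <- function(path) {
  m <- readRDS(path)
  stopifnot(inherits(m, "atac_model"))
  m
}
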