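#' Per-region embedding matrix
#'
#' Returns one embedding vector per vocabulary region. With `cells = NULL`
#' these are the static rows of the token embedding table. When cells are
#' given, each region's row is the mean of its contextualized embeddings
#' over every cell in which the region occurs (the representation used for
#' the TSS distribution score and icTSS detection); regions that occur in
#' no cell fall back to their static embedding.
#'
#' @param model an `atac_model`.
#' @param cells optional list of `token_sequence` to contextualize over.
#' @param batch_size cells encoded per forward pass.
#' @return V x d_model matrix; row `i` is vocabulary id `i - 1`.
#' @export
region_embedding_matrix <- function(model, cells = NULL, batch_size = 64L) {
  stopifnot(inherits(model, "atac_model"))
  V <- model$config$vocab_size
  d <- model$config$d_model
  static <- model$params$E[seq_len(V), , drop = FALSE]
  if (is.null(cells)) return(static)
  acc <- matrix(0, V, d)
  cnt <- numeric(V)
  tl <- as_token_list(cells)
  batches <- split(seq_along(tl), ceiling(seq_along(tl) / batch_size))
  for (b in batches) {
    fw <- transformer_forward(model$params, model$config, tl[b])
    if (!length(fw$ids)) next
    rs <- rowsum(fw$H, fw$ids)
    rows <- as.integer(rownames(rs)) + 1L
    acc[rows, ] <- acc[rows, , drop = FALSE] + rs
    tb <- table(fw$ids)
    cnt[as.integer(names(tb)) + 1L] <- cnt[as.integer(names(tb)) + 1L] +
      as.numeric(tb)
  }
  seen <- cnt > 0
  acc[seen, ] <- acc[seen, , drop = FALSE] / cnt[seen]
  acc[!seen, ] <- static[!seen, , drop = FALSE]
  acc
}
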