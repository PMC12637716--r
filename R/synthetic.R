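#' Synthetic atlas configuration
#'
#' Conditions of the desk-scale synthetic scATAC atlas: each cell type has a
#' disjoint set of marker regions (its accessible program) opened
#' independently with `marker_open_prob`; the remaining non-marker regions
#' form a shared background opened with `background_open_prob`. Expected
#' tokens per cell is therefore
#' `markers_per_type * marker_open_prob + n_background * background_open_prob`.
#'
#' @param n_cell_types number of cell types.
#' @param markers_per_type marker regions per type (disjoint across types).
#' @param marker_open_prob per-cell opening probability of an own-type marker.
#' @param background_open_prob per-cell opening probability of a background
#'   region.
#' @param cells_per_type cells generated per type.
#' @param seed RNG seed (generation is bit-reproducible given the seed).
#' @param marker_ids optional list of explicit 0-based marker id vectors
#'   (one per type, pairwise disjoint); overrides random assignment.
#' @return A `synthetic_atlas_config`.
#' @export
synthetic_atlas_config <- function(n_cell_types = 5L, markers_per_type = 100L,
                                   marker_open_prob = 0.9,
                                   background_open_prob = 0.02,
                                   cells_per_type = 200L, seed = 0L,
                                   marker_ids = NULL) {
  stopifnot(marker_open_prob >= 0, marker_open_prob <= 1,
            background_open_prob >= 0, background_open_prob <= 1,
            n_cell_types >= 1L, cells_per_type >= 1L)
  if (!is.null(marker_ids)) {
    stopifnot(length(marker_ids) == n_cell_types,
              anyDuplicated(unlist(marker_ids)) == 0L)
  }
  structure(list(n_cell_types = as.integer(n_cell_types),
                 markers_per_type = as.integer(markers_per_type),
                 marker_open_prob = marker_open_prob,
                 background_open_prob = background_open_prob,
                 cells_per_type = as.integer(cells_per_type),
                 seed = as.integer(seed), marker_ids = marker_ids),
            class = "synthetic_atlas_config")
}

#' Generate a toy vocabulary with TSS and cCRE truth
#'
#' Places `V` non-overlapping regions on a single toy chromosome, puts a TSS
#' near a configurable fraction of regions (half inside the region, half
#' within `promoter_window` bp downstream of it), and derives cCRE classes
#' from the realized TSS distances: 0 -> PLS, (0, promoter_window] -> pELS,
#' otherwise dELS. This gives the annotation modules coherent ground truth.
#'
#' @param genome_length toy chromosome length (bp).
#' @param V vocabulary size; requires `V * max_len < genome_length`.
#' @param min_len,max_len region length bounds (bp).
#' @param tss_fraction fraction of regions that receive a nearby TSS.
#' @param promoter_window proximity window defining the pELS class (bp).
#' @param seed RNG seed.
#' @param chrom chromosome name of the toy genome.
#' @return list with `vocab` (a `vocabulary`), `tss` (TSS records), `ccre`
#'   (labeled `region_set`), and `annotation` (a `region_annotation`).
#' @export
generate_vocabulary <- function(genome_length = 2e6, V = 2000L, min_len = 150L,
                                max_len = 500L, tss_fraction = 0.25,
                                promoter_window = 200L, seed = 0L,
                                chrom = "chrS") {
  stopifnot(V >= 1L, min_len >= 1L, max_len >= min_len)
  if (V * max_len >= genome_length) {
    stop("generate_vocabulary: infeasible packing (V * max_len >= genome_length)",
         call. = FALSE)
  }
  with_local_seed(seed, {
    len <- sample.int(max_len - min_len + 1L, V, replace = TRUE) + min_len - 1L
    slack <- genome_length - sum(len)
    if (slack < V) stop("generate_vocabulary: infeasible packing (no room for gaps)",
                        call. = FALSE)
    gaps <- diff(c(0L, sort(sample.int(slack, V))))
    starts <- cumsum(gaps) + cumsum(c(0L, len[-V]))
    vocab <- validate_vocabulary(region_set(rep(chrom, V), starts, starts + len))
    n_tss <- round(tss_fraction * V)
    with_tss <- sort(sample.int(V, n_tss))
    inside <- stats::runif(n_tss) < 0.5
    vdf <- as.data.frame(vocab)
    pos <- integer(n_tss)
    for (i in seq_len(n_tss)) {
      r <- with_tss[i]
      pos[i] <- if (inside[i]) {
        vdf$start[r] + sample.int(vdf$end[r] - vdf$start[r], 1L) - 1L
      } else {
        vdf$end[r] + sample.int(promoter_window, 1L)
      }
    }
    tss <- tss_records(chrom = rep(chrom, n_tss), position = pos,
                       strand = sample(c("+", "-"), n_tss, replace = TRUE),
                       gene_id = sprintf("G%05d", seq_len(n_tss)))
    dist_ann <- annotate_tss_distance(vocab, tss)
    cls <- ifelse(dist_ann$tss_distance == 0, "PLS",
                  ifelse(dist_ann$tss_distance <= promoter_window, "pELS",
                         "dELS"))
    ccre <- as_region_set(data.frame(chrom = vdf$chrom, start = vdf$start,
                                     end = vdf$end, class = cls,
                                     stringsAsFactors = FALSE))
    annotation <- data.frame(dist_ann, ccre_class = cls,
                             stringsAsFactors = FALSE)
    class(annotation) <- c("region_annotation", "data.frame")
    list(vocab = vocab, tss = tss, ccre = ccre, annotation = annotation)
  })
}

#' Generate synthetic cells from an atlas configuration
#'
#' Each cell opens its type's marker regions independently with
#' `marker_open_prob` and background (non-marker) regions with
#' `background_open_prob`. Cells are emitted either as token sequences or as
#' a fragment store (one fragment placed uniformly inside each open region),
#' exercising both ingestion routes; fragments tokenize back to exactly the
#' sampled open-region sets.
#'
#' @param vocab a `vocabulary`.
#' @param cfg a `synthetic_atlas_config`.
#' @param emit `"tokens"` (default) or `"fragments"`.
#' @param fragment_length fragment size when emitting fragments (clipped to
#'   the region).
#' @return list with `cells` (list of `token_sequence`, or a
#'   `cell_fragment_store`) and `truth` (labels, marker ids, config).
#' @export
generate_cells <- function(vocab, cfg = synthetic_atlas_config(),
                           emit = c("tokens", "fragments"),
                           fragment_length = 50L) {
  emit <- match.arg(emit)
  stopifnot(inherits(vocab, "vocabulary"),
            inherits(cfg, "synthetic_atlas_config"))
  V <- vocab_size(vocab)
  K <- cfg$n_cell_types
  with_local_seed(cfg$seed, {
    markers <- cfg$marker_ids
    if (is.null(markers)) {
      stopifnot(K * cfg$markers_per_type <= V)
      all_m <- sample.int(V, K * cfg$markers_per_type) - 1L
      markers <- split(all_m, rep(seq_len(K), each = cfg$markers_per_type))
    }
    markers <- lapply(markers, function(x) sort(as.integer(x)))
    background <- setdiff(seq_len(V) - 1L, unlist(markers))
    n_cells <- K * cfg$cells_per_type
    labels <- rep(sprintf("type%d", seq_len(K)), each = cfg$cells_per_type)
    cell_ids <- sprintf("cell%05d", seq_len(n_cells))
    token_sets <- vector("list", n_cells)
    for (i in seq_len(n_cells)) {
      t <- (i - 1L) %/% cfg$cells_per_type + 1L
      mk <- markers[[t]]
      open_m <- mk[stats::runif(length(mk)) < cfg$marker_open_prob]
      open_b <- background[stats::runif(length(background)) <
                             cfg$background_open_prob]
      token_sets[[i]] <- sort(c(open_m, open_b))
    }
    truth <- list(labels = labels, cell_ids = cell_ids, marker_ids = markers,
                  background_ids = background, config = cfg)
    if (emit == "tokens") {
      cells <- lapply(seq_len(n_cells), function(i)
        token_sequence(cell_ids[i], token_sets[[i]]))
      names(cells) <- cell_ids
      return(list(cells = cells, truth = truth))
    }
    vdf <- as.data.frame(vocab)
    frs <- lapply(seq_len(n_cells), function(i) {
      ids <- token_sets[[i]]
      if (!length(ids)) {
        return(data.frame(chrom = character(), start = integer(),
                          end = integer(), barcode = character(),
                          count = integer(), stringsAsFactors = FALSE))
      }
      s <- vdf$start[ids + 1L]; e <- vdf$end[ids + 1L]
      fl <- pmin(fragment_length, e - s)
      off <- vapply(e - s - fl + 1L, function(w) sample.int(w, 1L) - 1L,
                    integer(1L))
      data.frame(chrom = vdf$chrom[ids + 1L], start = s + off,
                 end = s + off + fl, barcode = cell_ids[i],
                 count = 1L, stringsAsFactors = FALSE)
    })
    names(frs) <- cell_ids
    list(cells = new_fragment_store(frs), truth = truth)
  })
}

#' Generate paired multiome cells (ATAC tokens + RNA expression)
#'
#' The ATAC side follows [generate_cells()]. The RNA side draws, for each
#' cell, its type's mean expression profile (a shared baseline with marker
#' genes elevated by `marker_boost` in their own type) plus Gaussian noise,
#' clamped non-negative.
#'
#' @param vocab a `vocabulary`.
#' @param cfg a `synthetic_atlas_config`.
#' @param n_genes number of genes.
#' @param marker_genes_per_type marker genes per type (disjoint).
#' @param marker_boost additive expression boost of a marker gene in its own
#'   type.
#' @param noise_sd Gaussian noise standard deviation on expression.
#' @param seed RNG seed for the RNA side (the ATAC side uses `cfg$seed`).
#' @return list with `cells` (list of `paired_multiome_cell`) and `truth`
#'   (including `gene_markers`, a list of marker gene indices per type, and
#'   `type_means`, the K x n_genes matrix of noise-free profiles).
#' @export
generate_paired_multiome <- function(vocab, cfg = synthetic_atlas_config(),
                                     n_genes = 100L,
                                     marker_genes_per_type = 5L,
                                     marker_boost = 3, noise_sd = 0.5,
                                     seed = cfg$seed + 1L) {
  atac <- generate_cells(vocab, cfg, emit = "tokens")
  K <- cfg$n_cell_types
  stopifnot(K * marker_genes_per_type <= n_genes)
  with_local_seed(seed, {
    baseline <- stats::runif(n_genes, 0, 2)
    gm <- split(sample.int(n_genes, K * marker_genes_per_type),
                rep(seq_len(K), each = marker_genes_per_type))
    type_means <- matrix(baseline, K, n_genes, byrow = TRUE)
    for (t in seq_len(K)) type_means[t, gm[[t]]] <- type_means[t, gm[[t]]] +
      marker_boost
    type_of <- rep(seq_len(K), each = cfg$cells_per_type)
    cells <- lapply(seq_along(atac$cells), function(i) {
      rna <- pmax(0, type_means[type_of[i], ] +
                    stats::rnorm(n_genes, sd = noise_sd))
      paired_multiome_cell(atac$cells[[i]], rna,
                           label = atac$truth$labels[i])
    })
    names(cells) <- atac$truth$cell_ids
    truth <- atac$truth
    truth$gene_markers <- gm
    truth$type_means <- type_means
    list(cells = cells, truth = truth)
  })
}

#' Plant inferred-cryptic-TSS ground truth
#'
#' Selects `n_plant` highly distal (dELS-labeled, largest TSS distance)
#' regions as latent promoters, and emits a promoter-mark-like signal track
#' carrying `signal_value` over the planted regions and `background_value`
#' over all other vocabulary regions. The returned ids are meant to be added
#' to one cell type's marker set (via `marker_ids` of
#' [synthetic_atlas_config()]) so that, after training, their embeddings
#' become promoter-context-like while their annotation stays distal.
#'
#' @param vocab a `vocabulary`.
#' @param annotation a `region_annotation` of `vocab`.
#' @param n_plant number of regions to plant.
#' @param signal_value track value over planted regions.
#' @param background_value track value elsewhere.
#' @param distal_pool_frac planted ids are sampled from this most-distal
#'   fraction of dELS regions.
#' @param seed RNG seed.
#' @return list with `annotation` (gains a logical `planted` column),
#'   `signal` (a `signal_track`), and `planted_ids`.
#' @export
plant_ictss <- function(vocab, annotation, n_plant = 10L, signal_value = 10,
                        background_value = 0.1, distal_pool_frac = 0.05,
                        seed = 0L) {
  stopifnot(inherits(vocab, "vocabulary"), n_plant >= 1L)
  distal <- which(annotation$ccre_class == "dELS" &
                    is.finite(annotation$tss_distance))
  if (length(distal) < n_plant) {
    stop(sprintf("plant_ictss: only %d distal region(s) available, need %d",
                 length(distal), n_plant), call. = FALSE)
  }
  pool_n <- max(n_plant, ceiling(distal_pool_frac * nrow(annotation)))
  pool <- distal[order(-annotation$tss_distance[distal])][
    seq_len(min(pool_n, length(distal)))]
  planted_rows <- with_local_seed(seed, sort(sample(pool, n_plant)))
  planted_ids <- annotation$id[planted_rows]
  annotation$planted <- FALSE
  annotation$planted[planted_rows] <- TRUE
  vdf <- as.data.frame(vocab)
  val <- rep(background_value, nrow(vdf))
  val[match(planted_ids, vdf$id)] <- signal_value
  signal <- as_region_set(data.frame(chrom = vdf$chrom, start = vdf$start,
                                     end = vdf$end, value = val,
                                     stringsAsFactors = FALSE))
  class(signal) <- c("signal_track", class(signal))
  list(annotation = annotation, signal = signal, planted_ids = planted_ids)
}
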