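# Cell searching: find regions with suitable single-molecule spot density in
# the fluorescence channel and true cell regions in the SRIC channel, then
# rank acquisition targets by area.

#' Predict suitable-density regions in a fluorescence snapshot
#'
#' Runs the trained suitability network, thresholds the probability map at
#' `cutoff` and labels connected components; components smaller than
#' `min_area` pixels are discarded as specks.
#'
#' @param snapshot fluorescence image matrix.
#' @param net trained encoder-decoder network.
#' @param cutoff probability cutoff (default 0.5).
#' @param min_area minimum component area in px (default 64, about one
#'   cell-scale blob at the default resolution).
#' @return list `map` (binary matrix), `labels` (integer component matrix),
#'   `regions` (data.frame `label, area, cx, cy`, 0-based centroids; empty if
#'   nothing qualifies), `prob` (raw probability map).
#' @export
predict_suitable_regions <- function(snapshot, net, cutoff = 0.5,
                                     min_area = 64L) {
  if (!isTRUE(net$trained)) stopf("network is untrained; refusing to predict")
  prob <- nn_forward(net, nn_normalize(snapshot))
  segment_prob_map(prob, cutoff, min_area)
}

#' Detect cell regions in an SRIC image
#'
#' Same mechanism as [predict_suitable_regions()] with a network trained on
#' SRIC masks; the mask excludes off-cell areas where fluorescent debris
#' would otherwise be picked up.
#'
#' @inheritParams predict_suitable_regions
#' @param sric SRIC image matrix.
#' @return as [predict_suitable_regions()], plus `mask` (alias of `map`).
#' @export
detect_cell_regions <- function(sric, net, cutoff = 0.5, min_area = 64L) {
  if (!isTRUE(net$trained)) stopf("network is untrained; refusing to predict")
  prob <- nn_forward(net, nn_normalize(sric))
  out <- segment_prob_map(prob, cutoff, min_area)
  out$mask <- out$map
  out
}

segment_prob_map <- function(prob, cutoff, min_area) {
  bin <- prob > cutoff
  labels <- EBImage::bwlabel(bin)
  regions <- component_table(labels)
  keep <- regions$area >= min_area
  drop <- regions$label[!keep]
  if (length(drop)) labels[labels %in% drop] <- 0L
  regions <- regions[keep, , drop = FALSE]
  map <- matrix(0L, nrow(prob), ncol(prob))
  map[labels > 0] <- 1L
  list(map = map, labels = labels, regions = regions, prob = prob)
}

component_table <- function(labels) {
  ids <- setdiff(sort(unique(as.integer(labels))), 0L)
  if (!length(ids))
    return(data.frame(label = integer(0), area = integer(0),
                      cx = numeric(0), cy = numeric(0)))
  idx <- which(labels > 0, arr.ind = TRUE)
  lab <- labels[labels > 0]
  area <- as.integer(table(factor(lab, levels = ids)))
  cy <- tapply(idx[, 1] - 1, factor(lab, levels = ids), mean)
  cx <- tapply(idx[, 2] - 1, factor(lab, levels = ids), mean)
  data.frame(label = ids, area = area, cx = as.numeric(cx), cy = as.numeric(cy))
}

#' Train a suitability / cell-region segmentation network
#'
#' Thin wrapper pairing images with binary masks and training with Adam.
#'
#' @param images list of image matrices.
#' @param masks list of 0/1 target masks.
#' @param channels,epochs,lr,batch_size,seed see [train_adam()].
#' @param strides encoder strides (see [nn_new()]).
#' @return list `net`, `trace`, `ars_after`.
#' @export
train_segmentation_net <- function(images, masks, channels = c(8L, 16L, 32L),
                                   epochs = 20L, lr = 1e-3, batch_size = 8L,
                                   strides = c(2L, 2L, 2L), seed = 1L) {
  net <- nn_new(channels = channels, strides = strides, seed = seed)
  fit <- train_adam(net, lapply(images, nn_normalize), masks,
                    epochs = epochs, lr = lr, batch_size = batch_size,
                    seed = seed)
  list(net = fit$net, trace = fit$trace, ars_after = fit$ars_after)
}

#' Rank acquisition targets across a tile scan
#'
#' Collects the suitable regions of every tile, sorts them by descending
#' area (ties broken by tile scan order, then label) and returns the top `k`
#' with stage coordinates at each region centroid.
#'
#' @param tile_regions list of region tables (one per tile, as returned in
#'   `$regions` by [predict_suitable_regions()]).
#' @param tile_origins data.frame `x, y` stage coordinate of each tile's
#'   pixel origin (same units as desired output, e.g. um), one row per tile
#'   in raster scan order.
#' @param k number of targets to return (default 10).
#' @param pixel_size um per pixel used to convert centroids to stage offsets.
#' @return data.frame `rank, tile, label, area, stage_x, stage_y` sorted by
#'   descending area; zero rows (with a `status` attribute
#'   `"no observable cells"`) when no region exists.
#' @export
rank_targets <- function(tile_regions, tile_origins, k = 10L,
                         pixel_size = 0.1) {
  rows <- list()
  for (t in seq_along(tile_regions)) {
    reg <- tile_regions[[t]]
    if (is.null(reg) || nrow(reg) == 0L) next
    rows[[length(rows) + 1L]] <- data.frame(
      tile = t, label = reg$label, area = reg$area,
      stage_x = tile_origins$x[t] + reg$cx * pixel_size,
      stage_y = tile_origins$y[t] + reg$cy * pixel_size)
  }
  if (!length(rows)) {
    out <- data.frame(rank = integer(0), tile = integer(0), label = integer(0),
                      area = integer(0), stage_x = numeric(0),
                      stage_y = numeric(0))
    attr(out, "status") <- "no observable cells"
    return(out)
  }
  all <- do.call(rbind, rows)
  ord <- order(-all$area, all$tile, all$label)
  all <- all[head(ord, k), , drop = FALSE]
  all <- cbind(rank = seq_len(nrow(all)), all)
  rownames(all) <- NULL
  all
}

#' Lay out a serpentine-free raster tile grid
#'
#' Stage origins for an `n x n` tile scan (raster rows, left to right), the
#' default acquisition layout of 225 = 15 x 15 fields of view.
#'
#' @param n tiles per side (default 15).
#' @param tile_px tile side in pixels.
#' @param pixel_size um per pixel.
#' @return data.frame `tile, row, col, x, y` in scan order.
#' @export
tile_grid <- function(n = 15L, tile_px = 512L, pixel_size = 0.1) {
  step <- tile_px * pixel_size
  grid <- expand.grid(col = seq_len(n) - 1L, row = seq_len(n) - 1L)
  data.frame(tile = seq_len(n * n), row = grid$row, col = grid$col,
             x = grid$col * step, y = grid$row * step)
}
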