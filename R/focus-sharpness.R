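# High-precision focus scoring: Otsu binarization, iris-edge ROI scan, and
# the peak/valley histogram sharpness score E.

#' Otsu intensity threshold
#'
#' Exhaustively maximizes the between-class variance over all candidate bin
#' boundaries. For integer-valued (e.g. 8-bit) images each distinct level is
#' its own bin, so the result coincides with a brute-force scan over all
#' levels; continuous images are binned into `n_bins` equal-width bins.
#'
#' @param image numeric matrix with at least two distinct values.
#' @param n_bins number of histogram bins for continuous data.
#' @return scalar threshold; binarize with `image > threshold`.
#' @export
otsu_threshold <- function(image, n_bins = 256L) {
  v <- as.numeric(image)
  rng <- range(v)
  if (rng[1] == rng[2]) stopf("cannot threshold a constant image")
  if (all(v == round(v)) && diff(rng) < n_bins) {
    levels <- seq(rng[1], rng[2])
    counts <- tabulate(v - rng[1] + 1L, nbins = length(levels))
    i <- otsu_split_index(counts, levels)
    return(levels[i] + 0.5)
  }
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  mids <- (breaks[-1] + breaks[-length(breaks)]) / 2
  bin <- pmin(pmax(findInterval(v, breaks, rightmost.closed = TRUE), 1L), n_bins)
  counts <- tabulate(bin, nbins = n_bins)
  i <- otsu_split_index(counts, mids)
  breaks[i + 1L]
}

#' Locate iris-edge regions of interest
#'
#' For each horizontal band of width `roi` (non-overlapping columns), a
#' `roi x roi` window is shifted from the top of the binarized image
#' downwards; the first position where the white fraction drops to 50% or
#' less straddles the edge and is kept. Bands without such a position (e.g.
#' all-white columns) are skipped.
#'
#' @param binary logical/0-1 matrix (TRUE/1 = white).
#' @param roi window side in pixels (default 21).
#' @return data.frame `row, col` of 1-based top-left window corners (empty if
#'   no window qualifies).
#' @export
find_edge_rois <- function(binary, roi = 21L) {
  b <- matrix(as.numeric(binary), nrow(binary), ncol(binary))
  H <- nrow(b); W <- ncol(b)
  out <- list()
  if (H < roi || W < roi) return(data.frame(row = integer(0), col = integer(0)))
  col_cum <- apply(b, 2, cumsum)
  for (c0 in seq(1L, W - roi + 1L, by = roi)) {
    cols <- c0:(c0 + roi - 1L)
    # white count of window starting at row r: sum over cols of cum[r+roi-1]-cum[r-1]
    band <- col_cum[, cols, drop = FALSE]
    tot <- rowSums(band)
    win <- tot[roi:H] - c(0, tot)[1:(H - roi + 1L)]
    hit <- which(win <= 0.5 * roi * roi)
    if (length(hit)) out[[length(out) + 1L]] <- data.frame(row = hit[1], col = c0)
  }
  if (!length(out)) return(data.frame(row = integer(0), col = integer(0)))
  do.call(rbind, out)
}

#' Sharpness score from a brightness histogram
#'
#' Implements the peak/valley evaluation: the histogram is bisected at the
#' Otsu split, each side is smoothed with a `smooth`-bin moving average
#' (windows shrink at the boundaries), the per-side maxima give the two peaks
#' and the minimum of the smoothed histogram strictly between them gives the
#' valley. The score is `E = N(Imax1) N(Imax2) / N(Imin)^2`; `E > 1` means
#' high sharpness (well-separated dark and bright edge populations). An empty
#' valley (`N(Imin) = 0`) yields `Inf`.
#'
#' @param counts histogram counts over ordered brightness bins.
#' @param mids optional bin centers (defaults to bin indices).
#' @param smooth moving-average width in bins (default 20; use 1 to skip
#'   smoothing).
#' @return list `E, peak1, peak2, valley` (bin indices into `counts`),
#'   `smoothed` (the smoothed histogram), `split` (last bin of the lower
#'   class).
#' @export
sharpness_from_histogram <- function(counts, mids = seq_along(counts),
                                     smooth = 20L) {
  if (sum(counts) <= 0) stopf("empty histogram")
  split <- otsu_split_index(counts, mids)
  lo <- moving_average(counts[1:split], smooth)
  hi <- moving_average(counts[(split + 1L):length(counts)], smooth)
  sm <- c(lo, hi)
  p1 <- which.max(lo)
  p2 <- split + which.max(hi)
  between <- if (p2 - p1 >= 2L) (p1 + 1L):(p2 - 1L) else integer(0)
  valley <- if (length(between)) between[which.min(sm[between])] else split
  Nmin <- sm[valley]
  E <- if (Nmin <= 0) Inf else sm[p1] * sm[p2] / Nmin^2
  list(E = E, peak1 = p1, peak2 = p2, valley = valley, smoothed = sm,
       split = split)
}

#' Iris-edge sharpness E of an image
#'
#' Full scoring pipeline on (the lower half of) an iris image: Otsu
#' binarization, edge ROI detection, a 512-bin brightness histogram of all
#' edge-ROI pixels between the minimum and maximum brightness, then the
#' peak/valley score of [sharpness_from_histogram()]. The binning spans the
#' observed intensity range, so E is invariant under affine rescaling of the
#' image brightness.
#'
#' @param image intensity matrix (lower half of the iris view).
#' @param roi edge ROI side (px).
#' @param n_bins histogram bins (default 512).
#' @param smooth moving-average width (bins).
#' @return list `E`, `histogram` (counts), `mids`, `rois` (ROI corners), plus
#'   the fields of [sharpness_from_histogram()].
#' @export
sharpness_E <- function(image, roi = 21L, n_bins = 512L, smooth = 20L) {
  thr <- otsu_threshold(image)
  rois <- find_edge_rois(image > thr, roi = roi)
  if (nrow(rois) == 0L) stopf("no edge ROI found")
  px <- unlist(lapply(seq_len(nrow(rois)), function(i) {
    image[rois$row[i]:(rois$row[i] + roi - 1L),
          rois$col[i]:(rois$col[i] + roi - 1L)]
  }))
  rng <- range(px)
  if (rng[1] == rng[2]) stopf("edge ROIs are constant")
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  bin <- pmin(pmax(findInterval(px, breaks, rightmost.closed = TRUE), 1L), n_bins)
  counts <- tabulate(bin, nbins = n_bins)
  mids <- (breaks[-1] + breaks[-length(breaks)]) / 2
  res <- sharpness_from_histogram(counts, mids, smooth = smooth)
  c(list(histogram = counts, mids = mids, rois = rois), res)
}
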