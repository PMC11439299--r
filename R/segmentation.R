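#' Segment nuclei from the blue counterstain channel
#'
#' The nuclear compartment is defined by the area encompassed by the blue
#' fluorescence. Pipeline: global Otsu threshold (on the min-max-normalized
#' image) -> binary closing -> hole filling -> removal of components below
#' `min_area` -> connected-component labeling -> optional distance-transform
#' watershed split of touching nuclei. Deterministic for fixed input and
#' parameters.
#'
#' @param blue 2-D non-negative intensity matrix (blue channel).
#' @param min_area minimum nucleus area in pixels; smaller components are
#'   discarded. Default is 25% of the area of a 10 px-radius disk.
#' @param closing_size diameter (odd, pixels) of the disc brush used for
#'   binary closing.
#' @param split_touching if `TRUE`, touching nuclei are split by watershed
#'   on the distance transform (ties broken toward the lower label id).
#' @param fill_holes fill interior holes after closing.
#' @return an object of class `nucleus_map`: list with `labels` (integer
#'   matrix; 0 = background, k > 0 = nucleus k, labels contiguous from 1),
#'   `nuclei` (data.frame: `label, row, col, area, equiv_radius, border` —
#'   centroid coordinates, pixel area, radius of the equal-area disk, and
#'   whether the nucleus touches the image border), `threshold` (on the
#'   original intensity scale), and the parameters used.
#'
#' A constant image (no contrast) yields an empty map with a warning, not
#' an error.
#' @export
segment_nuclei <- function(blue, min_area = 0.25 * pi * 10^2,
                           closing_size = 5, split_touching = FALSE,
                           fill_holes = TRUE) {
  stopifnot(is.matrix(blue), all(blue >= 0))
  rng <- range(blue)
  if (diff(rng) == 0) {
    warning("constant blue channel: no foreground/background contrast; ",
            "returning empty label map")
    return(empty_nucleus_map(blue, params = list(min_area = min_area)))
  }
  x <- (blue - rng[1]) / diff(rng)
  th_norm <- EBImage::otsu(EBImage::Image(x), range = c(0, 1), levels = 256)
  th <- rng[1] + th_norm * diff(rng)
  # a usable stain must lift the foreground clear of the background noise;
  # on a noise-only image Otsu just splits the noise in half
  if (th <= median(blue) + 3 * mad(blue)) {
    warning("no foreground/background contrast above noise; ",
            "returning empty label map")
    return(empty_nucleus_map(blue, params = list(min_area = min_area)))
  }
  bw <- x > th_norm
  if (closing_size >= 3) {
    brush <- EBImage::makeBrush(closing_size, shape = "disc")
    bw <- EBImage::closing(bw, brush) > 0
  }
  if (fill_holes) bw <- EBImage::fillHull(bw) > 0
  lab <- EBImage::bwlabel(bw)
  if (split_touching && max(lab) > 0) {
    dm <- EBImage::distmap(lab > 0)
    lab <- EBImage::watershed(dm)
  }
  lab <- matrix(as.integer(lab), nrow(blue), ncol(blue))
  # drop small components, relabel contiguously in raster order
  if (max(lab) > 0) {
    areas <- tabulate(lab, nbins = max(lab))
    keep <- which(areas >= min_area)
    remap <- integer(max(lab))
    remap[keep] <- seq_along(keep)
    lab[lab > 0] <- remap[lab[lab > 0]]
  }
  build_nucleus_map(blue, lab, threshold = th,
                    params = list(min_area = min_area,
                                  closing_size = closing_size,
                                  split_touching = split_touching))
}

empty_nucleus_map <- function(img, params = list()) {
  build_nucleus_map(img, matrix(0L, nrow(img), ncol(img)),
                    threshold = NA_real_, params = params)
}

build_nucleus_map <- function(img, lab, threshold, params) {
  k <- max(lab)
  if (k > 0) {
    idx <- which(lab > 0)
    l <- lab[idx]
    rw <- (idx - 1) %% nrow(lab) + 1
    cl <- (idx - 1) %/% nrow(lab) + 1
    area <- tabulate(l, nbins = k)
    cent_r <- rowsum(rw, l)[, 1] / area
    cent_c <- rowsum(cl, l)[, 1] / area
    on_border <- rw == 1 | rw == nrow(lab) | cl == 1 | cl == ncol(lab)
    border <- tabulate(l[on_border], nbins = k) > 0
    nuclei <- data.frame(label = seq_len(k), row = cent_r, col = cent_c,
                         area = area, equiv_radius = sqrt(area / pi),
                         border = border)
  } else {
    nuclei <- data.frame(label = integer(0), row = numeric(0),
                         col = numeric(0), area = integer(0),
                         equiv_radius = numeric(0), border = logical(0))
  }
  structure(list(labels = lab, nuclei = nuclei, threshold = threshold,
                 params = params),
            class = "nucleus_map")
}

#' @export
print.nucleus_map <- function(x, ...) {
  cat("nucleus_map:", nrow(x$nuclei), "nuclei,",
      nrow(x$labels), "x", ncol(x$labels), "px",
      if (!is.na(x$threshold)) paste0("(threshold ", signif(x$threshold, 4), ")"),
      "\n")
  invisible(x)
}

#' Number of segmented nuclei
#' @param map a `nucleus_map`.
#' @return integer count.
#' @export
n_nuclei <- function(map) nrow(map$nuclei)

#' Match segmented nuclei to ground-truth cells
#'
#' Greedy nearest-centroid matching: candidate (label, cell) pairs are
#' sorted by centroid distance and accepted while both sides are unmatched
#' and the distance is within `max_dist` (by default each cell's own
#' nucleus radius). Unmatched labels are false positives; unmatched
#' manifest cells are false negatives.
#'
#' @param map a `nucleus_map`.
#' @param truth manifest rows for the same field (needs `cell_id, row, col`
#'   and, if `max_dist` is `NULL`, `nucleus_radius`).
#' @param max_dist matching radius in pixels, or `NULL` to use each cell's
#'   `nucleus_radius`.
#' @return list with `matches` (data.frame `label, cell_id, dist`),
#'   `precision`, `recall`, `n_false_pos`, `n_false_neg`.
#' @export
match_to_ground_truth <- function(map, truth, max_dist = NULL) {
  stopifnot(inherits(map, "nucleus_map"), is.data.frame(truth))
  nl <- nrow(map$nuclei); nt <- nrow(truth)
  if (nl == 0 || nt == 0) {
    return(list(matches = data.frame(label = integer(0),
                                     cell_id = integer(0), dist = numeric(0)),
                precision = if (nl == 0) NA_real_ else 0,
                recall = if (nt == 0) NA_real_ else 0,
                n_false_pos = nl, n_false_neg = nt))
  }
  d <- outer(map$nuclei$row, truth$row, `-`)^2 +
    outer(map$nuclei$col, truth$col, `-`)^2
  d <- sqrt(d)
  lim <- if (is.null(max_dist)) {
    matrix(truth$nucleus_radius, nl, nt, byrow = TRUE)
  } else matrix(max_dist, nl, nt)
  ord <- order(d)
  used_l <- logical(nl); used_t <- logical(nt)
  ml <- integer(0); mt <- integer(0); md <- numeric(0)
  for (k in ord) {
    i <- (k - 1) %% nl + 1; j <- (k - 1) %/% nl + 1
    if (d[k] <= lim[k] && !used_l[i] && !used_t[j]) {
      used_l[i] <- TRUE; used_t[j] <- TRUE
      ml <- c(ml, map$nuclei$label[i]); mt <- c(mt, truth$cell_id[j])
      md <- c(md, d[k])
    }
  }
  list(matches = data.frame(label = ml, cell_id = mt, dist = md),
       precision = sum(used_l) / nl, recall = sum(used_t) / nt,
       n_false_pos = sum(!used_l), n_false_neg = sum(!used_t))
}
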