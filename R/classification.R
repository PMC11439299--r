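#' Delineate per-cell nuclear and cytoplasmic regions
#'
#' Each cell body is approximated by dilating its segmented nucleus by
#' `ring_width` pixels; where dilated bodies would overlap, pixels are
#' assigned to the nearest nucleus (a Voronoi partition, computed by
#' seeded region growing from the nucleus labels). The cytoplasmic region
#' of a cell is its cell region minus every nucleus pixel, so nuclear and
#' cytoplasmic regions are disjoint by construction.
#'
#' @param map a [segment_nuclei()] result.
#' @param ring_width dilation width in pixels; default 0.8 x the median
#'   equivalent nucleus radius (the cytoplasmic extent is not observable
#'   from the counterstain, so this is a tunable geometric assumption).
#' @return an object of class `cell_regions`: `cell_labels` (integer
#'   matrix, nucleus + cytoplasm per cell), `nucleus_labels` (the input
#'   label matrix), `ring_width`.
#' @export
define_cell_regions <- function(map, ring_width = NULL) {
  stopifnot(inherits(map, "nucleus_map"))
  if (is.null(ring_width)) {
    if (n_nuclei(map) == 0)
      stop_nucloc("empty label map: cannot derive a default ring_width")
    ring_width <- 0.8 * median(map$nuclei$equiv_radius)
  }
  if (ring_width <= 0) stop_nucloc("ring_width must be > 0")
  lab <- map$labels
  if (max(lab) == 0) {
    return(structure(list(cell_labels = lab, nucleus_labels = lab,
                          ring_width = ring_width),
                     class = "cell_regions"))
  }
  size <- 2L * as.integer(round(ring_width)) + 1L
  mask <- EBImage::dilate(lab > 0, EBImage::makeBrush(size, "disc")) > 0
  # constant-cost region growing from the nucleus seeds == nearest-nucleus
  cell <- EBImage::propagate(EBImage::Image(matrix(0, nrow(lab), ncol(lab))),
                             EBImage::Image(lab), mask = mask)
  cell <- matrix(as.integer(cell), nrow(lab), ncol(lab))
  structure(list(cell_labels = cell, nucleus_labels = lab,
                 ring_width = ring_width),
            class = "cell_regions")
}

#' Threshold the green channel into a positive-pixel mask
#'
#' A pixel is green-positive when its intensity exceeds
#' `background + k * noise_sd`, with background and noise estimated
#' robustly (median and MAD) from pixels outside every cell region. When
#' no such background pixels exist the threshold falls back to global Otsu
#' with a warning.
#'
#' @param green 2-D intensity matrix (green channel).
#' @param regions optional [define_cell_regions()] result; pixels with
#'   `cell_labels == 0` are the background sample. Without it, the whole
#'   image is used (adequate for sparse fields).
#' @param k threshold multiplier on the robust noise SD (default 3, the
#'   three-sigma rule: expected per-pixel false-positive rate under
#'   Gaussian noise about 0.0013 one-sided).
#' @return logical matrix with attributes `threshold`, `background`,
#'   `noise_sd`.
#' @export
green_positive_mask <- function(green, regions = NULL, k = 3) {
  stopifnot(is.matrix(green))
  bgpix <- if (is.null(regions)) as.vector(green)
           else green[regions$cell_labels == 0]
  if (length(bgpix) == 0) {
    warning("no background pixels outside cell regions; ",
            "falling back to a global Otsu threshold")
    rng <- range(green)
    if (diff(rng) == 0) {
      th <- Inf
    } else {
      x <- (green - rng[1]) / diff(rng)
      th <- rng[1] + diff(rng) *
        EBImage::otsu(EBImage::Image(x), range = c(0, 1), levels = 256)
    }
    bg <- NA_real_; nsd <- NA_real_
  } else {
    bg <- median(bgpix)
    nsd <- mad(bgpix)
    th <- bg + k * nsd
  }
  structure(green > th, threshold = th, background = bg, noise_sd = nsd)
}

#' Classify a cell from its positive-pixel fractions
#'
#' The localization call is a total function of the fraction of nuclear
#' pixels that are green-positive (`f_nuc`) and the fraction of
#' cytoplasmic pixels that are green-positive (`f_cyt`): signal is deemed
#' present in a compartment when its fraction reaches the compartment
#' threshold, and the call is `BOTH` if present in both, `NUCLEAR` or
#' `CYTOPLASMIC` if present in exactly one, `UNLABELED` if in neither.
#' The four calls are mutually exclusive and exhaustive.
#'
#' @param f_nuc,f_cyt positive-pixel fractions in `[0, 1]` (vectorized).
#' @param tau_nuc,tau_cyt presence thresholds in `(0, 1)`; the default 0.2
#'   registers partial compartment fill while ignoring segmentation bleed
#'   at the nuclear rim.
#' @return character vector of calls.
#' @export
#' @examples
#' classify_cell(0.9, 0.0)  # "NUCLEAR"
#' classify_cell(0.9, 0.9)  # "BOTH"
classify_cell <- function(f_nuc, f_cyt, tau_nuc = 0.2, tau_cyt = 0.2) {
  if (any(is.na(f_nuc)) || any(is.na(f_cyt)) ||
      any(f_nuc < 0 | f_nuc > 1) || any(f_cyt < 0 | f_cyt > 1))
    stop_nucloc("f_nuc and f_cyt must be in [0, 1]")
  if (tau_nuc <= 0 || tau_nuc >= 1 || tau_cyt <= 0 || tau_cyt >= 1)
    stop_nucloc("thresholds must be in (0, 1)")
  nuc <- f_nuc >= tau_nuc
  cyt <- f_cyt >= tau_cyt
  ifelse(nuc & cyt, "BOTH",
         ifelse(nuc, "NUCLEAR",
                ifelse(cyt, "CYTOPLASMIC", "UNLABELED")))
}

#' Classify every cell in a field
#'
#' Runs region delineation and green-channel thresholding, then calls
#' [classify_cell()] per nucleus. Cells whose nucleus touches the image
#' border are excluded by default because their cytoplasm is truncated.
#'
#' @param field a `field_image` (or a list with `blue` and `green`
#'   matrices of equal shape).
#' @param map optional precomputed [segment_nuclei()] result for the same
#'   field; segmented from `field$blue` when missing.
#' @param ring_width,k,tau_nuc,tau_cyt see [define_cell_regions()],
#'   [green_positive_mask()], [classify_cell()].
#' @param exclude_border drop border-flagged cells (default `TRUE`).
#' @param meta optional named list of provenance columns (experiment,
#'   plate, well, treatment, field) prepended to the output; defaults to
#'   `field$meta`.
#' @param ... passed to [segment_nuclei()] when `map` is missing.
#' @return data.frame, one row per retained cell: provenance columns (if
#'   any), `cell_id` (nucleus label), centroid `row`/`col`, `area`,
#'   `f_nuc`, `f_cyt`, `call`, `border_flag`. The thresholds used are
#'   attached as attribute `params`.
#' @export
classify_field <- function(field, map = NULL, ring_width = NULL, k = 3,
                           tau_nuc = 0.2, tau_cyt = 0.2,
                           exclude_border = TRUE, meta = NULL, ...) {
  blue <- field$blue; green <- field$green
  if (!identical(dim(blue), dim(green)))
    stop_nucloc("channel shape mismatch: blue is ",
                paste(dim(blue), collapse = "x"), ", green is ",
                paste(dim(green), collapse = "x"))
  meta <- meta %||% field$meta %||% list()
  if (is.null(map)) map <- segment_nuclei(blue, ...)
  empty <- data.frame(cell_id = integer(0), row = numeric(0),
                      col = numeric(0), area = integer(0),
                      f_nuc = numeric(0), f_cyt = numeric(0),
                      call = character(0), border_flag = logical(0))
  if (n_nuclei(map) == 0) return(add_meta(empty, meta))
  regions <- define_cell_regions(map, ring_width = ring_width)
  mask <- green_positive_mask(green, regions, k = k)
  kmax <- max(map$labels)
  n_nuc <- tabulate(map$labels[map$labels > 0], nbins = kmax)
  pos_nuc <- tabulate(map$labels[map$labels > 0 & mask], nbins = kmax)
  cyt_lab <- regions$cell_labels * (map$labels == 0)
  n_cyt <- tabulate(cyt_lab[cyt_lab > 0], nbins = kmax)
  pos_cyt <- tabulate(cyt_lab[cyt_lab > 0 & mask], nbins = kmax)
  lab <- map$nuclei$label
  f_nuc <- ifelse(n_nuc[lab] > 0, pos_nuc[lab] / n_nuc[lab], 0)
  f_cyt <- ifelse(n_cyt[lab] > 0, pos_cyt[lab] / n_cyt[lab], 0)
  out <- data.frame(cell_id = lab, row = map$nuclei$row,
                    col = map$nuclei$col, area = map$nuclei$area,
                    f_nuc = f_nuc, f_cyt = f_cyt,
                    call = classify_cell(f_nuc, f_cyt, tau_nuc, tau_cyt),
                    border_flag = map$nuclei$border,
                    stringsAsFactors = FALSE)
  if (exclude_border) out <- out[!out$border_flag, , drop = FALSE]
  rownames(out) <- NULL
  out <- add_meta(out, meta)
  attr(out, "params") <- list(tau_nuc = tau_nuc, tau_cyt = tau_cyt, k = k,
                              ring_width = regions$ring_width,
                              exclude_border = exclude_border)
  out
}

add_meta <- function(df, meta) {
  meta <- meta[intersect(c("experiment", "plate", "well", "treatment",
                           "field"), names(meta))]
  if (!length(meta)) return(df)
  cbind(as.data.frame(meta, stringsAsFactors = FALSE)[
    rep(1, max(nrow(df), 1))[seq_len(nrow(df))], , drop = FALSE],
    df, row.names = NULL)
}
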