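#' Specify one synthetic cell
#'
#' A cell is modeled as two concentric disks: a nucleus (blue counterstain)
#' inside a larger cell body. The green channel receives signal according to
#' `true_class`: inside the nucleus only (`NUCLEAR`), in the cytoplasmic
#' annulus only (`CYTOPLASMIC`), over the whole cell disk (`BOTH`), or
#' nowhere (`UNLABELED`, an untransfected cell).
#'
#' @param row,col nucleus center, 1-based pixel coordinates.
#' @param nucleus_radius,cell_radius disk radii in pixels;
#'   `cell_radius > nucleus_radius > 0`.
#' @param true_class one of `"NUCLEAR"`, `"CYTOPLASMIC"`, `"BOTH"`,
#'   `"UNLABELED"`.
#' @param nuclear_intensity,gfp_intensity signal amplitudes in fluorescence
#'   units added above background. UNLABELED cells contribute exactly 0 to
#'   the green channel regardless of `gfp_intensity`.
#' @return one-row data.frame.
#' @export
cell_spec <- function(row, col, nucleus_radius = 10, cell_radius = 18,
                      true_class = "BOTH",
                      nuclear_intensity = 2500, gfp_intensity = 2000) {
  true_class <- match.arg(true_class, LOC_CLASSES)
  if (!(cell_radius > nucleus_radius && nucleus_radius > 0))
    stop_nucloc("cell_radius > nucleus_radius > 0 is required (got ",
                cell_radius, ", ", nucleus_radius, ")")
  data.frame(row = row, col = col, nucleus_radius = nucleus_radius,
             cell_radius = cell_radius, true_class = true_class,
             nuclear_intensity = nuclear_intensity,
             gfp_intensity = gfp_intensity, stringsAsFactors = FALSE)
}

#' Specify one synthetic two-channel field
#'
#' @param cells data.frame of cells, one row per cell, as produced by
#'   [cell_spec()] / `rbind`, or `NULL` for an empty field.
#' @param shape `(height, width)` in pixels.
#' @param background_level background fluorescence, added to both channels.
#' @param gaussian_sd standard deviation of additive Gaussian read noise
#'   (0 disables).
#' @param poisson if `TRUE`, Poisson shot noise is applied (each pixel
#'   replaced by a Poisson draw with its value as the mean).
#' @param seed integer seed for the noise draws; `NULL` leaves the RNG
#'   stream untouched (only meaningful with noise off).
#' @param overlap_tol nuclei may approach up to `r_i + r_j - overlap_tol`;
#'   closer pairs are rejected because segmentation ground truth would be
#'   ambiguous.
#' @return an object of class `field_spec`.
#' @export
field_spec <- function(cells = NULL, shape = c(512, 512),
                       background_level = 100, gaussian_sd = 20,
                       poisson = FALSE, seed = NULL, overlap_tol = 0) {
  if (is.null(cells)) {
    cells <- cell_spec(1, 1)[0, ]
  }
  stopifnot(is.data.frame(cells), length(shape) == 2, all(shape >= 1))
  if (nrow(cells)) {
    if (any(cells$row < 1 | cells$row > shape[1] |
            cells$col < 1 | cells$col > shape[2]))
      stop_nucloc("cell centers must lie within image bounds ",
                  shape[1], "x", shape[2])
    if (any(!(cells$cell_radius > cells$nucleus_radius &
              cells$nucleus_radius > 0)))
      stop_nucloc("every cell needs cell_radius > nucleus_radius > 0")
    if (nrow(cells) > 1) {
      d <- as.matrix(stats::dist(cells[, c("row", "col")]))
      rs <- outer(cells$nucleus_radius, cells$nucleus_radius, `+`)
      diag(d) <- Inf
      if (any(d < rs - overlap_tol))
        stop_nucloc("nuclei overlap beyond tolerance (", overlap_tol,
                    " px): segmentation ground truth would be ambiguous")
    }
  }
  structure(list(cells = cells, shape = as.integer(shape),
                 background_level = background_level,
                 gaussian_sd = gaussian_sd, poisson = poisson,
                 seed = seed),
            class = "field_spec")
}

#' Randomly place cells for one field
#'
#' Draws radii, transfection status and localization class per cell, then
#' places cells by dart-throwing with minimum center separation
#' `2 * max(cell_radius)` (a Poisson-disk rule), so cell disks never overlap
#' and the ground truth stays unambiguous. Centers keep a margin of one cell
#' radius from the border so cell bodies are fully inside the field.
#'
#' @param n_cells number of cells to place.
#' @param shape field shape `(height, width)`.
#' @param class_probs probabilities of (NUCLEAR, CYTOPLASMIC, BOTH) for
#'   labeled cells; must sum to 1.
#' @param transfection_rate probability that a cell is labeled (expresses
#'   detectable GFP); unlabeled cells are `UNLABELED`.
#' @param nucleus_radius_range uniform range for nucleus radii (pixels).
#' @param cell_ratio cell radius as a multiple of the nucleus radius.
#' @param seed RNG seed for this field's geometry and class draws.
#' @param max_attempts dart-throwing attempts per cell before giving up.
#' @inheritParams field_spec
#' @return a `field_spec` whose noise seed is `seed + 5e8` (decoupled from
#'   the geometry seed so manifests are reproducible without rendering).
#' @export
random_field_spec <- function(n_cells = 30, shape = c(512, 512),
                              class_probs = c(0.0621, 0.4512, 0.4867),
                              transfection_rate = 0.6,
                              nucleus_radius_range = c(8, 12),
                              cell_ratio = 1.8, seed = 1,
                              background_level = 100, gaussian_sd = 20,
                              poisson = FALSE, max_attempts = 200) {
  stopifnot(length(class_probs) == 3, all(class_probs >= 0))
  if (abs(sum(class_probs) - 1) > 1e-8)
    stop_nucloc("class_probs must sum to 1")
  stopifnot(transfection_rate >= 0, transfection_rate <= 1)
  set.seed(as.integer(seed))
  nr <- runif(n_cells, nucleus_radius_range[1], nucleus_radius_range[2])
  cr <- nr * cell_ratio
  labeled <- rbinom(n_cells, 1, transfection_rate) == 1
  cls <- rep("UNLABELED", n_cells)
  if (any(labeled))
    cls[labeled] <- sample(LABELED_CLASSES, sum(labeled), replace = TRUE,
                           prob = class_probs)
  min_sep <- 2 * max(cr, 1)
  margin <- max(cr, 1)
  lo <- c(1 + margin, 1 + margin)
  hi <- c(shape[1] - margin, shape[2] - margin)
  if (any(hi <= lo))
    stop_nucloc("field too small for the requested cell radii")
  pos <- matrix(NA_real_, n_cells, 2)
  placed <- 0L
  for (i in seq_len(n_cells)) {
    ok <- FALSE
    for (a in seq_len(max_attempts)) {
      p <- c(runif(1, lo[1], hi[1]), runif(1, lo[2], hi[2]))
      if (placed == 0L ||
          all(sqrt(colSums((t(pos[seq_len(placed), , drop = FALSE]) - p)^2))
              >= min_sep)) {
        ok <- TRUE
        break
      }
    }
    if (!ok)
      stop_nucloc("could not place ", n_cells, " non-overlapping cells in a ",
                  shape[1], "x", shape[2], " field; reduce n_cells or radii")
    placed <- placed + 1L
    pos[i, ] <- p
  }
  cells <- data.frame(row = round(pos[, 1]), col = round(pos[, 2]),
                      nucleus_radius = nr, cell_radius = cr,
                      true_class = cls,
                      nuclear_intensity = 2500, gfp_intensity = 2000,
                      stringsAsFactors = FALSE)
  field_spec(cells, shape = shape, background_level = background_level,
             gaussian_sd = gaussian_sd, poisson = poisson,
             seed = as.integer(seed) + 500000000L)
}

#' Render a field specification to a two-channel image
#'
#' The blue channel receives `nuclear_intensity` over each nucleus disk;
#' the green channel receives `gfp_intensity` over the region dictated by
#' each cell's `true_class`. Background is added everywhere, then noise
#' (Gaussian read noise and optional Poisson shot noise), then pixel values
#' are rounded and clipped to the 16-bit range `[0, 65535]`. Rendering is
#' bit-reproducible for a fixed `spec$seed`.
#'
#' @param spec a [field_spec()].
#' @return a list with `field` (class `field_image`: integer matrices
#'   `blue`, `green`, plus `meta`) and `truth` (data.frame, one row per
#'   cell: `cell_id, row, col, nucleus_radius, cell_radius, true_class`).
#' @export
render_field <- function(spec) {
  stopifnot(inherits(spec, "field_spec"))
  h <- spec$shape[1]; w <- spec$shape[2]
  blue <- matrix(spec$background_level, h, w)
  green <- matrix(spec$background_level, h, w)
  cells <- spec$cells
  for (i in seq_len(nrow(cells))) {
    ci <- cells[i, ]
    rr <- max(1, floor(ci$row - ci$cell_radius)):min(h, ceiling(ci$row + ci$cell_radius))
    cc <- max(1, floor(ci$col - ci$cell_radius)):min(w, ceiling(ci$col + ci$cell_radius))
    d2 <- outer((rr - ci$row)^2, (cc - ci$col)^2, `+`)
    nuc <- d2 <= ci$nucleus_radius^2
    cell <- d2 <= ci$cell_radius^2
    blue[rr, cc][nuc] <- blue[rr, cc][nuc] + ci$nuclear_intensity
    gmask <- switch(ci$true_class,
                    NUCLEAR = nuc,
                    CYTOPLASMIC = cell & !nuc,
                    BOTH = cell,
                    UNLABELED = NULL)
    if (!is.null(gmask))
      green[rr, cc][gmask] <- green[rr, cc][gmask] + ci$gfp_intensity
  }
  if (!is.null(spec$seed)) set.seed(as.integer(spec$seed) %% 2147483647L)
  if (spec$gaussian_sd > 0) {
    blue <- blue + rnorm(h * w, 0, spec$gaussian_sd)
    green <- green + rnorm(h * w, 0, spec$gaussian_sd)
  }
  if (isTRUE(spec$poisson)) {
    blue <- rpois(h * w, pmax(blue, 0))
    green <- rpois(h * w, pmax(green, 0))
  }
  clipq <- function(x) matrix(pmin(pmax(round(x), 0), MAX_INTENSITY), h, w)
  truth <- data.frame(cell_id = seq_len(nrow(cells)),
                      row = cells$row, col = cells$col,
                      nucleus_radius = cells$nucleus_radius,
                      cell_radius = cells$cell_radius,
                      true_class = cells$true_class,
                      stringsAsFactors = FALSE)
  field <- structure(list(blue = clipq(blue), green = clipq(green),
                          meta = list()),
                     class = "field_image")
  list(field = field, truth = truth)
}

#' @export
print.field_image <- function(x, ...) {
  cat("field_image", nrow(x$blue), "x", ncol(x$blue), "px, 2 channels\n")
  if (length(x$meta))
    cat("  ", paste(names(x$meta), unlist(x$meta), sep = "=", collapse = " "),
        "\n")
  invisible(x)
}

#' Write / read a field as a 2-page 16-bit TIFF
#'
#' Page 1 is the blue (nuclear counterstain) channel, page 2 the green
#' (GFP) channel. Intensities are stored on the 16-bit scale.
#'
#' @param field a `field_image`.
#' @param path output path.
#' @export
write_field_tiff <- function(field, path) {
  stopifnot(inherits(field, "field_image"))
  tiff::writeTIFF(list(field$blue / MAX_INTENSITY,
                       field$green / MAX_INTENSITY),
                  path, bits.per.sample = 16, compression = "none")
  invisible(path)
}

#' @rdname write_field_tiff
#' @param blue_page,green_page TIFF page (or channel) index of each channel.
#' @param meta optional named list of provenance values attached to the
#'   returned `field_image`.
#' @export
read_field_tiff <- function(path, blue_page = 1, green_page = 2,
                            meta = list()) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (length(pages) == 1 && length(dim(pages[[1]])) == 3) {
    a <- pages[[1]]
    pages <- lapply(seq_len(dim(a)[3]), function(k) a[, , k])
  }
  if (length(pages) < max(blue_page, green_page))
    stop_nucloc("TIFF ", path, " has ", length(pages),
                " page(s); need pages ", blue_page, " and ", green_page)
  to_int <- function(m) matrix(round(m * MAX_INTENSITY), nrow(m), ncol(m))
  structure(list(blue = to_int(pages[[blue_page]]),
                 green = to_int(pages[[green_page]]), meta = meta),
            class = "field_image")
}

#' Describe a well-plate transfection experiment
#'
#' Defaults mirror a standard design: each treatment plated in triplicate
#' across two plates (2 wells on plate 1, 1 on plate 2) in two separate
#' experiments, for n = 6 wells per treatment, with 15 imaged fields per
#' well. Treatments default to a wildtype construct (`WT`), a risk-variant
#' construct (`RISK`), a pmaxGFP-style transfection control (`POS_CTRL`,
#' diffuse whole-cell GFP), and untreated cells (`NEG_CTRL`, transfection
#' rate 0).
#'
#' @param treatments named list; each element a list with `mixture`
#'   (probabilities of NUCLEAR/CYTOPLASMIC/BOTH among labeled cells,
#'   summing to 1) and `transfection_rate`.
#' @param wells_per_treatment_per_experiment,n_experiments,fields_per_well
#'   design counts.
#' @param cells_per_field cells placed per field (the imaging density at
#'   40x; a package default, not a measured value).
#' @param shape field shape in pixels.
#' @param gaussian_sd,poisson,background_level noise model, as in
#'   [field_spec()].
#' @param master_seed integer; all randomness derives from it via the
#'   per-field seed schedule (see [field_seed()]).
#' @return an object of class `experiment_design`.
#' @export
experiment_design <- function(
    treatments = list(
      WT = list(mixture = c(0.0621, 0.4512, 0.4867), transfection_rate = 0.6),
      RISK = list(mixture = c(0.0386, 0.6729, 0.2874) / 0.9989,
                  transfection_rate = 0.6),
      POS_CTRL = list(mixture = c(0.02, 0.08, 0.90), transfection_rate = 0.9),
      NEG_CTRL = list(mixture = c(1/3, 1/3, 1/3), transfection_rate = 0)),
    wells_per_treatment_per_experiment = 3, n_experiments = 2,
    fields_per_well = 15, cells_per_field = 30, shape = c(512, 512),
    background_level = 100, gaussian_sd = 20, poisson = FALSE,
    master_seed = 1) {
  stopifnot(length(treatments) >= 1, !is.null(names(treatments)))
  for (nm in names(treatments)) {
    tr <- treatments[[nm]]
    if (is.null(tr$mixture) || length(tr$mixture) != 3 ||
        any(tr$mixture < 0) || any(tr$mixture > 1) ||
        abs(sum(tr$mixture) - 1) > 1e-6)
      stop_nucloc("treatment ", nm,
                  ": mixture must be 3 probabilities in [0,1] summing to 1")
    if (is.null(tr$transfection_rate) || tr$transfection_rate < 0 ||
        tr$transfection_rate > 1)
      stop_nucloc("treatment ", nm, ": transfection_rate must be in [0,1]")
  }
  structure(list(treatments = treatments,
                 wells_per_treatment_per_experiment =
                   as.integer(wells_per_treatment_per_experiment),
                 n_experiments = as.integer(n_experiments),
                 fields_per_well = as.integer(fields_per_well),
                 cells_per_field = as.integer(cells_per_field),
                 shape = as.integer(shape),
                 background_level = background_level,
                 gaussian_sd = gaussian_sd, poisson = poisson,
                 master_seed = as.integer(master_seed)),
            class = "experiment_design")
}

#' Per-field seed schedule
#'
#' Every field's RNG seed is a fixed arithmetic function of the master seed
#' and the field's (experiment, treatment, well, field) indices, so any
#' single field can be regenerated in isolation and the whole experiment is
#' byte-reproducible.
#'
#' @param master_seed integer master seed.
#' @param exp_i,treat_i,well_i,field_i 1-based indices (well within
#'   treatment within experiment).
#' @return integer seed in `[0, 2^31 - 2]`.
#' @export
field_seed <- function(master_seed, exp_i, treat_i, well_i, field_i) {
  as.integer((as.double(master_seed) + 10000019 * exp_i + 999983 * treat_i +
                10007 * well_i + 101 * field_i) %% 2147483647)
}

#' Plate assignment for a well index
#'
#' Triplicate wells are split 2 + 1 across two plates within each
#' experiment: wells 1-2 on plate 1, well 3 (and any further wells,
#' alternating) on plate 2.
#' @param well_i well index within treatment within experiment (1-based).
#' @return plate number (1 or 2).
#' @export
plate_of_well <- function(well_i) {
  ifelse(well_i <= 2L, 1L, ifelse(well_i %% 2L == 1L, 2L, 1L))
}

#' Generate a full synthetic experiment
#'
#' Renders one 2-page TIFF per field under
#' `out_dir/exp<e>/plate<p>/<treatment>_w<well>_f<field>.tif` and writes a
#' ground-truth manifest CSV (`manifest.csv`) with one row per generated
#' cell. Per-well class counts are multinomial draws from the treatment's
#' mixture; labeled-cell counts are binomial in the transfection rate. All
#' randomness derives from `design$master_seed` via [field_seed()].
#'
#' @param design an [experiment_design()].
#' @param out_dir output directory (created if needed). May be `NULL` when
#'   `write_images = FALSE`.
#' @param write_images if `FALSE`, only the manifest is generated (fast;
#'   identical rows to a rendered run because geometry and render-noise
#'   seeds are decoupled).
#' @return invisibly, a list with `manifest` (data.frame: experiment,
#'   plate, well, treatment, field, cell_id, row, col, nucleus_radius,
#'   cell_radius, true_class) and `files` (paths, possibly empty).
#' @export
generate_experiment <- function(design, out_dir = NULL, write_images = TRUE) {
  stopifnot(inherits(design, "experiment_design"))
  if (write_images) {
    if (is.null(out_dir)) stop_nucloc("out_dir required when writing images")
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  }
  rows <- list(); files <- character(0)
  tnames <- names(design$treatments)
  for (e in seq_len(design$n_experiments)) {
    for (ti in seq_along(tnames)) {
      tr <- design$treatments[[ti]]
      for (wi in seq_len(design$wells_per_treatment_per_experiment)) {
        plate <- plate_of_well(wi)
        well_id <- sprintf("%s_e%d_w%d", tnames[ti], e, wi)
        for (fi in seq_len(design$fields_per_well)) {
          sd_f <- field_seed(design$master_seed, e, ti, wi, fi)
          spec <- random_field_spec(
            n_cells = design$cells_per_field, shape = design$shape,
            class_probs = tr$mixture,
            transfection_rate = tr$transfection_rate, seed = sd_f,
            background_level = design$background_level,
            gaussian_sd = design$gaussian_sd, poisson = design$poisson)
          truth <- data.frame(cell_id = seq_len(nrow(spec$cells)),
                              spec$cells[, c("row", "col", "nucleus_radius",
                                             "cell_radius", "true_class")],
                              stringsAsFactors = FALSE)
          if (write_images) {
            rend <- render_field(spec)
            dir_f <- file.path(out_dir, sprintf("exp%d", e),
                               sprintf("plate%d", plate))
            dir.create(dir_f, recursive = TRUE, showWarnings = FALSE)
            path <- file.path(dir_f, sprintf("%s_w%d_f%02d.tif",
                                             tnames[ti], wi, fi))
            write_field_tiff(rend$field, path)
            files <- c(files, path)
            truth <- rend$truth
          }
          if (nrow(truth))
            rows[[length(rows) + 1L]] <- data.frame(
              experiment = e, plate = plate, well = well_id,
              treatment = tnames[ti], field = fi, truth,
              stringsAsFactors = FALSE)
        }
      }
    }
  }
  manifest <- if (length(rows)) do.call(rbind, rows) else NULL
  rownames(manifest) <- NULL
  if (write_images && !is.null(manifest))
    write.csv(manifest, file.path(out_dir, "manifest.csv"),
              row.names = FALSE)
  invisible(list(manifest = manifest, files = files))
}
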