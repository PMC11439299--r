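# Independent oracle for the per-cell rule: decide each compartment's
# presence bit, then look the pair up in an explicit truth table.
oracle_call <- function(f_nuc, f_cyt, tau_nuc, tau_cyt) {
  # rows: nuclear signal absent/present; cols: cytoplasmic absent/present
  tab <- matrix(c("UNLABELED", "NUCLEAR", "CYTOPLASMIC", "BOTH"), 2, 2)
  tab[(f_nuc >= tau_nuc) + 1, (f_cyt >= tau_cyt) + 1]
}

test_that("classify_cell matches the truth-table oracle on a full grid", {
  grid <- seq(0, 1, by = 0.05)
  for (tau in list(c(0.2, 0.2), c(0.5, 0.1), c(0.05, 0.95))) {
    for (fn in grid) for (fc in grid) {
      expect_identical(classify_cell(fn, fc, tau[1], tau[2]),
                       oracle_call(fn, fc, tau[1], tau[2]))
    }
  }
})

test_that("classify_cell validates its inputs", {
  expect_error(classify_cell(-0.1, 0.5), "\\[0, 1\\]")
  expect_error(classify_cell(0.5, 1.2), "\\[0, 1\\]")
  expect_error(classify_cell(0.5, 0.5, tau_nuc = 0), "\\(0, 1\\)")
  expect_error(classify_cell(0.5, 0.5, tau_cyt = 1), "\\(0, 1\\)")
})

test_that("every (f_nuc, f_cyt) pair gets exactly one of the four calls", {
  set.seed(4)
  f <- matrix(runif(400), ncol = 2)
  calls <- classify_cell(f[, 1], f[, 2])
  expect_true(all(calls %in% c("NUCLEAR", "CYTOPLASMIC", "BOTH",
                               "UNLABELED")))
})

test_that("raising a threshold only demotes the affected compartment", {
  # allowed transitions when tau_nuc rises: BOTH->CYTOPLASMIC,
  # NUCLEAR->UNLABELED, or no change; symmetric for tau_cyt
  set.seed(5)
  f <- matrix(runif(600), ncol = 2)
  taus <- seq(0.05, 0.95, by = 0.1)
  for (i in seq_len(length(taus) - 1)) {
    lo <- classify_cell(f[, 1], f[, 2], taus[i], 0.2)
    hi <- classify_cell(f[, 1], f[, 2], taus[i + 1], 0.2)
    changed <- lo != hi
    expect_true(all(paste(lo, hi)[changed] %in%
                      c("BOTH CYTOPLASMIC", "NUCLEAR UNLABELED")))
    lo <- classify_cell(f[, 1], f[, 2], 0.2, taus[i])
    hi <- classify_cell(f[, 1], f[, 2], 0.2, taus[i + 1])
    changed <- lo != hi
    expect_true(all(paste(lo, hi)[changed] %in%
                      c("BOTH NUCLEAR", "CYTOPLASMIC UNLABELED")))
  }
})

test_that("cell regions form the expected annulus around a single nucleus", {
  r <- render_field(field_spec(cell_spec(128, 128, nucleus_radius = 10,
                                         cell_radius = 18),
                               shape = c(256, 256), gaussian_sd = 0))
  map <- segment_nuclei(r$field$blue)
  reg <- define_cell_regions(map, ring_width = 8)
  cyt <- reg$cell_labels == 1 & reg$nucleus_labels == 0
  d <- sqrt(outer((1:256 - 128)^2, (1:256 - 128)^2, `+`))
  # annulus 10 < d <= 18 up to pixelation of the dilation brush
  expect_true(all(d[cyt] > 9.5 & d[cyt] <= 19.5))
  expect_gt(sum(cyt), 0.8 * pi * (18^2 - 10^2))
})

test_that("distant nuclei get regions identical to the single-cell case", {
  one <- render_field(field_spec(cell_spec(64, 64, 10, 18),
                                 shape = c(256, 256), gaussian_sd = 0))
  two <- render_field(field_spec(rbind(cell_spec(64, 64, 10, 18),
                                       cell_spec(192, 192, 10, 18)),
                                 shape = c(256, 256), gaussian_sd = 0))
  reg1 <- define_cell_regions(segment_nuclei(one$field$blue), ring_width = 8)
  reg2 <- define_cell_regions(segment_nuclei(two$field$blue), ring_width = 8)
  expect_identical(reg2$cell_labels[1:128, 1:128] == 1,
                   reg1$cell_labels[1:128, 1:128] == 1)
})

test_that("close nuclei partition cytoplasm by nearest nucleus, no pixel twice", {
  # two nuclei far enough not to fuse under closing, but whose dilated
  # bodies overlap
  cells <- rbind(cell_spec(64, 46, 10, 18), cell_spec(64, 78, 10, 18))
  r <- render_field(field_spec(cells, shape = c(128, 128), gaussian_sd = 0))
  map <- segment_nuclei(r$field$blue)
  expect_equal(n_nuclei(map), 2)
  reg <- define_cell_regions(map, ring_width = 8)
  # exhaustive audit: each cytoplasm pixel belongs to exactly one cell and
  # to the nearer nucleus (ties excluded)
  cyt_idx <- which(reg$cell_labels > 0 & reg$nucleus_labels == 0)
  rw <- (cyt_idx - 1) %% 128 + 1; cl <- (cyt_idx - 1) %/% 128 + 1
  d1 <- sqrt((rw - 64)^2 + (cl - 46)^2) - 10
  d2 <- sqrt((rw - 64)^2 + (cl - 78)^2) - 10
  lab <- reg$cell_labels[cyt_idx]
  nearer <- ifelse(d1 < d2, 1L, 2L)
  strict <- abs(d1 - d2) > 1.5 # skip near-equidistant boundary pixels
  expect_gt(mean(lab[strict] == nearer[strict]), 0.99)
  expect_true(all(lab %in% c(1L, 2L)))
})

test_that("green mask is empty on a constant image and exact without noise", {
  const <- matrix(100, 64, 64)
  expect_false(any(green_positive_mask(const)))
  # no pixels outside cell regions -> Otsu fallback with a warning
  all_cells <- structure(list(cell_labels = matrix(1L, 64, 64)),
                         class = "cell_regions")
  expect_warning(m0 <- green_positive_mask(const, all_cells), "Otsu")
  expect_false(any(m0))
  r <- render_field(grid_field_spec("NUCLEAR", shape = c(128, 128)))
  map <- segment_nuclei(r$field$blue)
  reg <- define_cell_regions(map, ring_width = 8)
  mask <- green_positive_mask(r$field$green, reg)
  nuc <- disk_mask(c(128, 128), r$truth$row, r$truth$col,
                   r$truth$nucleus_radius)
  expect_identical(unclass(mask)[, ], nuc, ignore_attr = TRUE)
})

test_that("false-positive rate outside cells respects the 3-sigma rule", {
  # pure Gaussian noise outside true cells: expected one-sided tail 0.00135
  set.seed(6)
  reps <- vapply(1:20, function(i) {
    g <- matrix(rnorm(128 * 128, 100, 20), 128, 128)
    mean(green_positive_mask(g, regions = NULL, k = 3))
  }, numeric(1))
  # MAD-based sd estimate is noisy; allow twice the nominal rate
  expect_lt(mean(reps), 2 * 0.0027)
})

test_that("classify_field reproduces true classes on a noise-free field", {
  r <- render_field(grid_field_spec(c("NUCLEAR", "CYTOPLASMIC", "BOTH")))
  map <- segment_nuclei(r$field$blue)
  rec <- classify_field(r$field, map)
  expect_equal(nrow(rec), 3)
  mt <- match_to_ground_truth(map, r$truth)
  m <- merge(mt$matches, r$truth, by = "cell_id")
  expect_identical(rec$call[match(m$label, rec$cell_id)], m$true_class)
})

test_that("an untransfected field yields only UNLABELED calls", {
  sp <- random_field_spec(n_cells = 12, shape = c(384, 384),
                          transfection_rate = 0, seed = 31)
  r <- render_field(sp)
  rec <- classify_field(r$field)
  expect_gt(nrow(rec), 0)
  expect_true(all(rec$call == "UNLABELED"))
})

test_that("channel shape mismatch raises an error naming both shapes", {
  f <- list(blue = matrix(0, 64, 64), green = matrix(0, 64, 32))
  expect_error(classify_field(f), "64x64.*64x32")
})

test_that("calls are invariant to a positive intensity rescaling", {
  sp <- random_field_spec(n_cells = 15, shape = c(384, 384), seed = 77,
                          gaussian_sd = 20)
  r <- render_field(sp)
  rec1 <- classify_field(r$field)
  scaled <- list(blue = r$field$blue * 3, green = r$field$green * 3,
                 meta = list())
  class(scaled) <- "field_image"
  rec2 <- classify_field(scaled)
  expect_identical(rec1$call, rec2$call)
})

test_that("border cells are excluded by default and kept on request", {
  cells <- rbind(cell_spec(9, 128, 10, 18), cell_spec(128, 128, 10, 18))
  r <- render_field(field_spec(cells, shape = c(256, 256), gaussian_sd = 0))
  map <- segment_nuclei(r$field$blue)
  rec_excl <- classify_field(r$field, map)
  rec_keep <- classify_field(r$field, map, exclude_border = FALSE)
  expect_equal(nrow(rec_excl), 1)
  expect_equal(nrow(rec_keep), 2)
  expect_equal(sum(rec_keep$border_flag), 1)
})
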