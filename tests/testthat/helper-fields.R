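# Shared fixtures: small noise-free and default-noise synthetic fields.

# A deterministic noise-free field with n cells of given classes laid out
# on a grid. Radii fixed so geometry oracles are exact.
grid_field_spec <- function(classes, shape = c(256, 256),
                            nucleus_radius = 10, cell_radius = 18,
                            gaussian_sd = 0, background = 100) {
  n <- length(classes)
  per_row <- ceiling(sqrt(n))
  step <- 2 * cell_radius + 10
  idx <- seq_len(n) - 1
  cells <- do.call(rbind, lapply(seq_len(n), function(i) {
    cell_spec(row = 30 + (idx[i] %/% per_row) * step,
              col = 30 + (idx[i] %% per_row) * step,
              nucleus_radius = nucleus_radius, cell_radius = cell_radius,
              true_class = classes[i])
  }))
  field_spec(cells, shape = shape, background_level = background,
             gaussian_sd = gaussian_sd)
}

# True disk mask for one cell on a given shape (same inclusion rule as the
# renderer: squared distance from pixel center to cell center <= r^2).
disk_mask <- function(shape, row, col, r) {
  outer((seq_len(shape[1]) - row)^2, (seq_len(shape[2]) - col)^2, `+`) <= r^2
}

# Per-cell call accuracy of a classified field against its ground truth,
# via centroid matching. Returns NA if nothing matched.
call_accuracy <- function(records, truth, map) {
  mt <- match_to_ground_truth(map, truth)
  m <- merge(records, mt$matches, by.x = "cell_id", by.y = "label")
  m <- merge(m, truth[, c("cell_id", "true_class")],
             by.x = "cell_id.y", by.y = "cell_id")
  if (!nrow(m)) return(NA_real_)
  mean(m$call == m$true_class)
}
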