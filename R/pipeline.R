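#' Read an experiment design from YAML
#'
#' The YAML mirrors [experiment_design()]: a `treatments` mapping (each
#' with `mixture` and `transfection_rate`) plus optional top-level counts,
#' field shape, noise parameters and `master_seed`. Unknown keys are
#' rejected.
#'
#' @param path YAML file.
#' @return an [experiment_design()].
#' @export
read_design <- function(path) {
  y <- yaml::read_yaml(path)
  known <- c("treatments", "wells_per_treatment_per_experiment",
             "n_experiments", "fields_per_well", "cells_per_field",
             "shape", "background_level", "gaussian_sd", "poisson",
             "master_seed")
  bad <- setdiff(names(y), known)
  if (length(bad))
    stop_nucloc("unknown design key(s): ", paste(bad, collapse = ", "))
  if (!is.null(y$treatments))
    y$treatments <- lapply(y$treatments, function(tr)
      list(mixture = as.numeric(unlist(tr$mixture)),
           transfection_rate = as.numeric(tr$transfection_rate)))
  if (!is.null(y$shape)) y$shape <- as.integer(unlist(y$shape))
  do.call(experiment_design, y)
}

#' Write an experiment design to YAML
#' @param design an [experiment_design()].
#' @param path output file.
#' @export
write_design <- function(design, path) {
  stopifnot(inherits(design, "experiment_design"))
  yaml::write_yaml(unclass(design), path)
  invisible(path)
}

QUANTIFY_KEYS <- c("blue_page", "green_page", "min_area", "closing_size",
                   "split_touching", "ring_width", "k", "tau_nuc",
                   "tau_cyt", "exclude_border")

#' Read a quantification run configuration
#'
#' YAML with any subset of the quantification parameters (channel page
#' assignment, segmentation and classification settings). Unknown keys
#' are rejected so typos fail loudly.
#'
#' @param path YAML file, or `NULL` for all defaults.
#' @return named list of parameters.
#' @export
read_run_config <- function(path = NULL) {
  if (is.null(path)) return(list())
  y <- yaml::read_yaml(path)
  bad <- setdiff(names(y), QUANTIFY_KEYS)
  if (length(bad))
    stop_nucloc("unknown config key(s): ", paste(bad, collapse = ", "),
                "; known keys: ", paste(QUANTIFY_KEYS, collapse = ", "))
  y
}

#' Pipeline step: simulate a synthetic experiment
#'
#' Thin wrapper over [generate_experiment()] accepting a design object or
#' YAML path; the design actually used is serialized into the output
#' directory as a reproducibility record.
#'
#' @param design an [experiment_design()] or path to a design YAML.
#' @param out output directory.
#' @param seed optional master-seed override.
#' @return invisibly, the [generate_experiment()] result.
#' @export
cmd_simulate <- function(design, out, seed = NULL) {
  if (is.character(design)) design <- read_design(design)
  stopifnot(inherits(design, "experiment_design"))
  if (!is.null(seed)) design$master_seed <- as.integer(seed)
  res <- generate_experiment(design, out_dir = out, write_images = TRUE)
  write_design(design, file.path(out, "design.yaml"))
  message("simulate: wrote ", length(res$files), " fields, ",
          nrow(res$manifest), " manifest rows to ", out)
  invisible(res)
}

parse_field_path <- function(path) {
  # expects .../exp<e>/plate<p>/<treatment>_w<well>_f<field>.tif
  fn <- basename(path)
  m <- regmatches(fn, regexec("^(.+)_w(\\d+)_f(\\d+)\\.tiff?$", fn))[[1]]
  exp_m <- regmatches(path, regexec("exp(\\d+)", path))[[1]]
  plate_m <- regmatches(path, regexec("plate(\\d+)", path))[[1]]
  if (length(m) < 4 || length(exp_m) < 2)
    return(list(experiment = NA_integer_, plate = NA_integer_,
                well = sub("\\.tiff?$", "", fn), treatment = NA_character_,
                field = NA_integer_))
  e <- as.integer(exp_m[2])
  list(experiment = e,
       plate = if (length(plate_m) >= 2) as.integer(plate_m[2]) else NA_integer_,
       well = sprintf("%s_e%d_w%s", m[2], e, m[3]),
       treatment = m[2], field = as.integer(m[4]))
}

#' Pipeline step: quantify an image tree (or one field)
#'
#' Reads every `.tif`/`.tiff` under `input`, segments nuclei, classifies
#' each cell, and writes `cells.csv` (per-cell records), `wells.csv`
#' (per-well percentages) and `params.json` (the parameters used, for
#' provenance) to `out`. Fields are processed independently and results
#' are canonically sorted, so processing order cannot affect outputs.
#' Unreadable fields are skipped with a logged error and counted in
#' `n_failed`.
#'
#' @param input directory tree of field TIFFs (or a single TIFF path).
#' @param out output directory.
#' @param config parameter list (see [read_run_config()]) or a YAML path.
#' @return invisibly, list with `cells`, `wells`, `n_fields`, `n_failed`.
#' @export
cmd_quantify <- function(input, out, config = list()) {
  if (is.character(config)) config <- read_run_config(config)
  bad <- setdiff(names(config), QUANTIFY_KEYS)
  if (length(bad))
    stop_nucloc("unknown config key(s): ", paste(bad, collapse = ", "))
  p <- function(key, default) config[[key]] %||% default
  files <- if (length(input) == 1 && dir.exists(input)) {
    sort(list.files(input, pattern = "\\.tiff?$", recursive = TRUE,
                    full.names = TRUE))
  } else input
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  cells <- list(); n_failed <- 0L
  for (f in files) {
    rec <- tryCatch({
      meta <- parse_field_path(f)
      fi <- read_field_tiff(f, blue_page = p("blue_page", 1),
                            green_page = p("green_page", 2), meta = meta)
      map <- segment_nuclei(fi$blue,
                            min_area = p("min_area", 0.25 * pi * 100),
                            closing_size = p("closing_size", 5),
                            split_touching = p("split_touching", FALSE))
      df <- classify_field(fi, map, ring_width = p("ring_width", NULL),
                           k = p("k", 3), tau_nuc = p("tau_nuc", 0.2),
                           tau_cyt = p("tau_cyt", 0.2),
                           exclude_border = p("exclude_border", TRUE))
      message("quantify: ", f, ": ", nrow(df), " cells")
      attr(df, "params") <- NULL # run-level settings go to params.json
      df
    }, error = function(e) {
      message("quantify: skipping ", f, ": ", conditionMessage(e))
      n_failed <<- n_failed + 1L
      NULL
    })
    if (!is.null(rec) && nrow(rec)) cells[[length(cells) + 1L]] <- rec
  }
  cells_df <- if (length(cells)) do.call(rbind, cells) else NULL
  if (!is.null(cells_df)) {
    ord <- order(cells_df$well, cells_df$field, cells_df$cell_id)
    cells_df <- cells_df[ord, , drop = FALSE]
    rownames(cells_df) <- NULL
    wells_df <- summarize_wells(cells_df)
  } else {
    wells_df <- NULL
  }
  write.csv(cells_df %||% data.frame(), file.path(out, "cells.csv"),
            row.names = FALSE)
  write.csv(wells_df %||% data.frame(), file.path(out, "wells.csv"),
            row.names = FALSE)
  params <- list(blue_page = p("blue_page", 1), green_page = p("green_page", 2),
                 min_area = p("min_area", 0.25 * pi * 100),
                 closing_size = p("closing_size", 5),
                 split_touching = p("split_touching", FALSE),
                 ring_width = p("ring_width", NA), k = p("k", 3),
                 tau_nuc = p("tau_nuc", 0.2), tau_cyt = p("tau_cyt", 0.2),
                 exclude_border = p("exclude_border", TRUE),
                 n_fields = length(files), n_failed = n_failed)
  jsonlite::write_json(params, file.path(out, "params.json"),
                       auto_unbox = TRUE, null = "null")
  invisible(list(cells = cells_df, wells = wells_df,
                 n_fields = length(files), n_failed = n_failed))
}

#' Pipeline step: compare two treatment groups
#'
#' @param wells per-well summary data.frame or path to a `wells.csv`.
#' @param group_a,group_b treatment names.
#' @param variant `"pooled"` or `"welch"`.
#' @param out optional output directory for `comparison.csv` and
#'   `report.md`.
#' @return invisibly, list with `comparison` (a [compare_groups()] table)
#'   and `report` (Markdown lines).
#' @export
cmd_compare <- function(wells, group_a, group_b,
                        variant = c("pooled", "welch"), out = NULL) {
  if (is.character(wells)) wells <- read.csv(wells, stringsAsFactors = FALSE)
  cmp <- compare_groups(wells, group_a, group_b, variant = match.arg(variant))
  report <- format_localization_report(cmp)
  if (!is.null(out)) {
    dir.create(out, recursive = TRUE, showWarnings = FALSE)
    write.csv(cmp, file.path(out, "comparison.csv"), row.names = FALSE)
    writeLines(report, file.path(out, "report.md"))
  }
  invisible(list(comparison = cmp, report = report))
}
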