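#' Summarize one well's cell calls as percentages of labeled cells
#'
#' The plate well is the experimental unit. Percentages use labeled cells
#' (call in NUCLEAR / CYTOPLASMIC / BOTH) as the denominator; UNLABELED
#' cells are excluded from numerator and denominator, so the three
#' percentages sum to 100 whenever any labeled cell is present.
#'
#' @param records per-cell data.frame (from [classify_field()]) for a
#'   single well; must contain `call`, and all rows must share one `well`
#'   value when that column is present.
#' @return one-row data.frame: `well`, `treatment` (if present),
#'   `n_labeled`, `n_nuclear`, `n_cytoplasmic`, `n_both`, `pct_nuclear`,
#'   `pct_cytoplasmic`, `pct_both`, `flagged` (`TRUE` with `NA`
#'   percentages when `n_labeled == 0`).
#' @export
summarize_well <- function(records) {
  stopifnot(is.data.frame(records), "call" %in% names(records))
  well <- if ("well" %in% names(records)) unique(records$well) else NA
  if (length(well) > 1)
    stop_nucloc("records span ", length(well),
                " wells; summarize_well() takes a single well")
  cnt <- function(cl) sum(records$call == cl)
  n <- c(cnt("NUCLEAR"), cnt("CYTOPLASMIC"), cnt("BOTH"))
  n_lab <- sum(n)
  if (n_lab == 0) {
    warning("well ", well, ": no labeled cells; percentages undefined")
    pct <- rep(NA_real_, 3)
  } else {
    pct <- 100 * n / n_lab
  }
  out <- data.frame(well = if (length(well)) well else NA,
                    n_labeled = n_lab, n_nuclear = n[1],
                    n_cytoplasmic = n[2], n_both = n[3],
                    pct_nuclear = pct[1], pct_cytoplasmic = pct[2],
                    pct_both = pct[3], flagged = n_lab == 0,
                    stringsAsFactors = FALSE)
  if ("treatment" %in% names(records))
    out <- cbind(out[, "well", drop = FALSE],
                 treatment = unique(records$treatment)[1],
                 out[, -1, drop = FALSE])
  out
}

#' Summarize every well in a per-cell table
#'
#' @param records per-cell data.frame with a `well` column (and usually
#'   `treatment`).
#' @return data.frame with one [summarize_well()] row per well, in well
#'   order.
#' @export
summarize_wells <- function(records) {
  stopifnot(is.data.frame(records), "well" %in% names(records))
  parts <- split(records, records$well)
  out <- do.call(rbind, lapply(parts, summarize_well))
  rownames(out) <- NULL
  out[order(out$well), , drop = FALSE]
}

#' Group mean and standard error of well percentages
#'
#' @param x numeric vector of per-well percentages for one treatment and
#'   one localization class (length >= 2; the SE is undefined otherwise).
#' @return list with `mean`, `se` (sample SD / sqrt(n)), `n`.
#' @export
group_mean_se <- function(x) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 2) stop_nucloc("need >= 2 usable wells (got ", n,
                         "); SE is undefined")
  list(mean = mean(x), se = sd(x) / sqrt(n), n = n)
}

#' Two-sample t-test from group summary statistics
#'
#' Two-tailed independent-samples t-test computed directly from each
#' group's mean, standard error and well count — the form in which
#' published summary tables report localization percentages. The default
#' pooled-variance Student test recovers per-group SDs as
#' `se * sqrt(n)` and uses `df = n_A + n_B - 2`; the Welch variant uses
#' the Welch-Satterthwaite degrees of freedom.
#'
#' Degenerate inputs: when both SEs are zero the test is decided by the
#' means alone (p = 1 if equal, p = 0 with a warning otherwise).
#'
#' @param mean_a,se_a,n_a,mean_b,se_b,n_b group summaries (SE >= 0,
#'   n >= 2).
#' @param variant `"pooled"` (default) or `"welch"`.
#' @return list with `t`, `df`, `p` (two-tailed), and the echoed
#'   summaries.
#' @export
#' @examples
#' # cytoplasmic percentages, two groups of 6 wells
#' t_test_from_summary(45.12, 6.14, 6, 67.29, 6.61, 6)$p  # ~0.034
t_test_from_summary <- function(mean_a, se_a, n_a, mean_b, se_b, n_b,
                                variant = c("pooled", "welch")) {
  variant <- match.arg(variant)
  stopifnot(se_a >= 0, se_b >= 0, n_a >= 2, n_b >= 2)
  sd_a <- se_a * sqrt(n_a)
  sd_b <- se_b * sqrt(n_b)
  if (se_a == 0 && se_b == 0) {
    if (mean_a == mean_b) {
      t <- 0; df <- n_a + n_b - 2; p <- 1
    } else {
      warning("zero variance in both groups with unequal means; p = 0")
      t <- sign(mean_a - mean_b) * Inf; df <- n_a + n_b - 2; p <- 0
    }
  } else if (variant == "pooled") {
    df <- n_a + n_b - 2
    pooled_var <- ((n_a - 1) * sd_a^2 + (n_b - 1) * sd_b^2) / df
    t <- (mean_a - mean_b) / sqrt(pooled_var * (1 / n_a + 1 / n_b))
    p <- 2 * pt(-abs(t), df)
  } else {
    va <- sd_a^2 / n_a; vb <- sd_b^2 / n_b
    t <- (mean_a - mean_b) / sqrt(va + vb)
    df <- (va + vb)^2 / (va^2 / (n_a - 1) + vb^2 / (n_b - 1))
    p <- 2 * pt(-abs(t), df)
  }
  list(t = t, df = df, p = p, variant = variant,
       mean_a = mean_a, se_a = se_a, n_a = n_a,
       mean_b = mean_b, se_b = se_b, n_b = n_b)
}

#' Two-sample t-test from per-well summaries
#'
#' Computes each group's mean and SE with [group_mean_se()] and delegates
#' to [t_test_from_summary()], so the result is reproducible from a
#' per-well CSV alone.
#'
#' @param wells_a,wells_b [summarize_wells()] rows for the two groups
#'   (flagged wells are dropped), or plain numeric percentage vectors.
#' @param class localization class: `"nuclear"`, `"cytoplasmic"` or
#'   `"both"` (ignored for numeric input).
#' @param variant `"pooled"` or `"welch"`.
#' @return as [t_test_from_summary()].
#' @export
t_test_from_wells <- function(wells_a, wells_b,
                              class = c("nuclear", "cytoplasmic", "both"),
                              variant = c("pooled", "welch")) {
  class <- match.arg(class)
  pick <- function(w) {
    if (is.numeric(w)) return(w)
    stopifnot(is.data.frame(w))
    w <- w[!(w$flagged %||% FALSE), , drop = FALSE]
    w[[paste0("pct_", class)]]
  }
  a <- group_mean_se(pick(wells_a))
  b <- group_mean_se(pick(wells_b))
  t_test_from_summary(a$mean, a$se, a$n, b$mean, b$se, b$n,
                      variant = match.arg(variant))
}

#' Ratio effect size between two group means
#'
#' The fold difference reported alongside the t-tests: the larger mean
#' divided by the smaller, rounded half away from zero to one decimal.
#'
#' @param mean_a,mean_b positive group means.
#' @return ratio (>= 1) rounded to 1 decimal.
#' @export
#' @examples
#' ratio_effect(45.12, 67.29) # 1.5
ratio_effect <- function(mean_a, mean_b) {
  if (!(mean_a > 0 && mean_b > 0))
    stop_nucloc("ratio effect requires strictly positive means")
  round_half_up(max(mean_a, mean_b) / min(mean_a, mean_b), 1)
}

#' Compare two treatment groups across all three localization classes
#'
#' @param wells [summarize_wells()] output covering both groups (needs a
#'   `treatment` column), or a list of two data.frames.
#' @param group_a,group_b treatment names to compare.
#' @param variant t-test variant, `"pooled"` or `"welch"`.
#' @return data.frame with one row per class (`nuclear`, `cytoplasmic`,
#'   `both`): group means, SEs, n, `t`, `df`, `p`, and `ratio`
#'   (`NA` when either mean is not positive).
#' @export
compare_groups <- function(wells, group_a, group_b,
                           variant = c("pooled", "welch")) {
  variant <- match.arg(variant)
  stopifnot(is.data.frame(wells), "treatment" %in% names(wells))
  avail <- unique(wells$treatment)
  for (g in c(group_a, group_b))
    if (!g %in% avail)
      stop_nucloc("unknown group '", g, "'; available: ",
                  paste(avail, collapse = ", "))
  wa <- wells[wells$treatment == group_a & !wells$flagged, , drop = FALSE]
  wb <- wells[wells$treatment == group_b & !wells$flagged, , drop = FALSE]
  rows <- lapply(c("nuclear", "cytoplasmic", "both"), function(cl) {
    tt <- t_test_from_wells(wa, wb, class = cl, variant = variant)
    ratio <- if (tt$mean_a > 0 && tt$mean_b > 0)
      ratio_effect(tt$mean_a, tt$mean_b) else NA_real_
    data.frame(class = cl, group_a = group_a, mean_a = tt$mean_a,
               se_a = tt$se_a, n_a = tt$n_a, group_b = group_b,
               mean_b = tt$mean_b, se_b = tt$se_b, n_b = tt$n_b,
               t = tt$t, df = tt$df, p = tt$p, ratio = ratio,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "variant") <- variant
  out
}

#' Format a group comparison as a summary-table report
#'
#' Renders a Markdown table in the conventional layout of localization
#' summaries: one column per class, rows for each group's mean ± SE and a
#' final p-value row (p rounded to 2 decimals, half away from zero).
#'
#' @param cmp a [compare_groups()] result.
#' @return character vector of Markdown lines.
#' @export
format_localization_report <- function(cmp) {
  stopifnot(is.data.frame(cmp), nrow(cmp) == 3)
  hdr <- c("Nuclei labeled (%)", "Cytoplasm labeled (%)",
           "Nuclei and Cytoplasm labeled (%)")
  fmt_ms <- function(m, s) sprintf("%.2f ± %.2f", m, s)
  lines <- c(
    paste0("| | ", paste(hdr, collapse = " | "), " |"),
    paste0("|---|", paste(rep("---", 3), collapse = "|"), "|"),
    paste0("| ", cmp$group_a[1], " | ",
           paste(fmt_ms(cmp$mean_a, cmp$se_a), collapse = " | "), " |"),
    paste0("| ", cmp$group_b[1], " | ",
           paste(fmt_ms(cmp$mean_b, cmp$se_b), collapse = " | "), " |"),
    paste0("| p-value | ",
           paste(sprintf("%.2f", round_half_up(cmp$p, 2)),
                 collapse = " | "), " |"),
    paste0("| ratio (larger/smaller) | ",
           paste(ifelse(is.na(cmp$ratio), "-",
                        sprintf("%.1f", cmp$ratio)), collapse = " | "),
           " |"))
  lines
}
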