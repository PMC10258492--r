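# Two-group treatment comparison (e.g. control vs an in ovo feeding
# treatment): per-group aggregates with significance testing by one-way
# ANOVA followed by a pooled-variance Student t test.
#
# Statistical units: diameter and area are tested at the fiber level —
# the only unit consistent with SEMs of a few hundredths of a um on tens
# of thousands of fibers — while fiber density is tested at the image
# level, since a density value exists once per image. Fibers from the
# same image are not independent, so fiber-level p-values carry a
# pseudoreplication caveat (see the report attribute `note`).

#' Compare two treatment groups
#'
#' For each metric, runs a one-way ANOVA across the two groups followed
#' by a two-sample Student t test with pooled variance; with exactly two
#' groups the ANOVA F statistic equals the squared t statistic and the
#' p-values coincide. Diameter and area use fiber-level values from the
#' per-fiber tables; density uses image-level `fibers_per_mm2` from the
#' per-section summaries when these are supplied.
#'
#' @param group_a,group_b Per-fiber data frames (the
#'   [write_fiber_table()] schema; `source_id` identifies the image).
#' @param summary_a,summary_b Optional per-section summary data frames
#'   (from [measure_section()]), one row per image, providing
#'   `fibers_per_mm2` for the density test.
#' @param alpha Significance level (default 0.05); a metric is flagged
#'   significant when `p <= alpha`.
#' @param label_a,label_b Group labels for the report.
#' @return A list of class `group_report`: `groups`, a two-row data
#'   frame of per-group aggregates (count, mean +/- SEM of diameter,
#'   area and density), and `tests`, one row per metric with the t and F
#'   statistics, the p-value and the significance flag.
#' @export
compare_groups <- function(group_a, group_b,
                           summary_a = NULL, summary_b = NULL,
                           alpha = 0.05,
                           label_a = "group_a", label_b = "group_b") {
  if (alpha <= 0 || alpha >= 1) stop_validation("alpha must lie in (0, 1)")
  for (df in list(group_a, group_b)) {
    if (!is.data.frame(df) || nrow(df) == 0) {
      stop_validation("both groups need a nonempty fiber table")
    }
  }
  sem <- function(x) sd(x) / sqrt(length(x))
  agg <- function(df, label, smry) {
    data.frame(
      group_label = label,
      n_fibers = nrow(df),
      n_images = length(unique(df$source_id)),
      mean_diameter_um = mean(df$lesser_diameter_um),
      sem_diameter_um = sem(df$lesser_diameter_um),
      mean_area_um2 = mean(df$area_um2),
      sem_area_um2 = sem(df$area_um2),
      mean_fibers_per_mm2 = if (!is.null(smry)) mean(smry$fibers_per_mm2) else NA_real_,
      sem_fibers_per_mm2 = if (!is.null(smry) && nrow(smry) >= 2) {
        sem(smry$fibers_per_mm2)
      } else NA_real_
    )
  }
  groups <- rbind(agg(group_a, label_a, summary_a),
                  agg(group_b, label_b, summary_b))

  two_group_test <- function(a, b, metric) {
    if (length(a) < 2 || length(b) < 2) {
      stop_validation(sprintf(
        "metric '%s' needs >= 2 observations per group for testing", metric))
    }
    values <- c(a, b)
    grp <- factor(rep(c("a", "b"), c(length(a), length(b))))
    f_stat <- anova(aov(values ~ grp))[["F value"]][1]
    tt <- t.test(a, b, var.equal = TRUE)
    data.frame(metric = metric,
               t_statistic = unname(tt$statistic),
               f_statistic = f_stat,
               p_value = tt$p.value,
               significant = tt$p.value <= alpha)
  }
  tests <- rbind(
    two_group_test(group_a$lesser_diameter_um, group_b$lesser_diameter_um,
                   "diameter_um"),
    two_group_test(group_a$area_um2, group_b$area_um2, "area_um2"),
    if (!is.null(summary_a) && !is.null(summary_b)) {
      two_group_test(summary_a$fibers_per_mm2, summary_b$fibers_per_mm2,
                     "fibers_per_mm2")
    }
  )
  structure(list(groups = groups, tests = tests, alpha = alpha,
                 note = paste("diameter/area are tested on fiber-level values;",
                              "fibers from one image are not independent",
                              "(pseudoreplication); density is image-level")),
            class = "group_report")
}

#' @export
print.group_report <- function(x, ...) {
  cat("Two-group morphometry comparison (alpha =", x$alpha, ")\n\n")
  print(x$groups, row.names = FALSE)
  cat("\n")
  print(x$tests, row.names = FALSE)
  cat("\nNote:", x$note, "\n")
  invisible(x)
}

#' Flatten a group report for CSV export
#'
#' @param report A `group_report` from [compare_groups()].
#' @return A two-row data frame with per-group aggregates plus the
#'   shared p-values and significance flags per metric.
#' @export
group_report_table <- function(report) {
  stopifnot(inherits(report, "group_report"))
  out <- report$groups
  for (i in seq_len(nrow(report$tests))) {
    m <- report$tests$metric[i]
    out[[paste0("p_value_", m)]] <- report$tests$p_value[i]
    out[[paste0("significant_", m)]] <- report$tests$significant[i]
  }
  out
}
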