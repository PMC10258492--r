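# Method-agreement metrics: coefficient of variance, accuracy rate and
# productivity, plus the side-by-side comparison report of a reference
# (typically manual) and a test (typically automated) analysis.

#' Coefficient of variance
#'
#' `CV = (sample SD / mean) x 100`, the conventional spread metric for
#' fiber-size distributions. Scale-invariant: multiplying all values by a
#' positive constant leaves it unchanged.
#'
#' @param values Numeric vector, length >= 2, nonzero mean.
#' @return CV in percent.
#' @examples
#' coefficient_of_variance(c(1, 2, 3))  # 50
#' @export
coefficient_of_variance <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 2 || anyNA(values)) {
    stop_validation("CV requires at least 2 non-missing values")
  }
  m <- mean(values)
  if (m == 0) stop_validation("CV is undefined for a zero mean")
  sd(values) / m * 100
}

#' Accuracy rate of a test value against a reference
#'
#' `Accuracy = (1 - |test - reference| / |reference|) x 100`. The
#' denominator is the reference (e.g. manual) value, so the metric is
#' asymmetric: swapping the arguments changes the result unless the two
#' values are equal, in which case it is exactly 100.
#'
#' @param test_value Value produced by the method under evaluation.
#' @param reference_value Nonzero reference value.
#' @return Accuracy in percent (can be negative for gross disagreement).
#' @examples
#' accuracy_rate(22.84, 22.86)   # 99.91 to 2 d.p.
#' accuracy_rate(717.69, 676.44) # 93.90 to 2 d.p.
#' @export
accuracy_rate <- function(test_value, reference_value) {
  if (length(test_value) != 1 || length(reference_value) != 1 ||
      anyNA(c(test_value, reference_value))) {
    stop_validation("accuracy_rate takes two scalar values")
  }
  if (reference_value == 0) {
    stop_validation("accuracy rate is undefined for a zero reference value")
  }
  (1 - abs(test_value - reference_value) / abs(reference_value)) * 100
}

#' Productivity of an analysis method
#'
#' Data sets generated per hour of analysis. A fiber measured for both
#' diameter and area contributes two data sets; a diameter-only (manual)
#' measurement contributes one.
#'
#' @param n_data_sets Nonnegative count of data sets generated.
#' @param hours Positive total analysis time in hours.
#' @return Data sets per hour.
#' @examples
#' productivity(2 * 15881, 1.4)  # ~22687 per hour
#' productivity(17333, 54)       # ~321 per hour
#' @export
productivity <- function(n_data_sets, hours) {
  if (length(hours) != 1 || is.na(hours) || hours <= 0) {
    stop_validation("hours must be a positive scalar")
  }
  if (length(n_data_sets) != 1 || is.na(n_data_sets) || n_data_sets < 0) {
    stop_validation("n_data_sets must be a nonnegative scalar")
  }
  n_data_sets / hours
}

#' Compare two analysis methods on the same material
#'
#' Builds the standard method-comparison report from two per-fiber
#' record tables (the [write_fiber_table()] schema): fiber counts, means
#' and CVs pooled over all fibers regardless of how they are partitioned
#' into sections, the accuracy rate of the test means against the
#' reference means, and the productivity of each method. Records with a
#' missing `area_um2` (e.g. a diameter-only manual analysis) contribute
#' one data set each to the productivity count; records with both
#' metrics contribute two. Area agreement is reported only when both
#' tables carry areas.
#'
#' @param reference Per-fiber data frame of the reference (manual) method.
#' @param test Per-fiber data frame of the method under evaluation.
#' @param hours_reference,hours_test Total analysis times, hours.
#' @param reference_label,test_label Report labels.
#' @return A one-row data frame of class `method_comparison`.
#' @export
compare_methods <- function(reference, test, hours_reference, hours_test,
                            reference_label = "reference", test_label = "test") {
  for (df in list(reference, test)) {
    if (!is.data.frame(df) || nrow(df) == 0 ||
        !"lesser_diameter_um" %in% names(df)) {
      stop_validation("both methods need a nonempty fiber table with lesser_diameter_um")
    }
  }
  n_ref <- nrow(reference); n_test <- nrow(test)
  mean_ref <- mean(reference$lesser_diameter_um)
  mean_test <- mean(test$lesser_diameter_um)
  has_area <- function(df) "area_um2" %in% names(df) && !anyNA(df$area_um2)
  data_sets <- function(df) nrow(df) * (1L + has_area(df))
  area_ref <- if (has_area(reference)) mean(reference$area_um2) else NA_real_
  area_test <- if (has_area(test)) mean(test$area_um2) else NA_real_
  out <- data.frame(
    reference_label = reference_label,
    test_label = test_label,
    n_reference = n_ref,
    n_test = n_test,
    mean_diameter_reference_um = mean_ref,
    mean_diameter_test_um = mean_test,
    cv_reference_percent = coefficient_of_variance(reference$lesser_diameter_um),
    cv_test_percent = coefficient_of_variance(test$lesser_diameter_um),
    accuracy_diameter_percent = accuracy_rate(mean_test, mean_ref),
    mean_area_reference_um2 = area_ref,
    mean_area_test_um2 = area_test,
    accuracy_area_percent = if (!is.na(area_ref) && !is.na(area_test)) {
      accuracy_rate(area_test, area_ref)
    } else NA_real_,
    productivity_reference = productivity(data_sets(reference), hours_reference),
    productivity_test = productivity(data_sets(test), hours_test)
  )
  class(out) <- c("method_comparison", "data.frame")
  out
}
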