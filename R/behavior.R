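#' Score classification trials
#'
#' A response is correct when it matches the category of the nearer
#' prototype: items at distance 0-3 from the A prototype are correct when
#' labeled A; items at distance 5-7 (hence 3-1 from the B prototype) are
#' correct when labeled B. Adds the distance folded to the nearer prototype
#' (0-3). Equidistant stimuli are a design error and are rejected.
#'
#' @param trials Trial tibble with `dist_to_A` and `response` columns.
#' @return The tibble with `folded_dist` and logical `correct` columns
#'   (`correct` is `NA` for omitted trials).
#' @export
score_trials <- function(trials) {
  if (any(trials$dist_to_A == 4L))
    stop("equidistant stimuli cannot be scored", call. = FALSE)
  dplyr::mutate(trials,
    folded_dist = pmin(.data$dist_to_A, 8L - .data$dist_to_A),
    correct = dplyr::if_else(
      is.na(.data$response) | .data$response == "none", NA,
      .data$response == dplyr::if_else(.data$dist_to_A < 4L, "A", "B"))
  )
}

#' Per-subject accuracy table
#'
#' Mean accuracy per subject, phase, folded prototype distance (0-3) and
#' item type (old = trained items, which all sit at distance 2; everything
#' else, including the prototypes, is new). Omitted trials are excluded from
#' the denominators; cells with no responded trials are absent rather than
#' zero.
#'
#' @param trials Trial tibble with `subject` and `phase` columns.
#' @return A tibble: subject, phase, distance, item_type (`"old"`/`"new"`),
#'   n, n_correct, accuracy.
#' @export
accuracy_table <- function(trials) {
  scored <- score_trials(trials)
  scored |>
    dplyr::filter(!is.na(.data$correct)) |>
    dplyr::mutate(item_class = dplyr::if_else(.data$item_type == "training",
                                              "old", "new")) |>
    dplyr::group_by(.data$subject, .data$phase, distance = .data$folded_dist,
                    item_type = .data$item_class) |>
    dplyr::summarise(n = dplyr::n(), n_correct = sum(.data$correct),
                     accuracy = mean(.data$correct), .groups = "drop")
}

#' Group accuracy summary
#'
#' Across-subject mean and standard error of the per-subject cell
#' accuracies.
#'
#' @param acc An accuracy table from [accuracy_table()].
#' @return A tibble: phase, distance, item_type, n_subjects, mean_accuracy,
#'   se.
#' @export
group_accuracy <- function(acc) {
  acc |>
    dplyr::group_by(.data$phase, .data$distance, .data$item_type) |>
    dplyr::summarise(n_subjects = dplyr::n(),
                     mean_accuracy = mean(.data$accuracy),
                     se = sd(.data$accuracy) / sqrt(dplyr::n()),
                     .groups = "drop")
}

#' Linear-contrast score across ordered levels
#'
#' Centered linear-contrast weighted sum of per-level values, the
#' per-subject score behind linear-trend tests (e.g., increasing
#' generalization accuracy across the four interim tests). For `k` levels
#' the integer weights are `2 * (1:k) - (k + 1)` (for 4 levels: -3, -1, 1,
#' 3); `normalize = TRUE` halves them (-1.5, -0.5, 0.5, 1.5) so the score
#' for a unit step equals the number of level gaps.
#'
#' @param values Numeric vector of per-level means, in level order with
#'   equal spacing.
#' @param normalize Use half-integer weights.
#' @return The contrast score; `NA` (with a warning) if any level is
#'   missing.
#' @examples
#' linear_trend(c(0.6, 0.7, 0.8, 0.9)) # 10 * 0.1
#' @export
linear_trend <- function(values, normalize = FALSE) {
  k <- length(values)
  if (k < 2) stop("need at least two levels", call. = FALSE)
  if (any(is.na(values))) {
    warning("missing level in linear contrast; returning NA")
    return(NA_real_)
  }
  w <- 2 * seq_len(k) - (k + 1)
  if (normalize) w <- w / 2
  sum(w * values)
}

#' Per-subject linear trends from an accuracy table
#'
#' Computes the linear-contrast score over an ordered set of phases (by
#' default the four interim tests) for each subject, on new items only or
#' on a chosen cell.
#'
#' @param acc An accuracy table from [accuracy_table()].
#' @param phases Ordered character vector of phase levels.
#' @param item_type Which item class to track (`"new"` or `"old"`).
#' @param normalize Passed to [linear_trend()].
#' @return A tibble: subject, trend.
#' @export
linear_trend_by_subject <- function(acc, phases = paste0("interim_", 1:4),
                                    item_type = "new", normalize = FALSE) {
  acc |>
    dplyr::filter(.data$phase %in% phases, .data$item_type == !!item_type) |>
    dplyr::group_by(.data$subject, .data$phase) |>
    dplyr::summarise(accuracy = sum(.data$n_correct) / sum(.data$n),
                     .groups = "drop") |>
    tidyr::complete(subject = unique(.data$subject), phase = phases) |>
    dplyr::group_by(.data$subject) |>
    dplyr::summarise(
      trend = linear_trend(.data$accuracy[match(phases, .data$phase)],
                           normalize = normalize),
      .groups = "drop")
}
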