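## Identification of personalized therapy parameters from a class grid.
##
## The class grid holds one label per (position, current, muscle). A
## nested rule cascade picks the electrode position and the current at
## which reflex activity is densest; the therapy current is then 90% of
## the lowest current at which the first reflex occurred at the chosen
## position (sub-motor threshold).

# Per-position ranking statistics for the nested search.
position_stats <- function(grid) {
  grid %>%
    filter(!is.na(.data$label)) %>%
    group_by(.data$position, .data$current) %>%
    summarise(n1 = sum(.data$label == 1),
              n_resp = sum(.data$label > 0), .groups = "drop_last") %>%
    summarise(
      passes_rule1 = any(.data$n1 >= 2),
      max_n1 = max(.data$n1),
      candidate_current = ifelse(any(.data$n1 == max(.data$n1)),
                                 min(.data$current[.data$n1 ==
                                                     max(.data$n1)]),
                                 NA_real_),
      onset_current = if (any(.data$n_resp > 0))
        min(.data$current[.data$n_resp > 0]) else NA_real_,
      total_n1 = sum(.data$n1),
      .groups = "drop") %>%
    mutate(onset_gap = .data$candidate_current - .data$onset_current)
}

#' Nested search for the optimal electrode position and current
#'
#' Applies the rule cascade to a labeled class grid of one subject and
#' measurement: (1) only positions with at least two class-1 labels at
#' one current among the four muscles survive; survivors are then ranked
#' by (2) the largest number of class-1 labels at one current, (3) the
#' smallest current gap between the onset of any leg response and that
#' maximum, (4) the lowest such current, and (5) the largest total
#' class-1 count at the position, each rule breaking ties left by the
#' previous one. Residual ties go to the most caudal position.
#'
#' @param grid Tibble with columns `position`, `current`, `muscle`,
#'   `label` (integer class; `NA` = invalid event, ignored).
#' @return List with `position` and `current` (the current of the rule-2
#'   maximum), or `NULL` when no position passes rule 1.
#' @export
#' @examples
#' g <- tidyr::expand_grid(position = 0, current = c(10, 15),
#'                         muscle = c("Q_left", "Q_right", "TS_left",
#'                                    "TS_right"))
#' g$label <- c(0L, 0L, 0L, 0L, 1L, 1L, 0L, 0L)
#' select_position_current(g)
select_position_current <- function(grid) {
  stopifnot(nrow(grid) > 0)
  st <- position_stats(grid) %>% filter(.data$passes_rule1)
  if (nrow(st) == 0) return(NULL)
  st <- st %>%
    arrange(desc(.data$max_n1), .data$onset_gap, .data$candidate_current,
            desc(.data$total_n1), .data$position)
  list(position = st$position[1], current = st$candidate_current[1])
}

#' Lowest current with a reflex response at a position
#'
#' @param grid Class grid as in [select_position_current()].
#' @param position Electrode position to evaluate.
#' @return Smallest current with at least one class-1 label across the
#'   muscles, or `NA` when the position has none.
#' @export
first_reflex_current <- function(grid, position) {
  g <- grid %>% filter(.data$position == !!position, !is.na(.data$label),
                       .data$label == 1)
  if (nrow(g) == 0) return(NA_real_)
  min(g$current)
}

#' Sub-motor therapy current
#'
#' 90 percent of the current at which the first reflex occurred, exact
#' (no rounding); 0 stays 0 (no reflex found).
#'
#' @param first_reflex Current in mA (>= 0).
#' @return Therapy current in mA.
#' @export
#' @examples
#' therapy_current(15) # 13.5
therapy_current <- function(first_reflex) {
  stopifnot(all(first_reflex >= 0, na.rm = TRUE))
  0.9 * first_reflex
}

#' Derive therapy parameters for every subject and measurement
#'
#' Runs the nested position/current search on each (subject, measurement)
#' class grid and converts the first reflex current at the selected
#' position into the sub-motor therapy current. When no position passes
#' rule 1 (lack of class-1 events) the therapy current is 0 mA and the
#' position is `NA`. The class-1 label means "reflex response" under the
#' 3-class scheme and "response" under the 2-class scheme; the search is
#' the same.
#'
#' @param labels Labeled event tibble (e.g. from [label_events()] or a
#'   prediction table) with columns `subject_id`, `measurement`,
#'   `position`, `current`, `muscle` and the label column.
#' @param label_col Name of the label column (e.g. `"label_3"`,
#'   `"label_2"`, `"pred"`).
#' @return Tibble: one row per (subject, measurement) with `position`,
#'   `first_reflex`, `therapy_current`, `n_positions`.
#' @export
derive_therapy_params <- function(labels, label_col = "label_3") {
  labels %>%
    mutate(label = as.integer(as.character(.data[[label_col]]))) %>%
    group_by(.data$subject_id, .data$group, .data$measurement) %>%
    dplyr::group_modify(function(g, key) {
      sel <- select_position_current(g)
      if (is.null(sel))
        return(tibble(position = NA_real_, first_reflex = NA_real_,
                      therapy_current = 0,
                      n_positions = dplyr::n_distinct(g$position)))
      frc <- first_reflex_current(g, sel$position)
      tibble(position = sel$position, first_reflex = frc,
             therapy_current = therapy_current(frc),
             n_positions = dplyr::n_distinct(g$position))
    }) %>%
    ungroup()
}

#' Compare classifier-derived with EMG-derived therapy parameters
#'
#' Joins the two parameter tables by (subject, measurement) and computes
#' the per-measurement current difference (EMG minus predicted: negative
#' means the classifier chose a higher current), the exact and
#' within-margin current agreement, and -- for multi-position
#' measurements -- the position agreement. Missing currents are encoded
#' as 0 mA in both tables.
#'
#' @param gt Therapy parameters derived from the EMG ground-truth labels
#'   ([derive_therapy_params()]).
#' @param pred Therapy parameters derived from predicted labels.
#' @param margin Agreement margin in mA (inclusive).
#' @return Tibble with one row per (subject, measurement):
#'   `current_diff`, `exact_current`, `within_margin`, `position_match`
#'   (`NA` for single-position measurements).
#' @export
compare_therapy_params <- function(gt, pred, margin = 5) {
  joined <- dplyr::inner_join(
    gt %>% rename(gt_position = "position",
                  gt_current = "therapy_current"),
    pred %>% select("subject_id", "measurement",
                    pred_position = "position",
                    pred_current = "therapy_current"),
    by = c("subject_id", "measurement"))
  if (nrow(joined) != nrow(gt) || nrow(joined) != nrow(pred))
    stop("subject/measurement mismatch between parameter tables",
         call. = FALSE)
  joined %>%
    mutate(
      current_diff = .data$gt_current - .data$pred_current,
      exact_current = .data$current_diff == 0,
      within_margin = abs(.data$current_diff) <= margin,
      position_match = ifelse(
        .data$n_positions > 1,
        !is.na(.data$gt_position) & !is.na(.data$pred_position) &
          .data$gt_position == .data$pred_position,
        NA)) %>%
    select("subject_id", "measurement", "group",
           dplyr::any_of(c("gt_position", "pred_position")),
           "gt_current", "pred_current", "current_diff", "exact_current",
           "within_margin", "position_match", "n_positions")
}

#' Aggregate agreement proportions
#'
#' @param comparison Output of [compare_therapy_params()].
#' @return One-row tibble: proportions of measurements with exact current
#'   agreement, agreement within the margin, position agreement, and
#'   position + within-margin agreement (position proportions over the
#'   multi-position measurements only).
#' @export
agreement_summary <- function(comparison) {
  multi <- comparison %>% filter(!is.na(.data$position_match))
  tibble(
    n = nrow(comparison),
    prop_exact_current = mean(comparison$exact_current),
    prop_within_margin = mean(comparison$within_margin),
    n_position = nrow(multi),
    prop_position = if (nrow(multi)) mean(multi$position_match) else NA_real_,
    prop_position_and_margin = if (nrow(multi))
      mean(multi$position_match & multi$within_margin) else NA_real_)
}

#' Plot EMG-derived vs classifier-derived therapy currents
#'
#' Scatter of the two currents per measurement with the identity
#' diagonal; point size shows the number of coinciding measurements.
#'
#' @param comparison Output of [compare_therapy_params()].
#' @return A ggplot.
#' @export
plot_therapy_agreement <- function(comparison) {
  df <- comparison %>%
    count(.data$gt_current, .data$pred_current, .data$group)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$gt_current,
                                   y = .data$pred_current,
                                   size = .data$n,
                                   colour = .data$group)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "grey40") +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::labs(x = "EMG-derived therapy current (mA)",
                  y = "classifier-derived therapy current (mA)",
                  size = "measurements") +
    ggplot2::theme_minimal()
}
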