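#' Read a long-format daily-ratings table
#'
#' One row per person-day with the two daily mood item responses. The file
#' must be a UTF-8 CSV with a header containing at least
#' `person_id, day, item1, item2`; missing cells are empty. Responses are
#' validated against the declared range (1-5 on the daily Likert scale)
#' unless `continuous = TRUE`, in which case any finite value is accepted
#' (simulated continuous-indicator data).
#'
#' @param path path to a CSV file.
#' @param continuous logical; accept non-integer / out-of-range responses.
#' @return A validated data frame sorted by (person_id, day), of class
#'   `data.frame`, with columns `person_id` (character), `day` (integer),
#'   `item1`, `item2` (numeric).
#' @export
read_long_daily <- function(path, continuous = FALSE) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(person_id = "character"),
                        na.strings = "")
  validate_long_daily(df, continuous = continuous)
}

#' Write a long-format daily-ratings table
#' @param daily a validated daily table.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_long_daily <- function(daily, path) {
  utils::write.csv(daily, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Validate a long daily table
#'
#' Checks required columns, response ranges and the one-row-per-person-day
#' invariant, and returns the table stably sorted by (person_id, day).
#'
#' @param df data frame with columns person_id, day, item1, item2.
#' @param continuous logical; skip the 1-5 integer range check.
#' @return The validated, sorted data frame.
#' @export
validate_long_daily <- function(df, continuous = FALSE) {
  need <- c("person_id", "day", "item1", "item2")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("daily table format error: missing column(s) ",
         paste(miss, collapse = ", "), call. = FALSE)
  df$person_id <- as.character(df$person_id)
  df$day <- as.integer(df$day)
  for (col in c("item1", "item2")) df[[col]] <- as.numeric(df[[col]])
  if (!continuous) {
    for (col in c("item1", "item2")) {
      v <- df[[col]]
      bad <- which(!is.na(v) & (v < 1 | v > 5 | v != round(v)))
      if (length(bad))
        stop(sprintf("daily table integrity error: %s out of range {1..5} on row(s) %s",
                     col, paste(utils::head(bad, 10L), collapse = ", ")),
             call. = FALSE)
    }
  }
  key <- paste(df$person_id, df$day, sep = "\r")
  if (anyDuplicated(key))
    stop(sprintf("daily table integrity error: duplicate (person_id, day) on row(s) %s",
                 paste(utils::head(which(duplicated(key)), 10L), collapse = ", ")),
         call. = FALSE)
  df <- df[order(df$person_id, df$day, method = "radix"), , drop = FALSE]
  rownames(df) <- NULL
  df
}

panel_item_cols <- function() paste0("phq9_item", 1:9)

#' Read a questionnaire panel table
#'
#' Wide per-person, week-indexed rows holding the 9 questionnaire item
#' responses (0-3 each), the questionnaire sum (0-27), the 3-item
#' disability-scale sum (0-30) and demographic group labels.
#'
#' @param path path to a CSV file with header columns `person_id, week,
#'   phq9_item1..phq9_item9, phq9_sum, sds_sum, gender, age_band, minority`.
#' @param continuous logical; accept continuous item values (simulation mode).
#' @return A validated data frame sorted by (person_id, week).
#' @export
read_panel <- function(path, continuous = FALSE) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(person_id = "character"),
                        na.strings = "")
  validate_panel(df, continuous = continuous)
}

#' Write a questionnaire panel table
#' @param panel a validated panel table.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path) {
  utils::write.csv(panel, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Validate a questionnaire panel table
#' @param df data frame to validate.
#' @param continuous logical; skip the 0-3 integer item range check.
#' @return The validated data frame sorted by (person_id, week).
#' @export
validate_panel <- function(df, continuous = FALSE) {
  item_cols <- grep("^phq9_item[0-9]+$", names(df), value = TRUE)
  if (!length(item_cols)) item_cols <- panel_item_cols()
  need <- c("person_id", "week", item_cols, "phq9_sum", "sds_sum")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("panel format error: missing column(s) ",
         paste(miss, collapse = ", "), call. = FALSE)
  df$person_id <- as.character(df$person_id)
  df$week <- as.integer(df$week)
  for (col in c(item_cols, "phq9_sum", "sds_sum"))
    df[[col]] <- as.numeric(df[[col]])
  if (!continuous) {
    for (col in item_cols) {
      v <- df[[col]]
      bad <- which(!is.na(v) & (v < 0 | v > 3 | v != round(v)))
      if (length(bad))
        stop(sprintf("panel integrity error: %s out of range {0..3} on row(s) %s",
                     col, paste(utils::head(bad, 10L), collapse = ", ")),
             call. = FALSE)
    }
    items <- as.matrix(df[item_cols])
    full <- stats::complete.cases(items) & !is.na(df$phq9_sum)
    bad <- which(full & abs(rowSums(items) - df$phq9_sum) > 1e-8)
    if (length(bad))
      stop(sprintf("panel integrity error: phq9_sum != sum of items on row(s) %s",
                   paste(utils::head(bad, 10L), collapse = ", ")), call. = FALSE)
  }
  key <- paste(df$person_id, df$week, sep = "\r")
  if (anyDuplicated(key))
    stop(sprintf("panel integrity error: duplicate (person_id, week) on row(s) %s",
                 paste(utils::head(which(duplicated(key)), 10L), collapse = ", ")),
         call. = FALSE)
  df <- df[order(df$person_id, df$week, method = "radix"), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Analysis run configuration
#'
#' @param window_length_days length of the daily-rating window preceding the
#'   anchor questionnaire (days).
#' @param anchor_week week of the anchor questionnaire; the anchor day is
#'   `7 * anchor_week` and the window is the half-open interval
#'   `[anchor - window, anchor)`, so a rating on the anchor day itself is
#'   outside the window (the daily item asks about "yesterday").
#' @param outcome_week week of the outcome questionnaire.
#' @param seed integer seed for any stochastic step.
#' @param reltol relative convergence tolerance passed to the optimizer.
#' @param max_iter maximum quasi-Newton iterations per fit.
#' @return A list of class `phq_run_config`.
#' @export
run_config <- function(window_length_days = 14L, anchor_week = 4L,
                       outcome_week = 8L, seed = 1L,
                       reltol = 1e-12, max_iter = 500L) {
  stopifnot(window_length_days >= 1, reltol > 0, max_iter >= 1)
  structure(list(window_length_days = as.integer(window_length_days),
                 anchor_week = as.integer(anchor_week),
                 outcome_week = as.integer(outcome_week),
                 seed = as.integer(seed),
                 reltol = reltol, max_iter = as.integer(max_iter)),
            class = "phq_run_config")
}

#' Read a run configuration from a YAML file
#'
#' Unknown keys are rejected so configuration typos fail loudly.
#'
#' @param path YAML file whose top-level keys are [run_config()] arguments.
#' @return A `phq_run_config`.
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  bad <- setdiff(names(vals), names(formals(run_config)))
  if (length(bad))
    stop("unknown run-config key(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  do.call(run_config, vals)
}

#' Write a run configuration to YAML
#' @param cfg a `phq_run_config`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' Apply the analysis-sample eligibility filters
#'
#' Retains persons who (a) have an anchor-week questionnaire row with a
#' non-missing sum score and (b) have at least one daily rating inside the
#' window preceding the anchor day. The returned daily table keeps only
#' in-window rows of retained persons; the panel keeps all weeks of
#' retained persons. An exclusion log records each dropped person with a
#' reason, so that retained + excluded persons always partition the input.
#'
#' @param daily validated daily table.
#' @param panel validated panel table.
#' @param cfg a `phq_run_config`.
#' @return List with `daily`, `panel`, `exclusions` (data frame with
#'   columns person_id, reason), `anchor_day`.
#' @export
apply_sample_filters <- function(daily, panel, cfg = run_config()) {
  anchor <- 7L * cfg$anchor_week
  lo <- anchor - cfg$window_length_days
  in_window <- daily$day >= lo & daily$day < anchor
  anchor_rows <- panel$week == cfg$anchor_week & !is.na(panel$phq9_sum)
  has_anchor <- unique(panel$person_id[anchor_rows])
  has_daily <- unique(daily$person_id[in_window])

  everyone <- sort(unique(c(daily$person_id, panel$person_id)))
  reason <- rep(NA_character_, length(everyone))
  reason[!(everyone %in% has_anchor)] <- "no anchor-week questionnaire"
  reason[everyone %in% has_anchor & !(everyone %in% has_daily)] <-
    "no in-window daily rating"
  keep <- everyone[is.na(reason)]
  if (!length(keep))
    stop("no eligible persons after sample filters", call. = FALSE)
  exclusions <- data.frame(person_id = everyone[!is.na(reason)],
                           reason = reason[!is.na(reason)],
                           stringsAsFactors = FALSE)
  list(daily = daily[in_window & daily$person_id %in% keep, , drop = FALSE],
       panel = panel[panel$person_id %in% keep, , drop = FALSE],
       exclusions = exclusions,
       anchor_day = anchor)
}
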