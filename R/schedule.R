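#' Read a presentation schedule
#'
#' CSV with columns `trial_id, presentation_index, condition,
#' presentation_location, demonstrator_side, start_frame, end_frame,
#' experiment_id`. Conditions must be `test` or `control`, locations
#' `top` or `bottom`, sides `A` or `B`; every presentation window must
#' satisfy `start_frame < end_frame` and `presentation_index >= 1`.
#'
#' @param path CSV file path.
#' @return validated schedule data.frame (class `presentation_schedule`).
#' @export
read_schedule <- function(path) {
  if (!file.exists(path)) stop("schedule file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_schedule(df)
}

#' @rdname read_schedule
#' @param schedule a schedule data.frame to validate or write.
#' @export
validate_schedule <- function(schedule) {
  need <- c("trial_id", "presentation_index", "condition",
            "presentation_location", "demonstrator_side",
            "start_frame", "end_frame", "experiment_id")
  if (nrow(schedule) == 0L) stop("schedule is empty")
  miss <- setdiff(need, names(schedule))
  if (length(miss))
    stop("schedule is missing columns: ", paste(miss, collapse = ", "))
  bad <- setdiff(unique(schedule$condition), c("test", "control"))
  if (length(bad)) stop("unknown condition label: ", paste(bad, collapse = ", "))
  bad <- setdiff(unique(schedule$presentation_location), c("top", "bottom"))
  if (length(bad))
    stop("unknown presentation location: ", paste(bad, collapse = ", "))
  bad <- setdiff(unique(schedule$demonstrator_side), c("A", "B"))
  if (length(bad))
    stop("unknown demonstrator side: ", paste(bad, collapse = ", "))
  if (any(schedule$presentation_index < 1))
    stop("presentation_index must be >= 1")
  if (any(schedule$start_frame >= schedule$end_frame))
    stop("every presentation needs start_frame < end_frame")
  class(schedule) <- c("presentation_schedule", "data.frame")
  schedule
}

#' @rdname read_schedule
#' @export
write_schedule <- function(schedule, path) {
  utils::write.csv(as.data.frame(schedule), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Build a counterbalanced schedule from a condition pattern
#'
#' Expands a pattern string such as `"TTTTCCTTTTCC"` or
#' `"TC-CT-TC-TC-CT-TC-CT-CT"` (separators are ignored; `T` = test,
#' `C` = control) into one trial's presentation windows.
#'
#' @param pattern condition pattern string.
#' @param config a [scene_config()] (frame rate).
#' @param trial_id trial identifier.
#' @param experiment_id experiment identifier.
#' @param presentation_s presentation duration in seconds (the object is
#'   pulled back and forth for about 24 s).
#' @param gap_s inter-presentation interval in seconds.
#' @param start_frame first frame of the first presentation.
#' @param locations presentation locations per presentation (recycled).
#' @param demonstrator_side side(s) holding the demonstrators (recycled).
#' @return a `presentation_schedule`.
#' @export
schedule_from_pattern <- function(pattern, config, trial_id = 1L,
                                  experiment_id = 1L,
                                  presentation_s = 24, gap_s = 20,
                                  start_frame = 0L,
                                  locations = c("top", "bottom"),
                                  demonstrator_side = "A") {
  letters_ <- strsplit(gsub("[^TCtc]", "", pattern), "")[[1]]
  if (!length(letters_)) stop("pattern contains no T/C letters")
  cond <- ifelse(toupper(letters_) == "T", "test", "control")
  nfr <- round(presentation_s * config$frame_rate)
  gfr <- round(gap_s * config$frame_rate)
  n <- length(cond)
  starts <- start_frame + (seq_len(n) - 1L) * (nfr + gfr)
  validate_schedule(data.frame(
    trial_id = trial_id, presentation_index = seq_len(n),
    condition = cond,
    presentation_location = rep_len(locations, n),
    demonstrator_side = rep_len(demonstrator_side, n),
    start_frame = as.integer(starts),
    end_frame = as.integer(starts + nfr - 1L),
    experiment_id = experiment_id,
    stringsAsFactors = FALSE))
}
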