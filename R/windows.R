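#' Maximal runs of acceptable frames
#'
#' @param flags Logical vector, one element per frame (`TRUE` = the dog is
#'   standing square, still and looking forward).
#' @return Tibble of maximal `TRUE` runs: `start` (0-based), `length`, ordered
#'   by start. Zero rows if no frame is acceptable.
#' @export
acceptable_runs <- function(flags) {
  if (!is.logical(flags) || any(is.na(flags))) {
    abort("`flags` must be a logical vector without NAs.")
  }
  if (length(flags) == 0L) {
    return(tibble::tibble(start = integer(), length = integer()))
  }
  r <- rle(flags)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- r$values
  tibble::tibble(start = as.integer(starts[keep]), length = as.integer(r$lengths[keep]))
}

# earliest window of `len` acceptable frames in `flags` not overlapping any
# [start, start+len) interval in `blocked` (integer starts); NA if none
earliest_free_window <- function(flags, len, blocked) {
  runs <- acceptable_runs(flags)
  for (i in seq_len(nrow(runs))) {
    lo <- runs$start[i]
    hi <- runs$start[i] + runs$length[i] - len  # last admissible start in run
    s <- lo
    while (s <= hi) {
      clash <- blocked[blocked < s + len & blocked + len > s]
      if (length(clash) == 0L) return(s)
      s <- max(clash) + len  # jump past the last overlapping window
    }
  }
  NA_integer_
}

#' Select analysis windows of acceptable standing
#'
#' Implements the two-pass selection of `n_windows` non-overlapping windows of
#' `window_len` consecutive acceptable frames across a dog's trials. Pass 1
#' walks the trials in recording order and takes the earliest admissible
#' window of each trial. If fewer than `n_windows` result, Pass 2 cycles
#' through the trials again (round-robin, recording order), each time taking
#' the earliest acceptable window that does not overlap windows already taken
#' from that trial, until the quota is met or no trial can yield another
#' window.
#'
#' @param masks Named list of logical vectors (one per trial, in recording
#'   order; names are trial ids), or a tibble with columns `trial_id`,
#'   `frame_idx`, `acceptable` (trial order = first appearance).
#' @param n_windows Number of windows required (protocol default 7).
#' @param window_len Window length in frames (protocol default 70).
#' @return Tibble of selected windows in selection order: `trial_id`,
#'   `start_frame` (0-based, window is `[start_frame, start_frame +
#'   window_len)`), `window_idx`.
#' @section Exclusion: If fewer than `n_windows` windows are obtainable the
#'   subject cannot be analysed under the protocol; an error of class
#'   `caninesway_exclusion_error` is raised carrying `windows_found`.
#' @export
select_windows <- function(masks, n_windows = 7, window_len = 70) {
  if (is.data.frame(masks)) {
    stopifnot(all(c("trial_id", "frame_idx", "acceptable") %in% names(masks)))
    ids <- unique(masks$trial_id)
    masks <- lapply(ids, function(tid) {
      sub <- masks[masks$trial_id == tid, ]
      as.logical(sub$acceptable[order(sub$frame_idx)])
    })
    names(masks) <- ids
  }
  if (is.null(names(masks))) names(masks) <- as.character(seq_along(masks))
  chosen <- lapply(masks, function(...) integer())  # starts per trial
  sel_trial <- character()                          # selection order
  sel_start <- integer()
  taken <- 0L
  add <- function(trial, start) {
    chosen[[trial]] <<- c(chosen[[trial]], start)
    sel_trial <<- c(sel_trial, trial)
    sel_start <<- c(sel_start, start)
    taken <<- taken + 1L
  }
  # Pass 1: one window per trial, recording order
  for (trial in names(masks)) {
    if (taken >= n_windows) break
    s <- earliest_free_window(masks[[trial]], window_len, integer())
    if (!is.na(s)) add(trial, s)
  }
  # Pass 2: round-robin over trials, earliest non-overlapping window each visit
  while (taken < n_windows) {
    progressed <- FALSE
    for (trial in names(masks)) {
      if (taken >= n_windows) break
      s <- earliest_free_window(masks[[trial]], window_len, chosen[[trial]])
      if (!is.na(s)) {
        add(trial, s)
        progressed <- TRUE
      }
    }
    if (!progressed) break
  }
  if (taken < n_windows) {
    abort(sprintf("only %d of the required %d windows of %d acceptable frames found",
                  taken, n_windows, window_len),
          class = "caninesway_exclusion_error", windows_found = taken)
  }
  tibble::tibble(trial_id = sel_trial, start_frame = as.integer(sel_start),
                 window_idx = seq_len(taken))
}

#' Extract the COP segment of one analysis window
#'
#' @param series COP tibble (as from [extract_cop_series()] /
#'   [lowpass_filter()]) restricted to one trial, ordered by `frame`.
#' @param start_frame 0-based first frame of the window.
#' @param window_len Window length in frames.
#' @return The `window_len`-row segment, sampling rate preserved.
#' @export
apply_window <- function(series, start_frame, window_len = 70) {
  n <- nrow(series)
  if (start_frame < 0 || start_frame + window_len > n) {
    abort(sprintf("window [%d, %d) out of bounds for a %d-sample series",
                  start_frame, start_frame + window_len, n))
  }
  seg <- series[(start_frame + 1L):(start_frame + window_len), ]
  if (any(!seg$valid)) {
    abort("window contains invalid COP samples", class = "caninesway_validation_error")
  }
  seg
}
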