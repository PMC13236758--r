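#' Build a stimulus schedule
#'
#' A schedule is a timed on/off timeline for a fixed set of nodes, plus the
#' test windows over which peak A1 is read out and (optionally) the contrasts
#' defined on the tested objects.  All times are in integration steps (one
#' step = `dt_seconds`, 3 s by default); events are half-open intervals
#' `[start, end)` and a stimulus is on during steps `start .. end - 1`.
#'
#' @param nodes data frame with columns `id` (unique labels) and `role`
#'   (`"object"` or `"context"`); optional columns `p1`, `pd1`, `pd2` give
#'   per-node rate overrides.
#' @param events data frame with columns `stimulus`, `start`, `end` (steps).
#' @param test_windows data frame with columns `object`, `start`, `end`
#'   (grid points, inclusive); exactly one row per tested object.
#' @param contrasts optional data frame with columns `name`, `q`, `p`; `q`
#'   and `p` are tested-object labels (comma-separated sets are allowed and
#'   are averaged, e.g. `"Q,S"` for the displaced pair).
#' @param n_steps total schedule length in steps; defaults to the last event
#'   or test-window boundary.
#' @param label free-text identifier carried through to results tables.
#' @return An object of class `sop_schedule`.
#' @examples
#' sched <- sop_schedule(
#'   nodes = data.frame(id = c("x", "P"), role = c("context", "object")),
#'   events = data.frame(stimulus = c("x", "P"), start = 0, end = 100),
#'   test_windows = data.frame(object = "P", start = 0, end = 100))
#' sched
#' @export
sop_schedule <- function(nodes, events, test_windows,
                         contrasts = NULL, n_steps = NULL, label = "") {
  nodes <- as.data.frame(nodes, stringsAsFactors = FALSE)
  events <- as.data.frame(events, stringsAsFactors = FALSE)
  test_windows <- as.data.frame(test_windows, stringsAsFactors = FALSE)
  if (anyDuplicated(nodes$id)) stop("node ids must be unique")
  if (!all(nodes$role %in% c("object", "context")))
    stop("node roles must be 'object' or 'context'")
  bad <- setdiff(events$stimulus, nodes$id)
  if (length(bad)) stop("events reference unknown stimuli: ",
                        paste(bad, collapse = ", "))
  if (any(events$start < 0) || any(events$start >= events$end))
    stop("every event must satisfy 0 <= start < end")
  if (anyDuplicated(test_windows$object))
    stop("each tested object must have exactly one test window")
  bad <- setdiff(test_windows$object, nodes$id[nodes$role == "object"])
  if (length(bad)) stop("test windows reference non-object nodes: ",
                        paste(bad, collapse = ", "))
  if (any(test_windows$start > test_windows$end)) stop("empty test window")
  ends <- c(events$end, test_windows$end)
  if (is.null(n_steps)) {
    if (length(ends) == 0L) stop("cannot infer n_steps from an empty schedule")
    n_steps <- max(ends)
  }
  if (length(ends) && max(ends) > n_steps)
    stop("events or test windows extend beyond n_steps")
  if (!is.null(contrasts)) {
    contrasts <- as.data.frame(contrasts, stringsAsFactors = FALSE)
    labels <- unique(unlist(strsplit(c(contrasts$q, contrasts$p), ",")))
    bad <- setdiff(labels, test_windows$object)
    if (length(bad)) stop("contrast labels without a test window: ",
                          paste(bad, collapse = ", "))
  }
  structure(list(nodes = nodes, events = events, test_windows = test_windows,
                 contrasts = contrasts, n_steps = as.integer(n_steps),
                 label = label),
            class = "sop_schedule")
}

#' @export
print.sop_schedule <- function(x, ...) {
  cat(sprintf("SOP schedule%s: %d steps (%.1f min at 3 s/step)\n",
              if (nzchar(x$label)) paste0(" '", x$label, "'") else "",
              x$n_steps, x$n_steps * 3 / 60))
  cat(sprintf("  nodes: %d (%d objects, %d contexts); events: %d; tested: %s\n",
              nrow(x$nodes), sum(x$nodes$role == "object"),
              sum(x$nodes$role == "context"), nrow(x$events),
              paste(x$test_windows$object, collapse = ", ")))
  invisible(x)
}

#' Convert minutes to integration steps
#'
#' Boundaries are snapped to the step grid by rounding half up; snapping that
#' moves a boundary is recorded in the `"snapped"` attribute so that preset
#' constructors can log it once.
#'
#' @param minutes duration(s) in minutes.
#' @param dt_seconds seconds per step.
#' @return Integer step count(s), with attribute `snapped` (logical vector).
#' @export
min_to_steps <- function(minutes, dt_seconds = 3) {
  exact <- minutes * 60 / dt_seconds
  steps <- as.integer(floor(exact + 0.5))
  if (any(abs(exact - steps) > 0.5 + 1e-9))
    stop("boundary snapping would move an event by more than half a step")
  structure(steps, snapped = abs(exact - steps) > 1e-9)
}

# 0/1 activity matrix (n_steps x n_nodes) from an event table.
activity_matrix <- function(events, n_steps, node_ids) {
  act <- matrix(0L, nrow = n_steps, ncol = length(node_ids),
                dimnames = list(NULL, node_ids))
  for (k in seq_len(nrow(events))) {
    j <- match(events$stimulus[k], node_ids)
    s <- events$start[k]; e <- min(events$end[k], n_steps)
    if (e > s) act[(s + 1):e, j] <- 1L
  }
  act
}

#' Export a schedule as a tidy event table
#'
#' @param x an `sop_schedule`.
#' @param row.names,optional,... passed through for S3 compatibility.
#' @param dt_seconds seconds per step used for the wall-clock columns.
#' @return Data frame with columns `stimulus`, `start_step`, `end_step`,
#'   `start_s`, `end_s`.
#' @export
as.data.frame.sop_schedule <- function(x, row.names = NULL, optional = FALSE,
                                       dt_seconds = 3, ...) {
  data.frame(stimulus = x$events$stimulus,
             start_step = x$events$start, end_step = x$events$end,
             start_s = x$events$start * dt_seconds,
             end_s = x$events$end * dt_seconds)
}
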