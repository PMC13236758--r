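#' Peak A1 of an object over its test window
#'
#' The behavioural proxy for exploration: the maximum of the object's A1
#' series over the grid points of the window (no sub-step interpolation; the
#' step size is the temporal resolution of the model).
#'
#' @param trajectory an [sop_simulate()] result with recorded states.
#' @param object object label.
#' @param window optional `c(start, end)` grid-point window (defaults to the
#'   schedule's test window for the object).
#' @return Peak A1, a value in \code{[0, 1]}.
#' @export
peak_a1 <- function(trajectory, object, window = NULL) {
  stopifnot(inherits(trajectory, "sop_trajectory"))
  if (is.null(window)) {
    tw <- trajectory$schedule$test_windows
    row <- tw[tw$object == object, , drop = FALSE]
    if (nrow(row) == 0L) stop("no test window for object '", object, "'")
    window <- c(row$start, row$end)
  }
  if (window[2] < window[1]) stop("empty window")
  if (window[2] > trajectory$schedule$n_steps)
    stop("window extends beyond the trajectory")
  if (is.null(trajectory$node_states))
    stop("trajectory was simulated with record = FALSE")
  i <- match(object, trajectory$schedule$nodes$id)
  if (is.na(i)) stop("unknown object '", object, "'")
  max(trajectory$node_states[(window[1]:window[2]) + 1L, i, 2])
}

#' Contrast two test readouts
#'
#' Computes the predicted preference between the novel/remote/displaced
#' object Q and the familiar/recent/in-place object P as the difference and
#' ratio of their peak A1 values.  `q` and `p` may be comma-separated label
#' sets, which are averaged (e.g. the displaced pair `"Q,S"`).
#'
#' @param readouts named numeric vector of peak A1 values (or a data frame
#'   with columns `object`, `mean_peak_a1`).
#' @param q,p labels of the contrasted objects.
#' @param name contrast name carried into the record.
#' @return One-row data frame: `name`, `q`, `p`, `delta_a1`
#'   (`peak(Q) - peak(P)`), `ratio` (`peak(Q)/peak(P)`, `NA` when
#'   `peak(P) = 0`).
#' @examples
#' contrast(c(novel = 0.62, familiar = 0.35), "novel", "familiar")
#' @export
contrast <- function(readouts, q, p, name = paste0(q, "_vs_", p)) {
  if (is.data.frame(readouts))
    readouts <- setNames(readouts$mean_peak_a1, readouts$object)
  take <- function(labels) {
    ids <- strsplit(labels, ",")[[1]]
    miss <- setdiff(ids, names(readouts))
    if (length(miss)) stop("missing readout for: ", paste(miss, collapse = ", "))
    mean(readouts[ids])
  }
  aq <- take(q); ap <- take(p)
  data.frame(name = name, q = q, p = p, delta_a1 = aq - ap,
             ratio = if (ap > 0) aq / ap else NA_real_,
             stringsAsFactors = FALSE)
}

#' Run a task preset and summarise its readouts
#'
#' Simulates every counterbalanced schedule variant of the preset (for
#' conceptual presets: the per-condition runs), reads out peak A1 at test
#' for each tested object, and averages across variants.  Variability across
#' permutations reflects only order effects and is reported as the max-min
#' spread.
#'
#' @param preset an `sop_preset` from [conceptual_preset()] or
#'   [empirical_preset()].
#' @param params an [sop_params()] set.
#' @param engine integration engine, `"cpp"` or `"r"`.
#' @return List of class `sop_result` with `objects` (data frame: `object`,
#'   `mean_peak_a1`, `spread`, `n_runs`) and `contrasts` (data frame:
#'   `name`, `q`, `p`, `delta_a1`, `ratio`).
#' @examples
#' res <- run_preset(conceptual_preset("sor"))
#' res$contrasts
#' @export
run_preset <- function(preset, params = sop_params(),
                       engine = c("cpp", "r")) {
  engine <- match.arg(engine)
  stopifnot(inherits(preset, "sop_preset"))
  peak_rows <- cb_peaks(preset, params, engine = engine)
  all_labels <- unique(unlist(lapply(peak_rows, names)))
  mat <- do.call(rbind, lapply(peak_rows, function(pk)
    setNames(pk[all_labels], all_labels)))
  colnames(mat) <- all_labels
  means <- colMeans(mat, na.rm = TRUE)
  spread <- apply(mat, 2, function(v) diff(range(v, na.rm = TRUE)))
  objects <- data.frame(object = all_labels,
                        mean_peak_a1 = unname(means),
                        spread = unname(spread),
                        n_runs = colSums(!is.na(mat)),
                        row.names = NULL, stringsAsFactors = FALSE)
  cdef <- if (preset$kind == "conceptual") preset$contrasts else
    preset$contrasts
  contrasts <- do.call(rbind, lapply(seq_len(nrow(cdef)), function(k)
    contrast(means, cdef$q[k], cdef$p[k], name = cdef$name[k])))
  structure(list(preset = preset$name, objects = objects,
                 contrasts = contrasts, n_variants = nrow(mat)),
            class = "sop_result")
}

#' @export
print.sop_result <- function(x, ...) {
  cat(sprintf("Preset '%s' (%d counterbalanced run%s)\n", x$preset,
              x$n_variants, if (x$n_variants == 1) "" else "s"))
  cat("  mean peak A1 at test:\n")
  for (k in seq_len(nrow(x$objects)))
    cat(sprintf("    %-18s %.4f  (spread %.2g)\n", x$objects$object[k],
                x$objects$mean_peak_a1[k], x$objects$spread[k]))
  cat("  contrasts (delta = Q - P):\n")
  for (k in seq_len(nrow(x$contrasts)))
    cat(sprintf("    %-24s delta %+0.4f  ratio %s\n", x$contrasts$name[k],
                x$contrasts$delta_a1[k],
                ifelse(is.na(x$contrasts$ratio[k]), "NA",
                       sprintf("%.3f", x$contrasts$ratio[k]))))
  invisible(x)
}
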