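#' Canonical SOP parameter set
#'
#' Bundles the transition-rate and learning-rate parameters shared by all
#' simulations.  Rates are expressed per internal time unit tau, where one
#' tau corresponds to one integration step of `dt_seconds` wall-clock seconds
#' (3 s by default), so e.g. `pd2 = 0.02` means that about 2\% of A2
#' occupancy decays back to I per 3-s step.
#'
#' Defaults are the canonical values used throughout: objects are more
#' salient than contexts (`p1_object > p1_context`), secondary activity
#' outlasts primary activity (`pd2 < pd1`), and excitatory learning dominates
#' inhibitory learning at a 10:1 ratio (`l_plus = 10 * l_minus`).
#'
#' @param p1_object activation rate I -> A1 for object nodes while presented.
#' @param p1_context activation rate for context nodes while presented.
#' @param pd1 decay rate A1 -> A2 (all nodes).
#' @param pd2 decay rate A2 -> I (all nodes).
#' @param l_plus excitatory learning rate L+ (context A1 with object A1).
#' @param l_minus inhibitory learning rate L- (context A1 with object A2).
#' @param dt_seconds wall-clock seconds per integration step.
#' @return An object of class `sop_params`.
#' @examples
#' sop_params()
#' sop_params(l_plus = 0, l_minus = 0)  # learning switched off
#' @export
sop_params <- function(p1_object = 0.75, p1_context = 0.25,
                       pd1 = 0.1, pd2 = 0.02,
                       l_plus = 0.25, l_minus = 0.025,
                       dt_seconds = 3) {
  p <- list(p1_object = p1_object, p1_context = p1_context,
            pd1 = pd1, pd2 = pd2, l_plus = l_plus, l_minus = l_minus,
            dt_seconds = dt_seconds)
  validate_sop_params(p)
  structure(p, class = "sop_params")
}

validate_sop_params <- function(p) {
  for (nm in c("p1_object", "p1_context", "pd1", "pd2")) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 1)
      stop(sprintf("`%s` must be a single value in [0, 1], got %s",
                   nm, format(v)), call. = FALSE)
  }
  for (nm in c("l_plus", "l_minus")) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0)
      stop(sprintf("`%s` must be a single nonnegative value", nm), call. = FALSE)
  }
  if (!is.numeric(p$dt_seconds) || p$dt_seconds <= 0)
    stop("`dt_seconds` must be positive", call. = FALSE)
  invisible(p)
}

#' @export
print.sop_params <- function(x, ...) {
  cat("SOP parameters (rates per ", x$dt_seconds, "-s step)\n", sep = "")
  cat(sprintf("  p1: object %.3g, context %.3g\n", x$p1_object, x$p1_context))
  cat(sprintf("  decay: pd1 %.3g, pd2 %.3g\n", x$pd1, x$pd2))
  cat(sprintf("  learning: L+ %.3g, L- %.3g\n", x$l_plus, x$l_minus))
  invisible(x)
}

# Per-node rate vectors for a schedule's node table.  Node-level overrides
# (columns p1/pd1/pd2 in the node table) win over the role defaults.
node_rates <- function(nodes, params) {
  p1 <- ifelse(nodes$role == "object", params$p1_object, params$p1_context)
  pd1 <- rep(params$pd1, nrow(nodes))
  pd2 <- rep(params$pd2, nrow(nodes))
  for (nm in c("p1", "pd1", "pd2")) {
    if (nm %in% names(nodes)) {
      ov <- nodes[[nm]]
      keep <- !is.na(ov)
      if (any(ov[keep] < 0 | ov[keep] > 1))
        stop(sprintf("node-level `%s` values must lie in [0, 1]", nm))
      if (nm == "p1") p1[keep] <- ov[keep]
      if (nm == "pd1") pd1[keep] <- ov[keep]
      if (nm == "pd2") pd2[keep] <- ov[keep]
    }
  }
  list(p1 = p1, pd1 = pd1, pd2 = pd2)
}
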