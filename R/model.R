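#' Effective activation rate of a stimulus
#'
#' The I -> A1 transition rate p1 is driven by stimulus input: it equals the
#' node's salience while the stimulus is scheduled on and 0 otherwise.
#'
#' @param p1 the node's activation rate (salience), in \code{[0, 1]}.
#' @param active logical; is the stimulus currently presented?
#' @return The effective rate (vectorised over both arguments).
#' @examples
#' effective_p1(0.75, TRUE)
#' effective_p1(0.75, FALSE)
#' @export
effective_p1 <- function(p1, active) {
  stopifnot(all(p1 >= 0 & p1 <= 1))
  p1 * as.numeric(active)
}

#' Net associative strength of a context-to-object link
#'
#' Excitatory and inhibitory components accrue simultaneously on every link;
#' the net association is their difference and may be negative.
#'
#' @param v_plus excitatory accumulator V+ (nonnegative).
#' @param v_minus inhibitory accumulator V- (nonnegative).
#' @return `v_plus - v_minus`, vectorised.
#' @export
net_association <- function(v_plus, v_minus) {
  stopifnot(all(v_plus >= 0), all(v_minus >= 0))
  v_plus - v_minus
}

#' Associative promotion probability p2 for an object
#'
#' Aggregates the associative input an object receives from all linked
#' contexts, weighting each link's net association by the current primary
#' activity of its source context, and truncates the sum to \code{[0, 1]}.
#' A net-inhibitory context cannot make p2 negative: it only offsets
#' concurrent excitatory drive, and pure inhibition yields 0.
#'
#' @param target object label whose p2 is requested.
#' @param links data frame with columns `source`, `target`, `v_plus`,
#'   `v_minus` (one row per potential context-to-object link).
#' @param context_a1 named numeric vector of current context A1 values; a
#'   source context missing from this vector is treated as inactive (A1 = 0).
#' @return A single probability in \code{[0, 1]}.
#' @examples
#' links <- data.frame(source = c("x", "y"), target = "P",
#'                     v_plus = c(0.4, 0), v_minus = c(0, 0.3))
#' compute_p2("P", links, c(x = 0.5, y = 0.2))  # 0.5*0.4 + 0.2*(-0.3) = 0.14
#' @export
compute_p2 <- function(target, links, context_a1) {
  stopifnot(all(context_a1 >= 0 & context_a1 <= 1))
  rows <- links[links$target == target, , drop = FALSE]
  if (nrow(rows) == 0L) return(0)
  a1 <- context_a1[rows$source]
  a1[is.na(a1)] <- 0
  drive <- sum(a1 * (rows$v_plus - rows$v_minus))
  min(1, max(0, drive))
}

#' Rates of change of the node activity states
#'
#' Computes (dI, dA1, dA2) for every node given the current states, the
#' schedule's activity flags, and the associative input.  Context nodes never
#' receive associative input (their p2 is identically 0); for object nodes
#' the p2 inflow is routed from I directly into A2.  The three components sum
#' to zero exactly for every node, so total occupancy is conserved.
#'
#' @param states data frame with columns `id`, `I`, `A1`, `A2` (one row per
#'   node).
#' @param nodes data frame with columns `id`, `role` and per-node rates
#'   `p1`, `pd1`, `pd2`.
#' @param links data frame of links (`source`, `target`, `v_plus`,
#'   `v_minus`); may have zero rows.
#' @param active character vector of node ids currently scheduled on.
#' @return Data frame with columns `id`, `dI`, `dA1`, `dA2`.
#' @export
state_derivatives <- function(states, nodes, links, active) {
  stopifnot(identical(states$id, nodes$id))
  ctx_a1 <- setNames(states$A1, states$id)[nodes$id[nodes$role == "context"]]
  n <- nrow(states)
  p2 <- numeric(n)
  if (nrow(links) > 0L) {
    for (i in seq_len(n)) {
      if (nodes$role[i] == "object")
        p2[i] <- compute_p2(nodes$id[i], links, ctx_a1)
    }
  }
  p1 <- effective_p1(nodes$p1, nodes$id %in% active)
  dI  <- nodes$pd2 * states$A2 - (p1 + p2) * states$I
  dA1 <- p1 * states$I - nodes$pd1 * states$A1
  dA2 <- nodes$pd1 * states$A1 + p2 * states$I - nodes$pd2 * states$A2
  data.frame(id = states$id, dI = dI, dA1 = dA1, dA2 = dA2)
}

#' Rates of change of the associative accumulators
#'
#' Excitatory growth pairs context A1 with object A1; inhibitory growth pairs
#' context A1 with object A2.  Both derivatives are products of nonnegative
#' quantities, so V+ and V- are nondecreasing along any trajectory.
#'
#' @param links data frame of links (`source`, `target`).
#' @param states data frame with columns `id`, `A1`, `A2`.
#' @param l_plus,l_minus learning rates.
#' @return Data frame with columns `source`, `target`, `dVp`, `dVm`.
#' @export
learning_derivatives <- function(links, states, l_plus, l_minus) {
  a1 <- setNames(states$A1, states$id)
  a2 <- setNames(states$A2, states$id)
  data.frame(source = links$source, target = links$target,
             dVp = l_plus * a1[links$source] * a1[links$target],
             dVm = l_minus * a1[links$source] * a2[links$target],
             row.names = NULL)
}

# All potential context -> object links for a node table (lazily instantiated
# associations: every pair starts at V+ = V- = 0).
potential_links <- function(nodes) {
  ctx <- nodes$id[nodes$role == "context"]
  obj <- nodes$id[nodes$role == "object"]
  if (length(ctx) == 0L || length(obj) == 0L)
    return(data.frame(source = character(), target = character(),
                      stringsAsFactors = FALSE))
  expand.grid(source = ctx, target = obj, KEEP.OUT.ATTRS = FALSE,
              stringsAsFactors = FALSE)
}
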