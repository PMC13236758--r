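#' One classic fourth-order Runge-Kutta step
#'
#' Applies the classic RK4 update (stage weights 1, 2, 2, 1 over 6) to an
#' arbitrary state vector.  Used internally with step size 1 (one internal
#' time unit); exported mainly so the update rule itself can be validated
#' against closed-form solutions.
#'
#' @param y numeric state vector.
#' @param f derivative function, `f(y)` returning a vector like `y`.
#' @param h step size.
#' @return The state after one step.
#' @examples
#' rk4_step(1, function(y) -y, 0.1)  # ~ exp(-0.1)
#' @export
rk4_step <- function(y, f, h) {
  k1 <- f(y)
  k2 <- f(y + h / 2 * k1)
  k3 <- f(y + h / 2 * k2)
  k4 <- f(y + h * k3)
  out <- y + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  if (any(!is.finite(out)))
    stop("non-finite state component after RK4 step (indices: ",
         paste(which(!is.finite(out)), collapse = ", "), ")")
  out
}

#' Simulate a schedule
#'
#' Advances all node states and link accumulators through a schedule from
#' rest (I = 1, A1 = A2 = 0, V+ = V- = 0) using fixed-step RK4 with the
#' stimulus on/off flags held constant within each step.  The simulation is
#' deterministic: identical inputs give bit-identical output.
#'
#' @param schedule an [sop_schedule()].
#' @param params an [sop_params()] set.
#' @param engine `"cpp"` (compiled, default) or `"r"` (plain-R reference
#'   implementation of the same arithmetic, used for cross-validation).
#' @param record keep the full state time series (`TRUE`) or only the test
#'   readouts (`FALSE`, much lighter for large counterbalance sweeps).
#' @return An object of class `sop_trajectory` with elements `peaks` (named
#'   peak A1 per tested object), `node_states` (`(n_steps+1) x nodes x 3`
#'   array, if recorded), `link_states` (`(n_steps+1) x links x 2` array),
#'   `links`, `n_clamped` (count of conservation repairs; 0 in normal use),
#'   and the inputs.
#' @examples
#' sched <- sop_schedule(
#'   nodes = data.frame(id = c("x", "P"), role = c("context", "object")),
#'   events = data.frame(stimulus = c("x", "P"), start = 0, end = 100),
#'   test_windows = data.frame(object = "P", start = 0, end = 100))
#' traj <- sop_simulate(sched, sop_params())
#' traj$peaks
#' @export
sop_simulate <- function(schedule, params = sop_params(),
                         engine = c("cpp", "r"), record = TRUE) {
  engine <- match.arg(engine)
  stopifnot(inherits(schedule, "sop_schedule"))
  validate_sop_params(params)
  nodes <- schedule$nodes
  rates <- node_rates(nodes, params)
  links <- potential_links(nodes)
  act <- activity_matrix(schedule$events, schedule$n_steps, nodes$id)
  tw <- schedule$test_windows
  tobj <- match(tw$object, nodes$id) - 1L

  if (engine == "cpp") {
    res <- cpp_simulate(act, rates$p1, rates$pd1, rates$pd2,
                        as.integer(nodes$role == "object"),
                        as.matrix(cbind(match(links$source, nodes$id) - 1L,
                                        match(links$target, nodes$id) - 1L)),
                        params$l_plus, params$l_minus,
                        tobj, as.integer(tw$start), as.integer(tw$end),
                        record)
  } else {
    res <- r_simulate(act, rates, nodes, links, params, tobj, tw, record)
  }
  if (res$n_clamped > 0)
    warning(sprintf("conservation drift exceeded 1e-9 on %d step-node pairs; states were renormalized",
                    as.integer(res$n_clamped)))

  out <- list(peaks = setNames(res$peaks, tw$object),
              schedule = schedule, params = params,
              links = links, n_clamped = res$n_clamped, engine = engine)
  if (record) {
    nt <- res$node_traj
    dim(nt) <- c(schedule$n_steps + 1L, nrow(nodes), 3L)
    dimnames(nt) <- list(NULL, nodes$id, c("I", "A1", "A2"))
    out$node_states <- nt
    if (nrow(links) > 0L) {
      lt <- res$link_traj
      dim(lt) <- c(schedule$n_steps + 1L, max(nrow(links), 1L), 2L)
      lt <- lt[, seq_len(nrow(links)), , drop = FALSE]
      dimnames(lt) <- list(NULL, paste(links$source, links$target, sep = "-"),
                           c("v_plus", "v_minus"))
      out$link_states <- lt
    }
  }
  structure(out, class = "sop_trajectory")
}

# Reference R implementation of the same integration (identical arithmetic
# order to the compiled engine).
r_simulate <- function(act, rates, nodes, links, params, tobj, tw, record) {
  n_nodes <- nrow(nodes); n_links <- nrow(links)
  n_steps <- nrow(act)
  is_obj <- nodes$role == "object"
  lsrc <- match(links$source, nodes$id)
  ltgt <- match(links$target, nodes$id)

  deriv <- function(st, on) {
    p2 <- numeric(n_nodes)
    if (n_links > 0L) {
      drive <- st$Vp - st$Vm
      for (l in seq_len(n_links))
        p2[ltgt[l]] <- p2[ltgt[l]] + st$A1[lsrc[l]] * drive[l]
      p2 <- ifelse(is_obj, pmin(1, pmax(0, p2)), 0)
    }
    p1 <- rates$p1 * on
    list(dI = rates$pd2 * st$A2 - (p1 + p2) * st$I,
         dA1 = p1 * st$I - rates$pd1 * st$A1,
         dA2 = rates$pd1 * st$A1 + p2 * st$I - rates$pd2 * st$A2,
         dVp = if (n_links) params$l_plus * st$A1[lsrc] * st$A1[ltgt] else numeric(0),
         dVm = if (n_links) params$l_minus * st$A1[lsrc] * st$A2[ltgt] else numeric(0))
  }
  plus <- function(st, d, h)
    list(I = st$I + h * d$dI, A1 = st$A1 + h * d$dA1, A2 = st$A2 + h * d$dA2,
         Vp = st$Vp + h * d$dVp, Vm = st$Vm + h * d$dVm)

  st <- list(I = rep(1, n_nodes), A1 = rep(0, n_nodes), A2 = rep(0, n_nodes),
             Vp = rep(0, n_links), Vm = rep(0, n_links))
  node_traj <- if (record) array(0, c(n_steps + 1L, n_nodes, 3L)) else NULL
  link_traj <- if (record) array(0, c(n_steps + 1L, max(n_links, 1L), 2L)) else NULL
  peaks <- rep(0, length(tobj))
  n_clamped <- 0L
  store <- function(g) {
    if (record) {
      node_traj[g, , 1] <<- st$I; node_traj[g, , 2] <<- st$A1
      node_traj[g, , 3] <<- st$A2
      if (n_links > 0L) {
        link_traj[g, , 1] <<- st$Vp; link_traj[g, , 2] <<- st$Vm
      }
    }
    for (j in seq_along(tobj)) {
      if ((g - 1L) >= tw$start[j] && (g - 1L) <= tw$end[j])
        peaks[j] <<- max(peaks[j], st$A1[tobj[j] + 1L])
    }
  }
  store(1L)
  for (s in seq_len(n_steps)) {
    on <- as.numeric(act[s, ])
    k1 <- deriv(st, on)
    k2 <- deriv(plus(st, k1, 0.5), on)
    k3 <- deriv(plus(st, k2, 0.5), on)
    k4 <- deriv(plus(st, k3, 1), on)
    st <- list(
      I  = st$I  + (k1$dI  + 2 * k2$dI  + 2 * k3$dI  + k4$dI)  / 6,
      A1 = st$A1 + (k1$dA1 + 2 * k2$dA1 + 2 * k3$dA1 + k4$dA1) / 6,
      A2 = st$A2 + (k1$dA2 + 2 * k2$dA2 + 2 * k3$dA2 + k4$dA2) / 6,
      Vp = st$Vp + (k1$dVp + 2 * k2$dVp + 2 * k3$dVp + k4$dVp) / 6,
      Vm = st$Vm + (k1$dVm + 2 * k2$dVm + 2 * k3$dVm + k4$dVm) / 6)
    if (any(!is.finite(unlist(st))))
      stop("non-finite state at step ", s)
    drift <- abs(st$I + st$A1 + st$A2 - 1)
    bad <- drift > 1e-9 | st$I < -1e-9 | st$A1 < -1e-9 | st$A2 < -1e-9 |
      st$I > 1 + 1e-9 | st$A1 > 1 + 1e-9 | st$A2 > 1 + 1e-9
    if (any(bad)) {
      n_clamped <- n_clamped + sum(bad)
      for (i in which(bad)) {
        v <- pmin(1, pmax(0, c(st$I[i], st$A1[i], st$A2[i])))
        v <- v / sum(v)
        st$I[i] <- v[1]; st$A1[i] <- v[2]; st$A2[i] <- v[3]
      }
    }
    store(s + 1L)
  }
  list(peaks = peaks, node_traj = node_traj, link_traj = link_traj,
       n_clamped = n_clamped,
       final_I = st$I, final_A1 = st$A1, final_A2 = st$A2,
       final_Vp = st$Vp, final_Vm = st$Vm)
}

#' @export
print.sop_trajectory <- function(x, ...) {
  cat(sprintf("SOP trajectory: %d steps, %d nodes, %d links (engine: %s)\n",
              x$schedule$n_steps, nrow(x$schedule$nodes), nrow(x$links),
              x$engine))
  cat("  peak A1 at test:\n")
  for (nm in names(x$peaks))
    cat(sprintf("    %s: %.4f\n", nm, x$peaks[[nm]]))
  invisible(x)
}

#' Tidy export of a trajectory
#'
#' @param x an `sop_trajectory` (with recorded states).
#' @param row.names,optional,... S3 compatibility.
#' @param what `"nodes"` for the state series or `"links"` for the
#'   accumulator series.
#' @return For nodes: columns `step`, `seconds`, `node`, `I`, `A1`, `A2`.
#'   For links: `step`, `seconds`, `source`, `target`, `v_plus`, `v_minus`,
#'   `v_net`.
#' @export
as.data.frame.sop_trajectory <- function(x, row.names = NULL, optional = FALSE,
                                         what = c("nodes", "links"), ...) {
  what <- match.arg(what)
  if (is.null(x$node_states))
    stop("trajectory was simulated with record = FALSE")
  g <- seq_len(x$schedule$n_steps + 1L) - 1L
  dt <- x$params$dt_seconds
  if (what == "nodes") {
    ids <- x$schedule$nodes$id
    do.call(rbind, lapply(seq_along(ids), function(i)
      data.frame(step = g, seconds = g * dt, node = ids[i],
                 I = x$node_states[, i, 1], A1 = x$node_states[, i, 2],
                 A2 = x$node_states[, i, 3])))
  } else {
    if (nrow(x$links) == 0L)
      return(data.frame(step = integer(), seconds = numeric(),
                        source = character(), target = character(),
                        v_plus = numeric(), v_minus = numeric(),
                        v_net = numeric()))
    do.call(rbind, lapply(seq_len(nrow(x$links)), function(l)
      data.frame(step = g, seconds = g * dt,
                 source = x$links$source[l], target = x$links$target[l],
                 v_plus = x$link_states[, l, 1],
                 v_minus = x$link_states[, l, 2],
                 v_net = x$link_states[, l, 1] - x$link_states[, l, 2])))
  }
}

#' Exact solution for an isolated node
#'
#' For a node with no incoming associative input (p2 = 0 throughout) the
#' three-state system is linear and time-invariant within each constant
#' on/off segment, so the exact solution is a matrix exponential chained
#' across segments.  Serves as the independent oracle against which the RK4
#' integrator is validated.
#'
#' @param p1,pd1,pd2 the node's rates (per step).
#' @param segments data frame with columns `active` (logical) and `duration`
#'   (steps; need not be integer).
#' @param init initial state `(I, A1, A2)`.
#' @return Matrix of states at segment boundaries, first row `init`, one
#'   further row per segment.
#' @examples
#' seg <- data.frame(active = c(TRUE, FALSE), duration = c(50, 100))
#' closed_form_isolated_node(0.75, 0.1, 0.02, seg)
#' @export
closed_form_isolated_node <- function(p1, pd1, pd2, segments,
                                      init = c(I = 1, A1 = 0, A2 = 0)) {
  stopifnot(nrow(segments) >= 1, all(segments$duration >= 0))
  out <- matrix(NA_real_, nrow(segments) + 1L, 3,
                dimnames = list(NULL, c("I", "A1", "A2")))
  state <- as.numeric(init)
  out[1, ] <- state
  for (k in seq_len(nrow(segments))) {
    p1k <- if (segments$active[k]) p1 else 0
    M <- matrix(c(-p1k,    0,   pd2,
                   p1k, -pd1,     0,
                     0,  pd1,  -pd2), 3, 3, byrow = TRUE)
    E <- as.matrix(Matrix::expm(M * segments$duration[k]))
    state <- as.numeric(E %*% state)
    out[k + 1L, ] <- state
  }
  out
}
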