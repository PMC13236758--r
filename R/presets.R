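# Task preset construction: conceptual single-timeline conditions and the
# empirical study schedules (multi-context tiling, half-window object onsets,
# habituation blocks, counterbalanced context orders).

new_preset <- function(name, kind, schedules = NULL, contrasts = NULL,
                       build = NULL, build_light = NULL, perm_factors = NULL,
                       nodes = NULL) {
  structure(list(name = name, kind = kind, schedules = schedules,
                 contrasts = contrasts, build = build,
                 build_light = build_light,
                 perm_factors = perm_factors, nodes = nodes),
            class = "sop_preset")
}

#' @export
print.sop_preset <- function(x, ...) {
  cat(sprintf("SOP %s preset '%s'\n", x$kind, x$name))
  if (x$kind == "conceptual")
    cat("  condition runs:", paste(names(x$schedules), collapse = ", "), "\n")
  else
    cat(sprintf("  counterbalanced variants: %d\n", counterbalance_count(x)))
  cat("  contrasts:", paste(x$contrasts$name, collapse = ", "), "\n")
  invisible(x)
}

# ---------------------------------------------------------------------------
# Conceptual presets (single timeline: sample, ISI, sample, RI, test)
# ---------------------------------------------------------------------------

conceptual_conditions <- c("novel", "recent_in_place", "remote_in_place",
                           "recent_displaced")

# One condition = one independent run with two shared context nodes: the
# sampling/test context x and the alternative context y (used only as the
# changed test context of the displaced condition).  The context is
# coextensive with its phase; the object occupies the final half of the
# phase (the same location-first-then-object convention as the empirical
# schedules), so context identity is the *only* difference between the
# in-place and displaced conditions.
conceptual_condition_schedule <- function(condition, isi_steps, ri_steps,
                                          sample_steps, test_steps) {
  condition <- match.arg(condition, conceptual_conditions)
  s1 <- c(0, sample_steps)
  s2 <- s1[2] + isi_steps + c(0, sample_steps)
  te <- s2[2] + ri_steps + c(0, test_steps)
  displaced <- condition == "recent_displaced"
  final_half <- function(iv) c(iv[2] - as.integer(floor(diff(iv) / 2 + 0.5)),
                               iv[2])

  ev <- data.frame(stimulus = "ctx_x", start = s1[1], end = s1[2])
  ev <- rbind(ev, data.frame(stimulus = "ctx_x", start = s2[1], end = s2[2]))
  ev <- rbind(ev, data.frame(stimulus = if (displaced) "ctx_y" else "ctx_x",
                             start = te[1], end = te[2]))
  obj_on <- switch(condition,
    novel = list(final_half(te)),
    recent_in_place = list(final_half(s2), final_half(te)),
    remote_in_place = list(final_half(s1), final_half(te)),
    recent_displaced = list(final_half(s2), final_half(te)))
  for (iv in obj_on)
    ev <- rbind(ev, data.frame(stimulus = condition, start = iv[1], end = iv[2]))
  w <- final_half(te)

  sop_schedule(
    nodes = data.frame(id = c("ctx_x", "ctx_y", condition),
                       role = c("context", "context", "object")),
    events = ev,
    test_windows = data.frame(object = condition, start = w[1], end = w[2]),
    n_steps = te[2], label = paste0("conceptual_", condition))
}

#' Conceptual task preset
#'
#' Builds the simplified single-timeline demonstration of a recognition
#' task.  All conditions share the schedule sample, ISI, sample, RI, test
#' (5-min samples and test, 2-min intervals by default) and are simulated as
#' independent runs over two shared context nodes; the task contrast then
#' compares peak A1 at test across condition runs:
#' \itemize{
#'   \item `sor`: novel vs. recent in-place (novelty preference),
#'   \item `rr`: remote in-place vs. recent in-place (recency),
#'   \item `oip`: recent displaced vs. recent in-place (displacement).
#' }
#'
#' @param task `"sor"`, `"rr"` or `"oip"`.
#' @param isi_minutes interstimulus interval between the two samples.
#' @param ri_minutes retention interval before the test.
#' @param sample_minutes,test_minutes phase durations.
#' @return An `sop_preset` whose schedules are the two condition runs.
#' @examples
#' run_preset(conceptual_preset("sor"))
#' @export
conceptual_preset <- function(task = c("sor", "rr", "oip"),
                              isi_minutes = 2, ri_minutes = 2,
                              sample_minutes = 5, test_minutes = 5) {
  task <- match.arg(task)
  stopifnot(isi_minutes >= 0, ri_minutes >= 0,
            sample_minutes > 0, test_minutes > 0)
  stp <- lapply(c(isi = isi_minutes, ri = ri_minutes,
                  sample = sample_minutes, test = test_minutes), min_to_steps)
  q <- switch(task, sor = "novel", rr = "remote_in_place",
              oip = "recent_displaced")
  p <- "recent_in_place"
  scheds <- lapply(c(q, p), conceptual_condition_schedule,
                   isi_steps = stp$isi, ri_steps = stp$ri,
                   sample_steps = stp$sample, test_steps = stp$test)
  names(scheds) <- c(q, p)
  contrasts <- data.frame(
    name = switch(task, sor = "novel_vs_familiar", rr = "remote_vs_recent",
                  oip = "displaced_vs_in_place"),
    q = q, p = p, stringsAsFactors = FALSE)
  new_preset(paste0("conceptual_", task), "conceptual",
             schedules = scheds, contrasts = contrasts)
}

# ---------------------------------------------------------------------------
# Empirical presets
# ---------------------------------------------------------------------------

# Contexts tile a phase in the given order, each for an equal share; each
# assigned object occupies the final `obj_frac` of its context's tile.
# `assign` maps objects to contexts (an object may sit in several tiles,
# e.g. two copies of P).  Off-grid object onsets are rounded half up.
tiled_phase <- function(start, total_steps, context_order, assign,
                        obj_frac = 0.5) {
  n <- length(context_order)
  stopifnot(total_steps %% n == 0)
  tile <- total_steps %/% n
  offset <- as.integer(floor(tile * (1 - obj_frac) + 0.5))
  t0 <- start + (seq_len(n) - 1L) * tile
  k <- match(assign$context, context_order)
  stim <- c(context_order, assign$object)
  ev_start <- c(t0, t0[k] + offset)
  ev_end <- c(t0 + tile, t0[k] + tile)
  list(stim = stim, start = ev_start, end = ev_end,
       win_obj = assign$object, win_start = t0[k] + offset,
       win_end = t0[k] + tile, phase_end = start + total_steps,
       snapped = abs(tile * (1 - obj_frac) - offset) > 1e-9)
}

# Accumulate light phase pieces into an event list without data frames.
cat_phase <- function(acc, ph) {
  list(stim = c(acc$stim, ph$stim), start = c(acc$start, ph$start),
       end = c(acc$end, ph$end),
       win_obj = c(acc$win_obj, ph$win_obj),
       win_start = c(acc$win_start, ph$win_start),
       win_end = c(acc$win_end, ph$win_end))
}

light_to_schedule <- function(light, nodes, contrasts, label) {
  keep <- !duplicated(light$win_obj)
  sop_schedule(nodes,
               events = data.frame(stimulus = light$stim,
                                   start = light$start, end = light$end),
               test_windows = data.frame(object = light$win_obj[keep],
                                         start = light$win_start[keep],
                                         end = light$win_end[keep]),
               contrasts = contrasts, n_steps = light$n_steps, label = label)
}

perms_of <- function(x) {
  if (length(x) == 1L) return(list(x))
  out <- list()
  for (i in seq_along(x))
    for (rest in perms_of(x[-i])) out[[length(out) + 1L]] <- c(x[i], rest)
  out
}

assign_df <- function(...) {
  v <- c(...)
  if (length(v) == 0L)
    return(data.frame(object = character(), context = character(),
                      stringsAsFactors = FALSE))
  data.frame(object = names(v), context = unname(v), stringsAsFactors = FALSE)
}

# Preset tables.  Each entry describes the phase structure; `build` receives
# one ordering per counterbalanced factor.
empirical_preset_specs <- function() {
  good_like <- function(study, task, test_minutes, default_isi, default_ri) {
    function(isi_minutes = default_isi, ri_minutes = default_ri,
             habituation_minutes = 20, sample_minutes = 5) {
      n_ctx <- if (task %in% c("oip", "rr_oip")) 4L else 2L
      ctx <- paste0("C", seq_len(n_ctx))
      objs <- if (n_ctx == 4L) c("P", "Q", "R", "S") else c("P", "Q")
      two_samples <- task %in% c("rr", "rr_oip")
      sample_assign <- switch(task,
        sor = list(assign_df(P = "C1", P = "C2")),
        rr = list(assign_df(Q = "C1", Q = "C2"),
                  assign_df(P = "C1", P = "C2")),
        oip = list(assign_df(P = "C1", Q = "C2", R = "C3", S = "C4")),
        rr_oip = list(assign_df(P = "C1", Q = "C2"),
                      assign_df(R = "C3", S = "C4")))
      test_assign <- switch(task,
        sor = assign_df(P = "C1", Q = "C2"),
        rr = assign_df(P = "C1", Q = "C2"),
        oip = assign_df(P = "C1", S = "C2", R = "C3", Q = "C4"),
        rr_oip = assign_df(P = "C1", S = "C2", R = "C3", Q = "C4"))
      contrasts <- switch(task,
        sor = data.frame(name = "novel_vs_familiar", q = "Q", p = "P"),
        rr = data.frame(name = "remote_vs_recent", q = "Q", p = "P"),
        oip = data.frame(name = "displaced_vs_in_place", q = "Q,S", p = "P,R"),
        rr_oip = data.frame(
          name = c("combined", "temporal", "spatial"),
          q = c("Q", "P", "S"), p = c("R", "R", "R")))
      perm_factors <- c(rep(list(perms_of(ctx)), 1L + two_samples),
                        list(perms_of(ctx)))
      nodes <- data.frame(id = c(ctx, objs),
                          role = rep(c("context", "object"),
                                     c(n_ctx, length(objs))))
      hab_steps <- min_to_steps(habituation_minutes)
      sample_steps <- min_to_steps(sample_minutes)
      isi_steps <- min_to_steps(isi_minutes)
      ri_steps <- min_to_steps(ri_minutes)
      test_steps <- min_to_steps(test_minutes)
      build_light <- function(orders) {
        acc <- list(); t <- 0L
        if (hab_steps > 0L) {
          ph <- tiled_phase(0L, hab_steps, ctx, assign_df(), obj_frac = 0)
          acc <- cat_phase(acc, ph); t <- ph$phase_end
        }
        k <- 1L
        for (s in seq_along(sample_assign)) {
          if (s > 1L) t <- t + isi_steps
          ph <- tiled_phase(t, sample_steps, orders[[k]], sample_assign[[s]])
          acc <- cat_phase(acc, ph); t <- ph$phase_end; k <- k + 1L
        }
        t <- t + ri_steps
        ph <- tiled_phase(t, test_steps, orders[[k]], test_assign)
        list(stim = c(acc$stim, ph$stim), start = c(acc$start, ph$start),
             end = c(acc$end, ph$end),
             win_obj = ph$win_obj, win_start = ph$win_start,
             win_end = ph$win_end, n_steps = ph$phase_end)
      }
      build <- function(orders)
        light_to_schedule(build_light(orders), nodes, contrasts,
                          paste0(study, "_", task))
      new_preset(paste0(study, "_", task), "empirical",
                 contrasts = contrasts, build = build,
                 build_light = build_light,
                 perm_factors = perm_factors, nodes = nodes)
    }
  }

  whitt <- function(isi_minutes = 0.5, ri_minutes = 15, n_samples = 8,
                    habituation_minutes = 0) {
    ctx <- c("C1", "C2")
    nodes <- data.frame(id = c(ctx, "P", "Q"),
                        role = c("context", "context", "object", "object"))
    contrasts <- data.frame(name = "novel_vs_familiar", q = "Q", p = "P")
    perm_factors <- rep(list(perms_of(ctx)), n_samples + 1L)
    sample_steps <- min_to_steps(0.5)     # 30-s sample: two 15-s tiles
    isi_steps <- min_to_steps(isi_minutes)
    ri_steps <- min_to_steps(ri_minutes)
    test_steps <- min_to_steps(2)         # two 1-min context periods
    hab_steps <- min_to_steps(habituation_minutes)
    build_light <- function(orders) {
      acc <- list(); t <- 0L
      if (hab_steps > 0L) {
        ph <- tiled_phase(0L, hab_steps, ctx, assign_df(), obj_frac = 0)
        acc <- cat_phase(acc, ph); t <- ph$phase_end
      }
      for (s in seq_len(n_samples)) {
        if (s > 1L) t <- t + isi_steps
        ph <- tiled_phase(t, sample_steps, orders[[s]],
                          assign_df(P = "C1", P = "C2"))
        acc <- cat_phase(acc, ph); t <- ph$phase_end
      }
      t <- t + ri_steps
      ph <- tiled_phase(t, test_steps, orders[[n_samples + 1L]],
                        assign_df(P = "C1", Q = "C2"))
      list(stim = c(acc$stim, ph$stim), start = c(acc$start, ph$start),
           end = c(acc$end, ph$end),
           win_obj = ph$win_obj, win_start = ph$win_start,
           win_end = ph$win_end, n_steps = ph$phase_end)
    }
    build <- function(orders)
      light_to_schedule(build_light(orders), nodes, contrasts, "whitt")
    new_preset("whitt", "empirical", contrasts = contrasts, build = build,
               build_light = build_light,
               perm_factors = perm_factors, nodes = nodes)
  }

  sanderson <- function(isi_minutes = 1, ri_minutes = 1, n_samples = 10,
                        visit_start_minutes = 0.5, visit_arm_minutes = 1,
                        test_minutes = 2) {
    # Y-maze: arms are object nodes, each coextensive with its own context
    # node; the START stem context opens every visit and the test.
    nodes <- data.frame(
      id = c("start", "arm_ctx1", "arm_ctx2", "fam", "nov"),
      role = c("context", "context", "context", "object", "object"))
    contrasts <- data.frame(name = "novel_vs_familiar", q = "nov", p = "fam")
    perm_factors <- list(list(c(1L, 2L), c(2L, 1L)))  # familiar arm assignment
    start_steps <- min_to_steps(visit_start_minutes)
    arm_steps <- min_to_steps(visit_arm_minutes)
    isi_steps <- min_to_steps(isi_minutes)
    ri_steps <- min_to_steps(ri_minutes)
    test_steps <- min_to_steps(test_minutes)
    build_light <- function(orders) {
      fam_ctx <- paste0("arm_ctx", orders[[1L]][1])
      nov_ctx <- paste0("arm_ctx", orders[[1L]][2])
      stim <- character(); start <- integer(); end <- integer()
      t <- 0L
      for (v in seq_len(n_samples)) {
        if (v > 1L) t <- t + isi_steps
        stim <- c(stim, "start", fam_ctx, "fam")
        start <- c(start, t, t + start_steps, t + start_steps)
        end <- c(end, t + start_steps, rep(t + start_steps + arm_steps, 2))
        t <- t + start_steps + arm_steps
      }
      t <- t + ri_steps
      stim <- c(stim, "start", fam_ctx, "fam", nov_ctx, "nov")
      start <- c(start, t, rep(t + start_steps, 4))
      end <- c(end, t + start_steps, rep(t + start_steps + test_steps, 4))
      list(stim = stim, start = start, end = end,
           win_obj = c("fam", "nov"),
           win_start = rep(t + start_steps, 2),
           win_end = rep(t + start_steps + test_steps, 2),
           n_steps = t + start_steps + test_steps)
    }
    build <- function(orders)
      light_to_schedule(build_light(orders), nodes, contrasts, "sanderson")
    new_preset("sanderson", "empirical", contrasts = contrasts,
               build = build, build_light = build_light,
               perm_factors = perm_factors, nodes = nodes)
  }

  list(
    good_sor = good_like("good", "sor", 5, default_isi = 2, default_ri = 2),
    good_rr = good_like("good", "rr", 5, default_isi = 2, default_ri = 2),
    good_oip = good_like("good", "oip", 5, default_isi = 2, default_ri = 2),
    good_rr_oip = good_like("good", "rr_oip", 5, default_isi = 2,
                            default_ri = 2),
    tam_sor = good_like("tam", "sor", 3, default_isi = 2, default_ri = 5),
    tam_rr = good_like("tam", "rr", 3, default_isi = 5, default_ri = 2),
    tam_oip = good_like("tam", "oip", 3, default_isi = 2, default_ri = 5),
    whitt = whitt,
    sanderson = sanderson)
}

#' Empirical study preset
#'
#' Builds the schedule family emulating one of the simulated studies:
#' `good_sor` / `good_rr` / `good_oip` / `good_rr_oip` (multi-task battery:
#' 20-min habituation, 5-min samples with contexts tiling each phase and
#' objects in the final half of their context window, 2-min intervals,
#' 5-min test), `tam_sor` / `tam_rr` / `tam_oip` (same structure, 3-min
#' tests, delay manipulated: RI for SOR/OIP, ISI for RR), `whitt`
#' (eight 30-s samples, short/long ISI, 15-min RI) and `sanderson` (Y-maze:
#' 10 visits, ISI x RI manipulation, arms coextensive with their contexts).
#'
#' @param preset preset name (see above).
#' @param ... duration overrides passed to the preset constructor
#'   (`isi_minutes`, `ri_minutes`, `habituation_minutes`, ...).
#' @return An `sop_preset`; obtain concrete schedules with
#'   [enumerate_counterbalance()] or run it directly with [run_preset()].
#' @examples
#' p <- empirical_preset("good_sor")
#' counterbalance_count(p)
#' @export
empirical_preset <- function(preset, ...) {
  specs <- empirical_preset_specs()
  if (!preset %in% names(specs))
    stop("unknown preset '", preset, "'; available: ",
         paste(names(specs), collapse = ", "))
  specs[[preset]](...)
}

#' Number of counterbalanced schedule variants
#'
#' The Cartesian product of context-order permutations over the phases the
#' procedure permutes (e.g. 4! x 4! x 4! = 13,824 for the combined
#' recency/displacement battery).
#'
#' @param preset an `sop_preset`.
#' @return Integer count.
#' @export
counterbalance_count <- function(preset) {
  stopifnot(inherits(preset, "sop_preset"))
  if (preset$kind == "conceptual") return(length(preset$schedules))
  prod(vapply(preset$perm_factors, length, 1L))
}

# Iterate over the counterbalance grid calling fn(schedule) for each
# variant; avoids materializing every schedule at once.
cb_apply <- function(preset, fn) {
  if (preset$kind == "conceptual")
    return(lapply(preset$schedules, fn))
  lens <- vapply(preset$perm_factors, length, 1L)
  n <- prod(lens)
  out <- vector("list", n)
  idx <- rep(1L, length(lens))
  for (v in seq_len(n)) {
    orders <- mapply(function(f, i) f[[i]], preset$perm_factors, idx,
                     SIMPLIFY = FALSE)
    out[[v]] <- fn(preset$build(orders))
    # increment mixed-radix counter
    for (d in seq_along(idx)) {
      idx[d] <- idx[d] + 1L
      if (idx[d] <= lens[d]) break
      idx[d] <- 1L
    }
  }
  out
}

# Peak readouts for every counterbalanced variant.  For empirical presets
# on the compiled engine this bypasses schedule-object construction (the
# builders are trusted code; full validation still runs through
# enumerate_counterbalance()).
cb_peaks <- function(preset, params, engine = "cpp") {
  if (preset$kind == "conceptual" || engine != "cpp" ||
      is.null(preset$build_light))
    return(cb_apply(preset, function(s)
      sop_simulate(s, params, engine = engine, record = FALSE)$peaks))
  nodes <- preset$nodes
  rates <- node_rates(nodes, params)
  links <- potential_links(nodes)
  lmat <- matrix(as.integer(c(match(links$source, nodes$id) - 1L,
                              match(links$target, nodes$id) - 1L)), ncol = 2)
  is_obj <- as.integer(nodes$role == "object")
  ids <- nodes$id
  lens <- vapply(preset$perm_factors, length, 1L)
  n <- prod(lens)
  out <- vector("list", n)
  idx <- rep(1L, length(lens))
  for (v in seq_len(n)) {
    orders <- mapply(function(f, i) f[[i]], preset$perm_factors, idx,
                     SIMPLIFY = FALSE)
    light <- preset$build_light(orders)
    act <- matrix(0L, light$n_steps, length(ids))
    j <- match(light$stim, ids)
    for (k in seq_along(j))
      act[(light$start[k] + 1L):light$end[k], j[k]] <- 1L
    res <- cpp_simulate(act, rates$p1, rates$pd1, rates$pd2, is_obj, lmat,
                        params$l_plus, params$l_minus,
                        match(light$win_obj, ids) - 1L,
                        as.integer(light$win_start),
                        as.integer(light$win_end), FALSE)
    out[[v]] <- setNames(res$peaks, light$win_obj)
    for (d in seq_along(idx)) {
      idx[d] <- idx[d] + 1L
      if (idx[d] <= lens[d]) break
      idx[d] <- 1L
    }
  }
  out
}

#' Enumerate all counterbalanced schedules of a preset
#'
#' @param preset an `sop_preset`.
#' @return List of [sop_schedule()] objects, one per context-order
#'   permutation (for conceptual presets: the per-condition runs).
#' @examples
#' length(enumerate_counterbalance(empirical_preset("good_sor")))  # 4
#' @export
enumerate_counterbalance <- function(preset) {
  cb_apply(preset, identity)
}
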