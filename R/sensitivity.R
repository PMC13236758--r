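# Three-tier robustness machinery over the conceptual task presets:
# parameter space partitioning (outcome classification over log-uniform
# samples), Sobol' variance decomposition (Saltelli design with
# second-order terms), and a local 2^4 factorial around the canonical
# parameter set.  The four free parameters are (pd1, pd2, L+, L-); the p1
# saliences stay at their canonical values.

psp_parameters <- c("pd1", "pd2", "l_plus", "l_minus")

#' Classify a predicted task outcome
#'
#' Given the test peaks of the preferred object Q (novel/remote/displaced)
#' and the comparison object P (familiar/recent/in-place), an effect is
#' `robust` when `a1_q > (1 + epsilon) * a1_p`, `weak` when only the ordinal
#' relation `a1_q > a1_p` holds, and `fail` when the ordinal relation is
#' violated (ties included) or both responses are negligible
#' (`max(a1_q, a1_p) <= floor`).
#'
#' @param a1_q,a1_p peak A1 values in \code{[0, 1]} (vectorised).
#' @param epsilon proportional margin (0.05, 0.10 or 0.15 in the standard
#'   suite).
#' @param floor negligible-activity threshold.
#' @return Character vector of `"robust"`, `"weak"`, `"fail"`.
#' @examples
#' classify_outcome(c(0.50, 0.42, 0.004), c(0.40, 0.41, 0.003), 0.05)
#' @export
classify_outcome <- function(a1_q, a1_p, epsilon, floor = 0.005) {
  stopifnot(epsilon >= 0, floor > 0,
            all(a1_q >= 0 & a1_q <= 1), all(a1_p >= 0 & a1_p <= 1))
  unname(ifelse(pmax(a1_q, a1_p) <= floor, "fail",
         ifelse(a1_q > (1 + epsilon) * a1_p, "robust",
         ifelse(a1_q > a1_p, "weak", "fail"))))
}

#' Log-uniform parameter sample
#'
#' Draws (pd1, pd2, L+, L-) points log-uniformly over \code{[lower, upper]}
#' (the mathematically admissible range probed by the global analyses).
#'
#' @param n number of points.
#' @param lower,upper bounds of each parameter.
#' @return `n x 4` matrix with columns `pd1`, `pd2`, `l_plus`, `l_minus`.
#' @export
sample_param_points <- function(n, lower = 0.001, upper = 1) {
  stopifnot(n >= 1, lower > 0, upper >= lower)
  m <- matrix(10^runif(4 * n, log10(lower), log10(upper)), ncol = 4,
              dimnames = list(NULL, psp_parameters))
  m
}

task_conditions <- function(task) {
  switch(task,
         sor = c(q = "novel", p = "recent_in_place"),
         rr = c(q = "remote_in_place", p = "recent_in_place"),
         oip = c(q = "recent_displaced", p = "recent_in_place"),
         stop("unknown task '", task, "'"))
}

task_delay_minutes <- function(task, delay) {
  # delay is the RI for SOR/OIP and the ISI for RR; the other interval is 2
  if (task == "rr") c(isi = delay, ri = 2) else c(isi = 2, ri = delay)
}

# Precompute everything cpp_peak_batch needs for one schedule.
precompute_schedule <- function(sched, params) {
  nodes <- sched$nodes
  rates <- node_rates(nodes, params)
  links <- potential_links(nodes)
  list(act = activity_matrix(sched$events, sched$n_steps, nodes$id),
       p1 = rates$p1,
       is_obj = as.integer(nodes$role == "object"),
       links = matrix(as.integer(c(match(links$source, nodes$id) - 1L,
                                   match(links$target, nodes$id) - 1L)),
                      ncol = 2),
       tobj = match(sched$test_windows$object, nodes$id) - 1L,
       tstart = as.integer(sched$test_windows$start),
       tend = as.integer(sched$test_windows$end))
}

batch_peaks <- function(pre, theta) {
  cpp_peak_batch(pre$act, pre$p1, pre$is_obj, pre$links, theta,
                 pre$tobj, pre$tstart, pre$tend)[, 1]
}

# Peaks of the conceptual conditions for a matrix of parameter points.
conceptual_condition_peaks <- function(theta, conditions,
                                       isi_minutes = 2, ri_minutes = 2,
                                       params = sop_params()) {
  stp <- lapply(c(isi = isi_minutes, ri = ri_minutes, sample = 5, test = 5),
                min_to_steps)
  out <- sapply(conditions, function(cond) {
    sched <- conceptual_condition_schedule(cond, stp$isi, stp$ri,
                                           stp$sample, stp$test)
    batch_peaks(precompute_schedule(sched, params), theta)
  })
  matrix(out, nrow = nrow(theta), dimnames = list(NULL, conditions))
}

geo_stats <- function(x) {
  m <- mean(log(x))
  c(geo_mean = exp(m), gsd = exp(stats::sd(log(x))))
}

#' Parameter space partitioning
#'
#' Samples (pd1, pd2, L+, L-) log-uniformly, simulates the three conceptual
#' tasks at each point (2-min delays by default), classifies every task
#' outcome at each proportional margin, and reports volume proportions
#' (fraction of sampled points per class, a Monte Carlo volume in log-space
#' measure) with across-run standard deviations, region parameter summaries
#' (geometric mean and geometric sd within the all-robust region and the
#' selective-failure region where SOR and RR are robust but OIP fails), and
#' the probabilities of the canonical ordering constraints within those
#' regions.
#'
#' @param n_points points per run.
#' @param epsilons proportional margins evaluated.
#' @param n_runs independent runs (run r uses `seed + r - 1`).
#' @param seed base RNG seed.
#' @param isi_minutes,ri_minutes conceptual delays.
#' @param params canonical parameters (supplies the fixed p1 values).
#' @param lower,upper sampled parameter range.
#' @return Object of class `sop_psp` with elements `proportions`,
#'   `regions`, `constraints`, `n_points`, `n_runs`.
#' @export
run_psp <- function(n_points = 20000, epsilons = c(0.05, 0.10, 0.15),
                    n_runs = 5, seed = 1, isi_minutes = 2, ri_minutes = 2,
                    params = sop_params(), lower = 0.001, upper = 1) {
  stopifnot(n_points >= 1, n_runs >= 1)
  tasks <- c("sor", "rr", "oip")
  prop_rows <- NULL
  pooled_theta <- vector("list", n_runs)
  pooled_class <- vector("list", n_runs)
  for (r in seq_len(n_runs)) {
    set.seed(seed + r - 1L)
    theta <- sample_param_points(n_points, lower, upper)
    peaks <- conceptual_condition_peaks(theta, conceptual_conditions,
                                        isi_minutes, ri_minutes, params)
    cls <- array(NA_character_,
                 c(n_points, length(tasks), length(epsilons)),
                 dimnames = list(NULL, tasks, paste(epsilons)))
    for (task in tasks) {
      qp <- task_conditions(task)
      for (e in seq_along(epsilons))
        cls[, task, e] <- classify_outcome(peaks[, qp["q"]], peaks[, qp["p"]],
                                           epsilons[e])
    }
    for (e in seq_along(epsilons)) {
      for (task in tasks) {
        tab <- table(factor(cls[, task, e],
                            levels = c("robust", "weak", "fail")))
        prop_rows <- rbind(prop_rows, data.frame(
          run = r, task = task, epsilon = epsilons[e],
          outcome = names(tab), pct = 100 * as.numeric(tab) / n_points))
      }
      all_robust <- rowSums(cls[, , e] == "robust") == length(tasks)
      prop_rows <- rbind(prop_rows, data.frame(
        run = r, task = "all", epsilon = epsilons[e], outcome = "robust",
        pct = 100 * mean(all_robust)))
    }
    pooled_theta[[r]] <- theta
    pooled_class[[r]] <- cls
  }
  theta_all <- do.call(rbind, pooled_theta)
  cls_all <- do.call(abind1, pooled_class)

  proportions <- aggregate(pct ~ task + epsilon + outcome, prop_rows,
                           function(v) c(mean = mean(v), sd = stats::sd(v)))
  proportions <- data.frame(proportions[1:3],
                            mean_pct = proportions$pct[, "mean"],
                            sd_pct = proportions$pct[, "sd"])

  regions <- NULL; constraints <- NULL
  for (e in seq_along(epsilons)) {
    rob <- cls_all[, , e] == "robust"
    members <- list(
      all_robust = rowSums(rob) == 3,
      impaired_oip = rob[, "sor"] & rob[, "rr"] & cls_all[, "oip", e] == "fail")
    for (rg in names(members)) {
      sel <- members[[rg]]
      if (sum(sel) < 2) next
      th <- theta_all[sel, , drop = FALSE]
      for (pnm in psp_parameters) {
        gs <- geo_stats(th[, pnm])
        regions <- rbind(regions, data.frame(
          region = rg, epsilon = epsilons[e], parameter = pnm,
          geo_mean = gs["geo_mean"], gsd = gs["gsd"], row.names = NULL))
      }
      constraints <- rbind(constraints, data.frame(
        region = rg, epsilon = epsilons[e],
        p_pd1_gt_pd2 = mean(th[, "pd1"] > th[, "pd2"]),
        p_lplus_gt_lminus = mean(th[, "l_plus"] > th[, "l_minus"]),
        p_joint = mean(th[, "pd1"] > th[, "pd2"] &
                       th[, "l_plus"] > th[, "l_minus"]),
        n = sum(sel)))
    }
  }
  structure(list(proportions = proportions, regions = regions,
                 constraints = constraints, n_points = n_points,
                 n_runs = n_runs, epsilons = epsilons),
            class = "sop_psp")
}

# bind 3-d arrays along rows
abind1 <- function(...) {
  parts <- list(...)
  d <- dim(parts[[1]])
  out <- array(NA_character_, c(sum(vapply(parts, function(p) dim(p)[1], 1)),
                                d[2], d[3]),
               dimnames = c(list(NULL), dimnames(parts[[1]])[2:3]))
  at <- 0L
  for (p in parts) {
    out[at + seq_len(dim(p)[1]), , ] <- p
    at <- at + dim(p)[1]
  }
  out
}

#' @export
print.sop_psp <- function(x, ...) {
  cat(sprintf("Parameter space partitioning: %d points x %d runs\n",
              x$n_points, x$n_runs))
  pr <- x$proportions
  for (e in x$epsilons) {
    cat(sprintf("  epsilon = %.2f:\n", e))
    sub <- pr[pr$epsilon == e, ]
    for (k in seq_len(nrow(sub)))
      cat(sprintf("    %-4s %-6s %5.1f%% (sd %.1f)\n", sub$task[k],
                  sub$outcome[k], sub$mean_pct[k], sub$sd_pct[k]))
  }
  invisible(x)
}

# ---------------------------------------------------------------------------
# Sobol' variance decomposition (Saltelli design, second-order terms)
# ---------------------------------------------------------------------------

#' Saltelli cross-sampling design
#'
#' Two independent base matrices A and B on the unit hypercube plus the
#' column-swapped matrices AB_i (A with column i from B) and BA_i, giving
#' `n_base * (2k + 2)` model evaluations and supporting first-, total- and
#' second-order index estimation.
#'
#' @param n_base base sample size.
#' @param k number of factors.
#' @return List with matrices `A`, `B` and lists `AB`, `BA`.
#' @export
saltelli_design <- function(n_base, k) {
  A <- matrix(runif(n_base * k), n_base, k)
  B <- matrix(runif(n_base * k), n_base, k)
  AB <- lapply(seq_len(k), function(i) { M <- A; M[, i] <- B[, i]; M })
  BA <- lapply(seq_len(k), function(i) { M <- B; M[, i] <- A[, i]; M })
  list(A = A, B = B, AB = AB, BA = BA)
}

# Index estimators from the evaluated design (Saltelli 2010 for S1, Jansen
# for ST, and the closed-pair estimator for S2).
sobol_estimates <- function(yA, yB, yAB, yBA, idx = NULL) {
  if (!is.null(idx)) {
    yA <- yA[idx]; yB <- yB[idx]
    yAB <- yAB[idx, , drop = FALSE]; yBA <- yBA[idx, , drop = FALSE]
  }
  # centring does not change the expectations but removes the mean-squared
  # noise terms from the cross-product estimators
  mu <- mean(c(yA, yB))
  yA <- yA - mu; yB <- yB - mu; yAB <- yAB - mu; yBA <- yBA - mu
  k <- ncol(yAB)
  V <- var(c(yA, yB))
  S1 <- vapply(seq_len(k), function(i) mean(yB * (yAB[, i] - yA)) / V, 0)
  ST <- vapply(seq_len(k), function(i) mean((yA - yAB[, i])^2) / (2 * V), 0)
  S2 <- matrix(NA_real_, k, k)
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    Vij <- mean(yBA[, i] * yAB[, j]) - mean(yA * yB)
    S2[i, j] <- Vij / V - S1[i] - S1[j]
  }
  list(S1 = S1, ST = ST, S2 = S2, V = V)
}

#' Sobol' indices of an arbitrary model on the unit hypercube
#'
#' Generic estimation engine (also used to validate the estimators against
#' functions with known indices).  The model is evaluated on a Saltelli
#' design; bootstrap confidence half-widths resample design rows.
#'
#' @param f vectorised model: takes an `n x k` matrix in `[0,1]^k`, returns
#'   `n` outputs.
#' @param k number of factors.
#' @param n_base base sample size.
#' @param n_boot bootstrap replicates for CI half-widths (0 to skip).
#' @param seed RNG seed.
#' @return List with vectors `S1`, `ST`, matrix `S2`, `S_res`
#'   (`1 - sum(S1) - sum(S2)`), and CI half-width analogues `S1_ci`,
#'   `ST_ci`, `S2_ci`.
#' @examples
#' add4 <- function(X) rowSums(X)    # additive: S1 = 1/4 each, S2 = 0
#' sobol_indices(add4, k = 4, n_base = 256, seed = 1)$S1
#' @export
sobol_indices <- function(f, k, n_base = 1024, n_boot = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  dsn <- saltelli_design(n_base, k)
  yA <- f(dsn$A); yB <- f(dsn$B)
  if (any(!is.finite(yA)) || any(!is.finite(yB)))
    stop("non-finite model output at a design point")
  yAB <- vapply(dsn$AB, f, numeric(n_base))
  yBA <- vapply(dsn$BA, f, numeric(n_base))
  if (any(!is.finite(yAB)) || any(!is.finite(yBA)))
    stop("non-finite model output at a design point")
  est <- sobol_estimates(yA, yB, yAB, yBA)
  out <- list(S1 = est$S1, ST = est$ST, S2 = est$S2,
              S_res = 1 - sum(est$S1) - sum(est$S2, na.rm = TRUE),
              V = est$V)
  if (n_boot > 0) {
    bs1 <- matrix(NA_real_, n_boot, k); bst <- matrix(NA_real_, n_boot, k)
    bs2 <- array(NA_real_, c(n_boot, k, k))
    for (b in seq_len(n_boot)) {
      idx <- sample.int(n_base, replace = TRUE)
      eb <- sobol_estimates(yA, yB, yAB, yBA, idx = idx)
      bs1[b, ] <- eb$S1; bst[b, ] <- eb$ST; bs2[b, , ] <- eb$S2
    }
    hw <- function(m) apply(m, seq_along(dim(m))[-1], function(v)
      diff(quantile(v, c(0.025, 0.975), na.rm = TRUE)) / 2)
    out$S1_ci <- hw(bs1); out$ST_ci <- hw(bst); out$S2_ci <- hw(bs2)
  }
  out
}

#' Sobol' decomposition of a conceptual task contrast
#'
#' Variance-based sensitivity of the predicted contrast (peak A1 of Q minus
#' peak A1 of P on the conceptual preset) to (pd1, pd2, L+, L-), each
#' sampled log10-uniformly over \code{[0.001, 1]}.  Indices are averaged
#' over `n_runs` independent designs; brackets report the mean bootstrap
#' 95\% CI half-width.
#'
#' @param task `"sor"`, `"rr"` or `"oip"`.
#' @param delay_minutes 2 or 8 (RI for SOR/OIP, ISI for RR).
#' @param n_base base sample size (evaluations = `n_base * 10`).
#' @param n_runs independent designs averaged (run r uses `seed + r - 1`).
#' @param n_boot bootstrap replicates per run.
#' @param seed base seed.
#' @param params canonical parameters (fixed p1 values).
#' @param lower,upper parameter range.
#' @return Object of class `sop_sobol` with `indices` (data frame:
#'   `parameter`, `S1`, `S1_ci`, `ST`, `ST_ci`, `interaction` = ST - S1),
#'   `second_order` (data frame of named pairs) and `S_res`.
#' @export
run_sobol <- function(task, delay_minutes = 2, n_base = 1024, n_runs = 3,
                      n_boot = 500, seed = 1, params = sop_params(),
                      lower = 0.001, upper = 1) {
  qp <- task_conditions(task)
  dl <- task_delay_minutes(task, delay_minutes)
  to_theta <- function(X)
    10^(log10(lower) + X * (log10(upper) - log10(lower)))
  f <- function(X) {
    theta <- to_theta(X)
    colnames(theta) <- psp_parameters
    pk <- conceptual_condition_peaks(theta, unname(qp),
                                     isi_minutes = dl["isi"],
                                     ri_minutes = dl["ri"], params = params)
    pk[, qp["q"]] - pk[, qp["p"]]
  }
  runs <- lapply(seq_len(n_runs), function(r)
    sobol_indices(f, k = 4, n_base = n_base, n_boot = n_boot,
                  seed = seed + r - 1L))
  avg <- function(get) Reduce(`+`, lapply(runs, get)) / n_runs
  S1 <- avg(function(x) x$S1); ST <- avg(function(x) x$ST)
  S2 <- avg(function(x) x$S2)
  if (n_boot > 0) {
    S1_ci <- avg(function(x) x$S1_ci); ST_ci <- avg(function(x) x$ST_ci)
    S2_ci <- avg(function(x) x$S2_ci)
  } else {
    S1_ci <- ST_ci <- rep(NA_real_, 4)
    S2_ci <- matrix(NA_real_, 4, 4)
  }
  pairs <- which(upper.tri(S2), arr.ind = TRUE)
  structure(list(
    task = task, delay_minutes = delay_minutes,
    indices = data.frame(
      parameter = psp_parameters, S1 = S1, S1_ci = S1_ci,
      ST = ST, ST_ci = ST_ci, interaction = ST - S1),
    second_order = data.frame(
      pair = paste(psp_parameters[pairs[, 1]], psp_parameters[pairs[, 2]],
                   sep = " x "),
      S2 = S2[pairs], S2_ci = S2_ci[cbind(pairs[, 1], pairs[, 2])]),
    S_res = 1 - sum(S1) - sum(S2, na.rm = TRUE),
    n_base = n_base, n_runs = n_runs), class = "sop_sobol")
}

#' @export
print.sop_sobol <- function(x, ...) {
  cat(sprintf("Sobol' decomposition: %s contrast, %g-min delay (n_base %d, %d runs)\n",
              toupper(x$task), x$delay_minutes, x$n_base, x$n_runs))
  idx <- x$indices
  for (k in seq_len(nrow(idx)))
    cat(sprintf("  %-8s S1 %.2f [%.2f]  ST %.2f [%.2f]  ST-S1 %.2f\n",
                idx$parameter[k], idx$S1[k], idx$S1_ci[k], idx$ST[k],
                idx$ST_ci[k], idx$interaction[k]))
  top <- x$second_order[order(-x$second_order$S2), ][1, ]
  cat(sprintf("  largest S2: %s = %.2f; S_res = %.2f\n",
              top$pair, top$S2, x$S_res))
  invisible(x)
}

# ---------------------------------------------------------------------------
# Local 2^4 factorial
# ---------------------------------------------------------------------------

# Orthogonal +/-1 effect decomposition of a full two-level design: the
# effect of a term is its regression coefficient on the +/-1 codes (half the
# high-minus-low mean difference); SST shares are coefficient squares over
# their total and are invariant to the half/full-difference convention.
factorial_decompose <- function(signs, y) {
  X <- stats::model.matrix(
    ~ (pd1 + pd2 + l_plus + l_minus)^4,
    data = as.data.frame(signs))
  coefs <- drop(crossprod(X, y)) / nrow(X)
  terms <- setdiff(colnames(X), "(Intercept)")
  eff <- coefs[terms]
  tot <- sum(eff^2)
  list(term = terms, effect = unname(eff),
       sst_share = if (tot > 0) unname(eff^2) / tot else rep(0, length(eff)))
}

#' Local two-level factorial analysis around the canonical parameters
#'
#' Evaluates the predicted contrast at the 16 corners of a 2^4 design with
#' log-symmetric perturbations (`theta * perturbation^(+/-1)`) of
#' (pd1, pd2, L+, L-), decomposes it into main and interaction effects via
#' orthogonal +/-1 coding (an effect is half the high-minus-low mean
#' difference, i.e. the regression coefficient), and reports each effect
#' relative to the canonical contrast together with its share of the local
#' sum of squares.
#'
#' @param task `"sor"`, `"rr"` or `"oip"`.
#' @param delay_minutes RI for SOR/OIP, ISI for RR.
#' @param perturbation multiplicative perturbation factor (1.1 = +/-10\%).
#' @param params canonical parameter set (the design centre).
#' @param share_filter report terms with an SST share above this (the full
#'   table is kept in the returned object).
#' @return Object of class `sop_factorial` with `effects` (all 15 terms:
#'   `term`, `effect`, `relative_effect`, `sst_share`), `report` (filtered),
#'   `canonical_contrast`, `corner_contrasts`, `min_ratio` (smallest
#'   `a1_q / a1_p` over the corners).
#' @export
run_local_factorial <- function(task, delay_minutes = 2, perturbation = 1.1,
                                params = sop_params(), share_filter = 0.01) {
  stopifnot(perturbation > 0)
  qp <- task_conditions(task)
  dl <- task_delay_minutes(task, delay_minutes)
  canon <- c(pd1 = params$pd1, pd2 = params$pd2,
             l_plus = params$l_plus, l_minus = params$l_minus)
  signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), 4)))
  colnames(signs) <- psp_parameters
  theta <- sweep(perturbation^signs, 2, canon, `*`)
  peaks <- conceptual_condition_peaks(
    rbind(theta, canon), unname(qp),
    isi_minutes = dl["isi"], ri_minutes = dl["ri"], params = params)
  y <- peaks[, qp["q"]] - peaks[, qp["p"]]
  ratios <- peaks[, qp["q"]] / peaks[, qp["p"]]
  canonical <- y[17]; y <- y[1:16]
  if (canonical == 0) stop("canonical contrast is zero: relative effects undefined")

  dec <- factorial_decompose(signs, y)
  effects <- data.frame(term = gsub(":", " x ", dec$term),
                        effect = dec$effect,
                        relative_effect = dec$effect / canonical,
                        sst_share = dec$sst_share, row.names = NULL)
  effects <- effects[order(-effects$sst_share), ]
  structure(list(task = task, delay_minutes = delay_minutes,
                 effects = effects,
                 report = effects[effects$sst_share > share_filter, ],
                 canonical_contrast = canonical,
                 corner_contrasts = unname(y),
                 min_ratio = min(ratios[1:16])),
            class = "sop_factorial")
}

#' @export
print.sop_factorial <- function(x, ...) {
  cat(sprintf("Local 2^4 factorial: %s contrast, %g-min delay\n",
              toupper(x$task), x$delay_minutes))
  cat(sprintf("  canonical contrast %.4f; min corner ratio Q/P %.3f\n",
              x$canonical_contrast, x$min_ratio))
  r <- x$report
  for (k in seq_len(nrow(r)))
    cat(sprintf("  %-28s rel. effect %+0.2f  SST %.2f\n",
                r$term[k], r$relative_effect[k], r$sst_share[k]))
  invisible(x)
}
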