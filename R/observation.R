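# Observation model: a single global scaling k maps model activation (peak
# A1, dimensionless) to observed exploration seconds, y_hat = k * A1_hat.
# k is fit by weighted least squares through the origin with a two-stage
# weight normalization that gives every study, and every task within a
# study, equal total influence.

check_records <- function(records, need_y = TRUE) {
  req <- c("study", "task", "object", "a1_hat")
  if (need_y) req <- c(req, "y", "se")
  miss <- setdiff(req, names(records))
  if (length(miss)) stop("records lack columns: ", paste(miss, collapse = ", "))
  if (need_y && any(records$se <= 0)) stop("all `se` must be > 0")
  if (any(records$a1_hat < 0 | records$a1_hat > 1))
    stop("`a1_hat` must lie in [0, 1]")
  invisible(records)
}

#' Normalized inverse-variance weights
#'
#' Raw weights are inverse variances (1/se^2).  They are then rescaled in
#' two stages so that (i) every (study, task) cell carries the same total
#' weight within its study and (ii) every study carries the same total
#' weight overall — avoiding bias toward studies that report more object
#' means and tasks that contribute more objects.  Weights are returned
#' normalized to sum to 1.
#'
#' @param records data frame with columns `study`, `task`, `se` (and the
#'   other record columns, see [fit_k()]).
#' @return Numeric weight vector aligned with `records` rows.
#' @export
normalize_weights <- function(records) {
  stopifnot(nrow(records) > 0, all(records$se > 0))
  w <- 1 / records$se^2
  cell <- interaction(records$study, records$task, drop = TRUE)
  w <- w / ave(w, cell, FUN = sum)                  # equal cell totals (= 1)
  n_cells <- ave(as.integer(cell), records$study,
                 FUN = function(i) length(unique(i)))
  w <- w / n_cells                                  # equal study totals (= 1)
  w / sum(w)
}

#' Fit the activation-to-seconds scaling constant
#'
#' Closed-form weighted least squares through the origin:
#' `k = sum(w * a1 * y) / sum(w * a1^2)`.
#'
#' @param records data frame with columns `study`, `task`, `object`, `y`
#'   (observed mean exploration seconds), `se` (its standard error) and
#'   `a1_hat` (model peak A1 for the object).
#' @param weights optional weight vector; defaults to
#'   [normalize_weights()] of the records.
#' @return Object of class `sop_fit`: `k`, `weights`, `fitted`
#'   (`k * a1_hat`), `residuals` (`fitted - y`), `records`.
#' @examples
#' rec <- data.frame(study = "s", task = "sor", object = c("Q", "P"),
#'                   y = c(30, 15), se = 1, a1_hat = c(0.6, 0.3))
#' fit_k(rec)$k
#' @export
fit_k <- function(records, weights = NULL) {
  check_records(records)
  if (is.null(weights)) weights <- normalize_weights(records)
  stopifnot(length(weights) == nrow(records), all(weights > 0))
  denom <- sum(weights * records$a1_hat^2)
  if (denom <= 0) stop("cannot fit k: all model activations are zero")
  k <- sum(weights * records$a1_hat * records$y) / denom
  fitted <- k * records$a1_hat
  structure(list(k = k, weights = weights, fitted = fitted,
                 residuals = fitted - records$y, records = records),
            class = "sop_fit")
}

#' @export
print.sop_fit <- function(x, ...) {
  cat(sprintf("Observation-model fit: k = %.3f s per A1 unit (n = %d records)\n",
              x$k, length(x$fitted)))
  if (!is.null(x$ci95))
    cat(sprintf("  95%% exact study bootstrap CI: [%.2f, %.2f]\n",
                x$ci95[1], x$ci95[2]))
  invisible(x)
}

#' Exact study-level bootstrap interval for k
#'
#' Enumerates all S^S ordered with-replacement resamples of the S studies
#' (256 resamples for 4 studies), refits k on each resample with weights
#' re-normalized so each drawn study again carries equal weight, and returns
#' the 2.5/97.5 percentiles of the enumerated distribution (linear
#' interpolation; enumeration removes resampling noise).
#'
#' @param records record table (see [fit_k()]).
#' @param max_studies guard against combinatorial blow-up (S^S resamples).
#' @return List with `ci` (length-2 vector), `k_boot` (all resample
#'   estimates) and `n_resamples`.
#' @export
exact_study_bootstrap <- function(records, max_studies = 6) {
  check_records(records)
  studies <- unique(records$study)
  S <- length(studies)
  if (S > max_studies)
    stop("exact enumeration of ", S, "^", S, " resamples refused; ",
         "raise `max_studies` deliberately if intended")
  grid <- as.matrix(expand.grid(rep(list(seq_len(S)), S)))
  k_boot <- apply(grid, 1, function(draw) {
    parts <- lapply(seq_len(S), function(j) {
      rec <- records[records$study == studies[draw[j]], , drop = FALSE]
      rec$study <- paste0("resample_", j)   # each draw is its own pseudo-study
      rec
    })
    fit_k(do.call(rbind, parts))$k
  })
  list(ci = unname(quantile(k_boot, c(0.025, 0.975))), k_boot = k_boot,
       n_resamples = length(k_boot))
}

#' Leave-one-study-out sensitivity of k
#'
#' @param records record table (see [fit_k()]).
#' @return Data frame: `study`, `k` (refit without that study),
#'   `pct_change` relative to the full fit.
#' @export
loso <- function(records) {
  check_records(records)
  studies <- unique(records$study)
  if (length(studies) < 2) stop("leave-one-study-out needs >= 2 studies")
  k_full <- fit_k(records)$k
  out <- do.call(rbind, lapply(studies, function(s) {
    k_s <- fit_k(records[records$study != s, , drop = FALSE])$k
    data.frame(study = s, k = k_s, pct_change = 100 * (k_s - k_full) / k_full,
               stringsAsFactors = FALSE)
  }))
  attr(out, "k_full") <- k_full
  out
}

#' Weighted error metrics
#'
#' Summarises prediction error in seconds with the weighted bias, mean
#' absolute error, root mean squared error and (optionally) coefficient of
#' determination; at the contrast level a weighted sign accuracy (fraction
#' of contrasts whose predicted and observed signs agree) is added.
#'
#' @param residuals prediction errors `e = y_hat - y`.
#' @param weights weights (any positive scale).
#' @param y observed values (needed for `wR2`).
#' @param level `"object"` or `"contrast"`.
#' @param delta_pred,delta_obs predicted and observed contrast values
#'   (contrast level only, for sign accuracy).
#' @param r2 compute `wR2` (skipped when the weighted variance of `y` is 0
#'   or on small contrast sets where it is unstable).
#' @return One-row data frame: `n`, `wBias`, `wMAE`, `wRMSE`, `wR2`,
#'   `sign_accuracy`.
#' @export
weighted_metrics <- function(residuals, weights, y = NULL,
                             level = c("object", "contrast"),
                             delta_pred = NULL, delta_obs = NULL, r2 = TRUE) {
  level <- match.arg(level)
  stopifnot(length(residuals) == length(weights), all(weights > 0))
  w <- weights / sum(weights)
  out <- data.frame(
    n = length(residuals),
    wBias = sum(w * residuals),
    wMAE = sum(w * abs(residuals)),
    wRMSE = sqrt(sum(w * residuals^2)),
    wR2 = NA_real_, sign_accuracy = NA_real_)
  if (r2 && !is.null(y)) {
    ybar <- sum(w * y)
    den <- sum(w * (y - ybar)^2)
    if (den <= 0) stop("zero weighted variance of y: wR2 undefined")
    out$wR2 <- 1 - sum(w * residuals^2) / den
  }
  if (level == "contrast") {
    if (is.null(delta_pred) || is.null(delta_obs))
      stop("contrast-level metrics need `delta_pred` and `delta_obs`")
    out$sign_accuracy <- sum(w * (sign(delta_pred) == sign(delta_obs)))
  }
  out
}

#' Synthetic multi-study record tables
#'
#' Generates study tables with known scaling for tests and demonstrations:
#' each synthetic study runs the conceptual task presets at its own delays
#' to obtain model activations, then emits observed seconds
#' `y = k_true * a1_hat + noise` with plausible standard errors.  The
#' deposited studies behind the published comparisons report figure-adapted
#' values that are not machine-readable, so a generator with known ground
#' truth stands in for them.
#'
#' @param k_true true scaling constant (seconds per A1 unit).
#' @param n_studies number of synthetic studies.
#' @param tasks conceptual tasks each study contributes.
#' @param noise_sd Gaussian noise sd on `y`, in seconds.
#' @param seed RNG seed (the model runs themselves are deterministic).
#' @param params model parameters used for the underlying simulations.
#' @return Record data frame (`study`, `task`, `object`, `role`, `y`, `se`,
#'   `a1_hat`).
#' @examples
#' rec <- generate_synthetic_studies(k_true = 50, n_studies = 2,
#'                                   noise_sd = 0, seed = 1)
#' fit_k(rec)$k  # recovers 50 exactly
#' @export
generate_synthetic_studies <- function(k_true = 55, n_studies = 4,
                                       tasks = c("sor", "rr", "oip"),
                                       noise_sd = 2, seed = 1,
                                       params = sop_params()) {
  stopifnot(k_true > 0, noise_sd >= 0, n_studies >= 1)
  set.seed(seed)
  delay_grid <- c(2, 5, 8)
  out <- NULL
  for (s in seq_len(n_studies)) {
    delay <- sample(delay_grid, 1)
    for (task in tasks) {
      preset <- if (task == "rr")
        conceptual_preset(task, isi_minutes = delay) else
        conceptual_preset(task, ri_minutes = delay)
      res <- run_preset(preset, params)
      cdef <- res$contrasts
      for (lab in c(cdef$q[1], cdef$p[1])) {
        a1 <- res$objects$mean_peak_a1[res$objects$object == lab]
        out <- rbind(out, data.frame(
          study = paste0("study_", s), task = task, object = lab,
          role = if (lab == cdef$q[1]) "Q" else "P",
          y = max(0, k_true * a1 + rnorm(1, 0, noise_sd)),
          se = round(max(0.05, noise_sd) * runif(1, 0.7, 1.3), 3),
          a1_hat = a1, stringsAsFactors = FALSE))
      }
    }
  }
  out
}
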