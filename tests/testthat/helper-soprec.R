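# Shared fixtures: tiny schedules and independent oracles built in code.

# Single isolated object node (no contexts, hence no links, p2 = 0).
isolated_schedule <- function(segments, p1 = 0.75, pd1 = 0.1, pd2 = 0.02) {
  stopifnot(all(segments$duration == round(segments$duration)))
  ends <- cumsum(segments$duration)
  starts <- c(0, head(ends, -1))
  on <- segments$active
  ev <- data.frame(stimulus = rep("P", sum(on)),
                   start = starts[on], end = ends[on])
  sop_schedule(
    nodes = data.frame(id = "P", role = "object",
                       p1 = p1, pd1 = pd1, pd2 = pd2),
    events = ev,
    test_windows = data.frame(object = "P", start = 0, end = sum(segments$duration)),
    n_steps = sum(segments$duration))
}

# Tiny coupled fixture: one context, one object, both on together.
paired_schedule <- function(n_on = 50, n_off = 50) {
  sop_schedule(
    nodes = data.frame(id = c("x", "P"), role = c("context", "object")),
    events = data.frame(stimulus = c("x", "P"), start = 0, end = n_on),
    test_windows = data.frame(object = "P", start = 0, end = n_on + n_off),
    n_steps = n_on + n_off)
}

# Independent 1-d minimizer of the weighted SSE through the origin, by
# successively refined grid search (never uses the closed form).
grid_min_k <- function(records, weights, lo = 0, hi = 500, rounds = 6,
                       n_grid = 1000) {
  sse <- function(k) sum(weights * (k * records$a1_hat - records$y)^2)
  for (r in seq_len(rounds)) {
    ks <- seq(lo, hi, length.out = n_grid)
    vals <- vapply(ks, sse, 0)
    i <- which.min(vals)
    lo <- ks[max(1, i - 1)]; hi <- ks[min(n_grid, i + 1)]
  }
  (lo + hi) / 2
}

# Six-record heteroscedastic observation fixture with known structure:
# two studies, unequal task/record counts.
observation_fixture <- function() {
  data.frame(
    study = c("s1", "s1", "s1", "s1", "s2", "s2"),
    task = c("sor", "sor", "rr", "rr", "sor", "sor"),
    object = c("Q", "P", "Q", "P", "Q", "P"),
    role = c("Q", "P", "Q", "P", "Q", "P"),
    y = c(30, 12, 25, 18, 40, 22),
    se = c(1, 2, 1, 1, 4, 2),
    a1_hat = c(0.6, 0.25, 0.5, 0.35, 0.7, 0.4),
    stringsAsFactors = FALSE)
}

canonical_theta <- function() {
  matrix(c(0.1, 0.02, 0.25, 0.025), nrow = 1,
         dimnames = list(NULL, c("pd1", "pd2", "l_plus", "l_minus")))
}

# Peaks of the four conceptual conditions at given parameter points.
conceptual_peaks <- function(theta, isi = 2, ri = 2) {
  soprec:::conceptual_condition_peaks(
    theta, soprec:::conceptual_conditions, isi, ri)
}
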