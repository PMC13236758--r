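test_that("outcome classification follows the proportional criterion", {
  expect_equal(classify_outcome(0.50, 0.40, 0.05), "robust")
  expect_equal(classify_outcome(0.42, 0.41, 0.05), "weak")
  expect_equal(classify_outcome(0.004, 0.003, 0.15), "fail")  # activity floor
  expect_equal(classify_outcome(0.3, 0.4, 0.05), "fail")
  expect_equal(classify_outcome(0.4, 0.4, 0), "fail")         # ties fail
})

test_that("classification is exhaustive and mutually exclusive", {
  set.seed(8)
  q <- runif(500); p <- runif(500)
  q[1:50] <- p[1:50]                       # force ties
  for (eps in c(0.05, 0.10, 0.15)) {
    cls <- classify_outcome(q, p, eps)
    expect_true(all(cls %in% c("robust", "weak", "fail")))
    # re-derive from the definitions
    expected <- ifelse(pmax(q, p) <= 0.005, "fail",
                ifelse(q > (1 + eps) * p, "robust",
                ifelse(q > p, "weak", "fail")))
    expect_identical(cls, expected)
  }
  # robust shrinks and fail grows (weakly) as the margin rises
  c05 <- classify_outcome(q, p, 0.05); c15 <- classify_outcome(q, p, 0.15)
  expect_lte(sum(c15 == "robust"), sum(c05 == "robust"))
  expect_gte(sum(c15 == "fail"), sum(c05 == "fail"))
})

test_that("parameter samples are log-uniform on the stated box", {
  set.seed(2)
  th <- sample_param_points(4000)
  expect_equal(colnames(th), c("pd1", "pd2", "l_plus", "l_minus"))
  expect_true(all(th >= 0.001 & th <= 1))
  # log10 values should be uniform on [-3, 0]
  expect_equal(mean(log10(th)), -1.5, tolerance = 0.05)
  expect_equal(stats::sd(log10(th[, 1])), sqrt(9 / 12), tolerance = 0.05)
})

test_that("the canonical point is robust on all tasks at the strictest margin", {
  pk <- conceptual_peaks(canonical_theta())
  for (task in c("sor", "rr", "oip")) {
    qp <- soprec:::task_conditions(task)
    expect_equal(classify_outcome(pk[, qp["q"]], pk[, qp["p"]], 0.15),
                 "robust", info = task)
  }
})

test_that("a no-learning, strong-decay regime never yields robust OIP", {
  set.seed(4)
  th <- cbind(pd1 = runif(100, 0.3, 1), pd2 = runif(100, 0.001, 0.003),
              l_plus = rep(0.001, 100), l_minus = rep(0.001, 100))
  pk <- conceptual_peaks(th)
  cls <- classify_outcome(pk[, "recent_displaced"], pk[, "recent_in_place"],
                          0.05)
  expect_false(any(cls == "robust"))
})

test_that("PSP proportions are coherent and epsilon-monotone", {
  p <- run_psp(n_points = 800, n_runs = 2, seed = 99)
  pr <- p$proportions
  for (task in c("sor", "rr", "oip")) for (eps in p$epsilons) {
    tot <- sum(pr$mean_pct[pr$task == task & pr$epsilon == eps])
    expect_equal(tot, 100, tolerance = 1e-9)
  }
  rob <- function(task) {
    sub <- pr[pr$task == task & pr$outcome == "robust", ]
    sub$mean_pct[order(sub$epsilon)]
  }
  fail <- function(task) {
    sub <- pr[pr$task == task & pr$outcome == "fail", ]
    sub$mean_pct[order(sub$epsilon)]
  }
  for (task in c("sor", "rr", "oip", "all")) {
    expect_true(all(diff(rob(task)) <= 1e-12))
  }
  for (task in c("sor", "rr", "oip"))
    expect_true(all(diff(fail(task)) >= -1e-12))
  # all-robust cannot exceed any single-task robust volume
  for (eps in p$epsilons)
    expect_lte(rob("all")[which(p$epsilons == eps)],
               min(vapply(c("sor", "rr", "oip"), function(t)
                 rob(t)[which(p$epsilons == eps)], 0)))
})

test_that("the canonical point lies inside the all-robust high-mass box", {
  p <- run_psp(n_points = 3000, n_runs = 1, seed = 17)
  rg <- p$regions[p$regions$region == "all_robust" &
                  p$regions$epsilon == 0.05, ]
  canon <- c(pd1 = 0.1, pd2 = 0.02, l_plus = 0.25, l_minus = 0.025)
  for (k in seq_len(nrow(rg))) {
    gm <- rg$geo_mean[k]; gsd <- rg$gsd[k]
    v <- canon[rg$parameter[k]]
    expect_gte(v, gm / gsd^2); expect_lte(v, gm * gsd^2)
  }
  cs <- p$constraints[p$constraints$region == "all_robust", ]
  expect_true(all(cs$p_joint <= pmin(cs$p_pd1_gt_pd2, cs$p_lplus_gt_lminus)))
})

test_that("Sobol' estimators pass the additive oracle", {
  # Y = sum of four independent uniforms: S1 = 1/4 each, no interactions
  si <- sobol_indices(function(X) rowSums(X), k = 4, n_base = 4096,
                      n_boot = 100, seed = 1)
  expect_lt(max(abs(si$S1 - 0.25)), 0.05)
  expect_lt(max(abs(si$ST - 0.25)), 0.05)
  expect_lt(max(abs(si$S2), na.rm = TRUE), 0.05)
  expect_lt(abs(si$S_res), 0.1)
})

test_that("Sobol' estimators pass the Ishigami oracle", {
  a <- 7; b <- 0.1
  f <- function(X) {
    Z <- -pi + 2 * pi * X
    sin(Z[, 1]) + a * sin(Z[, 2])^2 + b * Z[, 3]^4 * sin(Z[, 1])
  }
  # closed-form variance components
  V1 <- 0.5 * (1 + b * pi^4 / 5)^2
  V2 <- a^2 / 8
  V13 <- b^2 * pi^8 * (1 / 18 - 1 / 50)
  V <- V1 + V2 + V13
  si <- sobol_indices(f, k = 3, n_base = 2048, n_boot = 100, seed = 2)
  expect_lt(abs(si$S1[1] - V1 / V), 0.06)
  expect_lt(abs(si$S1[2] - V2 / V), 0.06)
  expect_lt(abs(si$S1[3]), 0.06)
  expect_lt(abs(si$ST[1] - (V1 + V13) / V), 0.06)
  expect_lt(abs(si$ST[2] - V2 / V), 0.06)
  expect_lt(abs(si$ST[3] - V13 / V), 0.06)
  expect_lt(abs(si$S2[1, 3] - V13 / V), 0.1)
  expect_lt(abs(si$S2[1, 2]), 0.1)
})

test_that("task Sobol' runs produce coherent index tables", {
  s <- run_sobol("sor", 2, n_base = 128, n_runs = 2, n_boot = 50, seed = 6)
  idx <- s$indices
  expect_equal(idx$parameter, c("pd1", "pd2", "l_plus", "l_minus"))
  # total effects bound first-order effects up to estimator noise
  expect_true(all(idx$ST >= idx$S1 - 2 * (idx$S1_ci + idx$ST_ci)))
  expect_equal(nrow(s$second_order), 6)
  expect_true(all(is.finite(idx$S1)))
})

test_that("RR variance attribution is delay-stable in rank order", {
  s2 <- run_sobol("rr", 2, n_base = 512, n_runs = 1, n_boot = 0, seed = 10)
  s8 <- run_sobol("rr", 8, n_base = 512, n_runs = 1, n_boot = 0, seed = 10)
  expect_identical(order(s2$indices$ST), order(s8$indices$ST))
})

test_that("factorial effects match a brute-force regression", {
  f <- run_local_factorial("sor", 2)
  expect_equal(nrow(f$effects), 15)
  expect_equal(sum(f$effects$sst_share), 1, tolerance = 1e-9)
  expect_gt(f$min_ratio, 1)
  # brute force: linear model on the +/-1 coded corners
  signs <- as.data.frame(as.matrix(expand.grid(rep(list(c(-1, 1)), 4))))
  names(signs) <- c("pd1", "pd2", "l_plus", "l_minus")
  theta <- sweep(1.1^as.matrix(signs), 2,
                 c(0.1, 0.02, 0.25, 0.025), `*`)
  colnames(theta) <- names(signs)
  pk <- conceptual_peaks(theta)
  y <- pk[, "novel"] - pk[, "recent_in_place"]
  lmfit <- stats::lm(y ~ (pd1 + pd2 + l_plus + l_minus)^4, data = signs)
  co <- coef(lmfit)[-1]
  got <- setNames(f$effects$effect, gsub(" x ", ":", f$effects$term))
  expect_equal(got[names(co)], co, tolerance = 1e-10)
})

test_that("a flat response yields zero effects, an additive one no interactions", {
  signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), 4)))
  colnames(signs) <- c("pd1", "pd2", "l_plus", "l_minus")
  dec <- soprec:::factorial_decompose(signs, rep(0.3, 16))
  expect_true(all(dec$effect == 0))
  expect_true(all(dec$sst_share == 0))
  y_add <- signs %*% c(1, 2, -1, 0.5)
  dec <- soprec:::factorial_decompose(signs, drop(y_add))
  inter <- grepl(":", dec$term)
  expect_true(all(abs(dec$effect[inter]) < 1e-12))
  expect_equal(sum(dec$sst_share[!inter]), 1, tolerance = 1e-12)
})
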