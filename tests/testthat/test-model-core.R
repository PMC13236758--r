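test_that("effective p1 is gated by stimulus presence", {
  expect_equal(effective_p1(0.75, TRUE), 0.75)
  expect_equal(effective_p1(0.75, FALSE), 0)
  expect_equal(effective_p1(0, TRUE), 0)
  expect_error(effective_p1(1.2, TRUE))
})

test_that("p2 aggregates net associations and truncates to [0, 1]", {
  links <- data.frame(source = c("x", "y"), target = c("P", "P"),
                      v_plus = c(0.4, 0), v_minus = c(0, 0.3))
  expect_equal(compute_p2("P", links, c(x = 0.5, y = 0.2)), 0.14)
  # pure inhibition cannot push p2 below zero
  inhib <- data.frame(source = "x", target = "P", v_plus = 0, v_minus = 0.5)
  expect_equal(compute_p2("P", inhib, c(x = 1)), 0)
  # upper clamp
  strong <- data.frame(source = c("x", "y"), target = c("P", "P"),
                       v_plus = c(0.9, 0.8), v_minus = c(0, 0))
  expect_equal(compute_p2("P", strong, c(x = 1, y = 1)), 1)
  # a context missing from the A1 map contributes nothing
  expect_equal(compute_p2("P", links, c(x = 0.5)), 0.2)
  # no links targeting the object
  expect_equal(compute_p2("Z", links, c(x = 0.5)), 0)
})

test_that("p2 stays in [0, 1] and is 0 under pure inhibition (random draws)", {
  set.seed(42)
  for (i in 1:200) {
    nc <- sample(1:4, 1)
    links <- data.frame(source = paste0("c", 1:nc), target = "P",
                        v_plus = runif(nc, 0, 3), v_minus = runif(nc, 0, 3))
    a1 <- setNames(runif(nc), links$source)
    p2 <- compute_p2("P", links, a1)
    expect_gte(p2, 0); expect_lte(p2, 1)
    neg <- links
    neg$v_plus <- pmin(neg$v_plus, neg$v_minus)  # net <= 0 on every link
    expect_identical(compute_p2("P", neg, a1), 0)
  }
})

test_that("state derivatives conserve occupancy and match hand arithmetic", {
  nodes <- data.frame(id = "P", role = "object",
                      p1 = 0.75, pd1 = 0.1, pd2 = 0.02)
  no_links <- data.frame(source = character(), target = character(),
                         v_plus = numeric(), v_minus = numeric())
  # rest is a fixed point when everything is off
  rest <- data.frame(id = "P", I = 1, A1 = 0, A2 = 0)
  d <- state_derivatives(rest, nodes, no_links, active = character())
  expect_equal(unlist(d[, c("dI", "dA1", "dA2")]), c(dI = 0, dA1 = 0, dA2 = 0))
  # onset from rest routes I into A1 at rate p1
  d <- state_derivatives(rest, nodes, no_links, active = "P")
  expect_equal(d$dI, -0.75); expect_equal(d$dA1, 0.75); expect_equal(d$dA2, 0)
  # decay arithmetic with the stimulus off
  st <- data.frame(id = "P", I = 0, A1 = 0.4, A2 = 0.6)
  d <- state_derivatives(st, nodes, no_links, active = character())
  expect_equal(d$dI, 0.012); expect_equal(d$dA1, -0.04)
  expect_equal(d$dA2, 0.028)
})

test_that("derivatives sum to zero for random states, including p2 routing", {
  set.seed(7)
  nodes <- data.frame(id = c("x", "P"), role = c("context", "object"),
                      p1 = c(0.25, 0.75), pd1 = 0.1, pd2 = 0.02)
  for (i in 1:100) {
    a <- runif(2); b <- runif(2) * (1 - a)
    st <- data.frame(id = c("x", "P"), I = 1 - a - b, A1 = a, A2 = b)
    links <- data.frame(source = "x", target = "P",
                        v_plus = runif(1, 0, 2), v_minus = runif(1, 0, 2))
    d <- state_derivatives(st, nodes, links,
                           active = sample(c("x", "P"), sample(0:2, 1)))
    expect_equal(d$dI + d$dA1 + d$dA2, c(0, 0), tolerance = 1e-14)
  }
})

test_that("learning derivatives pair context A1 with object A1/A2", {
  links <- data.frame(source = "x", target = "P")
  st <- data.frame(id = c("x", "P"), A1 = c(1, 1), A2 = c(0, 0))
  d <- learning_derivatives(links, st, l_plus = 0.25, l_minus = 0.025)
  expect_equal(d$dVp, 0.25); expect_equal(d$dVm, 0)
  st <- data.frame(id = c("x", "P"), A1 = c(0.5, 0), A2 = c(0, 0.8))
  d <- learning_derivatives(links, st, l_plus = 0.25, l_minus = 0.025)
  expect_equal(d$dVp, 0); expect_equal(d$dVm, 0.01)
  st <- data.frame(id = c("x", "P"), A1 = c(0, 1), A2 = c(0, 0))
  d <- learning_derivatives(links, st, l_plus = 0.25, l_minus = 0.025)
  expect_equal(c(d$dVp, d$dVm), c(0, 0))
})

test_that("net association is the difference of the accumulators", {
  expect_equal(net_association(0.3, 0.1), 0.2)
  expect_equal(net_association(0, 0), 0)
  expect_equal(net_association(0.1, 0.4), -0.3)
  expect_error(net_association(-0.1, 0))
})

test_that("trajectories conserve occupancy and accumulators never decrease", {
  set.seed(3)
  for (i in 1:5) {
    par <- sop_params(pd1 = runif(1, 0.01, 0.5), pd2 = runif(1, 0.005, 0.2),
                      l_plus = runif(1, 0, 0.5), l_minus = runif(1, 0, 0.1))
    tr <- sop_simulate(paired_schedule(80, 80), par)
    tot <- apply(tr$node_states, c(1, 2), sum)
    expect_lt(max(abs(tot - 1)), 1e-9)
    expect_gte(min(tr$node_states), -1e-12)
    expect_lte(max(tr$node_states), 1 + 1e-12)
    expect_true(all(diff(tr$link_states[, 1, "v_plus"]) >= -1e-15))
    expect_true(all(diff(tr$link_states[, 1, "v_minus"]) >= -1e-15))
    expect_equal(tr$n_clamped, 0)
  }
})

test_that("context dynamics are unaffected by links (context passivity)", {
  sched <- paired_schedule(60, 40)
  with_links <- sop_simulate(sched, sop_params())
  alone <- sop_schedule(
    nodes = data.frame(id = "x", role = "context"),
    events = data.frame(stimulus = "x", start = 0, end = 60),
    test_windows = data.frame(object = character(), start = integer(),
                              end = integer()),
    n_steps = 100)
  ctx_alone <- sop_simulate(alone, sop_params())
  expect_equal(with_links$node_states[, "x", ], ctx_alone$node_states[, "x", ],
               tolerance = 1e-15)
})
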