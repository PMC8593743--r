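# independent frontier reference: greedy minimum-ICUR walk from the least-cost
# point (textbook construction of the efficiency frontier)
reference_frontier <- function(cost, qaly) {
  n <- length(cost)
  strictly_dominated <- vapply(seq_len(n), function(i)
    any(cost <= cost[i] & qaly >= qaly[i] &
          (cost < cost[i] | qaly > qaly[i])), TRUE)
  frontier <- integer(0)
  cand <- which(!strictly_dominated)
  cur <- cand[which.min(cost[cand])]
  frontier <- cur
  repeat {
    ahead <- cand[qaly[cand] > qaly[cur] & cost[cand] > cost[cur]]
    if (!length(ahead)) break
    ic <- (cost[ahead] - cost[cur]) / (qaly[ahead] - qaly[cur])
    cur <- ahead[which.min(ic)]
    frontier <- c(frontier, cur)
  }
  list(frontier = sort(frontier), strictly_dominated = which(strictly_dominated))
}

fake_arms <- function(cost, qaly)
  lapply(seq_along(cost), function(i)
    list(strategy = sprintf("s%02d", i), total_cost = cost[i],
         total_qaly = qaly[i]))

test_that("incremental cost-utility ratios preserve sign and flag ties", {
  expect_equal(icur(100, 1.0, 50, 0.5), 100)
  expect_true(is.na(icur(10, 1, 20, 1)))
  expect_equal(icur(42696, 1.582, 39930, 1.568), 2766 / 0.014)
  expect_lt(icur(42384, 1.554, 39930, 1.568), 0)  # dominated comparator
})

test_that("a single strategy forms the whole frontier", {
  fr <- classify_strategies(fake_arms(100, 1))
  expect_equal(fr$status, "frontier")
  expect_true(is.na(fr$icur_vs_next_on_frontier))
})

test_that("base-case classification reproduces the reference dominance pattern", {
  fr <- classify_strategies(evaluate_all_arms(base_cfg))
  status <- setNames(fr$status, fr$strategy)
  expect_setequal(fr$strategy[fr$status == "frontier"],
                  c("tildrakizumab", "secukinumab", "risankizumab"))
  expect_equal(unname(status[c("adalimumab", "etanercept", "ustekinumab")]),
               rep("strictly_dominated", 3))
  expect_true(all(status[c("guselkumab", "ixekizumab")] != "frontier"))
  expect_equal(fr$strategy[1], "tildrakizumab")  # least cost
})

test_that("classification matches the brute-force reference on random point sets", {
  set.seed(42)
  for (rep in 1:50) {
    n <- sample(3:8, 1)
    cost <- round(runif(n, 1000, 9000))
    qaly <- round(runif(n, 0.5, 2.5), 3)
    fr <- classify_strategies(fake_arms(cost, qaly))
    ref <- reference_frontier(cost, qaly)
    got_frontier <- sort(match(fr$strategy[fr$status == "frontier"],
                               sprintf("s%02d", seq_len(n))))
    got_strict <- sort(match(fr$strategy[fr$status == "strictly_dominated"],
                             sprintf("s%02d", seq_len(n))))
    expect_equal(got_frontier, ref$frontier)
    expect_equal(got_strict, sort(ref$strictly_dominated))
  }
})

test_that("frontier invariants hold", {
  fr <- classify_strategies(evaluate_all_arms(base_cfg))
  onf <- fr[fr$status == "frontier", ]
  expect_true(all(diff(onf$cost) > 0))
  expect_true(all(diff(onf$qaly) > 0))
  ic <- onf$icur_vs_next_on_frontier[-1]
  expect_true(all(diff(ic) > 0 | length(ic) < 2))
  # least-cost strategy always on the frontier
  expect_equal(fr$status[which.min(fr$cost)], "frontier")
})

test_that("classification is invariant to cost translation and QALY scaling", {
  arms <- evaluate_all_arms(base_cfg)
  fr0 <- classify_strategies(arms)
  shifted <- lapply(arms, function(a) {
    a$total_cost <- a$total_cost + 5000
    a$total_qaly <- a$total_qaly * 3.7
    a
  })
  fr1 <- classify_strategies(shifted)
  expect_equal(fr1$status, fr0$status)
  expect_equal(fr1$strategy, fr0$strategy)
})
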