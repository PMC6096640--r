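test_that("identity-by-state coancestry closed forms", {
  # fully homozygous individual: every X entry is +/-1 -> self-coancestry 1
  M <- rbind(hom = c(0, 2, 0, 2), het = c(1, 1, 1, 1))
  C <- ibs_coancestry(M)
  expect_equal(unname(C["hom", "hom"]), 1.0)
  expect_equal(unname(C["het", "het"]), 0.5)
  # 4-marker hand example
  M2 <- rbind(a = c(0, 2, 1, 2), b = c(2, 2, 1, 0))
  expect_equal(unname(ibs_coancestry(M2)["a", "b"]), 0.375)
  expect_error(ibs_coancestry(matrix(numeric(0), 0, 0)), "non-empty")
  expect_error(ibs_coancestry(rbind(c(0, 3))), "0, 1 or 2")
})

test_that("plan evaluation matches closed forms and a loop oracle", {
  # single pair, one cross: gain is the mid-parent value
  cand <- tibble::tibble(id = c("f", "m"), gebv = c(1, 3),
                         pool = c("female", "male"))
  C <- matrix(c(0.8, 0.2, 0.2, 0.6), 2, 2, dimnames = list(c("f", "m"), c("f", "m")))
  prob <- ocs_problem(cand, C, n_crosses = 1)
  ev <- evaluate_plan(setNames(c(1L, 1L), c("f", "m")), prob)
  expect_equal(ev$gain, 2)
  expect_equal(ev$group_coancestry, (0.8 + 2 * 0.2 + 0.6) / 4)

  prob6 <- small_problem(seed = 7, n_per_pool = 3, n_crosses = 2)
  n <- setNames(c(2L, 0L, 0L, 1L, 1L, 0L), prob6$candidates$id)
  ev6 <- evaluate_plan(n, prob6)
  x <- unname(n[prob6$candidates$id]) / 4
  loop <- 0
  for (i in 1:6) for (j in 1:6) loop <- loop + x[i] * x[j] * prob6$C[i, j]
  expect_equal(ev6$group_coancestry, loop)
  expect_equal(ev6$gain, sum(x * prob6$candidates$gebv))

  # equal breeding values make the gain plan-invariant
  cand_eq <- dplyr::mutate(prob6$candidates, gebv = 1.5)
  prob_eq <- ocs_problem(cand_eq, prob6$C, n_crosses = 2)
  n2 <- setNames(c(1L, 1L, 0L, 0L, 1L, 1L), cand_eq$id)
  expect_equal(evaluate_plan(n, prob_eq)$gain, 1.5)
  expect_equal(evaluate_plan(n2, prob_eq)$gain, 1.5)
})

test_that("plan invariants are enforced", {
  prob <- small_problem(seed = 8, n_per_pool = 3, n_crosses = 2)
  ids <- prob$candidates$id
  expect_error(evaluate_plan(setNames(c(2L, 1L, 0L, 1L, 0L, 0L), ids), prob),
               class = "twopartsim_infeasible")  # sum != 2 n_c
  expect_error(evaluate_plan(setNames(c(5L, 0L, -1L, 1L, 1L, 0L), ids), prob),
               class = "twopartsim_infeasible")  # bounds
  expect_error(evaluate_plan(setNames(c(2L, 1L, 1L, 0L, 0L, 0L), ids), prob),
               class = "twopartsim_infeasible")  # pool imbalance
  expect_error(ocs_problem(prob$candidates, prob$C, n_crosses = 20),
               class = "twopartsim_infeasible")  # capacity
})

test_that("optimizer endpoints match the exhaustive oracle", {
  prob <- small_problem(seed = 42)
  oracle <- enumerate_ocs(prob)
  p0 <- ocs_optimize(prob, degrees = 0, seed = 1)
  expect_equal(attr(p0, "evaluation")$gain, oracle$max_gain, tolerance = 1e-12)
  p90 <- ocs_optimize(prob, degrees = 90, seed = 1)
  expect_equal(attr(p90, "evaluation")$group_coancestry, oracle$min_cbar,
               tolerance = 1e-9)
})

test_that("intermediate-degree plans are not Pareto-dominated by any enumerated plan", {
  prob <- small_problem(seed = 43, n_per_pool = 6, n_crosses = 3)
  oracle <- enumerate_ocs(prob)
  for (deg in c(20, 45, 70)) {
    plan <- ocs_optimize(prob, degrees = deg, seed = deg)
    ev <- attr(plan, "evaluation")
    dominated <- any(oracle$gain > ev$gain + 1e-9 &
                       oracle$cbar < ev$group_coancestry - 1e-9)
    expect_false(dominated)
  }
})

test_that("optimized plans beat 1000 random feasible plans", {
  prob <- small_problem(seed = 44, n_per_pool = 8, n_crosses = 6)
  set.seed(45)
  random_plan <- function() {
    n <- integer(nrow(prob$candidates))
    for (p in c("female", "male")) {
      idx <- sample(which(prob$candidates$pool == p))
      left <- prob$n_crosses
      for (i in idx) {
        if (left == 0) break
        take <- sample.int(min(4, left), 1)
        n[i] <- take; left <- left - take
      }
    }
    n
  }
  rand <- replicate(1000, {
    n <- random_plan()
    x <- n / (2 * prob$n_crosses)
    c(gain = sum(x * prob$candidates$gebv),
      cbar = as.numeric(x %*% prob$C %*% x))
  })
  best_gain <- max(rand["gain", ])
  min_cbar <- min(rand["cbar", ])
  p0 <- ocs_optimize(prob, degrees = 0, seed = 46)
  p90 <- ocs_optimize(prob, degrees = 90, seed = 46)
  expect_gte(attr(p0, "evaluation")$gain, best_gain)
  expect_lte(attr(p90, "evaluation")$group_coancestry, min_cbar)
})

test_that("contributions are conserved and coancestry stays in [0, 1]", {
  for (seed in 1:5) {
    prob <- small_problem(seed = seed, n_per_pool = 5 + seed,
                          n_crosses = 2 + seed %% 3)
    plan <- ocs_optimize(prob, degrees = c(10, 30, 50, 70, 90)[seed], seed = seed)
    n <- contributions(plan)
    expect_equal(sum(n), 2 * prob$n_crosses)
    expect_true(all(n >= 0 & n <= prob$max_per_parent))
    expect_equal(nrow(plan), prob$n_crosses)
    ev <- attr(plan, "evaluation")
    expect_gte(ev$group_coancestry, 0)
    expect_lte(ev$group_coancestry, 1)
    expect_gte(ev$achieved_degrees, 0)
    expect_lte(ev$achieved_degrees, 90)
    # every cross pairs opposite pools
    pools <- setNames(prob$candidates$pool, prob$candidates$id)
    expect_true(all(pools[plan$female] == "female"))
    expect_true(all(pools[plan$male] == "male"))
  }
})

test_that("achieved coancestry decreases as penalty degrees increase", {
  prob <- small_problem(seed = 47)
  degs <- c(1, seq(5, 85, 10))
  cbars <- vapply(degs, function(d) {
    attr(ocs_optimize(prob, degrees = d, seed = 48), "evaluation")$group_coancestry
  }, numeric(1))
  # non-increasing within DE noise
  expect_true(all(diff(cbars) <= 1e-6))
})

test_that("the default degree sweep uses the 18-point grid", {
  grid <- eval(formals(ocs_frontier)$degrees)
  expect_equal(grid, c(1, seq(5, 85, by = 5)))
  expect_length(grid, 18)
  prob <- small_problem(seed = 49, n_per_pool = 4, n_crosses = 2)
  fr <- ocs_frontier(prob, degrees = c(5, 45, 85), seed = 50)
  expect_equal(nrow(fr), 3)
  expect_true(all(diff(fr$group_coancestry) <= 1e-9))
})

test_that("truncation plans select the top candidates with even contributions", {
  set.seed(60)
  cand <- tibble::tibble(id = sprintf("c%03d", 1:640), gebv = rnorm(640))
  plan <- truncation_plan(cand, n_parents = 32, n_crosses = 64)
  n <- contributions(plan)
  expect_equal(sum(n > 0), 32)
  expect_true(all(n[n > 0] == 4))   # 64 crosses / 32 parents: 4 each
  # sort oracle with deterministic tie-breaking
  expected <- cand$id[order(-cand$gebv, cand$id)][1:32]
  expect_setequal(names(n[n > 0]), expected)

  plan2 <- truncation_plan(cand, n_parents = 128, n_crosses = 64)
  n2 <- contributions(plan2)
  expect_true(all(n2[n2 > 0] == 1))  # 128 parents: 1 cross each
  expect_equal(sum(n2), 128)
  expect_false(anyDuplicated(paste(plan2$female, plan2$male)) > 0)

  expect_error(truncation_plan(cand, n_parents = 33, n_crosses = 64), "even")
  expect_error(truncation_plan(cand, n_parents = 10, n_crosses = 64),
               class = "twopartsim_infeasible")
  expect_error(truncation_plan(cand[1:10, ], n_parents = 32, n_crosses = 64),
               class = "twopartsim_infeasible")
})
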