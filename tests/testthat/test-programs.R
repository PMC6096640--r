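test_that("the budget planner reproduces the per-cycle characteristics", {
  b4 <- plan_budget(4)
  expect_equal(unlist(b4[, c("crosses", "candidates", "min_parents", "max_parents")]),
               c(crosses = 16, candidates = 160, min_parents = 8, max_parents = 32))
  b1 <- plan_budget(1)
  expect_equal(b1$crosses, 64)
  expect_equal(b1$candidates, 640)
  expect_equal(b1$min_parents, 32)
  expect_equal(b1$max_parents, 128)
  b3 <- plan_budget(3)
  expect_equal(unname(unlist(b3[, 2:5])), c(22, 214, 12, 44))
  # unconstrained costs keep the full per-cycle numbers
  bu <- plan_budget(6, constrained = FALSE)
  expect_equal(bu$crosses, 64)
  expect_equal(bu$candidates, 640)
  expect_error(plan_budget(0), class = "twopartsim_config_error")
  expect_error(plan_budget(7), class = "twopartsim_config_error")
})

test_that("burn-in is deterministic and sets up standardization and training", {
  cfg <- tiny_config()
  s1 <- run_burnin(cfg, seed = 5)
  s2 <- run_burnin(cfg, seed = 5)
  expect_identical(s1$headrow$pop$haplo, s2$headrow$pop$haplo)
  expect_identical(dplyr::bind_rows(s1$metrics_raw), dplyr::bind_rows(s2$metrics_raw))
  # training set: training_years x (preliminary + advanced + elite) records
  expect_equal(n_records(s1$training), 2 * (100 + 10 + 5))
  expect_true(all(s1$training$records$stage %in%
                    c("preliminary", "advanced", "elite")))
  # reference year standardizes to mean 0, SD 1, genic SD 1
  series <- twopartsim:::finalize_series(s1, from_year = cfg$burnin$years)
  ref <- series[series$year == cfg$burnin$years, ]
  expect_equal(ref$value[ref$metric == "gain"], 0)
  expect_equal(ref$value[ref$metric == "genetic_sd"], 1)
  expect_equal(ref$value[ref$metric == "genic_sd"], 1)
})

test_that("conventional programs advance the pipeline and grow the training set", {
  cfg <- tiny_config()
  burn <- run_burnin(cfg, seed = 6)
  n0 <- n_records(burn$training)
  set.seed(61)
  res <- run_conventional(burn, "ConvH", years = 3)
  st <- attr(res, "state")
  expect_equal(n_records(st$training), n0 + 3 * cfg$pd$n_preliminary)
  expect_equal(st$year, cfg$burnin$years + 3)
  # series covers reference + evaluation years, with accuracy recorded
  gain <- res[res$metric == "gain", ]
  expect_equal(gain$year, cfg$burnin$years + 0:3)
  acc <- res$value[res$metric == "accuracy" & res$year > cfg$burnin$years]
  expect_true(all(is.finite(acc)))
  expect_true(all(acc > -1 & acc < 1))
})

test_that("selection produces positive expected gain in the conventional program", {
  cfg <- tiny_config()
  final_gain <- vapply(1:4, function(r) {
    burn <- run_burnin(cfg, seed = 100 + r)
    set.seed(200 + r)
    res <- run_conventional(burn, "Conv", years = 4)
    g <- res[res$metric == "gain", ]
    g$value[which.max(g$year)]
  }, numeric(1))
  expect_gt(mean(final_gain), 0)
})

test_that("two-part programs respect the per-cycle budget and parent counts", {
  cfg <- tiny_config()
  burn <- run_burnin(cfg, seed = 7)
  for (sel in c("TS", "TS+")) {
    k <- 4
    set.seed(70)
    res <- run_two_part(burn, sel, k = k, years = 2)
    st <- attr(res, "state")
    ped <- dplyr::bind_rows(st$pedigree)
    pi_rows <- ped[ped$type == "pi_cross" & ped$year > cfg$burnin$years, ]
    budget <- plan_budget(k)
    # per-cycle candidate production matches the budget for every cycle
    pi_rows$cycle <- sub("^Y\\d+C(\\d+).*$", "\\1", pi_rows$id)
    counts <- table(pi_rows$year, pi_rows$cycle)
    expect_true(all(counts == budget$candidates))
    expect_equal(ncol(counts), k)
    # parents per cycle: TS uses the minimum, TS+ the maximum
    expected_parents <- if (sel == "TS") budget$min_parents else budget$max_parents
    for (yr in unique(pi_rows$year)) {
      for (cy in unique(pi_rows$cycle)) {
        sub <- pi_rows[pi_rows$year == yr & pi_rows$cycle == cy, ]
        expect_equal(length(unique(c(sub$mother, sub$father))), expected_parents)
      }
    }
  }
})

test_that("every product-development line traces to germplasm at most one year old", {
  cfg <- tiny_config()
  burn <- run_burnin(cfg, seed = 8)
  set.seed(80)
  res <- run_two_part(burn, "TS", k = 2, years = 3)
  st <- attr(res, "state")
  ped <- dplyr::bind_rows(st$pedigree)
  yr0 <- cfg$burnin$years
  # PD crossing blocks in evaluation years draw on current PI candidates
  f1 <- ped[ped$type == "f1" & ped$year > yr0 + 1, ]
  pi_ids <- ped$id[ped$type == "pi_cross"]
  pi_year <- setNames(ped$year[ped$type == "pi_cross"], pi_ids)
  expect_true(all(c(f1$mother, f1$father) %in% pi_ids))
  expect_true(all(f1$year - pi_year[f1$mother] <= 1))
  expect_true(all(f1$year - pi_year[f1$father] <= 1))
  # every DH line's parent is an F1 of the previous year
  dh <- ped[ped$type == "dh" & ped$year > yr0 + 1, ]
  f1_year <- setNames(ped$year[ped$type == "f1"], ped$id[ped$type == "f1"])
  expect_true(all(dh$year - f1_year[dh$mother] == 1))
})

test_that("scenario grids aggregate replicates and reproduce exactly under a seed", {
  cfg <- tiny_config()
  scen <- tibble::tibble(scenario = "Conv", program = "conventional",
                         variant = "Conv", selection = NA, k = NA,
                         constrained = TRUE, degrees = NA)
  r1 <- run_scenario_grid(scen, cfg, replicates = 2, years = 2, seed = 9)
  r2 <- run_scenario_grid(scen, cfg, replicates = 2, years = 2, seed = 9)
  expect_identical(as.data.frame(r1), as.data.frame(r2))
  expect_setequal(unique(r1$replicate), 1:2)
  agg <- summarize_replicates(r1)
  one <- agg[agg$metric == "gain" & agg$year == max(agg$year), ]
  byhand <- mean(r1$value[r1$metric == "gain" & r1$year == max(r1$year)])
  expect_equal(one$mean, byhand)
  expect_true(all(c("lo", "hi", "n") %in% names(agg)))
})

test_that("the best penalty degrees per cycle number are identified from results", {
  res <- tibble::tibble(
    replicate = rep(1:2, times = 6),
    scenario = rep(c("OCS4_15", "OCS4_45", "OCS6_45"), each = 4),
    year = rep(c(29, 30), 6),
    metric = "gain",
    value = c(1, 5, 1.2, 5.1, 1, 7, 1.1, 7.2, 1, 6, 1, 6.1)
  )
  dmap <- tibble::tibble(scenario = c("OCS4_15", "OCS4_45", "OCS6_45"),
                         k = c(4, 4, 6), degrees = c(15, 45, 45))
  best <- best_ocs_degrees(res, dmap)
  expect_equal(best$degrees[best$k == 4], 45)
  expect_equal(best$degrees[best$k == 6], 45)
})

test_that("program estimates return one row per scenario and replicate", {
  cfg <- tiny_config()
  scen <- comparison_scenarios("core")[c(1, 4), ]  # Conv and OCS_k4
  res <- run_scenario_grid(scen, cfg, replicates = 2, years = 4, seed = 10)
  est <- program_estimates(res)
  expect_equal(nrow(est), 4)
  expect_true(all(c("Ne", "efficiency", "delta_C") %in% names(est)))
})
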