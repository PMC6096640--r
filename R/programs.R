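#' Per-cycle budget of the population improvement component
#'
#' With constrained costs a fixed yearly genotyping budget of 64 crosses and
#' 640 selection candidates is split over the `k` recurrent selection cycles
#' per year: crosses = ceiling(64 / k), candidates = ceiling(640 / k),
#' minimum parents = 2 ceiling(crosses / 4) (every parent at the 4-cross
#' cap) and maximum parents = 2 crosses (every parent in a single cross).
#' With unconstrained costs every cycle keeps 64 crosses and 640 candidates.
#'
#' @param k Recurrent selection cycles per year, 1 to 6.
#' @param constrained Constrained (default) or unconstrained costs.
#' @param crosses_per_year,candidates_per_year Yearly budget being split.
#' @return One-row tibble: `cycles`, `crosses`, `candidates`, `min_parents`,
#'   `max_parents`.
#' @examples
#' plan_budget(4) # 16 crosses, 160 candidates, 8 to 32 parents
#' @export
plan_budget <- function(k, constrained = TRUE, crosses_per_year = 64,
                        candidates_per_year = 640) {
  if (length(k) != 1 || is.na(k) || k < 1 || k > 6 || k != round(k)) {
    abort("k must be an integer between 1 and 6", class = "twopartsim_config_error")
  }
  crosses <- if (constrained) ceiling(crosses_per_year / k) else crosses_per_year
  candidates <- if (constrained) ceiling(candidates_per_year / k) else candidates_per_year
  tibble(cycles = as.integer(k), crosses = as.integer(crosses),
         candidates = as.integer(candidates),
         min_parents = 2L * as.integer(ceiling(crosses / 4)),
         max_parents = 2L * as.integer(crosses))
}

#' Configuration of a simulated breeding program
#'
#' Nested defaults for the genome, founders, trait, product-development
#' pipeline, population improvement and optimizer. Any block can be
#' partially overridden, e.g. `program_config(pd = list(dh_per_cross = 5))`.
#'
#' @param ... Named blocks overriding defaults (`genome`, `founders`,
#'   `burnin`, `pd`, `pi`, `ocs`).
#' @return A `program_config` list.
#' @export
program_config <- function(...) {
  cfg <- list(
    genome = list(n_chr = 10, n_causal = 100, n_marker = 100, length_morgans = 1),
    founders = list(n = 100, maf_floor = 0.05, generations = 10),
    burnin = list(years = 20, training_years = 3),
    pd = list(
      crosses = 64, parents = 32, dh_per_cross = 50,
      n_preliminary = 1000, n_advanced = 30, n_elite = 10,
      # entry-stage heritabilities relative to the initial genic variance
      h2 = c(headrow = 0.1, preliminary = 0.2, advanced = 0.5, elite = 2 / 3),
      weights = c(headrow = 1, preliminary = 2, advanced = 4, elite = 8)
    ),
    pi = list(n_init = 640, pd_parents = 32, pd_to_pi = 64),
    ocs = list(de = de_config(np = 24, generations = 200, stagnation = 60,
                              restarts = 1))
  )
  over <- list(...)
  for (nm in names(over)) {
    if (!nm %in% names(cfg)) {
      abort(sprintf("unknown config block '%s'", nm), class = "twopartsim_config_error")
    }
    cfg[[nm]] <- modifyList(cfg[[nm]], over[[nm]])
  }
  structure(cfg, class = "program_config")
}

#' @export
print.program_config <- function(x, ...) {
  cat("<program_config>\n")
  utils::str(unclass(x), max.level = 2, give.attr = FALSE)
  invisible(x)
}

# residual SD so that a stage has heritability h2 against the initial
# (reference) genic variance of 1 trait unit squared
stage_sd <- function(cfg, stage) {
  h2 <- cfg$pd$h2[[stage]]
  sqrt((1 - h2) / h2)
}

make_cohort <- function(state, pop, stage) {
  gv <- gv_vec(pop, state$trait)
  pheno <- gv + rnorm(n_ind(pop), 0, stage_sd(state$config, stage))
  list(pop = pop, gv = setNames(gv, pop$id), pheno = setNames(pheno, pop$id),
       stage = stage)
}

promote_cohort <- function(state, cohort, n, stage) {
  if (is.null(cohort)) return(NULL)
  n <- min(n, n_ind(cohort$pop))
  ord <- order(-cohort$pheno, names(cohort$pheno))
  make_cohort(state, cohort$pop[ord[seq_len(n)]], stage)
}

record_pedigree <- function(state, ids, mother, father, type) {
  state$pedigree[[length(state$pedigree) + 1L]] <-
    tibble(id = ids, mother = mother, father = father,
           year = state$year, type = type)
  state
}

record_metrics <- function(state, cohort_pop, gv, model, component) {
  acc <- NA_real_
  if (!is.null(model) && n_ind(cohort_pop) >= 3) {
    gebv <- predict(model, cohort_pop)$gebv
    acc <- gp_accuracy(gebv, gv)
  }
  state$metrics_raw[[length(state$metrics_raw) + 1L]] <- tibble(
    year = state$year, component = component,
    mean_gv = mean(gv), sd_gv = sd(gv),
    genic_var = pop_genic_variance(cohort_pop, state$trait),
    accuracy = acc
  )
  state
}

# advance the product-development pipeline by one year:
# elite <- advanced <- preliminary <- headrow <- DH(f1)
advance_pd <- function(state) {
  cfg <- state$config$pd
  new_elite <- promote_cohort(state, state$advanced, cfg$n_elite, "elite")
  new_advanced <- promote_cohort(state, state$preliminary, cfg$n_advanced, "advanced")
  new_preliminary <- promote_cohort(state, state$headrow, cfg$n_preliminary, "preliminary")
  new_headrow <- NULL
  if (!is.null(state$f1)) {
    nf1 <- n_ind(state$f1)
    pidx <- rep(seq_len(nf1), each = cfg$dh_per_cross)
    dh <- make_dh(state$f1, pidx,
                  ids = sprintf("Y%02dHR%05d", state$year, seq_along(pidx)),
                  cohort = sprintf("headrow_y%02d", state$year))
    state <- record_pedigree(state, dh$id, state$f1$id[pidx], state$f1$id[pidx], "dh")
    new_headrow <- make_cohort(state, dh, "headrow")
  }
  state$elite <- new_elite
  state$advanced <- new_advanced
  state$preliminary <- new_preliminary
  state$headrow <- new_headrow
  state
}

# phenotype/genotype records of the trial stages for the training set
cohort_records <- function(state, cohort) {
  w <- state$config$pd$weights[[cohort$stage]]
  list(
    records = tibble(id = cohort$pop$id, year = state$year,
                     stage = cohort$stage, weight = w,
                     phenotype = unname(cohort$pheno)),
    geno = marker_dosages(cohort$pop)
  )
}

append_records <- function(buffer, rec) {
  buffer$records[[length(buffer$records) + 1L]] <- rec$records
  buffer$geno[[length(buffer$geno) + 1L]] <- rec$geno
  buffer
}

# make one F1 per cross of a plan
make_f1 <- function(state, parent_pop, plan, tag = "F1") {
  mi <- match(plan$female, parent_pop$id)
  fi <- match(plan$male, parent_pop$id)
  ids <- sprintf("Y%02d%s%04d", state$year, tag, seq_len(nrow(plan)))
  f1 <- cross_batch(parent_pop, mi, fi, ids, cohort = sprintf("%s_y%02d", tag, state$year))
  list(pop = f1, state = record_pedigree(state, ids, plan$female, plan$male,
                                         tolower(tag)))
}

# parent selection + new crossing block of the conventional program
conventional_crossing <- function(state, variant) {
  cfg <- state$config$pd
  pools <- switch(variant,
    Conv = purrr::compact(list(state$preliminary, state$advanced, state$elite)),
    ConvP = purrr::compact(list(state$preliminary)),
    ConvH = purrr::compact(list(state$headrow))
  )
  if (!length(pools)) {
    # pipeline not yet filled (early burn-in): random founder parents
    cand <- tibble(id = state$founders$id, gebv = runif(n_ind(state$founders)))
    parent_pop <- state$founders
  } else {
    parent_pop <- bind_pops(lapply(pools, function(co) co$pop))
    if (variant == "Conv") {
      cand <- tibble(id = parent_pop$id,
                     gebv = unlist(lapply(pools, function(co) unname(co$pheno))))
    } else {
      cand <- predict(state$model, parent_pop)
      names(cand)[2] <- "gebv"
    }
  }
  n_par <- min(cfg$parents, 2L * floor(nrow(cand) / 2) )
  n_par <- max(n_par, 2L * ceiling(cfg$crosses / 4))
  plan <- truncation_plan(cand, n_parents = n_par, n_crosses = cfg$crosses)
  res <- make_f1(state, parent_pop, plan, tag = "F1")
  state <- res$state
  state$f1 <- res$pop
  state
}

retrain <- function(state) {
  if (is.null(state$training)) return(state)
  model <- tryCatch(train_gp(state$training),
                    twopartsim_estimation_failure = function(e) {
                      warn("model retraining failed; keeping previous model")
                      state$model
                    })
  state$model <- model
  state
}

#' Run the 20-year phenotypic burn-in
#'
#' Simulates founders, an additive trait, and `years` of the conventional
#' program with phenotypic selection. The last `training_years` of trial
#' records (preliminary, advanced and elite stages) initialise the genomic
#' selection training set, and the final year's headrow-entry DH cohort
#' provides the standardization constants (mean and SD of true genetic
#' values, genic variance) used by all later comparisons.
#'
#' @param config A [program_config()].
#' @param seed Integer seed; identical seeds give identical states.
#' @return A `program_state`.
#' @export
run_burnin <- function(config = program_config(), seed = 1) {
  set.seed(seed)
  map <- genetic_map(config$genome$n_chr, config$genome$n_causal,
                     config$genome$n_marker, config$genome$length_morgans)
  founders <- sim_founders(config$founders$n, map,
                           maf_floor = config$founders$maf_floor,
                           n_generations = config$founders$generations)
  state <- structure(list(
    year = 0L, config = config, map = map,
    trait = sim_trait(founders),
    founders = founders, f1 = NULL,
    headrow = NULL, preliminary = NULL, advanced = NULL, elite = NULL,
    model = NULL, training = NULL, pi_pop = NULL,
    metrics_raw = list(), pedigree = list(), ref = NULL
  ), class = "program_state")

  buffer <- list(records = list(), geno = list())
  burn_years <- config$burnin$years
  collect_from <- burn_years - config$burnin$training_years + 1L
  for (yr in seq_len(burn_years)) {
    state$year <- yr
    state <- advance_pd(state)
    if (!is.null(state$headrow)) {
      state <- record_metrics(state, state$headrow$pop, unname(state$headrow$gv),
                              NULL, "pd")
    }
    if (yr >= collect_from) {
      for (co in purrr::compact(list(state$preliminary, state$advanced, state$elite))) {
        buffer <- append_records(buffer, cohort_records(state, co))
      }
    }
    state <- conventional_crossing(state, "Conv")
  }
  state$training <- training_set(dplyr::bind_rows(buffer$records),
                                 do.call(rbind, buffer$geno))
  hr <- state$headrow
  state$ref <- list(mean = mean(hr$gv), sd = sd(hr$gv),
                    genic_var = pop_genic_variance(hr$pop, state$trait))
  state
}

#' @export
print.program_state <- function(x, ...) {
  cat(sprintf("<program_state> year %d; training %s records; PI %s\n",
              x$year,
              if (is.null(x$training)) 0 else n_records(x$training),
              if (is.null(x$pi_pop)) "uninitialised" else
                sprintf("%d candidates", n_ind(x$pi_pop))))
  invisible(x)
}

# turn accumulated raw metrics into the standardized per-year series
finalize_series <- function(state, from_year) {
  raw <- dplyr::bind_rows(state$metrics_raw)
  raw <- raw[raw$year >= from_year, ]
  ref <- state$ref
  rel_var <- raw$genic_var / ref$genic_var
  out <- tibble(
    year = raw$year, component = raw$component,
    gain = (raw$mean_gv - ref$mean) / ref$sd,
    genetic_sd = raw$sd_gv / ref$sd,
    genic_var = rel_var,
    genic_sd = sqrt(rel_var),
    accuracy = raw$accuracy
  )
  out <- tidyr::pivot_longer(out,
                             cols = c("gain", "genetic_sd", "genic_var",
                                      "genic_sd", "accuracy") |> unique(),
                             names_to = "metric", values_to = "value")
  out$metric <- ifelse(out$component == "pi", paste0("pi_", out$metric),
                       out$metric)
  out <- dplyr::select(out, "year", "metric", "value")
  class(out) <- c("metrics_series", class(out))
  out
}

#' Continue a program with conventional selection
#'
#' Advances the product-development pipeline yearly. Parents of the new
#' crossing block are selected phenotypically from the trial stages (Conv),
#' or by GEBV among the preliminary-trial entries (ConvP) or the
#' headrow-stage DH lines (ConvH); the genomic selection model is retrained
#' once per year from the growing training set. Metrics are recorded on the
#' headrow-entry DH cohort, standardized against the burn-in reference.
#'
#' @param state A post-burn-in `program_state`.
#' @param variant One of "Conv", "ConvP", "ConvH".
#' @param years Evaluation years to simulate.
#' @return A `metrics_series` tibble (year, metric, value), including the
#'   reference year; the final state is attached as attribute `state`.
#' @export
run_conventional <- function(state, variant = c("Conv", "ConvP", "ConvH"),
                             years = 10) {
  variant <- match.arg(variant)
  if (is.null(state$ref)) abort("burn-in must be completed first")
  ref_year <- state$year
  for (yr in seq_len(years)) {
    state$year <- state$year + 1L
    if (variant != "Conv") state <- retrain(state)
    state <- advance_pd(state)
    state <- record_metrics(state, state$headrow$pop, unname(state$headrow$gv),
                            state$model, "pd")
    rec <- cohort_records(state, state$preliminary)
    state$training <- update_training(state$training, rec$records, rec$geno)
    state <- conventional_crossing(state, variant)
  }
  out <- finalize_series(state, ref_year)
  attr(out, "state") <- state
  out
}

pi_candidate_gebv <- function(state, pop) {
  pred <- predict(state$model, pop)
  tibble(id = pop$id, gebv = pred$gebv)
}

# one population-improvement cycle: plan crosses among the candidate pool
# and replace the candidates with the progeny
pi_cycle <- function(state, pool_pop, selection, budget, degrees, cycle) {
  cand <- pi_candidate_gebv(state, pool_pop)
  plan <- switch(selection,
    TS = truncation_plan(cand, n_parents = budget$min_parents,
                         n_crosses = budget$crosses),
    `TS+` = truncation_plan(cand, n_parents = budget$max_parents,
                            n_crosses = budget$crosses),
    OCS = {
      C <- ibs_coancestry(marker_dosages(pool_pop))
      prob <- ocs_problem(cand, C, n_crosses = budget$crosses)
      tryCatch(
        ocs_optimize(prob, degrees = degrees, de = state$config$ocs$de),
        twopartsim_infeasible = function(e) {
          warn("infeasible OCS cycle; falling back to truncation selection")
          truncation_plan(cand, n_parents = budget$max_parents,
                          n_crosses = budget$crosses)
        })
    })
  nc <- nrow(plan)
  per_cross <- rep(budget$candidates %/% nc, nc)
  extra <- budget$candidates %% nc
  if (extra > 0) per_cross[seq_len(extra)] <- per_cross[seq_len(extra)] + 1L
  mothers <- rep(match(plan$female, pool_pop$id), per_cross)
  fathers <- rep(match(plan$male, pool_pop$id), per_cross)
  ids <- sprintf("Y%02dC%dPI%04d", state$year, cycle, seq_along(mothers))
  progeny <- cross_batch(pool_pop, mothers, fathers, ids,
                         cohort = sprintf("pi_y%02dc%d", state$year, cycle))
  state <- record_pedigree(state, ids, pool_pop$id[mothers],
                           pool_pop$id[fathers], "pi_cross")
  state$pi_pop <- progeny
  state
}

#' Continue a program as a two-part program
#'
#' Splits the program into a population-improvement (PI) component running
#' `k` recurrent genomic selection cycles per year and a product-development
#' (PD) component identical to the conventional pipeline. Once per year the
#' top PI germplasm seeds the PD crossing block, current PD headrow lines
#' become eligible as PI candidates (first cycle of the year), the model is
#' retrained, and the training set grows with the new preliminary-trial
#' records. Metrics are recorded on the headrow-entry DH cohort and, under
#' `pi_`-prefixed names, on the PI candidates.
#'
#' @param state A post-burn-in `program_state`.
#' @param selection "TS" (truncation, minimum parents), "TS+" (truncation,
#'   maximum parents) or "OCS" (optimal cross selection).
#' @param k Recurrent selection cycles per year (1 to 6).
#' @param constrained Constrained or unconstrained yearly budget.
#' @param degrees Penalty degrees for OCS.
#' @param years Evaluation years to simulate.
#' @return A `metrics_series` tibble; final state attached as attribute
#'   `state`.
#' @export
run_two_part <- function(state, selection = c("TS", "TS+", "OCS"), k = 1,
                         constrained = TRUE, degrees = 45, years = 10) {
  selection <- match.arg(selection)
  if (is.null(state$ref)) abort("burn-in must be completed first")
  budget <- plan_budget(k, constrained)
  ref_year <- state$year
  for (yr in seq_len(years)) {
    state$year <- state$year + 1L
    state <- retrain(state)
    if (is.null(state$pi_pop)) {
      # initialise PI from the best current headrow germplasm
      cand <- pi_candidate_gebv(state, state$headrow$pop)
      n_init <- min(state$config$pi$n_init, nrow(cand))
      top <- cand$id[order(-cand$gebv, cand$id)][seq_len(n_init)]
      state$pi_pop <- state$headrow$pop[top]
    }
    # PD crossing block seeded by the top PI germplasm
    pd_cand <- pi_candidate_gebv(state, state$pi_pop)
    n_par <- min(state$config$pi$pd_parents, 2L * floor(nrow(pd_cand) / 2))
    pd_plan <- truncation_plan(pd_cand, n_parents = n_par,
                               n_crosses = state$config$pd$crosses)
    res <- make_f1(state, state$pi_pop, pd_plan, tag = "F1")
    state <- res$state
    new_f1 <- res$pop
    state <- advance_pd(state)
    state$f1 <- new_f1
    state <- record_metrics(state, state$headrow$pop, unname(state$headrow$gv),
                            state$model, "pd")
    rec <- cohort_records(state, state$preliminary)
    state$training <- update_training(state$training, rec$records, rec$geno)
    # k population-improvement cycles; PD lines join the pool once a year
    for (cyc in seq_len(k)) {
      pool_pop <- state$pi_pop
      if (cyc == 1L && !is.null(state$headrow)) {
        hr_cand <- pi_candidate_gebv(state, state$headrow$pop)
        n_pd <- min(state$config$pi$pd_to_pi, nrow(hr_cand))
        top_pd <- hr_cand$id[order(-hr_cand$gebv, hr_cand$id)][seq_len(n_pd)]
        pool_pop <- bind_pops(state$pi_pop, state$headrow$pop[top_pd],
                              cohort = pool_pop$cohort)
      }
      state <- pi_cycle(state, pool_pop, selection, budget, degrees, cyc)
    }
    state <- record_metrics(state, state$pi_pop,
                            gv_vec(state$pi_pop, state$trait),
                            state$model, "pi")
  }
  out <- finalize_series(state, ref_year)
  attr(out, "state") <- state
  out
}

#' Run a replicate x scenario grid
#'
#' Each replicate shares one burn-in across all scenarios; scenarios then
#' diverge with scenario-specific random streams derived deterministically
#' from the root seed.
#'
#' @param scenarios Tibble with columns `scenario` (label), `program`
#'   ("conventional" or "two_part"), and the per-program fields `variant`,
#'   `selection`, `k`, `constrained`, `degrees` (unused fields may be `NA`).
#' @param config A [program_config()].
#' @param replicates Number of replicates.
#' @param years Evaluation years.
#' @param seed Root seed; all child streams derive from it.
#' @return A `scenario_results` tibble: `replicate`, `scenario`, `year`,
#'   `metric`, `value`.
#' @export
run_scenario_grid <- function(scenarios, config = program_config(),
                              replicates = 10, years = 10, seed = 1) {
  scenarios <- as_tibble(scenarios)
  out <- vector("list", replicates * nrow(scenarios))
  pos <- 0L
  for (r in seq_len(replicates)) {
    burn <- run_burnin(config, seed = child_seed(seed, r))
    for (s in seq_len(nrow(scenarios))) {
      sc <- scenarios[s, ]
      set.seed(child_seed(child_seed(seed, r), 1000 + s))
      series <- tryCatch(
        if (sc$program == "conventional") {
          run_conventional(burn, variant = sc$variant, years = years)
        } else {
          run_two_part(burn, selection = sc$selection, k = sc$k,
                       constrained = isTRUE(sc$constrained),
                       degrees = if (is.null(sc$degrees) || is.na(sc$degrees)) 45
                                 else sc$degrees,
                       years = years)
        },
        error = function(e) {
          warn(sprintf("scenario '%s' replicate %d failed: %s",
                       sc$scenario, r, conditionMessage(e)))
          NULL
        })
      if (is.null(series)) next
      attr(series, "state") <- NULL  # keep only the series; states are large
      pos <- pos + 1L
      out[[pos]] <- dplyr::mutate(as_tibble(series), replicate = r,
                                  scenario = sc$scenario, .before = 1)
    }
  }
  res <- dplyr::bind_rows(out[seq_len(pos)])
  class(res) <- c("scenario_results", class(res))
  res
}

#' Canonical comparison scenarios
#'
#' The scenario sets used throughout the package to compare selection
#' methods under constrained costs: "core" covers the four-cycle programs
#' (Conv, TS, TS+, OCS, k = 4), "full" adds the cycle-number sweep (TS and
#' OCS at k = 1, 4, 6). The OCS penalty degrees are per cycle number - 14
#' degrees at one cycle, 45 at four, 49 at six: more cycles per year
#' compound the per-cycle coancestry budget and therefore need a more
#' conservative angle to maximise long-term gain.
#'
#' @param kind "core" or "full".
#' @return Scenario tibble for [run_scenario_grid()].
#' @export
comparison_scenarios <- function(kind = c("core", "full")) {
  kind <- match.arg(kind)
  conv <- tibble(scenario = "Conv", program = "conventional", variant = "Conv",
                 selection = NA_character_, k = NA_integer_,
                 constrained = TRUE, degrees = NA_real_)
  two <- function(sel, k, degrees = 45) {
    tibble(scenario = sprintf("%s_k%d", sub("\\+", "plus", sel), k),
           program = "two_part", variant = NA_character_, selection = sel,
           k = k, constrained = TRUE, degrees = degrees)
  }
  core <- dplyr::bind_rows(conv, two("TS", 4), two("TS+", 4),
                           two("OCS", 4, degrees = 45))
  if (kind == "core") return(core)
  dplyr::bind_rows(core, two("TS", 1), two("TS", 6),
                   two("OCS", 1, degrees = 14), two("OCS", 6, degrees = 49))
}

#' Per-scenario diversity and efficiency estimates
#'
#' For every (scenario, replicate) pair, estimates the realized effective
#' population size from the genic-variance decay and the efficiency of
#' converting genetic diversity into genetic gain from the gain/diversity
#' trajectory.
#'
#' @param results A `scenario_results` tibble from [run_scenario_grid()].
#' @return Tibble: `scenario`, `replicate`, `delta_C`, `Ne`, `efficiency`.
#' @export
program_estimates <- function(results) {
  wide <- tidyr::pivot_wider(
    results[results$metric %in% c("gain", "genic_sd", "genic_var"), ],
    names_from = "metric", values_from = "value")
  dplyr::group_modify(
    dplyr::group_by(wide, .data$scenario, .data$replicate),
    function(df, key) {
      df <- df[order(df$year), ]
      ne <- tryCatch(glance(estimate_ne(df[, c("year", "genic_var")],
                                        var_col = "genic_var")),
                     error = function(e) tibble(delta_C = NA_real_, Ne = NA_real_))
      eff <- tryCatch(
        glance(estimate_efficiency(
          tibble(gain = df$gain, diversity_loss = 1 - df$genic_sd)))$efficiency,
        error = function(e) NA_real_)
      tibble(delta_C = ne$delta_C, Ne = ne$Ne, efficiency = eff)
    }) |> dplyr::ungroup()
}

#' Penalty degrees that maximise final-year gain
#'
#' For grids whose OCS scenarios carry a `degrees` column in their labels,
#' returns, per grouping column, the degrees with the largest mean
#' final-year gain.
#'
#' @param results A `scenario_results` tibble whose scenario labels are of
#'   the form "OCS<k>_<degrees>".
#' @param degrees_map Tibble mapping `scenario` to `degrees` (and optional
#'   grouping columns such as `k`).
#' @return Tibble of the best degrees per group.
#' @export
best_ocs_degrees <- function(results, degrees_map) {
  final <- results[results$metric == "gain", ]
  final <- final[final$year == max(final$year), ]
  final <- dplyr::summarise(dplyr::group_by(final, .data$scenario),
                            gain = mean(.data$value), .groups = "drop")
  merged <- dplyr::inner_join(final, degrees_map, by = "scenario")
  grp <- setdiff(names(degrees_map), c("scenario", "degrees"))
  merged <- dplyr::group_by(merged, dplyr::across(dplyr::all_of(grp)))
  dplyr::ungroup(dplyr::slice_max(merged, .data$gain, n = 1, with_ties = FALSE))
}
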