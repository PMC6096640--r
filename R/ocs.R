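#' Identity-by-state coancestry from marker dosages
#'
#' C = (1 + X X' / n_m) / 2 with X = M - 1, where M is the individuals x
#' markers dosage matrix coded 0/1/2. C_jk is the proportion of marker
#' alleles identical by state between j and k; the diagonal is
#' (1 + fraction of homozygous loci) / 2.
#'
#' @param M Dosage matrix (individuals x markers, entries 0/1/2), or a data
#'   frame with an `id` column followed by dosage columns.
#' @return Symmetric coancestry matrix with entries in \[0, 1\].
#' @examples
#' M <- rbind(a = c(0, 2, 1, 2), b = c(2, 2, 1, 0))
#' ibs_coancestry(M)["a", "b"] # 0.375
#' @export
ibs_coancestry <- function(M) {
  if (is.data.frame(M)) {
    ids <- M$id
    M <- as.matrix(M[, setdiff(names(M), "id"), drop = FALSE])
    rownames(M) <- ids
  }
  if (!is.matrix(M) || nrow(M) == 0L || ncol(M) == 0L) {
    abort("dosage matrix must be non-empty")
  }
  if (!all(M %in% c(0, 1, 2))) abort("dosages must be coded 0, 1 or 2")
  X <- M - 1
  C <- (1 + tcrossprod(X) / ncol(M)) / 2
  dimnames(C) <- list(rownames(M), rownames(M))
  C
}

#' Define an optimal cross selection problem
#'
#' @param candidates Tibble/data frame with columns `id`, `gebv` and
#'   optionally `pool` ("female"/"male"). Without a `pool` column,
#'   candidates are assigned to pools by alternating GEBV rank (sensible for
#'   hermaphroditic plants where pools are a crossing-design device).
#' @param coancestry Coancestry matrix over the candidates (rows/columns in
#'   candidate order, or named by id).
#' @param n_crosses Number of crosses n_c in the plan.
#' @param max_per_parent Maximum crosses per selected parent (default 4; the
#'   minimum for a selected parent is 1 by construction).
#' @return An `ocs_problem`.
#' @export
ocs_problem <- function(candidates, coancestry, n_crosses, max_per_parent = 4) {
  candidates <- as_tibble(candidates)
  if (!all(c("id", "gebv") %in% names(candidates))) {
    abort("candidates need columns id and gebv")
  }
  n <- nrow(candidates)
  if (!is.null(rownames(coancestry)) && !identical(rownames(coancestry), candidates$id)) {
    idx <- match(candidates$id, rownames(coancestry))
    if (anyNA(idx)) abort("coancestry matrix lacks some candidate ids")
    coancestry <- coancestry[idx, idx]
  }
  if (!identical(dim(coancestry), c(n, n) + 0L) && !identical(dim(coancestry), c(n, n))) {
    abort("coancestry must be n x n over the candidates")
  }
  if (max(abs(coancestry - t(coancestry))) > 1e-8) abort("coancestry must be symmetric")
  if (min(coancestry) < -1e-8 || max(coancestry) > 1 + 1e-8) {
    abort("coancestry entries must lie in [0, 1]")
  }
  dg <- diag(coancestry)
  if (min(dg) < 0.5 - 1e-8 || max(dg) > 1 + 1e-8) {
    abort("self-coancestry must lie in [0.5, 1]")
  }
  if (!all(is.finite(candidates$gebv))) abort("breeding values must be finite")
  if (!"pool" %in% names(candidates)) {
    rank <- order(-candidates$gebv, candidates$id)
    pool <- character(n)
    pool[rank] <- rep(c("female", "male"), length.out = n)
    candidates$pool <- pool
  }
  if (!all(candidates$pool %in% c("female", "male"))) {
    abort("pool labels must be 'female' or 'male'")
  }
  sizes <- table(factor(candidates$pool, levels = c("female", "male")))
  if (any(sizes == 0)) abort("both pools must be non-empty")
  if (any(max_per_parent * sizes < n_crosses)) {
    abort(sprintf(
      "infeasible: %d crosses need at least %d parents per pool (cap %d per parent)",
      n_crosses, ceiling(n_crosses / max_per_parent), max_per_parent),
      class = "twopartsim_infeasible")
  }
  structure(list(candidates = candidates, C = unname(coancestry),
                 n_crosses = as.integer(n_crosses),
                 max_per_parent = as.integer(max_per_parent)),
            class = "ocs_problem")
}

#' @export
print.ocs_problem <- function(x, ...) {
  cat(sprintf("<ocs_problem> %d candidates (%d female / %d male), %d crosses, cap %d\n",
              nrow(x$candidates), sum(x$candidates$pool == "female"),
              sum(x$candidates$pool == "male"), x$n_crosses, x$max_per_parent))
  invisible(x)
}

# Build a cross_plan tibble from integer contributions + pairing keys.
# Female and male "slots" are ordered by key and paired; a repair sweep
# removes duplicate (female, male) pairs where possible.
new_cross_plan <- function(problem, n, keys = NULL, allow_duplicates = TRUE) {
  cand <- problem$candidates
  if (is.null(keys)) keys <- runif(nrow(cand))
  slots <- function(pool) {
    sel <- which(cand$pool == pool & n > 0)
    sel <- sel[order(keys[sel])]
    rep(sel, times = n[sel])
  }
  f <- slots("female")
  m <- slots("male")
  stopifnot(length(f) == problem$n_crosses, length(m) == problem$n_crosses)
  nc <- problem$n_crosses
  for (sweep in 1:50) {
    key <- paste(f, m)
    dup <- which(duplicated(key))
    if (!length(dup)) break
    for (j in dup) {
      for (j2 in seq_len(nc)) {
        if (j2 == j) next
        if (m[j2] != m[j] && f[j2] != f[j] &&
            !(paste(f[j], m[j2]) %in% key) && !(paste(f[j2], m[j]) %in% key)) {
          tmp <- m[j]; m[j] <- m[j2]; m[j2] <- tmp
          key <- paste(f, m)
          break
        }
      }
    }
    if (!anyDuplicated(paste(f, m))) break
  }
  if (!allow_duplicates && anyDuplicated(paste(f, m))) {
    abort("could not build a plan without duplicate crosses",
          class = "twopartsim_infeasible")
  }
  plan <- tibble(female = cand$id[f], male = cand$id[m])
  attr(plan, "contributions") <- setNames(as.integer(n), cand$id)
  attr(plan, "n_crosses") <- nc
  class(plan) <- c("cross_plan", class(plan))
  plan
}

#' Contributions of a cross plan
#' @param plan A `cross_plan`.
#' @return Named integer vector of per-candidate contributions n (crosses
#'   per parent); x = n / (2 n_c).
#' @export
contributions <- function(plan) attr(plan, "contributions")

#' Evaluate a cross plan
#'
#' Expected genetic gain a_bar = x' a and group coancestry (expected
#' inbreeding of the next generation) c_bar = x' C x, with x = n / (2 n_c).
#' When anchor solutions are available (attached by [ocs_optimize()] or
#' passed explicitly) the normalized coordinates and achieved penalty
#' degrees are reported as well.
#'
#' @param plan A `cross_plan` (or named integer contribution vector).
#' @param problem The `ocs_problem`.
#' @param anchors Optional anchors list as attached by [ocs_optimize()].
#' @return One-row tibble: `gain`, `group_coancestry`, `gain_norm`,
#'   `coancestry_norm`, `achieved_degrees`.
#' @export
evaluate_plan <- function(plan, problem, anchors = NULL) {
  n <- if (is.numeric(plan)) plan else contributions(plan)
  if (is.null(anchors) && !is.numeric(plan)) anchors <- attr(plan, "anchors")
  cand <- problem$candidates
  if (!is.null(names(n))) n <- n[cand$id]
  if (length(n) != nrow(cand) || anyNA(n)) abort("contributions do not match candidates")
  if (sum(n) != 2L * problem$n_crosses) {
    abort("contributions must sum to 2 * n_crosses", class = "twopartsim_infeasible")
  }
  if (any(n < 0 | n > problem$max_per_parent)) {
    abort("contributions outside [0, max_per_parent]", class = "twopartsim_infeasible")
  }
  for (p in c("female", "male")) {
    if (sum(n[cand$pool == p]) != problem$n_crosses) {
      abort("each pool must contribute one parent slot per cross",
            class = "twopartsim_infeasible")
    }
  }
  x <- n / (2 * problem$n_crosses)
  gain <- sum(x * cand$gebv)
  cbar <- as.numeric(x %*% problem$C %*% x)
  gn <- cn <- deg <- NA_real_
  if (!is.null(anchors)) {
    gn <- normalize(gain, anchors$gain90, anchors$gain0)
    cn <- normalize(cbar, anchors$c90, anchors$c0)
    deg <- 180 / pi * acos(pmin(pmax(cn, 0), 1))
  }
  tibble(gain = gain, group_coancestry = cbar,
         gain_norm = gn, coancestry_norm = cn, achieved_degrees = deg)
}

normalize <- function(v, lo, hi) {
  if (abs(hi - lo) < 1e-12) return(0) else (v - lo) / (hi - lo)
}

#' Differential-evolution settings
#'
#' @param np Population size.
#' @param F_weight Differential weight F.
#' @param CR Crossover rate. The default is deliberately low: a genotype has
#'   two dimensions per candidate, and coordinate-sparse trial vectors climb
#'   the decoded allocation landscape far more reliably than near-complete
#'   crossover.
#' @param generations Maximum generations.
#' @param stagnation Early stop after this many generations without
#'   improvement of the best solution.
#' @param penalty_mult Multiplier on the positive excess of normalized group
#'   coancestry over the degree target.
#' @param restarts Independent optimizer runs; the best solution is kept.
#'   Restarts decorrelate the integer local optima the search can settle
#'   into.
#' @return A `de_config` list.
#' @export
de_config <- function(np = 40, F_weight = 0.7, CR = 0.1, generations = 1000,
                      stagnation = 200, penalty_mult = 10, restarts = 2) {
  structure(list(np = np, F_weight = F_weight, CR = CR,
                 generations = generations, stagnation = stagnation,
                 penalty_mult = penalty_mult, restarts = restarts),
            class = "de_config")
}

# exact greedy maximal-gain allocation (optimal for a linear objective with
# a per-parent cap): fill top-GEBV candidates of each pool at the cap
greedy_max_gain <- function(problem) {
  cand <- problem$candidates
  n <- integer(nrow(cand))
  for (p in c("female", "male")) {
    idx <- which(cand$pool == p)
    idx <- idx[order(-cand$gebv[idx], cand$id[idx])]
    left <- problem$n_crosses
    i <- 1L
    while (left > 0) {
      take <- min(left, problem$max_per_parent)
      n[idx[i]] <- take
      left <- left - take
      i <- i + 1L
    }
  }
  n
}

pool_code <- function(problem) {
  as.integer(problem$candidates$pool == "male")
}

#' Optimal cross selection
#'
#' Jointly optimises integer parental contributions (0 to `max_per_parent`
#' crosses per parent) and cross allocation between the female and male
#' pools. The balance between expected genetic gain and group coancestry is
#' set by penalty degrees: 0 degrees returns the maximal-gain solution
#' (truncation-equivalent), 90 degrees the minimal group-coancestry
#' solution, and intermediate angles target a normalized coancestry of
#' cos(degrees) between the two anchor solutions, enforced as a penalty in
#' the differential-evolution fitness.
#'
#' @param problem An `ocs_problem`.
#' @param degrees Penalty degrees in \[0, 90\].
#' @param de A `de_config`.
#' @param seed Optional integer seed (results are deterministic given the
#'   seed).
#' @param allow_duplicates Allow repeated (female, male) pairs in the plan
#'   (a repeated pair means the same cross is made more than once).
#' @return A `cross_plan` with attributes `evaluation` (see
#'   [evaluate_plan()]) and `anchors`.
#' @export
ocs_optimize <- function(problem, degrees = 45, de = de_config(), seed = NULL,
                         allow_duplicates = TRUE) {
  if (!is.null(seed)) set.seed(seed)
  if (degrees < 0 || degrees > 90) abort("degrees must lie in [0, 90]")
  a <- problem$candidates$gebv
  C <- problem$C
  pool <- pool_code(problem)
  nc <- problem$n_crosses
  cap <- problem$max_per_parent

  n0 <- greedy_max_gain(problem)
  e0 <- cpp_ocs_decode(as.numeric(n0), a, C, pool, nc, cap)
  # equal-spread genotype: contributions as even as the pools allow
  spread <- numeric(length(n0))
  for (p in c(0L, 1L)) {
    idx <- which(pool == p)
    spread[idx] <- nc / length(idx)
  }
  warm <- function(...) {
    rows <- list(...)
    do.call(rbind, lapply(rows, function(s) c(s, runif(length(s)))))
  }
  de_run <- function(mode, gain_off = 0, gain_scl = 1, c_off = 0, c_scl = 1,
                     c_target = 0, mult = 0, init) {
    best <- NULL
    for (r in seq_len(max(1L, de$restarts %||% 1L))) {
      cand <- cpp_ocs_de(a, C, pool, nc, cap, mode = mode,
                         gain_off = gain_off, gain_scl = gain_scl,
                         c_off = c_off, c_scl = c_scl,
                         c_target = c_target, mult = mult,
                         np = de$np, Fw = de$F_weight, CR = de$CR,
                         gens = de$generations, stagnation = de$stagnation,
                         init = init)
      if (is.null(best) || cand$fitness > best$fitness) best <- cand
    }
    best
  }
  s90 <- de_run(mode = 1L, init = warm(spread, as.numeric(n0)))
  anchors <- list(gain0 = e0$gain, c0 = e0$coancestry,
                  gain90 = s90$gain, c90 = s90$coancestry)

  if (degrees <= 0) {
    n <- n0; keys <- runif(length(n0))
  } else if (degrees >= 90) {
    n <- s90$n; keys <- s90$keys
  } else {
    gden <- anchors$gain0 - anchors$gain90
    cden <- anchors$c0 - anchors$c90
    best <- de_run(mode = 2L,
                   gain_off = anchors$gain90,
                   gain_scl = if (abs(gden) > 1e-12) 1 / gden else 0,
                   c_off = anchors$c90,
                   c_scl = if (abs(cden) > 1e-12) 1 / cden else 0,
                   c_target = cos(degrees * pi / 180),
                   mult = de$penalty_mult,
                   init = warm(as.numeric(n0), as.numeric(s90$n), spread,
                               as.numeric(n0) * 0.5 + spread * 0.5))
    n <- best$n; keys <- best$keys
  }
  plan <- new_cross_plan(problem, n, keys, allow_duplicates = allow_duplicates)
  attr(plan, "anchors") <- anchors
  attr(plan, "degrees") <- degrees
  attr(plan, "evaluation") <- evaluate_plan(plan, problem, anchors = anchors)
  plan
}

#' Sweep a problem over a grid of penalty degrees
#'
#' @inheritParams ocs_optimize
#' @param degrees Degree grid; the default is the 18-point grid
#'   1, 5, 10, ..., 85.
#' @return Tibble of class `ocs_frontier`: one row per degree with gain,
#'   group coancestry and achieved degrees.
#' @export
ocs_frontier <- function(problem, degrees = c(1, seq(5, 85, by = 5)),
                         de = de_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  out <- purrr::map_dfr(degrees, function(d) {
    plan <- ocs_optimize(problem, degrees = d, de = de)
    ev <- attr(plan, "evaluation")
    dplyr::mutate(ev, degrees = d, .before = 1)
  })
  class(out) <- c("ocs_frontier", class(out))
  out
}

#' Truncation-selection crossing plan
#'
#' Selects the top `n_parents` candidates by GEBV (stable tie-break on id),
#' splits them into female/male pools by alternating rank, assigns each
#' parent an equal number of crosses (plus/minus one), and pairs the pools
#' at random without duplicate pairs.
#'
#' @param candidates Tibble with columns `id` and `gebv`.
#' @param n_parents Even number of parents in
#'   \[2 ceil(n_crosses / max_per_parent), 2 n_crosses\].
#' @param n_crosses Number of crosses.
#' @param max_per_parent Cap on crosses per parent.
#' @param seed Optional integer seed for the random pairing.
#' @param allow_duplicates Permit repeated (female, male) pairs. Pairing
#'   still avoids them where possible; with very few parents (fewer distinct
#'   pairs than crosses) repeats are unavoidable and mean the same cross is
#'   made more than once.
#' @return A `cross_plan`.
#' @export
truncation_plan <- function(candidates, n_parents, n_crosses,
                            max_per_parent = 4, seed = NULL,
                            allow_duplicates = TRUE) {
  if (!is.null(seed)) set.seed(seed)
  candidates <- as_tibble(candidates)
  if (n_parents %% 2 != 0) abort("n_parents must be even")
  if (n_parents < 2 * ceiling(n_crosses / max_per_parent) ||
      n_parents > 2 * n_crosses) {
    abort(sprintf("n_parents must lie in [%d, %d] for %d crosses",
                  2 * ceiling(n_crosses / max_per_parent), 2 * n_crosses,
                  n_crosses),
          class = "twopartsim_infeasible")
  }
  if (nrow(candidates) < n_parents) {
    abort("not enough candidates", class = "twopartsim_infeasible")
  }
  ord <- order(-candidates$gebv, candidates$id)
  sel <- candidates[ord[seq_len(n_parents)], ]
  sel$pool <- rep(c("female", "male"), length.out = n_parents)
  half <- n_parents / 2L
  contrib_per_parent <- function() {
    base <- n_crosses %/% half
    extra <- n_crosses %% half
    c(rep(base + 1L, extra), rep(base, half - extra))
  }
  n <- integer(n_parents)
  n[sel$pool == "female"] <- contrib_per_parent()
  n[sel$pool == "male"] <- contrib_per_parent()
  if (any(n > max_per_parent)) {
    abort("per-parent cap violated; increase n_parents",
          class = "twopartsim_infeasible")
  }
  prob <- ocs_problem(sel, diag(0.75, n_parents), n_crosses,
                      max_per_parent = max_per_parent)
  plan <- new_cross_plan(prob, n, keys = runif(n_parents),
                         allow_duplicates = allow_duplicates)
  attr(plan, "selected") <- sel$id
  plan
}
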