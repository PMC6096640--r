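# Shared fixtures and independent oracles used across the suite.

# A genetic map with arbitrary locus positions (Morgans) on one chromosome.
custom_map <- function(pos, chr_len, causal = rep(FALSE, length(pos)),
                       marker = !causal) {
  map <- tibble::tibble(chr = 1L, pos = pos,
                        id = sprintf("L%02d", seq_along(pos)),
                        causal = causal, marker = marker)
  attr(map, "chr_len") <- chr_len
  class(map) <- c("genetic_map", class(map))
  map
}

# A haplotype population from an explicit phased matrix (2 rows/individual).
pop_from_haplo <- function(haplo, map, ids = sprintf("I%02d", seq_len(nrow(haplo) / 2))) {
  twopartsim:::new_haplo_pop(haplo, ids, map)
}

# Small configuration that keeps whole-program runs fast. Budgets of the
# population-improvement component stay at their standard values.
tiny_config <- function(...) {
  program_config(
    genome = list(n_chr = 2, n_causal = 20, n_marker = 20),
    founders = list(n = 40, generations = 3),
    burnin = list(years = 6, training_years = 2),
    pd = list(crosses = 16, parents = 16, dh_per_cross = 10,
              n_preliminary = 100, n_advanced = 10, n_elite = 5),
    pi = list(n_init = 200, pd_parents = 16, pd_to_pi = 16),
    ocs = list(de = de_config(np = 16, generations = 60, stagnation = 25)),
    ...
  )
}

# --- exhaustive OCS oracle --------------------------------------------------
# Enumerates every feasible per-pool contribution vector (sum n_c, entries
# 0..cap). Gain and group coancestry depend only on contributions, so the
# enumeration covers every feasible plan.
compositions <- function(total, slots, cap) {
  if (slots == 1) {
    if (total <= cap) return(matrix(total, 1, 1)) else return(NULL)
  }
  do.call(rbind, lapply(0:min(cap, total), function(v) {
    m <- compositions(total - v, slots - 1, cap)
    if (is.null(m)) NULL else cbind(v, m, deparse.level = 0)
  }))
}

enumerate_ocs <- function(problem) {
  cand <- problem$candidates
  C <- problem$C
  nc <- problem$n_crosses
  cap <- problem$max_per_parent
  fidx <- which(cand$pool == "female")
  midx <- which(cand$pool == "male")
  cf <- compositions(nc, length(fidx), cap)
  cm <- compositions(nc, length(midx), cap)
  Xf <- cf / (2 * nc)
  Xm <- cm / (2 * nc)
  gf <- as.numeric(Xf %*% cand$gebv[fidx])
  gm <- as.numeric(Xm %*% cand$gebv[midx])
  qf <- rowSums((Xf %*% C[fidx, fidx, drop = FALSE]) * Xf)
  qm <- rowSums((Xm %*% C[midx, midx, drop = FALSE]) * Xm)
  cross <- 2 * (Xf %*% C[fidx, midx, drop = FALSE] %*% t(Xm))
  gain <- outer(gf, gm, "+")
  cbar <- outer(qf, qm, "+") + cross
  list(gain = gain, cbar = cbar,
       max_gain = max(gain), min_cbar = min(cbar),
       # fitness surface under the package's degree operationalisation,
       # recomputed here from the enumeration's own anchors
       best_fitness = function(target_deg, mult = 10) {
         gmax <- max(gain)
         cmin <- min(cbar)
         c_at_gmax <- min(cbar[gain >= gmax - 1e-12])
         g_at_cmin <- max(gain[cbar <= cmin + 1e-12])
         gn <- (gain - g_at_cmin) / (gmax - g_at_cmin)
         cn <- (cbar - cmin) / (c_at_gmax - cmin)
         fit <- gn - mult * pmax(0, cn - cos(target_deg * pi / 180))
         max(fit)
       })
}

# A reproducible small two-pool problem.
small_problem <- function(seed = 42, n_per_pool = 8, n_markers = 60, n_crosses = 4) {
  set.seed(seed)
  n <- 2 * n_per_pool
  M <- matrix(sample(0:2, n * n_markers, TRUE, prob = c(.3, .4, .3)), n, n_markers,
              dimnames = list(sprintf("c%02d", seq_len(n)), NULL))
  cand <- tibble::tibble(id = rownames(M), gebv = rnorm(n),
                         pool = rep(c("female", "male"), each = n_per_pool))
  ocs_problem(cand, ibs_coancestry(M), n_crosses = n_crosses)
}
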