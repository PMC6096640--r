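#' Build a genetic map
#'
#' Lays out causal and marker loci on `n_chr` chromosomes of equal genetic
#' length. Causal loci carry allele substitution effects of the simulated
#' trait; marker loci are the ones genotyped for genomic prediction and
#' identity-by-state coancestry. Within a chromosome the two sets are
#' interleaved at evenly spaced, strictly increasing positions.
#'
#' @param n_chr Number of chromosomes.
#' @param n_causal,n_marker Causal and marker loci per chromosome. A locus is
#'   either causal or a marker here; overlapping roles are not generated.
#' @param length_morgans Genetic length of each chromosome in Morgans.
#' @return A tibble of class `genetic_map` with columns `chr`, `pos`
#'   (Morgans within chromosome), `id`, `causal`, `marker`, and an attribute
#'   `chr_len` giving per-chromosome lengths.
#' @examples
#' map <- genetic_map(n_chr = 2, n_causal = 5, n_marker = 5)
#' @export
genetic_map <- function(n_chr = 10, n_causal = 100, n_marker = 100,
                        length_morgans = 1) {
  if (n_chr < 1 || (n_causal + n_marker) < 1) {
    abort("a genetic map needs at least one chromosome and one locus",
          class = "twopartsim_config_error")
  }
  one_chr <- function(chr) {
    pos_c <- if (n_causal > 0) (seq_len(n_causal) - 0.50) / n_causal * length_morgans else numeric()
    pos_m <- if (n_marker > 0) (seq_len(n_marker) - 0.25) / n_marker * length_morgans else numeric()
    pos <- c(pos_c, pos_m)
    causal <- rep(c(TRUE, FALSE), c(n_causal, n_marker))
    ord <- order(pos)
    tibble(
      chr = chr,
      pos = pos[ord],
      causal = causal[ord],
      marker = !causal[ord]
    )
  }
  map <- purrr::map_dfr(seq_len(n_chr), one_chr)
  map$id <- sprintf("C%02dL%04d", map$chr, stats::ave(map$chr, map$chr, FUN = seq_along))
  map <- map[, c("chr", "pos", "id", "causal", "marker")]
  attr(map, "chr_len") <- rep(length_morgans, n_chr)
  class(map) <- c("genetic_map", class(map))
  map
}

# first/last row index of each chromosome (map rows are ordered chr, pos)
map_bounds <- function(map) {
  idx <- split(seq_len(nrow(map)), map$chr)
  list(first = vapply(idx, min, integer(1)), last = vapply(idx, max, integer(1)))
}

#' @export
print.genetic_map <- function(x, ...) {
  cat(sprintf("<genetic_map> %d chromosomes, %d loci (%d causal, %d marker)\n",
              length(unique(x$chr)), nrow(x), sum(x$causal), sum(x$marker)))
  NextMethod()
}

new_haplo_pop <- function(haplo, ids, map, pool = NULL, cohort = NA_character_) {
  stopifnot(is.matrix(haplo), nrow(haplo) == 2L * length(ids))
  if (anyDuplicated(ids)) abort("individual ids must be unique")
  structure(
    list(haplo = haplo, id = as.character(ids), map = map,
         pool = pool, cohort = cohort),
    class = "haplo_pop"
  )
}

#' Number of individuals in a haplotype population
#' @param pop A `haplo_pop`.
#' @export
n_ind <- function(pop) length(pop$id)

#' @export
print.haplo_pop <- function(x, ...) {
  cat(sprintf("<haplo_pop> %d individuals x %d loci (cohort: %s)\n",
              n_ind(x), ncol(x$haplo), x$cohort %||% NA))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Subset a haplotype population
#' @param x A `haplo_pop`.
#' @param i Individual indices or ids.
#' @export
`[.haplo_pop` <- function(x, i) {
  if (is.character(i)) i <- match(i, x$id)
  if (anyNA(i)) abort("unknown individual id in subset")
  rows <- as.vector(rbind(2L * i - 1L, 2L * i))
  new_haplo_pop(x$haplo[rows, , drop = FALSE], x$id[i], x$map,
                pool = x$pool[i], cohort = x$cohort)
}

#' Combine haplotype populations sharing a map
#' @param ... `haplo_pop` objects on the same map.
#' @param cohort Cohort label of the combined population.
#' @export
bind_pops <- function(..., cohort = NA_character_) {
  pops <- list(...)
  if (length(pops) == 1L && is.list(pops[[1]]) && !inherits(pops[[1]], "haplo_pop")) {
    pops <- pops[[1]]
  }
  ids <- unlist(lapply(pops, function(p) p$id))
  if (anyDuplicated(ids)) abort("combined populations must have unique ids")
  pool <- unlist(lapply(pops, function(p) p$pool %||% rep(NA_character_, n_ind(p))))
  new_haplo_pop(do.call(rbind, lapply(pops, function(p) p$haplo)),
                ids, pops[[1]]$map, pool = pool, cohort = cohort)
}

#' Allele dosages of a population
#'
#' @param pop A `haplo_pop`.
#' @param loci Optional locus column indices (defaults to all loci).
#' @return Integer matrix, individuals x loci, entries 0/1/2, with individual
#'   ids as row names and locus ids as column names.
#' @export
dosages <- function(pop, loci = NULL) {
  h <- pop$haplo
  n <- n_ind(pop)
  d <- h[seq(1L, 2L * n, by = 2L), , drop = FALSE] +
    h[seq(2L, 2L * n, by = 2L), , drop = FALSE]
  dimnames(d) <- list(pop$id, pop$map$id)
  if (!is.null(loci)) d <- d[, loci, drop = FALSE]
  d
}

#' @rdname dosages
#' @export
marker_dosages <- function(pop) dosages(pop, loci = which(pop$map$marker))

#' Allele frequencies in a population
#' @param pop A `haplo_pop`.
#' @param loci Optional locus indices.
#' @return Numeric vector of per-locus allele frequencies.
#' @export
allele_freqs <- function(pop, loci = NULL) {
  h <- pop$haplo
  if (!is.null(loci)) h <- h[, loci, drop = FALSE]
  colMeans(h)
}

#' Per-individual heterozygosity
#' @param pop A `haplo_pop`.
#' @return Numeric vector, fraction of heterozygous loci per individual.
#' @export
heterozygosity <- function(pop) {
  d <- dosages(pop)
  rowMeans(d == 1L)
}

#' Simulate founder haplotypes
#'
#' Draws per-locus allele frequencies from U(`maf_floor`, 1 - `maf_floor`),
#' samples haplotypes as independent Bernoulli draws, and then performs
#' `n_generations` generations of random mating (selfing excluded) to build
#' linkage disequilibrium. Loci whose realized minor allele frequency falls
#' below `maf_floor` are resampled so every locus segregates.
#'
#' @param n_individuals Number of founders (>= 2).
#' @param map A `genetic_map`.
#' @param seed Optional integer seed; identical seeds give bit-identical
#'   populations.
#' @param maf_floor Minimum minor allele frequency retained (default 0.05).
#' @param n_generations Random-mating generations used to build LD.
#' @return A `haplo_pop` of founders.
#' @export
sim_founders <- function(n_individuals, map, seed = NULL, maf_floor = 0.05,
                         n_generations = 10) {
  if (!is.null(seed)) set.seed(seed)
  L <- nrow(map)
  if (is.null(L) || L < 1 || n_individuals < 2) {
    abort("founder simulation needs >= 2 individuals and >= 1 locus",
          class = "twopartsim_config_error")
  }
  p <- runif(L, maf_floor, 1 - maf_floor)
  haplo <- matrix(rbinom(2L * n_individuals * L, 1L, rep(p, each = 2L * n_individuals)),
                  nrow = 2L * n_individuals, ncol = L)
  pop <- new_haplo_pop(haplo, sprintf("FND%04d", seq_len(n_individuals)), map,
                       cohort = "founder")
  for (g in seq_len(n_generations)) {
    mothers <- sample.int(n_individuals, n_individuals, replace = TRUE)
    fathers <- sample.int(n_individuals, n_individuals, replace = TRUE)
    clash <- which(fathers == mothers)
    while (length(clash)) {
      fathers[clash] <- sample.int(n_individuals, length(clash), replace = TRUE)
      clash <- clash[fathers[clash] == mothers[clash]]
    }
    pop <- cross_batch(pop, mothers, fathers,
                       ids = sprintf("FND%04d", seq_len(n_individuals)),
                       cohort = "founder")
  }
  # resample loci drifted to (near) fixation so every locus segregates
  for (iter in seq_len(100)) {
    f <- allele_freqs(pop)
    bad <- which(pmin(f, 1 - f) < maf_floor)
    if (!length(bad)) break
    pb <- runif(length(bad), maf_floor, 1 - maf_floor)
    pop$haplo[, bad] <- matrix(
      rbinom(2L * n_individuals * length(bad), 1L, rep(pb, each = 2L * n_individuals)),
      nrow = 2L * n_individuals
    )
  }
  pop
}

# One progeny per (mother, father) pair; the vectorized meiosis entry point.
cross_batch <- function(pop, mothers, fathers, ids, pool = NULL, cohort = NA_character_) {
  b <- map_bounds(pop$map)
  mg <- cpp_gametes(pop$haplo, as.integer(mothers), pop$map$pos, b$first, b$last,
                    attr(pop$map, "chr_len"))
  fg <- cpp_gametes(pop$haplo, as.integer(fathers), pop$map$pos, b$first, b$last,
                    attr(pop$map, "chr_len"))
  n <- length(mothers)
  haplo <- matrix(0L, nrow = 2L * n, ncol = ncol(pop$haplo))
  haplo[seq(1L, 2L * n, by = 2L), ] <- mg
  haplo[seq(2L, 2L * n, by = 2L), ] <- fg
  new_haplo_pop(haplo, ids, pop$map, pool = pool, cohort = cohort)
}

#' Cross two individuals
#'
#' Each progeny receives one recombinant gamete from each parent. Crossover
#' counts per chromosome are Poisson with mean equal to the chromosome length
#' in Morgans and chiasma positions are uniform (the Haldane model).
#'
#' @param pop A `haplo_pop` containing both parents.
#' @param mother,father Parent id (or index). Selfing is rejected.
#' @param n_progeny Number of progeny.
#' @param ids Optional progeny ids.
#' @param cohort Cohort label for the progeny.
#' @return A `haplo_pop` of progeny.
#' @export
make_cross <- function(pop, mother, father, n_progeny, ids = NULL,
                       cohort = "cross") {
  mi <- if (is.character(mother)) match(mother, pop$id) else as.integer(mother)
  fi <- if (is.character(father)) match(father, pop$id) else as.integer(father)
  if (anyNA(c(mi, fi))) abort("unknown parent")
  if (mi == fi) abort("selfing is not allowed in generated crosses")
  if (is.null(ids)) ids <- sprintf("%s_x_%s_%03d", pop$id[mi], pop$id[fi],
                                   seq_len(n_progeny))
  cross_batch(pop, rep(mi, n_progeny), rep(fi, n_progeny), ids, cohort = cohort)
}

#' Produce doubled-haploid lines
#'
#' Each DH line is a single recombinant gamete doubled, hence fully
#' homozygous at every locus.
#'
#' @param pop A `haplo_pop` containing the parent.
#' @param parent Parent id or index (one individual), or a vector of parent
#'   indices with one DH per entry when `n_dh` is `NULL`.
#' @param n_dh Number of DH lines from the single parent.
#' @param ids Optional ids.
#' @param cohort Cohort label.
#' @return A `haplo_pop` of DH lines.
#' @export
make_dh <- function(pop, parent, n_dh = NULL, ids = NULL, cohort = "dh") {
  pi_ <- if (is.character(parent)) match(parent, pop$id) else as.integer(parent)
  if (anyNA(pi_)) abort("unknown parent")
  idx <- if (is.null(n_dh)) pi_ else rep(pi_[1], n_dh)
  b <- map_bounds(pop$map)
  g <- cpp_gametes(pop$haplo, idx, pop$map$pos, b$first, b$last,
                   attr(pop$map, "chr_len"))
  n <- nrow(g)
  haplo <- matrix(0L, nrow = 2L * n, ncol = ncol(g))
  haplo[seq(1L, 2L * n, by = 2L), ] <- g
  haplo[seq(2L, 2L * n, by = 2L), ] <- g
  if (is.null(ids)) ids <- sprintf("DH_%s_%04d", pop$id[idx[1]], seq_len(n))
  new_haplo_pop(haplo, ids, pop$map, cohort = cohort)
}

#' Simulate an additive trait architecture
#'
#' Draws allele substitution effects at the causal loci from N(0, 1) and
#' rescales them so the genic variance in `pop` equals `genic_var`.
#'
#' @param pop Reference `haplo_pop` (supplies causal allele frequencies).
#' @param seed Optional integer seed.
#' @param genic_var Target genic variance in `pop` (trait units squared).
#' @param intercept Trait intercept.
#' @return A `trait_arch` with fields `causal` (locus indices), `alpha`
#'   (substitution effects) and `intercept`.
#' @export
sim_trait <- function(pop, seed = NULL, genic_var = 1, intercept = 0) {
  if (!is.null(seed)) set.seed(seed)
  causal <- which(pop$map$causal)
  if (!length(causal)) abort("map has no causal loci", class = "twopartsim_config_error")
  alpha <- rnorm(length(causal))
  p <- allele_freqs(pop, causal)
  v0 <- genic_variance(p, alpha)
  if (v0 <= 0) abort("degenerate trait: zero genic variance in reference population")
  alpha <- alpha * sqrt(genic_var / v0)
  structure(list(causal = causal, alpha = alpha, intercept = intercept),
            class = "trait_arch")
}

#' @export
print.trait_arch <- function(x, ...) {
  cat(sprintf("<trait_arch> %d causal loci, intercept %.3g\n",
              length(x$causal), x$intercept))
  invisible(x)
}

# fast internal path: numeric vector of true genetic values
gv_vec <- function(pop, trait) {
  d <- dosages(pop, trait$causal)
  as.numeric(trait$intercept + d %*% trait$alpha)
}

#' True genetic values under an additive model
#'
#' value = intercept + sum over causal loci of dosage * effect.
#'
#' @param pop A `haplo_pop`.
#' @param trait A `trait_arch`.
#' @return A tibble with columns `id` and `gv`.
#' @export
genetic_values <- function(pop, trait) {
  tibble(id = pop$id, gv = gv_vec(pop, trait))
}

#' Genic variance
#'
#' The additive variance attributable to allele frequencies at the causal
#' loci, ignoring linkage disequilibrium and homozygosity excess:
#' 2 * sum p_i (1 - p_i) alpha_i^2. Its square root is the genic standard
#' deviation used to track genetic diversity.
#'
#' @param freqs Allele frequencies at the causal loci, each in \[0, 1\].
#' @param alpha Allele substitution effects, same length.
#' @return Genic variance (trait units squared).
#' @examples
#' genic_variance(c(0.5, 0.5), c(1, 1)) # == 1
#' @export
genic_variance <- function(freqs, alpha) {
  if (length(freqs) != length(alpha)) {
    abort("freqs and alpha must have the same length")
  }
  if (any(freqs < 0 | freqs > 1)) abort("allele frequencies must lie in [0, 1]")
  2 * sum(freqs * (1 - freqs) * alpha^2)
}

# genic variance of a population under a trait
pop_genic_variance <- function(pop, trait) {
  genic_variance(allele_freqs(pop, trait$causal), trait$alpha)
}

#' Export marker dosages as CSV
#'
#' Plain CSV, individuals x loci, dosages 0/1/2, first column `id`, header
#' row of locus ids; the format consumed by the stand-alone OCS command
#' line.
#'
#' @param pop A `haplo_pop`.
#' @param path Output file.
#' @param markers_only Export only marker loci (default) or all loci.
#' @export
export_dosages <- function(pop, path, markers_only = TRUE) {
  d <- if (markers_only) marker_dosages(pop) else dosages(pop)
  df <- data.frame(id = rownames(d), d, check.names = FALSE)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write/read phased haplotypes as CSV
#'
#' Layout: columns `id`, `phase` (1 or 2), then one 0/1 column per locus.
#'
#' @param pop A `haplo_pop`.
#' @param path File path.
#' @export
write_haplotypes <- function(pop, path) {
  df <- data.frame(id = rep(pop$id, each = 2L), phase = rep(1:2, n_ind(pop)),
                   pop$haplo, check.names = FALSE)
  names(df)[-(1:2)] <- pop$map$id
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_haplotypes
#' @param map The `genetic_map` the haplotypes were written under.
#' @export
read_haplotypes <- function(path, map) {
  df <- read.csv(path, check.names = FALSE)
  ids <- unique(df$id)
  h <- as.matrix(df[, -(1:2), drop = FALSE])
  storage.mode(h) <- "integer"
  dimnames(h) <- NULL
  new_haplo_pop(h, ids, map)
}
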