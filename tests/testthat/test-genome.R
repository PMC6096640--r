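test_that("founder simulation is deterministic and respects the MAF floor", {
  map <- genetic_map(n_chr = 10, n_causal = 50, n_marker = 50)
  p1 <- sim_founders(200, map, seed = 1)
  p2 <- sim_founders(200, map, seed = 1)
  expect_identical(p1$haplo, p2$haplo)
  expect_equal(n_ind(p1), 200)
  expect_equal(ncol(p1$haplo), 1000)
  f <- allele_freqs(p1)
  expect_true(all(pmin(f, 1 - f) >= 0.05))
  p3 <- sim_founders(200, map, seed = 2)
  expect_false(identical(p1$haplo, p3$haplo))
})

test_that("allele frequencies match a brute-force recount of the haplotypes", {
  map <- genetic_map(n_chr = 1, n_causal = 5, n_marker = 5)
  pop <- sim_founders(2, map, seed = 7)
  recount <- apply(pop$haplo, 2, function(col) sum(col) / length(col))
  expect_equal(unname(allele_freqs(pop)), unname(recount))
})

test_that("map construction validates its inputs", {
  expect_error(genetic_map(0, 10, 10), class = "twopartsim_config_error")
  map <- genetic_map(3, 7, 13, length_morgans = 2)
  for (ch in 1:3) {
    expect_true(all(diff(map$pos[map$chr == ch]) > 0))
  }
  expect_equal(sum(map$causal), 21)
  expect_equal(sum(map$marker), 39)
})

test_that("a fully homozygous parent transmits its haplotype exactly", {
  map <- genetic_map(1, 0, 20)
  hap <- rep(c(0L, 1L), 10)
  haplo <- rbind(hap, hap,            # homozygous mother
                 rbinom(20, 1, 0.5), rbinom(20, 1, 0.5))
  pop <- pop_from_haplo(haplo, map)
  set.seed(5)
  kids <- make_cross(pop, 1, 2, n_progeny = 30)
  for (i in seq_len(30)) {
    maternal <- kids$haplo[2L * i - 1L, ]
    expect_identical(unname(maternal), hap)
  }
})

test_that("progeny alleles are inherited from the parents at every locus", {
  map <- genetic_map(2, 10, 10)
  pop <- sim_founders(10, map, seed = 11)
  set.seed(12)
  kids <- make_cross(pop, 1, 2, n_progeny = 25)
  dos_par <- dosages(pop)[1:2, ]
  h1 <- pop$haplo[1:2, ]; h2 <- pop$haplo[3:4, ]
  for (i in seq_len(25)) {
    mat <- kids$haplo[2L * i - 1L, ]
    pat <- kids$haplo[2L * i, ]
    expect_true(all(mat == h1[1, ] | mat == h1[2, ]))
    expect_true(all(pat == h2[1, ] | pat == h2[2, ]))
  }
})

test_that("recombinant fraction follows the Haldane map function", {
  # two loci 1 Morgan apart: r = 0.5 (1 - exp(-2)) ~ 0.432
  map <- custom_map(pos = c(0.25, 1.25), chr_len = 1.5)
  haplo <- rbind(c(1L, 1L), c(0L, 0L))  # doubly heterozygous in coupling
  pop <- pop_from_haplo(haplo, map, ids = "P1")
  set.seed(99)
  n_gam <- 10000
  dh <- make_dh(pop, 1, n_dh = n_gam)
  g <- dosages(dh) / 2
  rec <- mean(g[, 1] != g[, 2])
  r_expect <- 0.5 * (1 - exp(-2))
  se <- sqrt(r_expect * (1 - r_expect) / n_gam)
  expect_lt(abs(rec - r_expect), 3 * se)
})

test_that("doubled haploids are fully homozygous and reproduce a homozygous parent", {
  map <- genetic_map(2, 10, 10)
  pop <- sim_founders(10, map, seed = 21)
  set.seed(22)
  dh <- make_dh(pop, 3, n_dh = 50)
  expect_equal(unname(heterozygosity(dh)), rep(0, 50))
  # fully homozygous parent -> all DH identical to it
  hom <- make_dh(dh, 1, n_dh = 10)
  for (i in 1:10) expect_identical(unname(hom$haplo[2L * i - 1L, ]),
                                   unname(dh$haplo[1, ]))
})

test_that("DH allele frequencies are binomial around half the parent dosage", {
  map <- genetic_map(1, 10, 10)
  pop <- sim_founders(10, map, seed = 31)
  set.seed(32)
  n_dh <- 5000
  dh <- make_dh(pop, 1, n_dh = n_dh)
  p_expect <- dosages(pop)[1, ] / 2
  p_obs <- allele_freqs(dh)
  se <- sqrt(pmax(p_expect * (1 - p_expect), 1e-12) / n_dh)
  het <- p_expect == 0.5
  expect_true(all(abs(p_obs - p_expect)[het] < 3 * se[het]))
  expect_equal(unname(p_obs[!het]), unname(p_expect[!het]))
})

test_that("genetic values follow the additive model", {
  map <- genetic_map(1, 1, 1)
  haplo <- rbind(c(0L, 0L), c(0L, 0L),   # dosage 0 at causal locus
                 c(1L, 0L), c(0L, 0L),   # dosage 1
                 c(1L, 1L), c(1L, 0L))   # dosage 2
  pop <- pop_from_haplo(haplo, map, ids = c("a", "b", "c"))
  trait <- structure(list(causal = which(map$causal), alpha = 2, intercept = 5),
                     class = "trait_arch")
  expect_equal(genetic_values(pop, trait)$gv, c(5, 7, 9))
  # zero effects -> intercept everywhere
  trait0 <- structure(list(causal = which(map$causal), alpha = 0, intercept = 3),
                      class = "trait_arch")
  expect_equal(genetic_values(pop, trait0)$gv, rep(3, 3))
})

test_that("genetic values match a per-individual loop oracle", {
  map <- genetic_map(2, 10, 10)
  pop <- sim_founders(15, map, seed = 41)
  trait <- sim_trait(pop, seed = 42)
  got <- genetic_values(pop, trait)$gv
  d <- dosages(pop, trait$causal)
  oracle <- vapply(seq_len(15), function(i) {
    s <- trait$intercept
    for (j in seq_along(trait$alpha)) s <- s + d[i, j] * trait$alpha[j]
    s
  }, numeric(1))
  expect_equal(got, oracle)
})

test_that("genic variance closed forms and error handling", {
  expect_equal(genic_variance(c(0.5, 0.5), c(1, 1)), 1)
  expect_equal(genic_variance(c(0, 1, 0), c(3, -2, 1)), 0)
  expect_error(genic_variance(c(0.5, 0.5), 1))
  expect_error(genic_variance(c(-0.1, 0.5), c(1, 1)))
})

test_that("genic variance matches the empirical variance under HWE and LE", {
  set.seed(51)
  nq <- 40
  p <- runif(nq, 0.1, 0.9)
  alpha <- rnorm(nq)
  n <- 40000
  dos <- vapply(seq_len(nq), function(j) rbinom(n, 2, p[j]), numeric(n))
  emp <- var(as.numeric(dos %*% alpha))
  expect_lt(abs(emp / genic_variance(p, alpha) - 1), 0.05)
})

test_that("mean allele frequency is conserved under random mating (neutral drift)", {
  map <- genetic_map(1, 0, 10)
  pop0 <- sim_founders(20, map, seed = 61, n_generations = 0)
  p0 <- allele_freqs(pop0)
  set.seed(62)
  n_rep <- 200
  pbar <- matrix(0, n_rep, 10)
  for (r in seq_len(n_rep)) {
    mothers <- sample.int(20, 20, TRUE)
    fathers <- ((mothers + sample.int(19, 20, TRUE) - 1L) %% 20L) + 1L
    kids <- twopartsim:::cross_batch(pop0, mothers, fathers,
                                     ids = sprintf("k%02d", 1:20))
    pbar[r, ] <- allele_freqs(kids)
  }
  drift_se <- sqrt(p0 * (1 - p0) / (2 * 20) / n_rep)  # SE of the replicate mean
  expect_true(all(abs(colMeans(pbar) - p0) < 3 * pmax(drift_se, 1e-6)))
})

test_that("selfing is rejected and unknown parents error", {
  map <- genetic_map(1, 5, 5)
  pop <- sim_founders(5, map, seed = 71)
  expect_error(make_cross(pop, 2, 2, 1), "selfing")
  expect_error(make_cross(pop, "nope", 1, 1), "unknown")
  expect_error(sim_founders(1, map), class = "twopartsim_config_error")
})

test_that("dosage export and haplotype serialization round-trip", {
  map <- genetic_map(1, 4, 4)
  pop <- sim_founders(6, map, seed = 81)
  f1 <- tempfile(fileext = ".csv")
  export_dosages(pop, f1)
  got <- read.csv(f1, check.names = FALSE)
  expect_equal(got$id, pop$id)
  expect_equal(as.matrix(got[, -1]), marker_dosages(pop),
               ignore_attr = TRUE)
  f2 <- tempfile(fileext = ".csv")
  write_haplotypes(pop, f2)
  back <- read_haplotypes(f2, map)
  expect_identical(back$haplo, pop$haplo)
  expect_identical(back$id, pop$id)
})
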