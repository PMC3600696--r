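test_that("default design reproduces the reference population structure", {
  d <- simulate_design(design_config(), seed = 3)
  ped <- d$pedigree
  expect_equal(sum(ped$generation == "F0"), 28)
  expect_equal(sum(ped$generation == "F1"), 127)
  expect_equal(sum(ped$generation == "F2"), 474)
  expect_equal(sum(d$covariates$retained), 454)
  expect_equal(sum(d$covariates$dead_early), 5)
  expect_equal(sum(d$covariates$removed), 15)
  # litter sizes within bounds
  litters <- table(d$covariates$litter)
  expect_true(all(litters >= 2 & litters <= 12))
  # F1 parents: no boar mated to a litter mate
  f1 <- ped[ped$generation == "F1", ]
  f2 <- ped[ped$generation == "F2", ]
  f1_litter <- sapply(f1$animal, function(a) paste(f1$sire[f1$animal == a],
                                                   f1$dam[f1$animal == a]))
  expect_true(all(f1_litter[f2$sire] != f1_litter[f2$dam]))
  # three SOB cohorts approximating the configured sizes
  sob_n <- table(d$covariates$sob)
  expect_equal(length(sob_n), 3)
  expect_true(all(abs(as.numeric(sob_n) - c(250, 124, 100)) < 15))
  # deterministic given the seed
  d2 <- simulate_design(design_config(), seed = 3)
  expect_identical(d$pedigree, d2$pedigree)
  expect_identical(d$covariates, d2$covariates)
  # infeasible litter partition errors
  expect_error(
    simulate_design(design_config(
      n_f2_born = 474L, litter_size = list(mean = 3, min = 2, max = 3),
      sob_group_sizes = c(250L, 124L, 100L)), seed = 1),
    "partition")
})

test_that("design config invariants are enforced", {
  expect_error(design_config(litter_size = list(mean = 8, min = 9, max = 5)),
               "min exceeds max")
  expect_error(design_config(n_f1_parents = 200L), "exceeds n_f1_born")
  expect_error(design_config(sob_group_sizes = c(1L, 2L, 3L)), "sum to")
})

test_that("gene drop matches the pedigree covariance structure", {
  # zero genetic variance -> all breeding values exactly zero
  d <- simulate_design(design_config(), seed = 4)
  arch0 <- genetic_architecture("y", G = matrix(0, 1, 1,
                                                dimnames = list("y", "y")),
                                R = matrix(1, 1, 1, dimnames = list("y", "y")))
  bv0 <- simulate_breeding_values(d$pedigree, arch0, seed = 1)
  expect_true(all(bv0$y == 0))

  # founder variance: 2000 unrelated founders, sigma2_a = 1
  big <- as_pedigree(data.frame(animal = paste0("f", 1:2000),
                                sire = "0", dam = "0"))
  bv <- simulate_breeding_values(big, matrix(1, 1, 1), seed = 2)
  v <- stats::var(bv[[2]])
  expect_gt(v, 0.9)
  expect_lt(v, 1.1)

  # replicated gene drops on a small pedigree reproduce A * sigma2_a
  ped <- as_pedigree(random_pedigree(6, 12, 2, seed = 5))
  A <- additive_relationship(ped)
  reps <- 400
  n <- nrow(ped)
  acc <- matrix(0, n, n)
  for (r in seq_len(reps)) {
    b <- simulate_breeding_values(ped, matrix(1, 1, 1), seed = 1000 + r)[[2]]
    acc <- acc + tcrossprod(b)
  }
  emp <- acc / reps
  # entrywise agreement within Monte-Carlo error (SE ~ sqrt(2/reps))
  expect_lt(max(abs(emp - A)), 6 * sqrt(2 / reps))
  expect_error(simulate_breeding_values(ped, matrix(-1, 1, 1)), "positive semi")
})

test_that("phenotype simulation composes effects and applies missingness", {
  d <- simulate_design(design_config(), seed = 6)
  # R = 0 and no fixed effects: y = mean + BV exactly
  arch <- genetic_architecture("y", G = matrix(0.5, 1, 1),
                               R = matrix(0, 1, 1), means = c(y = 10))
  sim <- simulate_phenotypes(d, arch, seed = 6)
  bv <- sim$breeding_values
  m <- match(sim$phenotypes$animal, bv$animal)
  expect_equal(sim$phenotypes$y, 10 + bv$y[m], tolerance = 1e-12)

  # fixed observed count (fasting-glucose style subset)
  arch2 <- study_arch_uni("glu", 0.49, n_observed = 146)
  sim2 <- simulate_phenotypes(d, arch2, seed = 7)
  expect_equal(sum(!is.na(sim2$phenotypes$glu)), 146)

  # reproducibility: identical seed, identical output
  sim3 <- simulate_phenotypes(d, arch2, seed = 7)
  expect_identical(sim2$phenotypes, sim3$phenotypes)

  # length covariate must be generated before its dependent trait
  arch_bad <- genetic_architecture(
    "fat", var_p = 1, h2 = 0.4,
    fixed_effects = list(fat = list(length_slope = 0.1, length_from = "len")))
  expect_error(simulate_phenotypes(d, arch_bad, seed = 1), "length")

  # and works when the source trait comes first
  arch_ok <- genetic_architecture(
    c("len", "fat"), var_p = c(1, 1), h2 = c(0.5, 0.4),
    fixed_effects = list(len = list(),
                         fat = list(length_slope = 0.1, length_from = "len")))
  sim4 <- simulate_phenotypes(d, arch_ok, seed = 2)
  expect_true(all(!is.na(sim4$phenotypes$fat)))
})

test_that("phenotypes regress on true breeding values with unit slope", {
  d <- simulate_design(design_config(), seed = 8)
  arch <- study_arch_uni("y", 0.5)
  slopes <- numeric(20)
  for (r in seq_len(20)) {
    sim <- simulate_phenotypes(d, arch, seed = 100 + r)
    bv <- sim$breeding_values
    m <- match(sim$phenotypes$animal, bv$animal)
    slopes[r] <- stats::coef(stats::lm(sim$phenotypes$y ~ bv$y[m]))[2]
  }
  expect_equal(mean(slopes), 1, tolerance = 0.06)

  # line divergence shifts means through the pedigree expectation
  arch_div <- genetic_architecture(
    "y", var_p = 1, h2 = 0.5, means = c(y = 0),
    line_divergence = list(y = c(M = 4, D = -4, Y = -4)))
  sim_div <- simulate_phenotypes(d, arch_div, seed = 9)
  # F2 expectation: mid of F1 means = (4 + (-4)) / 2 = 0, so mean near zero
  expect_lt(abs(mean(sim_div$phenotypes$y)), 0.6)
})
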