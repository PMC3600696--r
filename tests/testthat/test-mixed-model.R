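test_that("design construction codes factors, centers covariates, drops missing", {
  d <- simulate_design(design_config(), seed = 10)
  arch <- study_arch_uni("y", 0.5)
  sim <- simulate_phenotypes(d, arch, seed = 10)
  ped <- prune_to_phenotyped(d$pedigree, sim$phenotypes$animal)
  phen <- sim$phenotypes
  ds <- build_design(phen, trait_spec("y"), ped)
  X <- ds$parts[[1]]$X
  # intercept + sex + 2 SOB dummies + age for a no-length trait
  expect_equal(ncol(X), 5)
  expect_equal(colnames(X)[1], "(Intercept)")
  expect_equal(unname(colMeans(X)[5]), 0, tolerance = 1e-12) # centered age

  # a record with missing age is excluded and logged
  phen2 <- phen
  phen2$age_m2[3] <- NA
  ds2 <- build_design(phen2, trait_spec("y"), ped)
  expect_equal(nrow(ds2$parts[[1]]$X), nrow(phen) - 1)
  expect_true(phen$animal[3] %in% ds2$parts[[1]]$dropped$animal)

  # disjoint record sets for a pair: valid system, residual cov inestimable
  phen3 <- phen
  phen3$y2 <- phen3$y + rnorm(nrow(phen3))
  half <- seq_len(nrow(phen3)) <= nrow(phen3) / 2
  phen3$y[!half] <- NA
  phen3$y2[half] <- NA
  expect_warning(
    ds3 <- build_design(phen3, list(trait_spec("y"), trait_spec("y2")), ped),
    "disjoint")
  expect_false(ds3$residual_cov_estimable)

  # single-level factor errors
  phen4 <- phen
  phen4$sex <- "M"
  expect_error(build_design(phen4, trait_spec("y"), ped), "single level")
})

test_that("fixed-effect screening has nominal size and detects real effects", {
  set.seed(31)
  n <- 200
  base <- tibble::tibble(
    animal = paste0("a", 1:n),
    sex = sample(c("M", "F"), n, TRUE),
    sob = sample(c("S1", "S2", "S3"), n, TRUE)
  )
  # null factor: rejection rate near alpha across replicate screens
  hits <- logical(200)
  for (r in seq_len(200)) {
    dat <- base
    dat$y <- rnorm(n)
    sc <- screen_fixed_effects(dat, "y", factors = "sob")
    hits[r] <- sc$significant[sc$effect == "sob"]
  }
  expect_gt(mean(hits), 0.02)
  expect_lt(mean(hits), 0.10)

  # a 1-SD sex effect at n = 454 is essentially always flagged
  n2 <- 454
  big <- tibble::tibble(animal = paste0("b", 1:n2),
                        sex = sample(c("M", "F"), n2, TRUE))
  found <- vapply(1:50, function(r) {
    big$y <- rnorm(n2) + 1 * (big$sex == "M")
    screen_fixed_effects(big, "y", factors = "sex")$significant
  }, TRUE)
  expect_true(all(found))

  # degenerate designs error informatively
  one_lvl <- tibble::tibble(animal = "x", sex = "M", y = 1)
  expect_error(screen_fixed_effects(one_lvl, "y", factors = "sex"),
               "single level")
  aliased <- tibble::tibble(animal = paste0("c", 1:20),
                            f1 = rep(c("a", "b"), 10),
                            f2 = rep(c("a", "b"), 10),
                            y = rnorm(20))
  expect_error(screen_fixed_effects(aliased, "y", factors = c("f1", "f2")),
               "aliased|rank")
})

test_that("EM iterations never decrease the REML log-likelihood", {
  n_bad <- 0
  for (r in seq_len(100)) {
    dat <- make_small_dataset(n_founders = 5, n_per_gen = 10, n_gen = 2,
                              h2 = runif(1, 0.05, 0.9), seed = r)
    fit <- f2qg:::reml_uni_core(dat$y, dat$X, dat$K, q = nrow(dat$A),
                         f2qg:::reml_options(algorithm = "em", max_iter = 25))
    if (any(diff(fit$trace$loglik) < -1e-8)) n_bad <- n_bad + 1
  }
  expect_equal(n_bad, 0)
})

test_that("AI-REML agrees with the brute-force likelihood-surface oracle", {
  for (s in c(2, 13)) {
    dat <- make_small_dataset(n_founders = 5, n_per_gen = 10, n_gen = 2,
                              h2 = 0.5, seed = s)
    fit <- f2qg:::reml_uni_core(dat$y, dat$X, dat$K, q = nrow(dat$A),
                         f2qg:::reml_options())
    oracle <- oracle_reml_bruteforce(dat$y, dat$X, dat$K, grid_n = 120)
    expect_equal(fit$sigma2_a, oracle$sigma2_a, tolerance = 1e-4)
    expect_equal(fit$sigma2_e, oracle$sigma2_e, tolerance = 1e-4)
  }
})

test_that("record order does not change the estimates", {
  dat <- make_small_dataset(n_founders = 6, n_per_gen = 12, n_gen = 2,
                            h2 = 0.4, seed = 21)
  fit1 <- f2qg:::reml_uni_core(dat$y, dat$X, dat$K, q = nrow(dat$A),
                        f2qg:::reml_options())
  set.seed(77)
  perm <- sample(length(dat$y))
  fit2 <- f2qg:::reml_uni_core(dat$y[perm], dat$X[perm, , drop = FALSE],
                        dat$K[perm, perm], q = nrow(dat$A),
                        f2qg:::reml_options())
  expect_lt(abs(fit1$sigma2_a - fit2$sigma2_a), 1e-10)
  expect_lt(abs(fit1$sigma2_e - fit2$sigma2_e), 1e-10)
})

test_that("boundary data drives the genetic variance to the floor", {
  set.seed(55)
  dat <- make_small_dataset(n_founders = 8, n_per_gen = 20, n_gen = 2,
                            h2 = 0.4, seed = 3)
  y_null <- rnorm(length(dat$y)) # no genetic signal at all
  fit <- f2qg:::reml_uni_core(y_null, dat$X, dat$K, q = nrow(dat$A),
                       f2qg:::reml_options())
  h2 <- fit$sigma2_a / (fit$sigma2_a + fit$sigma2_e)
  expect_lt(h2, 0.2)
})

test_that("heritability and correlation SEs match numeric propagation", {
  # random component sets with a synthetic sampling covariance
  set.seed(9)
  for (r in 1:20) {
    g <- runif(1, 0.1, 2)
    e <- runif(1, 0.1, 2)
    Lr <- matrix(rnorm(4, sd = 0.1), 2)
    S <- crossprod(Lr)
    fake <- structure(list(sigma2_a = g, sigma2_e = e, sampling_cov = S,
                           trait = "t", converged = TRUE),
                      class = c("f2qg_reml_uni", "f2qg_reml"))
    h <- heritability(fake)
    f_h2 <- function(th) th[1] / (th[1] + th[2])
    gr <- numeric_grad(f_h2, c(g, e))
    expect_equal(h$se, sqrt(drop(t(gr) %*% S %*% gr)), tolerance = 1e-8)
    expect_equal(h$h2, g / (g + e))
  }
  # bivariate rg / rp with a random PSD 6x6 sampling covariance
  set.seed(10)
  for (r in 1:10) {
    g11 <- runif(1, 0.3, 2); g22 <- runif(1, 0.3, 2)
    rho_g <- runif(1, -0.8, 0.8)
    g12 <- rho_g * sqrt(g11 * g22)
    r11 <- runif(1, 0.3, 2); r22 <- runif(1, 0.3, 2)
    rho_r <- runif(1, -0.8, 0.8)
    r12 <- rho_r * sqrt(r11 * r22)
    th <- c(g11 = g11, g12 = g12, g22 = g22, r11 = r11, r12 = r12, r22 = r22)
    Lr <- matrix(rnorm(36, sd = 0.05), 6)
    S <- crossprod(Lr)
    dimnames(S) <- list(names(th), names(th))
    fake <- structure(list(theta = th, sampling_cov = S, boundary = FALSE,
                           converged = TRUE, traits = c("a", "b"),
                           options = f2qg:::reml_options()),
                      class = c("f2qg_reml_biv", "f2qg_reml"))
    cc <- correlations(fake)
    f_rg <- function(v) v[2] / sqrt(v[1] * v[3])
    f_rp <- function(v) (v[2] + v[5]) / sqrt((v[1] + v[4]) * (v[3] + v[6]))
    gr_g <- numeric_grad(f_rg, unname(th))
    gr_p <- numeric_grad(f_rp, unname(th))
    expect_equal(cc$se[cc$term == "rg"], sqrt(drop(t(gr_g) %*% S %*% gr_g)),
                 tolerance = 1e-8)
    expect_equal(cc$se[cc$term == "rp"], sqrt(drop(t(gr_p) %*% S %*% gr_p)),
                 tolerance = 1e-8)
    expect_equal(cc$estimate[cc$term == "rg"], rho_g, tolerance = 1e-12)
  }
})

test_that("heritability algebra and selection rule behave", {
  fake <- structure(list(sigma2_a = 0.57, sigma2_e = 0.43,
                         sampling_cov = diag(2) * 0.01, trait = "t",
                         converged = TRUE),
                    class = c("f2qg_reml_uni", "f2qg_reml"))
  expect_equal(heritability(fake)$h2, 0.57)
  fake$sigma2_a <- fake$sigma2_e <- 1
  expect_equal(heritability(fake)$h2, 0.5)

  uni <- tibble::tibble(trait = "t", h2 = 0.5, se = 0.14,
                        source = "univariate", converged = TRUE)
  biv <- tibble::tibble(trait = "t", h2 = 0.48, se = 0.12,
                        source = "bivariate(t,u)", converged = TRUE)
  expect_equal(select_heritability(list(uni, biv))$h2, 0.48)
  biv$se <- 0.14 # tie goes to the univariate estimate
  expect_equal(select_heritability(list(uni, biv))$source, "univariate")
  expect_equal(select_heritability(list(uni))$h2, 0.5)
  uni$converged <- biv$converged <- FALSE
  expect_error(select_heritability(list(uni, biv)), "no converged")
})

test_that("a trait paired with its own noisy copy has rg near 1", {
  d <- simulate_design(design_config(), seed = 12)
  arch <- study_arch_uni("y", 0.6)
  sim <- simulate_phenotypes(d, arch, seed = 12)
  phen <- sim$phenotypes
  set.seed(12)
  phen$y_copy <- phen$y + rnorm(nrow(phen), sd = 0.3)
  ped <- prune_to_phenotyped(d$pedigree, phen$animal)
  relmat <- relationship_matrix(ped)
  ds <- build_design(phen, list(trait_spec("y"), trait_spec("y_copy")), ped)
  fit <- reml_bivariate(ds, relmat)
  rg <- correlations(fit)$estimate[1]
  expect_gt(rg, 0.99)
})

test_that("EBVs shrink to zero without genetic variance and track true BVs", {
  d <- simulate_design(design_config(), seed = 14)
  arch <- study_arch_uni("y", 0.5)
  sim <- simulate_phenotypes(d, arch, seed = 14)
  ped <- prune_to_phenotyped(d$pedigree, sim$phenotypes$animal)
  relmat <- relationship_matrix(ped)
  ds <- build_design(sim$phenotypes, trait_spec("y"), ped)
  fit <- reml_univariate(ds, relmat)
  ebv <- predict_ebv(fit)
  expect_equal(nrow(ebv), nrow(ped)) # every pedigree animal, parents included
  # BLUP accuracy at h2 = 0.5 on ~450 phenotyped animals
  bv <- sim$breeding_values
  phenotyped <- ds$parts[[1]]$animal
  m <- match(phenotyped, ebv$animal)
  mb <- match(phenotyped, bv$animal)
  expect_gt(stats::cor(ebv$ebv[m], bv$y[mb]), 0.6)
  # unphenotyped F0 parents pick up progeny information
  f0 <- ped$animal[ped$generation == "F0"]
  expect_gt(max(abs(ebv$ebv[match(f0, ebv$animal)])), 0)
  expect_true(all(ebv$pev >= 0))

  # variance at the floor: shrinkage kills all EBVs
  fit0 <- fit
  fit0$sigma2_a <- fit$var_floor
  fit0$sigma2_e <- 1
  ebv0 <- predict_ebv(fit0)
  expect_lt(max(abs(ebv0$ebv)), 1e-3)
})

test_that("tidy, glance and autoplot expose the fit", {
  dat <- make_small_dataset(seed = 30)
  ped <- dat$ped
  phen <- tibble::tibble(animal = dat$animal, y = dat$y, x = dat$X[, "x"],
                         sex = sample(c("M", "F"), length(dat$y), TRUE))
  relmat <- relationship_matrix(ped)
  ds <- build_design(phen, trait_spec("y", fixed_factors = "sex", age = "x"), ped)
  fit <- reml_univariate(ds, relmat)
  td <- tidy(fit)
  expect_setequal(td$term, c("sigma2_a", "sigma2_e", "h2"))
  gl <- glance(fit)
  expect_true(gl$n_records <= length(dat$y))
  expect_s3_class(autoplot(fit), "ggplot")
  expect_output(print(fit), "univariate animal model")
})

test_that("independent traits recover a genetic correlation near zero", {
  d <- simulate_design(design_config(), seed = 16)
  arch <- study_arch_biv(0.5, 0.5, rg = 0, re = 0)
  ped <- NULL
  rgs <- numeric(8)
  for (r in seq_len(8)) {
    sim <- simulate_phenotypes(d, arch, seed = 500 + r)
    if (is.null(ped)) {
      ped <- prune_to_phenotyped(d$pedigree, sim$phenotypes$animal)
      relmat <- relationship_matrix(ped)
    }
    ds <- build_design(sim$phenotypes, list(trait_spec("t1"), trait_spec("t2")), ped)
    fit <- reml_bivariate(ds, relmat)
    rgs[r] <- suppressMessages(correlations(fit))$estimate[1]
  }
  expect_lt(abs(mean(rgs)), 0.15)
})

test_that("bivariate EM iterations also ascend the likelihood", {
  d <- simulate_design(design_config(), seed = 20)
  arch <- study_arch_biv(0.4, 0.6, rg = 0.5, re = 0.3)
  sim <- simulate_phenotypes(d, arch, seed = 20)
  set.seed(20)
  ph <- sim$phenotypes[sample(nrow(sim$phenotypes), 120), ]
  ped <- prune_to_phenotyped(d$pedigree, ph$animal)
  relmat <- relationship_matrix(ped)
  ds <- build_design(ph, list(trait_spec("t1"), trait_spec("t2")), ped)
  fit <- reml_bivariate(ds, relmat,
                        reml_options(algorithm = "em", max_iter = 25))
  expect_true(all(diff(fit$trace$loglik) > -1e-8))
  # EM approaches the same optimum the AI path reaches
  fit2 <- reml_bivariate(ds, relmat)
  expect_gt(fit$loglik, fit2$loglik - 1)
})
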