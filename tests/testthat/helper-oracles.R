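# Independent oracles used across the test suite. These deliberately avoid
# the package's own algorithms: relationships by Wright's path counting,
# REML by direct evaluation of the likelihood surface, derivatives by
# central differences.

# Random multi-generation pedigree as a plain data frame accepted by
# as_pedigree(). Later generations mate randomly within the previous ones,
# so inbreeding arises naturally.
random_pedigree <- function(n_founders = 10, n_per_gen = 30, n_gen = 3,
                            seed = 1) {
  set.seed(seed)
  animal <- paste0("A", seq_len(n_founders))
  sire <- rep("0", n_founders)
  dam <- rep("0", n_founders)
  sex <- sample(c("M", "F"), n_founders, replace = TRUE)
  sex[1:2] <- c("M", "F") # guarantee both sexes exist
  for (g in seq_len(n_gen)) {
    pool_m <- animal[sex == "M"]
    pool_f <- animal[sex == "F"]
    k <- n_per_gen
    new_ids <- paste0("G", g, "_", seq_len(k))
    new_sex <- sample(c("M", "F"), k, replace = TRUE)
    new_sex[1:2] <- c("M", "F")
    animal <- c(animal, new_ids)
    sire <- c(sire, sample(pool_m, k, replace = TRUE))
    dam <- c(dam, sample(pool_f, k, replace = TRUE))
    sex <- c(sex, new_sex)
  }
  data.frame(animal = animal, sire = sire, dam = dam, sex = sex)
}

# Wright's path-counting relationship: a_ij = sum over pairs of
# non-overlapping ascent paths meeting at a common ancestor c of
# 0.5^(total path length) * (1 + F_c); a_ii = 1 + F_i with
# F_i = 0.5 a(sire, dam).
oracle_A_path <- function(ped) {
  n <- nrow(ped)
  si <- match(ped$sire, ped$animal)
  di <- match(ped$dam, ped$animal)
  paths_memo <- vector("list", n)
  paths_up <- function(i) {
    if (!is.null(paths_memo[[i]])) return(paths_memo[[i]])
    out <- list(i)
    for (p in c(si[i], di[i])) {
      if (!is.na(p)) {
        out <- c(out, lapply(paths_up(p), function(pp) c(i, pp)))
      }
    }
    paths_memo[[i]] <<- out
    out
  }
  Fv <- numeric(n)
  rel <- function(i, j) {
    if (i == j) return(1 + Fv[i])
    tot <- 0
    for (pi in paths_up(i)) {
      for (pj in paths_up(j)) {
        ci <- pi[length(pi)]
        if (ci == pj[length(pj)]) {
          shared <- intersect(pi, pj)
          if (length(shared) == 1 && shared == ci) {
            tot <- tot + 0.5^(length(pi) + length(pj) - 2) * (1 + Fv[ci])
          }
        }
      }
    }
    tot
  }
  A <- matrix(0, n, n, dimnames = list(ped$animal, ped$animal))
  for (i in seq_len(n)) { # topological order: F of ancestors ready first
    Fv[i] <- if (is.na(si[i]) || is.na(di[i])) 0 else 0.5 * rel(si[i], di[i])
    A[i, i] <- 1 + Fv[i]
    if (i > 1) {
      for (j in seq_len(i - 1)) {
        A[i, j] <- A[j, i] <- rel(i, j)
      }
    }
  }
  A
}

# Direct REML log-likelihood, written independently of the package's
# cholesky-based evaluator: explicit inverse and log-determinants.
oracle_reml_loglik <- function(sa, se, y, X, K) {
  V <- sa * K + se * diag(length(y))
  Vi <- solve(V)
  XtViX <- t(X) %*% Vi %*% X
  P <- Vi - Vi %*% X %*% solve(XtViX) %*% t(X) %*% Vi
  ld_V <- determinant(V, logarithm = TRUE)$modulus
  ld_X <- determinant(XtViX, logarithm = TRUE)$modulus
  as.numeric(-0.5 * (ld_V + ld_X + t(y) %*% P %*% y))
}

# Brute-force REML: coarse 200 x 200 grid over the variance components,
# then Nelder-Mead refinement of the same oracle surface.
oracle_reml_bruteforce <- function(y, X, K, grid_n = 200) {
  vp <- stats::var(stats::lm.fit(X, y)$residuals)
  sa_grid <- seq(vp * 1e-3, 3 * vp, length.out = grid_n)
  se_grid <- seq(vp * 1e-3, 3 * vp, length.out = grid_n)
  best <- c(NA, NA)
  best_ll <- -Inf
  for (sa in sa_grid) {
    for (se in se_grid) {
      ll <- oracle_reml_loglik(sa, se, y, X, K)
      if (ll > best_ll) {
        best_ll <- ll
        best <- c(sa, se)
      }
    }
  }
  ref <- stats::optim(log(best), function(lth) {
    -oracle_reml_loglik(exp(lth[1]), exp(lth[2]), y, X, K)
  }, method = "Nelder-Mead",
  control = list(reltol = 1e-14, maxit = 5000))
  list(sigma2_a = exp(ref$par[1]), sigma2_e = exp(ref$par[2]),
       loglik = -ref$value)
}

# Central-difference gradient for delta-method SE cross-checks.
numeric_grad <- function(f, x, h = 1e-6) {
  vapply(seq_along(x), function(i) {
    hp <- h * max(1, abs(x[i]))
    xp <- x; xp[i] <- x[i] + hp
    xm <- x; xm[i] <- x[i] - hp
    (f(xp) - f(xm)) / (2 * hp)
  }, 0)
}

# Monte-Carlo power of the single-locus F2 test: additive genotype
# {-1,0,1} with HWE F2 frequencies, variance fraction p, F-test at `alpha`.
mc_f2_power <- function(n, p, alpha, nrep = 2000, seed = 99) {
  set.seed(seed)
  a <- sqrt(2 * p)
  rej <- logical(nrep)
  for (r in seq_len(nrep)) {
    g <- sample(c(-1, 0, 1), n, replace = TRUE, prob = c(.25, .5, .25))
    y <- a * g + stats::rnorm(n, sd = sqrt(1 - p))
    rho <- stats::cor(g, y)
    fstat <- (n - 2) * rho^2 / (1 - rho^2)
    rej[r] <- stats::pf(fstat, 1, n - 2, lower.tail = FALSE) < alpha
  }
  mean(rej)
}

# Small phenotyped dataset on a random pedigree for REML unit tests.
make_small_dataset <- function(n_founders = 6, n_per_gen = 10, n_gen = 2,
                               h2 = 0.4, n_records = NULL, seed = 1) {
  ped <- f2qg::as_pedigree(random_pedigree(n_founders, n_per_gen, n_gen, seed))
  A <- f2qg::additive_relationship(ped)
  set.seed(seed + 1000)
  n <- nrow(ped)
  L <- chol(A + diag(1e-10, n))
  bv <- sqrt(h2) * drop(crossprod(L, stats::rnorm(n)))
  keep <- if (is.null(n_records)) seq_len(n) else sample.int(n, n_records)
  x <- stats::rnorm(length(keep))
  y <- 1 + 0.5 * x + bv[keep] + stats::rnorm(length(keep), sd = sqrt(1 - h2))
  X <- cbind(`(Intercept)` = 1, x = x - mean(x))
  list(ped = ped, A = A, y = y, X = X, K = A[keep, keep],
       animal = ped$animal[keep], bv = bv)
}

# Study-scale simulation helpers shared by acceptance tests: one design
# pedigree, replicate phenotype draws.
study_design_once <- function(seed = 1) {
  design <- f2qg::simulate_design(f2qg::design_config(), seed = seed)
  sim0 <- f2qg::simulate_phenotypes(
    design, study_arch_uni("y", 0.5), seed = seed)
  ped <- f2qg::prune_to_phenotyped(design$pedigree, sim0$phenotypes$animal)
  list(design = design, ped = ped, relmat = f2qg::relationship_matrix(ped))
}

study_arch_uni <- function(trait, h2, n_observed = NULL) {
  f2qg::genetic_architecture(
    trait, var_p = 1, h2 = h2,
    means = stats::setNames(10, trait),
    fixed_effects = stats::setNames(list(list(
      sex = 0.3, sob = c(0, 0.2, 0.4), age_slope = 0.01,
      age_column = "age_m2")), trait),
    missingness = if (is.null(n_observed)) list() else
      stats::setNames(list(n_observed), trait)
  )
}

study_arch_biv <- function(h2_1, h2_2, rg, re) {
  f2qg::genetic_architecture(
    c("t1", "t2"), var_p = c(1, 1), h2 = c(h2_1, h2_2),
    cor_g = matrix(c(1, rg, rg, 1), 2),
    cor_r = matrix(c(1, re, re, 1), 2),
    means = c(t1 = 10, t2 = 20),
    fixed_effects = list(
      t1 = list(sex = 0.3, sob = c(0, 0.2, 0.4), age_slope = 0.01,
                age_column = "age_m2"),
      t2 = list(sex = 0.3, sob = c(0, 0.2, 0.4), age_slope = 0.02,
                age_column = "age_m2"))
  )
}
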