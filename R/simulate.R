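#' Design configuration for the F2 resource population
#'
#' Encodes the three-generation breeding design: divergent founder boars
#' (minipig line, `M`) mated to sows of two lean production lines (`D`, `Y`),
#' an F1 generation from which parents are selected, and an F2 generation
#' born in litters and split over three season-of-birth (SOB) cohorts. The
#' defaults reproduce the reference design: 28 F0, 127 F1 born of which 81
#' become parents, 474 F2 born, 5 early deaths and 15 later removals leaving
#' 454 retained F2, SOB cohorts of roughly 250/124/100 animals.
#'
#' @param n_f0_boars Founder boars (line `M`).
#' @param n_f0_sows_per_breed Named counts of founder sows per lean breed.
#' @param n_f1_born F1 piglets born across the F0 litters.
#' @param n_f1_parents F1 animals selected as F2 parents (about one sire per
#'   two dams; each sire serves one or two litters).
#' @param litter_size List with `mean`, `min`, `max` litter bounds.
#' @param n_f2_born,n_dead_early,n_removed F2 born, dead by 5 weeks, and
#'   removed later (retained = born - dead - removed).
#' @param sob_group_sizes Season-of-birth cohort sizes; must sum to
#'   `n_f2_born`.
#' @param age_schedules Named list of `c(mean, sd)` nominal ages in days for
#'   the measurement timepoints.
#' @return A list of class `design_config`.
#' @export
design_config <- function(n_f0_boars = 14L,
                          n_f0_sows_per_breed = c(D = 7L, Y = 7L),
                          n_f1_born = 127L,
                          n_f1_parents = 81L,
                          litter_size = list(mean = 8, min = 2, max = 12),
                          n_f2_born = 474L,
                          n_dead_early = 5L,
                          n_removed = 15L,
                          sob_group_sizes = c(250L, 124L, 100L),
                          age_schedules = list(
                            wk2 = c(14.5, 1),
                            wk5 = c(36, 1.5),
                            m2 = c(64, 11),
                            d125 = c(115, 27),
                            m7 = c(220, 45)
                          )) {
  cfg <- list(
    n_f0_boars = as.integer(n_f0_boars),
    n_f0_sows_per_breed = n_f0_sows_per_breed,
    n_f1_born = as.integer(n_f1_born),
    n_f1_parents = as.integer(n_f1_parents),
    litter_size = litter_size,
    n_f2_born = as.integer(n_f2_born),
    n_dead_early = as.integer(n_dead_early),
    n_removed = as.integer(n_removed),
    sob_group_sizes = as.integer(sob_group_sizes),
    age_schedules = age_schedules
  )
  class(cfg) <- "design_config"
  validate_design_config(cfg)
  cfg
}

validate_design_config <- function(cfg) {
  ls <- cfg$litter_size
  if (ls$min > ls$max) stop("litter_size min exceeds max")
  if (cfg$n_f1_parents > cfg$n_f1_born) {
    stop("n_f1_parents exceeds n_f1_born")
  }
  if (sum(cfg$sob_group_sizes) != cfg$n_f2_born) {
    stop("sob_group_sizes must sum to n_f2_born (",
         sum(cfg$sob_group_sizes), " != ", cfg$n_f2_born, ")")
  }
  if (cfg$n_dead_early + cfg$n_removed >= cfg$n_f2_born) {
    stop("deaths plus removals exceed F2 born")
  }
  if (cfg$n_f0_boars != sum(cfg$n_f0_sows_per_breed)) {
    stop("need one founder sow per founder boar (single-pair matings)")
  }
  invisible(cfg)
}

# Deterministic per-stage seed derived from the global seed and a stage
# label, keeping results below 2^31.
derive_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 69069 + h * 12345) %% 2147483029)
}

# Partition `total` into `k` integers within [lo, hi], randomly perturbed
# around the even split. Errors when infeasible.
partition_litters <- function(total, k, lo, hi) {
  if (total < k * lo || total > k * hi) {
    stop("cannot partition ", total, " births into ", k,
         " litters of size [", lo, ", ", hi, "]")
  }
  sizes <- rep(total %/% k, k)
  extra <- total - sum(sizes)
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  # random pairwise transfers keep the total fixed and bounds respected
  for (step in seq_len(3L * k)) {
    ij <- sample.int(k, 2L)
    if (sizes[ij[1]] < hi && sizes[ij[2]] > lo) {
      sizes[ij[1]] <- sizes[ij[1]] + 1L
      sizes[ij[2]] <- sizes[ij[2]] - 1L
    }
  }
  sample(sizes)
}

rtruncnorm1 <- function(n, mean, sd, lower = 1) {
  p_lo <- stats::pnorm(lower, mean, sd)
  stats::qnorm(stats::runif(n, p_lo, 1), mean, sd)
}

#' Simulate the F2 breeding design
#'
#' Generates the three-generation pedigree and the covariate table (sex,
#' season of birth, litter, per-timepoint ages, death/removal flags).
#' F0 matings pair each minipig boar with one lean-breed sow; F1 parents are
#' selected per cross line (`MD` with `MD`, `MY` with `MY`), boars never
#' mated to litter-mates and each serving one or two dams where feasible.
#'
#' @param cfg A [design_config()].
#' @param seed Integer seed; the full design is reproducible given the seed.
#' @return A list of class `f2_design` with elements `pedigree` (the full
#'   born pedigree: F0, all F1, all F2), `covariates` (one row per F2 with
#'   `retained`, `dead_early`, `removed` flags) and `config`.
#' @examples
#' d <- simulate_design(design_config(), seed = 1)
#' sum(d$pedigree$generation == "F0") # 28
#' sum(d$covariates$retained) # 454
#' @export
simulate_design <- function(cfg = design_config(), seed = 1L) {
  validate_design_config(cfg)
  set.seed(derive_seed(seed, "design"))
  breeds <- rep(names(cfg$n_f0_sows_per_breed), cfg$n_f0_sows_per_breed)

  f0_boars <- sprintf("F0B%02d", seq_len(cfg$n_f0_boars))
  f0_sows <- sprintf("F0S%02d", seq_along(breeds))
  f0 <- tibble::tibble(
    animal = c(f0_boars, f0_sows),
    sire = NA_character_, dam = NA_character_,
    sex = rep(c("M", "F"), c(length(f0_boars), length(f0_sows))),
    generation = "F0",
    line = c(rep("M", length(f0_boars)), breeds)
  )

  # F1: one litter per F0 pair
  n_pairs <- cfg$n_f0_boars
  f1_sizes <- partition_litters(cfg$n_f1_born, n_pairs,
                                cfg$litter_size$min, cfg$litter_size$max)
  f1 <- tibble::tibble(
    animal = sprintf("F1_%03d", seq_len(cfg$n_f1_born)),
    sire = rep(f0_boars, f1_sizes),
    dam = rep(f0_sows, f1_sizes),
    sex = sample(c("M", "F"), cfg$n_f1_born, replace = TRUE),
    generation = "F1",
    line = paste0("M", rep(breeds, f1_sizes)),
    litter = rep(seq_len(n_pairs), f1_sizes)
  )

  # select F1 parents: ~1 sire per 2 dams, within cross line
  n_sires <- max(1L, round(cfg$n_f1_parents / 3))
  n_dams <- cfg$n_f1_parents - n_sires
  lines <- sort(unique(f1$line))
  sire_quota <- diff(round(seq(0, n_sires, length.out = length(lines) + 1)))
  dam_quota <- diff(round(seq(0, n_dams, length.out = length(lines) + 1)))
  sel_sires <- character(0)
  sel_dams <- character(0)
  for (li in seq_along(lines)) {
    in_line <- f1[f1$line == lines[li], ]
    males <- in_line$animal[in_line$sex == "M"]
    females <- in_line$animal[in_line$sex == "F"]
    # sex assignment is random; reassign roles if a line runs short of a sex
    if (length(males) < sire_quota[li] || length(females) < dam_quota[li]) {
      shuffled <- sample(in_line$animal)
      males <- shuffled[seq_len(sire_quota[li])]
      females <- setdiff(shuffled, males)
    }
    sel_sires <- c(sel_sires, sample(males, sire_quota[li]))
    sel_dams <- c(sel_dams, sample(setdiff(females, sel_sires), dam_quota[li]))
  }

  # assign each dam a non-litter-mate sire of the same line, balancing use
  f1_line <- stats::setNames(f1$line, f1$animal)
  f1_litter <- stats::setNames(f1$litter, f1$animal)
  mate_of <- character(length(sel_dams))
  use_count <- stats::setNames(integer(length(sel_sires)), sel_sires)
  for (di in seq_along(sel_dams)) {
    dam <- sel_dams[di]
    cands <- sel_sires[f1_line[sel_sires] == f1_line[dam] &
                         f1_litter[sel_sires] != f1_litter[dam]]
    if (length(cands) == 0) cands <- sel_sires[f1_line[sel_sires] == f1_line[dam]]
    cands <- cands[order(use_count[cands], stats::runif(length(cands)))]
    mate_of[di] <- cands[1]
    use_count[cands[1]] <- use_count[cands[1]] + 1L
  }

  f2_sizes <- partition_litters(cfg$n_f2_born, length(sel_dams),
                                cfg$litter_size$min, cfg$litter_size$max)
  f2 <- tibble::tibble(
    animal = sprintf("F2_%03d", seq_len(cfg$n_f2_born)),
    sire = rep(mate_of, f2_sizes),
    dam = rep(sel_dams, f2_sizes),
    sex = sample(c("M", "F"), cfg$n_f2_born, replace = TRUE),
    generation = "F2",
    line = "F2",
    litter = rep(seq_along(sel_dams), f2_sizes)
  )

  ped <- as_pedigree(dplyr::bind_rows(f0, f1[names(f0)], f2[names(f0)]))

  # SOB cohorts filled litter by litter to approximate the configured sizes
  litter_order <- sample(seq_along(sel_dams))
  litter_n <- f2_sizes
  cum <- cumsum(litter_n[litter_order])
  bounds <- cumsum(cfg$sob_group_sizes)
  litter_sob <- stats::setNames(
    findInterval(cum - litter_n[litter_order] / 2, c(0, bounds[-length(bounds)] + 0.5)),
    litter_order
  )
  sob <- paste0("SOB", litter_sob[as.character(f2$litter)])

  dead <- sample(f2$animal, cfg$n_dead_early)
  removed <- sample(setdiff(f2$animal, dead), cfg$n_removed)
  sched <- cfg$age_schedules
  ages <- lapply(sched, function(ms) round(rtruncnorm1(cfg$n_f2_born, ms[1], ms[2])))
  names(ages) <- paste0("age_", names(sched))
  cov <- tibble::tibble(
    animal = f2$animal,
    sex = f2$sex,
    sob = sob,
    litter = f2$litter,
    dead_early = f2$animal %in% dead,
    removed = f2$animal %in% removed,
    !!!ages
  )
  cov$retained <- !cov$dead_early & !cov$removed

  structure(list(pedigree = ped, covariates = cov, config = cfg),
            class = "f2_design")
}

#' @export
print.f2_design <- function(x, ...) {
  cat("<f2_design> ", nrow(x$pedigree), " animals (",
      sum(x$pedigree$generation == "F0"), " F0, ",
      sum(x$pedigree$generation == "F1"), " F1, ",
      sum(x$pedigree$generation == "F2"), " F2 born; ",
      sum(x$covariates$retained), " F2 retained)\n", sep = "")
  invisible(x)
}

#' Genetic architecture for phenotype simulation
#'
#' Per-trait means, genetic and residual (co)variances, fixed-effect sizes
#' and missingness rules used by [simulate_phenotypes()]. `G` and `R` can be
#' given directly, or assembled from per-trait phenotypic variances,
#' heritabilities and correlation matrices.
#'
#' @param traits Character vector of trait names.
#' @param G,R Genetic / residual covariance matrices (`t x t`), or `NULL` to
#'   assemble from `var_p`, `h2`, `cor_g`, `cor_r`.
#' @param var_p,h2 Per-trait phenotypic variances and heritabilities used
#'   when `G`/`R` are not supplied (`G = diag(sqrt(h2 var_p)) cor_g ...`).
#' @param cor_g,cor_r Genetic and residual correlation matrices (default
#'   identity).
#' @param means Per-trait means.
#' @param fixed_effects Named list per trait; each element may contain
#'   `sex` (effect of males vs females), `sob` (numeric vector of cohort
#'   deviations, recycled), `age_slope` plus `age_column`, `length_slope`
#'   plus `length_from` (name of an earlier trait serving as covariate).
#' @param line_divergence Named list per trait of founder-line mean offsets
#'   (named by line, e.g. `c(M = 3, D = -1.5, Y = -1.5)`), inherited as the
#'   mid-parent expectation down the pedigree.
#' @param missingness Named list per trait: an integer fixes the number of
#'   observed (non-missing) retained animals.
#' @return A list of class `genetic_architecture`.
#' @export
genetic_architecture <- function(traits, G = NULL, R = NULL,
                                 var_p = NULL, h2 = NULL,
                                 cor_g = NULL, cor_r = NULL,
                                 means = stats::setNames(rep(0, length(traits)), traits),
                                 fixed_effects = list(),
                                 line_divergence = list(),
                                 missingness = list()) {
  t <- length(traits)
  if (is.null(G) || is.null(R)) {
    if (is.null(var_p) || is.null(h2)) {
      stop("supply either G and R, or var_p and h2")
    }
    var_p <- rep_len(var_p, t)
    h2 <- rep_len(h2, t)
    if (is.null(cor_g)) cor_g <- diag(t)
    if (is.null(cor_r)) cor_r <- diag(t)
    sg <- sqrt(h2 * var_p)
    sr <- sqrt((1 - h2) * var_p)
    G <- outer(sg, sg) * cor_g
    R <- outer(sr, sr) * cor_r
  }
  G <- as.matrix(G)
  R <- as.matrix(R)
  dimnames(G) <- dimnames(R) <- list(traits, traits)
  check_psd <- function(M, label) {
    if (!isSymmetric(unname(M), tol = 1e-8)) stop(label, " must be symmetric")
    ev <- eigen(M, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-8 * max(abs(ev), 1)) {
      stop(label, " is not positive semi-definite")
    }
  }
  check_psd(G, "G")
  check_psd(R, "R")
  arch <- list(traits = traits, G = G, R = R,
               means = means, fixed_effects = fixed_effects,
               line_divergence = line_divergence, missingness = missingness)
  class(arch) <- "genetic_architecture"
  arch
}

# Matrix square root via eigendecomposition; works for PSD G (including
# singular G, e.g. a zero-variance trait).
psd_sqrt <- function(M) {
  e <- eigen(M, symmetric = TRUE)
  e$vectors %*% (sqrt(pmax(e$values, 0)) * t(e$vectors))
}

#' Gene-drop simulation of breeding values
#'
#' Founders draw from `N(0, G)`; each non-founder is the parent average plus
#' a Mendelian-sampling deviate with covariance
#' `(0.5 - 0.25 (F_s + F_d)) G` (both parents known; `0.75 - 0.25 F_p` with
#' one, `G` with none), so breeding values have covariance `A (x) G` exactly.
#'
#' @param ped An `f2qg_ped` pedigree.
#' @param arch A [genetic_architecture()] (only `G` is used), or a covariance
#'   matrix.
#' @param seed Integer seed.
#' @return A tibble with column `animal` and one column per trait.
#' @export
simulate_breeding_values <- function(ped, arch, seed = 1L) {
  G <- if (inherits(arch, "genetic_architecture")) arch$G else as.matrix(arch)
  traits <- colnames(G)
  if (is.null(traits)) traits <- paste0("trait", seq_len(ncol(G)))
  ev <- eigen(G, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(abs(ev), 1)) stop("G is not positive semi-definite")
  set.seed(derive_seed(seed, "gene_drop"))
  L <- psd_sqrt(G)
  t <- ncol(G)
  n <- nrow(ped)
  f <- inbreeding_coefficients(ped)$f
  ix <- ped_indices(ped)
  bv <- matrix(0, n, t)
  z <- matrix(stats::rnorm(n * t), n, t) %*% t(L)
  for (i in seq_len(n)) {
    s <- ix$sire[i]
    d <- ix$dam[i]
    npar <- sum(!is.na(c(s, d)))
    msv <- if (npar == 2L) {
      0.5 - 0.25 * (f[s] + f[d])
    } else if (npar == 1L) {
      0.75 - 0.25 * f[c(s, d)[!is.na(c(s, d))]]
    } else 1
    pa <- 0.5 * ((if (is.na(s)) 0 else bv[s, ]) + (if (is.na(d)) 0 else bv[d, ]))
    bv[i, ] <- pa + sqrt(msv) * z[i, ]
  }
  colnames(bv) <- traits
  dplyr::bind_cols(tibble::tibble(animal = ped$animal), tibble::as_tibble(bv))
}

# Expected line offset per animal: founders get their line's offset,
# descendants the mid-parent value (unknown parent contributes 0).
line_offsets <- function(ped, divergence) {
  n <- nrow(ped)
  ix <- ped_indices(ped)
  off <- numeric(n)
  for (i in seq_len(n)) {
    s <- ix$sire[i]
    d <- ix$dam[i]
    if (is.na(s) && is.na(d)) {
      off[i] <- if (ped$line[i] %in% names(divergence)) divergence[[ped$line[i]]] else 0
    } else {
      off[i] <- 0.5 * ((if (is.na(s)) 0 else off[s]) + (if (is.na(d)) 0 else off[d]))
    }
  }
  off
}

#' Simulate phenotypes on the F2 design
#'
#' Builds each retained F2 animal's phenotype as mean + fixed effects
#' (sex, season of birth, age slope, optional length covariate) + founder
#' line offset + breeding value + residual, with residual vectors drawn per
#' animal from `N(0, R)` and per-trait missingness applied afterwards.
#' Traits are generated in the order given so an earlier trait (e.g. body
#' length) can serve as covariate for a later one via `length_from`.
#'
#' @param design An `f2_design` from [simulate_design()].
#' @param arch A [genetic_architecture()].
#' @param seed Integer seed.
#' @return A list of class `f2_sim`: `phenotypes` (retained F2 only, trait
#'   columns with `NA` for missing), `breeding_values` (all pedigree
#'   animals), `design`, `arch`.
#' @export
simulate_phenotypes <- function(design, arch, seed = 1L) {
  stopifnot(inherits(design, "f2_design"), inherits(arch, "genetic_architecture"))
  ped <- design$pedigree
  bv <- simulate_breeding_values(ped, arch, seed = seed)
  set.seed(derive_seed(seed, "phenotypes"))
  cov <- design$covariates[design$covariates$retained, , drop = FALSE]
  n <- nrow(cov)
  t <- length(arch$traits)
  resid <- matrix(stats::rnorm(n * t), n, t) %*% t(psd_sqrt(arch$R))
  bv_f2 <- as.matrix(bv[match(cov$animal, bv$animal), arch$traits, drop = FALSE])

  out <- cov[, c("animal", "sex", "sob", "litter",
                 grep("^age_", names(cov), value = TRUE))]
  for (k in seq_len(t)) {
    tr <- arch$traits[k]
    fe <- arch$fixed_effects[[tr]] %||% list()
    y <- rep(arch$means[[tr]] %||% 0, n)
    if (!is.null(fe$sex)) y <- y + fe$sex * (cov$sex == "M")
    if (!is.null(fe$sob)) {
      lev <- sort(unique(cov$sob))
      y <- y + rep_len(fe$sob, length(lev))[match(cov$sob, lev)]
    }
    if (!is.null(fe$age_slope)) {
      acol <- fe$age_column %||% "age_m2"
      if (!acol %in% names(cov)) stop("age column not simulated: ", acol)
      y <- y + fe$age_slope * cov[[acol]]
    }
    if (!is.null(fe$length_slope)) {
      src <- fe$length_from
      if (is.null(src) || !src %in% names(out)) {
        stop("trait ", tr, " uses a length covariate but '", src %||% "?",
             "' has not been generated yet")
      }
      y <- y + fe$length_slope * out[[src]]
    }
    div <- arch$line_divergence[[tr]]
    if (!is.null(div)) {
      y <- y + line_offsets(ped, as.list(div))[match(cov$animal, ped$animal)]
    }
    y <- y + bv_f2[, k] + resid[, k]
    m <- arch$missingness[[tr]]
    if (!is.null(m)) {
      m <- as.integer(m)
      if (m > n) stop("missingness for ", tr, " exceeds retained count")
      drop_idx <- sample.int(n, n - m)
      y[drop_idx] <- NA_real_
    }
    out[[tr]] <- y
  }
  structure(list(phenotypes = out, breeding_values = bv,
                 design = design, arch = arch),
            class = "f2_sim")
}

#' @export
print.f2_sim <- function(x, ...) {
  cat("<f2_sim> ", nrow(x$phenotypes), " phenotyped animals, traits: ",
      paste(x$arch$traits, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Write simulated data to pedigree and phenotype files
#'
#' @param sim An `f2_sim` object.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the two file paths.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pp <- file.path(dir, "pedigree.csv")
  fp <- file.path(dir, "phenotypes.csv")
  write_pedigree(sim$design$pedigree, pp)
  readr::write_csv(sim$phenotypes, fp, na = "")
  invisible(c(pedigree = pp, phenotypes = fp))
}
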