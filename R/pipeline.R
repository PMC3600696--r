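#' Default run configuration
#'
#' The fully populated default configuration for [run_pipeline()]:
#' simulation mode on the reference F2 design, with three demonstration
#' traits patterned on the reference population's fat percentage at DXA
#' scanning (h2 0.57), weight at two months (h2 0.78, genetic correlation
#' 0.90 with the fat trait) and fasting glucose level (h2 0.49, observed on
#' a 146-animal subset).
#'
#' @return A named list understood by [validate_config()].
#' @export
default_config <- function() {
  list(
    mode = "simulate",
    seed = 1L,
    output_dir = "f2qg-results",
    design = list(),
    architecture = list(
      traits = list(
        list(name = "dxa_fat_pct", mean = 18.6, var_p = 1, h2 = 0.57,
             sex_effect = 0.3, sob_effects = c(0, 0.2, 0.4),
             age_slope = 0.01, age_column = "age_m2"),
        list(name = "wt_2m", mean = 12.4, var_p = 1, h2 = 0.78,
             sex_effect = 0.3, sob_effects = c(0, 0.2, 0.4),
             age_slope = 0.02, age_column = "age_m2"),
        list(name = "fgl", mean = 4.5, var_p = 1, h2 = 0.49,
             sex_effect = 0.2, sob_effects = c(0, 0.1, 0.2),
             age_slope = 0.005, age_column = "age_m7", n_observed = 146L)
      ),
      genetic_correlations = list(
        list("dxa_fat_pct", "wt_2m", 0.90),
        list("dxa_fat_pct", "fgl", 0.59),
        list("wt_2m", "fgl", 0.61)
      ),
      residual_correlations = list(
        list("dxa_fat_pct", "wt_2m", 0.50),
        list("dxa_fat_pct", "fgl", 0.30),
        list("wt_2m", "fgl", 0.30)
      )
    ),
    paths = list(),
    trait_specs = NULL,
    pairs = "all",
    reml = list(),
    power_queries = list(
      list(n = 454, var_fraction = 0.005),
      list(n = 454, var_fraction = 0.02, input_scale = "genetic",
           heritability = 0.25),
      list(n = 454, var_fraction = 0.15)
    ),
    log_level = "info"
  )
}

known_config_keys <- c("mode", "seed", "output_dir", "design", "architecture",
                       "paths", "trait_specs", "pairs", "reml",
                       "power_queries", "log_level")

#' Validate a run configuration
#'
#' Reads a YAML file (or takes a list), checks keys and cross-field
#' constraints, and fills documented defaults. Unknown keys are an error in
#' strict mode, a warning otherwise.
#'
#' @param config Path to a YAML file, or a configuration list.
#' @param strict Error (default) or warn on unknown keys.
#' @return A validated configuration list of class `run_config` with all
#'   defaults filled in.
#' @export
validate_config <- function(config, strict = TRUE) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
    # YAML 1.1 reads a bare `n:` key as boolean FALSE; restore it where it
    # is a legitimate field (power queries take a sample size `n`)
    config$power_queries <- lapply(config$power_queries, function(pq) {
      names(pq)[names(pq) == "FALSE"] <- "n"
      pq
    })
  }
  stopifnot(is.list(config))
  unknown <- setdiff(names(config), known_config_keys)
  if (length(unknown) > 0) {
    msg <- paste0("unknown config key(s): ", paste(unknown, collapse = ", "))
    if (strict) stop(msg) else warning(msg)
    config <- config[intersect(names(config), known_config_keys)]
  }
  # shallow merge: a supplied top-level section replaces the default
  # wholesale (partial design overrides are completed by design_config())
  cfg <- default_config()
  cfg[names(config)] <- config
  if (!cfg$mode %in% c("simulate", "load")) {
    stop("mode must be 'simulate' or 'load'")
  }
  if (cfg$mode == "load") {
    for (k in c("pedigree", "phenotypes")) {
      if (is.null(cfg$paths[[k]])) stop("load mode requires paths$", k)
    }
  } else {
    # design overrides must construct a valid design_config
    dc <- do.call(design_config, cfg$design)
    arch <- arch_from_config(cfg$architecture)
    known_cols <- c("animal", "sex", "sob", "litter",
                    paste0("age_", names(dc$age_schedules)), arch$traits)
    cfg$.design_config <- dc
    cfg$.arch <- arch
    if (is.null(cfg$trait_specs)) {
      cfg$trait_specs <- lapply(cfg$architecture$traits, function(tr) {
        list(name = tr$name, transformation = tr$transformation %||% "none",
             fixed_factors = c("sex", "sob"),
             age = tr$age_column %||% "age_m2", length = tr$length_from)
      })
    }
    for (ts in cfg$trait_specs) {
      for (cv in c(ts$age, ts$length)) {
        if (!is.null(cv) && !cv %in% known_cols) {
          stop("trait '", ts$name, "' references undefined covariate '", cv, "'")
        }
      }
    }
  }
  cfg$seed <- as.integer(cfg$seed)
  class(cfg) <- c("run_config", "list")
  cfg
}

# Build a genetic_architecture from the config's per-trait list plus
# correlation triples.
arch_from_config <- function(ac) {
  traits <- vapply(ac$traits, `[[`, "", "name")
  t <- length(traits)
  var_p <- vapply(ac$traits, function(x) x$var_p %||% 1, 0)
  h2 <- vapply(ac$traits, function(x) x$h2 %||% 0.3, 0)
  fill_cor <- function(entries) {
    M <- diag(t)
    dimnames(M) <- list(traits, traits)
    for (e in entries %||% list()) {
      a <- e[[1]]; b <- e[[2]]; v <- as.numeric(e[[3]])
      if (!a %in% traits || !b %in% traits) {
        stop("correlation references unknown trait: ", a, " / ", b)
      }
      M[a, b] <- M[b, a] <- v
    }
    M
  }
  fixed_effects <- stats::setNames(lapply(ac$traits, function(x) {
    fe <- list()
    if (!is.null(x$sex_effect)) fe$sex <- x$sex_effect
    if (!is.null(x$sob_effects)) fe$sob <- x$sob_effects
    if (!is.null(x$age_slope)) {
      fe$age_slope <- x$age_slope
      fe$age_column <- x$age_column %||% "age_m2"
    }
    if (!is.null(x$length_slope)) {
      fe$length_slope <- x$length_slope
      fe$length_from <- x$length_from
    }
    fe
  }), traits)
  missingness <- stats::setNames(lapply(ac$traits, function(x) x$n_observed), traits)
  missingness <- missingness[!vapply(missingness, is.null, TRUE)]
  divergence <- stats::setNames(lapply(ac$traits, function(x) x$line_divergence), traits)
  divergence <- divergence[!vapply(divergence, is.null, TRUE)]
  genetic_architecture(
    traits = traits,
    var_p = var_p, h2 = h2,
    cor_g = fill_cor(ac$genetic_correlations),
    cor_r = fill_cor(ac$residual_correlations),
    means = stats::setNames(vapply(ac$traits, function(x) x$mean %||% 0, 0), traits),
    fixed_effects = fixed_effects,
    line_divergence = divergence,
    missingness = missingness
  )
}

spec_from_list <- function(ts) {
  trait_spec(name = ts$name,
             transformation = ts$transformation %||% "none",
             fixed_factors = ts$fixed_factors %||% c("sex", "sob"),
             age = ts$age, length = ts$length,
             unit = ts$unit %||% "")
}

write_tsv_commented <- function(x, path, comments) {
  readr::write_lines(paste0("# ", comments), path)
  readr::write_tsv(x, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

fmt2 <- function(est, se) {
  ifelse(is.na(est), "n.e.", sprintf("%.2f (%.2f)", est, se))
}

#' Run the full analysis pipeline
#'
#' Configuration-driven end-to-end run: simulate (or load) the population,
#' compute descriptive statistics, fit every trait univariately and every
#' requested pair bivariately, select the lowest-SE heritability per trait,
#' predict breeding values, evaluate the power queries, and write a report
#' bundle (TSV tables, full-precision JSON of every fit, and a manifest
#' with the seed and config hash). Runs are byte-reproducible given the
#' same configuration and seed.
#'
#' @param config A configuration (path, list or `run_config`); see
#'   [validate_config()].
#' @param output_dir Overrides the configured output directory.
#' @param seed Overrides the configured seed.
#' @return Invisibly, a list with every table in memory plus the output
#'   paths.
#' @export
run_pipeline <- function(config = default_config(), output_dir = NULL,
                         seed = NULL) {
  cfg <- if (inherits(config, "run_config")) config else validate_config(config)
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  if (!is.null(output_dir)) cfg$output_dir <- output_dir
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  out <- list(config = cfg)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("[stage ", name, "] ", conditionMessage(e), call. = FALSE)
    })
  }
  # ---- data
  if (cfg$mode == "simulate") {
    sim <- stage("simulate", {
      design <- simulate_design(cfg$.design_config, seed = cfg$seed)
      simulate_phenotypes(design, cfg$.arch, seed = cfg$seed)
    })
    phen <- sim$phenotypes
    ped_full <- sim$design$pedigree
    out$sim <- sim
  } else {
    phen <- stage("load", {
      readr::read_csv(cfg$paths$phenotypes, show_col_types = FALSE,
                      progress = FALSE)
    })
    ped_full <- stage("load", read_pedigree(cfg$paths$pedigree))
  }
  specs <- lapply(cfg$trait_specs, spec_from_list)
  trait_names <- vapply(specs, `[[`, "", "name")
  ped <- stage("pedigree", prune_to_phenotyped(ped_full, phen$animal))
  relmat <- stage("pedigree", relationship_matrix(ped))
  reml_opts <- do.call(reml_options, cfg$reml)

  # ---- descriptives
  desc <- stage("describe", describe_traits(phen, trait_names))
  write_tsv_commented(desc, file.path(cfg$output_dir, "descriptives.tsv"),
                      c("descriptive statistics (non-missing records)",
                        "cv_percent = 100 * sd / mean"))
  out$descriptives <- desc

  # ---- univariate fits
  fits_uni <- stage("fit", {
    stats::setNames(lapply(specs, function(sp) {
      ds <- build_design(phen, sp, ped)
      reml_univariate(ds, relmat, reml_opts)
    }), trait_names)
  })
  out$fits_uni <- fits_uni

  # ---- bivariate fits
  pair_list <- if (identical(cfg$pairs, "all")) {
    if (length(specs) >= 2) utils::combn(seq_along(specs), 2, simplify = FALSE) else list()
  } else {
    lapply(cfg$pairs, function(p) match(unlist(p), trait_names))
  }
  fits_biv <- stage("fit", lapply(pair_list, function(ij) {
    ds <- build_design(phen, specs[ij], ped)
    reml_bivariate(ds, relmat, reml_opts)
  }))
  out$fits_biv <- fits_biv

  # ---- heritability table: univariate and lowest-SE selection
  h2_tbl <- stage("report", {
    purrr::map_dfr(trait_names, function(tr) {
      cand <- list(heritability(fits_uni[[tr]]))
      for (bf in fits_biv) {
        if (tr %in% bf$traits && bf$converged) {
          cand <- c(cand, list(heritability(bf, tr)))
        }
      }
      uni <- cand[[1]]
      sel <- tryCatch(select_heritability(cand), error = function(e) NULL)
      tibble::tibble(
        trait = tr,
        h2_univariate = uni$h2, se_univariate = uni$se,
        h2_selected = if (is.null(sel)) NA_real_ else sel$h2,
        se_selected = if (is.null(sel)) NA_real_ else sel$se,
        selected_source = if (is.null(sel)) "none converged" else sel$source
      )
    })
  })
  write_tsv_commented(h2_tbl, file.path(cfg$output_dir, "heritability.tsv"),
                      c("heritability: univariate and lowest-SE selection",
                        "SEs by first-order delta method from the inverse AI matrix"))
  out$heritability <- h2_tbl

  # ---- pairwise correlation matrix: rg above diagonal, rp below
  if (length(fits_biv) > 0) {
    k <- length(trait_names)
    M <- matrix("-", k, k, dimnames = list(trait_names, trait_names))
    cor_rows <- list()
    for (bf in fits_biv) {
      i <- match(bf$traits[1], trait_names)
      j <- match(bf$traits[2], trait_names)
      if (bf$converged) {
        cc <- suppressMessages(correlations(bf))
        rg_est <- cc$estimate[cc$term == "rg"]
        rg_se <- cc$se[cc$term == "rg"]
        rp_est <- cc$estimate[cc$term == "rp"]
        rp_se <- cc$se[cc$term == "rp"]
        M[min(i, j), max(i, j)] <- fmt2(rg_est, rg_se)
        M[max(i, j), min(i, j)] <- fmt2(rp_est, rp_se)
        cor_rows[[length(cor_rows) + 1]] <- tibble::tibble(
          trait1 = bf$traits[1], trait2 = bf$traits[2],
          rg = rg_est, rg_se = rg_se, rp = rp_est, rp_se = rp_se,
          significant = !is.na(rg_est) & abs(rg_est) > 2 * rg_se,
          converged = TRUE)
      } else {
        M[min(i, j), max(i, j)] <- "n.c."
        M[max(i, j), min(i, j)] <- "n.c."
        cor_rows[[length(cor_rows) + 1]] <- tibble::tibble(
          trait1 = bf$traits[1], trait2 = bf$traits[2],
          rg = NA_real_, rg_se = NA_real_, rp = NA_real_, rp_se = NA_real_,
          significant = NA, converged = FALSE)
      }
    }
    cor_mat <- tibble::as_tibble(M, rownames = "trait")
    write_tsv_commented(
      cor_mat, file.path(cfg$output_dir, "correlations.tsv"),
      c("genetic correlations above the diagonal, phenotypic below; SE in parentheses",
        "estimates flagged significant when |estimate| > 2 SE; n.c. = not converged"))
    out$correlations <- dplyr::bind_rows(cor_rows)
    readr::write_tsv(out$correlations,
                     file.path(cfg$output_dir, "correlations_long.tsv"))
  }

  # ---- EBVs
  ebv_all <- stage("predict", {
    purrr::map_dfr(trait_names, function(tr) {
      f <- fits_uni[[tr]]
      if (!f$converged) return(tibble::tibble())
      predict_ebv(f)
    })
  })
  if (nrow(ebv_all) > 0) {
    readr::write_tsv(ebv_all, file.path(cfg$output_dir, "ebv.tsv"))
    hist_tbl <- purrr::map_dfr(split(ebv_all, ebv_all$trait), function(d) {
      dplyr::bind_cols(tibble::tibble(trait = d$trait[1]), ebv_histogram(d))
    })
    readr::write_tsv(hist_tbl, file.path(cfg$output_dir, "ebv_histogram.tsv"))
    out$ebv <- ebv_all
  }

  # ---- power
  if (length(cfg$power_queries) > 0) {
    pow <- stage("power", purrr::map_dfr(cfg$power_queries, function(pq) {
      do.call(f2_qtl_power, pq)
    }))
    write_tsv_commented(pow, file.path(cfg$output_dir, "power.tsv"),
                        "analytic F2 single-locus power; all assumptions echoed per row")
    out$power <- pow
  }

  # ---- full-precision fit dump + manifest
  fit_json <- c(
    lapply(fits_uni, function(f) list(
      type = "univariate", trait = f$trait,
      sigma2_a = f$sigma2_a, sigma2_e = f$sigma2_e,
      sampling_cov = f$sampling_cov, loglik = f$loglik,
      converged = f$converged, boundary = f$boundary,
      iterations = f$iterations, trace = f$trace)),
    lapply(fits_biv, function(f) list(
      type = "bivariate", traits = f$traits,
      G = f$G, R = f$R, sampling_cov = f$sampling_cov, loglik = f$loglik,
      converged = f$converged, boundary = f$boundary,
      iterations = f$iterations))
  )
  jsonlite::write_json(fit_json, file.path(cfg$output_dir, "fits.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       matrix = "rowmajor")
  manifest <- list(
    seed = cfg$seed,
    config_hash = rlang::hash(
      unclass(cfg)[setdiff(names(cfg), c("output_dir", ".design_config", ".arch"))]),
    package_version = as.character(utils::packageVersion("f2qg")),
    mode = cfg$mode,
    traits = trait_names,
    n_phenotyped = nrow(phen),
    n_pedigree = nrow(ped),
    converged_univariate = vapply(fits_uni, `[[`, TRUE, "converged"),
    converged_bivariate = vapply(fits_biv, `[[`, TRUE, "converged")
  )
  jsonlite::write_json(manifest, file.path(cfg$output_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  out$manifest <- manifest
  invisible(out)
}
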