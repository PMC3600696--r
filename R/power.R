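#' QTL-detection power for an F2 intercross
#'
#' Analytic power of the single-locus test in an F2 design. The
#' noncentrality is `lambda = n p / (1 - p)` with `p` the fraction of
#' phenotypic variance explained by the QTL, attenuated for imperfect marker
#' coverage by the squared correlation `(1 - 2r)^2` between the QTL and the
#' nearest marker at half the average spacing (Haldane map function). Power
#' is the upper-tail probability of a noncentral chi-square (1 df additive,
#' 2 df with dominance) beyond the threshold implied by the significance
#' level; genome-wide control uses a Sidak correction over the effective
#' number of independent tests (`genome_length / spacing`).
#'
#' @param n F2 sample size.
#' @param var_fraction Proportion of variance explained by the QTL; in
#'   `[0, 1)`.
#' @param input_scale `"phenotypic"` (default) or `"genetic"`; on the
#'   genetic scale the fraction is multiplied by `heritability` to convert
#'   to the phenotypic scale.
#' @param heritability Trait heritability, required for
#'   `input_scale = "genetic"`.
#' @param marker_spacing_cm Average marker spacing, cM.
#' @param alpha Significance level.
#' @param alpha_scope `"genomewide"` (default) or `"pointwise"`.
#' @param genome_length_cm,n_chromosomes Genome model for the genome-wide
#'   correction (defaults: 2300 cM over 18 autosomes, a standard pig map).
#' @param dominance If `TRUE`, a 2-df additive+dominance test.
#' @return A one-row tibble: `power`, `noncentrality`, `threshold`, `df`,
#'   `alpha_pointwise`, plus an echo of the assumptions.
#' @examples
#' f2_qtl_power(n = 454, var_fraction = 0.05)
#' @export
f2_qtl_power <- function(n, var_fraction,
                         input_scale = c("phenotypic", "genetic"),
                         heritability = NULL,
                         marker_spacing_cm = 1, alpha = 0.05,
                         alpha_scope = c("genomewide", "pointwise"),
                         genome_length_cm = 2300, n_chromosomes = 18L,
                         dominance = FALSE) {
  input_scale <- match.arg(input_scale)
  alpha_scope <- match.arg(alpha_scope)
  if (n < 10) stop("n must be at least 10")
  if (marker_spacing_cm <= 0) stop("marker spacing must be positive")
  p <- var_fraction
  if (input_scale == "genetic") {
    if (is.null(heritability)) {
      stop("heritability is required to convert a genetic-variance fraction")
    }
    p <- var_fraction * heritability
  }
  if (p < 0 || p >= 1) stop("variance fraction must be in [0, 1)")
  # attenuation: marker at most spacing/2 from the QTL on average
  r <- 0.5 * (1 - exp(-2 * (marker_spacing_cm / 2) / 100))
  shrink <- (1 - 2 * r)^2
  lambda <- n * p / (1 - p) * shrink
  df <- if (dominance) 2L else 1L
  alpha_pt <- if (alpha_scope == "genomewide") {
    m <- max(1, ceiling(genome_length_cm / marker_spacing_cm))
    1 - (1 - alpha)^(1 / m)
  } else {
    alpha
  }
  threshold <- stats::qchisq(1 - alpha_pt, df)
  pow <- stats::pchisq(threshold, df, ncp = lambda, lower.tail = FALSE)
  tibble::tibble(
    power = pow, noncentrality = lambda, threshold = threshold, df = df,
    alpha_pointwise = alpha_pt, n = n, var_fraction_phenotypic = p,
    marker_spacing_cm = marker_spacing_cm, alpha = alpha,
    alpha_scope = alpha_scope, genome_length_cm = genome_length_cm,
    n_chromosomes = as.integer(n_chromosomes), dominance = dominance
  )
}

#' Smallest F2 sample size reaching a target power
#'
#' Integer bisection on [f2_qtl_power()]: returns the smallest `n` whose
#' power reaches `target_power`.
#'
#' @param target_power Required power, in (0, 1).
#' @param ... Passed to [f2_qtl_power()] (everything except `n`).
#' @param n_max Search ceiling.
#' @return The smallest sufficient integer `n`.
#' @export
f2_sample_size <- function(target_power, ..., n_max = 1e6L) {
  if (target_power <= 0 || target_power >= 1) {
    stop("target_power must be in (0, 1)")
  }
  pw <- function(n) f2_qtl_power(n = n, ...)$power
  lo <- 10L
  hi <- as.integer(n_max)
  if (pw(hi) < target_power) {
    stop("target power unreachable below n_max = ", n_max)
  }
  if (pw(lo) >= target_power) return(lo)
  while (hi - lo > 1L) {
    mid <- (lo + hi) %/% 2L
    if (pw(mid) >= target_power) hi <- mid else lo <- mid
  }
  hi
}

#' Observed-scale to liability-scale heritability
#'
#' Dempster-Lerner conversion for a categorical (threshold) trait:
#' `h2_liab = h2_obs * p (1 - p) / z^2` with `p` the prevalence and `z` the
#' standard-normal density at the liability threshold.
#'
#' @param h2_observed Heritability on the observed (0/1) scale.
#' @param prevalence Trait prevalence, in (0, 1).
#' @return Heritability on the underlying liability scale.
#' @examples
#' liability_scale_h2(0.3, 0.5) # multiplier pi/2 at 50% prevalence
#' @export
liability_scale_h2 <- function(h2_observed, prevalence) {
  if (any(prevalence <= 0 | prevalence >= 1)) {
    stop("prevalence must be strictly between 0 and 1")
  }
  z <- stats::dnorm(stats::qnorm(1 - prevalence))
  h2_observed * prevalence * (1 - prevalence) / z^2
}

#' Power curve over a grid
#'
#' Evaluates [f2_qtl_power()] over a grid of sample sizes and variance
#' fractions, for reporting and plotting.
#'
#' @param n Vector of sample sizes.
#' @param var_fraction Vector of variance fractions.
#' @param ... Passed to [f2_qtl_power()].
#' @return A tibble with one row per grid point.
#' @export
power_curve <- function(n, var_fraction, ...) {
  grid <- tidyr::expand_grid(n = n, var_fraction = var_fraction)
  purrr::pmap_dfr(grid, function(n, var_fraction) {
    f2_qtl_power(n = n, var_fraction = var_fraction, ...)
  })
}

#' Plot a power curve
#'
#' @param curve Output of [power_curve()].
#' @return A ggplot of power against sample size, one line per variance
#'   fraction.
#' @export
plot_power_curve <- function(curve) {
  ggplot2::ggplot(curve,
                  ggplot2::aes(x = .data$n, y = .data$power,
                               color = factor(.data$var_fraction_phenotypic))) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 0.8, linetype = "dashed", color = "grey50") +
    ggplot2::labs(x = "F2 sample size", y = "power",
                  color = "variance fraction") +
    ggplot2::theme_minimal()
}
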