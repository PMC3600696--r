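#' Trait analysis specification
#'
#' Describes how one trait enters the animal model: the normalizing
#' transformation, which fixed factors apply, and which age/length columns
#' serve as covariates.
#'
#' @param name Trait (column) name in the phenotype table.
#' @param transformation `"none"`, `"log10"` or `"sqrt"`, applied to the
#'   response before fitting.
#' @param fixed_factors Subset of `c("sex", "sob")`.
#' @param age Name of the age covariate column, or `NULL`.
#' @param length Name of the body-length covariate column, or `NULL`
#'   (used only for the mass-type traits where conformation differences
#'   between founder breeds must be adjusted for).
#' @param unit Free-text unit for reports.
#' @return A list of class `trait_spec`.
#' @export
trait_spec <- function(name, transformation = "none",
                       fixed_factors = c("sex", "sob"),
                       age = "age_m2", length = NULL, unit = "") {
  stopifnot(is.character(name), length(name) == 1)
  transformation <- match.arg(transformation, c("none", "log10", "sqrt"))
  if (length(fixed_factors) > 0) {
    fixed_factors <- match.arg(fixed_factors, c("sex", "sob"), several.ok = TRUE)
  }
  structure(list(name = name, transformation = transformation,
                 fixed_factors = fixed_factors, age = age,
                 length = length, unit = unit),
            class = "trait_spec")
}

#' REML fitting options
#'
#' @param max_iter Maximum iterations.
#' @param em_iter Number of initial EM iterations before switching to
#'   average-information updates (EM guarantees likelihood ascent; AI then
#'   converges quadratically).
#' @param algorithm `"em+ai"` (default), `"em"` (EM only) or `"ai"`.
#' @param tol_loglik Relative log-likelihood change declaring convergence.
#' @param tol_param Maximum relative parameter change declaring convergence.
#' @param var_floor_frac Variance floor as a fraction of the phenotypic
#'   variance; estimates clamped here are flagged as boundary solutions.
#' @param max_halvings Step halvings allowed before an AI step falls back
#'   to one EM step.
#' @return A list of class `reml_options`.
#' @export
reml_options <- function(max_iter = 200L, em_iter = 5L,
                         algorithm = c("em+ai", "em", "ai"),
                         tol_loglik = 1e-9, tol_param = 1e-6,
                         var_floor_frac = 1e-6, max_halvings = 10L) {
  structure(list(max_iter = as.integer(max_iter), em_iter = as.integer(em_iter),
                 algorithm = match.arg(algorithm),
                 tol_loglik = tol_loglik, tol_param = tol_param,
                 var_floor_frac = var_floor_frac,
                 max_halvings = as.integer(max_halvings)),
            class = "reml_options")
}

# ---- design construction -------------------------------------------------

build_one_design <- function(data, spec, ped_ids) {
  if (!spec$name %in% names(data)) stop("trait column not found: ", spec$name)
  y_raw <- data[[spec$name]]
  needed <- c(spec$age, spec$length)
  usable <- !is.na(y_raw)
  for (cv in needed) {
    if (!cv %in% names(data)) stop("covariate column not found: ", cv)
    usable <- usable & !is.na(data[[cv]])
  }
  for (ff in spec$fixed_factors) {
    if (!ff %in% names(data)) stop("factor column not found: ", ff)
    usable <- usable & !is.na(data[[ff]])
  }
  dropped <- tibble::tibble(animal = data$animal[!usable],
                            reason = "missing response or covariate")
  d <- data[usable, , drop = FALSE]
  if (nrow(d) == 0) stop("no usable records for trait ", spec$name)
  missing_ped <- setdiff(d$animal, ped_ids)
  if (length(missing_ped) > 0) {
    stop("phenotyped animal(s) not in pedigree: ",
         paste(utils::head(missing_ped, 5), collapse = ", "))
  }
  y <- transform_values(d[[spec$name]], spec$transformation)
  cols <- list(`(Intercept)` = rep(1, nrow(d)))
  for (ff in spec$fixed_factors) {
    lev <- sort(unique(as.character(d[[ff]])))
    if (length(lev) < 2) {
      stop("factor '", ff, "' has a single level among usable records")
    }
    for (l in lev[-1]) { # reference coding, sorted first level as reference
      cols[[paste0(ff, l)]] <- as.numeric(d[[ff]] == l)
    }
  }
  for (cv in needed) {
    x <- as.numeric(d[[cv]])
    cols[[cv]] <- x - mean(x) # centered to decouple the intercept
  }
  X <- do.call(cbind, cols)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    aliased <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("rank-deficient fixed-effect design; aliased: ",
         paste(aliased, collapse = ", "))
  }
  list(trait = spec$name, spec = spec, y = y, X = X,
       animal = d$animal, dropped = dropped)
}

#' Build the animal-model design system
#'
#' Drops records with missing response or covariates, applies the trait
#' transformation, and builds the fixed-effects incidence matrix (intercept,
#' reference-coded factors with the sorted-first level as reference, and
#' centered covariates). With two trait specifications a stacked system is
#' prepared, permitting different record sets per trait.
#'
#' @param data Phenotype data frame with an `animal` column.
#' @param spec A [trait_spec()], or a list of two for a bivariate system.
#' @param ped An `f2qg_ped` pedigree covering all phenotyped animals.
#' @return A list of class `design_system` with one element per trait
#'   (`y`, `X`, `animal`, `dropped`) plus the shared pedigree ids.
#' @export
build_design <- function(data, spec, ped) {
  specs <- if (inherits(spec, "trait_spec")) list(spec) else spec
  stopifnot(length(specs) %in% 1:2,
            all(vapply(specs, inherits, TRUE, "trait_spec")))
  parts <- lapply(specs, build_one_design, data = data, ped_ids = ped$animal)
  ds <- list(parts = parts, ped_ids = ped$animal,
             traits = vapply(parts, `[[`, "", "trait"))
  if (length(parts) == 2) {
    ds$overlap <- intersect(parts[[1]]$animal, parts[[2]]$animal)
    if (length(ds$overlap) == 0) {
      ds$residual_cov_estimable <- FALSE
      warning("trait record sets are disjoint; residual covariance is not estimable")
    } else {
      ds$residual_cov_estimable <- length(ds$overlap) >= 10
    }
  }
  class(ds) <- "design_system"
  ds
}

# ---- univariate REML core ------------------------------------------------

# Likelihood machinery for V = sa*K + se*I. `lite` skips the projection
# matrix P (only needed for gradients/traces, not for step acceptance).
uni_eval <- function(th, y, X, K, lite = FALSE) {
  n <- length(y)
  V <- th[1] * K
  diag(V) <- diag(V) + th[2]
  cV <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(cV)) return(NULL)
  solveV <- function(B) backsolve(cV, forwardsolve(t(cV), B))
  VinvX <- solveV(X)
  Vinvy <- drop(solveV(y))
  XtVinvX <- crossprod(X, VinvX)
  cXX <- tryCatch(chol(XtVinvX), error = function(e) NULL)
  if (is.null(cXX)) return(NULL)
  beta <- backsolve(cXX, forwardsolve(t(cXX), crossprod(X, Vinvy)))
  Py <- Vinvy - drop(VinvX %*% beta)
  ll <- -0.5 * (2 * sum(log(diag(cV))) + 2 * sum(log(diag(cXX))) + sum(y * Py))
  out <- list(ll = ll, Py = Py, beta = drop(beta))
  if (!lite) {
    Vinv <- chol2inv(cV)
    out$P <- Vinv - VinvX %*% chol2inv(cXX) %*% t(VinvX)
  }
  out
}

reml_uni_core <- function(y, X, K, q, options) {
  n <- length(y)
  p <- ncol(X)
  vp <- sum(stats::lm.fit(X, y)$residuals^2) / max(1L, n - p)
  floor_v <- options$var_floor_frac * vp
  th <- c(sigma2_a = vp / 2, sigma2_e = vp / 2)
  st <- uni_eval(th, y, X, K)
  if (is.null(st)) stop("singular starting value in REML")
  trace <- vector("list", options$max_iter)
  converged <- FALSE
  it <- 0L
  stall <- 0L
  repeat {
    it <- it + 1L
    Py <- st$Py
    P <- st$P
    KPy <- drop(K %*% Py)
    yPKPy <- sum(Py * KPy)
    yPPy <- sum(Py^2)
    trPK <- sum(P * K)
    trP <- sum(diag(P))
    grad <- -0.5 * c(trPK - yPKPy, trP - yPPy)
    use_em <- options$algorithm == "em" ||
      (options$algorithm == "em+ai" && it <= options$em_iter)
    em_step <- function() {
      pmax(c(th[1] + th[1]^2 / q * (yPKPy - trPK),
             th[2] + th[2]^2 / n * (yPPy - trP)), floor_v)
    }
    PKPy <- drop(P %*% KPy)
    PPy <- drop(P %*% Py)
    AI <- 0.5 * matrix(c(sum(KPy * PKPy), sum(KPy * PPy),
                         sum(KPy * PPy), sum(Py * PPy)), 2L, 2L)
    method <- if (use_em) "em" else "ai"
    trace[[it]] <- c(iter = it, sigma2_a = unname(th[1]),
                     sigma2_e = unname(th[2]), loglik = st$ll,
                     method = method)
    th_new <- NULL
    st_new <- NULL
    if (!use_em) {
      step <- tryCatch(solve(AI, grad), error = function(e) NULL)
      if (!is.null(step)) {
        h <- 1
        for (halv in 0:options$max_halvings) {
          cand <- pmax(th + h * step, floor_v)
          st_try <- uni_eval(cand, y, X, K, lite = TRUE)
          if (!is.null(st_try) && st_try$ll >= st$ll - 1e-12) {
            th_new <- cand
            break
          }
          h <- h / 2
        }
      }
      if (is.null(th_new)) method <- "em" # AI step failed; EM fallback
    }
    if (is.null(th_new)) th_new <- em_step()
    names(th_new) <- names(th)
    st_new <- uni_eval(th_new, y, X, K)
    dll <- st_new$ll - st$ll
    dpar <- max(abs(th_new - th) / (abs(th) + floor_v))
    th <- th_new
    st <- st_new
    ll_flat <- abs(dll) < options$tol_loglik * (1 + abs(st$ll))
    if (ll_flat && dpar < options$tol_param) {
      converged <- TRUE
      break
    }
    stall <- if (ll_flat) stall + 1L else 0L
    if (stall >= 3L) { # flat likelihood with a floored component
      converged <- TRUE
      break
    }
    if (it >= options$max_iter) break
  }
  # final gradients/AI at the optimum for the sampling covariance
  Py <- st$Py
  P <- st$P
  KPy <- drop(K %*% Py)
  PKPy <- drop(P %*% KPy)
  PPy <- drop(P %*% Py)
  AI <- 0.5 * matrix(c(sum(KPy * PKPy), sum(KPy * PPy),
                       sum(KPy * PPy), sum(Py * PPy)), 2L, 2L)
  sampling_cov <- tryCatch(solve(AI), error = function(e) matrix(NA_real_, 2L, 2L))
  dimnames(sampling_cov) <- list(c("sigma2_a", "sigma2_e"),
                                 c("sigma2_a", "sigma2_e"))
  tr <- do.call(rbind, trace[seq_len(it)])
  trace_tbl <- tibble::tibble(
    iter = as.integer(tr[, "iter"]),
    method = as.character(tr[, "method"]),
    sigma2_a = as.numeric(tr[, "sigma2_a"]),
    sigma2_e = as.numeric(tr[, "sigma2_e"]),
    loglik = as.numeric(tr[, "loglik"])
  )
  list(sigma2_a = unname(th[1]), sigma2_e = unname(th[2]),
       sampling_cov = sampling_cov, loglik = st$ll, converged = converged,
       boundary = any(th <= floor_v * (1 + 1e-9)),
       beta = st$beta, Py = st$Py, trace = trace_tbl,
       n_records = n, var_floor = floor_v, iterations = it)
}

#' Univariate animal-model REML
#'
#' Fits `y = X b + Z a + e` with `var(a) = A sigma2_a`, `var(e) = I sigma2_e`
#' by restricted maximum likelihood: a handful of EM iterations (guaranteed
#' ascent) followed by average-information (AI) updates, any AI step that
#' would decrease the log-likelihood or leave the feasible region being
#' halved and ultimately replaced by an EM step. The sampling covariance of
#' the estimates is the inverse AI matrix at the optimum.
#'
#' @param ds A univariate [build_design()] system.
#' @param relmat A [relationship_matrix()] covering the design's animals.
#' @param options [reml_options()].
#' @return An object of class `f2qg_reml` (and `f2qg_reml_uni`) holding the
#'   variance components, their sampling covariance, fixed-effect solutions,
#'   the REML log-likelihood, a per-iteration trace, and what is needed to
#'   compute breeding values with [predict_ebv()]. Non-convergence is
#'   flagged, not an error.
#' @export
reml_univariate <- function(ds, relmat, options = reml_options()) {
  stopifnot(inherits(ds, "design_system"), length(ds$parts) == 1)
  part <- ds$parts[[1]]
  z <- match(part$animal, relmat$ids)
  if (anyNA(z)) stop("design animals missing from relationship matrix")
  K <- relmat$A[z, z]
  core <- reml_uni_core(part$y, part$X, K, q = length(relmat$ids), options)
  names(core$beta) <- colnames(part$X)
  fit <- c(core, list(trait = part$trait, design = part, z = z,
                      relmat = relmat, options = options))
  class(fit) <- c("f2qg_reml_uni", "f2qg_reml")
  fit
}

# ---- bivariate REML ------------------------------------------------------

biv_structures <- function(ds, relmat) {
  p1 <- ds$parts[[1]]
  p2 <- ds$parts[[2]]
  z1 <- match(p1$animal, relmat$ids)
  z2 <- match(p2$animal, relmat$ids)
  if (anyNA(c(z1, z2))) stop("design animals missing from relationship matrix")
  n1 <- length(z1)
  n2 <- length(z2)
  ov <- intersect(p1$animal, p2$animal)
  o1 <- match(ov, p1$animal)
  o2 <- match(ov, p2$animal)
  list(z1 = z1, z2 = z2, n1 = n1, n2 = n2, o1 = o1, o2 = o2,
       K11 = relmat$A[z1, z1], K12 = relmat$A[z1, z2], K22 = relmat$A[z2, z2],
       y = c(p1$y, p2$y),
       X = rbind(cbind(p1$X, matrix(0, n1, ncol(p2$X))),
                 cbind(matrix(0, n2, ncol(p1$X)), p2$X)))
}

biv_V <- function(th, S) {
  n <- S$n1 + S$n2
  i1 <- seq_len(S$n1)
  i2 <- S$n1 + seq_len(S$n2)
  V <- matrix(0, n, n)
  V[i1, i1] <- th["g11"] * S$K11
  V[i1, i2] <- th["g12"] * S$K12
  V[i2, i1] <- t(V[i1, i2])
  V[i2, i2] <- th["g22"] * S$K22
  diag(V)[i1] <- diag(V)[i1] + th["r11"]
  diag(V)[i2] <- diag(V)[i2] + th["r22"]
  if (length(S$o1) > 0 && th["r12"] != 0) {
    idx <- cbind(S$o1, S$n1 + S$o2)
    V[idx] <- V[idx] + th["r12"]
    V[idx[, 2:1, drop = FALSE]] <- V[idx[, 2:1, drop = FALSE]] + th["r12"]
  }
  V
}

# Bi %*% v for each of the six structure matrices, without materializing Bi
biv_Bmul <- function(k, v, S) {
  i1 <- seq_len(S$n1)
  i2 <- S$n1 + seq_len(S$n2)
  out <- numeric(S$n1 + S$n2)
  switch(k,
    g11 = { out[i1] <- S$K11 %*% v[i1] },
    g12 = { out[i1] <- S$K12 %*% v[i2]; out[i2] <- crossprod(S$K12, v[i1]) },
    g22 = { out[i2] <- S$K22 %*% v[i2] },
    r11 = { out[i1] <- v[i1] },
    r12 = {
      if (length(S$o1) > 0) {
        out[S$o1] <- v[S$n1 + S$o2]
        out[S$n1 + S$o2] <- v[S$o1]
      }
    },
    r22 = { out[i2] <- v[i2] }
  )
  out
}

# tr(M Bk) for dense symmetric M
biv_trMB <- function(k, M, S) {
  i1 <- seq_len(S$n1)
  i2 <- S$n1 + seq_len(S$n2)
  switch(k,
    g11 = sum(M[i1, i1] * S$K11),
    g12 = 2 * sum(M[i1, i2] * S$K12),
    g22 = sum(M[i2, i2] * S$K22),
    r11 = sum(diag(M)[i1]),
    r12 = if (length(S$o1) > 0) 2 * sum(M[cbind(S$o1, S$n1 + S$o2)]) else 0,
    r22 = sum(diag(M)[i2])
  )
}

biv_eval <- function(th, S, lite = FALSE) {
  V <- biv_V(th, S)
  cV <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(cV)) return(NULL)
  y <- S$y
  X <- S$X
  solveV <- function(B) backsolve(cV, forwardsolve(t(cV), B))
  VinvX <- solveV(X)
  Vinvy <- drop(solveV(y))
  XtVinvX <- crossprod(X, VinvX)
  cXX <- tryCatch(chol(XtVinvX), error = function(e) NULL)
  if (is.null(cXX)) return(NULL)
  beta <- backsolve(cXX, forwardsolve(t(cXX), crossprod(X, Vinvy)))
  Py <- Vinvy - drop(VinvX %*% beta)
  ll <- -0.5 * (2 * sum(log(diag(cV))) + 2 * sum(log(diag(cXX))) + sum(y * Py))
  out <- list(ll = ll, Py = Py, beta = drop(beta))
  if (!lite) {
    Vinv <- chol2inv(cV)
    out$P <- Vinv - VinvX %*% chol2inv(cXX) %*% t(VinvX)
  }
  out
}

biv_feasible <- function(th, floors) {
  th["g11"] >= floors["g"] && th["g22"] >= floors["g"] &&
    th["r11"] >= floors["r"] && th["r22"] >= floors["r"] &&
    abs(th["g12"]) <= 0.999 * sqrt(th["g11"] * th["g22"]) &&
    abs(th["r12"]) <= 0.999 * sqrt(th["r11"] * th["r22"])
}

# One matrix-form EM step for (G, R): conditional expectations of
# u' Ainv u and e e' given the data at the current parameters.
biv_em_step <- function(th, st, S, relmat, estimate_r12) {
  q <- length(relmat$ids)
  A <- relmat$A
  Py <- st$Py
  P <- st$P
  i1 <- seq_len(S$n1)
  i2 <- S$n1 + seq_len(S$n2)
  t1 <- numeric(q); t1[S$z1] <- Py[i1]
  t2 <- numeric(q); t2[S$z2] <- Py[i2]
  At1 <- drop(A %*% t1)
  At2 <- drop(A %*% t2)
  u1 <- th["g11"] * At1 + th["g12"] * At2
  u2 <- th["g12"] * At1 + th["g22"] * At2
  # M = Zs' P Zs scattered onto pedigree levels (records are unique levels)
  M11 <- matrix(0, q, q); M11[S$z1, S$z1] <- P[i1, i1]
  M12 <- matrix(0, q, q); M12[S$z1, S$z2] <- P[i1, i2]
  M22 <- matrix(0, q, q); M22[S$z2, S$z2] <- P[i2, i2]
  g <- th
  # T = M (G x A) blockwise, then W = (G x A) T
  T11 <- (g["g11"] * M11 + g["g12"] * M12) %*% A
  T21 <- (g["g11"] * t(M12) + g["g12"] * M22) %*% A
  T12 <- (g["g12"] * M11 + g["g22"] * M12) %*% A
  T22 <- (g["g12"] * t(M12) + g["g22"] * M22) %*% A
  W11 <- A %*% (g["g11"] * T11 + g["g12"] * T21)
  W12 <- A %*% (g["g11"] * T12 + g["g12"] * T22)
  W22 <- A %*% (g["g12"] * T12 + g["g22"] * T22)
  # general (not symmetric-storage) triplets: both triangles needed below
  Ainv <- as(as(relmat$Ainv, "generalMatrix"), "TsparseMatrix")
  ai <- Ainv@i + 1L
  aj <- Ainv@j + 1L
  ax <- Ainv@x
  trAinv <- function(B) sum(ax * B[cbind(aj, ai)]) # tr(Ainv B) = sum Ainv_ij B_ji
  Euu11 <- trAinv(tcrossprod(u1) + g["g11"] * A - W11)
  Euu12 <- trAinv(tcrossprod(u1, u2) + g["g12"] * A - W12)
  Euu22 <- trAinv(tcrossprod(u2) + g["g22"] * A - W22)
  g11 <- Euu11 / q
  g12 <- Euu12 / q
  g22 <- Euu22 / q
  # residual part
  Rs <- biv_V(stats::setNames(c(0, 0, 0, th["r11"], th["r12"], th["r22"]),
                              c("g11", "g12", "g22", "r11", "r12", "r22")), S)
  e <- drop(Rs %*% Py)
  RPR <- Rs %*% P %*% Rs
  r11 <- mean(e[i1]^2 + th["r11"] - diag(RPR)[i1])
  r22 <- mean(e[i2]^2 + th["r22"] - diag(RPR)[i2])
  r12 <- if (estimate_r12 && length(S$o1) > 0) {
    idx <- cbind(S$o1, S$n1 + S$o2)
    mean(e[S$o1] * e[S$n1 + S$o2] + th["r12"] - RPR[idx])
  } else 0
  stats::setNames(c(g11, g12, g22, r11, r12, r22),
                  c("g11", "g12", "g22", "r11", "r12", "r22"))
}

#' Bivariate animal-model REML
#'
#' Fits the stacked two-trait animal model with genetic covariance
#' structured by the relationship matrix and a residual covariance estimated
#' only from animals recording both traits. Estimation follows the same
#' EM-warm-start + average-information scheme as [reml_univariate()]; AI
#' steps that would decrease the likelihood or leave the feasible region
#' (non-PSD G or R) are halved and finally replaced by one matrix-form EM
#' step. When fewer than 10 animals record both traits the residual
#' covariance is fixed at zero with a warning.
#'
#' @param ds A two-trait [build_design()] system.
#' @param relmat A [relationship_matrix()].
#' @param options [reml_options()].
#' @return An object of class `f2qg_reml` (and `f2qg_reml_biv`) with `G`,
#'   `R` (2x2 matrices), the 6x6 sampling covariance of
#'   `(g11, g12, g22, r11, r12, r22)`, log-likelihood, trace, and flags.
#' @export
reml_bivariate <- function(ds, relmat, options = reml_options()) {
  stopifnot(inherits(ds, "design_system"), length(ds$parts) == 2)
  S <- biv_structures(ds, relmat)
  q <- length(relmat$ids)
  estimate_r12 <- isTRUE(ds$residual_cov_estimable)
  if (!estimate_r12 && length(S$o1) > 0 && length(S$o1) < 10) {
    warning("fewer than 10 animals record both traits; residual covariance fixed at 0")
  }
  # univariate warm starts per trait
  uopt <- options
  uopt$max_iter <- 50L
  u1 <- reml_uni_core(ds$parts[[1]]$y, ds$parts[[1]]$X, S$K11, q, uopt)
  u2 <- reml_uni_core(ds$parts[[2]]$y, ds$parts[[2]]$X, S$K22, q, uopt)
  rho <- if (length(S$o1) > 1) {
    r1 <- stats::lm.fit(ds$parts[[1]]$X, ds$parts[[1]]$y)$residuals[S$o1]
    r2 <- stats::lm.fit(ds$parts[[2]]$X, ds$parts[[2]]$y)$residuals[S$o2]
    stats::cor(r1, r2)
  } else 0
  th <- c(g11 = u1$sigma2_a, g12 = 0.5 * rho * sqrt(u1$sigma2_a * u2$sigma2_a),
          g22 = u2$sigma2_a, r11 = u1$sigma2_e,
          r12 = if (estimate_r12) 0.5 * rho * sqrt(u1$sigma2_e * u2$sigma2_e) else 0,
          r22 = u2$sigma2_e)
  floors <- c(g = options$var_floor_frac * (u1$sigma2_a + u1$sigma2_e +
                                              u2$sigma2_a + u2$sigma2_e) / 2,
              r = options$var_floor_frac * (u1$sigma2_e + u2$sigma2_e) / 2)
  th[c("g11", "g22")] <- pmax(th[c("g11", "g22")], floors["g"])
  th[c("r11", "r22")] <- pmax(th[c("r11", "r22")], floors["r"])
  free <- if (estimate_r12) 1:6 else c(1:4, 6)
  nm <- names(th)
  st <- biv_eval(th, S)
  if (is.null(st)) stop("singular starting value in bivariate REML")
  trace <- vector("list", options$max_iter)
  converged <- FALSE
  it <- 0L
  stall <- 0L
  # the univariate warm starts stand in for the EM phase; one EM pass suffices
  biv_em_iter <- min(options$em_iter, 1L)
  compute_grad_ai <- function(st) {
    Py <- st$Py
    P <- st$P
    w <- lapply(nm, biv_Bmul, v = Py, S = S)
    Pw <- lapply(w, function(v) drop(P %*% v))
    grad <- vapply(seq_along(nm), function(i) {
      -0.5 * (biv_trMB(nm[i], P, S) - sum(Py * w[[i]]))
    }, 0)
    AI <- matrix(0, 6, 6)
    for (i in 1:6) {
      for (j in i:6) {
        AI[i, j] <- AI[j, i] <- 0.5 * sum(w[[i]] * Pw[[j]])
      }
    }
    dimnames(AI) <- list(nm, nm)
    names(grad) <- nm
    list(grad = grad, AI = AI)
  }
  repeat {
    it <- it + 1L
    ga <- compute_grad_ai(st)
    ai_info <- ga
    use_em <- options$algorithm == "em" ||
      (options$algorithm == "em+ai" && it <= biv_em_iter)
    trace[[it]] <- tibble::tibble(iter = it,
                                  method = if (use_em) "em" else "ai",
                                  loglik = st$ll,
                                  !!!stats::setNames(as.list(th), nm))
    th_new <- NULL
    if (!use_em) {
      step <- tryCatch(
        {
          s <- numeric(6)
          s[free] <- solve(ga$AI[free, free], ga$grad[free])
          s
        },
        error = function(e) NULL
      )
      if (!is.null(step)) {
        h <- 1
        for (halv in 0:options$max_halvings) {
          cand <- th + h * step
          cand[c("g11", "g22")] <- pmax(cand[c("g11", "g22")], floors["g"])
          cand[c("r11", "r22")] <- pmax(cand[c("r11", "r22")], floors["r"])
          if (!estimate_r12) cand["r12"] <- 0
          if (biv_feasible(cand, floors)) {
            st_try <- biv_eval(cand, S, lite = TRUE)
            if (!is.null(st_try) && st_try$ll >= st$ll - 1e-12) {
              th_new <- cand
              break
            }
          }
          h <- h / 2
        }
      }
    }
    if (is.null(th_new)) {
      th_new <- biv_em_step(th, st, S, relmat, estimate_r12)
      th_new[c("g11", "g22")] <- pmax(th_new[c("g11", "g22")], floors["g"])
      th_new[c("r11", "r22")] <- pmax(th_new[c("r11", "r22")], floors["r"])
      cap_g <- 0.999 * sqrt(th_new["g11"] * th_new["g22"])
      cap_r <- 0.999 * sqrt(th_new["r11"] * th_new["r22"])
      th_new["g12"] <- max(min(th_new["g12"], cap_g), -cap_g)
      th_new["r12"] <- max(min(th_new["r12"], cap_r), -cap_r)
      if (!estimate_r12) th_new["r12"] <- 0
    }
    st_new <- biv_eval(th_new, S)
    if (is.null(st_new)) { # degenerate; keep previous state and stop
      converged <- FALSE
      break
    }
    dll <- st_new$ll - st$ll
    dpar <- max(abs(th_new - th) / (abs(th) + floors["g"] + floors["r"]))
    th <- th_new
    st <- st_new
    ll_flat <- abs(dll) < options$tol_loglik * (1 + abs(st$ll))
    if (ll_flat && dpar < options$tol_param) {
      converged <- TRUE
      break
    }
    # a correlation pinned at its admissibility cap keeps the parameters
    # jittering while the likelihood is flat; call that converged (boundary)
    stall <- if (ll_flat) stall + 1L else 0L
    if (stall >= 3L) {
      converged <- TRUE
      break
    }
    if (it >= options$max_iter) break
  }
  ga <- compute_grad_ai(st)
  sampling_cov <- tryCatch(
    {
      sc <- matrix(NA_real_, 6, 6, dimnames = list(nm, nm))
      sc[free, free] <- solve(ga$AI[free, free])
      sc
    },
    error = function(e) matrix(NA_real_, 6, 6, dimnames = list(nm, nm))
  )
  G <- matrix(th[c("g11", "g12", "g12", "g22")], 2, 2,
              dimnames = list(ds$traits, ds$traits))
  R <- matrix(th[c("r11", "r12", "r12", "r22")], 2, 2,
              dimnames = list(ds$traits, ds$traits))
  fit <- list(G = G, R = R, theta = th, sampling_cov = sampling_cov,
              loglik = st$ll, converged = converged,
              boundary = any(th[c("g11", "g22", "r11", "r22")] <=
                               c(floors["g"], floors["g"], floors["r"], floors["r"]) * (1 + 1e-9)),
              beta = st$beta, Py = st$Py,
              trace = dplyr::bind_rows(trace[seq_len(it)]),
              traits = ds$traits, design = ds, structures = S,
              relmat = relmat, options = options,
              residual_cov_estimated = estimate_r12,
              n_records = S$n1 + S$n2, iterations = it)
  class(fit) <- c("f2qg_reml_biv", "f2qg_reml")
  fit
}

#' @export
print.f2qg_reml <- function(x, ...) {
  if (inherits(x, "f2qg_reml_uni")) {
    h2 <- heritability(x)
    cat("<f2qg_reml> univariate animal model for '", x$trait, "'\n",
        "  sigma2_a = ", signif(x$sigma2_a, 4),
        ", sigma2_e = ", signif(x$sigma2_e, 4),
        ", h2 = ", signif(h2$h2, 3), " (SE ", signif(h2$se, 3), ")\n",
        "  logLik = ", signif(x$loglik, 8),
        ", converged = ", x$converged, "\n", sep = "")
  } else {
    cat("<f2qg_reml> bivariate animal model for '",
        paste(x$traits, collapse = "' x '"), "'\n", sep = "")
    cc <- correlations(x)
    cat("  rg = ", signif(cc$estimate[cc$term == "rg"], 3),
        ", rp = ", signif(cc$estimate[cc$term == "rp"], 3),
        ", logLik = ", signif(x$loglik, 8),
        ", converged = ", x$converged, "\n", sep = "")
  }
  invisible(x)
}

# ---- derived genetic parameters ------------------------------------------

delta_se <- function(grad, cov) {
  v <- drop(t(grad) %*% cov %*% grad)
  if (!is.finite(v) || v < 0) return(NA_real_)
  sqrt(v)
}

#' Heritability with delta-method standard error
#'
#' `h2 = sigma2_a / (sigma2_a + sigma2_e)`; the SE propagates the sampling
#' covariance of the components through the first-order delta method.
#'
#' @param fit A univariate or bivariate `f2qg_reml` fit.
#' @param trait For bivariate fits, which trait (1 or 2, or the name).
#' @return A one-row tibble: `trait`, `h2`, `se`, `source`, `converged`.
#' @export
heritability <- function(fit, trait = 1L) {
  if (inherits(fit, "f2qg_reml_uni")) {
    g <- fit$sigma2_a
    e <- fit$sigma2_e
    S <- fit$sampling_cov
    tr_name <- fit$trait
    source <- "univariate"
  } else {
    k <- if (is.character(trait)) match(trait, fit$traits) else as.integer(trait)
    if (is.na(k) || !k %in% 1:2) stop("trait must identify one of the two fitted traits")
    gk <- c("g11", "g22")[k]
    rk <- c("r11", "r22")[k]
    g <- fit$theta[[gk]]
    e <- fit$theta[[rk]]
    S <- fit$sampling_cov[c(gk, rk), c(gk, rk)]
    tr_name <- fit$traits[k]
    source <- paste0("bivariate(", paste(fit$traits, collapse = ","), ")")
  }
  tot <- g + e
  if (tot <= 0) stop("total variance is zero")
  h2 <- g / tot
  grad <- c(e, -g) / tot^2
  tibble::tibble(trait = tr_name, h2 = h2, se = delta_se(grad, S),
                 source = source, converged = fit$converged)
}

#' Genetic and phenotypic correlations with delta-method SEs
#'
#' `rg = g12 / sqrt(g11 g22)` and
#' `rp = (g12 + r12) / sqrt((g11 + r11)(g22 + r22))`, with SEs from the
#' 6x6 sampling covariance of the components. `rg` is undefined (returned
#' `NA`) when either genetic variance is at the floor.
#'
#' @param fit An `f2qg_reml_biv` fit.
#' @return A tibble with rows `rg` and `rp`: `term`, `estimate`, `se`.
#' @export
correlations <- function(fit) {
  stopifnot(inherits(fit, "f2qg_reml_biv"))
  th <- fit$theta
  S <- fit$sampling_cov
  floor_g <- fit$options$var_floor_frac
  g11 <- th[["g11"]]; g12 <- th[["g12"]]; g22 <- th[["g22"]]
  r11 <- th[["r11"]]; r12 <- th[["r12"]]; r22 <- th[["r22"]]
  if (fit$boundary && (g11 <= 10 * floor_g * (g11 + r11) ||
                       g22 <= 10 * floor_g * (g22 + r22))) {
    rg <- NA_real_
    rg_se <- NA_real_
    message("genetic variance at the floor; rg undefined")
  } else {
    rg <- g12 / sqrt(g11 * g22)
    grad_rg <- c(-0.5 * rg / g11, 1 / sqrt(g11 * g22), -0.5 * rg / g22, 0, 0, 0)
    rg_se <- delta_se(grad_rg, S)
  }
  p1 <- g11 + r11
  p2 <- g22 + r22
  rp <- (g12 + r12) / sqrt(p1 * p2)
  grad_rp <- c(-0.5 * rp / p1, 1 / sqrt(p1 * p2), -0.5 * rp / p2,
               -0.5 * rp / p1, 1 / sqrt(p1 * p2), -0.5 * rp / p2)
  rp_se <- delta_se(grad_rp, S)
  tibble::tibble(term = c("rg", "rp"),
                 estimate = c(rg, rp),
                 se = c(rg_se, rp_se))
}

#' Select the heritability estimate with the smallest standard error
#'
#' Given the univariate estimate and the estimates from each bivariate model
#' involving the trait, returns the converged candidate with the lowest SE;
#' ties go to the univariate estimate.
#'
#' @param candidates A list of one-row tibbles from [heritability()] (or a
#'   single bound tibble).
#' @return The selected row.
#' @export
select_heritability <- function(candidates) {
  tbl <- if (is.data.frame(candidates)) candidates else dplyr::bind_rows(candidates)
  tbl <- tbl[tbl$converged & !is.na(tbl$se), , drop = FALSE]
  if (nrow(tbl) == 0) stop("no converged heritability candidates")
  best_se <- min(tbl$se)
  at_best <- tbl[tbl$se <= best_se + 1e-12, , drop = FALSE]
  uni <- at_best[at_best$source == "univariate", , drop = FALSE]
  if (nrow(uni) > 0) uni[1, ] else at_best[1, ]
}

# ---- fixed-effect screening ----------------------------------------------

#' Screen candidate fixed effects by ordinary least squares
#'
#' Fits the trait on all candidate effects jointly by OLS and tests each by
#' a drop-one partial F-test, the classical preliminary screen before the
#' animal-model fit.
#'
#' @param data Phenotype data frame.
#' @param trait Trait column name (or a [trait_spec()], whose transformation
#'   is applied).
#' @param factors Candidate factor columns.
#' @param covariates Candidate covariate columns.
#' @param alpha Flagging threshold (default 0.05).
#' @return A tibble: `effect`, `df`, `f_value`, `p_value`, `significant`.
#' @export
screen_fixed_effects <- function(data, trait, factors = c("sex", "sob"),
                                 covariates = character(0), alpha = 0.05) {
  spec <- if (inherits(trait, "trait_spec")) trait else trait_spec(trait, age = NULL)
  keep <- !is.na(data[[spec$name]])
  for (v in c(factors, covariates)) {
    if (!v %in% names(data)) stop("column not found: ", v)
    keep <- keep & !is.na(data[[v]])
  }
  d <- data[keep, , drop = FALSE]
  df <- data.frame(.y = transform_values(d[[spec$name]], spec$transformation))
  for (v in factors) {
    f <- factor(d[[v]])
    if (nlevels(f) < 2) stop("factor '", v, "' has a single level")
    df[[v]] <- f
  }
  for (v in covariates) df[[v]] <- as.numeric(d[[v]])
  fit <- stats::lm(.y ~ ., data = df)
  if (any(is.na(stats::coef(fit)))) {
    aliased <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop("rank-deficient design; aliased: ", paste(aliased, collapse = ", "))
  }
  an <- stats::drop1(fit, test = "F")
  an <- an[-1, , drop = FALSE] # drop the <none> row
  tibble::tibble(
    effect = rownames(an),
    df = an$Df,
    f_value = an$`F value`,
    p_value = an$`Pr(>F)`,
    significant = an$`Pr(>F)` < alpha
  )
}

# ---- breeding values -----------------------------------------------------

#' BLUP breeding values at the REML estimates
#'
#' For univariate fits, solves Henderson's mixed-model equations with the
#' sparse A-inverse, returning EBVs and prediction-error variances for every
#' pedigree animal (unphenotyped parents included, their EBVs shrunk toward
#' progeny information). For bivariate fits the equivalent GLS identities
#' `a_hat = Cov(a, y) P y` are used.
#'
#' @param fit An `f2qg_reml` fit.
#' @return A tibble: `animal`, `trait`, `ebv`, `pev`, `accuracy`.
#' @export
predict_ebv <- function(fit) {
  relmat <- fit$relmat
  q <- length(relmat$ids)
  if (inherits(fit, "f2qg_reml_uni")) {
    n <- fit$n_records
    X <- fit$design$X
    y <- fit$design$y
    Z <- matrix(0, n, q)
    Z[cbind(seq_len(n), fit$z)] <- 1
    lambda <- fit$sigma2_e / max(fit$sigma2_a, fit$var_floor)
    XtX <- crossprod(X)
    XtZ <- crossprod(X, Z)
    ZtZ <- crossprod(Z)
    C <- rbind(cbind(XtX, XtZ),
               cbind(t(XtZ), ZtZ + lambda * as.matrix(relmat$Ainv)))
    rhs <- c(crossprod(X, y), as.numeric(crossprod(Z, y)))
    Cinv <- solve(C)
    sol <- drop(Cinv %*% rhs)
    p <- ncol(X)
    ebv <- sol[(p + 1):(p + q)]
    pev <- diag(Cinv)[(p + 1):(p + q)] * fit$sigma2_e
    acc2 <- pmax(0, 1 - pev / ((1 + relmat$f) * max(fit$sigma2_a, fit$var_floor)))
    tibble::tibble(animal = relmat$ids, trait = fit$trait,
                   ebv = ebv, pev = pev, accuracy = sqrt(acc2))
  } else {
    S <- fit$structures
    st <- biv_eval(fit$theta, S)
    Py <- st$Py
    A <- relmat$A
    i1 <- seq_len(S$n1)
    i2 <- S$n1 + seq_len(S$n2)
    t1 <- numeric(q); t1[S$z1] <- Py[i1]
    t2 <- numeric(q); t2[S$z2] <- Py[i2]
    At1 <- drop(A %*% t1)
    At2 <- drop(A %*% t2)
    th <- fit$theta
    ebv1 <- th[["g11"]] * At1 + th[["g12"]] * At2
    ebv2 <- th[["g12"]] * At1 + th[["g22"]] * At2
    # PEV: diag of Cov(a) - Cov(a,y) P Cov(y,a), trait by trait
    P <- st$P
    cov_y_a1 <- rbind(th[["g11"]] * A[S$z1, , drop = FALSE],
                      th[["g12"]] * A[S$z2, , drop = FALSE])
    cov_y_a2 <- rbind(th[["g12"]] * A[S$z1, , drop = FALSE],
                      th[["g22"]] * A[S$z2, , drop = FALSE])
    pev1 <- th[["g11"]] * (1 + relmat$f) - colSums(cov_y_a1 * (P %*% cov_y_a1))
    pev2 <- th[["g22"]] * (1 + relmat$f) - colSums(cov_y_a2 * (P %*% cov_y_a2))
    dplyr::bind_rows(
      tibble::tibble(animal = relmat$ids, trait = fit$traits[1], ebv = ebv1,
                     pev = pmax(pev1, 0),
                     accuracy = sqrt(pmax(0, 1 - pev1 / (th[["g11"]] * (1 + relmat$f))))),
      tibble::tibble(animal = relmat$ids, trait = fit$traits[2], ebv = ebv2,
                     pev = pmax(pev2, 0),
                     accuracy = sqrt(pmax(0, 1 - pev2 / (th[["g22"]] * (1 + relmat$f)))))
    )
  }
}

#' Histogram bin data for an EBV distribution
#'
#' @param ebv_table Output of [predict_ebv()] (one trait).
#' @param bins Number of bins.
#' @return A tibble of bin midpoints and counts.
#' @export
ebv_histogram <- function(ebv_table, bins = 20L) {
  h <- graphics::hist(ebv_table$ebv, breaks = bins, plot = FALSE)
  tibble::tibble(mid = h$mids, count = h$counts,
                 lower = utils::head(h$breaks, -1), upper = h$breaks[-1])
}

# ---- broom-style methods -------------------------------------------------

#' Tidy a REML animal-model fit
#'
#' Returns the variance components and the derived genetic parameters with
#' their delta-method standard errors, one row per term.
#'
#' @param x An `f2qg_reml` fit.
#' @param ... Unused.
#' @return A tibble with columns `term`, `estimate`, `std.error`.
#' @method tidy f2qg_reml
#' @export
tidy.f2qg_reml <- function(x, ...) {
  if (inherits(x, "f2qg_reml_uni")) {
    h <- heritability(x)
    tibble::tibble(
      term = c("sigma2_a", "sigma2_e", "h2"),
      estimate = c(x$sigma2_a, x$sigma2_e, h$h2),
      std.error = c(sqrt(diag(x$sampling_cov)), h$se)
    )
  } else {
    h1 <- heritability(x, 1)
    h2 <- heritability(x, 2)
    cc <- correlations(x)
    tibble::tibble(
      term = c(names(x$theta), paste0("h2_", x$traits), cc$term),
      estimate = c(unname(x$theta), h1$h2, h2$h2, cc$estimate),
      std.error = c(sqrt(diag(x$sampling_cov)), h1$se, h2$se, cc$se)
    )
  }
}

#' Glance at a REML animal-model fit
#'
#' @param x An `f2qg_reml` fit.
#' @param ... Unused.
#' @return A one-row tibble with the log-likelihood, convergence flags and
#'   problem size.
#' @method glance f2qg_reml
#' @export
glance.f2qg_reml <- function(x, ...) {
  tibble::tibble(
    logLik = x$loglik,
    converged = x$converged,
    boundary = x$boundary,
    iterations = x$iterations,
    n_records = x$n_records,
    n_animals = length(x$relmat$ids)
  )
}

#' Plot the REML convergence trace
#'
#' @param object An `f2qg_reml` fit.
#' @param ... Unused.
#' @return A ggplot of log-likelihood against iteration, colored by update
#'   type (EM vs AI).
#' @method autoplot f2qg_reml
#' @export
autoplot.f2qg_reml <- function(object, ...) {
  ggplot2::ggplot(object$trace,
                  ggplot2::aes(x = .data$iter, y = .data$loglik,
                               color = .data$method)) +
    ggplot2::geom_line(color = "grey60") +
    ggplot2::geom_point() +
    ggplot2::labs(x = "iteration", y = "REML log-likelihood",
                  color = "update",
                  title = "REML convergence") +
    ggplot2::theme_minimal()
}

#' Plot an EBV distribution
#'
#' Histogram of estimated breeding values, the standard way of displaying
#' the spread of genetic merit in the population.
#'
#' @param ebv_table Output of [predict_ebv()].
#' @param bins Number of bins.
#' @return A ggplot.
#' @export
plot_ebv_distribution <- function(ebv_table, bins = 20L) {
  ggplot2::ggplot(ebv_table, ggplot2::aes(x = .data$ebv)) +
    ggplot2::geom_histogram(bins = bins, fill = "steelblue", color = "white") +
    ggplot2::facet_wrap(~trait, scales = "free") +
    ggplot2::labs(x = "estimated breeding value", y = "animals") +
    ggplot2::theme_minimal()
}
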