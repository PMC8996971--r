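#' Build the design structure for the nested-random-intercept model
#'
#' Produces the fixed-effects matrix (intercept, treatment indicator, and
#' reference-coded batch indicators when more than one batch is present and
#' `include_batch` is `TRUE`), the `log(total)` offset for log-link
#' families, and the index structures mapping each FoV row to its
#' individual- and sample-level random intercept. Rows are sorted by
#' individual then sample.
#'
#' @param dataset A `fov_dataset` (see [read_count_table()],
#'   [simulate_dataset()]).
#' @param family Family id or `fov_family`.
#' @param include_batch Include batch as a fixed effect when the data have
#'   more than one batch level.
#' @param include_treatment Include the treatment indicator (dropping it
#'   gives the null model, used e.g. to check that adding treatment never
#'   lowers the maximized likelihood).
#' @param random Character vector naming the random-intercept levels to keep
#'   (`"individual"`, `"sample"`); both by default. `character(0)` drops all
#'   random effects (degenerate designs only).
#' @return A list of class `fov_design_matrix` used by [marginal_loglik()]
#'   and [fit_glmm()].
#' @export
build_design <- function(dataset, family = "betabinomial",
                         include_batch = TRUE, include_treatment = TRUE,
                         random = c("individual", "sample")) {
  validate_fov_dataset(dataset)
  if (is.character(family)) family <- family_spec(family)
  if (length(random))
    random <- match.arg(random, c("individual", "sample"), several.ok = TRUE)

  ord <- order(dataset$individual_id, dataset$sample_id, dataset$fov_index)
  d <- as.data.frame(dataset)[ord, ]
  n_obs <- nrow(d)

  # FoVs within a sample share the linear predictor, so rows with identical
  # (sample, positive, total) contribute identical likelihood terms;
  # aggregate them with weights (exact, purely computational)
  key <- paste(d$sample_id, d$positive, d$total, sep = "\r")
  first <- !duplicated(key)
  wts <- as.numeric(table(factor(key, levels = key[first])))
  d <- d[first, ]

  X <- cbind("(Intercept)" = rep(1, nrow(d)))
  if (include_treatment) X <- cbind(X, treatment = as.numeric(d$treatment))
  batch_lv <- sort(unique(d$batch))
  if (include_batch && length(batch_lv) > 1L) {
    nm0 <- colnames(X)
    for (b in batch_lv[-1])
      X <- cbind(X, as.numeric(d$batch == b))
    colnames(X) <- c(nm0, paste0("batch", batch_lv[-1]))
  }

  ind <- factor(d$individual_id, levels = unique(d$individual_id))
  ind_i <- as.integer(ind)
  n_ind <- nlevels(ind)
  ind_start <- c(0L, cumsum(tabulate(ind_i, n_ind)))
  samp_of_row <- integer(nrow(d))
  n_samp <- integer(n_ind)
  for (i in seq_len(n_ind)) {
    rows <- (ind_start[i] + 1L):ind_start[i + 1L]
    sf <- factor(d$sample_id[rows], levels = unique(d$sample_id[rows]))
    samp_of_row[rows] <- as.integer(sf) - 1L
    n_samp[i] <- nlevels(sf)
  }

  structure(list(
    family = family,
    fam_code = .fam_codes[[family$family_id]],
    X = X,
    offset = if (family$uses_offset) log(d$total) else rep(0, nrow(d)),
    k = as.numeric(d$positive),
    m = as.numeric(d$total),
    w = wts,
    # theta-independent part of the log-likelihood, excluded from the
    # compiled hot path and added back to every marginal_loglik value
    const_sum = if (family$link == "logit")
      sum(wts * lchoose(d$total, d$positive))
    else sum(wts * -lgamma(d$positive + 1)),
    ind_start = ind_start,
    samp_of_row = samp_of_row,
    n_samp = n_samp,
    has_u = "individual" %in% random,
    has_v = "sample" %in% random,
    n_modes = sum(1L + n_samp),
    n_obs = n_obs,
    n_ind = n_ind
  ), class = "fov_design_matrix")
}

# parameter packing: fixed effects, then log_sd_individual / log_sd_sample
# (when the corresponding random term is present), then the unconstrained
# dispersion t with disp = exp(t), except genpois where phi = 1 + exp(t)
.theta_names <- function(dsn) {
  nm <- colnames(dsn$X)
  if (dsn$has_u) nm <- c(nm, "log_sd_individual")
  if (dsn$has_v) nm <- c(nm, "log_sd_sample")
  if (dsn$family$n_disp) nm <- c(nm, "log_disp")
  nm
}

.unpack_theta <- function(theta, dsn) {
  p <- ncol(dsn$X)
  beta <- theta[seq_len(p)]
  i <- p
  sd_u <- 1e-8
  sd_v <- 1e-8
  if (dsn$has_u) { i <- i + 1; sd_u <- max(exp(theta[i]), 1e-8) }
  if (dsn$has_v) { i <- i + 1; sd_v <- max(exp(theta[i]), 1e-8) }
  disp <- 0
  if (dsn$family$n_disp) {
    i <- i + 1
    disp <- if (dsn$family$family_id == "genpois") 1 + exp(theta[i]) else exp(theta[i])
  }
  list(beta = unname(beta), sd_u = unname(sd_u), sd_v = unname(sd_v),
       disp = unname(disp))
}

.mloglik <- function(theta, dsn, modes) {
  pa <- .unpack_theta(theta, dsn)
  res <- laplace_loglik_cpp(pa$beta, pa$sd_u, pa$sd_v, pa$disp, dsn$fam_code,
                            dsn$X, dsn$offset, dsn$k, dsn$m, dsn$w,
                            dsn$ind_start, dsn$samp_of_row, dsn$n_samp,
                            dsn$has_u, dsn$has_v, modes)
  res$loglik <- res$loglik + dsn$const_sum
  res
}

#' Laplace-approximated marginal log-likelihood
#'
#' Integrates the random intercepts out of the joint likelihood by the
#' Laplace approximation: per individual, the joint mode of that
#' individual's `1 + n_samples` random effects is found by damped Newton
#' iterations and a log-determinant curvature correction is added;
#' individuals are independent so contributions sum.
#'
#' @param theta Packed parameter vector: fixed effects in the column order of
#'   the design matrix, then `log_sd_individual`, `log_sd_sample` (for the
#'   random terms present), then the log dispersion (for families that have
#'   one; for the generalized Poisson the packing is `log(phi - 1)`).
#' @param dataset A `fov_dataset`, or a prebuilt [build_design()] structure.
#' @inheritParams build_design
#' @return The approximate marginal log-likelihood, with attribute
#'   `n_laplace_failures` counting individuals whose inner optimization
#'   failed (the value is `-Inf` when any fail).
#' @export
marginal_loglik <- function(theta, dataset, family = "betabinomial",
                            include_batch = TRUE,
                            random = c("individual", "sample")) {
  dsn <- if (inherits(dataset, "fov_design_matrix")) dataset
         else build_design(dataset, family, include_batch = include_batch,
                           random = random)
  if (length(theta) != length(.theta_names(dsn)))
    stop("theta must have length ", length(.theta_names(dsn)),
         " (", paste(.theta_names(dsn), collapse = ", "), ")", call. = FALSE)
  res <- .mloglik(theta, dsn, numeric(dsn$n_modes))
  structure(res$loglik, n_laplace_failures = res$n_fail)
}

# deterministic, family-agnostic starting values
.start_theta <- function(dsn) {
  X <- dsn$X
  if (dsn$family$link == "logit") {
    fit0 <- suppressWarnings(stats::glm.fit(X, dsn$k / dsn$m,
                                            weights = dsn$m * dsn$w,
                                            family = binomial()))
  } else {
    fit0 <- suppressWarnings(stats::glm.fit(X, dsn$k, weights = dsn$w,
                                            offset = dsn$offset,
                                            family = poisson()))
  }
  beta <- fit0$coefficients
  beta[!is.finite(beta)] <- 0
  theta <- beta
  if (dsn$has_u) theta <- c(theta, log(0.3))
  if (dsn$has_v) theta <- c(theta, log(0.3))
  if (dsn$family$n_disp) {
    eta <- as.numeric(X %*% beta)
    fid <- dsn$family$family_id
    if (fid == "betabinomial") {
      # moment estimate of the intra-FoV correlation from residual
      # overdispersion of the FoV proportions
      p <- plogis(eta)
      v <- (dsn$k - dsn$m * p)^2 / (dsn$m * p * (1 - p))
      infl <- max(sum(dsn$w * v) / sum(dsn$w), 1.01)
      mbar <- sum(dsn$w * dsn$m) / sum(dsn$w)
      rho <- min(max((infl - 1) / max(mbar - 1, 1), 1e-3), 0.9)
      theta <- c(theta, log(min(max(1 / rho - 1, 0.2), 100)))
    } else {
      mu <- exp(eta + dsn$offset)
      x2 <- max(sum(dsn$w * (dsn$k - mu)^2 / mu) / sum(dsn$w), 1.01)
      t0 <- switch(fid,
        genpois = log(min(max(x2 - 1, 1e-3), 100)),
        nb1 = log(min(max(x2 - 1, 0.01), 100)),
        nb2 = log(min(max(sum(dsn$w * mu) / sum(dsn$w) / (x2 - 1), 0.05), 1e4)))
      theta <- c(theta, t0)
    }
  }
  setNames(theta, .theta_names(dsn))
}

# finite-difference observed information (central differences); the step is
# chosen so the quadratic signal dominates the ~1e-9 evaluation noise left
# by the inner Laplace mode search
.fd_hessian <- function(fn, theta, h_rel = 1e-4) {
  p <- length(theta)
  h <- h_rel * (1 + abs(theta))
  H <- matrix(NA_real_, p, p)
  f0 <- fn(theta)
  for (i in seq_len(p)) {
    ei <- replace(numeric(p), i, h[i])
    H[i, i] <- (fn(theta + ei) - 2 * f0 + fn(theta - ei)) / h[i]^2
    for (j in seq_len(p)) {
      if (j >= i) next
      ej <- replace(numeric(p), j, h[j])
      H[i, j] <- H[j, i] <-
        (fn(theta + ei + ej) - fn(theta + ei - ej) -
           fn(theta - ei + ej) + fn(theta - ei - ej)) / (4 * h[i] * h[j])
    }
  }
  H
}

#' Fit the nested-random-intercept mixed model by maximum likelihood
#'
#' Maximizes the Laplace-approximated marginal likelihood over the packed
#' parameter vector with a quasi-Newton outer optimization (`nlminb`).
#' Fixed effects are treatment and (optionally) batch; random intercepts are
#' sample nested within individual. Standard errors come from the inverse of
#' a central finite-difference observed-information matrix at the optimum.
#'
#' @inheritParams build_design
#' @param start Optional named start vector (see [marginal_loglik()] for the
#'   packing); by default fixed effects start from a dispersion-free
#'   fixed-effects (IRLS) fit, random-effect SDs at 0.3, and dispersion at a
#'   method-of-moments guess.
#' @param max_iter,tol Outer optimizer iteration cap and relative tolerance.
#' @return An object of class `fov_glmm` with elements `fixed_estimates`,
#'   `sd_individual_hat`, `sd_sample_hat` (SDs at the optimization floor are
#'   reported as 0), `dispersion_hat`, `std_errors` (for the full packed
#'   vector; `NA` when the information matrix is singular), `vcov`,
#'   `loglik`, `n_params`, `aic`, `converged`, `n_laplace_failures`.
#'   Non-convergence is reported through `converged = FALSE`, never an
#'   error.
#' @export
fit_glmm <- function(dataset, family = "betabinomial", include_batch = TRUE,
                     include_treatment = TRUE,
                     random = c("individual", "sample"), start = NULL,
                     max_iter = 300L, tol = 1e-8) {
  dsn <- if (inherits(dataset, "fov_design_matrix")) dataset
         else build_design(dataset, family, include_batch, include_treatment,
                           random)
  family <- dsn$family
  nm <- .theta_names(dsn)
  theta0 <- if (is.null(start)) .start_theta(dsn) else {
    if (length(start) != length(nm))
      stop("start must have length ", length(nm), call. = FALSE)
    setNames(as.numeric(start), nm)
  }

  modes <- numeric(dsn$n_modes)  # warm-started across outer iterations
  negll <- function(th) {
    r <- .mloglik(th, dsn, modes)
    if (!is.finite(r$loglik)) return(1e10)
    -r$loglik
  }

  lower <- rep(-Inf, length(nm))
  upper <- rep(Inf, length(nm))
  lower[nm %in% c("log_sd_individual", "log_sd_sample")] <- log(1e-8)
  upper[nm %in% c("log_sd_individual", "log_sd_sample")] <- log(10)
  lower[nm == "log_disp"] <- -12
  upper[nm == "log_disp"] <- 12

  opt <- suppressWarnings(
    nlminb(theta0, negll, lower = lower, upper = upper,
           control = list(iter.max = max_iter, eval.max = 4L * max_iter,
                          rel.tol = tol)))
  theta_hat <- setNames(opt$par, nm)
  fin <- .mloglik(theta_hat, dsn, modes)
  loglik <- fin$loglik
  n_fail <- fin$n_fail
  converged <- opt$convergence == 0 && is.finite(loglik) && n_fail == 0

  n_params <- ncol(dsn$X) + dsn$has_u + dsn$has_v + family$n_disp
  aic <- -2 * loglik + 2 * n_params

  # observed information on the packed scale
  std_errors <- setNames(rep(NA_real_, length(nm)), nm)
  vcov <- NULL
  se_ok <- FALSE
  if (is.finite(loglik)) {
    # Parameters pinned at a box bound, or with vanishing curvature (a
    # variance-component SD collapsing towards zero leaves its log-SD
    # direction flat), are profiled out of the observed-information inverse
    # and get NA standard errors; the rest are conditioned on them.
    H <- try(.fd_hessian(negll, theta_hat), silent = TRUE)
    if (!inherits(H, "try-error")) {
      active <- which(theta_hat > lower + 1e-4 & theta_hat < upper - 1e-4 &
                        is.finite(diag(H)) & diag(H) > 1e-3)
      while (length(active)) {
        V <- try(solve(H[active, active, drop = FALSE]), silent = TRUE)
        if (!inherits(V, "try-error") && all(is.finite(diag(V))) &&
            all(diag(V) > 0)) {
          vcov <- matrix(NA_real_, length(nm), length(nm),
                         dimnames = list(nm, nm))
          vcov[active, active] <- V
          std_errors[active] <- sqrt(diag(V))
          se_ok <- TRUE
          break
        }
        active <- active[-which.min(diag(H)[active])]
      }
    }
  }
  if (!se_ok) warning("observed information matrix singular or invalid; ",
                      "standard errors unavailable", call. = FALSE)

  pa <- .unpack_theta(theta_hat, dsn)
  floor_zero <- function(s) if (s <= 1.5e-8) 0 else s
  structure(list(
    family = family,
    fixed_estimates = setNames(pa$beta, colnames(dsn$X)),
    sd_individual_hat = if (dsn$has_u) floor_zero(pa$sd_u) else NA_real_,
    sd_sample_hat = if (dsn$has_v) floor_zero(pa$sd_v) else NA_real_,
    dispersion_hat = if (family$n_disp) pa$disp else NULL,
    theta = theta_hat,
    std_errors = std_errors,
    vcov = vcov,
    loglik = loglik,
    n_params = n_params,
    aic = aic,
    converged = converged,
    n_laplace_failures = n_fail,
    n_obs = dsn$n_obs,
    n_individuals = dsn$n_ind,
    se_ok = se_ok
  ), class = "fov_glmm")
}

#' @export
print.fov_glmm <- function(x, ...) {
  cat("Mixed-effects FoV count model (", x$family$family_id, " family)\n",
      sep = "")
  cat(sprintf("  logLik %.3f  AIC %.3f  (%d parameters, %d FoV rows, %d individuals)\n",
              x$loglik, x$aic, x$n_params, x$n_obs, x$n_individuals))
  est <- x$fixed_estimates
  se <- x$std_errors[seq_along(est)]
  for (i in seq_along(est))
    cat(sprintf("  %-14s %9.4f  (SE %.4f)\n", names(est)[i], est[i], se[i]))
  cat(sprintf("  sd(individual) %.4f   sd(sample|individual) %.4f\n",
              x$sd_individual_hat, x$sd_sample_hat))
  if (!is.null(x$dispersion_hat))
    cat(sprintf("  dispersion (%s) %.4f\n", x$family$dispersion_name,
                x$dispersion_hat))
  if (!x$converged) cat("  WARNING: optimizer did not converge\n")
  invisible(x)
}

#' @export
logLik.fov_glmm <- function(object, ...) {
  structure(object$loglik, df = object$n_params, nobs = object$n_obs,
            class = "logLik")
}

#' Wald test of a fixed-effect term
#'
#' @param fit An `fov_glmm`.
#' @param term Fixed-effect name, default `"treatment"`.
#' @param alpha Two-sided significance level.
#' @return List with `z`, `p_value`, `reject`, and `available` (`FALSE` when
#'   the standard error is missing, in which case `reject` is `FALSE` so the
#'   result counts as a non-rejection downstream).
#' @export
wald_test <- function(fit, term = "treatment", alpha = 0.05) {
  stopifnot(inherits(fit, "fov_glmm"))
  if (!term %in% names(fit$fixed_estimates))
    stop("term '", term, "' is not a fixed effect of this fit", call. = FALSE)
  est <- fit$fixed_estimates[[term]]
  se <- fit$std_errors[[term]]
  if (!is.finite(se) || se <= 0)
    return(list(z = NA_real_, p_value = NA_real_, reject = FALSE,
                available = FALSE))
  z <- est / se
  p <- 2 * pnorm(-abs(z))
  list(z = z, p_value = p, reject = p < alpha, available = TRUE)
}

.mean_pct <- function(fit, treated, batch_average = FALSE) {
  est <- fit$fixed_estimates
  trt <- if ("treatment" %in% names(est)) est[["treatment"]] else 0
  eta <- est[["(Intercept)"]] + if (treated) trt else 0
  bcols <- grep("^batch", names(est), value = TRUE)
  etas <- if (batch_average && length(bcols))
    eta + c(0, unlist(est[bcols])) else eta
  inv <- if (fit$family$link == "logit") plogis else exp
  100 * mean(inv(etas))
}

#' Compare the candidate error distributions by AIC
#'
#' Fits each family with the shared fixed/random structure, sorts by AIC,
#' and reports the AIC difference from the best-fitting family together
#' with the model-implied mean percent positivity for the average subject
#' (random effects at zero): `mean_pct_*` at the reference batch and
#' `mean_pct_*_avg` averaged over batch levels. Families that fail to
#' converge are retained (`converged = FALSE`) but excluded from the
#' delta-AIC reference.
#'
#' @inheritParams build_design
#' @param families Character vector of family ids (default: all six).
#' @param ... Passed to [fit_glmm()].
#' @return A tibble of class `fov_model_comparison`, one row per family,
#'   sorted by AIC; attribute `fits` holds the `fov_glmm` objects.
#' @export
compare_models <- function(dataset, families = list_families(),
                           include_batch = TRUE,
                           random = c("individual", "sample"), ...) {
  stopifnot(length(families) >= 1)
  validate_fov_dataset(dataset)
  fits <- lapply(families, function(f)
    suppressWarnings(fit_glmm(dataset, family = f,
                              include_batch = include_batch,
                              random = random, ...)))
  names(fits) <- families
  tab <- tibble::tibble(
    family_id = families,
    loglik = unname(vapply(fits, `[[`, numeric(1), "loglik")),
    n_params = unname(vapply(fits, `[[`, numeric(1), "n_params")),
    aic = unname(vapply(fits, `[[`, numeric(1), "aic")),
    mean_pct_control = unname(vapply(fits, .mean_pct, numeric(1),
                                     treated = FALSE)),
    mean_pct_treated = unname(vapply(fits, .mean_pct, numeric(1),
                                     treated = TRUE)),
    mean_pct_control_avg = unname(vapply(fits, .mean_pct, numeric(1),
                                  treated = FALSE, batch_average = TRUE)),
    mean_pct_treated_avg = unname(vapply(fits, .mean_pct, numeric(1),
                                  treated = TRUE, batch_average = TRUE)),
    converged = unname(vapply(fits, `[[`, logical(1), "converged")))
  ref <- if (any(tab$converged)) min(tab$aic[tab$converged]) else NA_real_
  tab$delta_aic <- tab$aic - ref
  tab <- tab[order(tab$aic), c("family_id", "loglik", "n_params", "aic",
                               "delta_aic", "mean_pct_control",
                               "mean_pct_treated", "mean_pct_control_avg",
                               "mean_pct_treated_avg", "converged")]
  attr(tab, "fits") <- fits
  class(tab) <- c("fov_model_comparison", class(tab))
  tab
}
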