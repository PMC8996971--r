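#' @useDynLib fovpower, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats qlogis plogis pnorm qnorm rnorm rbinom rbeta rnbinom
#'   rpois runif glm binomial poisson coef nlminb setNames
NULL

# integer family codes shared with src/glmm.cpp
.fam_codes <- c(binomial = 0L, betabinomial = 1L, poisson = 2L,
                genpois = 3L, nb1 = 4L, nb2 = 5L)

#' Candidate error distributions for FoV cell counts
#'
#' The six count families considered for field-of-view (FoV) immunostaining
#' data: binomial and beta-binomial on the logit scale for the pair
#' (positive, total), and Poisson, generalized Poisson, NB1 and NB2 on the
#' log scale for the positive count with `log(total)` as an offset.
#'
#' @return Character vector of family identifiers.
#' @export
list_families <- function() names(.fam_codes)

#' Describe one candidate error distribution
#'
#' @param family_id One of `"binomial"`, `"betabinomial"`, `"poisson"`,
#'   `"genpois"`, `"nb1"`, `"nb2"`.
#' @return An object of class `fov_family`: a list with `family_id`, `link`
#'   (`"logit"` for the two binomial-type families, `"log"` otherwise),
#'   `uses_offset` (`TRUE` for the log-link families, whose linear predictor
#'   includes `log(total)`), `dispersion_name` (`NULL` for binomial and
#'   Poisson, which have no dispersion parameter), and `n_disp` (0 or 1).
#' @details Dispersion conventions: the beta-binomial uses a precision `phi`
#'   with Beta shapes `a = mu*phi`, `b = (1-mu)*phi` and intra-FoV correlation
#'   `rho = 1/(phi+1)`; the generalized Poisson uses `phi >= 1` with variance
#'   `mu*phi`; NB1 uses `alpha` with variance `mu*(1+alpha)`; NB2 uses
#'   `theta` with variance `mu + mu^2/theta`.
#' @export
family_spec <- function(family_id) {
  family_id <- match.arg(family_id, list_families())
  logit <- family_id %in% c("binomial", "betabinomial")
  disp_name <- switch(family_id,
    betabinomial = "phi", genpois = "phi", nb1 = "alpha", nb2 = "theta",
    NULL)
  structure(list(
    family_id = family_id,
    link = if (logit) "logit" else "log",
    uses_offset = !logit,
    dispersion_name = disp_name,
    n_disp = if (is.null(disp_name)) 0L else 1L
  ), class = "fov_family")
}

#' @export
print.fov_family <- function(x, ...) {
  cat("<fov_family> ", x$family_id, ": link=", x$link,
      ", offset=", x$uses_offset,
      if (x$n_disp) paste0(", dispersion=", x$dispersion_name) else
        ", no dispersion parameter",
      "\n", sep = "")
  invisible(x)
}

.check_counts <- function(k, m) {
  if (any(k < 0) || any(k != floor(k)))
    stop("`k` must be a non-negative integer", call. = FALSE)
  if (any(m < 1) || any(m != floor(m)))
    stop("`m` must be a positive integer", call. = FALSE)
  if (any(k > m)) stop("`k` must not exceed `m`", call. = FALSE)
}

#' Binomial log probability mass
#'
#' @param k Number of positive cells (0 <= k <= m).
#' @param m Total cells in the FoV.
#' @param p Positivity probability, strictly inside (0, 1).
#' @return Log probability, computed via log-gamma for numerical stability.
#' @export
binom_logpmf <- function(k, m, p) {
  .check_counts(k, m)
  if (any(p <= 0) || any(p >= 1))
    stop("`p` must lie strictly in (0, 1)", call. = FALSE)
  as.numeric(logpmf_eta_cpp(0L, as.numeric(k), as.numeric(m),
                            qlogis(p), 0, 0))
}

#' Beta-binomial log probability mass
#'
#' Mean/precision parameterization: the FoV-level positivity varies as
#' Beta(`mu*phi`, `(1-mu)*phi`), giving mean `m*mu` and variance
#' `m*mu*(1-mu)*(1 + (m-1)*rho)` with intra-FoV correlation
#' `rho = 1/(phi+1)`. As `phi` grows the distribution approaches the
#' binomial.
#'
#' @inheritParams binom_logpmf
#' @param mu Mean positivity, strictly inside (0, 1).
#' @param phi Precision, > 0.
#' @export
betabinom_logpmf <- function(k, m, mu, phi) {
  .check_counts(k, m)
  if (any(mu <= 0) || any(mu >= 1))
    stop("`mu` must lie strictly in (0, 1)", call. = FALSE)
  if (any(phi <= 0)) stop("`phi` must be positive", call. = FALSE)
  as.numeric(logpmf_eta_cpp(1L, as.numeric(k), as.numeric(m),
                            qlogis(mu), 0, phi))
}

#' Poisson log probability mass
#'
#' @param k Observed count.
#' @param mu Mean, > 0.
#' @export
pois_logpmf <- function(k, mu) {
  if (any(k < 0) || any(k != floor(k)))
    stop("`k` must be a non-negative integer", call. = FALSE)
  if (any(mu <= 0)) stop("`mu` must be positive", call. = FALSE)
  as.numeric(logpmf_eta_cpp(2L, as.numeric(k), 1, log(mu), 0, 0))
}

#' Generalized Poisson log probability mass
#'
#' Mean/variance parameterization with variance `mu * phi`. Internally
#' `theta = mu/sqrt(phi)`, `lambda = 1 - 1/sqrt(phi)` and
#' `P(k) = theta * (theta + lambda*k)^(k-1) * exp(-theta - lambda*k) / k!`.
#' Reduces to the Poisson at `phi = 1`. Underdispersion (`phi < 1`) is not
#' supported: it truncates the support and is never needed for
#' immunostaining count data.
#'
#' @inheritParams pois_logpmf
#' @param phi Dispersion factor, >= 1.
#' @export
genpois_logpmf <- function(k, mu, phi) {
  if (any(k < 0) || any(k != floor(k)))
    stop("`k` must be a non-negative integer", call. = FALSE)
  if (any(mu <= 0)) stop("`mu` must be positive", call. = FALSE)
  if (any(phi < 1))
    stop("`phi` < 1 (underdispersion) is not supported", call. = FALSE)
  as.numeric(logpmf_eta_cpp(3L, as.numeric(k), 1, log(mu), 0, phi))
}

#' Negative binomial log probability mass (NB1 and NB2 variants)
#'
#' NB1 has variance linear in the mean, `mu * (1 + disp)`, obtained by the
#' size = `mu/disp` reparameterization of the standard negative binomial;
#' NB2 has variance quadratic in the mean, `mu + mu^2/disp`, with
#' size = `disp`. NB1 approaches the Poisson as `disp -> 0`, NB2 as
#' `disp -> Inf`.
#'
#' @inheritParams pois_logpmf
#' @param disp Dispersion parameter, > 0.
#' @param variant `"nb1"` or `"nb2"`.
#' @export
nb_logpmf <- function(k, mu, disp, variant = c("nb2", "nb1")) {
  variant <- match.arg(variant)
  if (any(k < 0) || any(k != floor(k)))
    stop("`k` must be a non-negative integer", call. = FALSE)
  if (any(mu <= 0)) stop("`mu` must be positive", call. = FALSE)
  if (any(disp <= 0)) stop("`disp` must be positive", call. = FALSE)
  fam <- if (variant == "nb1") 4L else 5L
  as.numeric(logpmf_eta_cpp(fam, as.numeric(k), 1, log(mu), 0, disp))
}
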