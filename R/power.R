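#' Wilson score confidence interval for a proportion
#'
#' @param x Number of successes.
#' @param n Number of trials.
#' @param conf Confidence level.
#' @return Named vector `c(low, high)`. Behaves sensibly at 0 and n, unlike
#'   the Wald interval.
#' @export
wilson_ci <- function(x, n, conf = 0.95) {
  if (n == 0) return(c(low = 0, high = 1))
  z <- qnorm(1 - (1 - conf) / 2)
  p <- x / n
  den <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / den
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
  c(low = max(0, centre - half), high = min(1, centre + half))
}

#' Translate a logit-scale treatment effect into percentage points
#'
#' @param baseline_pct Baseline positivity as a percentage in (0, 100).
#' @param logit_shift Additive shift on the logit scale.
#' @return Change in percentage points:
#'   `100 * plogis(qlogis(baseline/100) + shift) - baseline`. A shift of
#'   -0.2 from a 30% baseline is a reduction of about 4 percentage points.
#' @export
effect_translation <- function(baseline_pct, logit_shift) {
  if (any(baseline_pct <= 0) || any(baseline_pct >= 100))
    stop("`baseline_pct` must lie strictly between 0 and 100", call. = FALSE)
  100 * plogis(qlogis(baseline_pct / 100) + logit_shift) - baseline_pct
}

#' Specify a simulation-based power study
#'
#' Defaults follow the reference design: a grid of 10-25 FoVs per sample by
#' 10-100 cells per FoV, 25 individuals each contributing a paired
#' control/treated sample, a -0.2 logit treatment effect under the
#' beta-binomial generative truth of [default_sim_params()], analyzed with
#' the beta-binomial mixed model and a two-sided Wald test at alpha 0.05.
#' `n_reps` defaults to 2000 per grid cell; smaller desk-scale runs carry
#' their Monte-Carlo uncertainty in the Wilson interval columns.
#'
#' @param fov_values,cells_values Strictly increasing grids of FoVs per
#'   sample and cells per FoV.
#' @param n_reps Simulation replicates per grid cell.
#' @param alpha Two-sided test level.
#' @param design Template [study_design()]; its `n_fov`/`cells_per_fov` are
#'   overridden cell by cell.
#' @param params Generative [sim_params()].
#' @param analysis_family Family used for fitting in the power loop.
#' @param include_batch Include batch in the analysis model (the default
#'   simulated design has a single batch, so none is included).
#' @param master_seed Master seed; each replicate derives an independent
#'   substream seed from `(master_seed, n_fov, cells_per_fov, replicate)`,
#'   so results do not depend on execution order.
#' @return A list of class `fov_power_spec`.
#' @export
power_spec <- function(fov_values = c(10L, 15L, 20L, 25L),
                       cells_values = c(10L, 25L, 50L, 75L, 100L),
                       n_reps = 2000L, alpha = 0.05,
                       design = study_design(), params = sim_params(),
                       analysis_family = "betabinomial",
                       include_batch = FALSE, master_seed = 1L) {
  stopifnot(length(fov_values) >= 1, length(cells_values) >= 1,
            all(diff(fov_values) > 0), all(diff(cells_values) > 0),
            all(fov_values >= 1), all(cells_values >= 1), n_reps >= 1,
            alpha > 0, alpha < 1)
  structure(list(
    fov_values = as.integer(fov_values),
    cells_values = as.integer(cells_values),
    n_reps = as.integer(n_reps), alpha = alpha,
    design = design, params = params,
    analysis_family = analysis_family,
    include_batch = include_batch,
    master_seed = as.integer(master_seed)
  ), class = "fov_power_spec")
}

# counter-based substream seed: deterministic in (master, n_fov, cells, rep)
# and independent of execution order; kept inside 32-bit integer range
.substream_seed <- function(master, n_fov, cells, rep) {
  h <- (as.numeric(master) %% 2147483647) + 1
  for (v in c(n_fov, 7919 * cells, 104729 * rep)) {
    h <- (h * 48271 + v * 16807 + 12345) %% 2147483647
  }
  as.integer(h %% 2147483646 + 1)
}

#' Estimate power for one FoV-by-cells design cell
#'
#' Runs the simulate-fit-test loop: each replicate simulates a dataset under
#' the generative truth with the requested FoV and cell counts, fits the
#' analysis family's nested-random-intercept model, and applies the
#' two-sided Wald test to the treatment coefficient. Replicates whose fit
#' does not converge are excluded from the power denominator and counted.
#'
#' @param spec A [power_spec()].
#' @param n_fov,cells_per_fov The grid cell.
#' @return One-row tibble: `n_fov`, `cells_per_fov`, `total_cells`,
#'   `n_reps_attempted`, `n_converged`, `n_rejections`, `power`
#'   (rejections / converged), Wilson 95% bounds `ci_low`/`ci_high`, and
#'   `unreliable` (`TRUE` when more than 20% of fits failed).
#' @export
run_power_cell <- function(spec, n_fov, cells_per_fov) {
  stopifnot(inherits(spec, "fov_power_spec"), n_fov >= 1, cells_per_fov >= 1)
  design <- spec$design
  design$n_fov <- as.integer(n_fov)
  design$cells_per_fov <- as.integer(cells_per_fov)
  n_conv <- 0L
  n_rej <- 0L
  for (r in seq_len(spec$n_reps)) {
    seed_r <- .substream_seed(spec$master_seed, n_fov, cells_per_fov, r)
    d <- suppressWarnings(simulate_dataset(design, spec$params, seed_r))
    fit <- suppressWarnings(fit_glmm(d, family = spec$analysis_family,
                                     include_batch = spec$include_batch))
    if (!fit$converged) next
    n_conv <- n_conv + 1L
    w <- wald_test(fit, "treatment", spec$alpha)
    if (isTRUE(w$reject)) n_rej <- n_rej + 1L
  }
  pow <- if (n_conv > 0) n_rej / n_conv else NA_real_
  ci <- wilson_ci(n_rej, max(n_conv, 1L))
  tibble::tibble(
    n_fov = as.integer(n_fov),
    cells_per_fov = as.integer(cells_per_fov),
    total_cells = as.integer(n_fov * cells_per_fov),
    n_reps_attempted = spec$n_reps,
    n_converged = n_conv,
    n_rejections = n_rej,
    power = pow,
    ci_low = ci[["low"]],
    ci_high = ci[["high"]],
    unreliable = (spec$n_reps - n_conv) / spec$n_reps > 0.2)
}

#' Estimate power over the full FoV-by-cells grid
#'
#' @param spec A [power_spec()].
#' @return A tibble of class `fov_power_grid` with one [run_power_cell()]
#'   row per grid cell; the spec is attached as attribute `spec`. Because
#'   every replicate uses its own counter-derived substream seed, the table
#'   is identical regardless of the order in which cells are computed.
#' @export
run_power_grid <- function(spec) {
  stopifnot(inherits(spec, "fov_power_spec"))
  cells <- expand.grid(cells_per_fov = spec$cells_values,
                       n_fov = spec$fov_values)
  rows <- lapply(seq_len(nrow(cells)), function(i)
    run_power_cell(spec, cells$n_fov[i], cells$cells_per_fov[i]))
  out <- do.call(rbind, rows)
  out <- out[order(out$n_fov, out$cells_per_fov), ]
  attr(out, "spec") <- spec
  class(out) <- c("fov_power_grid", class(out))
  out
}
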