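#' Describe a FoV counting study design
#'
#' The hierarchy emulated is patients -> samples -> fields-of-view (FoV) ->
#' cells: each individual contributes `samples_per_individual` tissue
#' samples, each sample is scored over `n_fov` FoVs, and `cells_per_fov`
#' cells are counted in each FoV.
#'
#' @param n_individuals Number of individuals (patients).
#' @param samples_per_individual Samples per individual; must be >= 2 for the
#'   paired scheme.
#' @param treatment_scheme `"paired_within_individual"` assigns control and
#'   treated samples within each individual (the explant design: one control
#'   and one treated sample per patient); `"between_individual"` splits
#'   individuals into two arms.
#' @param n_batches Number of assessment batches; samples are assigned to
#'   batches round-robin.
#' @param n_fov Fields-of-view per sample.
#' @param cells_per_fov Cells counted per FoV: a scalar or a vector of length
#'   `n_fov`.
#' @return An object of class `fov_design` (a named list).
#' @export
study_design <- function(n_individuals = 25L, samples_per_individual = 2L,
                         treatment_scheme = c("paired_within_individual",
                                              "between_individual"),
                         n_batches = 1L, n_fov = 25L, cells_per_fov = 25L) {
  treatment_scheme <- match.arg(treatment_scheme)
  stopifnot(n_individuals >= 1, samples_per_individual >= 1,
            n_batches >= 1, n_fov >= 1, all(cells_per_fov >= 1))
  if (treatment_scheme == "paired_within_individual" &&
      samples_per_individual < 2)
    stop("paired_within_individual requires samples_per_individual >= 2",
         call. = FALSE)
  if (!length(cells_per_fov) %in% c(1L, n_fov))
    stop("cells_per_fov must be a scalar or have length n_fov", call. = FALSE)
  structure(list(
    n_individuals = as.integer(n_individuals),
    samples_per_individual = as.integer(samples_per_individual),
    treatment_scheme = treatment_scheme,
    n_batches = as.integer(n_batches),
    n_fov = as.integer(n_fov),
    cells_per_fov = as.integer(cells_per_fov)
  ), class = "fov_design")
}

#' Generative parameters for the FoV count simulator
#'
#' Parameters live on the link scale of the chosen family (logit for
#' binomial/beta-binomial). The defaults are the declared generative truth
#' used throughout the power study: baseline positivity 30%
#' (`beta0 = qlogis(0.3)`), a treatment shift of -0.2 on the logit scale
#' (roughly a 4 percentage-point reduction), no batch effects,
#' between-individual SD 0.5 and between-sample (within-individual) SD 0.1
#' on the logit scale, and beta-binomial dispersion `phi = 3` (intra-FoV
#' correlation 0.25).
#'
#' @param beta0 Baseline (control, reference batch) linear predictor.
#' @param beta_treatment Additive treatment effect on the link scale.
#' @param beta_batch Reference-coded batch effects, length `n_batches - 1`.
#' @param sd_individual,sd_sample Random-intercept SDs on the link scale.
#' @param family A family id (see [list_families()]) or `fov_family`.
#' @param dispersion Dispersion parameter; must be absent for binomial and
#'   Poisson, present otherwise.
#' @return An object of class `fov_sim_params`.
#' @export
sim_params <- function(beta0 = qlogis(0.3), beta_treatment = -0.2,
                       beta_batch = numeric(0), sd_individual = 0.5,
                       sd_sample = 0.1, family = "betabinomial",
                       dispersion = NULL) {
  if (is.character(family)) family <- family_spec(family)
  stopifnot(inherits(family, "fov_family"),
            sd_individual >= 0, sd_sample >= 0)
  if (is.null(dispersion) && family$family_id == "betabinomial")
    dispersion <- 3  # declared default: intra-FoV correlation 0.25
  if (family$n_disp == 1L) {
    if (is.null(dispersion) || dispersion <= 0)
      stop("family '", family$family_id,
           "' requires a positive dispersion parameter", call. = FALSE)
  } else if (!is.null(dispersion)) {
    stop("family '", family$family_id,
         "' has no dispersion parameter; leave `dispersion` NULL",
         call. = FALSE)
  }
  structure(list(
    beta0 = beta0, beta_treatment = beta_treatment,
    beta_batch = as.numeric(beta_batch),
    sd_individual = sd_individual, sd_sample = sd_sample,
    family = family, dispersion = dispersion
  ), class = "fov_sim_params")
}

#' Default generative truth for the power study
#' @return The [sim_params()] defaults.
#' @export
default_sim_params <- function() sim_params()

# draw n counts from `family` with per-draw mean mu (log-link families),
# redrawing any value above the total m; returns list(counts, n_redraw)
.draw_count_family <- function(family, n, mu, m, dispersion) {
  draw <- switch(family$family_id,
    poisson = function(idx) rpois(length(idx), mu[idx]),
    nb2 = function(idx) rnbinom(length(idx), size = dispersion, mu = mu[idx]),
    nb1 = function(idx) rnbinom(length(idx), size = mu[idx] / dispersion,
                                mu = mu[idx]),
    genpois = function(idx) vapply(mu[idx], .rgenpois1,
                                   numeric(1), phi = dispersion),
    stop("not a count family"))
  counts <- draw(seq_len(n))
  n_redraw <- 0L
  bad <- which(counts > m)
  tries <- 0L
  while (length(bad) && tries < 1000L) {
    n_redraw <- n_redraw + length(bad)
    counts[bad] <- draw(bad)
    bad <- bad[counts[bad] > m[bad]]
    tries <- tries + 1L
  }
  if (length(bad)) counts[bad] <- m[bad]
  list(counts = as.integer(counts), n_redraw = n_redraw)
}

# single generalized-Poisson draw by pmf inversion
.rgenpois1 <- function(mu, phi) {
  u <- runif(1)
  kmax <- max(50, ceiling(mu + 20 * sqrt(mu * phi)))
  k <- 0:kmax
  cdf <- cumsum(exp(genpois_logpmf(k, mu, phi)))
  as.integer(k[match(TRUE, u <= cdf, nomatch = kmax + 1L)])
}

#' Simulate a FoV count dataset
#'
#' Draws per-individual and per-sample random intercepts on the link scale,
#' forms the linear predictor `beta0 + beta_treatment*treat + batch effect +
#' u_i + v_ij`, and draws per-FoV positive counts from the chosen family.
#' Logit families draw `positive` out of `total` directly; log-link count
#' families draw counts with mean `total * exp(eta)` and redraw the rare
#' values exceeding `total` (a redraw counter is attached as attribute
#' `n_redraw`).
#'
#' @param design A [study_design()].
#' @param params A [sim_params()]; `beta_batch` must have length
#'   `design$n_batches - 1`.
#' @param seed Integer seed; the caller's RNG state is left untouched.
#' @return A tibble of class `fov_dataset` with columns `individual_id`,
#'   `sample_id`, `batch`, `treatment`, `fov_index`, `positive`, `total`,
#'   plus attributes `design` and `provenance`. Deterministic given `seed`.
#' @export
simulate_dataset <- function(design, params, seed) {
  stopifnot(inherits(design, "fov_design"), inherits(params, "fov_sim_params"))
  if (length(params$beta_batch) != design$n_batches - 1L)
    stop("beta_batch must have length n_batches - 1 (",
         design$n_batches - 1L, "), got ", length(params$beta_batch),
         call. = FALSE)

  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(as.integer(seed))

  nI <- design$n_individuals
  nS <- design$samples_per_individual
  n_fov <- design$n_fov
  m_fov <- rep_len(design$cells_per_fov, n_fov)
  fam <- params$family
  batch_eff <- c(0, params$beta_batch)
  total_redraw <- 0L

  # sample-level structure
  ind <- rep(seq_len(nI), each = nS)
  within <- rep(seq_len(nS), nI)
  treat <- switch(design$treatment_scheme,
    paired_within_individual = as.integer(within %% 2L == 0L), # samples 2,4,... treated
    between_individual = as.integer(ind > nI %/% 2L))
  batch <- ((seq_len(nI * nS) - 1L) %% design$n_batches) + 1L

  u <- rnorm(nI, 0, params$sd_individual)
  v <- rnorm(nI * nS, 0, params$sd_sample)
  eta_samp <- params$beta0 + params$beta_treatment * treat +
    batch_eff[batch] + u[ind] + v

  # FoV-level draws
  row_samp <- rep(seq_len(nI * nS), each = n_fov)
  eta <- eta_samp[row_samp]
  m_row <- rep(m_fov, nI * nS)
  n_row <- length(eta)
  if (fam$link == "logit") {
    if (fam$family_id == "binomial") {
      pos <- rbinom(n_row, m_row, plogis(eta))
    } else {
      p_fov <- rbeta(n_row, plogis(eta) * params$dispersion,
                     (1 - plogis(eta)) * params$dispersion)
      pos <- rbinom(n_row, m_row, p_fov)
    }
  } else {
    dr <- .draw_count_family(fam, n_row, m_row * exp(eta), m_row,
                             params$dispersion)
    pos <- dr$counts
    total_redraw <- dr$n_redraw
  }

  out <- tibble::tibble(
    individual_id = sprintf("I%03d", ind[row_samp]),
    sample_id = sprintf("I%03d_S%d", ind[row_samp], within[row_samp]),
    batch = batch[row_samp],
    treatment = treat[row_samp],
    fov_index = rep(seq_len(n_fov), nI * nS),
    positive = as.integer(pos),
    total = as.integer(m_row))
  attr(out, "design") <- design
  attr(out, "provenance") <- sprintf("fovpower simulate_dataset seed=%d",
                                     as.integer(seed))
  attr(out, "n_redraw") <- total_redraw
  if (total_redraw > 0)
    warning(total_redraw,
            " log-link draws exceeded the FoV total and were redrawn",
            call. = FALSE)
  class(out) <- c("fov_dataset", class(out))
  out
}

.fov_columns <- c("individual_id", "sample_id", "batch", "treatment",
                  "fov_index", "positive", "total")

#' Validate a FoV count table
#'
#' Checks the column set, count integrality, `0 <= positive <= total`,
#' uniqueness of `(individual_id, sample_id, fov_index)`, and that batch and
#' treatment are constant within each sample. Errors list the offending rows.
#'
#' @param x A data frame with the columns of [simulate_dataset()] output.
#' @return `x`, invisibly, with class `fov_dataset`.
#' @export
validate_fov_dataset <- function(x) {
  missing_cols <- setdiff(.fov_columns, names(x))
  if (length(missing_cols))
    stop("missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  if (nrow(x) == 0) stop("count table is empty", call. = FALSE)
  num_bad <- which(!is.finite(x$positive) | !is.finite(x$total) |
                     x$positive != floor(x$positive) |
                     x$total != floor(x$total) | x$total < 1)
  if (length(num_bad))
    stop("non-integer or invalid counts in row(s): ",
         paste(utils::head(num_bad, 10), collapse = ", "), call. = FALSE)
  bad <- which(x$positive < 0 | x$positive > x$total)
  if (length(bad))
    stop("positive > total (or negative) in row(s): ",
         paste(utils::head(bad, 10), collapse = ", "), call. = FALSE)
  key <- paste(x$individual_id, x$sample_id, x$fov_index)
  if (anyDuplicated(key))
    stop("duplicated (individual_id, sample_id, fov_index) in row(s): ",
         paste(utils::head(which(duplicated(key)), 10), collapse = ", "),
         call. = FALSE)
  per_sample <- split(seq_len(nrow(x)), x$sample_id)
  for (idx in per_sample) {
    if (length(unique(x$batch[idx])) > 1L ||
        length(unique(x$treatment[idx])) > 1L)
      stop("sample '", x$sample_id[idx[1]],
           "' spans multiple batches or treatments", call. = FALSE)
  }
  if (!inherits(x, "fov_dataset")) class(x) <- c("fov_dataset", class(x))
  invisible(x)
}

.delim_for <- function(path) {
  if (grepl("\\.(tsv|tab)$", path, ignore.case = TRUE)) "\t" else ","
}

#' Read a long-format FoV count table
#'
#' Expects a UTF-8 CSV or TSV (delimiter inferred from the extension;
#' `.tsv`/`.tab` means tab) with header columns `individual_id, sample_id,
#' batch, treatment, fov_index, positive, total`. Windows line endings are
#' accepted.
#'
#' @param path File path.
#' @return A validated `fov_dataset` tibble.
#' @export
read_count_table <- function(path) {
  x <- readr::read_delim(path, delim = .delim_for(path),
                         col_types = readr::cols(
                           individual_id = readr::col_character(),
                           sample_id = readr::col_character(),
                           batch = readr::col_integer(),
                           treatment = readr::col_integer(),
                           fov_index = readr::col_integer(),
                           positive = readr::col_double(),
                           total = readr::col_double()),
                         progress = FALSE, show_col_types = FALSE)
  prob <- readr::problems(x)
  if (nrow(prob))
    stop("malformed value(s) at row(s): ",
         paste(utils::head(unique(prob$row), 10), collapse = ", "),
         call. = FALSE)
  validate_fov_dataset(x)
  x$positive <- as.integer(x$positive)
  x$total <- as.integer(x$total)
  attr(x, "provenance") <- paste0("read from ", path)
  class(x) <- c("fov_dataset", class(x))
  x
}

#' Write a FoV count table
#'
#' @param dataset A `fov_dataset` (or any data frame with the standard
#'   columns).
#' @param path Destination; `.tsv`/`.tab` extension writes tab-separated,
#'   anything else comma-separated. `read_count_table(write_count_table(d))`
#'   reproduces `d` exactly.
#' @return `path`, invisibly.
#' @export
write_count_table <- function(dataset, path) {
  validate_fov_dataset(dataset)
  readr::write_delim(dataset[, .fov_columns], path,
                     delim = .delim_for(path), progress = FALSE)
  invisible(path)
}
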