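# Independent oracles used across the test files. These deliberately avoid
# the package's own computational path: pmfs are written out via base R
# lbeta/lchoose/dbinom, and the marginal likelihood is computed by dense
# Gauss-Hermite quadrature rather than the Laplace approximation.

# beta-binomial log-pmf via log-beta functions (mean/precision form)
bb_lpmf_oracle <- function(k, m, mu, phi) {
  a <- mu * phi
  b <- (1 - mu) * phi
  lchoose(m, k) + lbeta(k + a, m - k + b) - lbeta(a, b)
}

# marginal log-likelihood by tensor-product Gauss-Hermite quadrature over
# the (u, v_1, ..., v_J) random effects of each individual; exact up to
# quadrature error, feasible only for tiny instances
gh_loglik_oracle <- function(dataset, beta0, beta_treatment, sd_u, sd_v,
                             family = "binomial", phi = NULL, nodes = 32) {
  gh <- pracma::gaussHermite(nodes)
  x <- gh$x
  wq <- gh$w / sqrt(pi)
  d <- as.data.frame(dataset)
  total <- 0
  for (id in unique(d$individual_id)) {
    di <- d[d$individual_id == id, ]
    samples <- unique(di$sample_id)
    J <- length(samples)
    # grid over u and each v_j
    grids <- c(list(u = sqrt(2) * sd_u * x),
               stats::setNames(rep(list(sqrt(2) * sd_v * x), J),
                               paste0("v", seq_len(J))))
    grid <- expand.grid(grids)
    wgt <- Reduce(`*`, lapply(seq_len(J + 1), function(j)
      wq[match(grid[[j]], grids[[j]])]))
    log_integrand <- numeric(nrow(grid))
    for (j in seq_len(J)) {
      dj <- di[di$sample_id == samples[j], ]
      eta <- beta0 + beta_treatment * dj$treatment[1] + grid$u + grid[[j + 1]]
      for (r in seq_len(nrow(dj))) {
        p <- stats::plogis(eta)
        log_integrand <- log_integrand +
          if (family == "binomial")
            stats::dbinom(dj$positive[r], dj$total[r], p, log = TRUE)
          else
            bb_lpmf_oracle(dj$positive[r], dj$total[r], p, phi)
      }
    }
    mx <- max(log_integrand)
    total <- total + mx + log(sum(wgt * exp(log_integrand - mx)))
  }
  total
}

# small default-truth dataset for fitter tests
tiny_dataset <- function(seed, n_ind = 2, n_fov = 2, cells = 10, ...) {
  simulate_dataset(
    study_design(n_individuals = n_ind, n_fov = n_fov,
                 cells_per_fov = cells),
    sim_params(...), seed = seed)
}
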