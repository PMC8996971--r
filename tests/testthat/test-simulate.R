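test_that("simulation is deterministic given the seed and leaves RNG alone", {
  des <- study_design(n_individuals = 4, n_fov = 3, cells_per_fov = 10,
                      n_batches = 2)
  par <- sim_params(beta_batch = 0.1)
  set.seed(99)
  before <- .Random.seed
  d1 <- simulate_dataset(des, par, seed = 7)
  expect_identical(.Random.seed, before)
  d2 <- simulate_dataset(des, par, seed = 7)
  expect_identical(as.data.frame(d1), as.data.frame(d2))
  d3 <- simulate_dataset(des, par, seed = 8)
  expect_false(identical(d1$positive, d3$positive))
})

test_that("simulated datasets satisfy the structural invariants", {
  des <- study_design(n_individuals = 6, n_fov = 4, cells_per_fov = 20,
                      n_batches = 4)
  d <- simulate_dataset(des, sim_params(beta_batch = c(0.1, -0.1, 0.2)),
                        seed = 3)
  expect_silent(validate_fov_dataset(d))
  expect_equal(nrow(d), 6 * 2 * 4)
  expect_true(all(d$positive >= 0 & d$positive <= d$total))
  # paired scheme: exactly one treated sample per individual
  per_ind <- tapply(d$treatment, d$individual_id,
                    function(x) length(unique(x)))
  expect_true(all(per_ind == 2))
})

test_that("pooled positivity matches the baseline under a degenerate truth", {
  # no random effects, no treatment effect: law of large numbers at 1e5 cells
  des <- study_design(n_individuals = 25, n_fov = 20, cells_per_fov = 100)
  par <- sim_params(beta_treatment = 0, sd_individual = 0, sd_sample = 0,
                    family = "binomial")
  d <- simulate_dataset(des, par, seed = 11)
  n_cells <- sum(d$total)
  phat <- sum(d$positive) / n_cells
  se <- sqrt(0.3 * 0.7 / n_cells)
  expect_lt(abs(phat - 0.3), 3 * se)
})

test_that("beta-binomial FoV proportions show the implied overdispersion", {
  # single pair of samples, no random effects: within-sample variance of
  # FoV proportions is p(1-p)(1 + (m-1) rho)/m with rho = 1/(phi+1)
  des <- study_design(n_individuals = 1, n_fov = 4000, cells_per_fov = 25)
  par <- sim_params(beta_treatment = 0, sd_individual = 0, sd_sample = 0)
  d <- simulate_dataset(des, par, seed = 5)
  one <- d[d$sample_id == d$sample_id[1], ]
  props <- one$positive / one$total
  expected <- 0.3 * 0.7 * (1 + 24 * 0.25) / 25
  expect_equal(var(props), expected, tolerance = 0.08)
  # implied intra-FoV correlation recovers 1/(phi+1)
  rho_hat <- (var(props) * 25 / (mean(props) * (1 - mean(props))) - 1) / 24
  expect_equal(rho_hat, 0.25, tolerance = 0.1)
})

test_that("treatment shift and sample-level variance are recovered empirically", {
  # logit-scale difference of arm means tracks beta_treatment
  des <- study_design(n_individuals = 200, n_fov = 10, cells_per_fov = 100)
  par <- sim_params(sd_individual = 0, sd_sample = 0, family = "binomial")
  d <- simulate_dataset(des, par, seed = 21)
  p_arm <- tapply(d$positive, d$treatment, sum) /
    tapply(d$total, d$treatment, sum)
  expect_equal(qlogis(p_arm[["1"]]) - qlogis(p_arm[["0"]]), -0.2,
               tolerance = 0.05)

  # between-sample logit variance minus the binomial sampling part
  # (delta method) recovers sd_sample^2
  par2 <- sim_params(beta_treatment = 0, sd_individual = 0, sd_sample = 0.3,
                     family = "binomial")
  d2 <- simulate_dataset(des, par2, seed = 22)
  agg_p <- tapply(d2$positive, d2$sample_id, sum) /
    tapply(d2$total, d2$sample_id, sum)
  n_per <- tapply(d2$total, d2$sample_id, sum)
  samp_var <- mean(1 / (n_per * agg_p * (1 - agg_p)))
  expect_equal(var(qlogis(agg_p)) - samp_var, 0.09, tolerance = 0.02)
})

test_that("log-link families respect the total-count ceiling", {
  des <- study_design(n_individuals = 5, n_fov = 10, cells_per_fov = 10)
  for (fam in c("nb2", "nb1", "genpois", "poisson")) {
    par <- sim_params(beta0 = log(0.45), sd_individual = 0.2,
                      sd_sample = 0.1, family = fam,
                      dispersion = switch(fam, poisson = NULL, 2))
    d <- suppressWarnings(simulate_dataset(des, par, seed = 13))
    expect_true(all(d$positive <= d$total))
    expect_true(all(d$positive >= 0))
  }
})

test_that("count tables round-trip through CSV and TSV", {
  d <- simulate_dataset(study_design(n_individuals = 3, n_fov = 2,
                                     cells_per_fov = 15, n_batches = 2),
                        sim_params(beta_batch = 0.2), seed = 2)
  for (ext in c("csv", "tsv")) {
    path <- file.path(withr::local_tempdir(), paste0("counts.", ext))
    write_count_table(d, path)
    d2 <- read_count_table(path)
    expect_equal(as.data.frame(d)[, names(as.data.frame(d2))],
                 as.data.frame(d2), ignore_attr = TRUE)
  }
})

test_that("Windows line endings parse identically to Unix", {
  d <- simulate_dataset(study_design(n_individuals = 2, n_fov = 2,
                                     cells_per_fov = 10),
                        sim_params(), seed = 4)
  dir <- withr::local_tempdir()
  unix_path <- file.path(dir, "u.tsv")
  crlf_path <- file.path(dir, "w.tsv")
  write_count_table(d, unix_path)
  writeLines(sub("$", "\r", readLines(unix_path)), crlf_path, sep = "\n")
  expect_equal(as.data.frame(read_count_table(crlf_path)),
               as.data.frame(read_count_table(unix_path)),
               ignore_attr = TRUE)
})

test_that("malformed count tables are rejected with row numbers", {
  d <- as.data.frame(simulate_dataset(
    study_design(n_individuals = 2, n_fov = 3, cells_per_fov = 10),
    sim_params(), seed = 6))
  bad <- d
  bad$positive[4] <- bad$total[4] + 2
  expect_error(validate_fov_dataset(bad), "positive > total.*4")
  path <- file.path(withr::local_tempdir(), "bad.csv")
  readr::write_csv(bad, path)
  expect_error(read_count_table(path), "4")
  expect_error(validate_fov_dataset(d[, -7]), "missing column")
  frac <- d
  frac$positive[2] <- 1.5
  expect_error(validate_fov_dataset(frac), "non-integer.*2")
  dup <- rbind(d, d[1, ])
  expect_error(validate_fov_dataset(dup), "duplicated")
  span <- d
  span$batch[1] <- 2L
  expect_error(validate_fov_dataset(span), "spans")
})
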