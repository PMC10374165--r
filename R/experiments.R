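## Experiment orchestration: phase diagrams (MSE vs SNR), the spectral
## cleaning demo, and the eigenbasis universality swap.

#' Experiment configuration
#'
#' Validated container for a phase-diagram experiment.  Every trial's seed
#' is derived deterministically from \code{(seed, snr index, trial index)},
#' so any cell of the result table can be regenerated in isolation.
#'
#' @param family,mu Noise family and quartic interpolation parameter.
#' @param prior_kind,sparsity Signal prior.
#' @param snr_grid Numeric vector of \eqn{\lambda} values.
#' @param n Dimension per trial.
#' @param trials Trials per \eqn{\lambda}.
#' @param algorithms Subset of \code{c("bamp", "riamp_single",
#'   "amp_fullmem", "amp_ap", "pca")}.
#' @param T_max,eps_init Algorithm settings.
#' @param seed Root seed.
#' @param basis Noise eigenbasis (\code{"haar"} or \code{"hadamard"}).
#' @return An \code{"experiment_config"} list.
#' @export
experiment_config <- function(family = "quartic", mu = 0,
                              prior_kind = "rademacher", sparsity = NULL,
                              snr_grid = c(3, 4, 5), n = 2000, trials = 10,
                              algorithms = c("bamp", "riamp_single"),
                              T_max = 30, eps_init = 0.8, seed = 1,
                              basis = "haar") {
  ok <- c("bamp", "riamp_single", "amp_fullmem", "amp_ap", "pca")
  if (!all(algorithms %in% ok))
    stop("unknown algorithm(s): ", paste(setdiff(algorithms, ok), collapse = ", "))
  if (basis == "identity")
    stop("identity eigenbasis excluded: a diagonal noise matrix is maximally non-generic")
  stopifnot(basis %in% c("haar", "hadamard"), n >= 2, trials >= 1,
            all(snr_grid >= 0))
  if (basis == "hadamard" && !is_power_of_two(n))
    stop("hadamard basis needs n to be a power of 2")
  structure(list(family = family, mu = mu, prior_kind = prior_kind,
                 sparsity = sparsity, snr_grid = snr_grid, n = n,
                 trials = trials, algorithms = algorithms, T_max = T_max,
                 eps_init = eps_init, seed = seed, basis = basis),
            class = "experiment_config")
}

trial_seed <- function(root, isnr, itrial) {
  derive_seed(root * 1000 + isnr * 97 + itrial, "trial")
}

#' Run a phase-diagram experiment
#'
#' For each \eqn{\lambda} on the grid: compute the state evolution of every
#' requested AMP variant once, then run \code{trials} independent datasets
#' through each algorithm.  Non-converged trials (final MSE not finite or
#' above 0.45) are flagged, counted and excluded from the aggregate means,
#' never silently dropped.
#'
#' @param config An [experiment_config()].
#' @param progress Print one line per \eqn{\lambda}.
#' @return A \code{"result_table"}: \code{results} (one row per trial x
#'   algorithm), \code{theory} (state-evolution/BBP predictions per
#'   \eqn{\lambda}), \code{summary} (per-cell mean/sd of converged trials),
#'   \code{exclusions} (counts), and the echoed \code{config}.
#' @export
run_phase_diagram <- function(config, progress = FALSE) {
  stopifnot(inherits(config, "experiment_config"))
  spec <- ensemble_spec(config$family, config$mu)
  prior <- prior_spec(config$prior_kind, config$sparsity)
  amp_algos <- setdiff(config$algorithms, "pca")
  rows <- list(); theo <- list()
  for (isnr in seq_along(config$snr_grid)) {
    lam <- config$snr_grid[isnr]
    ses <- list()
    for (alg in amp_algos) {
      ses[[alg]] <- tryCatch(
        if (alg == "bamp") {
          bamp_state_evolution(spec, j_coefficients(spec, lam), prior, lam,
                               T_max = config$T_max, eps_init = config$eps_init)
        } else {
          amp_state_evolution(spec, prior, lam, alg, T_max = config$T_max,
                              eps_init = config$eps_init)
        }, error = function(e) e)
      se <- ses[[alg]]
      theo[[length(theo) + 1]] <- data.frame(
        snr = lam, algorithm = alg,
        se_mse = if (inherits(se, "error")) NA_real_ else se$mse[se$final_t],
        se_overlap = if (inherits(se, "error")) NA_real_ else se$overlap[se$T + 1],
        se_converged = if (inherits(se, "error")) FALSE else se$converged,
        error = if (inherits(se, "error")) conditionMessage(se) else "")
    }
    if ("pca" %in% config$algorithms) {
      th <- bbp_theory(spec, lam)
      theo[[length(theo) + 1]] <- data.frame(
        snr = lam, algorithm = "pca",
        se_mse = (1 - th$overlap_sq^2) / 2, se_overlap = th$overlap_sq,
        se_converged = TRUE, error = "")
    }
    for (itrial in seq_len(config$trials)) {
      sd <- trial_seed(config$seed, isnr, itrial)
      ds <- spiked_dataset(config$n, lam, spec, prior, sd, basis = config$basis)
      for (alg in config$algorithms) {
        row <- data.frame(family = spec$family, mu = spec$mu, snr = lam,
                          algorithm = alg, n = config$n, trial = itrial,
                          seed = sd, mse_final = NA_real_,
                          overlap_final = NA_real_, iterations = NA_integer_,
                          converged = FALSE, error = "")
        res <- tryCatch({
          if (alg == "pca") {
            pe <- spectral_pca_estimate(ds, spec)
            row$mse_final <- pe$mse
            row$overlap_final <- sum(pe$nu * ds$signal)^2 / config$n
            row$iterations <- NA_integer_
            row$converged <- !pe$below_threshold
          } else if (!inherits(ses[[alg]], "error")) {
            rr <- amp_run_engine(ds, ses[[alg]], sd, algorithm = alg)
            row$mse_final <- rr$final_mse
            row$overlap_final <- rr$final_overlap
            row$iterations <- rr$iterations
            row$converged <- rr$converged
          } else row$error <- "state evolution failed"
          row
        }, error = function(e) { row$error <- conditionMessage(e); row })
        rows[[length(rows) + 1]] <- res
      }
    }
    if (progress)
      message(sprintf("snr=%.3g done (%d trials x %d algorithms)",
                      lam, config$trials, length(config$algorithms)))
  }
  results <- do.call(rbind, rows)
  theory <- do.call(rbind, theo)
  conv <- results[results$converged & is.finite(results$mse_final), ]
  summary <- if (nrow(conv) > 0) {
    agg <- stats::aggregate(mse_final ~ snr + algorithm, data = conv,
                            FUN = function(x) c(mean = mean(x), sd = stats::sd(x),
                                                n = length(x)))
    data.frame(snr = agg$snr, algorithm = agg$algorithm,
               mse_mean = agg$mse_final[, "mean"],
               mse_sd = agg$mse_final[, "sd"],
               n_converged = agg$mse_final[, "n"])
  } else {
    data.frame(snr = numeric(0), algorithm = character(0),
               mse_mean = numeric(0), mse_sd = numeric(0),
               n_converged = integer(0))
  }
  excl <- stats::aggregate(converged ~ snr + algorithm, data = results,
                           FUN = function(x) sum(!x))
  names(excl)[3] <- "n_excluded"
  structure(list(results = results, theory = theory, summary = summary,
                 exclusions = excl, config = config),
            class = "result_table")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.result_table <- function(x, ...) {
  cat("<result_table>\n")
  print(x$summary, row.names = FALSE)
  ne <- sum(x$exclusions$n_excluded)
  cat(sprintf("  excluded (non-converged) trials: %d\n", ne))
  invisible(x)
}

#' Spectral-cleaning demonstration
#'
#' Generates one spiked dataset, computes the eigenvalues of \eqn{Y} and of
#' the preprocessed \eqn{J(Y)} (via the scalar spectral mapping), the
#' limiting density curve, and the predicted outlier locations.  Above the
#' BBP threshold the preprocessing maps the whole noise bulk to the
#' negative axis while the signal outlier stays isolated on the positive
#' side.
#'
#' @param family,mu Noise ensemble.
#' @param snr \eqn{\lambda}.
#' @param n Dimension (\eqn{\ge 500} for a meaningful histogram).
#' @param seed Seed.
#' @return List with \code{eigenvalues} (of \eqn{Y}), \code{eigenvalues_j}
#'   (of \eqn{J(Y)}), \code{density} (tabulated limiting curve),
#'   \code{outlier_theory}, \code{poly}, and the dataset parameters.
#' @export
run_spectral_demo <- function(family = "quartic", mu = 0, snr = 5, n = 4000,
                              seed = 1) {
  stopifnot(n >= 500)
  spec <- ensemble_spec(family, mu)
  prior <- prior_spec("rademacher")
  ds <- spiked_dataset(n, snr, spec, prior, seed)
  ev <- eigen(ds$data, symmetric = TRUE, only.values = TRUE)$values
  poly <- j_coefficients(spec, snr)
  evj <- j_scalar(poly, ev)
  a <- sqrt(spec$a_sq)
  xs <- seq(-2 * a, 2 * a, length.out = 512)
  th <- bbp_theory(spec, snr)
  list(family = spec$family, mu = spec$mu, snr = snr, n = n, seed = seed,
       eigenvalues = ev, eigenvalues_j = evj,
       density = data.frame(x = xs, rho = rho_density(xs, spec)),
       outlier_theory = th, outlier_j = j_scalar(poly, th$outlier),
       poly = poly)
}

#' Universality experiment: Haar vs Hadamard-Walsh eigenbasis
#'
#' Runs the same phase diagram twice, once with the Haar noise eigenbasis
#' and once with the randomized Hadamard-Walsh basis (which is not
#' rotationally invariant), and reports per-\eqn{\lambda} MSE differences
#' with standard errors.  Matching results support the universality of the
#' rotational-invariance predictions.
#'
#' @param config An [experiment_config()] (its \code{n} must be a power of
#'   2).
#' @param basis The alternative basis, currently \code{"hadamard"}.
#' @return List of class \code{"universality_table"}: the two
#'   \code{"result_table"}s and a \code{comparison} data frame.
#' @export
run_universality <- function(config, basis = "hadamard") {
  if (basis == "identity")
    stop("identity eigenbasis excluded: a diagonal noise matrix is maximally non-generic")
  stopifnot(basis == "hadamard")
  if (!is_power_of_two(config$n)) stop("n must be a power of 2 for hadamard")
  cfg_h <- config; cfg_h$basis <- "haar"
  cfg_w <- config; cfg_w$basis <- basis
  rt_h <- run_phase_diagram(cfg_h)
  rt_w <- run_phase_diagram(cfg_w)
  cmp <- merge(rt_h$summary, rt_w$summary, by = c("snr", "algorithm"),
               suffixes = c("_haar", "_hadamard"))
  cmp$diff <- cmp$mse_mean_hadamard - cmp$mse_mean_haar
  cmp$diff_se <- sqrt(cmp$mse_sd_haar^2 / cmp$n_converged_haar +
                      cmp$mse_sd_hadamard^2 / cmp$n_converged_hadamard)
  structure(list(haar = rt_h, hadamard = rt_w, comparison = cmp),
            class = "universality_table")
}

#' Export a result table to CSV files
#'
#' Writes \code{<stem>_results.csv}, \code{<stem>_theory.csv},
#' \code{<stem>_summary.csv} and \code{<stem>_exclusions.csv}.
#'
#' @param rt A \code{"result_table"}.
#' @param stem Output path stem.
#' @return Invisibly, the vector of files written.
#' @export
write_result_table <- function(rt, stem) {
  stopifnot(inherits(rt, "result_table"))
  files <- paste0(stem, "_", c("results", "theory", "summary", "exclusions"),
                  ".csv")
  utils::write.csv(rt$results, files[1], row.names = FALSE)
  utils::write.csv(rt$theory, files[2], row.names = FALSE)
  utils::write.csv(rt$summary, files[3], row.names = FALSE)
  utils::write.csv(rt$exclusions, files[4], row.names = FALSE)
  invisible(files)
}
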