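## Baseline algorithms for the phase diagram: the rotationally-invariant
## AMP with a single-iterate posterior-mean denoiser, the full-memory
## posterior-mean AMP, and AMP with alternating posteriors (AMP-AP).  All
## three operate on the raw data matrix Y (no polynomial preprocessing);
## they are instances of the same engine with J(Y) = Y and different
## denoiser schedules, so their Onsager corrections also come from the free
## cumulants of the noise spectrum.

baseline_schedule <- function(algorithm, T_max, K_pot = 1L) {
  switch(algorithm,
    riamp_single = rep("single", T_max),
    amp_fullmem = rep("full", T_max),
    amp_ap = {
      if (K_pot == 1L) {
        ## degenerate batches: no identity steps to aggregate, so the
        ## alternating schedule is the plain single-iterate AMP
        rep("single", T_max)
      } else {
        sch <- rep("identity", T_max)
        sch[seq_along(sch) %% K_pot == 0] <- "full"
        sch
      }
    },
    stop("unknown baseline algorithm: ", algorithm))
}

#' State evolution of a baseline AMP
#'
#' @param spec An [ensemble_spec()].
#' @param prior A [prior_spec()].
#' @param snr \eqn{\lambda}.
#' @param algorithm \code{"riamp_single"} (rotationally-invariant AMP,
#'   single-iterate posterior mean), \code{"amp_fullmem"} (full-memory
#'   posterior mean), or \code{"amp_ap"} (alternating posteriors: within
#'   each batch of \eqn{K} iterations, \eqn{K-1} identity denoisers then
#'   one full-memory posterior mean, \eqn{K} the potential degree minus 1;
#'   it needs the spectrum's cumulants but not the coefficients of
#'   \eqn{J(Y)}).
#' @param T_max Maximum main iterations (for \code{amp_ap} this counts
#'   batches, each of \eqn{K} iterations).
#' @param eps_init,tol As in [bamp_state_evolution()].
#' @return An \code{"se_state"}.
#' @export
amp_state_evolution <- function(spec, prior, snr,
                                algorithm = c("riamp_single", "amp_fullmem",
                                              "amp_ap"),
                                T_max = 30, eps_init = 0.8, tol = 1e-7, ...) {
  algorithm <- match.arg(algorithm)
  K_pot <- max(spec$degree - 1L, 1L)
  Tt <- if (algorithm == "amp_ap") T_max * K_pot else T_max
  sched <- baseline_schedule(algorithm, Tt, K_pot)
  kappa <- free_cumulants(spec, 2 * Tt + 2)
  out <- se_engine(kappa, 1, prior, snr, Tt, eps_init,
                   schedule = sched, tol = tol, ...)
  out$spec_family <- spec$family
  out$algorithm <- algorithm
  class(out) <- "se_state"
  out
}

baseline_run_impl <- function(dataset, prior, spec, algorithm, T_max,
                              eps_init, tol, seed, se) {
  if (is.null(se))
    se <- amp_state_evolution(spec, prior, dataset$snr, algorithm,
                              T_max = T_max, eps_init = eps_init, tol = tol)
  amp_run_engine(dataset, se, seed, algorithm = algorithm, tol = tol)
}

#' Rotationally-invariant AMP with single-iterate posterior mean
#'
#' The existing-AMP baseline: iterates on the raw \eqn{Y} with Onsager
#' corrections from the free cumulants of the noise spectrum and the
#' denoiser \eqn{g_{t+1}(f) = E[X^* | F_t = f]}.  Coincides with classical
#' spiked-Wigner AMP when the noise is GOE.
#'
#' @inheritParams bamp_run
#' @return A \code{"bamp_run"} with \code{algorithm = "riamp_single"}.
#' @export
riamp_run <- function(dataset, prior, spec, T_max = 30, eps_init = 0.8,
                      tol = 1e-7, seed = 1, se = NULL) {
  baseline_run_impl(dataset, prior, spec, "riamp_single", T_max, eps_init,
                    tol, seed, se)
}

#' Full-memory posterior-mean AMP
#'
#' Same recursion on raw \eqn{Y}, with the denoiser
#' \eqn{h_{t+1}(f^1,\dots,f^t) = E[X^* \mid F_1..F_t = f^1..f^t]}
#' conditioning on the whole trajectory.
#'
#' @inheritParams bamp_run
#' @return A \code{"bamp_run"} with \code{algorithm = "amp_fullmem"}.
#' @export
amp_fullmem_run <- function(dataset, prior, spec, T_max = 30, eps_init = 0.8,
                            tol = 1e-7, seed = 1, se = NULL) {
  baseline_run_impl(dataset, prior, spec, "amp_fullmem", T_max, eps_init,
                    tol, seed, se)
}

#' AMP with alternating posteriors (AMP-AP)
#'
#' For a degree-\eqn{K+1} potential, runs batches of \eqn{K} iterations on
#' raw \eqn{Y}: the first \eqn{K-1} use the identity denoiser (collecting
#' the powers \eqn{Y^k u^t}), the \eqn{K}-th applies the full-memory
#' posterior mean, which implicitly reassembles \eqn{J(Y)u^t} without ever
#' being told the coefficients of \eqn{J}.  With GOE noise (\eqn{K = 1})
#' this reduces to [riamp_run()].
#'
#' @inheritParams bamp_run
#' @param T_max Number of batches.
#' @return A \code{"bamp_run"} with \code{algorithm = "amp_ap"}; the
#'   \code{final_mse}/\code{final_overlap} refer to the last posterior-mean
#'   step.
#' @export
amp_ap_run <- function(dataset, prior, spec, T_max = 30, eps_init = 0.8,
                       tol = 1e-7, seed = 1, se = NULL) {
  baseline_run_impl(dataset, prior, spec, "amp_ap", T_max, eps_init,
                    tol, seed, se)
}
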