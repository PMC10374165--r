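## Multistage state-evolution engine.
##
## One engine drives every algorithm in the package.  The main recursion is
##     f^t = J(Y) u^t - sum_{i<=t} c_{t,i} u^i,   u^{t+1} = g_{t+1}(f^t),
## with J(Y) = sum_{k<=K} c_k Y^k.  Because J(Y)u^t cannot be split into
## signal + rotationally-invariant noise directly, each main iteration is
## unrolled into K steps of an auxiliary AMP on the noise matrix Z alone,
##     ztil^s = Z util^s - sum_{i<=s} bbar_{s,i} util^i,
## whose iterates reconstruct the powers util^{K(t-1)+l} ~ Y^{l-1} u^t via
## the splitting  Y^k u^t = sqrt(lambda)/N X* <X*, Y^{k-1}u^t> + Z Y^{k-1}u^t.
## The auxiliary AMP is the standard rotationally-invariant AMP, so its
## Onsager row is  bbar_{s,.} = [sum_j kappa_{j+1} Phi^j]_{s,.}  and its
## noise vector (ztil^1..ztil^s) is centered Gaussian with covariance
##     S = sum_{j>=0} kappa_{j+2} sum_{i+k=j} Phi^i Delta (Phi^T)^k,
## where Phi is the matrix of mean partial derivatives d util^i / d ztil^j
## and Delta the Gram matrix of the util's.  Expanding J(Y)u^t over the
## "atoms" {X*, u^1..u^t, ztil^1..ztil^{Kt}} and reading off coefficients
## gives (a) the Onsager coefficients c_{t,i} (coefficients on past main
## iterates), (b) the signal strength mu_t (coefficient on X*), and (c) the
## effective noise W_t (the ztil-combination), whose covariance Sigma comes
## from S.  Every scalar expectation the recursion needs is computed by
## Gauss-Hermite quadrature over the limiting scalar law.

## ---- scalar channels ----------------------------------------------------

## A "channel" is the scalar statistic the denoiser sees:
##   varsigma = s0 * X + noise, Var(noise) = v,
## together with the denoiser h applied to it.  `lin` marks denoisers that
## are exactly linear (identity; Gaussian-prior posterior mean), for which
## cross-moments have closed forms.
make_channel <- function(prior, s0, v, type = c("posterior", "identity")) {
  type <- match.arg(type)
  if (type == "identity") {
    return(list(type = type, s0 = s0, v = v, lin = TRUE, k = 1,
                h = function(x) x, hp = function(x) rep(1, length(x))))
  }
  if (abs(s0) < 1e-13) {
    ## uninformative channel: posterior mean of a centered prior is 0
    return(list(type = type, s0 = 0, v = v, lin = TRUE, k = 0,
                h = function(x) rep(0, length(x)),
                hp = function(x) rep(0, length(x))))
  }
  if (prior$kind == "gaussian") {
    k <- s0 / (s0^2 + v)
    return(list(type = type, s0 = s0, v = v, lin = TRUE, k = k,
                h = function(x) k * x, hp = function(x) rep(k, length(x))))
  }
  if (is.null(prior$atoms))
    stop("posterior-mean denoiser needs a discrete or gaussian prior")
  atoms <- prior$atoms; probs <- prior$probs
  rate <- s0 / v
  h <- function(x) {
    lw <- outer(atoms * rate, x) - atoms^2 * s0 * rate / 2 + log(probs)
    mx <- apply(lw, 2, max)
    w <- exp(sweep(lw, 2, mx))
    colSums(atoms * w) / colSums(w)
  }
  hp <- function(x) {
    lw <- outer(atoms * rate, x) - atoms^2 * s0 * rate / 2 + log(probs)
    mx <- apply(lw, 2, max)
    w <- exp(sweep(lw, 2, mx))
    z <- colSums(w)
    m1 <- colSums(atoms * w) / z
    m2 <- colSums(atoms^2 * w) / z
    rate * (m2 - m1^2)
  }
  list(type = type, s0 = s0, v = v, lin = FALSE, h = h, hp = hp)
}

## E[X h], E[h^2], E[h'] for a channel (X ~ prior, unit second moment)
channel_stats <- function(ch, prior, gh_nodes = 151) {
  if (ch$lin) {
    k <- ch$k
    return(list(beta = k * ch$s0, q = k^2 * (ch$s0^2 + ch$v), chi = k))
  }
  gh <- gauss_hermite_prob(gh_nodes)
  sdv <- sqrt(max(ch$v, 0))
  beta <- 0; q <- 0; chi <- 0
  for (a in seq_along(prior$atoms)) {
    x <- prior$atoms[a]; p <- prior$probs[a]
    zs <- ch$s0 * x + sdv * gh$x
    hv <- ch$h(zs)
    beta <- beta + p * x * sum(gh$w * hv)
    q <- q + p * sum(gh$w * hv^2)
    chi <- chi + p * sum(gh$w * ch$hp(zs))
  }
  list(beta = beta, q = q, chi = chi)
}

## E[h_a(varsigma_a) h_b(varsigma_b)] with joint noise covariance
## [[va, cab], [cab, vb]]
channel_cross <- function(cha, chb, cab, prior, gh_nodes = 61) {
  if (cha$lin && chb$lin) {
    return(cha$k * chb$k * (cha$s0 * chb$s0 + cab))
  }
  gh <- gauss_hermite_prob(gh_nodes)
  va <- max(cha$v, 0); vb <- max(chb$v, 0)
  if (va < 1e-14) {
    ## degenerate first channel: varsigma_a deterministic given X
    out <- 0
    sdb <- sqrt(vb)
    for (a in seq_along(prior$atoms)) {
      x <- prior$atoms[a]; p <- prior$probs[a]
      ha <- cha$h(cha$s0 * x)
      hb <- chb$h(chb$s0 * x + sdb * gh$x)
      out <- out + p * ha * sum(gh$w * hb)
    }
    return(out)
  }
  l11 <- sqrt(va)
  l21 <- cab / l11
  l22 <- sqrt(max(vb - l21^2, 0))
  atoms <- if (is.null(prior$atoms)) stop("gaussian prior pairs are linear") else prior$atoms
  out <- 0
  for (a in seq_along(atoms)) {
    x <- atoms[a]; p <- prior$probs[a]
    za <- cha$s0 * x + l11 * gh$x
    hva <- cha$h(za)
    ## inner expectation over the second Gaussian for each outer node
    hb_mat <- vapply(seq_along(gh$x), function(i) {
      zb <- chb$s0 * x + l21 * gh$x[i] + l22 * gh$x
      sum(gh$w * chb$h(zb))
    }, numeric(1))
    out <- out + p * sum(gh$w * hva * hb_mat)
  }
  out
}

## ---- the engine ----------------------------------------------------------

## kappa: free cumulants of the noise spectrum, length >= K*Tmax + 2
## cvec:  J(Y) coefficients c_1..c_K, trailing zeros already trimmed
## schedule: per main iteration, one of "single", "full", "identity"
se_engine <- function(kappa, cvec, prior, lambda, Tmax, eps,
                      schedule = rep("single", Tmax),
                      tol = 1e-7, sigma_floor = 1e-12, gh_nodes = 151,
                      gh_cross = 61) {
  K <- length(cvec)
  KT <- K * Tmax
  if (length(kappa) < KT + 2)
    stop("free cumulants supplied only to order ", length(kappa),
         "; need ", KT + 2)
  stopifnot(length(schedule) == Tmax, eps > 0, lambda >= 0)
  sl <- sqrt(lambda)

  ## auxiliary iterate expansions over atoms {X*, u^1..u^T, ztil^1..ztil^KT}
  UA <- numeric(KT + 1)                 # X* coefficient
  UD <- matrix(0, KT + 1, Tmax + 1)     # main-iterate coefficients
  UE <- matrix(0, KT + 1, KT)           # ztil coefficients
  Phi <- matrix(0, KT, KT)
  Delta <- matrix(0, KT, KT)
  S <- matrix(0, KT, KT)
  bbar <- matrix(0, KT, KT)
  P <- vector("list", KT)               # P[[k]] = Phi^k (grown row by row)
  for (k in seq_len(KT)) P[[k]] <- matrix(0, KT, KT)

  beta <- numeric(Tmax + 1); beta[1] <- eps
  qmat <- matrix(0, Tmax + 1, Tmax + 1); qmat[1, 1] <- 1
  chib <- numeric(Tmax + 1)             # E[h'] per main iterate (u^1 -> 0)
  ycoef <- matrix(0, Tmax, KT)          # ztil-coefficients of each channel
  channels <- vector("list", Tmax)
  alphas <- vector("list", Tmax)
  muvec <- numeric(Tmax)
  wmat <- matrix(0, Tmax, KT)
  ctab <- matrix(0, Tmax, Tmax)
  SigmaT <- matrix(0, Tmax, Tmax)
  gamma_tab <- matrix(0, Tmax, K)       # gamma_{t, l} = E[X* . Y^(l-1) u^t]
  mse <- rep(NA_real_, Tmax)
  UD[1, 1] <- 1                         # util^1 = u^1

  converged <- FALSE
  t_done <- 0L

  for (s in seq_len(KT)) {
    t <- (s - 1L) %/% K + 1L
    l <- s - (t - 1L) * K
    ucount <- t                          # u^1..u^t exist

    ## Phi row s: mean derivative of util^s w.r.t. each past ztil
    if (s >= 2) {
      prow <- UE[s, 1:(s - 1)]
      if (ucount >= 2) for (tp in 2:ucount) {
        d <- UD[s, tp]
        if (d != 0 && chib[tp] != 0)
          prow <- prow + d * chib[tp] * ycoef[tp - 1, 1:(s - 1)]
      }
      Phi[s, 1:(s - 1)] <- prow
      ## grow the powers of Phi by their new row (full-width rows: the
      ## padding is zero, so no submatrix extraction is needed)
      P[[1]][s, ] <- Phi[s, ]
      if (s >= 3) for (k in 2:(s - 1)) {
        P[[k]][s, ] <- as.numeric(Phi[s, ] %*% P[[k - 1]])
      }
    }

    ## Onsager row of the auxiliary AMP
    if (s >= 2) {
      br <- numeric(KT)
      for (k in 1:(s - 1)) {
        if (kappa[k + 1] != 0) br <- br + kappa[k + 1] * P[[k]][s, ]
      }
      bbar[s, ] <- br
    }

    ## Gram (Delta) row s: E[util^s util^i] through the atom Gram matrix
    nz <- s - 1L
    dim_atoms <- 1L + ucount + nz
    M <- matrix(0, dim_atoms, dim_atoms)
    M[1, 1] <- 1
    if (ucount >= 1) {
      M[1, 2:(1 + ucount)] <- beta[1:ucount]
      M[2:(1 + ucount), 1] <- beta[1:ucount]
      M[2:(1 + ucount), 2:(1 + ucount)] <- qmat[1:ucount, 1:ucount]
    }
    if (nz >= 1) {
      if (ucount >= 2) for (tp in 2:ucount) {
        if (chib[tp] != 0) {
          rv <- chib[tp] * as.numeric(ycoef[tp - 1, 1:nz] %*% S[1:nz, 1:nz])
          M[1 + tp, (1 + ucount + 1):dim_atoms] <- rv
          M[(1 + ucount + 1):dim_atoms, 1 + tp] <- rv
        }
      }
      M[(1 + ucount + 1):dim_atoms, (1 + ucount + 1):dim_atoms] <- S[1:nz, 1:nz]
    }
    Cmat <- cbind(UA[1:s], UD[1:s, 1:ucount, drop = FALSE],
                  if (nz >= 1) UE[1:s, 1:nz, drop = FALSE])
    drow <- as.numeric(Cmat %*% (M %*% Cmat[s, ]))
    Delta[s, 1:s] <- drow
    Delta[1:s, s] <- drow

    ## covariance row of the new ztil^s:
    ## S[s, ] = sum_{i,k>=0} kappa_{i+k+2} (Phi^i Delta Phi^T^k)[s, ]
    ## (all products on the full zero-padded matrices)
    Gmat <- matrix(0, s, KT)             # row (k+1) = (Phi^k)[s, ] Delta
    Gmat[1, ] <- Delta[s, ]
    if (s >= 2) for (k in 1:(s - 1)) {
      Gmat[k + 1, ] <- as.numeric(P[[k]][s, ] %*% Delta)
    }
    srow <- numeric(KT)
    for (ll in 0:(s - 1)) {
      kseg <- kappa[(ll + 2):(ll + s + 1)]
      ghat <- as.numeric(crossprod(Gmat, kseg))     # sum_k kappa_{k+ll+2} g_k
      srow <- srow + if (ll == 0) ghat else
        as.numeric(P[[ll]] %*% ghat)
    }
    S[s, 1:s] <- srow[1:s]
    S[1:s, s] <- srow[1:s]
    if (S[s, s] < -1e-8)
      stop("state evolution produced a negative noise variance at step ", s)

    if (l < K) {
      ## build util^{s+1} ~ Y^l u^t via the splitting identity
      gam <- UA[s] + sum(UD[s, 1:ucount] * beta[1:ucount])
      gamma_tab[t, l] <- gam
      bc <- bbar[s, 1:s]
      UA[s + 1] <- sl * gam + sum(bc * UA[1:s])
      UD[s + 1, ] <- as.numeric(bc %*% UD[1:s, , drop = FALSE])
      if (s >= 2) UE[s + 1, 1:(s - 1)] <- as.numeric(bc %*% UE[1:s, 1:(s - 1), drop = FALSE])
      UE[s + 1, s] <- 1
    } else {
      ## ---- stage end: read off mu_t, c_{t,.}, W_t ----
      gamma_tab[t, K] <- UA[s] + sum(UD[s, 1:ucount] * beta[1:ucount])
      tot_a <- 0; tot_d <- numeric(Tmax + 1); tot_e <- numeric(KT)
      if (K >= 2) for (k in 1:(K - 1)) {
        idx <- (t - 1L) * K + k + 1L
        tot_a <- tot_a + cvec[k] * UA[idx]
        tot_d <- tot_d + cvec[k] * UD[idx, ]
        tot_e <- tot_e + cvec[k] * UE[idx, ]
      }
      bc <- bbar[s, 1:s]
      tot_a <- tot_a + cvec[K] * (sl * gamma_tab[t, K] + sum(bc * UA[1:s]))
      tot_d <- tot_d + cvec[K] * as.numeric(bc %*% UD[1:s, , drop = FALSE])
      ee <- numeric(KT)
      if (s >= 2) ee[1:(s - 1)] <- as.numeric(bc %*% UE[1:s, 1:(s - 1), drop = FALSE])
      ee[s] <- ee[s] + 1
      tot_e <- tot_e + cvec[K] * ee

      if (max(abs(tot_d[(t + 1):(Tmax + 1)])) > 1e-9)
        stop("internal error: J(Y)u^t read-off touches future iterates")
      muvec[t] <- tot_a
      ctab[t, 1:t] <- tot_d[1:t]
      wmat[t, ] <- tot_e
      Sv <- as.numeric(S[1:s, 1:s] %*% tot_e[1:s])
      for (j in 1:t) SigmaT[t, j] <- SigmaT[j, t] <- sum(wmat[j, 1:s] * Sv)
      sig2 <- SigmaT[t, t]
      if (!is.finite(sig2) || sig2 < -1e-10)
        stop("state evolution unstable at iteration ", t,
             " (negative effective noise variance)")
      sig2 <- max(sig2, 0)

      ## denoiser for u^{t+1}
      sched <- schedule[t]
      if (sched == "full") {
        ## truncated pseudo-inverse: directions of the F-covariance below
        ## the relative cutoff carry only redundant (collinear) information;
        ## flooring them instead would blow up the effective SNR spuriously
        Sb <- SigmaT[1:t, 1:t, drop = FALSE]
        es <- eigen(Sb, symmetric = TRUE)
        keep <- es$values > 1e-10 * max(es$values, 0) & es$values > sigma_floor
        Vk <- es$vectors[, keep, drop = FALSE]
        alpha <- as.numeric(Vk %*% (crossprod(Vk, muvec[1:t]) / es$values[keep]))
        theta <- sum(alpha * muvec[1:t])
        ch <- make_channel(prior, theta, max(theta, 0), "posterior")
        yrow <- as.numeric(alpha %*% wmat[1:t, , drop = FALSE])
      } else if (sched == "identity") {
        alpha <- c(numeric(t - 1), 1)
        ch <- make_channel(prior, muvec[t], sig2, "identity")
        yrow <- wmat[t, ]
      } else {
        alpha <- c(numeric(t - 1), 1)
        ch <- make_channel(prior, muvec[t], sig2, "posterior")
        yrow <- wmat[t, ]
      }
      alphas[[t]] <- alpha
      channels[[t]] <- ch
      ycoef[t, ] <- yrow

      st <- channel_stats(ch, prior, gh_nodes)
      beta[t + 1] <- st$beta
      qmat[t + 1, t + 1] <- st$q
      chib[t + 1] <- st$chi
      qmat[t + 1, 1] <- qmat[1, t + 1] <- eps * st$beta
      if (t >= 2) for (j in 2:t) {
        cab <- as.numeric(ycoef[t, 1:s] %*% S[1:s, 1:s] %*% ycoef[j - 1, 1:s])
        qq <- channel_cross(channels[[t]], channels[[j - 1]], cab, prior,
                            gh_nodes = gh_cross)
        qmat[t + 1, j] <- qmat[j, t + 1] <- qq
      }
      mse[t] <- (1 - 2 * beta[t + 1]^2 + qmat[t + 1, t + 1]^2) / 2
      t_done <- t
      ## convergence is judged on estimating iterations only (identity
      ## steps of the alternating schedule carry no estimate)
      if (schedule[t] != "identity" && is.finite(mse[t])) {
        prev <- if (t >= 2) rev(which(schedule[1:(t - 1)] != "identity")) else integer(0)
        if (length(prev) >= 1 && is.finite(mse[prev[1]]) &&
            abs(mse[t] - mse[prev[1]]) < tol) {
          converged <- TRUE
          break
        }
      }
      if (t < Tmax) UD[s + 1, t + 1] <- 1     # util^{Kt+1} = u^{t+1}
    }
  }

  Td <- t_done
  est <- which(schedule[1:Td] != "identity")
  list(K = K, cvec = cvec, T = Td, lambda = lambda, eps = eps,
       final_t = if (length(est)) est[length(est)] else Td,
       schedule = schedule[1:Td],
       mu = muvec[1:Td], Sigma = SigmaT[1:Td, 1:Td, drop = FALSE],
       onsager = ctab[1:Td, 1:Td, drop = FALSE],
       overlap = beta[1:(Td + 1)], q = diag(qmat)[1:(Td + 1)],
       mse = mse[1:Td], converged = converged,
       channels = channels[1:Td], alphas = alphas[1:Td],
       gamma_tab = gamma_tab[1:Td, , drop = FALSE],
       bbar = bbar[1:(K * Td), 1:(K * Td), drop = FALSE],
       S = S[1:(K * Td), 1:(K * Td), drop = FALSE],
       Delta = Delta[1:(K * Td), 1:(K * Td), drop = FALSE],
       Phi = Phi[1:(K * Td), 1:(K * Td), drop = FALSE],
       qmat = qmat[1:(Td + 1), 1:(Td + 1), drop = FALSE],
       w = wmat[1:Td, 1:(K * Td), drop = FALSE],
       prior = prior)
}

## trim trailing zero coefficients of J (Wigner limit of the quartic family)
trim_poly <- function(cf) {
  nz <- which(cf != 0)
  if (length(nz) == 0) return(0)
  cf[1:max(nz)]
}
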