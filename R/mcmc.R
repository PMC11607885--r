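# MCMC machinery for the behavioural multilevel models.
#
# Two samplers share the bookkeeping (chains, burn-in, thinning, split-Rhat):
#  * gibbs_lmm(): exact conjugate Gibbs sampling for the square-root-scale
#    Gaussian mixed model (all full conditionals are closed-form);
#  * mh_beta_mlm(): Metropolis-within-Gibbs for the logit-link beta mixed
#    model, with proposal covariances from a ridge-penalised Fisher-scoring
#    fit and scale adaptation restricted to burn-in.

#' Sampler settings
#'
#' The full preset runs three chains of 10,000 iterations with the first half
#' discarded as burn-in and the remainder thinned by keeping every fourth
#' draw, giving 3 x 1250 = 3750 retained draws. The reduced preset (two
#' chains of 2,000) is for quick experimentation and continuous testing.
#'
#' @param preset `"full"` or `"reduced"`.
#' @param chains,iter,burnin,thin Override individual settings.
#' @return list of sampler settings with the implied `n_draws`.
#' @export
sampler_settings <- function(preset = c("full", "reduced"),
                             chains = NULL, iter = NULL, burnin = NULL,
                             thin = NULL) {
  preset <- match.arg(preset)
  s <- if (preset == "full") {
    list(chains = 3L, iter = 10000L, burnin = 5000L, thin = 4L)
  } else {
    list(chains = 2L, iter = 2000L, burnin = 1000L, thin = 4L)
  }
  s$chains <- as.integer(chains %||% s$chains)
  s$iter <- as.integer(iter %||% s$iter)
  s$burnin <- as.integer(burnin %||% s$burnin)
  s$thin <- as.integer(thin %||% s$thin)
  stop_if_not(s$burnin < s$iter, "burnin must be below iter")
  s$n_draws <- s$chains * ((s$iter - s$burnin) %/% s$thin)
  s
}

# Split-Rhat (each chain split in half) for a draws array organised as a list
# of per-chain matrices (iterations x parameters).
split_rhat <- function(chain_list) {
  halves <- list()
  for (ch in chain_list) {
    n <- nrow(ch)
    h <- n %/% 2
    halves <- c(halves, list(ch[1:h, , drop = FALSE],
                             ch[(h + 1):(2 * h), , drop = FALSE]))
  }
  m <- length(halves)
  n <- nrow(halves[[1]])
  means <- sapply(halves, colMeans)
  vars <- sapply(halves, function(x) apply(x, 2, stats::var))
  if (is.null(dim(means))) { means <- rbind(means); vars <- rbind(vars) }
  B <- n * apply(means, 1, stats::var)
  W <- rowMeans(vars)
  var_plus <- (n - 1) / n * W + B / n
  rh <- sqrt(var_plus / W)
  rh[W < .Machine$double.eps] <- 1
  rh
}

rinvgamma <- function(n, shape, rate) 1 / stats::rgamma(n, shape = shape, rate = rate)

# Conjugate Gibbs sampler for
#   y = X beta + u1[z1] + u2[z2] + eps,  eps ~ N(0, sigma2),
#   u1 ~ N(0, tau1^2), u2 ~ N(0, tau2^2),
# with weakly-informative priors beta ~ N(0, prior_sd^2 I) and
# sigma2, tau^2 ~ InvGamma(0.01, 0.01).
# `sweeps` lists extra Metropolis moves along near-likelihood-invariant
# directions (a fixed-effect column traded against a loading on the random
# intercepts): each element is list(col = j, re = 1 or 2, load = numeric over
# the units of that random term). These ridges (intercept vs mouse means,
# covariates constant within mouse vs mouse intercepts, block indicators vs
# block-within-mouse means) are resolved only by the priors and otherwise mix
# very slowly.
gibbs_lmm <- function(y, X, z1, z2, settings, seed,
                      prior_sd = 10, ig_a = 0.01, ig_b = 0.01,
                      sweeps = list(list(col = 1L, re = 1L, load = NULL))) {
  n <- length(y); p <- ncol(X)
  z1 <- as.integer(z1); z2 <- as.integer(z2)
  q1 <- max(z1); q2 <- max(z2)
  n1 <- tabulate(z1, q1); n2 <- tabulate(z2, q2)
  XtX <- crossprod(X)
  u2_mouse <- integer(q2)
  u2_mouse[z2] <- z1
  sweeps <- lapply(sweeps, function(sw) {
    if (is.null(sw$load)) sw$load <- rep(1, if (sw$re == 1) q1 else q2)
    sw
  })
  keep_per_chain <- (settings$iter - settings$burnin) %/% settings$thin
  chains_beta <- vector("list", settings$chains)
  chains_sigma2 <- vector("list", settings$chains)

  for (ch in seq_len(settings$chains)) {
    set.seed(seed + 1000L * ch)
    beta <- stats::rnorm(p, 0, 0.1)
    u1 <- rep(0, q1); u2 <- rep(0, q2)
    sigma2 <- stats::var(y); tau1 <- tau2 <- 0.1
    s_sw <- rep(0.2, length(sweeps)); s_swB <- 0.2
    Bkeep <- matrix(NA_real_, keep_per_chain, p)
    Skeep <- numeric(keep_per_chain)
    k <- 0L
    for (it in seq_len(settings$iter)) {
      # beta | rest
      r <- y - u1[z1] - u2[z2]
      A <- XtX / sigma2
      diag(A) <- diag(A) + 1 / prior_sd^2
      Ch <- chol(A)
      mu <- backsolve(Ch, forwardsolve(t(Ch), crossprod(X, r) / sigma2))
      beta <- drop(mu + backsolve(Ch, stats::rnorm(p)))
      eta <- drop(X %*% beta)
      # u1 | rest
      r1 <- y - eta - u2[z2]
      s1 <- rowsum(r1, z1, reorder = TRUE)[, 1]
      v1 <- 1 / (n1 / sigma2 + 1 / tau1)
      u1 <- stats::rnorm(q1, v1 * s1 / sigma2, sqrt(v1))
      # u2 | rest
      r2 <- y - eta - u1[z1]
      s2 <- rowsum(r2, z2, reorder = TRUE)[, 1]
      v2 <- 1 / (n2 / sigma2 + 1 / tau2)
      u2 <- stats::rnorm(q2, v2 * s2 / sigma2, sqrt(v2))
      # recentring sweeps: trade each listed fixed-effect column against its
      # random-intercept loading, then per-mouse u1 <-> u2 means
      res <- y - eta - u1[z1] - u2[z2]
      for (sk in seq_along(sweeps)) {
        sw <- sweeps[[sk]]
        dl <- stats::rnorm(1, 0, s_sw[sk])
        ld <- sw$load
        if (sw$re == 1L) {
          u_new <- u1 - dl * ld
          res_new <- res - dl * (X[, sw$col] - ld[z1])
          pr <- sum(stats::dnorm(u_new, 0, sqrt(tau1), log = TRUE) -
                      stats::dnorm(u1, 0, sqrt(tau1), log = TRUE))
        } else {
          u_new <- u2 - dl * ld
          res_new <- res - dl * (X[, sw$col] - ld[z2])
          pr <- sum(stats::dnorm(u_new, 0, sqrt(tau2), log = TRUE) -
                      stats::dnorm(u2, 0, sqrt(tau2), log = TRUE))
        }
        lr <- (sum(res^2) - sum(res_new^2)) / (2 * sigma2) + pr +
          stats::dnorm(beta[sw$col] + dl, 0, prior_sd, log = TRUE) -
          stats::dnorm(beta[sw$col], 0, prior_sd, log = TRUE)
        accS <- log(stats::runif(1)) < lr
        if (accS) {
          beta[sw$col] <- beta[sw$col] + dl
          eta <- eta + dl * X[, sw$col]
          if (sw$re == 1L) u1 <- u_new else u2 <- u_new
          res <- res_new
        }
        if (it <= settings$burnin) s_sw[sk] <- s_sw[sk] * exp((accS - 0.3) / sqrt(it))
      }
      mB <- stats::rnorm(q1, 0, s_swB)
      lrB <- rowsum(stats::dnorm(u2 - mB[u2_mouse], 0, sqrt(tau2), log = TRUE) -
                      stats::dnorm(u2, 0, sqrt(tau2), log = TRUE),
                    u2_mouse, reorder = TRUE)[, 1] +
        stats::dnorm(u1 + mB, 0, sqrt(tau1), log = TRUE) -
        stats::dnorm(u1, 0, sqrt(tau1), log = TRUE)
      accB <- log(stats::runif(q1)) < lrB
      if (any(accB)) {
        u1[accB] <- u1[accB] + mB[accB]
        selB <- accB[u2_mouse]
        u2[selB] <- u2[selB] - mB[u2_mouse][selB]
      }
      if (it <= settings$burnin) s_swB <- s_swB * exp((mean(accB) - 0.3) / sqrt(it))
      # variances
      res <- y - eta - u1[z1] - u2[z2]
      sigma2 <- rinvgamma(1, ig_a + n / 2, ig_b + sum(res^2) / 2)
      tau1 <- rinvgamma(1, ig_a + q1 / 2, ig_b + sum(u1^2) / 2)
      tau2 <- rinvgamma(1, ig_a + q2 / 2, ig_b + sum(u2^2) / 2)
      if (it > settings$burnin && (it - settings$burnin) %% settings$thin == 0) {
        k <- k + 1L
        Bkeep[k, ] <- beta
        Skeep[k] <- sigma2
      }
    }
    chains_beta[[ch]] <- Bkeep
    chains_sigma2[[ch]] <- Skeep
  }
  rhat <- split_rhat(lapply(seq_len(settings$chains), function(ch)
    cbind(chains_beta[[ch]], sigma2 = chains_sigma2[[ch]])))
  list(beta = do.call(rbind, chains_beta),
       sigma2 = unlist(chains_sigma2),
       rhat = rhat)
}

# Ridge-penalised Fisher scoring for a fixed-effects beta regression with
# logit link (random effects ignored): supplies the starting point, proposal
# covariance and dispersion initialiser for the Metropolis sampler. The ridge
# keeps the step well-defined under near-collinear designs.
beta_fisher_init <- function(y, X, lambda = 1e-2, iters = 40) {
  p <- ncol(X)
  yc <- pmin(pmax(y, 1e-4), 1 - 1e-4)
  ystar <- stats::qlogis(yc)
  XtX <- crossprod(X)
  beta <- solve(XtX + diag(lambda, p), crossprod(X, ystar))
  mu <- stats::plogis(drop(X %*% beta))
  phi <- max(mean(mu * (1 - mu)) / max(stats::var(yc - mu), 1e-8) - 1, 5)
  H <- XtX
  for (it in seq_len(iters)) {
    eta <- drop(X %*% beta)
    mu <- pmin(pmax(stats::plogis(eta), 1e-6), 1 - 1e-6)
    mustar <- digamma(mu * phi) - digamma((1 - mu) * phi)
    info <- phi^2 * (mu * (1 - mu))^2 * (trigamma(mu * phi) + trigamma((1 - mu) * phi))
    score <- crossprod(X, phi * mu * (1 - mu) * (stats::qlogis(yc) - mustar)) -
      lambda * beta
    H <- crossprod(X, X * info) + diag(lambda, p)
    # damped update for stability far from the optimum
    beta <- beta + 0.8 * drop(solve(H, score))
    if (it %% 5 == 0) {
      mu <- pmin(pmax(stats::plogis(drop(X %*% beta)), 1e-6), 1 - 1e-6)
      phi <- max(mean(mu * (1 - mu)) / max(stats::var(yc - mu), 1e-8) - 1, 5)
    }
  }
  list(beta = drop(beta), V = solve(H), phi = phi)
}

# Metropolis-within-Gibbs for
#   y ~ Beta(mu * phi, (1 - mu) * phi),  logit(mu) = X beta + u1[z1] + u2[z2].
# The fixed effects are sampled in whitened coordinates theta = L^-1 beta,
# where L L' = Vprop (the Fisher covariance of the initialising fit), so the
# conditional posterior of theta is approximately isotropic and blockwise
# random walks mix well; random intercepts are updated simultaneously across
# their (conditionally independent) units; tau^2 are conjugate; phi gets a
# log-scale random walk. Proposal scales adapt during burn-in only.
mh_beta_mlm <- function(y, X, z1, z2, settings, seed, Vprop, beta_init,
                        phi_init, prior_sd = 10, ig_a = 0.01, ig_b = 0.01,
                        block_size = 12L,
                        sweeps = list(list(col = 1L, re = 1L, load = NULL))) {
  n <- length(y); p <- ncol(X)
  z1 <- as.integer(z1); z2 <- as.integer(z2)
  q1 <- max(z1); q2 <- max(z2)
  Lw <- t(chol(Vprop + diag(1e-10, p)))  # beta = Lw theta
  Xw <- X %*% Lw
  theta_init <- drop(forwardsolve(Lw, beta_init))
  blocks <- split(seq_len(p), ceiling(seq_len(p) / block_size))
  sweeps <- lapply(sweeps, function(sw) {
    if (is.null(sw$load)) sw$load <- rep(1, if (sw$re == 1) q1 else q2)
    ej <- rep(0, p); ej[sw$col] <- 1
    sw$ejw <- drop(forwardsolve(Lw, ej))  # theta shift for a unit beta shift
    sw
  })
  # mouse owning each mouse-block unit (nesting map for sweep b)
  u2_mouse <- integer(q2)
  u2_mouse[z2] <- z1
  keep_per_chain <- (settings$iter - settings$burnin) %/% settings$thin
  chains_beta <- vector("list", settings$chains)
  chains_phi <- vector("list", settings$chains)
  accept <- numeric(settings$chains)

  obs_ll <- function(eta, phi) {
    mu <- stats::plogis(eta)
    mu <- pmin(pmax(mu, 1e-12), 1 - 1e-12)
    stats::dbeta(y, mu * phi, (1 - mu) * phi, log = TRUE)
  }

  for (ch in seq_len(settings$chains)) {
    set.seed(seed + 2000L * ch)
    theta <- theta_init + stats::rnorm(p, 0, 0.02)
    beta <- drop(Lw %*% theta)
    u1 <- rep(0, q1); u2 <- rep(0, q2)
    tau1 <- tau2 <- 0.1
    phi <- phi_init
    s_blk <- rep(1, length(blocks)); s_u1 <- 0.3; s_u2 <- 0.3; s_phi <- 0.15
    s_sw <- rep(0.2, length(sweeps)); s_swB <- 0.2
    eta_fix <- drop(Xw %*% theta)
    ll <- obs_ll(eta_fix + u1[z1] + u2[z2], phi)
    Bkeep <- matrix(NA_real_, keep_per_chain, p)
    Pkeep <- numeric(keep_per_chain)
    k <- 0L; n_acc <- 0L; n_try <- 0L
    for (it in seq_len(settings$iter)) {
      adapting <- it <= settings$burnin
      # fixed-effect blocks (whitened coordinates)
      for (bi in seq_along(blocks)) {
        ix <- blocks[[bi]]
        d <- stats::rnorm(length(ix)) * (2.38 / sqrt(length(ix))) * s_blk[bi]
        dbeta <- drop(Lw[, ix, drop = FALSE] %*% d)
        eta_new <- eta_fix + drop(Xw[, ix, drop = FALSE] %*% d)
        ll_new <- obs_ll(eta_new + u1[z1] + u2[z2], phi)
        lr <- sum(ll_new) - sum(ll) +
          sum(stats::dnorm(beta + dbeta, 0, prior_sd, log = TRUE)) -
          sum(stats::dnorm(beta, 0, prior_sd, log = TRUE))
        acc <- is.finite(lr) && log(stats::runif(1)) < lr
        if (acc) {
          theta[ix] <- theta[ix] + d
          beta <- beta + dbeta
          eta_fix <- eta_new
          ll <- ll_new
        }
        n_try <- n_try + 1L; n_acc <- n_acc + acc
        if (adapting) s_blk[bi] <- s_blk[bi] * exp((acc - 0.25) / sqrt(it))
      }
      # u1: simultaneous per-unit proposals (units conditionally independent)
      d1 <- stats::rnorm(q1, 0, s_u1)
      ll_new <- obs_ll(eta_fix + (u1 + d1)[z1] + u2[z2], phi)
      lr1 <- rowsum(ll_new - ll, z1, reorder = TRUE)[, 1] +
        stats::dnorm(u1 + d1, 0, sqrt(tau1), log = TRUE) -
        stats::dnorm(u1, 0, sqrt(tau1), log = TRUE)
      acc1 <- log(stats::runif(q1)) < lr1
      if (any(acc1)) {
        u1[acc1] <- u1[acc1] + d1[acc1]
        ll <- obs_ll(eta_fix + u1[z1] + u2[z2], phi)
      }
      if (adapting) s_u1 <- s_u1 * exp((mean(acc1) - 0.35) / sqrt(it))
      # u2
      d2 <- stats::rnorm(q2, 0, s_u2)
      ll_new <- obs_ll(eta_fix + u1[z1] + (u2 + d2)[z2], phi)
      lr2 <- rowsum(ll_new - ll, z2, reorder = TRUE)[, 1] +
        stats::dnorm(u2 + d2, 0, sqrt(tau2), log = TRUE) -
        stats::dnorm(u2, 0, sqrt(tau2), log = TRUE)
      acc2 <- log(stats::runif(q2)) < lr2
      if (any(acc2)) {
        u2[acc2] <- u2[acc2] + d2[acc2]
        ll <- obs_ll(eta_fix + u1[z1] + u2[z2], phi)
      }
      if (adapting) s_u2 <- s_u2 * exp((mean(acc2) - 0.35) / sqrt(it))
      # recentring sweeps: trade listed fixed-effect columns against their
      # random-intercept loadings (near-likelihood-invariant ridges)
      for (sk in seq_along(sweeps)) {
        sw <- sweeps[[sk]]
        dl <- stats::rnorm(1, 0, s_sw[sk])
        ld <- sw$load
        eta_fix_new <- eta_fix + dl * X[, sw$col]
        if (sw$re == 1L) {
          u1_new <- u1 - dl * ld; u2_new <- u2
          pr <- sum(stats::dnorm(u1_new, 0, sqrt(tau1), log = TRUE) -
                      stats::dnorm(u1, 0, sqrt(tau1), log = TRUE))
        } else {
          u1_new <- u1; u2_new <- u2 - dl * ld
          pr <- sum(stats::dnorm(u2_new, 0, sqrt(tau2), log = TRUE) -
                      stats::dnorm(u2, 0, sqrt(tau2), log = TRUE))
        }
        ll_new <- obs_ll(eta_fix_new + u1_new[z1] + u2_new[z2], phi)
        lr <- sum(ll_new) - sum(ll) + pr +
          stats::dnorm(beta[sw$col] + dl, 0, prior_sd, log = TRUE) -
          stats::dnorm(beta[sw$col], 0, prior_sd, log = TRUE)
        accS <- is.finite(lr) && log(stats::runif(1)) < lr
        if (accS) {
          beta[sw$col] <- beta[sw$col] + dl
          theta <- theta + dl * sw$ejw
          eta_fix <- eta_fix_new
          u1 <- u1_new; u2 <- u2_new
          ll <- ll_new
        }
        if (adapting) s_sw[sk] <- s_sw[sk] * exp((accS - 0.3) / sqrt(it))
      }
      # (b) shift mass between each mouse's intercept and its block intercepts
      mB <- stats::rnorm(q1, 0, s_swB)
      lrB <- rowsum(stats::dnorm(u2 - mB[u2_mouse], 0, sqrt(tau2), log = TRUE) -
                      stats::dnorm(u2, 0, sqrt(tau2), log = TRUE),
                    u2_mouse, reorder = TRUE)[, 1] +
        stats::dnorm(u1 + mB, 0, sqrt(tau1), log = TRUE) -
        stats::dnorm(u1, 0, sqrt(tau1), log = TRUE)
      accB <- log(stats::runif(q1)) < lrB
      if (any(accB)) {
        u1[accB] <- u1[accB] + mB[accB]
        sel <- accB[u2_mouse]
        u2[sel] <- u2[sel] - mB[u2_mouse][sel]
      }
      if (adapting) s_swB <- s_swB * exp((mean(accB) - 0.3) / sqrt(it))
      # variance components (conjugate)
      tau1 <- rinvgamma(1, ig_a + q1 / 2, ig_b + sum(u1^2) / 2)
      tau2 <- rinvgamma(1, ig_a + q2 / 2, ig_b + sum(u2^2) / 2)
      # phi: log-scale random walk, Gamma(0.01, 0.01) prior
      phi_new <- phi * exp(stats::rnorm(1, 0, s_phi))
      ll_new <- obs_ll(eta_fix + u1[z1] + u2[z2], phi_new)
      lrp <- sum(ll_new) - sum(ll) +
        ig_a * (log(phi_new) - log(phi)) - ig_b * (phi_new - phi)
      accp <- is.finite(lrp) && log(stats::runif(1)) < lrp
      if (accp) { phi <- phi_new; ll <- ll_new }
      if (adapting) s_phi <- s_phi * exp((accp - 0.3) / sqrt(it))
      if (it > settings$burnin && (it - settings$burnin) %% settings$thin == 0) {
        k <- k + 1L
        Bkeep[k, ] <- beta
        Pkeep[k] <- phi
      }
    }
    chains_beta[[ch]] <- Bkeep
    chains_phi[[ch]] <- Pkeep
    accept[ch] <- n_acc / n_try
  }
  rhat <- split_rhat(lapply(seq_len(settings$chains), function(ch)
    cbind(chains_beta[[ch]], phi = chains_phi[[ch]])))
  list(beta = do.call(rbind, chains_beta),
       phi = unlist(chains_phi),
       rhat = rhat, accept = accept)
}
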