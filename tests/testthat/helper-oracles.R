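# Independent brute-force oracles: enumerate every latent occupancy
# configuration explicitly and sum the exact joint probabilities. Deliberately
# naive (nested loops, probability scale) and independent of the package's
# marginalized log-sum-exp implementation.

# P(history | occupancy u) as a plain product over observed visits
oracle_hist_prob <- function(h, p, u) {
  pr <- 1
  for (l in seq_along(h)) {
    if (is.na(h[l])) next
    pe <- u * p[l]
    pr <- pr * if (h[l] == 1) pe else (1 - pe)
  }
  pr
}

# single-scale: psi is an array [I, J, K], p an array [I, J, K, L]
oracle_loglik_single <- function(y, psi, p) {
  dm <- dim(y)
  cells <- expand.grid(i = seq_len(dm[1]), j = seq_len(dm[2]), k = seq_len(dm[3]))
  nc <- nrow(cells)
  total <- 0
  for (cfg in 0:(2^nc - 1)) {
    u <- as.integer(intToBits(cfg))[seq_len(nc)]
    pr <- 1
    for (c in seq_len(nc)) {
      i <- cells$i[c]; j <- cells$j[c]; k <- cells$k[c]
      ps <- psi[i, j, k]
      pr <- pr * (if (u[c] == 1) ps else 1 - ps) *
        oracle_hist_prob(y[i, j, k, ], p[i, j, k, ], u[c])
    }
    total <- total + pr
  }
  log(total)
}

# multi-scale: theta [I, J], constant psi and p; enumerate all (z, u) jointly
oracle_loglik_multi <- function(y, theta, psi, p) {
  dm <- dim(y)
  uys <- expand.grid(i = seq_len(dm[1]), j = seq_len(dm[2]))
  cells <- expand.grid(i = seq_len(dm[1]), j = seq_len(dm[2]), k = seq_len(dm[3]))
  nz <- nrow(uys); nc <- nrow(cells)
  total <- 0
  for (zc in 0:(2^nz - 1)) {
    z <- as.integer(intToBits(zc))[seq_len(nz)]
    prz <- 1
    for (a in seq_len(nz))
      prz <- prz * (if (z[a] == 1) theta[uys$i[a], uys$j[a]]
                    else 1 - theta[uys$i[a], uys$j[a]])
    for (uc in 0:(2^nc - 1)) {
      u <- as.integer(intToBits(uc))[seq_len(nc)]
      pr <- prz
      for (c in seq_len(nc)) {
        i <- cells$i[c]; j <- cells$j[c]; k <- cells$k[c]
        zij <- z[uys$i == i & uys$j == j]
        pu <- zij * psi # plot occupancy prob is 0 under an unoccupied unit
        pr <- pr * (if (u[c] == 1) pu else 1 - pu) *
          oracle_hist_prob(y[i, j, k, ], rep(p, dm[4]), u[c])
        if (pr == 0) break
      }
      total <- total + pr
    }
  }
  log(total)
}

# independently coded Gelman-Rubin reference (textbook formula)
oracle_gelman_rubin <- function(chains) {
  m <- length(chains); n <- length(chains[[1]])
  chain_means <- sapply(chains, mean)
  grand <- mean(chain_means)
  B <- n / (m - 1) * sum((chain_means - grand)^2)
  W <- mean(sapply(chains, function(x) sum((x - mean(x))^2) / (n - 1)))
  sqrt(((n - 1) / n * W + B / n) / W)
}

# random small single-scale problem for oracle comparisons
random_single_problem <- function() {
  I <- 2L; J <- 2L; K <- 2L; L <- 2L
  y <- array(rbinom(I * J * K * L, 1, 0.4), dim = c(I, J, K, L))
  nmiss <- sample(0:3, 1)
  if (nmiss > 0) y[sample(length(y), nmiss)] <- NA
  beta <- rnorm(4, 0, 1.2)
  gamma <- rnorm(1, 0, 1)
  b0 <- rnorm(I, 0, 0.8)
  treatment <- c(0L, 1L); year_after <- c(0L, 1L)
  list(y = y, beta = beta, gamma = gamma, b0 = b0,
       treatment = treatment, year_after = year_after)
}

# psi/p arrays implied by the BACI single-scale parameterization
single_prob_arrays <- function(pr) {
  dm <- dim(pr$y)
  psi <- array(0, dim = dm[1:3]); p <- array(plogis(pr$gamma), dim = dm)
  for (i in seq_len(dm[1])) for (j in seq_len(dm[2])) {
    eta <- pr$beta[1] + pr$b0[i] + pr$beta[2] * pr$year_after[j] +
      pr$beta[3] * pr$treatment[i] +
      pr$beta[4] * pr$treatment[i] * pr$year_after[j]
    psi[i, j, ] <- plogis(eta)
  }
  list(psi = psi, p = p)
}

# compact MCMC settings for tests that only need a working fit
tiny_mcmc <- list(chains = 2, n_iter = 600, burnin = 300, thin = 1)
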