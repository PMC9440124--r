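# Independent oracles used by the unit and acceptance tests. Nothing here
# touches the package's own fitting code paths.

# Gauss-Hermite nodes/weights (physicists' convention) by Golub-Welsch:
# eigen-decomposition of the Jacobi matrix of the Hermite recurrence.
gh_rule <- function(k) {
  J <- matrix(0, k, k)
  i <- seq_len(k - 1L)
  J[cbind(i, i + 1L)] <- sqrt(i / 2)
  J[cbind(i + 1L, i)] <- sqrt(i / 2)
  e <- eigen(J, symmetric = TRUE)
  ord <- order(e$values)
  list(nodes = e$values[ord], weights = sqrt(pi) * e$vectors[1, ord]^2)
}

# Dense product Gauss-Hermite marginal log-likelihood of the crossed
# random-intercept logistic model. Equivalent to the full (k^(nr+nl))-node
# product grid: the integrand factorizes over lesions once the rater
# effects are fixed, so the lesion dimensions are summed exactly inside.
gh_crossed_loglik <- function(beta, sigma_rater, sigma_lesion,
                              y, session, rater, lesion, k = 9L) {
  rater <- as.integer(factor(rater))
  lesion <- as.integer(factor(lesion))
  nr <- max(rater); nl <- max(lesion)
  gh <- gh_rule(k)
  ur <- sqrt(2) * sigma_rater * gh$nodes
  ul <- sqrt(2) * sigma_lesion * gh$nodes
  w <- gh$weights / sqrt(pi)
  grid <- as.matrix(do.call(expand.grid, rep(list(seq_len(k)), nr)))
  G <- nrow(grid)
  Umat <- matrix(ur[grid], G, nr)
  # log-weight of each rater-node combination, then per-lesion exact sums
  total_log <- rowSums(matrix(log(w[grid]), G, nr))
  for (l in seq_len(nl)) {
    idx <- which(lesion == l)
    off <- beta[1] + beta[2] * session[idx]
    lik <- matrix(1, G, k)
    for (j in seq_along(idx)) {
      p <- stats::plogis(outer(Umat[, rater[idx[j]]], ul, "+") + off[j])
      lik <- lik * (if (y[idx[j]] == 1) p else 1 - p)
    }
    total_log <- total_log + log(as.numeric(lik %*% w))
  }
  m <- max(total_log)
  m + log(sum(exp(total_log - m)))
}

# brute-force ML fit of the crossed model under the GH oracle likelihood
gh_crossed_fit <- function(y, session, rater, lesion, k = 9L,
                           start = c(0, 0, log(0.5), log(0.5))) {
  nll <- function(par) {
    -gh_crossed_loglik(par[1:2], exp(par[3]), exp(par[4]),
                       y, session, rater, lesion, k)
  }
  opt <- stats::optim(start, nll, method = "Nelder-Mead",
                      control = list(reltol = 1e-9, maxit = 600))
  list(beta = opt$par[1:2], sigma = exp(opt$par[3:4]),
       loglik = -opt$value, convergence = opt$convergence)
}

# simulate responses directly from the crossed-intercept logistic model
# (bypassing the cohort generator) on the full rater x lesion x session grid
simulate_glmm_rows <- function(n_raters, n_lesions, beta0, beta1,
                               sigma_rater, sigma_lesion) {
  u <- rnorm(n_raters, 0, sigma_rater)
  v <- rnorm(n_lesions, 0, sigma_lesion)
  grid <- expand.grid(rater_id = seq_len(n_raters), lesion_id = seq_len(n_lesions),
                      session = c(0L, 1L))
  eta <- beta0 + beta1 * grid$session + u[grid$rater_id] + v[grid$lesion_id]
  grid$y <- rbinom(nrow(grid), 1L, plogis(eta))
  grid
}
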