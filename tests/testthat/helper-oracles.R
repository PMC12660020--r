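# Independent oracles used across the suite. These deliberately avoid the
# package's own vectorized code paths: plain loops and sums only.

# brute-force EAP by very fine rectangle-rule quadrature
oracle_eap <- function(responses, prob_funs, n_nodes = 1e5,
                       lower = -6, upper = 6, prior_mean = 0, prior_sd = 1) {
  nodes <- seq(lower, upper, length.out = n_nodes)
  post <- dnorm(nodes, prior_mean, prior_sd)
  for (i in seq_along(responses)) {
    v <- responses[[i]]
    if (is.na(v)) next
    post <- post * prob_funs[[i]](nodes, v)
  }
  post <- post / sum(post)
  eap <- sum(nodes * post)
  psd <- sqrt(sum(nodes^2 * post) - eap^2)
  list(eap = eap, psd = psd)
}

# brute-force marginalization: sum the joint over all manual categories
oracle_marginal <- function(theta, manual_prob_fun, p_v_given_u, v) {
  K <- nrow(p_v_given_u)
  out <- 0
  for (u in 0:(K - 1)) {
    out <- out + manual_prob_fun(theta, u) * p_v_given_u[u + 1, v + 1]
  }
  out
}

# random row-stochastic confusion matrix
random_confusion <- function(K) {
  m <- matrix(rgamma(K * K, shape = 1), K, K)
  m / rowSums(m)
}

# simple paired-score generator with constant error rates
gen_cer_pairs <- function(n, fp, fn, a = 1, b = 0) {
  theta <- rnorm(n)
  u <- rbinom(n, 1, plogis(a * (theta - b)))
  v <- ifelse(u == 1, rbinom(n, 1, 1 - fn), rbinom(n, 1, fp))
  list(theta = theta, u = u, v = v)
}
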