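test_that("confusion-matrix MLE reproduces hand-countable proportions", {
  # perfect classifier
  cm <- estimate_confusion(c(0, 1, 2, 0, 1, 2), c(0, 1, 2, 0, 1, 2), K = 3)
  expect_equal(unname(cm$p_v_given_u), diag(3))

  # dichotomous: 100 manually-correct pairs, 10 scored incorrect
  u <- rep(1, 100)
  v <- c(rep(0, 10), rep(1, 90))
  cm2 <- suppressWarnings(estimate_confusion(c(u, 0, 0), c(v, 0, 0), K = 2))
  expect_equal(cm2$p_v_given_u["1", "0"], 0.10)

  # K = 3 toy table
  u3 <- c(rep(0, 10), rep(1, 10), rep(2, 10))
  v3 <- c(rep(0, 8), rep(1, 2), rep(1, 9), 2, rep(2, 10))
  cm3 <- estimate_confusion(u3, v3, K = 3)
  expect_equal(unname(cm3$p_v_given_u),
               rbind(c(0.8, 0.2, 0), c(0, 0.9, 0.1), c(0, 0, 1)))

  expect_error(estimate_confusion(integer(), integer()), "no complete")
  expect_error(estimate_confusion(c(0, 0), c(0, 1), K = 2,
                                  zero_rows = "strict"), "never observed")
  # uniform fill with degeneracy flag by default
  cmu <- estimate_confusion(c(0, 0), c(0, 1), K = 2)
  expect_equal(cmu$degenerate_rows, 1L)
  expect_equal(unname(cmu$p_v_given_u[2, ]), c(0.5, 0.5))
  # Laplace smoothing keeps rows proper
  cms <- estimate_confusion(c(0, 0), c(0, 1), K = 2, zero_rows = "smooth")
  expect_equal(rowSums(cms$p_v_given_u), c(`0` = 1, `1` = 1))
})

test_that("constant error rates are empirical conditional proportions", {
  r <- estimate_error_rates(c(0, 0, 1, 1), c(0, 0, 1, 1))
  expect_equal(c(r$fp, r$fn), c(0, 0))
  # constant classifier: everything scored correct
  r2 <- suppressWarnings(estimate_error_rates(c(0, 1, 0, 1), c(1, 1, 1, 1)))
  expect_equal(c(r2$fp, r2$fn), c(1, 0))
  expect_warning(estimate_error_rates(c(1, 1), c(1, 1)), "degenerate")
  # matches the dichotomous cells of the confusion matrix
  set.seed(41)
  d <- gen_cer_pairs(500, 0.2, 0.1)
  r3 <- estimate_error_rates(d$u, d$v)
  cm <- estimate_confusion(d$u, d$v, K = 2)
  expect_equal(r3$fp, cm$p_v_given_u["0", "1"])
  expect_equal(r3$fn, cm$p_v_given_u["1", "0"])
})

test_that("Monte-Carlo rate estimates recover the truth within binomial error", {
  set.seed(42)
  hits <- 0L
  n_rep <- 40
  for (i in seq_len(n_rep)) {
    d <- gen_cer_pairs(1000, 0.10, 0.05)
    r <- estimate_error_rates(d$u, d$v)
    se_fp <- sqrt(0.10 * 0.90 / sum(d$u == 0))
    se_fn <- sqrt(0.05 * 0.95 / sum(d$u == 1))
    ok <- abs(r$fp - 0.10) <= 3 * se_fp && abs(r$fn - 0.05) <= 3 * se_fn
    hits <- hits + ok
  }
  expect_gte(hits / n_rep, 0.95)
})

test_that("CER joint probabilities factor and normalize", {
  jm <- joint_cer(item_2pl(1, 0), error_rates(0.2, 0.1))
  # P(U=1, V=0 | theta=0) = 0.5 * 0.1
  expect_equal(joint_prob_cer(jm, 0, u = 1, v = 0), 0.05)
  th <- seq(-3, 3, by = 0.5)
  total <- Reduce(`+`, lapply(0:1, function(u) {
    Reduce(`+`, lapply(0:1, function(v) joint_prob_cer(jm, th, u, v)))
  }))
  expect_equal(total, rep(1, length(th)), tolerance = 1e-12)
  # identity confusion: mass only on the diagonal
  jid <- joint_cer(item_2pl(1, 0), confusion_matrix(diag(2)))
  expect_equal(joint_prob_cer(jid, 0.7, u = 1, v = 0), 0)
  expect_equal(joint_prob_cer(jid, 0.7, u = 1, v = 1),
               icc_2pl(0.7, item_2pl(1, 0)))
  expect_error(joint_prob_cer(jm, 0, u = 2, v = 0), "0..1")
})

test_that("marginal CER probabilities match the brute-force total-probability sum", {
  # worked constant-rate case
  jm <- joint_cer(item_2pl(1, 0), error_rates(0.2, 0.1))
  expect_equal(marginal_cer_prob(jm, 0, v = 1), 0.55)

  # identity confusion returns the manual model
  jid <- joint_cer(item_2pl(1.2, -0.3), confusion_matrix(diag(2)))
  th <- seq(-4, 4, by = 0.25)
  expect_equal(marginal_cer_prob(jid, th, v = 1),
               icc_2pl(th, item_2pl(1.2, -0.3)), tolerance = 1e-15)

  # random polytomous confusion matrices against the oracle
  set.seed(43)
  for (rep in 1:10) {
    Cm <- random_confusion(4)
    base <- random_confusion(1 * 4)  # unused draw keeps stream moving
    probs <- function(th) {
      raw <- cbind(1, exp(0.8 * th), exp(1.2 * th), exp(0.5 * th))
      raw / rowSums(raw)
    }
    man <- categorical_model(probs, K = 4)
    jp <- joint_cer(man, confusion_matrix(Cm))
    man_fun <- function(th, u) probs(th)[, u + 1]
    for (v in 0:3) {
      expect_equal(marginal_cer_prob(jp, th, v = v),
                   oracle_marginal(th, man_fun, Cm, v), tolerance = 1e-12)
    }
    # normalization of the marginal
    tot <- Reduce(`+`, lapply(0:3, function(v) marginal_cer_prob(jp, th, v)))
    expect_equal(tot, rep(1, length(th)), tolerance = 1e-12)
  }
})

test_that("the marginal of a 2PL under constant error rates is the printed 4PL", {
  m <- marginal_4pl(item_2pl(1, 0), error_rates(0.023, 0.005))
  expect_identical(m$c, 0.023)
  expect_identical(m$d, 0.995)

  # agrees with the law-of-total-probability marginal pointwise
  jm <- joint_cer(item_2pl(1, 0), error_rates(0.023, 0.005))
  th <- -3:3
  expect_equal(icc_4pl(th, m), marginal_cer_prob(jm, th, v = 1),
               tolerance = 1e-15)

  # zero rates: asymptotes collapse to the clamp width
  m0 <- marginal_4pl(item_2pl(1, 0), suppressWarnings(error_rates(0, 0)))
  expect_equal(icc_4pl(th, m0), icc_2pl(th, item_2pl(1, 0)), tolerance = 1e-5)

  expect_error(marginal_4pl(item_2pl(1, 0),
                            suppressWarnings(error_rates(0.7, 0.4))),
               "anti-informative")
})

test_that("the marginal of a 4PL composes asymptotes as the oracle dictates", {
  set.seed(44)
  th <- seq(-4, 4, by = 0.5)
  for (rep in 1:10) {
    cd <- sort(runif(2, 0, 1))
    fp <- runif(1, 0.01, 0.3)
    fn <- runif(1, 0.01, 0.3)
    it <- item_4pl(runif(1, 0.5, 2), rnorm(1), cd[1], cd[2])
    m <- marginal_4pl(it, error_rates(fp, fn))
    jm <- joint_cer(it, error_rates(fp, fn))
    expect_equal(icc_4pl(th, m), marginal_cer_prob(jm, th, v = 1),
                 tolerance = 1e-12)
  }
  # c = 0, d = 1 nests the 2PL composition
  m2 <- marginal_4pl(item_4pl(1, 0, 0, 1), error_rates(0.2, 0.1))
  m1 <- marginal_4pl(item_2pl(1, 0), error_rates(0.2, 0.1))
  expect_equal(c(m2$c, m2$d), c(m1$c, m1$d), tolerance = 1e-5)
  # zero rates leave the item untouched (up to the clamp)
  mi <- marginal_4pl(item_4pl(1, 0, 0.1, 0.9),
                     suppressWarnings(error_rates(0, 0)))
  expect_equal(c(mi$c, mi$d), c(0.1, 0.9), tolerance = 1e-5)
})

test_that("CER log-likelihood decomposes into manual and classifier terms", {
  # 5 persons x 2 items, hand-computable
  scores <- tibble::tibble(
    person_id = rep(paste0("p", 1:5), each = 2),
    item_id = rep(c("i1", "i2"), times = 5),
    manual = c(1, 0, 1, 1, 0, 0, 1, 0, 0, 1),
    automatic = c(1, 0, 0, 1, 0, 1, 1, 0, 0, 1)
  )
  thetas <- tibble::tibble(person_id = paste0("p", 1:5),
                           theta = c(-1, 0, 0.5, 1, -0.5))
  i1 <- item_2pl(1, 0); i2 <- item_2pl(1.5, 0.5)
  cm1 <- error_rates(0.2, 0.1); cm2 <- error_rates(0.1, 0.3)
  models <- list(i1 = joint_cer(i1, cm1), i2 = joint_cer(i2, cm2))
  ll <- loglik_cer(scores, thetas, models)

  # independent hand computation, observation by observation
  expected_man <- 0; expected_cls <- 0
  par <- list(i1 = c(1, 0, 0.2, 0.1), i2 = c(1.5, 0.5, 0.1, 0.3))
  for (k in seq_len(nrow(scores))) {
    p <- par[[scores$item_id[k]]]
    th <- thetas$theta[thetas$person_id == scores$person_id[k]]
    pU1 <- plogis(p[1] * (th - p[2]))
    uu <- scores$manual[k]; vv <- scores$automatic[k]
    expected_man <- expected_man + log(ifelse(uu == 1, pU1, 1 - pU1))
    pc <- if (uu == 0) ifelse(vv == 1, p[3], 1 - p[3])
          else ifelse(vv == 0, p[4], 1 - p[4])
    expected_cls <- expected_cls + log(pc)
  }
  expect_equal(ll$manual, expected_man, tolerance = 1e-12)
  expect_equal(ll$classifier, expected_cls, tolerance = 1e-12)
  expect_equal(ll$total, ll$manual + ll$classifier)  # exact additivity

  # classifier term is maximized by the MLE rates
  r_hat <- fit_cer(scores)
  mle_models <- list(i1 = joint_cer(i1, r_hat$rates$i1),
                     i2 = joint_cer(i2, r_hat$rates$i2))
  ll_mle <- loglik_cer(scores, thetas, mle_models)
  for (eps in c(-0.05, 0.05)) {
    pert <- list(
      i1 = joint_cer(i1, error_rates(min(max(r_hat$rates$i1$fp + eps, 0.01), 0.9),
                                     r_hat$rates$i1$fn)),
      i2 = mle_models$i2)
    ll_p <- loglik_cer(scores, thetas, pert)
    expect_gte(ll_mle$classifier, ll_p$classifier)
  }

  # identity confusion with U = V: classifier term is log(1) = 0
  sc_id <- scores; sc_id$automatic <- sc_id$manual
  id_models <- list(i1 = joint_cer(i1, confusion_matrix(diag(2))),
                    i2 = joint_cer(i2, confusion_matrix(diag(2))))
  ll_id <- loglik_cer(sc_id, thetas, id_models)
  expect_equal(ll_id$classifier, 0)
  expect_equal(ll_id$total, ll_id$manual)
})

test_that("CER person estimates stay on the manual-score scale", {
  cond <- simulation_condition(6, 150, "balanced", "CER", seed = 7)
  ds <- generate_dataset(cond)
  # with no classification error (V = U) and zero rates, the marginal model
  # reproduces the manual-model EAPs on the same grid and prior
  sc <- ds$scores
  sc$automatic <- sc$manual
  manual_est <- eap_abilities(sc, ds$items, score = "manual")
  models4 <- purrr::imap(items_from_table(ds$items), function(m, id) {
    marginal_4pl(m, suppressWarnings(error_rates(0, 0)))
  })
  auto_est <- eap_abilities(sc, models4, score = "automatic")
  expect_equal(auto_est$eap, manual_est$eap, tolerance = 1e-4)
})

test_that("fit_cer tidies into a per-item table with marginal parameters", {
  cond <- simulation_condition(5, 400, "balanced", "CER", seed = 99)
  ds <- generate_dataset(cond)
  fit <- fit_cer(ds$scores, items = ds$items)
  td <- tidy(fit)
  expect_equal(nrow(td), 5)
  expect_true(all(c("fp", "fn", "a", "b", "c", "d") %in% names(td)))
  expect_equal(td$c, td$fp, tolerance = 1e-12)
  expect_equal(td$d, 1 - td$fn, tolerance = 1e-12)
  gl <- glance(fit)
  expect_equal(gl$n_items, 5)
})
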