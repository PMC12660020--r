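test_that("logit error rates evaluate the closed-form logistic", {
  m <- logit_error_model(fp_intercept = qlogis(0.1), fp_slope = 0,
                         fn_intercept = 0, fn_slope = 1)
  th <- seq(-3, 3, by = 1)
  expect_equal(eps_fp(m, th), rep(0.1, length(th)))
  expect_equal(eps_fn(m, 0), 0.5)
  m2 <- logit_error_model(-2, 0.5, 0, 0)
  expect_equal(eps_fp(m2, 2), plogis(-1))
  expect_equal(eps_fp(m2, 2), 0.2689, tolerance = 1e-3)
  expect_error(logit_error_model(Inf, 0, 0, 0), "finite")
})

test_that("G4PL equals the two-term total-probability sum and nests the 4PL", {
  th <- seq(-4, 4, by = 0.25)
  # constant rates: identical to the marginal 4PL construction
  it <- item_2pl(1.1, 0.4)
  em_const <- logit_error_model(qlogis(0.2), 0, qlogis(0.1), 0)
  jv <- joint_ver(it, em_const)
  m4 <- marginal_4pl(it, error_rates(0.2, 0.1))
  expect_equal(g4pl_prob(jv, th), icc_4pl(th, m4), tolerance = 1e-12)

  # random coefficients against the brute-force sum over u
  set.seed(51)
  for (rep in 1:10) {
    a <- runif(1, 0.5, 2); b <- rnorm(1)
    co <- rnorm(4, sd = 1)
    jvr <- joint_ver(item_2pl(a, b), logit_error_model(co[1], co[2], co[3], co[4]))
    pU <- function(t) plogis(a * (t - b))
    brute <- plogis(co[1] + co[2] * th) * (1 - pU(th)) +
      (1 - plogis(co[3] + co[4] * th)) * pU(th)
    expect_equal(g4pl_prob(jvr, th), brute, tolerance = 1e-12)
    expect_true(all(g4pl_prob(jvr, th) > 0 & g4pl_prob(jvr, th) < 1))
  }

  # where both error probabilities vanish the G4PL meets the manual ICC
  em_dead <- logit_error_model(-30, 0, -30, 0)
  expect_equal(g4pl_prob(joint_ver(it, em_dead), 0), icc_2pl(0, it),
               tolerance = 1e-10)
})

test_that("G4PL information can exceed the 2PL's in part of the range", {
  # a strongly ability-dependent false-negative rate makes score disagreement
  # informative, lifting information above the error-free item locally
  it <- item_2pl(0.8, 0)
  jv <- joint_ver(it, logit_error_model(-6, 0, 1.5, -2.5))
  th <- seq(-4, 4, length.out = 161)
  i_g4 <- item_information(jv, th)
  i_2pl <- item_information(it, th)
  expect_true(any(i_g4 > i_2pl))
  expect_true(any(i_g4 < i_2pl))
})

test_that("intercept-only VER fit equals the CER rates on the logit scale", {
  set.seed(52)
  d <- gen_cer_pairs(600, 0.15, 0.08)
  fit <- fit_ver_item(d$u, d$v, d$theta, which = "none")
  r <- estimate_error_rates(d$u, d$v)
  expect_identical(fit$fp_intercept, qlogis(r$fp))
  expect_identical(fit$fn_intercept, qlogis(r$fn))
  expect_identical(c(fit$fp_slope, fit$fn_slope), c(0, 0))
  expect_false(fit$fp_fitted || fit$fn_fitted)
})

test_that("VER regression recovers generating coefficients within 3 SEs", {
  set.seed(53)
  n <- 5000
  theta <- rnorm(n)
  u <- rbinom(n, 1, plogis(theta))
  p_fn <- plogis(-2 + 0.8 * theta)
  v <- ifelse(u == 1, rbinom(n, 1, 1 - p_fn), 0L)
  fit <- fit_ver_item(u, v, theta, which = "fn")
  ref <- glm(I(v == 0)[u == 1] ~ theta[u == 1], family = binomial())
  se <- sqrt(diag(vcov(ref)))
  expect_lt(abs(fit$fn_intercept - (-2)), 3 * se[1])
  expect_lt(abs(fit$fn_slope - 0.8), 3 * se[2])
  # matches the glm fit exactly (same MLE)
  expect_equal(unname(coef(ref)), c(fit$fn_intercept, fit$fn_slope),
               tolerance = 1e-8)
  # the unrequested error type is intercept-only
  expect_false(fit$fp_fitted)
  expect_identical(fit$fp_slope, 0)
})

test_that("slopes shrink to zero when the generating rates are constant", {
  set.seed(54)
  slopes <- replicate(15, {
    d <- gen_cer_pairs(1e4, 0.15, 0.10)
    fit <- fit_ver_item(d$u, d$v, d$theta, which = "both")
    c(fit$fp_slope, fit$fn_slope)
  })
  # each fitted slope is near zero in at least 90% of the fits
  expect_gte(mean(abs(slopes) < 0.1), 0.9)
  expect_lt(mean(abs(slopes)), 0.06)
})

test_that("separation triggers the penalized fallback with finite output", {
  # deterministic error indicator: errors iff theta > 0 -> complete separation
  theta <- c(seq(-2, 2, length.out = 200), rep(0, 12))
  u <- c(rep(1, 200), rep(0, 12))
  v <- c(as.integer(theta[1:200] <= 0), rep(0, 12))
  expect_warning(
    fit <- fit_ver_item(u, v, theta, which = "fn"),
    "separation|penalty"
  )
  expect_true(is.finite(fit$fn_intercept) && is.finite(fit$fn_slope))
  expect_true(attr(fit, "penalized")[["fn"]])
})

test_that("sparse error types fall back to intercept-only below min_cases", {
  set.seed(55)
  theta <- rnorm(50)
  u <- c(rep(0, 5), rep(1, 45))
  v <- u
  v[1] <- 1
  v[c(10, 20, 30)] <- 0  # a few false negatives keep that fit regular
  expect_warning(fit <- fit_ver_item(u, v, theta, which = "both"),
                 "min_cases")
  expect_false(fit$fp_fitted)  # only 5 manually-incorrect responses
  expect_equal(fit$fp_intercept, qlogis(1 / 5))
})

test_that("fitting the VER model never mutates its inputs", {
  set.seed(56)
  d <- gen_cer_pairs(300, 0.2, 0.1)
  u0 <- d$u + 0L; v0 <- d$v + 0L; t0 <- d$theta + 0
  invisible(fit_ver_item(d$u, d$v, d$theta))
  expect_identical(d$u, u0)
  expect_identical(d$v, v0)
  expect_identical(d$theta, t0)
})

test_that("VER classifier log-likelihood is maximized at the fitted coefficients", {
  set.seed(57)
  n <- 800
  theta <- rnorm(n)
  u <- rbinom(n, 1, plogis(theta))
  efp <- plogis(-1.5 + 0.6 * theta)
  efn <- plogis(-2 - 0.4 * theta)
  v <- ifelse(u == 1, rbinom(n, 1, 1 - efn), rbinom(n, 1, efp))
  scores <- tibble::tibble(person_id = seq_len(n), item_id = "i1",
                           manual = u, automatic = v, theta_hat = theta)
  fit <- fit_ver_item(u, v, theta, which = "both")
  ll_hat <- loglik_ver(scores, list(i1 = fit))$loglik
  for (delta in list(c(0.1, 0, 0, 0), c(0, -0.1, 0, 0), c(0, 0, 0.15, 0),
                     c(0, 0, 0, 0.2))) {
    pert <- logit_error_model(fit$fp_intercept + delta[1],
                              fit$fp_slope + delta[2],
                              fit$fn_intercept + delta[3],
                              fit$fn_slope + delta[4])
    expect_gte(ll_hat, loglik_ver(scores, list(i1 = pert))$loglik)
  }
})

test_that("VER log-likelihood matches a hand-computed small fixture", {
  scores <- tibble::tibble(
    person_id = paste0("p", 1:5), item_id = "i1",
    manual = c(1, 1, 0, 0, 1),
    automatic = c(1, 0, 0, 1, 1),
    theta_hat = c(0.5, -0.5, 0, 1, -1)
  )
  m <- logit_error_model(-1, 0.5, -2, 0.3)
  ll <- loglik_ver(scores, list(i1 = m))
  hand <- log(1 - plogis(-2 + 0.3 * 0.5)) +  # u=1,v=1
    log(plogis(-2 + 0.3 * -0.5)) +           # u=1,v=0 (false negative)
    log(1 - plogis(-1 + 0.5 * 0)) +          # u=0,v=0
    log(plogis(-1 + 0.5 * 1)) +              # u=0,v=1 (false positive)
    log(1 - plogis(-2 + 0.3 * -1))           # u=1,v=1
  expect_equal(ll$loglik, hand, tolerance = 1e-12)
  expect_equal(ll$n_pairs, 5L)
})

test_that("VER-vs-CER likelihood gain under the null matches chi-square scale", {
  set.seed(58)
  gains <- replicate(40, {
    d <- gen_cer_pairs(1500, 0.15, 0.10)
    scores <- tibble::tibble(person_id = seq_along(d$u), item_id = "i1",
                             manual = d$u, automatic = d$v,
                             theta_hat = d$theta)
    f_ver <- fit_ver_item(d$u, d$v, d$theta, which = "both")
    f_cer <- fit_ver_item(d$u, d$v, d$theta, which = "none")
    2 * (loglik_ver(scores, list(i1 = f_ver))$loglik -
           loglik_ver(scores, list(i1 = f_cer))$loglik)
  })
  expect_true(all(gains >= -1e-8))
  # two extra slope parameters: 2*gain ~ chi^2_2, median about 1.39
  expect_gt(median(gains), 0.3)
  expect_lt(median(gains), 3.5)
})

test_that("fit_ver wires KS decisions and theta sources through per item", {
  cond <- simulation_condition(4, 300, "balanced", "VER", seed = 60)
  ds <- generate_dataset(cond)
  which_tab <- tibble::tibble(item_id = sprintf("i%03d", 1:4),
                              which = c("both", "fp", "fn", "none"))
  fit <- fit_ver(ds$scores, theta = ds$persons, which = which_tab)
  td <- tidy(fit)
  expect_equal(nrow(td), 8)
  slope_by_item <- split(td$slope_fitted, td$item_id)
  expect_equal(sum(slope_by_item$i001), 2)
  expect_equal(sum(slope_by_item$i004), 0)
  fp_row <- td[td$item_id == "i002" & td$error_type == "fp", ]
  expect_true(fp_row$slope_fitted)
  fn_row <- td[td$item_id == "i002" & td$error_type == "fn", ]
  expect_false(fn_row$slope_fitted)
  # internally computed reference EAP also works
  fit2 <- fit_ver(ds$scores, items = ds$items, which = "none")
  expect_s3_class(fit2, "ver_fit")
})
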