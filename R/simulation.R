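#' Calibrate the Beta distribution of classifier error rates
#'
#' The simulation draws *doubled* classification error rates from a Beta
#' distribution, so realized error rates (the halved draws) stay below 0.5.
#' The Beta parameters are found by two-dimensional root finding so that the
#' 2.5th and 97.5th percentiles of the *error rates* hit the requested
#' targets: `(0.05, 0.25)` in the balanced condition and `(0.1, 0.4)` for
#' the increased error type of the unbalanced conditions.
#'
#' @param pct_lo Target 2.5th percentile of the error-rate distribution.
#' @param pct_hi Target 97.5th percentile.
#' @param tol Maximum absolute percentile error accepted (default `1e-6`).
#' @return A `beta_calibration` object with elements `alpha`, `beta`,
#'   `pct_lo`, `pct_hi`, `achieved` (the fitted percentiles on the
#'   error-rate scale).
#' @export
#' @examples
#' cal <- calibrate_beta(0.05, 0.25)
#' qbeta(c(0.025, 0.975), cal$alpha, cal$beta) / 2
calibrate_beta <- function(pct_lo = 0.05, pct_hi = 0.25, tol = 1e-6) {
  if (!(0 < pct_lo && pct_lo < pct_hi)) {
    stop("need 0 < pct_lo < pct_hi", call. = FALSE)
  }
  t_lo <- 2 * pct_lo
  t_hi <- 2 * pct_hi
  if (t_hi >= 1) {
    stop("infeasible targets: doubled 97.5th percentile reaches 1",
         call. = FALSE)
  }
  resid <- function(logab) {
    a <- exp(logab[1]); b <- exp(logab[2])
    stats::qbeta(c(0.025, 0.975), a, b) - c(t_lo, t_hi)
  }
  # moment-flavored start: mean near the midpoint of the target interval
  m <- (t_lo + t_hi) / 2
  x <- log(c(2, 2 * (1 - m) / m))
  for (it in 1:100) {
    f <- resid(x)
    if (max(abs(f)) < tol / 10) break
    # numerical Jacobian
    h <- 1e-6
    J <- vapply(1:2, function(j) {
      xp <- x; xp[j] <- xp[j] + h
      (resid(xp) - f) / h
    }, numeric(2))
    step <- tryCatch(solve(J, f), error = function(e) f * 0.1)
    # damped update
    lambda <- 1
    repeat {
      xn <- x - lambda * step
      fn <- resid(xn)
      if (sum(fn^2) < sum(f^2) || lambda < 1e-6) break
      lambda <- lambda / 2
    }
    x <- xn
  }
  a <- exp(x[1]); b <- exp(x[2])
  achieved <- stats::qbeta(c(0.025, 0.975), a, b) / 2
  if (max(abs(achieved - c(pct_lo, pct_hi))) > tol) {
    stop("Beta calibration did not converge to the percentile targets",
         call. = FALSE)
  }
  structure(list(alpha = a, beta = b, pct_lo = pct_lo, pct_hi = pct_hi,
                 achieved = achieved),
            class = "beta_calibration")
}

#' @export
print.beta_calibration <- function(x, ...) {
  cat(sprintf(
    "<beta calibration> Beta(%.4f, %.4f) on doubled rates; error-rate 2.5/97.5 percentiles %.4f/%.4f\n",
    x$alpha, x$beta, x$achieved[1], x$achieved[2]))
  invisible(x)
}

#' Draw classifier error rates from a calibrated generator
#'
#' Error rates are halved draws from the calibrated Beta distribution of
#' doubled rates, hence bounded by 0.5.
#'
#' @param n Number of draws.
#' @param calibration A [calibrate_beta()] object.
#' @return Numeric vector of error rates in `(0, 0.5)`.
#' @export
draw_error_rates <- function(n, calibration = calibrate_beta()) {
  stats::rbeta(n, calibration$alpha, calibration$beta) / 2
}

#' Define a simulation condition
#'
#' One cell of the simulation design: numbers of items and persons, the
#' balance of the two classifier error types, and the generating model for
#' the automatic scores.
#'
#' @param n_items,n_persons Positive integers.
#' @param error_balance `"balanced"` (both error types from the
#'   0.05/0.25-calibrated generator), `"fp_increased"` (false positives from
#'   the 0.1/0.4 generator), or `"fn_increased"` (mirrored).
#' @param model_kind `"CER"` (constant rates) or `"VER"` (logit-linear
#'   ability-dependent rates).
#' @param seed Integer seed; fully determines the generated dataset.
#' @return A `simulation_condition` object.
#' @export
simulation_condition <- function(n_items = 30, n_persons = 2000,
                                 error_balance = c("balanced",
                                                   "fp_increased",
                                                   "fn_increased"),
                                 model_kind = c("CER", "VER"),
                                 seed = 1L) {
  error_balance <- match.arg(error_balance)
  model_kind <- match.arg(model_kind)
  stopifnot(n_items >= 1, n_persons >= 1)
  structure(
    list(n_items = as.integer(n_items), n_persons = as.integer(n_persons),
         error_balance = error_balance, model_kind = model_kind,
         seed = as.integer(seed)),
    class = "simulation_condition"
  )
}

# calibrations for the two generators, cached per session
the <- new.env(parent = emptyenv())
generator_calibrations <- function() {
  if (is.null(the$cal)) {
    the$cal <- list(
      balanced = calibrate_beta(0.05, 0.25),
      increased = calibrate_beta(0.10, 0.40)
    )
  }
  the$cal
}

#' Generate a synthetic joint manual/automatic score dataset
#'
#' Emulates the structure of an automatically scored assessment: abilities
#' and item difficulties are standard normal, discriminations log-normal
#' (`meanlog` 0, `sdlog` 0.25), manual scores follow the 2PL, and automatic
#' scores are produced by per-response error injection. Under `"CER"` each
#' item's false-positive and false-negative rates are independent halved
#' Beta draws from the calibrated generators; under `"VER"` the error-rate
#' intercepts are the logits of such draws and ability slopes are
#' `N(0, 0.5^2)`, with error probabilities evaluated at the person's true
#' ability.
#'
#' @param condition A [simulation_condition()].
#' @param slope_sd Standard deviation of the VER ability slopes.
#' @return A `sim_dataset` list: tibbles `persons` (`person_id`, `theta`),
#'   `items` (parameters plus true classifier parameters), `scores`
#'   (long `person_id`, `item_id`, `manual`, `automatic`), integer score
#'   matrices `U` and `V` (persons x items), and the `condition`.
#' @export
generate_dataset <- function(condition, slope_sd = 0.5) {
  stopifnot(inherits(condition, "simulation_condition"))
  cal <- generator_calibrations()
  fp_cal <- if (condition$error_balance == "fp_increased") cal$increased else cal$balanced
  fn_cal <- if (condition$error_balance == "fn_increased") cal$increased else cal$balanced
  n_i <- condition$n_items
  n_p <- condition$n_persons

  with_seed(condition$seed, {
    theta <- stats::rnorm(n_p)
    b <- stats::rnorm(n_i)
    a <- stats::rlnorm(n_i, meanlog = 0, sdlog = 0.25)
    fp_base <- draw_error_rates(n_i, fp_cal)
    fn_base <- draw_error_rates(n_i, fn_cal)

    if (condition$model_kind == "VER") {
      fp_int <- stats::qlogis(fp_base)
      fn_int <- stats::qlogis(fn_base)
      fp_slope <- stats::rnorm(n_i, sd = slope_sd)
      fn_slope <- stats::rnorm(n_i, sd = slope_sd)
    }

    # manual scores from the 2PL
    P <- stats::plogis(outer(theta, b, `-`) * rep(a, each = n_p))
    U <- matrix(stats::rbinom(n_p * n_i, 1, P), n_p, n_i)

    # automatic scores by error injection conditional on the manual score
    if (condition$model_kind == "CER") {
      EFP <- matrix(fp_base, n_p, n_i, byrow = TRUE)
      EFN <- matrix(fn_base, n_p, n_i, byrow = TRUE)
    } else {
      EFP <- stats::plogis(outer(theta, fp_slope) +
                             matrix(fp_int, n_p, n_i, byrow = TRUE))
      EFN <- stats::plogis(outer(theta, fn_slope) +
                             matrix(fn_int, n_p, n_i, byrow = TRUE))
    }
    p_correct_auto <- ifelse(U == 1, 1 - EFN, EFP)
    V <- matrix(stats::rbinom(n_p * n_i, 1, p_correct_auto), n_p, n_i)
  })

  person_id <- sprintf("p%05d", seq_len(n_p))
  item_id <- sprintf("i%03d", seq_len(n_i))
  items <- tibble::tibble(item_id = item_id, a = a, b = b)
  if (condition$model_kind == "CER") {
    items$fp <- fp_base
    items$fn <- fn_base
  } else {
    items$fp_intercept <- fp_int
    items$fp_slope <- fp_slope
    items$fn_intercept <- fn_int
    items$fn_slope <- fn_slope
  }
  scores <- tibble::tibble(
    person_id = rep(person_id, times = n_i),
    item_id = rep(item_id, each = n_p),
    manual = as.integer(U),
    automatic = as.integer(V)
  )
  dimnames(U) <- dimnames(V) <- list(person_id, item_id)
  structure(
    list(persons = tibble::tibble(person_id = person_id, theta = theta),
         items = items, scores = scores, U = U, V = V,
         condition = condition),
    class = "sim_dataset"
  )
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat(sprintf(
    "<simulated dataset> %d persons x %d items, %s errors, %s model, seed %d\n",
    x$condition$n_persons, x$condition$n_items, x$condition$error_balance,
    x$condition$model_kind, x$condition$seed))
  invisible(x)
}

#' Bias, RMSE and correlation of estimates against true values
#'
#' @param true,est Aligned numeric vectors.
#' @return A one-row tibble: `bias = mean(est - true)`,
#'   `rmse = sqrt(mean((est - true)^2))`, Pearson `r` (`NA` when either
#'   vector has zero variance), and `n`.
#' @export
performance_measures <- function(true, est) {
  stopifnot(length(true) == length(est))
  keep <- !(is.na(true) | is.na(est))
  true <- true[keep]; est <- est[keep]
  d <- est - true
  r <- if (length(true) > 1 && stats::sd(true) > 0 && stats::sd(est) > 0) {
    stats::cor(true, est)
  } else NA_real_
  tibble::tibble(bias = mean(d), rmse = sqrt(mean(d^2)), r = r,
                 n = length(true))
}

# fast EAP over a persons x items 0/1/NA score matrix
eap_from_matrix <- function(Y, models, grid, D = 1) {
  lp <- node_log_probs(models, grid, D = D)
  L <- matrix(0, nrow(Y), length(grid$nodes))
  for (i in seq_along(models)) {
    idx <- Y[, i] + 1L
    ok <- !is.na(idx)
    if (!all(ok)) {
      L[ok, ] <- L[ok, , drop = FALSE] + lp[[i]][idx[ok], , drop = FALSE]
    } else {
      L <- L + lp[[i]][idx, , drop = FALSE]
    }
  }
  posterior_summaries(L, grid)
}

clamp_rate <- function(x, floor = 1e-6) pmin(pmax(x, floor), 1 - floor)

# one replicate of the study for a given condition seed; returns a tibble of
# per-parameter-group performance rows
study_replicate <- function(condition, grid, D = 1) {
  ds <- generate_dataset(condition)
  n_i <- condition$n_items
  models_2pl <- purrr::map2(ds$items$a, ds$items$b, item_2pl)

  out <- list()
  theta <- ds$persons$theta

  est_manual <- eap_from_matrix(ds$U, models_2pl, grid, D = D)
  out$manual_2pl <- dplyr::mutate(performance_measures(theta, est_manual$eap),
                                  estimator = "manual_2pl",
                                  parameter_group = "ability")
  est_naive <- eap_from_matrix(ds$V, models_2pl, grid, D = D)
  out$naive_2pl <- dplyr::mutate(performance_measures(theta, est_naive$eap),
                                 estimator = "naive_2pl",
                                 parameter_group = "ability")

  # CER: estimate constant rates per item, build the marginal 4PL
  n0 <- colSums(ds$U == 0)
  n1 <- colSums(ds$U == 1)
  fp_hat <- ifelse(n0 > 0, colSums(ds$U == 0 & ds$V == 1) / n0, 0)
  fn_hat <- ifelse(n1 > 0, colSums(ds$U == 1 & ds$V == 0) / n1, 0)
  models_4pl <- purrr::map(seq_len(n_i), function(i) {
    marginal_4pl(models_2pl[[i]],
                 suppressWarnings(error_rates(fp_hat[i], fn_hat[i])))
  })
  est_cer <- eap_from_matrix(ds$V, models_4pl, grid, D = D)
  out$cer_ability <- dplyr::mutate(performance_measures(theta, est_cer$eap),
                                   estimator = "cer_4pl",
                                   parameter_group = "ability")

  # classifier intercepts on the logit scale, both error types pooled
  if (condition$model_kind == "CER") {
    true_int <- stats::qlogis(c(ds$items$fp, ds$items$fn))
  } else {
    true_int <- c(ds$items$fp_intercept, ds$items$fn_intercept)
  }
  est_int_cer <- stats::qlogis(clamp_rate(c(fp_hat, fn_hat)))
  out$cer_int <- dplyr::mutate(performance_measures(true_int, est_int_cer),
                               estimator = "cer_4pl",
                               parameter_group = "error_intercept")

  if (condition$model_kind == "VER") {
    theta_hat <- est_manual$eap
    ver_fits <- purrr::map(seq_len(n_i), function(i) {
      fit_ver_item(ds$U[, i], ds$V[, i], theta_hat, which = "both")
    })
    models_g4pl <- purrr::map(seq_len(n_i), function(i) {
      joint_ver(models_2pl[[i]], ver_fits[[i]])
    })
    est_ver <- eap_from_matrix(ds$V, models_g4pl, grid, D = D)
    out$ver_ability <- dplyr::mutate(performance_measures(theta, est_ver$eap),
                                     estimator = "ver_g4pl",
                                     parameter_group = "ability")
    est_int_ver <- c(purrr::map_dbl(ver_fits, "fp_intercept"),
                     purrr::map_dbl(ver_fits, "fn_intercept"))
    est_slp_ver <- c(purrr::map_dbl(ver_fits, "fp_slope"),
                     purrr::map_dbl(ver_fits, "fn_slope"))
    true_slp <- c(ds$items$fp_slope, ds$items$fn_slope)
    out$ver_int <- dplyr::mutate(performance_measures(true_int, est_int_ver),
                                 estimator = "ver_g4pl",
                                 parameter_group = "error_intercept")
    out$ver_slp <- dplyr::mutate(performance_measures(true_slp, est_slp_ver),
                                 estimator = "ver_g4pl",
                                 parameter_group = "error_slope")
  }
  dplyr::bind_rows(out)
}

#' Default simulation study design
#'
#' The full crossed design: four numbers of items by four sample sizes by
#' three error-balance conditions, for one generating model kind.
#'
#' @param model_kind `"CER"` or `"VER"`.
#' @param n_items,n_persons Design margins.
#' @return A tibble of conditions, one row per cell.
#' @export
default_study_design <- function(model_kind = "CER",
                                 n_items = c(10, 20, 30, 40),
                                 n_persons = c(500, 1000, 2000, 4000)) {
  tidyr::expand_grid(
    n_items = as.integer(n_items),
    n_persons = as.integer(n_persons),
    error_balance = c("balanced", "fp_increased", "fn_increased"),
    model_kind = model_kind
  )
}

#' Run the Monte-Carlo parameter-recovery study
#'
#' For every design cell and replicate, generates a dataset, computes four
#' ability estimators — the 2PL on manual scores (reference), the 2PL on
#' automatic scores (naive baseline that ignores classification error), the
#' marginal 4PL with CER rates estimated from the paired scores, and, for
#' VER-generated data, the G4PL with logit error models fitted at the
#' manual-score EAP — always with the true item parameters, and recovers the
#' classifier parameters. Bias, RMSE and Pearson correlation are computed
#' within each replicate and averaged across replicates with Monte-Carlo
#' standard errors.
#'
#' @param design A data frame of conditions (columns `n_items`, `n_persons`,
#'   `error_balance`, `model_kind`), e.g. [default_study_design()], or a
#'   list of [simulation_condition()] objects.
#' @param replicates Replicates per condition (default 100).
#' @param seed Master seed; per-replicate seeds are derived from it.
#' @param grid Quadrature grid; the default `N(0, 1)` prior matches the
#'   generating ability distribution.
#' @param D Logistic scaling constant.
#' @return A `study_summary` tibble: one row per condition x estimator x
#'   parameter group with columns `bias`, `rmse`, `r`, their Monte-Carlo
#'   standard errors `mc_se_*`, `n_replicates`, and `n_failed`.
#' @export
run_study <- function(design, replicates = 100, seed = 1L,
                      grid = quadrature_grid(), D = 1) {
  stopifnot(replicates >= 1)
  if (is.data.frame(design)) {
    conds <- purrr::pmap(design[, c("n_items", "n_persons", "error_balance",
                                    "model_kind")],
                         simulation_condition)
  } else {
    conds <- design
  }
  rep_seeds <- with_seed(seed, {
    matrix(sample.int(.Machine$integer.max - 1, length(conds) * replicates),
           nrow = length(conds))
  })

  res <- purrr::imap_dfr(conds, function(cond, ci) {
    rows <- purrr::map(seq_len(replicates), function(r) {
      cond$seed <- rep_seeds[ci, r]
      tryCatch(
        dplyr::mutate(study_replicate(cond, grid, D = D), replicate = r,
                      failed = FALSE),
        error = function(e) {
          tibble::tibble(replicate = r, failed = TRUE,
                         message = conditionMessage(e))
        }
      )
    })
    dplyr::mutate(dplyr::bind_rows(rows),
                  n_items = cond$n_items, n_persons = cond$n_persons,
                  error_balance = cond$error_balance,
                  model_kind = cond$model_kind)
  })

  failed <- dplyr::summarise(
    dplyr::group_by(res, .data$n_items, .data$n_persons, .data$error_balance,
                    .data$model_kind),
    n_failed = dplyr::n_distinct(.data$replicate[.data$failed]),
    .groups = "drop"
  )
  mc_se <- function(x) stats::sd(x) / sqrt(sum(!is.na(x)))
  summary <- dplyr::summarise(
    dplyr::group_by(
      dplyr::filter(res, !.data$failed),
      .data$n_items, .data$n_persons, .data$error_balance, .data$model_kind,
      .data$estimator, .data$parameter_group),
    mc_se_bias = mc_se(.data$bias), mc_se_rmse = mc_se(.data$rmse),
    mc_se_r = mc_se(.data$r),
    bias = mean(.data$bias), rmse = mean(.data$rmse),
    r = mean(.data$r, na.rm = TRUE),
    n_replicates = dplyr::n(), .groups = "drop"
  )
  out <- dplyr::left_join(
    summary, failed,
    by = c("n_items", "n_persons", "error_balance", "model_kind"))
  out <- dplyr::select(
    out, "n_items", "n_persons", "error_balance", "model_kind", "estimator",
    "parameter_group", "bias", "rmse", "r", "mc_se_bias", "mc_se_rmse",
    "mc_se_r", "n_replicates", "n_failed")
  class(out) <- c("study_summary", class(out))
  out
}
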