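#' Logit error-rate model for a dichotomous classifier
#'
#' Under the variable-error-rate (VER) model the two classification error
#' probabilities are logit-linear in ability:
#' \eqn{\varepsilon^{+}(\theta) = \mathrm{logistic}(\alpha^{+} + \beta^{+}\theta)}
#' (false positive) and
#' \eqn{\varepsilon^{-}(\theta) = \mathrm{logistic}(\alpha^{-} + \beta^{-}\theta)}
#' (false negative). A slope of zero reduces an error type to the constant
#' rate \eqn{\mathrm{logistic}(\alpha)}, i.e. the CER model on the logit
#' scale.
#'
#' @param fp_intercept,fp_slope Logit-scale coefficients of the
#'   false-positive model.
#' @param fn_intercept,fn_slope Coefficients of the false-negative model.
#' @param fp_fitted,fn_fitted Logical: whether the slope of each error type
#'   was actually fitted (as opposed to held at a constant rate).
#' @return A `logit_error_model` object.
#' @export
logit_error_model <- function(fp_intercept, fp_slope = 0,
                              fn_intercept, fn_slope = 0,
                              fp_fitted = fp_slope != 0,
                              fn_fitted = fn_slope != 0) {
  co <- c(fp_intercept, fp_slope, fn_intercept, fn_slope)
  if (any(!is.finite(co))) {
    stop("logit error model coefficients must be finite", call. = FALSE)
  }
  structure(
    list(fp_intercept = fp_intercept, fp_slope = fp_slope,
         fn_intercept = fn_intercept, fn_slope = fn_slope,
         fp_fitted = isTRUE(fp_fitted), fn_fitted = isTRUE(fn_fitted)),
    class = "logit_error_model"
  )
}

#' @export
print.logit_error_model <- function(x, ...) {
  cat(sprintf(
    "<logit error model> fp: logistic(%.3f %+.3f theta)%s, fn: logistic(%.3f %+.3f theta)%s\n",
    x$fp_intercept, x$fp_slope, if (x$fp_fitted) "" else " [constant]",
    x$fn_intercept, x$fn_slope, if (x$fn_fitted) "" else " [constant]"))
  invisible(x)
}

#' Ability-dependent classifier error rates
#'
#' Evaluate the false-positive and false-negative probabilities of a
#' [logit_error_model()] at given abilities.
#'
#' @param model A `logit_error_model`.
#' @param theta Ability values.
#' @return Probabilities in `(0, 1)` along `theta`.
#' @export
eps_fp <- function(model, theta) {
  stats::plogis(model$fp_intercept + model$fp_slope * theta)
}

#' @rdname eps_fp
#' @export
eps_fn <- function(model, theta) {
  stats::plogis(model$fn_intercept + model$fn_slope * theta)
}

#' Joint VER model for one dichotomous item
#'
#' @param manual_model An [item_2pl()] or [item_4pl()] manual-score model.
#' @param error_model A [logit_error_model()].
#' @return A `joint_ver` object, usable as a `response_model` for automatic
#'   scores (its [category_probs()] are the G4PL probabilities).
#' @export
joint_ver <- function(manual_model, error_model) {
  if (n_categories(manual_model) != 2L) {
    stop("the VER model is defined for dichotomous items only", call. = FALSE)
  }
  stopifnot(inherits(error_model, "logit_error_model"))
  structure(list(manual_model = manual_model, error_model = error_model),
            class = c("joint_ver", "response_model"))
}

#' Generalized 4PL (G4PL) probability of a correct automatic score
#'
#' Marginalizing the manual score out of the VER model yields
#' \deqn{P(V = 1 \mid \theta) = \varepsilon^{+}(\theta)\,(1 - P_U(\theta)) +
#'   (1 - \varepsilon^{-}(\theta))\,P_U(\theta),}
#' a 4PL-like curve whose asymptotes vary with ability. With constant error
#' rates it reduces exactly to the marginal 4PL.
#'
#' @param model A [joint_ver()] object.
#' @param theta Ability values.
#' @param D Logistic scaling constant.
#' @return Probabilities in `(0, 1)` along `theta`. Monotonicity in `theta`
#'   is not guaranteed: strongly ability-dependent error rates can bend the
#'   curve.
#' @export
g4pl_prob <- function(model, theta, D = 1) {
  pU <- prob_correct(model$manual_model, theta, D = D)
  eps_fp(model$error_model, theta) * (1 - pU) +
    (1 - eps_fn(model$error_model, theta)) * pU
}

#' @export
category_probs.joint_ver <- function(model, theta, D = 1, ...) {
  p <- g4pl_prob(model, theta, D = D)
  cbind(1 - p, p, deparse.level = 0)
}

#' @export
n_categories.joint_ver <- function(model) 2L

# logistic regression of a binary error indicator on theta with a
# weak-L2-penalty fallback for separation (penalty on the slope only)
fit_error_logit <- function(y, theta, lambda = 1e-4, max_abs_coef = 15) {
  fit <- suppressWarnings(
    stats::glm(y ~ theta, family = stats::binomial())
  )
  co <- stats::coef(fit)
  separated <- !fit$converged || any(abs(co) > max_abs_coef)
  if (!separated) {
    return(list(intercept = unname(co[1]), slope = unname(co[2]),
                penalized = FALSE))
  }
  warning("separation or nonconvergence in error-rate regression; ",
          "refitting with weak L2 penalty on the slope", call. = FALSE)
  co <- penalized_logit(y, theta, lambda = lambda)
  list(intercept = co[1], slope = co[2], penalized = TRUE)
}

# Newton iterations for logistic regression with ridge penalty on the slope;
# the intercept is unpenalized
penalized_logit <- function(y, theta, lambda = 1e-4, max_iter = 200,
                            tol = 1e-10) {
  X <- cbind(1, theta)
  beta <- c(stats::qlogis(min(max(mean(y), 1e-3), 1 - 1e-3)), 0)
  pen <- diag(c(0, lambda))
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    p <- stats::plogis(eta)
    w <- pmax(p * (1 - p), 1e-10)
    grad <- drop(crossprod(X, y - p)) - pen %*% beta
    H <- crossprod(X * w, X) + pen
    step <- solve(H, grad)
    beta <- beta + drop(step)
    if (max(abs(step)) < tol) break
  }
  unname(beta)
}

#' Fit the VER error model for one item
#'
#' Fixed-parameter linking: the supplied ability point estimates (typically
#' the manual-score EAP) are treated as known constants, so each error-type
#' model becomes a manifest logistic regression of the error indicator on
#' ability, fitted among the responses where that error can occur (false
#' positives among manually-incorrect responses, false negatives among
#' manually-correct ones). Error types not selected for a slope — or with
#' fewer than `min_cases` eligible responses — are fitted intercept-only,
#' which equals the CER rate on the logit scale. Inputs are never modified.
#'
#' @param u,v Paired dichotomous scores (manual, automatic); `NA` pairs are
#'   dropped together with their `theta_hat`.
#' @param theta_hat Ability point estimates aligned with `u`, `v`.
#' @param which Which error types receive an ability slope: `"both"`,
#'   `"fp"`, `"fn"`, or `"none"` (intercept-only throughout).
#' @param min_cases Minimum eligible responses per fitted error type
#'   (default 10); below it the fit falls back to intercept-only with a
#'   warning.
#' @param rate_floor Rates of exactly 0 or 1 have no finite logit; intercepts
#'   of intercept-only fits are clamped to `logit(rate_floor)` /
#'   `logit(1 - rate_floor)` in that case (default `1e-6`).
#' @return A [logit_error_model()] with attribute `"penalized"` flagging
#'   separation fallbacks per error type.
#' @export
fit_ver_item <- function(u, v, theta_hat,
                         which = c("both", "fp", "fn", "none"),
                         min_cases = 10, rate_floor = 1e-6) {
  which <- match.arg(which)
  keep <- !(is.na(u) | is.na(v) | is.na(theta_hat))
  u <- u[keep]; v <- v[keep]; theta_hat <- theta_hat[keep]
  if (any(!u %in% 0:1) || any(!v %in% 0:1)) {
    stop("scores must be dichotomous 0/1", call. = FALSE)
  }

  fit_type <- function(sel, err_ind, want_slope, label) {
    n <- sum(sel)
    if (n == 0) {
      warning("no eligible responses for ", label,
              " model; returning rate 0 intercept", call. = FALSE)
      return(list(intercept = stats::qlogis(rate_floor), slope = 0,
                  fitted = FALSE, penalized = FALSE))
    }
    y <- err_ind[sel]
    if (want_slope && n < min_cases) {
      warning("fewer than min_cases = ", min_cases, " responses for ",
              label, " model; falling back to intercept-only", call. = FALSE)
      want_slope <- FALSE
    }
    if (!want_slope) {
      r <- mean(y)
      r <- min(max(r, rate_floor), 1 - rate_floor)
      return(list(intercept = stats::qlogis(r), slope = 0,
                  fitted = FALSE, penalized = FALSE))
    }
    f <- fit_error_logit(y, theta_hat[sel])
    list(intercept = f$intercept, slope = f$slope, fitted = TRUE,
         penalized = f$penalized)
  }

  fp <- fit_type(u == 0, as.numeric(v == 1),
                 which %in% c("both", "fp"), "false-positive")
  fn <- fit_type(u == 1, as.numeric(v == 0),
                 which %in% c("both", "fn"), "false-negative")

  out <- logit_error_model(
    fp_intercept = fp$intercept, fp_slope = fp$slope,
    fn_intercept = fn$intercept, fn_slope = fn$slope,
    fp_fitted = fp$fitted, fn_fitted = fn$fitted
  )
  attr(out, "penalized") <- c(fp = fp$penalized, fn = fn$penalized)
  out
}

#' Fit the VER classifier model per item
#'
#' Data-frame-first wrapper over [fit_ver_item()]. The ability point
#' estimates can be given as a `theta_hat` column of `scores`, as a
#' per-person data frame, or computed from a manual-score item table via
#' [eap_abilities()].
#'
#' @param scores Long data frame with columns `person_id`, `item_id`,
#'   `manual`, `automatic`, and optionally `theta_hat`.
#' @param theta Optional data frame `(person_id, theta)` or
#'   `(person_id, eap)` with ability point estimates; overrides a
#'   `theta_hat` column.
#' @param items Optional manual-score item parameter table; when neither
#'   `theta` nor a `theta_hat` column is present, the reference EAP is
#'   computed from the manual scores with these items.
#' @param which Per-item specification of which error types get slopes:
#'   a single string (recycled) or a data frame `(item_id, which)`, e.g.
#'   from [ks_independence()] decisions.
#' @param grid Quadrature grid for the reference EAP when it is computed
#'   internally.
#' @inheritParams fit_ver_item
#' @return A `ver_fit` object; see [tidy.ver_fit()].
#' @export
fit_ver <- function(scores, theta = NULL, items = NULL, which = "both",
                    min_cases = 10, grid = quadrature_grid()) {
  scores <- tibble::as_tibble(scores)
  if (!is.null(theta)) {
    tcol <- if ("theta" %in% names(theta)) theta$theta else theta$eap
    scores$theta_hat <- tcol[match(scores$person_id, theta$person_id)]
  } else if (!"theta_hat" %in% names(scores)) {
    if (is.null(items)) {
      stop("supply `theta`, a `theta_hat` column, or `items` to compute ",
           "the reference EAP", call. = FALSE)
    }
    ref <- eap_abilities(scores, items, score = "manual", grid = grid)
    scores$theta_hat <- ref$eap[match(scores$person_id, ref$person_id)]
  }
  ids <- unique(as.character(scores$item_id))
  if (is.data.frame(which)) {
    wmap <- stats::setNames(as.character(which$which),
                            as.character(which$item_id))
  } else {
    wmap <- stats::setNames(rep(which, length(ids)), ids)
  }
  fits <- purrr::map(ids, function(id) {
    sel <- scores$item_id == id
    w <- wmap[[id]] %||% "both"
    fit_ver_item(scores$manual[sel], scores$automatic[sel],
                 scores$theta_hat[sel], which = w, min_cases = min_cases)
  })
  names(fits) <- ids
  structure(list(error_models = fits), class = "ver_fit")
}

#' @export
print.ver_fit <- function(x, ...) {
  cat(sprintf("<VER fit> %d items\n", length(x$error_models)))
  print(generics::tidy(x), n = Inf)
  invisible(x)
}

#' VER classifier log-likelihood
#'
#' Log-likelihood of the classifier part of the VER model at fixed ability
#' point estimates; the manual-score term is constant in the classifier
#' parameters and omitted. The total decomposes per item, and each item term
#' is maximized by the corresponding [fit_ver_item()] output.
#'
#' @param scores Long data frame with columns `person_id`, `item_id`,
#'   `manual`, `automatic`, plus `theta_hat` unless `theta` is supplied.
#' @param error_models Named list of [logit_error_model()] objects keyed by
#'   `item_id` (or a `ver_fit`).
#' @param theta Optional per-person data frame `(person_id, theta)`.
#' @return A tibble with per-item classifier log-likelihoods and the total as
#'   attribute-free rows: columns `item_id`, `loglik`, `n_pairs`.
#' @export
loglik_ver <- function(scores, error_models, theta = NULL) {
  if (inherits(error_models, "ver_fit")) error_models <- error_models$error_models
  scores <- tibble::as_tibble(scores)
  if (!is.null(theta)) {
    tcol <- if ("theta" %in% names(theta)) theta$theta else theta$eap
    scores$theta_hat <- tcol[match(scores$person_id, theta$person_id)]
  }
  keep <- !(is.na(scores$manual) | is.na(scores$automatic) |
              is.na(scores$theta_hat))
  scores <- scores[keep, , drop = FALSE]
  purrr::map_dfr(unique(as.character(scores$item_id)), function(id) {
    m <- error_models[[id]]
    if (is.null(m)) stop("no error model for item ", id, call. = FALSE)
    sel <- scores$item_id == id
    uu <- scores$manual[sel]
    vv <- scores$automatic[sel]
    th <- scores$theta_hat[sel]
    efp <- eps_fp(m, th)
    efn <- eps_fn(m, th)
    # P(V = v | U = u, theta)
    p <- ifelse(uu == 0, ifelse(vv == 1, efp, 1 - efp),
                ifelse(vv == 0, efn, 1 - efn))
    if (any(p == 0)) {
      warning("zero-probability classification for item ", id, call. = FALSE)
    }
    tibble::tibble(item_id = id, loglik = sum(log(p)), n_pairs = sum(sel))
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
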