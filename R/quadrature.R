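#' Quadrature grid for posterior ability computations
#'
#' Rectangle-rule quadrature: equally spaced nodes with a normal prior
#' evaluated at the nodes and normalized to sum to one.
#'
#' @param n_nodes Number of nodes (default 100).
#' @param lower,upper Grid interval endpoints (default `[-6, 6]`).
#' @param prior_mean,prior_sd Moments of the normal prior (default standard
#'   normal, matching the generating distribution of the simulation study; a
#'   flatter prior such as `prior_sd = 2` suits empirical-style estimation).
#' @return A `quadrature_grid` object with `nodes` and `weights`.
#' @export
#' @examples
#' g <- quadrature_grid()
#' sum(g$weights)  # 1
quadrature_grid <- function(n_nodes = 100, lower = -6, upper = 6,
                            prior_mean = 0, prior_sd = 1) {
  stopifnot(n_nodes >= 2, lower < upper, prior_sd > 0)
  nodes <- seq(lower, upper, length.out = n_nodes)
  w <- stats::dnorm(nodes, mean = prior_mean, sd = prior_sd)
  structure(
    list(nodes = nodes, weights = w / sum(w),
         prior_mean = prior_mean, prior_sd = prior_sd),
    class = "quadrature_grid"
  )
}

#' @export
print.quadrature_grid <- function(x, ...) {
  cat(sprintf("<quadrature grid> %d nodes on [%.3g, %.3g], prior N(%g, %g^2)\n",
              length(x$nodes), min(x$nodes), max(x$nodes),
              x$prior_mean, x$prior_sd))
  invisible(x)
}

# log category probabilities of each model at the grid nodes:
# list of K_i x n_nodes matrices
node_log_probs <- function(models, grid, D = 1) {
  lapply(models, function(m) {
    P <- category_probs(m, grid$nodes, D = D)
    t(log(P))
  })
}

# posterior summaries from a persons x nodes log-likelihood matrix
posterior_summaries <- function(loglik, grid) {
  lw <- sweep(loglik, 2, log(grid$weights), `+`)
  m <- apply(lw, 1, max)
  w <- exp(lw - m)
  tot <- rowSums(w)
  w <- w / tot
  eap <- drop(w %*% grid$nodes)
  second <- drop(w %*% grid$nodes^2)
  psd <- sqrt(pmax(second - eap^2, 0))
  list(eap = eap, psd = psd)
}

#' EAP ability estimate for a single response vector
#'
#' Computes the expected a posteriori (EAP) estimate and posterior standard
#' deviation of ability by rectangle-rule quadrature: the posterior over the
#' grid nodes is proportional to the prior weight times the likelihood of the
#' observed responses. Missing responses (`NA`) are skipped; if all responses
#' are missing, the prior mean and prior standard deviation (as represented
#' on the grid) are returned with `flagged = TRUE`.
#'
#' @param responses Integer score vector, one entry per model in `models`;
#'   each non-missing value must lie in `0 .. K_i - 1`.
#' @param models List of `response_model` objects.
#' @param grid A [quadrature_grid()].
#' @param D Logistic scaling constant.
#' @return A tibble with columns `eap`, `psd`, `n_items`, `flagged`.
#' @export
eap_estimate <- function(responses, models, grid = quadrature_grid(), D = 1) {
  stopifnot(length(responses) == length(models))
  lp <- node_log_probs(models, grid, D = D)
  ll <- rep(0, length(grid$nodes))
  n_obs <- 0L
  for (i in seq_along(models)) {
    v <- responses[[i]]
    if (is.na(v)) next
    K <- n_categories(models[[i]])
    if (v < 0 || v >= K) {
      stop("response ", v, " outside 0..", K - 1, " for item ", i,
           call. = FALSE)
    }
    ll <- ll + lp[[i]][v + 1L, ]
    n_obs <- n_obs + 1L
  }
  post <- posterior_summaries(matrix(ll, nrow = 1), grid)
  tibble::tibble(eap = post$eap, psd = post$psd, n_items = n_obs,
                 flagged = n_obs == 0L)
}

#' EAP ability estimates for a long score table
#'
#' Data-frame-first EAP estimation: takes a long score table with one row per
#' person-item observation and returns one row per person. This is the
#' workhorse used for manual-score reference estimation, the naive baseline
#' (manual-score model applied to automatic scores), and the marginal
#' 4PL/G4PL models for automatic scores.
#'
#' @param scores A data frame with columns `person_id`, `item_id`, and the
#'   score column named by `score`.
#' @param items Either an item parameter data frame (see [items_from_table()])
#'   or a named list of `response_model` objects keyed by `item_id`.
#' @param score Name of the score column to use (e.g. `"manual"` or
#'   `"automatic"`). Default `"manual"`.
#' @inheritParams eap_estimate
#' @return A tibble with columns `person_id`, `eap`, `psd`, `n_items`,
#'   `flagged`, one row per person present in `scores`.
#' @export
#' @examples
#' scores <- tibble::tibble(
#'   person_id = c(1, 1, 2, 2), item_id = c("i1", "i2", "i1", "i2"),
#'   manual = c(1L, 0L, 1L, 1L)
#' )
#' items <- tibble::tibble(item_id = c("i1", "i2"), a = c(1, 1.5),
#'                         b = c(0, -0.5))
#' eap_abilities(scores, items)
eap_abilities <- function(scores, items, score = "manual",
                          grid = quadrature_grid(), D = 1) {
  scores <- tibble::as_tibble(scores)
  if (!score %in% names(scores)) {
    stop("score column `", score, "` not found", call. = FALSE)
  }
  models <- if (is.data.frame(items)) items_from_table(items) else items
  if (is.null(names(models))) stop("`items` list must be named by item_id")

  persons <- unique(scores$person_id)
  pid <- match(scores$person_id, persons)
  v <- scores[[score]]

  lp <- node_log_probs(models, grid, D = D)
  n_nodes <- length(grid$nodes)
  L <- matrix(0, nrow = length(persons), ncol = n_nodes)

  item_idx <- match(as.character(scores$item_id), names(models))
  if (anyNA(item_idx)) {
    bad <- unique(scores$item_id[is.na(item_idx)])
    stop("items missing from model list: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  keep <- !is.na(v)
  for (i in seq_along(models)) {
    sel <- keep & item_idx == i
    if (!any(sel)) next
    K <- nrow(lp[[i]])
    vi <- v[sel]
    if (any(vi < 0 | vi >= K)) {
      stop("scores outside 0..", K - 1, " for item ", names(models)[i],
           call. = FALSE)
    }
    L[pid[sel], ] <- L[pid[sel], , drop = FALSE] + lp[[i]][vi + 1L, , drop = FALSE]
  }
  n_obs <- tabulate(pid[keep], nbins = length(persons))
  post <- posterior_summaries(L, grid)
  tibble::tibble(person_id = persons, eap = post$eap, psd = post$psd,
                 n_items = n_obs, flagged = n_obs == 0L)
}

#' EAP reliability
#'
#' Ratio of estimated true-score variance to total variance,
#' \eqn{\mathrm{Var}(\hat\theta_{EAP}) / (\mathrm{Var}(\hat\theta_{EAP}) +
#' \overline{\mathrm{PSD}^2})}.
#'
#' @param estimates A data frame with columns `eap` and `psd` (as returned by
#'   [eap_abilities()]), or a numeric vector of EAPs together with `psd`.
#' @param psd Posterior standard deviations when `estimates` is a vector.
#' @return Reliability in `[0, 1]`; `0` when the EAPs have zero variance.
#' @export
eap_reliability <- function(estimates, psd = NULL) {
  if (is.data.frame(estimates)) {
    eap <- estimates$eap
    psd <- estimates$psd
  } else {
    eap <- estimates
  }
  if (length(eap) < 2) stop("need at least 2 persons", call. = FALSE)
  v <- stats::var(eap)
  if (v == 0) return(0)
  v / (v + mean(psd^2))
}
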