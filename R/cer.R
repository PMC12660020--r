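#' Constant classifier error rates
#'
#' Container for the two error probabilities of a dichotomous classifier
#' under the constant-error-rate (CER) model: the false-positive rate
#' \eqn{\varepsilon^{+} = P(V = 1 \mid U = 0)} and the false-negative rate
#' \eqn{\varepsilon^{-} = P(V = 0 \mid U = 1)}, where the manual score `U`
#' is the ground truth reproduced imperfectly by the automatic score `V`.
#' Their complements are the classifier specificity and sensitivity.
#'
#' @param fp False-positive rate in `[0, 1]`.
#' @param fn False-negative rate in `[0, 1]`.
#' @param n_fp,n_fn Optional counts of manually-incorrect / manually-correct
#'   responses behind the estimates (carried for degeneracy reporting).
#' @param degenerate Logical flag set when an estimate rests on an empty cell.
#' @return An `error_rates` object.
#' @export
error_rates <- function(fp, fn, n_fp = NA_integer_, n_fn = NA_integer_,
                        degenerate = FALSE) {
  stopifnot(is.numeric(fp), is.numeric(fn), length(fp) == 1, length(fn) == 1)
  if (is.na(fp) || is.na(fn) || fp < 0 || fp > 1 || fn < 0 || fn > 1) {
    stop("error rates must lie in [0, 1]", call. = FALSE)
  }
  if (fp + fn >= 1) {
    warning("fp + fn >= 1: classifier is uninformative or anti-informative",
            call. = FALSE)
  }
  structure(
    list(fp = fp, fn = fn, n_fp = n_fp, n_fn = n_fn, degenerate = degenerate),
    class = "error_rates"
  )
}

#' @export
print.error_rates <- function(x, ...) {
  cat(sprintf("<error rates> fp = %.4f, fn = %.4f%s\n", x$fp, x$fn,
              if (isTRUE(x$degenerate)) " (degenerate)" else ""))
  invisible(x)
}

#' Classifier confusion matrix
#'
#' Row-stochastic `K x K` matrix with entry `(u, v)` equal to
#' `P(V = v | U = u)`; rows index the manual score, columns the automatic
#' score, both `0 .. K-1`.
#'
#' @param p_v_given_u Numeric `K x K` matrix with rows summing to one.
#' @param degenerate_rows Optional integer vector of 0-based manual-score
#'   categories whose row was unobserved (filled per the smoothing policy).
#' @return A `confusion_matrix` object.
#' @export
confusion_matrix <- function(p_v_given_u, degenerate_rows = integer()) {
  m <- as.matrix(p_v_given_u)
  if (nrow(m) != ncol(m)) stop("confusion matrix must be square", call. = FALSE)
  if (any(m < 0) || any(m > 1) ||
      any(abs(rowSums(m) - 1) > 1e-8)) {
    stop("confusion matrix rows must be probabilities summing to 1",
         call. = FALSE)
  }
  dimnames(m) <- list(u = 0:(nrow(m) - 1), v = 0:(ncol(m) - 1))
  structure(list(K = nrow(m), p_v_given_u = m,
                 degenerate_rows = as.integer(degenerate_rows)),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat(sprintf("<confusion matrix> K = %d categories, P(V = v | U = u):\n", x$K))
  print(round(x$p_v_given_u, 4))
  invisible(x)
}

#' Estimate a classifier confusion matrix from paired scores
#'
#' Maximum likelihood estimation under the CER model: entry `(u, v)` is the
#' proportion of responses manually scored `u` that the classifier scored
#' `v`. Manual-score categories never observed yield a degenerate row,
#' handled per `zero_rows`: a uniform row (flagged) by default, or Laplace
#' add-`alpha` smoothing of the whole table, or an error in `"strict"` mode.
#'
#' @param u,v Paired integer score vectors (manual, automatic) in `0 .. K-1`;
#'   pairs with any `NA` are dropped.
#' @param K Number of score categories; default inferred as
#'   `max(u, v) + 1`.
#' @param zero_rows One of `"uniform"`, `"smooth"`, `"strict"`.
#' @param alpha Laplace smoothing constant used when `zero_rows = "smooth"`.
#' @return A [confusion_matrix()].
#' @export
#' @examples
#' estimate_confusion(c(0, 0, 1, 1), c(0, 1, 1, 1), K = 2)
estimate_confusion <- function(u, v, K = NULL,
                               zero_rows = c("uniform", "smooth", "strict"),
                               alpha = 0.5) {
  zero_rows <- match.arg(zero_rows)
  keep <- !(is.na(u) | is.na(v))
  u <- u[keep]; v <- v[keep]
  if (length(u) == 0) stop("no complete score pairs", call. = FALSE)
  if (length(u) != length(v)) stop("u and v must be aligned", call. = FALSE)
  if (is.null(K)) K <- max(u, v) + 1L
  if (any(u < 0 | u >= K | v < 0 | v >= K)) {
    stop("scores outside 0..", K - 1, call. = FALSE)
  }
  counts <- table(factor(u, levels = 0:(K - 1)), factor(v, levels = 0:(K - 1)))
  counts <- matrix(as.numeric(counts), nrow = K)
  row_n <- rowSums(counts)
  empty <- which(row_n == 0)
  if (length(empty) > 0 && zero_rows == "strict") {
    stop("manual-score categories never observed: ",
         paste(empty - 1, collapse = ", "), call. = FALSE)
  }
  if (zero_rows == "smooth") {
    counts <- counts + alpha
    row_n <- rowSums(counts)
    empty <- integer()
  }
  P <- counts / ifelse(row_n > 0, row_n, 1)
  P[row_n == 0, ] <- 1 / K
  confusion_matrix(P, degenerate_rows = empty - 1L)
}

#' Estimate constant error rates from paired dichotomous scores
#'
#' The dichotomous specialization of [estimate_confusion()]: the
#' false-positive rate is the proportion of manually-incorrect responses the
#' classifier scored correct; the false-negative rate the proportion of
#' manually-correct responses scored incorrect. When a manual category is
#' unobserved, the corresponding rate is set to 0 and the estimate flagged
#' degenerate.
#'
#' @inheritParams estimate_confusion
#' @return An [error_rates()] object.
#' @export
estimate_error_rates <- function(u, v) {
  keep <- !(is.na(u) | is.na(v))
  u <- u[keep]; v <- v[keep]
  if (length(u) == 0) stop("no complete score pairs", call. = FALSE)
  if (any(!u %in% 0:1) || any(!v %in% 0:1)) {
    stop("scores must be dichotomous 0/1", call. = FALSE)
  }
  n0 <- sum(u == 0)
  n1 <- sum(u == 1)
  fp <- if (n0 > 0) sum(u == 0 & v == 1) / n0 else 0
  fn <- if (n1 > 0) sum(u == 1 & v == 0) / n1 else 0
  degenerate <- n0 == 0 || n1 == 0
  if (degenerate) {
    warning("a manual-score category is unobserved; rate estimate degenerate",
            call. = FALSE)
  }
  error_rates(fp, fn, n_fp = n0, n_fn = n1, degenerate = degenerate)
}

#' Joint CER model for one item
#'
#' Couples a manual-score response model with a classifier confusion matrix
#' (or constant dichotomous error rates) under the assumption that the
#' classification outcome is conditionally independent of ability given the
#' manual score.
#'
#' @param manual_model A `response_model` for the manual score.
#' @param confusion A [confusion_matrix()] or an [error_rates()] object
#'   (dichotomous shortcut).
#' @return A `joint_cer` object.
#' @export
joint_cer <- function(manual_model, confusion) {
  if (inherits(confusion, "error_rates")) {
    confusion <- confusion_matrix(matrix(
      c(1 - confusion$fp, confusion$fp,
        confusion$fn, 1 - confusion$fn),
      nrow = 2, byrow = TRUE))
  }
  if (n_categories(manual_model) != confusion$K) {
    stop("category counts of manual model and confusion matrix differ",
         call. = FALSE)
  }
  structure(list(manual_model = manual_model, confusion = confusion),
            class = "joint_cer")
}

#' Joint probability of a manual/automatic score pair under the CER model
#'
#' \eqn{P(U = u, V = v \mid \theta) = P(U = u \mid \theta)\, P(V = v \mid U = u)}.
#'
#' @param model A [joint_cer()] object.
#' @param theta Ability values.
#' @param u,v Scalar score categories in `0 .. K-1`.
#' @param D Logistic scaling constant.
#' @return Probabilities along `theta`.
#' @export
joint_prob_cer <- function(model, theta, u, v, D = 1) {
  K <- model$confusion$K
  if (!u %in% 0:(K - 1) || !v %in% 0:(K - 1)) {
    stop("u, v must lie in 0..", K - 1, call. = FALSE)
  }
  pu <- category_probs(model$manual_model, theta, D = D)[, u + 1L]
  pu * model$confusion$p_v_given_u[u + 1L, v + 1L]
}

#' Marginal probability of an automatic score under the CER model
#'
#' Law of total probability over the unobserved manual score:
#' \eqn{P(V = v \mid \theta) = \sum_u P(V = v \mid U = u)\, P(U = u \mid \theta)}.
#' This is the measurement model that permits ability estimation from
#' automatic scores alone.
#'
#' @inheritParams joint_prob_cer
#' @param v Scalar automatic-score category.
#' @return Probabilities along `theta`.
#' @export
marginal_cer_prob <- function(model, theta, v, D = 1) {
  K <- model$confusion$K
  if (!v %in% 0:(K - 1)) stop("v must lie in 0..", K - 1, call. = FALSE)
  PU <- category_probs(model$manual_model, theta, D = D)
  drop(PU %*% model$confusion$p_v_given_u[, v + 1L])
}

#' @export
category_probs.joint_cer <- function(model, theta, D = 1, ...) {
  PU <- category_probs(model$manual_model, theta, D = D)
  PU %*% model$confusion$p_v_given_u
}

#' @export
n_categories.joint_cer <- function(model) model$confusion$K

#' Marginal 4PL measurement model for automatic scores
#'
#' Under the CER model with a dichotomous manual-score model, the marginal
#' distribution of the automatic score is itself a four-parameter logistic
#' model. From a 2PL manual model the asymptotes are the error rates
#' directly: \eqn{c = \varepsilon^{+}} and \eqn{d = 1 - \varepsilon^{-}}.
#' From a 4PL manual model with asymptotes `(c, d)` they compose as
#' \eqn{c^{*} = \varepsilon^{+} + (1 - \varepsilon^{+} - \varepsilon^{-})\,c}
#' and
#' \eqn{d^{*} = \varepsilon^{+} + (1 - \varepsilon^{+} - \varepsilon^{-})\,d}.
#' Rates are clamped to `[1e-6, 1 - 1e-6]` before construction so that exact
#' 0/1 asymptotes cannot break downstream log-likelihoods; the supplied
#' `rates` object is not modified.
#'
#' @param item An [item_2pl()] or [item_4pl()] manual-score model.
#' @param rates An [error_rates()] object.
#' @return An [item_4pl()] equal pointwise to [marginal_cer_prob()].
#' @export
#' @examples
#' marginal_4pl(item_2pl(1, 0), error_rates(0.023, 0.005))
marginal_4pl <- function(item, rates) {
  stopifnot(inherits(rates, "error_rates"))
  eps <- 1e-6
  fp <- min(max(rates$fp, eps), 1 - eps)
  fn <- min(max(rates$fn, eps), 1 - eps)
  if (fp >= 1 - fn) {
    stop("fp >= 1 - fn: marginal ICC would be non-increasing; the ",
         "classifier is anti-informative", call. = FALSE)
  }
  if (inherits(item, "item_2pl")) {
    cc <- rates$fp
    dd <- 1 - rates$fn
  } else if (inherits(item, "item_4pl")) {
    slope_factor <- 1 - fp - fn
    cc <- fp + slope_factor * item$c
    dd <- fp + slope_factor * item$d
  } else {
    stop("`item` must be a 2PL or 4PL model", call. = FALSE)
  }
  cc <- min(max(cc, eps), 1 - eps)
  dd <- min(max(dd, eps), 1 - eps)
  if (cc >= dd) stop("degenerate marginal: c* >= d*", call. = FALSE)
  item_4pl(item$a, item$b, cc, dd, item_id = item$item_id)
}

#' CER log-likelihood of paired scores
#'
#' Total log-likelihood of manual and automatic scores under the CER model,
#' returned together with its exact decomposition into the manual-score IRT
#' term and the classifier term; the two sums involve disjoint parameters
#' and are maximized independently, which is why classifier rates can be
#' estimated from paired scores alone.
#'
#' @param scores Long data frame with columns `person_id`, `item_id`,
#'   `manual`, `automatic`; rows with a missing score are dropped pairwise.
#' @param thetas Data frame with columns `person_id`, `theta` (abilities at
#'   which the manual-model term is evaluated), or a numeric vector named by
#'   person id.
#' @param models Named list of `joint_cer` objects keyed by `item_id`.
#' @param D Logistic scaling constant.
#' @return A tibble with one row: `total`, `manual`, `classifier`, `n_pairs`.
#'   Zero-probability observations yield `-Inf` with a warning.
#' @export
loglik_cer <- function(scores, thetas, models, D = 1) {
  scores <- tibble::as_tibble(scores)
  keep <- !(is.na(scores$manual) | is.na(scores$automatic))
  scores <- scores[keep, , drop = FALSE]
  if (is.data.frame(thetas)) {
    th <- thetas$theta[match(scores$person_id, thetas$person_id)]
  } else {
    th <- thetas[match(as.character(scores$person_id), names(thetas))]
  }
  if (anyNA(th)) stop("missing theta for some persons", call. = FALSE)

  man <- 0
  cls <- 0
  for (id in unique(as.character(scores$item_id))) {
    m <- models[[id]]
    if (is.null(m)) stop("no model for item ", id, call. = FALSE)
    sel <- scores$item_id == id
    uu <- scores$manual[sel]
    vv <- scores$automatic[sel]
    PU <- category_probs(m$manual_model, th[sel], D = D)
    pm <- PU[cbind(seq_len(sum(sel)), uu + 1L)]
    pc <- m$confusion$p_v_given_u[cbind(uu + 1L, vv + 1L)]
    if (any(pm == 0) || any(pc == 0)) {
      warning("zero-probability observation for item ", id,
              "; log-likelihood is -Inf", call. = FALSE)
    }
    man <- man + sum(log(pm))
    cls <- cls + sum(log(pc))
  }
  tibble::tibble(total = man + cls, manual = man, classifier = cls,
                 n_pairs = nrow(scores))
}

#' Fit the CER classifier model per item
#'
#' Data-frame-first wrapper: estimates constant false-positive and
#' false-negative rates for every item of a long paired-score table and,
#' when an item parameter table is supplied, the implied marginal 4PL
#' asymptotes.
#'
#' @param scores Long data frame with columns `person_id`, `item_id`,
#'   `manual`, `automatic`.
#' @param items Optional item parameter data frame (columns `item_id`, `a`,
#'   `b`, optional `c`, `d`) used to attach marginal 4PL parameters.
#' @return A `cer_fit` object; see [tidy.cer_fit()] for the per-item table.
#' @export
fit_cer <- function(scores, items = NULL) {
  scores <- tibble::as_tibble(scores)
  ids <- unique(as.character(scores$item_id))
  rates <- purrr::map(ids, function(id) {
    sel <- scores$item_id == id
    suppressWarnings(
      estimate_error_rates(scores$manual[sel], scores$automatic[sel])
    )
  })
  names(rates) <- ids
  marginals <- NULL
  if (!is.null(items)) {
    models <- items_from_table(items)
    marginals <- purrr::imap(rates, function(r, id) {
      if (!id %in% names(models)) return(NULL)
      marginal_4pl(models[[id]], r)
    })
    marginals <- purrr::compact(marginals)
  }
  structure(list(rates = rates, marginals = marginals),
            class = "cer_fit")
}

#' @export
print.cer_fit <- function(x, ...) {
  cat(sprintf("<CER fit> %d items\n", length(x$rates)))
  print(generics::tidy(x), n = Inf)
  invisible(x)
}
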