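#' Define a two-parameter logistic (2PL) item
#'
#' The 2PL item characteristic curve (ICC) gives the probability of a correct
#' manual score as a logistic function of ability:
#' \eqn{P(U = 1 \mid \theta) = \mathrm{logistic}(D\,a\,(\theta - b))}.
#'
#' @param a Discrimination parameter, must be positive.
#' @param b Difficulty parameter on the logit (ability) scale.
#' @param item_id Optional item identifier carried through tabular output.
#'
#' @return An object of class `item_2pl` (also a `response_model`).
#' @seealso [item_4pl()], [icc_2pl()]
#' @export
#' @examples
#' it <- item_2pl(a = 1.2, b = -0.5)
#' icc_2pl(c(-1, 0, 1), it)
item_2pl <- function(a, b, item_id = NULL) {
  stopifnot(is.numeric(a), is.numeric(b), length(a) == 1, length(b) == 1)
  if (!is.finite(a) || a <= 0) {
    stop("discrimination `a` must be finite and > 0, got ", a, call. = FALSE)
  }
  if (!is.finite(b)) stop("difficulty `b` must be finite", call. = FALSE)
  structure(
    list(a = a, b = b, item_id = item_id),
    class = c("item_2pl", "response_model")
  )
}

#' Define a four-parameter logistic (4PL) item
#'
#' The 4PL adds a lower asymptote `c` ("guessing") and an upper asymptote `d`
#' ("slipping") to the 2PL:
#' \eqn{P(U = 1 \mid \theta) = c + (d - c)\,\mathrm{logistic}(D\,a\,(\theta - b))}.
#' In this package 4PL items arise chiefly as the marginal measurement model
#' for automatic scores under constant classifier error rates, where
#' `c` equals the false-positive rate and `d` one minus the false-negative
#' rate (see [marginal_4pl()]).
#'
#' @inheritParams item_2pl
#' @param c Lower asymptote, in `[0, 1)`.
#' @param d Upper asymptote, in `(0, 1]`; must exceed `c`.
#'
#' @return An object of class `item_4pl` (also a `response_model`).
#' @export
#' @examples
#' item_4pl(a = 1, b = 0, c = 0.023, d = 0.995)
item_4pl <- function(a, b, c = 0, d = 1, item_id = NULL) {
  stopifnot(is.numeric(c), is.numeric(d), length(c) == 1, length(d) == 1)
  if (!is.finite(a) || a <= 0) {
    stop("discrimination `a` must be finite and > 0, got ", a, call. = FALSE)
  }
  if (!is.finite(b)) stop("difficulty `b` must be finite", call. = FALSE)
  if (c < 0 || c >= 1 || d <= 0 || d > 1 || c >= d) {
    stop("asymptotes must satisfy 0 <= c < d <= 1, got c = ", c, ", d = ", d,
         call. = FALSE)
  }
  structure(
    list(a = a, b = b, c = c, d = d, item_id = item_id),
    class = c("item_4pl", "response_model")
  )
}

#' @export
print.item_2pl <- function(x, ...) {
  cat(sprintf("<2PL item%s> a = %.3f, b = %.3f\n",
              if (is.null(x$item_id)) "" else paste0(" ", x$item_id),
              x$a, x$b))
  invisible(x)
}

#' @export
print.item_4pl <- function(x, ...) {
  cat(sprintf("<4PL item%s> a = %.3f, b = %.3f, c = %.3f, d = %.3f\n",
              if (is.null(x$item_id)) "" else paste0(" ", x$item_id),
              x$a, x$b, x$c, x$d))
  invisible(x)
}

#' 2PL item characteristic curve
#'
#' @param theta Numeric vector of ability values; must be finite.
#' @param item An [item_2pl()] object.
#' @param D Logistic scaling constant. The default `1` keeps parameters on the
#'   pure logit metric; `1.702` approximates the normal-ogive metric.
#'
#' @return Probabilities in `(0, 1)`, same length as `theta`.
#' @export
icc_2pl <- function(theta, item, D = 1) {
  check_theta(theta)
  stats::plogis(D * item$a * (theta - item$b))
}

#' 4PL item characteristic curve
#'
#' @inheritParams icc_2pl
#' @param item An [item_4pl()] object.
#' @return Probabilities in `[c, d]`, same length as `theta`.
#' @export
icc_4pl <- function(theta, item, D = 1) {
  check_theta(theta)
  item$c + (item$d - item$c) * stats::plogis(D * item$a * (theta - item$b))
}

check_theta <- function(theta) {
  if (!is.numeric(theta) || anyNA(theta) || any(!is.finite(theta))) {
    stop("`theta` must be finite numeric", call. = FALSE)
  }
  invisible(theta)
}

#' Category probabilities of a response model
#'
#' Generic contract used by the EAP estimator: every response model maps an
#' ability vector to a matrix of category probabilities (rows = theta values,
#' columns = score categories `0 .. K-1`) that sum to one rowwise.
#'
#' @inheritParams icc_2pl
#' @param model A `response_model` object.
#' @param ... Passed to methods.
#' @return A `length(theta) x K` matrix of probabilities.
#' @export
category_probs <- function(model, theta, D = 1, ...) {
  UseMethod("category_probs")
}

#' @export
category_probs.item_2pl <- function(model, theta, D = 1, ...) {
  p <- icc_2pl(theta, model, D = D)
  cbind(1 - p, p, deparse.level = 0)
}

#' @export
category_probs.item_4pl <- function(model, theta, D = 1, ...) {
  p <- icc_4pl(theta, model, D = D)
  cbind(1 - p, p, deparse.level = 0)
}

#' Wrap an arbitrary probability function as a response model
#'
#' Mainly used for polytomous manual-score models entering the CER
#' marginalization, and in tests. `prob_fun(theta)` must return a
#' `length(theta) x K` matrix of category probabilities.
#'
#' @param prob_fun Function of a numeric `theta` vector.
#' @param K Number of score categories.
#' @param item_id Optional identifier.
#' @return A `categorical_model` response model.
#' @export
categorical_model <- function(prob_fun, K, item_id = NULL) {
  stopifnot(is.function(prob_fun), K >= 2)
  structure(
    list(prob_fun = prob_fun, K = K, item_id = item_id),
    class = c("categorical_model", "response_model")
  )
}

#' @export
category_probs.categorical_model <- function(model, theta, D = 1, ...) {
  P <- model$prob_fun(theta)
  if (!is.matrix(P)) P <- matrix(P, nrow = length(theta))
  if (ncol(P) != model$K) stop("prob_fun returned wrong category count")
  P
}

#' Number of score categories of a response model
#' @param model A `response_model`.
#' @return Integer category count `K`.
#' @export
n_categories <- function(model) UseMethod("n_categories")

#' @export
n_categories.item_2pl <- function(model) 2L
#' @export
n_categories.item_4pl <- function(model) 2L
#' @export
n_categories.categorical_model <- function(model) as.integer(model$K)

#' Probability of a correct score for a dichotomous response model
#'
#' @inheritParams category_probs
#' @return `P(score = 1 | theta)`, same length as `theta`.
#' @export
prob_correct <- function(model, theta, D = 1) {
  if (n_categories(model) != 2L) {
    stop("`prob_correct` requires a dichotomous model", call. = FALSE)
  }
  category_probs(model, theta, D = D)[, 2L]
}

#' Fisher item information
#'
#' For a dichotomous response model with ICC \eqn{P(\theta)}, the item
#' information is \eqn{I(\theta) = P'(\theta)^2 / [P(\theta)(1 - P(\theta))]}.
#' Analytic derivatives are used for 2PL and 4PL items; other response models
#' are differentiated by central differences (step `1e-4`).
#'
#' @inheritParams category_probs
#' @return Nonnegative information values, same length as `theta`.
#' @export
#' @examples
#' item_information(item_2pl(2, 0), 0)  # a^2 / 4 = 1
item_information <- function(model, theta, D = 1, ...) {
  UseMethod("item_information")
}

#' @export
item_information.item_2pl <- function(model, theta, D = 1, ...) {
  check_theta(theta)
  p <- stats::plogis(D * model$a * (theta - model$b))
  (D * model$a)^2 * p * (1 - p)
}

#' @export
item_information.item_4pl <- function(model, theta, D = 1, ...) {
  check_theta(theta)
  p2 <- stats::plogis(D * model$a * (theta - model$b))
  P <- model$c + (model$d - model$c) * p2
  dP <- (model$d - model$c) * D * model$a * p2 * (1 - p2)
  info_from_p(P, dP)
}

#' @export
item_information.default <- function(model, theta, D = 1, h = 1e-4, ...) {
  check_theta(theta)
  P <- prob_correct(model, theta, D = D)
  dP <- (prob_correct(model, theta + h, D = D) -
           prob_correct(model, theta - h, D = D)) / (2 * h)
  info_from_p(P, dP)
}

info_from_p <- function(P, dP) {
  denom <- P * (1 - P)
  out <- numeric(length(P))
  ok <- denom > .Machine$double.eps
  out[ok] <- dP[ok]^2 / denom[ok]
  if (any(!ok)) {
    warning("ICC at machine 0/1; information set to 0 there", call. = FALSE)
  }
  out
}

#' Test information and standard error of measurement
#'
#' Information is additive over items; the standard error of measurement is
#' its inverse square root, \eqn{\mathrm{SEM}(\theta) = 1/\sqrt{\sum_i I_i(\theta)}}.
#' Points of zero total information yield `Inf`.
#'
#' @param models Non-empty list of dichotomous response models.
#' @inheritParams icc_2pl
#' @return For `test_information()` the summed information; for `test_sem()`
#'   the standard error of measurement. Both are vectors along `theta`.
#' @export
test_information <- function(models, theta, D = 1) {
  if (length(models) == 0) stop("empty test: no items supplied", call. = FALSE)
  infos <- lapply(models, item_information, theta = theta, D = D)
  Reduce(`+`, infos)
}

#' @rdname test_information
#' @export
test_sem <- function(models, theta, D = 1) {
  total <- test_information(models, theta, D = D)
  ifelse(total > 0, 1 / sqrt(total), Inf)
}

#' Build response models from an item parameter table
#'
#' @param items A data frame with columns `item_id`, `a`, `b` and optionally
#'   `c`, `d` (missing or `NA` asymptotes default to 0 and 1, giving 2PL
#'   items).
#' @return Named list of `response_model` objects, one per row.
#' @export
items_from_table <- function(items) {
  items <- tibble::as_tibble(items)
  need <- c("item_id", "a", "b")
  if (!all(need %in% names(items))) {
    stop("item table needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(items$item_id)) stop("duplicate item_id in item table")
  cc <- if ("c" %in% names(items)) items$c else rep(NA_real_, nrow(items))
  dd <- if ("d" %in% names(items)) items$d else rep(NA_real_, nrow(items))
  cc[is.na(cc)] <- 0
  dd[is.na(dd)] <- 1
  mods <- purrr::pmap(
    list(items$a, items$b, cc, dd, as.character(items$item_id)),
    function(a, b, c, d, id) {
      if (c == 0 && d == 1) item_2pl(a, b, item_id = id)
      else item_4pl(a, b, c, d, item_id = id)
    }
  )
  stats::setNames(mods, as.character(items$item_id))
}

#' Read an item parameter table from a delimited text file
#'
#' Expects columns `item_id`, `a`, `b` and optional `c`, `d`.
#'
#' @param path File path.
#' @param delim Field delimiter, default tab.
#' @return A tibble of item parameters.
#' @export
read_item_table <- function(path, delim = "\t") {
  readr::read_delim(path, delim = delim, show_col_types = FALSE,
                    progress = FALSE)
}
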