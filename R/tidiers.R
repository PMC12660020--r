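#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a CER fit into a per-item table
#'
#' @param x A `cer_fit` from [fit_cer()].
#' @param ... Unused.
#' @return A tibble with one row per item: `item_id`, `fp`, `fn`,
#'   `n_incorrect`, `n_correct`, `degenerate`, and, when marginal models
#'   were constructed, the 4PL parameters `a`, `b`, `c`, `d`.
#' @method tidy cer_fit
#' @export
tidy.cer_fit <- function(x, ...) {
  out <- purrr::imap_dfr(x$rates, function(r, id) {
    tibble::tibble(item_id = id, fp = r$fp, fn = r$fn,
                   n_incorrect = r$n_fp, n_correct = r$n_fn,
                   degenerate = r$degenerate)
  })
  if (!is.null(x$marginals) && length(x$marginals) > 0) {
    mar <- purrr::imap_dfr(x$marginals, function(m, id) {
      tibble::tibble(item_id = id, a = m$a, b = m$b, c = m$c, d = m$d)
    })
    out <- dplyr::left_join(out, mar, by = "item_id")
  }
  out
}

#' @rdname tidy.cer_fit
#' @method glance cer_fit
#' @export
glance.cer_fit <- function(x, ...) {
  td <- tidy.cer_fit(x)
  tibble::tibble(
    n_items = nrow(td),
    mean_fp = mean(td$fp), mean_fn = mean(td$fn),
    n_degenerate = sum(td$degenerate)
  )
}

#' Tidy a VER fit into a per-item coefficient table
#'
#' @param x A `ver_fit` from [fit_ver()].
#' @param ... Unused.
#' @return A tibble with one row per item and error type: `item_id`,
#'   `error_type`, `intercept`, `slope`, `slope_fitted`.
#' @method tidy ver_fit
#' @export
tidy.ver_fit <- function(x, ...) {
  purrr::imap_dfr(x$error_models, function(m, id) {
    tibble::tibble(
      item_id = id,
      error_type = c("fp", "fn"),
      intercept = c(m$fp_intercept, m$fn_intercept),
      slope = c(m$fp_slope, m$fn_slope),
      slope_fitted = c(m$fp_fitted, m$fn_fitted)
    )
  })
}

#' @rdname tidy.ver_fit
#' @method glance ver_fit
#' @export
glance.ver_fit <- function(x, ...) {
  td <- tidy.ver_fit(x)
  tibble::tibble(
    n_items = length(x$error_models),
    n_slopes_fitted = sum(td$slope_fitted),
    mean_abs_slope = mean(abs(td$slope[td$slope_fitted]))
  )
}
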