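#' Read a long-format paired-score table
#'
#' The canonical input format: one row per person-item observation with
#' columns `person_id`, `item_id`, `manual`, `automatic` (and optionally
#' `theta_hat`). Long format accommodates incomplete designs naturally.
#'
#' @param path File path.
#' @param delim Field delimiter, default tab.
#' @param missing Strings mapped to missing scores (default `"NA"`).
#' @return A tibble; scores are integers with `NA` for missing.
#' @export
read_score_table <- function(path, delim = "\t", missing = "NA") {
  tab <- readr::read_delim(path, delim = delim, na = missing,
                           show_col_types = FALSE, progress = FALSE,
                           col_types = readr::cols(
                             person_id = readr::col_character(),
                             item_id = readr::col_character(),
                             .default = readr::col_guess()))
  need <- c("person_id", "item_id")
  if (!all(need %in% names(tab))) {
    stop("score table needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  key <- paste(tab$person_id, tab$item_id, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)][1]
    stop("duplicate (person_id, item_id) key: ",
         gsub("\r", ", ", dup), call. = FALSE)
  }
  for (col in intersect(c("manual", "automatic"), names(tab))) {
    x <- tab[[col]]
    if (is.character(x)) x <- suppressWarnings(as.numeric(x))
    if (any(!is.na(x) & (x < 0 | x != round(x)))) {
      stop("column `", col, "` must contain nonnegative integer scores",
           call. = FALSE)
    }
    tab[[col]] <- as.integer(x)
  }
  tab
}

#' @rdname read_score_table
#' @param table A score data frame to write.
#' @export
write_score_table <- function(table, path, delim = "\t") {
  readr::write_delim(tibble::as_tibble(table), path, delim = delim, na = "NA")
  invisible(path)
}

#' Convert a wide person-by-item score matrix to the long format
#'
#' @param mat Matrix with persons in rows and items in columns; dimnames are
#'   used as identifiers when present.
#' @param score Name of the score column in the output (default `"manual"`).
#' @return A long tibble `person_id`, `item_id`, `<score>`.
#' @export
scores_from_matrix <- function(mat, score = "manual") {
  pid <- rownames(mat) %||% sprintf("p%05d", seq_len(nrow(mat)))
  iid <- colnames(mat) %||% sprintf("i%03d", seq_len(ncol(mat)))
  out <- tibble::tibble(
    person_id = rep(pid, times = ncol(mat)),
    item_id = rep(iid, each = nrow(mat)),
    value = as.integer(mat)
  )
  names(out)[3] <- score
  out
}

#' Serialize and restore a model bundle
#'
#' A model bundle ties item parameters, per-item classifier error models and
#' the estimation configuration (quadrature grid, prior, logistic scaling)
#' into one JSON document that round-trips losslessly.
#'
#' @param items Item parameter data frame (`item_id`, `a`, `b`, optional
#'   `c`, `d`).
#' @param error_models Named list keyed by `item_id`; each element an
#'   [error_rates()], [confusion_matrix()] or [logit_error_model()].
#' @param grid A [quadrature_grid()].
#' @param D Logistic scaling constant.
#' @param path Output / input file path.
#' @return `write_model_bundle()` returns `path` invisibly;
#'   `read_model_bundle()` returns a list with `items`, `error_models`,
#'   `grid`, `D`.
#' @export
write_model_bundle <- function(path, items, error_models = NULL,
                               grid = quadrature_grid(), D = 1) {
  ser_em <- function(m) {
    if (inherits(m, "error_rates")) {
      list(type = "error_rates", fp = m$fp, fn = m$fn)
    } else if (inherits(m, "confusion_matrix")) {
      list(type = "confusion_matrix",
           p_v_given_u = unname(m$p_v_given_u))
    } else if (inherits(m, "logit_error_model")) {
      list(type = "logit_error_model",
           fp_intercept = m$fp_intercept, fp_slope = m$fp_slope,
           fn_intercept = m$fn_intercept, fn_slope = m$fn_slope,
           fp_fitted = m$fp_fitted, fn_fitted = m$fn_fitted)
    } else stop("unsupported error model class", call. = FALSE)
  }
  doc <- list(
    items = tibble::as_tibble(items),
    error_models = if (is.null(error_models)) NULL else
      purrr::map(error_models, ser_em),
    config = list(
      n_nodes = length(grid$nodes), lower = min(grid$nodes),
      upper = max(grid$nodes), prior_mean = grid$prior_mean,
      prior_sd = grid$prior_sd, scaling_D = D
    )
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_model_bundle
#' @export
read_model_bundle <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = TRUE,
                             simplifyMatrix = TRUE)
  cfg <- doc$config
  grid <- quadrature_grid(n_nodes = cfg$n_nodes, lower = cfg$lower,
                          upper = cfg$upper, prior_mean = cfg$prior_mean,
                          prior_sd = cfg$prior_sd)
  ems <- NULL
  if (!is.null(doc$error_models) && length(doc$error_models) > 0) {
    ems <- purrr::map(doc$error_models, function(m) {
      switch(m$type,
        error_rates = suppressWarnings(error_rates(m$fp, m$fn)),
        confusion_matrix = confusion_matrix(m$p_v_given_u),
        logit_error_model = logit_error_model(
          fp_intercept = m$fp_intercept, fp_slope = m$fp_slope,
          fn_intercept = m$fn_intercept, fn_slope = m$fn_slope,
          fp_fitted = m$fp_fitted, fn_fitted = m$fn_fitted),
        stop("unknown error model type: ", m$type, call. = FALSE)
      )
    })
  }
  list(items = tibble::as_tibble(doc$items), error_models = ems,
       grid = grid, D = cfg$scaling_D)
}

#' ICC, information and SEM curves over an ability grid
#'
#' Tabulates, for each item, the manual-score 2PL curve alongside the
#' marginal model for automatic scores (4PL under constant error rates,
#' G4PL under a logit error model), giving the model-implied effect of
#' automatic scoring on item functioning; the test-level standard error of
#' measurement is appended per model as a pseudo-item `"_test_"` row set.
#'
#' @param items Item parameter data frame for the manual-score model.
#' @param error_models Optional named list (by `item_id`) of
#'   [error_rates()] or [logit_error_model()] objects; items present get
#'   marginal-model curves.
#' @param theta Ability grid (default 121 points on `[-6, 6]`).
#' @param D Logistic scaling constant.
#' @return A long tibble: `item_id`, `model` (`"manual"` or `"marginal"`),
#'   `theta`, `icc`, `info`, plus `sem` rows with `item_id = "_test_"`.
#' @export
curve_table <- function(items, error_models = NULL,
                        theta = seq(-6, 6, length.out = 121), D = 1) {
  manual <- items_from_table(items)
  rows <- list()
  marg <- list()
  for (id in names(manual)) {
    m <- manual[[id]]
    rows[[length(rows) + 1]] <- tibble::tibble(
      item_id = id, model = "manual", theta = theta,
      icc = prob_correct(m, theta, D = D),
      info = item_information(m, theta, D = D))
    em <- error_models[[id]]
    if (!is.null(em)) {
      mm <- if (inherits(em, "logit_error_model")) {
        joint_ver(m, em)
      } else {
        marginal_4pl(m, em)
      }
      marg[[id]] <- mm
      rows[[length(rows) + 1]] <- tibble::tibble(
        item_id = id, model = "marginal", theta = theta,
        icc = prob_correct(mm, theta, D = D),
        info = item_information(mm, theta, D = D))
    }
  }
  out <- dplyr::bind_rows(rows)
  sem <- tibble::tibble(
    item_id = "_test_", model = "manual", theta = theta,
    icc = NA_real_, info = NA_real_,
    sem = test_sem(manual, theta, D = D))
  out$sem <- NA_real_
  if (length(marg) > 0) {
    sem <- dplyr::bind_rows(sem, tibble::tibble(
      item_id = "_test_", model = "marginal", theta = theta,
      icc = NA_real_, info = NA_real_,
      sem = test_sem(marg, theta, D = D)))
  }
  dplyr::bind_rows(out, sem)
}
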