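#' Split abilities by manual/automatic score cell
#'
#' Partitions ability point estimates into the four subsamples
#' \eqn{\Theta^{(uv)}}, `(u, v)` in `{0,1}^2`: test takers whose response was
#' scored `u` by the human rater and `v` by the classifier. Under constant
#' error rates each row split (`u` fixed) is purely random with respect to
#' ability, which is the null hypothesis of the conditional-independence
#' test.
#'
#' @param theta_hat Ability point estimates.
#' @param u,v Paired dichotomous scores aligned with `theta_hat`; incomplete
#'   triples are dropped.
#' @return A `cell_split`: named list `theta_00`, `theta_01`, `theta_10`,
#'   `theta_11` with attribute `n` (total complete triples).
#' @export
split_cells <- function(theta_hat, u, v) {
  keep <- !(is.na(theta_hat) | is.na(u) | is.na(v))
  theta_hat <- theta_hat[keep]; u <- u[keep]; v <- v[keep]
  if (any(!u %in% 0:1) || any(!v %in% 0:1)) {
    stop("scores must be dichotomous 0/1", call. = FALSE)
  }
  out <- list(
    theta_00 = theta_hat[u == 0 & v == 0],
    theta_01 = theta_hat[u == 0 & v == 1],
    theta_10 = theta_hat[u == 1 & v == 0],
    theta_11 = theta_hat[u == 1 & v == 1]
  )
  attr(out, "n") <- length(theta_hat)
  class(out) <- "cell_split"
  out
}

# two-sample KS; asymptotic p by default. Ability point estimates from
# identical response patterns coincide, so ties are expected; the tie warning
# from ks.test is muffled (the D statistic itself is tie-tolerant).
ks_two_sample <- function(x, y, exact = FALSE) {
  res <- suppressWarnings(stats::ks.test(x, y, exact = if (exact) TRUE else FALSE))
  list(statistic = unname(res$statistic), p.value = res$p.value)
}

#' Kolmogorov-Smirnov test of conditional independence for one item
#'
#' Tests, separately for each error type, whether the classification outcome
#' is independent of ability given the manual score: the false-positive test
#' compares \eqn{\Theta^{(00)}} with \eqn{\Theta^{(01)}} and the
#' false-negative test compares \eqn{\Theta^{(11)}} with \eqn{\Theta^{(10)}},
#' each by a two-sample Kolmogorov-Smirnov test. A Bonferroni correction
#' holds the cumulative item-level type-I error at `alpha` across the two
#' tests, so each is evaluated at `alpha / 2`. An empty subsample renders
#' that error type untestable (reported `NA`, not rejected).
#'
#' @inheritParams split_cells
#' @param alpha Item-level significance level (default 0.05).
#' @param exact Use the exact two-sample KS p-value (small samples, no ties);
#'   default asymptotic.
#' @return A tibble with one row per error type: `error_type`, `statistic`,
#'   `p_value`, `n_ok`, `n_err`, `testable`, `reject`, `alpha_adjusted`.
#' @export
ks_independence_test <- function(theta_hat, u, v, alpha = 0.05,
                                 exact = FALSE) {
  cells <- split_cells(theta_hat, u, v)
  a2 <- alpha / 2
  one <- function(ok, err, type) {
    if (length(ok) == 0 || length(err) == 0) {
      return(tibble::tibble(
        error_type = type, statistic = NA_real_, p_value = NA_real_,
        n_ok = length(ok), n_err = length(err),
        testable = FALSE, reject = FALSE, alpha_adjusted = a2))
    }
    res <- ks_two_sample(ok, err, exact = exact)
    tibble::tibble(
      error_type = type, statistic = res$statistic, p_value = res$p.value,
      n_ok = length(ok), n_err = length(err),
      testable = TRUE, reject = res$p.value < a2, alpha_adjusted = a2)
  }
  dplyr::bind_rows(
    one(cells$theta_00, cells$theta_01, "fp"),
    one(cells$theta_11, cells$theta_10, "fn")
  )
}

#' Per-item conditional-independence screening for a score table
#'
#' Runs [ks_independence_test()] for every item of a long paired-score table
#' and derives the error-model recommendation consumed by [fit_ver()]: an
#' error type whose constant-rate null is rejected gets an ability slope.
#'
#' @param scores Long data frame with `person_id`, `item_id`, `manual`,
#'   `automatic` and a `theta_hat` column, unless `theta` is given.
#' @param theta Optional per-person data frame `(person_id, theta)` or the
#'   output of [eap_abilities()].
#' @inheritParams ks_independence_test
#' @return A tibble with one row per item: KS statistics and p-values per
#'   error type (`fp_D`, `fp_p`, `fn_D`, `fn_p`), decisions (`decision_fp`,
#'   `decision_fn`), and the `which` recommendation (`"both"`, `"fp"`,
#'   `"fn"`, `"none"`).
#' @export
ks_independence <- function(scores, theta = NULL, alpha = 0.05,
                            exact = FALSE) {
  scores <- tibble::as_tibble(scores)
  if (!is.null(theta)) {
    tcol <- if ("theta" %in% names(theta)) theta$theta else theta$eap
    scores$theta_hat <- tcol[match(scores$person_id, theta$person_id)]
  }
  if (!"theta_hat" %in% names(scores)) {
    stop("need a `theta_hat` column or `theta` data frame", call. = FALSE)
  }
  purrr::map_dfr(unique(as.character(scores$item_id)), function(id) {
    sel <- scores$item_id == id
    res <- ks_independence_test(scores$theta_hat[sel], scores$manual[sel],
                                scores$automatic[sel], alpha = alpha,
                                exact = exact)
    fp <- res[res$error_type == "fp", ]
    fn <- res[res$error_type == "fn", ]
    tibble::tibble(
      item_id = id,
      fp_D = fp$statistic, fp_p = fp$p_value,
      fn_D = fn$statistic, fn_p = fn$p_value,
      decision_fp = fp$reject, decision_fn = fn$reject,
      which = dplyr::case_when(
        fp$reject & fn$reject ~ "both",
        fp$reject ~ "fp",
        fn$reject ~ "fn",
        TRUE ~ "none"
      )
    )
  })
}

#' Agreement statistics between manual and automatic scores
#'
#' Cohen's kappa plus the binary classification summary used throughout the
#' CER model: false-positive and false-negative rates, sensitivity,
#' specificity, accuracy. Kappa is the chance-corrected agreement
#' \eqn{(p_o - p_e) / (1 - p_e)}; it is undefined (reported `NA`) when
#' either score uses a single category.
#'
#' @param u,v Paired dichotomous scores; incomplete pairs dropped.
#' @return A one-row tibble with columns `kappa`, `fp_rate`, `fn_rate`,
#'   `sensitivity`, `specificity`, `accuracy`, `n`.
#' @export
#' @examples
#' agreement_stats(c(0, 0, 1, 1), c(0, 1, 1, 1))
agreement_stats <- function(u, v) {
  keep <- !(is.na(u) | is.na(v))
  u <- u[keep]; v <- v[keep]
  if (any(!u %in% 0:1) || any(!v %in% 0:1)) {
    stop("scores must be dichotomous 0/1", call. = FALSE)
  }
  n <- length(u)
  if (n == 0) stop("no complete score pairs", call. = FALSE)
  po <- mean(u == v)
  pu1 <- mean(u == 1); pv1 <- mean(v == 1)
  pe <- pu1 * pv1 + (1 - pu1) * (1 - pv1)
  kappa <- if (pu1 %in% c(0, 1) || pv1 %in% c(0, 1) || pe == 1) {
    NA_real_
  } else {
    (po - pe) / (1 - pe)
  }
  n0 <- sum(u == 0); n1 <- sum(u == 1)
  fp <- if (n0 > 0) sum(u == 0 & v == 1) / n0 else NA_real_
  fn <- if (n1 > 0) sum(u == 1 & v == 0) / n1 else NA_real_
  tibble::tibble(
    kappa = kappa, fp_rate = fp, fn_rate = fn,
    sensitivity = if (is.na(fn)) NA_real_ else 1 - fn,
    specificity = if (is.na(fp)) NA_real_ else 1 - fp,
    accuracy = po, n = n
  )
}

#' Compare two sets of ability estimates
#'
#' Pearson correlation plus the mean bias of `alt` relative to `ref` with a
#' normal-approximation 95% confidence interval for the paired mean
#' difference.
#'
#' @param ref,alt Aligned numeric ability vectors (reference first), or data
#'   frames with `person_id` and `eap` columns, matched on `person_id`.
#' @return A one-row tibble: `pearson_r`, `mean_bias`, `bias_ci_lower`,
#'   `bias_ci_upper`, `n`.
#' @export
compare_estimates <- function(ref, alt) {
  if (is.data.frame(ref)) {
    common <- intersect(ref$person_id, alt$person_id)
    r0 <- ref$eap[match(common, ref$person_id)]
    a0 <- alt$eap[match(common, alt$person_id)]
    ref <- r0; alt <- a0
  }
  keep <- !(is.na(ref) | is.na(alt))
  ref <- ref[keep]; alt <- alt[keep]
  n <- length(ref)
  if (n < 3) stop("need at least 3 aligned pairs", call. = FALSE)
  d <- alt - ref
  bias <- mean(d)
  se <- stats::sd(d) / sqrt(n)
  r <- if (stats::sd(ref) == 0 || stats::sd(alt) == 0) {
    NA_real_
  } else {
    stats::cor(ref, alt)
  }
  tibble::tibble(
    pearson_r = r, mean_bias = bias,
    bias_ci_lower = bias - 1.96 * se,
    bias_ci_upper = bias + 1.96 * se,
    n = n
  )
}

#' Per-item train/test split of a long score table
#'
#' Randomly assigns, within each item, a `fraction` of that item's observed
#' responses to the training split and the rest to the test split. The split
#' is reproducible under `seed`, disjoint, and exhaustive.
#'
#' @param scores Long score data frame with an `item_id` column.
#' @param fraction Training fraction in `(0, 1)`, default 0.9.
#' @param seed Integer seed.
#' @return A list with tibbles `train` and `test`.
#' @export
train_test_split <- function(scores, fraction = 0.9, seed = 1L) {
  stopifnot(fraction > 0, fraction < 1)
  scores <- tibble::as_tibble(scores)
  with_seed(seed, {
    in_train <- logical(nrow(scores))
    for (id in unique(scores$item_id)) {
      idx <- which(scores$item_id == id)
      n_train <- round(fraction * length(idx))
      in_train[sample(idx, n_train)] <- TRUE
    }
    list(train = scores[in_train, , drop = FALSE],
         test = scores[!in_train, , drop = FALSE])
  })
}

# evaluate code under a temporary RNG state seeded with `seed`,
# restoring the caller's RNG state afterwards
with_seed <- function(seed, code) {
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}
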