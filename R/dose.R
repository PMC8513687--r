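#' Aggregate per-beat features across doses
#'
#' Per (dose, feature): arithmetic mean, sample standard deviation (n - 1
#' denominator) and beat count — the multi-parametric dose-response summary.
#'
#' @param features A data frame of per-beat records with columns `dose_nM`,
#'   `feature`, `value` (extra columns are ignored).
#' @return A tibble of class `quadcell_dose_table` with columns `dose_nM`,
#'   `feature`, `mean`, `sd`, `n`, one row per (dose, feature).
#' @examples
#' aggregate_features(tibble::tibble(
#'   dose_nM = rep(c(0, 3), each = 3), feature = "ct_pks_ms",
#'   value = c(212, 210, 214, 208, 206, 209)))
#' @export
aggregate_features <- function(features) {
  features <- tibble::as_tibble(features)
  need <- c("dose_nM", "feature", "value")
  if (!all(need %in% names(features))) {
    stop("features must carry columns dose_nM, feature, value", call. = FALSE)
  }
  if (nrow(features) == 0) stop("empty feature table", call. = FALSE)
  out <- dplyr::summarise(
    dplyr::group_by(features, dose_nM, feature),
    mean = mean(value), sd = stats::sd(value), n = dplyr::n(),
    .groups = "drop")
  class(out) <- c("quadcell_dose_table", class(out))
  out
}

#' Permutation trend test across doses
#'
#' Tests for a monotone dose trend in one feature. The statistic is the
#' least-squares slope of the per-beat feature value against the dense rank
#' of its dose (rank, not log-concentration: with a handful of doses no
#' curve is fitted). The two-sided p-value comes from permuting dose labels
#' across beats: either Monte-Carlo (with the add-one correction) or
#' exhaustive enumeration of all distinct label assignments.
#'
#' @param features Per-beat records with columns `dose_nM`, `feature`,
#'   `value` (or just `dose_nM` and `value` when `feature` is NULL).
#' @param feature Feature name to test (NULL when `features` holds a single
#'   feature without a `feature` column).
#' @param n_permutations Monte-Carlo permutation count (default 999).
#' @param seed Integer seed for the permutation draws.
#' @param method `"montecarlo"` (default) or `"exhaustive"` (all distinct
#'   assignments of values to dose groups; feasible for small n).
#' @param alpha Significance level deciding the reported direction
#'   (default 0.05).
#' @return A one-row tibble of class `quadcell_trend`: `feature`,
#'   `direction` (`"decreasing"`, `"increasing"` or `"none"`), `statistic`
#'   (slope per dose rank), `p_value`, `n_permutations`, `n_beats`,
#'   `n_doses`.
#' @examples
#' trend_test(tibble::tibble(
#'     dose_nM = rep(c(0, 3, 10), each = 5),
#'     value = c(rnorm(5, 238), rnorm(5, 226), rnorm(5, 210))),
#'   n_permutations = 199, seed = 1)
#' @export
trend_test <- function(features, feature = NULL, n_permutations = 999,
                       seed = 1L, method = c("montecarlo", "exhaustive"),
                       alpha = 0.05) {
  method <- match.arg(method)
  features <- tibble::as_tibble(features)
  if (!is.null(feature)) {
    features <- features[features$feature == feature, ]
  }
  stopifnot(all(c("dose_nM", "value") %in% names(features)))
  doses <- features$dose_nM
  y <- features$value
  if (length(unique(doses)) < 2) {
    stop("trend test needs at least 2 doses", call. = FALSE)
  }
  x <- as.numeric(factor(doses, levels = sort(unique(doses)))) # dense rank
  slope <- function(xx) stats::cov(xx, y) / stats::var(xx)
  obs <- slope(x)

  if (method == "exhaustive") {
    perms <- distinct_label_permutations(x)
    stats_null <- apply(perms, 1, slope)
    p <- mean(abs(stats_null) >= abs(obs) - 1e-12)
    n_perm <- nrow(perms)
  } else {
    stats_null <- withr::with_seed(seed, {
      vapply(seq_len(n_permutations), function(i) slope(sample(x)),
             numeric(1))
    })
    p <- (1 + sum(abs(stats_null) >= abs(obs) - 1e-12)) /
      (n_permutations + 1)
    n_perm <- n_permutations
  }
  direction <- if (p < alpha) {
    if (obs < 0) "decreasing" else "increasing"
  } else {
    "none"
  }
  out <- tibble::tibble(
    feature = feature %||% NA_character_, direction = direction,
    statistic = obs, p_value = p, n_permutations = n_perm,
    n_beats = length(y), n_doses = length(unique(doses)))
  class(out) <- c("quadcell_trend", class(out))
  out
}

# all distinct assignments of the multiset of labels x to positions
distinct_label_permutations <- function(x) {
  ux <- sort(unique(x))
  n <- length(x)
  fill <- function(free, labels) {
    if (length(labels) == 1) {
      m <- matrix(0, 1, n)
      m[1, free] <- labels
      return(m)
    }
    k <- sum(x == labels[1])
    picks <- utils::combn(free, k)
    do.call(rbind, lapply(seq_len(ncol(picks)), function(j) {
      sub <- fill(setdiff(free, picks[, j]), labels[-1])
      sub[, picks[, j]] <- labels[1]
      sub
    }))
  }
  fill(seq_len(n), ux)
}

#' @rdname trend_test
#' @param x A `quadcell_trend` row.
#' @param ... Unused.
#' @exportS3Method generics::glance
glance.quadcell_trend <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}

#' Plot a dose-response table
#'
#' Mean +/- sd per dose, one panel per feature.
#'
#' @param object A `quadcell_dose_table` from [aggregate_features()].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.quadcell_dose_table <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = factor(dose_nM), y = mean)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = mean - sd,
                                          ymax = mean + sd)) +
    ggplot2::facet_wrap(~feature, scales = "free_y") +
    ggplot2::labs(x = "dose (nM)", y = "feature value") +
    ggplot2::theme_minimal()
}
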