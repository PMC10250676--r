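#' Per-group summary of feature values
#'
#' Sample mean and sample standard deviation (n - 1 denominator) per group,
#' the form in which per-feature results are conventionally tabulated
#' (mean +/- SD). Singleton groups report `NA` for the SD.
#'
#' @param df A data frame of per-ROI features.
#' @param feature Name of the feature column to summarize.
#' @param group Name of the grouping column (default `"label"`).
#' @return A tibble with columns `group`, `n`, `mean`, `sd`.
#' @export
summarize_groups <- function(df, feature, group = "label") {
  check_feature_frame(df, feature, group)
  df |>
    dplyr::group_by(group = .data[[group]]) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean = mean(.data[[feature]]),
      sd = ifelse(dplyr::n() > 1, stats::sd(.data[[feature]]), NA_real_),
      .groups = "drop"
    )
}

check_feature_frame <- function(df, feature, group) {
  if (!is.data.frame(df)) abort_validation("`df` must be a data frame.")
  for (col in c(feature, group)) {
    if (!col %in% names(df)) {
      abort_validation(sprintf("Column '%s' not found in `df`.", col))
    }
  }
  if (!all(is.finite(df[[feature]]))) {
    abort_validation(sprintf("Column '%s' contains non-finite values.", feature))
  }
  invisible(df)
}

#' Kruskal-Wallis test with Dunn's post-hoc comparisons
#'
#' The nonparametric group-comparison workflow for per-ROI texture features:
#' a Kruskal-Wallis omnibus test on mid-ranks (with the standard tie
#' correction, chi-square reference distribution on k - 1 degrees of
#' freedom), followed by Dunn's rank-based z tests for the requested pairs,
#' optionally Bonferroni-adjusted (`p_adj = min(1, m * p)` where `m` is the
#' number of compared pairs).
#'
#' @param df A data frame of per-ROI features.
#' @param feature Name of the feature column to test.
#' @param group Name of the grouping column (default `"label"`).
#' @param comparisons `"all"` for all pairwise comparisons or
#'   `"versus-control"` for control-versus-each-other-group only.
#' @param control Control group label, required for `"versus-control"`.
#' @param adjust `"bonferroni"` (default) or `"none"`.
#' @return An object of class `kw_dunn`: a list with `feature`, `statistic`
#'   (H), `df`, `p.value`, `n`, `method`, and `pairwise`, a tibble with
#'   columns `group1`, `group2`, `z`, `p`, `p_adj`.
#' @examples
#' df <- data.frame(v = c(1, 2, 3, 4, 5, 6), g = rep(c("a", "b"), each = 3))
#' kw_dunn_test(df, "v", "g")  # H = 3.857
#' @export
kw_dunn_test <- function(df, feature, group = "label",
                         comparisons = c("all", "versus-control"),
                         control = NULL,
                         adjust = c("bonferroni", "none")) {
  comparisons <- match.arg(comparisons)
  adjust <- match.arg(adjust)
  check_feature_frame(df, feature, group)
  x <- df[[feature]]
  g <- factor(df[[group]])
  if (nlevels(g) < 2L) abort_validation("Need at least two groups.")
  if (any(table(g) == 0L)) g <- droplevels(g)
  n_total <- length(x)
  if (n_total < 3L) abort_validation("Need at least 3 observations in total.")

  degenerate <- length(unique(x)) == 1L
  kw <- if (degenerate) {
    # every observation tied: no rank information, H = 0 by convention
    list(statistic = 0, parameter = nlevels(g) - 1L, p.value = 1)
  } else {
    stats::kruskal.test(x, g)
  }

  # Dunn's z statistics on the pooled mid-ranks
  r <- rank(x)
  rbar <- tapply(r, g, mean)
  ns <- tapply(r, g, length)
  ties <- table(x)
  tie_term <- sum(ties^3 - ties) / (12 * (n_total - 1))
  s2 <- n_total * (n_total + 1) / 12 - tie_term

  levs <- levels(g)
  if (comparisons == "versus-control") {
    if (is.null(control) || !control %in% levs) {
      abort_validation("`control` must name one of the groups for versus-control comparisons.")
    }
    pairs <- lapply(setdiff(levs, control), function(b) c(control, b))
  } else {
    cmb <- utils::combn(levs, 2)
    pairs <- lapply(seq_len(ncol(cmb)), function(k) cmb[, k])
  }
  m <- length(pairs)
  pw <- purrr::map_dfr(pairs, function(pr) {
    a <- pr[1]; b <- pr[2]
    se <- sqrt(s2 * (1 / ns[[a]] + 1 / ns[[b]]))
    z <- if (se > 0) (rbar[[a]] - rbar[[b]]) / se else 0
    p <- 2 * stats::pnorm(-abs(z))
    tibble::tibble(group1 = a, group2 = b, z = z, p = p)
  })
  pw$p_adj <- if (adjust == "bonferroni") pmin(1, m * pw$p) else pw$p

  structure(
    list(
      feature = feature,
      statistic = unname(kw$statistic),
      df = unname(kw$parameter),
      p.value = kw$p.value,
      n = n_total,
      method = sprintf("Kruskal-Wallis + Dunn (%s, %s adjustment)", comparisons, adjust),
      degenerate = degenerate,
      comparisons = comparisons,
      adjust = adjust,
      pairwise = pw
    ),
    class = "kw_dunn"
  )
}

#' @export
print.kw_dunn <- function(x, ...) {
  cat(sprintf(
    "<kw_dunn> %s: H = %.4f, df = %d, p = %.4g (n = %d)\n",
    x$feature, x$statistic, x$df, x$p.value, x$n
  ))
  print(x$pairwise)
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the pairwise comparisons of a Kruskal-Wallis/Dunn result
#' @param x A `kw_dunn` object.
#' @param ... Unused.
#' @return A tibble with one row per compared pair: `feature`, `group1`,
#'   `group2`, `z`, `p`, `p_adj`.
#' @export
tidy.kw_dunn <- function(x, ...) {
  dplyr::bind_cols(tibble::tibble(feature = x$feature), x$pairwise)
}

#' One-row omnibus summary of a Kruskal-Wallis/Dunn result
#' @param x A `kw_dunn` object.
#' @param ... Unused.
#' @return A one-row tibble with `feature`, `statistic`, `df`, `p.value`,
#'   `n`, `method`.
#' @export
glance.kw_dunn <- function(x, ...) {
  tibble::tibble(
    feature = x$feature, statistic = x$statistic, df = x$df,
    p.value = x$p.value, n = x$n, method = x$method
  )
}

#' Run the group-comparison workflow over every texture feature
#'
#' Applies [kw_dunn_test()] to each feature column of a per-ROI feature
#' table.
#'
#' @param df Feature table with a grouping column.
#' @param features Feature column names (default the eight texture features
#'   present in `df`).
#' @param group,comparisons,control,adjust Passed to [kw_dunn_test()].
#' @return A tibble with one row per feature: the omnibus `statistic`, `df`,
#'   `p.value`, `n`, and a `pairwise` list column of Dunn comparison tibbles.
#' @export
feature_group_tests <- function(df, features = NULL, group = "label",
                                comparisons = c("all", "versus-control"),
                                control = NULL,
                                adjust = c("bonferroni", "none")) {
  comparisons <- match.arg(comparisons)
  adjust <- match.arg(adjust)
  if (is.null(features)) {
    features <- intersect(texture_feature_names(), names(df))
  }
  if (length(features) == 0L) abort_validation("No feature columns found in `df`.")
  purrr::map_dfr(features, function(f) {
    res <- kw_dunn_test(df, f, group = group, comparisons = comparisons,
                        control = control, adjust = adjust)
    tibble::tibble(
      feature = f, statistic = res$statistic, df = res$df,
      p.value = res$p.value, n = res$n, pairwise = list(res$pairwise)
    )
  })
}

#' Boxplots of feature distributions by group
#'
#' @param df Feature table.
#' @param features Feature columns to plot (default all eight present).
#' @param group Grouping column (default `"label"`).
#' @return A ggplot object, faceted by feature on free y scales.
#' @export
plot_feature_groups <- function(df, features = NULL, group = "label") {
  if (is.null(features)) features <- intersect(texture_feature_names(), names(df))
  long <- df |>
    dplyr::select(dplyr::all_of(c(group, features))) |>
    tidyr::pivot_longer(dplyr::all_of(features),
                        names_to = "feature", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data[[group]], y = .data$value,
                                     fill = .data[[group]])) +
    ggplot2::geom_boxplot(show.legend = FALSE) +
    ggplot2::facet_wrap(~feature, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_bw()
}
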