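#' Excess signal above background
#'
#' Normalized signals map untreated background to 1, so the excess is simply
#' `signal - 1`. Negative excess (sub-background) is preserved, not clipped:
#' truncation would bias control distributions upward.
#'
#' @param signal Normalized signal (fold of control).
#' @param s_background Background level after normalization (1 by definition).
#' @return The excess, same length as `signal`.
#' @export
#' @examples
#' excess(c(1, 1.10, 0.98))
excess <- function(signal, s_background = 1) {
  stopifnot(is.numeric(signal), all(is.finite(signal)))
  signal - s_background
}

tes_pairs <- c("presyn_postsyn", "presyn_axons", "axons_postsyn")

tes_pair_parts <- function(pair) {
  switch(pair,
    presyn_postsyn = c(source = "presyn", target = "postsyn"),
    presyn_axons = c(source = "presyn", target = "axons"),
    axons_postsyn = c(source = "axons", target = "postsyn"),
    abort(sprintf("unknown TES pair '%s'", pair))
  )
}

#' Transmitted Excess Signal per experiment
#'
#' For each experiment, the excess normalized signal in the target compartment
#' is divided by the across-experiment mean excess in the source compartment
#' of the same condition and DIV:
#' `TES = (S_target - 1) / mean_n(S_source,n - 1)`,
#' with the background fixed at 1 because control values cluster around 1
#' after session normalization. The denominator spans all `n` experiments of
#' the condition for which the source compartment was measured.
#'
#' Device-level rows are first averaged to experiment-level means. A source
#' excess at or below the floor `epsilon` would amplify noise rather than
#' measure transfer, and raises an error; for tables without usable source
#' signal (e.g. control-only tables) an explicit `denominator_excess` can be
#' supplied instead.
#'
#' @param signals Tibble in the [gen_signal_table()] schema: `experiment_id`,
#'   `condition`, `div`, `compartment`, `signal` (normalized; device rows
#'   allowed).
#' @param pair One or more of `"presyn_postsyn"`, `"presyn_axons"`,
#'   `"axons_postsyn"`.
#' @param epsilon Minimum usable mean source excess.
#' @param denominator_excess Optional fixed source mean excess overriding the
#'   table-derived denominator.
#' @param exclude_control Drop rows of this condition label (they define the
#'   background, not a transfer arm) unless a denominator override is given.
#' @return Tibble with one row per experiment x condition x div x pair:
#'   `tes` (fraction), `target_excess`, `source_mean_excess`,
#'   `n_source_experiments`.
#' @export
#' @examples
#' tbl <- tibble::tibble(
#'   experiment_id = "E1", condition = "hFib", div = 14,
#'   compartment = c("presyn", "postsyn"), signal = c(21, 1.10)
#' )
#' compute_tes(tbl, "presyn_postsyn")$tes # 0.10 / 20 = 0.5%
compute_tes <- function(signals, pair = tes_pairs, epsilon = 0.05,
                        denominator_excess = NULL,
                        exclude_control = "ctrl") {
  pair <- match.arg(pair, tes_pairs, several.ok = TRUE)
  needed <- c("experiment_id", "condition", "div", "compartment", "signal")
  if (!all(needed %in% names(signals))) {
    abort(paste("`signals` must have columns:", paste(needed, collapse = ", ")))
  }
  dat <- signals
  if (is.null(denominator_excess)) {
    dat <- dplyr::filter(dat, !.data$condition %in% exclude_control)
  }
  if (!nrow(dat)) abort("no usable (non-control) rows in `signals`")
  exp_means <- dat |>
    dplyr::group_by(
      .data$experiment_id, .data$condition, .data$div,
      .data$compartment
    ) |>
    dplyr::summarise(signal = mean(.data$signal), .groups = "drop")
  purrr::map_dfr(pair, function(p) {
    parts <- tes_pair_parts(p)
    denom <- exp_means |>
      dplyr::filter(.data$compartment == parts[["source"]]) |>
      dplyr::group_by(.data$condition, .data$div) |>
      dplyr::summarise(
        source_mean_excess = mean(excess(.data$signal)),
        n_source_experiments = dplyr::n(), .groups = "drop"
      )
    if (!is.null(denominator_excess)) {
      assert_scalar_num(denominator_excess, "denominator_excess")
      conds <- exp_means |> dplyr::distinct(.data$condition, .data$div)
      denom <- dplyr::mutate(conds,
        source_mean_excess = denominator_excess,
        n_source_experiments = NA_integer_
      )
    }
    bad <- denom$source_mean_excess <= epsilon
    if (any(bad)) {
      abort(sprintf(
        "source excess indistinguishable from background (<= %.3g) for: %s",
        epsilon,
        paste(denom$condition[bad], denom$div[bad], collapse = ", ")
      ))
    }
    exp_means |>
      dplyr::filter(.data$compartment == parts[["target"]]) |>
      dplyr::inner_join(denom, by = c("condition", "div")) |>
      dplyr::transmute(
        experiment_id = .data$experiment_id,
        condition = .data$condition, div = .data$div, pair = p,
        target_excess = excess(.data$signal),
        source_mean_excess = .data$source_mean_excess,
        n_source_experiments = .data$n_source_experiments,
        tes = .data$target_excess / .data$source_mean_excess
      )
  })
}

#' Aggregate per-experiment TES values
#'
#' Experiment-level mean, standard error of the mean and count per condition,
#' DIV and compartment pair (log-scale display is a plotting concern, handled
#' by [plot_tes()]).
#'
#' @param profiles Output of [compute_tes()].
#' @return Tibble with `condition`, `div`, `pair`, `mean_tes`, `sem_tes`
#'   (`NA` with a single experiment), `n_experiments`.
#' @export
aggregate_tes <- function(profiles) {
  stopifnot(all(c("condition", "div", "pair", "tes") %in% names(profiles)))
  profiles |>
    dplyr::group_by(.data$condition, .data$div, .data$pair) |>
    dplyr::summarise(
      mean_tes = mean(.data$tes),
      sem_tes = if (dplyr::n() > 1) {
        sd(.data$tes) / sqrt(dplyr::n())
      } else {
        NA_real_
      },
      n_experiments = dplyr::n(),
      .groups = "drop"
    )
}

new_stat_result <- function(test_name, statistic, p_value, group_sizes,
                            effect_direction, note = NULL) {
  stopifnot(p_value >= 0, p_value <= 1)
  structure(
    list(
      test_name = test_name, statistic = statistic, p_value = p_value,
      group_sizes = group_sizes, effect_direction = effect_direction,
      note = note
    ),
    class = "syn_stat"
  )
}

#' @export
print.syn_stat <- function(x, ...) {
  cat(sprintf(
    "<%s> statistic = %.4g, p = %.4g (n = %s)%s\n",
    x$test_name, x$statistic, x$p_value,
    paste(x$group_sizes, collapse = ", "),
    if (!is.null(x$note)) paste0(" [", x$note, "]") else ""
  ))
  invisible(x)
}

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @export
tidy.syn_stat <- function(x, ...) {
  tibble::tibble(
    test = x$test_name, statistic = x$statistic,
    p.value = x$p_value,
    direction = x$effect_direction %||% NA_character_
  )
}

#' @export
glance.syn_stat <- function(x, ...) tidy(x)

#' One-sample t-test against the control value 1
#'
#' Used for comparing normalized conditions to the control, whose normalized
#' mean is 1 by construction in each experiment.
#'
#' @param values Numeric vector of experiment-level normalized values
#'   (`n >= 2`).
#' @return A `syn_stat` result (two-sided).
#' @export
one_sample_t_vs_unity <- function(values) {
  if (length(values) < 2) abort("one-sample t-test needs at least 2 values")
  if (sd(values) == 0) {
    if (all(values == 1)) {
      return(new_stat_result("one_sample_t_vs_1", 0, 1, length(values),
        "none",
        note = "zero variance at the null value"
      ))
    }
    abort("zero variance: one-sample t-test undefined")
  }
  tt <- stats::t.test(values, mu = 1)
  new_stat_result(
    "one_sample_t_vs_1", unname(tt$statistic), tt$p.value,
    length(values),
    if (mean(values) > 1) "above 1" else "below 1"
  )
}

#' Welch two-sample t-test
#'
#' Two-group comparison with Welch's correction (Satterthwaite degrees of
#' freedom), two-sided.
#'
#' @param group_a,group_b Numeric vectors (`n >= 2` each).
#' @return A `syn_stat` result; the Satterthwaite df is attached as
#'   `$df`.
#' @export
welch_t <- function(group_a, group_b) {
  if (length(group_a) < 2 || length(group_b) < 2) {
    abort("Welch t-test needs at least 2 values per group")
  }
  if (sd(group_a) == 0 && sd(group_b) == 0) {
    if (mean(group_a) == mean(group_b)) {
      return(new_stat_result("welch_t", 0, 1,
        c(length(group_a), length(group_b)), "none",
        note = "both groups constant and equal"
      ))
    }
    abort("zero variance in both groups: Welch t-test undefined")
  }
  tt <- stats::t.test(group_a, group_b, var.equal = FALSE)
  out <- new_stat_result(
    "welch_t", unname(tt$statistic), tt$p.value,
    c(length(group_a), length(group_b)),
    if (mean(group_a) > mean(group_b)) "A > B" else "A < B"
  )
  out$df <- unname(tt$parameter)
  out
}

#' Normality gate for two-group comparisons
#'
#' Shapiro-Wilk on every group at `alpha`; all groups normal routes to the
#' parametric Welch t-test, otherwise to the rank-sum (Mann-Whitney)
#' comparison. Groups too small to test (`n < 3`) fall through to the
#' parametric path with a warning; constant groups route non-parametric with a
#' zero-variance note.
#'
#' @param groups List of numeric vectors.
#' @param alpha Significance level of the gate.
#' @return List with `route` (`"parametric"` / `"nonparametric"`),
#'   `shapiro_p` per group, and `note`.
#' @export
normality_gate <- function(groups, alpha = 0.05) {
  stopifnot(is.list(groups), length(groups) >= 1)
  note <- NULL
  ps <- vapply(groups, function(g) {
    if (length(g) < 3) {
      return(NA_real_)
    }
    if (sd(g) == 0) {
      return(0)
    }
    stats::shapiro.test(g)$p.value
  }, numeric(1))
  if (any(vapply(groups, function(g) length(g) >= 3 && sd(g) == 0, logical(1)))) {
    note <- "zero-variance group"
  }
  if (all(is.na(ps))) {
    warn("all groups too small for a normality test; using the parametric path")
    return(list(route = "parametric", shapiro_p = ps, note = "groups too small"))
  }
  route <- if (all(ps > alpha, na.rm = TRUE)) "parametric" else "nonparametric"
  list(route = route, shapiro_p = ps, note = note)
}

#' Gated two-group comparison
#'
#' Applies [normality_gate()] and runs either [welch_t()] or the Mann-Whitney
#' rank-sum test.
#'
#' @param group_a,group_b Numeric vectors.
#' @return A `syn_stat` result.
#' @export
compare_two_groups <- function(group_a, group_b) {
  gate <- normality_gate(list(group_a, group_b))
  if (gate$route == "parametric") {
    return(welch_t(group_a, group_b))
  }
  wt <- suppressWarnings(stats::wilcox.test(group_a, group_b))
  new_stat_result(
    "mann_whitney", unname(wt$statistic), wt$p.value,
    c(length(group_a), length(group_b)),
    if (median(group_a) > median(group_b)) "A > B" else "A < B",
    note = gate$note
  )
}

#' Multi-group comparisons (delegated)
#'
#' Standard multi-group machinery behind the same result contract: two-way
#' ANOVA + Tukey HSD for factorial TES comparisons, Kruskal-Wallis for
#' non-parametric one-way comparisons. These delegate to the standard
#' implementations, they are not reimplemented.
#'
#' @param data Data frame.
#' @param value,group,group2 Column names (strings).
#' @return A tibble of per-contrast statistics.
#' @name multi_group
NULL

#' @rdname multi_group
#' @export
anova_tukey <- function(data, value, group, group2 = NULL) {
  fml <- if (is.null(group2)) {
    stats::as.formula(paste(value, "~", group))
  } else {
    stats::as.formula(paste(value, "~", group, "*", group2))
  }
  fit <- stats::aov(fml, data = data)
  tk <- stats::TukeyHSD(fit)
  purrr::imap_dfr(tk, function(tab, term) {
    tibble::tibble(
      term = term, contrast = rownames(tab),
      estimate = tab[, "diff"], p.value = tab[, "p adj"]
    )
  })
}

#' @rdname multi_group
#' @export
kruskal_groups <- function(data, value, group) {
  kw <- stats::kruskal.test(
    stats::as.formula(paste(value, "~", group)),
    data = data
  )
  tibble::tibble(
    term = group, statistic = unname(kw$statistic),
    p.value = kw$p.value
  )
}
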