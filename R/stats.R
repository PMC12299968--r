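#' Per-class summaries of labelled events
#'
#' One row per class present: number of events, number of distinct membranes
#' (recordings), and mean +/- SD of peak conductance, mean conductance and
#' lifetime. Sample SDs use the n-1 denominator; singleton classes are
#' reported with SD 0 and flagged rather than dropped.
#'
#' @param events Labelled event tibble; needs `class_label`,
#'   `mean_conductance_pS`, `peak_conductance_pS`, `lifetime_ms` and
#'   (optionally) `membrane_id`.
#' @return A tibble with one row per class, columns `class_label`,
#'   `n_membranes`, `n_events`, `peak_conductance_mean_pS` / `_sd_pS`,
#'   `mean_conductance_mean_pS` / `_sd_pS`, `lifetime_mean_ms` / `_sd_ms`,
#'   `singleton`.
#' @export
summarize_by_class <- function(events) {
  stopifnot(nrow(events) >= 1)
  if (!"membrane_id" %in% names(events)) events$membrane_id <- "r1"
  sd0 <- function(x) if (length(x) < 2) 0 else sd(x)
  events |>
    dplyr::group_by(.data$class_label) |>
    dplyr::summarise(
      n_membranes = dplyr::n_distinct(.data$membrane_id),
      n_events = dplyr::n(),
      peak_conductance_mean_pS = mean(.data$peak_conductance_pS),
      peak_conductance_sd_pS = sd0(.data$peak_conductance_pS),
      mean_conductance_mean_pS = mean(.data$mean_conductance_pS),
      mean_conductance_sd_pS = sd0(.data$mean_conductance_pS),
      lifetime_mean_ms = mean(.data$lifetime_ms),
      lifetime_sd_ms = sd0(.data$lifetime_ms),
      singleton = dplyr::n() == 1,
      .groups = "drop"
    )
}

#' Empirical lifetime quantile
#'
#' Linear interpolation between order statistics (the default `type = 7`
#' convention of [stats::quantile()]); the convention matters because
#' statements like "75% of channel lifetimes fall below 165 ms" depend on it.
#'
#' @param lifetimes_ms Numeric vector of event lifetimes (ms), nonempty.
#' @param q Probability in (0, 1).
#' @return The quantile, in ms.
#' @export
lifetime_quantile <- function(lifetimes_ms, q) {
  if (length(lifetimes_ms) == 0) {
    abort("no lifetimes supplied", class = "blm_error_empty")
  }
  stopifnot(q > 0, q < 1)
  unname(quantile(lifetimes_ms, probs = q, type = 7))
}

#' Compare conductance between event classes and between channel populations
#'
#' Thin wrappers over the standard routines: a one-way ANOVA with Tukey HSD
#' on peak conductance across the spike/bump/step classes of `events`, and,
#' when a second population of events is supplied (e.g. gramicidin step
#' events), a Welch two-sample t-test on mean conductance between the step
#' events of the two populations. Welch's unequal-variance form is used
#' because the class SDs of interest are grossly unequal.
#'
#' @param events Labelled event tibble.
#' @param events_b Optional second labelled event tibble for the two-sample
#'   comparison (its `step` events against those of `events`).
#' @return A list of class `blm_comparison` with elements `anova` (tibble:
#'   statistic, df, p.value), `tukey` (tibble of pairwise contrasts), and,
#'   if `events_b` was given, `t_test` (tibble: statistic, df, p.value,
#'   estimate_a, estimate_b). Use [tidy()] / [glance()] to extract.
#' @export
compare_classes <- function(events, events_b = NULL) {
  main <- dplyr::filter(events,
    .data$class_label %in% c("spike", "bump", "step"))
  counts <- table(main$class_label)
  if (length(counts) < 2 || any(counts < 2)) {
    abort("need >= 2 classes with >= 2 events each",
      class = "blm_error_insufficient")
  }
  dat <- data.frame(g = factor(main$class_label),
    y = main$peak_conductance_pS)
  fit <- aov(y ~ g, data = dat)
  s <- summary(fit)[[1]]
  anova_tbl <- tibble::tibble(
    statistic = s[["F value"]][1],
    df = s[["Df"]][1], df_residual = s[["Df"]][2],
    p.value = s[["Pr(>F)"]][1]
  )
  tk <- TukeyHSD(fit)$g
  tukey_tbl <- tibble::tibble(
    contrast = rownames(tk),
    estimate = tk[, "diff"], conf.low = tk[, "lwr"],
    conf.high = tk[, "upr"], adj.p.value = tk[, "p adj"]
  )
  out <- list(anova = anova_tbl, tukey = tukey_tbl, t_test = NULL)
  if (!is.null(events_b)) {
    a <- dplyr::filter(events, .data$class_label == "step")$mean_conductance_pS
    b <- dplyr::filter(events_b, .data$class_label == "step")$mean_conductance_pS
    if (length(a) < 2 || length(b) < 2) {
      abort("need >= 2 step events in each population",
        class = "blm_error_insufficient")
    }
    tt <- t.test(a, b)   # Welch by default
    out$t_test <- tibble::tibble(
      statistic = unname(tt$statistic), df = unname(tt$parameter),
      p.value = tt$p.value,
      estimate_a = unname(tt$estimate[1]), estimate_b = unname(tt$estimate[2])
    )
  }
  structure(out, class = "blm_comparison")
}

#' @export
print.blm_comparison <- function(x, ...) {
  cat("Peak conductance across classes (one-way ANOVA):\n")
  print(x$anova)
  cat("\nTukey HSD contrasts:\n")
  print(x$tukey)
  if (!is.null(x$t_test)) {
    cat("\nStep-event mean conductance, population A vs B (Welch t-test):\n")
    print(x$t_test)
  }
  invisible(x)
}

#' Tidy a class comparison
#'
#' @param x A `blm_comparison` from [compare_classes()].
#' @param ... Unused.
#' @return `tidy()` returns one row per test/contrast with `term`,
#'   `statistic`, `df`, `estimate`, `p.value`; `glance()` returns a one-row
#'   tibble with the headline p-values.
#' @export
tidy.blm_comparison <- function(x, ...) {
  rows <- list(
    tibble::tibble(term = "anova", statistic = x$anova$statistic,
      df = x$anova$df, estimate = NA_real_, p.value = x$anova$p.value),
    tibble::tibble(term = paste0("tukey:", x$tukey$contrast),
      statistic = NA_real_, df = NA_real_, estimate = x$tukey$estimate,
      p.value = x$tukey$adj.p.value)
  )
  if (!is.null(x$t_test)) {
    rows <- c(rows, list(tibble::tibble(term = "welch_t",
      statistic = x$t_test$statistic, df = x$t_test$df,
      estimate = x$t_test$estimate_a - x$t_test$estimate_b,
      p.value = x$t_test$p.value)))
  }
  dplyr::bind_rows(rows)
}

#' @rdname tidy.blm_comparison
#' @export
glance.blm_comparison <- function(x, ...) {
  tibble::tibble(
    anova_p.value = x$anova$p.value,
    t_test_p.value = if (is.null(x$t_test)) NA_real_ else x$t_test$p.value
  )
}
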