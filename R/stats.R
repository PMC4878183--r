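#' Normalize measurements to each day's control median
#'
#' Measurements acquired on different days are made comparable by dividing
#' every value by the median of that day's control measurements (per metric).
#' Normalization is a positive monotone rescaling within each day, so
#' within-day rankings — and hence rank-based tests — are unchanged.
#'
#' @param table data frame with at least `value`, `condition` and `day`
#'   columns; a `metric` column, when present, is normalized separately.
#' @param control the condition label treated as control.
#' @return The input as a tibble with `value_norm` added.
#' @examples
#' t <- tibble::tibble(value = c(2, 4, 8, 10), day = 1,
#'                     condition = c("control", "control", "control", "treated"))
#' day_normalize(t)$value_norm # controls become 0.5, 1, 2
#' @export
day_normalize <- function(table, control = "control") {
  need <- c("value", "condition", "day")
  missing <- setdiff(need, names(table))
  if (length(missing))
    abort(paste("table is missing column(s):", paste(missing, collapse = ", ")))
  tbl <- tibble::as_tibble(table)
  grp <- intersect(c("day", "metric"), names(tbl))
  out <- tbl |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grp))) |>
    dplyr::mutate(.ctrl_med = median(.data$value[.data$condition == control])) |>
    dplyr::ungroup()
  bad <- out |>
    dplyr::filter(is.na(.data$.ctrl_med) | .data$.ctrl_med == 0) |>
    dplyr::distinct(.data$day)
  if (nrow(bad) > 0)
    abort(paste0("control median is zero or missing for day(s): ",
                 paste(bad$day, collapse = ", ")))
  out |>
    dplyr::mutate(value_norm = .data$value / .data$.ctrl_med) |>
    dplyr::select(-".ctrl_med")
}

#' Wilcoxon rank-sum test with exact small-sample null
#'
#' Two-sided Wilcoxon rank-sum (Mann-Whitney) test, the default comparison
#' for per-cell measurements whose distributions are markedly non-normal
#' (many cells respond weakly, a few strongly). Ties receive midranks. For
#' small samples (`n_a + n_b <= exact_limit`, default 12) the null
#' distribution of the rank sum is computed by full enumeration of all
#' `choose(n, n_a)` group assignments — exact even under ties; larger samples
#' use the normal approximation with tie correction and continuity
#' correction. The two-sided p-value is the null probability of a rank sum at
#' least as far from its expectation as observed.
#'
#' @param a,b numeric samples (non-empty).
#' @param mode `"auto"` (exact below the limit), `"exact"` or `"normal"`.
#' @param exact_limit maximum `n_a + n_b` for enumeration in `"auto"` mode.
#' @return A `rank_sum_test`: list with `statistic` (rank sum of `a`, `W`),
#'   `p_value`, `method`, and sample sizes. Supports [tidy()] and [glance()].
#' @examples
#' rank_sum_test(c(1, 2), c(3, 4))$p_value # 2/6
#' @export
rank_sum_test <- function(a, b, mode = c("auto", "exact", "normal"),
                          exact_limit = 12) {
  mode <- match.arg(mode)
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) == 0 || length(b) == 0) abort("both samples must be non-empty.")
  if (anyNA(c(a, b))) abort("samples must not contain NA.")
  na <- length(a); nb <- length(b); n <- na + nb
  pooled <- c(a, b)
  r <- rank(pooled) # midranks for ties
  w <- sum(r[seq_len(na)])
  mu <- na * (n + 1) / 2

  degenerate <- length(unique(pooled)) == 1
  if (degenerate) {
    warn("all values identical across both samples; p = 1.")
    return(new_rank_sum(w, 1, "degenerate", na, nb))
  }

  use_exact <- mode == "exact" || (mode == "auto" && n <= exact_limit)
  if (use_exact) {
    if (choose(n, na) > 5e6)
      abort("exact enumeration infeasible at this sample size; use mode = 'normal'.")
    dev <- abs(w - mu)
    sums <- combn(n, na, FUN = function(ix) sum(r[ix]))
    p <- mean(abs(sums - mu) >= dev - 1e-9)
    return(new_rank_sum(w, p, "exact enumeration", na, nb))
  }

  ties <- table(r)
  tie_term <- sum(ties^3 - ties) / (n * (n - 1))
  sigma2 <- na * nb / 12 * ((n + 1) - tie_term)
  z <- (w - mu - sign(w - mu) * 0.5) / sqrt(sigma2)
  p <- min(1, 2 * pnorm(-abs(z)))
  new_rank_sum(w, p, "normal approximation (tie/continuity corrected)", na, nb)
}

new_rank_sum <- function(w, p, method, na, nb) {
  structure(list(statistic = w, p_value = p, method = method,
                 n_a = na, n_b = nb),
            class = "rank_sum_test")
}

#' @export
print.rank_sum_test <- function(x, ...) {
  cat(sprintf("Wilcoxon rank-sum: W = %.4g, p = %.4g (%s; n = %d, %d)\n",
              x$statistic, x$p_value, x$method, x$n_a, x$n_b))
  invisible(x)
}

#' @export
tidy.rank_sum_test <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, p_value = x$p_value,
                 method = x$method, n_a = x$n_a, n_b = x$n_b)
}

#' @export
glance.rank_sum_test <- function(x, ...) tidy(x)

#' Pooled-variance two-sample t-test
#'
#' Student's t-test for measurements that are approximately normal. With zero
#' pooled variance: equal means give p = 1 by convention, unequal means give
#' p = 0 with a warning.
#'
#' @param a,b numeric samples with `n >= 2` each.
#' @return A tibble with `statistic`, `p_value`, `df`, `mean_a`, `mean_b`.
#' @export
student_t_test <- function(a, b) {
  if (length(a) < 2 || length(b) < 2) abort("t-test needs n >= 2 per sample.")
  if (sd(a) == 0 && sd(b) == 0) {
    if (isTRUE(all.equal(mean(a), mean(b)))) {
      warn("zero variance and equal means; p = 1 by convention.")
      return(tibble::tibble(statistic = 0, p_value = 1,
                            df = length(a) + length(b) - 2,
                            mean_a = mean(a), mean_b = mean(b)))
    }
    warn("zero pooled variance with unequal means; p = 0.")
    return(tibble::tibble(statistic = Inf, p_value = 0,
                          df = length(a) + length(b) - 2,
                          mean_a = mean(a), mean_b = mean(b)))
  }
  ht <- t.test(a, b, var.equal = TRUE)
  tibble::tibble(statistic = unname(ht$statistic), p_value = ht$p.value,
                 df = unname(ht$parameter),
                 mean_a = mean(a), mean_b = mean(b))
}

#' Mean and standard error of the mean
#'
#' @param values numeric vector.
#' @return Tibble with `mean`, `sem` (`sd/sqrt(n)`) and `n`.
#' @examples
#' summary_sem(c(2, 4, 6)) # mean 4, sem 2/sqrt(3)
#' @export
summary_sem <- function(values) {
  n <- length(values)
  tibble::tibble(mean = mean(values),
                 sem = if (n > 1) sd(values) / sqrt(n) else NA_real_,
                 n = n)
}

#' Two-condition comparison report
#'
#' Runs the appropriate two-group comparison per metric on a measurement
#' table, optionally after per-day control-median normalization, and returns
#' one report row per metric.
#'
#' @param table data frame with `value`, `condition`, `day` (and optionally
#'   `metric`) columns and exactly two condition levels.
#' @param test `"rank_sum"` (default, for non-normal per-cell data) or
#'   `"t"`.
#' @param normalize apply [day_normalize()] first.
#' @param control control condition label.
#' @return Tibble: `metric`, `n_a`, `n_b`, `statistic`, `p_value`,
#'   `test_used`, `normalized`, `fold_change` (treated median / control
#'   median).
#' @export
compare_conditions <- function(table, test = c("rank_sum", "t"),
                               normalize = TRUE, control = "control") {
  test <- match.arg(test)
  tbl <- tibble::as_tibble(table)
  if (!"metric" %in% names(tbl)) tbl$metric <- "value"
  conds <- unique(tbl$condition)
  if (length(conds) != 2)
    abort("`compare_conditions()` needs exactly two conditions.")
  treated <- setdiff(conds, control)
  if (normalize) {
    tbl <- day_normalize(tbl, control = control)
    tbl$value <- tbl$value_norm
  }
  tbl |>
    dplyr::group_by(.data$metric) |>
    dplyr::group_modify(function(d, key) {
      a <- d$value[d$condition == treated]
      b <- d$value[d$condition == control]
      res <- if (test == "rank_sum") {
        r <- rank_sum_test(a, b)
        tibble::tibble(statistic = r$statistic, p_value = r$p_value)
      } else {
        r <- student_t_test(a, b)
        tibble::tibble(statistic = r$statistic, p_value = r$p_value)
      }
      dplyr::mutate(res, n_a = length(a), n_b = length(b),
                    fold_change = median(a) / median(b))
    }) |>
    dplyr::ungroup() |>
    dplyr::mutate(test_used = test, normalized = normalize) |>
    dplyr::select("metric", "n_a", "n_b", "statistic", "p_value",
                  "fold_change", "test_used", "normalized")
}
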