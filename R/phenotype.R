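#' Growth rate as the slope of the linear range of a growth curve
#'
#' Fits ordinary least squares to every contiguous window of at least
#' `k_min` time points and returns, among windows whose R-squared reaches
#' `r2_min`, the one with the maximum slope. If no window fits well enough,
#' the maximum-slope window of minimal length is returned with a `low_fit`
#' flag. A perfectly flat window (zero variance in absorbance) counts as a
#' perfect fit with slope 0.
#'
#' @param time_h Strictly increasing time points (hours), length >= `k_min`.
#' @param abs450 Absorbance values, same length.
#' @param k_min Minimum window length in points (default 5).
#' @param r2_min Minimum R-squared of an acceptable window (default 0.95).
#' @return One-row tibble: `slope` (ABS450 per hour), `intercept`,
#'   `window_start`, `window_end` (1-based point indices, inclusive),
#'   `r_squared`, `low_fit`.
#' @export
growth_rate <- function(time_h, abs450, k_min = 5, r2_min = 0.95) {
  n <- length(time_h)
  if (n != length(abs450)) abort("time and absorbance lengths differ.")
  if (n < k_min) abort(sprintf("Need at least k_min = %d points.", k_min))
  if (any(diff(time_h) <= 0)) abort("Time points must be strictly increasing.")
  if (k_min < 3) abort("k_min must be at least 3.")

  # closed-form OLS for all windows from cumulative sums
  ct <- c(0, cumsum(time_h)); cy <- c(0, cumsum(abs450))
  ct2 <- c(0, cumsum(time_h^2)); cy2 <- c(0, cumsum(abs450^2))
  cty <- c(0, cumsum(time_h * abs450))
  best <- NULL; fallback <- NULL
  for (s in seq_len(n - k_min + 1)) {
    for (e in seq(s + k_min - 1, n)) {
      k <- e - s + 1
      st <- ct[e + 1] - ct[s]; sy <- cy[e + 1] - cy[s]
      st2 <- ct2[e + 1] - ct2[s]; sy2 <- cy2[e + 1] - cy2[s]
      sty <- cty[e + 1] - cty[s]
      sxx <- st2 - st^2 / k
      sxy <- sty - st * sy / k
      syy <- sy2 - sy^2 / k
      slope <- sxy / sxx
      r2 <- if (syy <= .Machine$double.eps * abs(sy2)) 1 else sxy^2 / (sxx * syy)
      cand <- list(slope = slope, intercept = (sy - slope * st) / k,
                   s = s, e = e, r2 = r2)
      if (r2 >= r2_min && (is.null(best) || slope > best$slope)) best <- cand
      if (k == k_min && (is.null(fallback) || slope > fallback$slope)) {
        fallback <- cand
      }
    }
  }
  low_fit <- is.null(best)
  res <- if (low_fit) fallback else best
  tibble(slope = res$slope, intercept = res$intercept,
         window_start = res$s, window_end = res$e,
         r_squared = res$r2, low_fit = low_fit)
}

#' Growth rates for every curve in a tidy growth table
#'
#' @param growth Tibble with `sample`, `condition`, `replicate`, `time_h`,
#'   `abs450` (one row per reading).
#' @inheritParams growth_rate
#' @return Tibble with one row per sample x condition x replicate and the
#'   columns of [growth_rate()].
#' @export
growth_rates <- function(growth, k_min = 5, r2_min = 0.95) {
  stopifnot(all(c("sample", "condition", "replicate", "time_h", "abs450")
                %in% names(growth)))
  growth |>
    group_by(.data$sample, .data$condition, .data$replicate) |>
    arrange(.data$time_h, .by_group = TRUE) |>
    summarise(growth_rate(.data$time_h, .data$abs450, k_min, r2_min),
              .groups = "drop")
}

#' Mann-Whitney U comparison of two groups of growth rates
#'
#' U is computed by rank sums with midranks for ties. The p-value is exact
#' (full enumeration of group assignments) when the combined sample size is
#' at most 16 and there are no ties, and otherwise uses the normal
#' approximation with tie and continuity corrections. Two-sided by default.
#'
#' @param rates_a,rates_b Numeric vectors of rates for the two groups.
#' @param alternative Passed to the test (default `"two.sided"`).
#' @return One-row tibble: `U_a`, `U_b` (with `U_a + U_b = n_a * n_b`),
#'   `p_value`, `n_a`, `n_b`, `exact`.
#' @export
compare_groups <- function(rates_a, rates_b,
                           alternative = c("two.sided", "less", "greater")) {
  alternative <- match.arg(alternative)
  if (length(rates_a) == 0 || length(rates_b) == 0) {
    abort("Both groups must be nonempty.")
  }
  na <- length(rates_a); nb <- length(rates_b)
  pooled <- c(rates_a, rates_b)
  ranks <- rank(pooled)  # midranks
  u_a <- sum(ranks[seq_len(na)]) - na * (na + 1) / 2
  ties <- any(duplicated(pooled))
  exact <- (na + nb) <= 16 && !ties
  p <- if (alternative == "two.sided" && u_a == na * nb / 2) {
    1  # U at the centre of its symmetric null: no evidence either way
  } else {
    suppressWarnings(
      wilcox.test(rates_a, rates_b, alternative = alternative,
                  exact = exact, correct = TRUE))$p.value
  }
  tibble(U_a = u_a, U_b = na * nb - u_a, p_value = p,
         n_a = na, n_b = nb, exact = exact)
}

#' Compare growth rates between clades for each condition
#'
#' Aggregates replicate slopes to strain means by default (each strain is
#' one statistical unit) before the rank test; `aggregate = "replicate"`
#' ranks all replicate slopes instead.
#'
#' @param rates Output of [growth_rates()].
#' @param clades Clade assignment of samples (named vector or metadata).
#' @param aggregate `"strain_mean"` (default) or `"replicate"`.
#' @inheritParams compare_groups
#' @return Tibble with one row per condition: clade labels, group sizes, U
#'   statistics and p-value.
#' @export
compare_growth <- function(rates, clades,
                           aggregate = c("strain_mean", "replicate"),
                           alternative = "two.sided") {
  aggregate <- match.arg(aggregate)
  cl <- as_clades(clades, unique(rates$sample))
  labs <- unique(cl)
  if (length(labs) != 2) abort("Exactly 2 clades are required.")
  vals <- if (aggregate == "strain_mean") {
    rates |>
      group_by(.data$sample, .data$condition) |>
      summarise(slope = mean(.data$slope), .groups = "drop")
  } else {
    select(rates, "sample", "condition", "slope")
  }
  vals$clade <- unname(cl[vals$sample])
  vals |>
    group_by(.data$condition) |>
    summarise({
      a <- .data$slope[.data$clade == labs[1]]
      b <- .data$slope[.data$clade == labs[2]]
      cmp <- compare_groups(a, b, alternative = alternative)
      mutate(cmp, clade_a = labs[1], clade_b = labs[2],
             mean_a = mean(a), mean_b = mean(b))
    }, .groups = "drop")
}
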