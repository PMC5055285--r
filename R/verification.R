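#' @importFrom stats sd
NULL

#' Bias, MAE and RMSE of paired daily maxima
#'
#' Bias follows the forecast-verification sign convention: predicted minus
#' observed, so a model that runs cold has negative bias.
#'
#' @param pairs A data frame with numeric columns `forecast_max` and
#'   `observed_max` (one row per paired day), as produced by
#'   [daily_max_pairs()].
#' @return A one-row tibble with columns `bias`, `mae`, `rmse` (degrees
#'   Celsius) and `n_days`.
#' @export
error_summaries <- function(pairs) {
  check_pairs(pairs)
  if (nrow(pairs) < 1L) stop("need at least one forecast/observation pair")
  d <- pairs$forecast_max - pairs$observed_max
  tibble::tibble(bias = mean(d),
                 mae = mean(abs(d)),
                 rmse = sqrt(mean(d^2)),
                 n_days = length(d))
}

check_pairs <- function(pairs) {
  if (!is.data.frame(pairs) ||
      !all(c("forecast_max", "observed_max") %in% names(pairs))) {
    stop("`pairs` must be a data frame with forecast_max and observed_max columns")
  }
  invisible(pairs)
}

#' Build a forecast-by-observation contingency table
#'
#' Counts paired daily maxima by thermal-performance category. Rows index the
#' forecast category and columns the observed category; the diagonal holds
#' hits.
#'
#' @inheritParams error_summaries
#' @param scheme A [category_scheme()].
#' @return A `contingency_table`: an integer k x k matrix with the scheme
#'   labels as dimnames and the scheme attached as an attribute.
#' @export
build_table <- function(pairs, scheme = category_scheme()) {
  check_pairs(pairs)
  k <- scheme$k
  f <- categorize(pairs$forecast_max, scheme)
  o <- categorize(pairs$observed_max, scheme)
  counts <- table(factor(f, levels = 0:(k - 1L)),
                  factor(o, levels = 0:(k - 1L)))
  m <- matrix(as.integer(counts), k, k,
              dimnames = list(forecast = scheme$labels,
                              observed = scheme$labels))
  as_contingency_table(m, scheme)
}

#' Coerce a count matrix to a contingency table
#'
#' @param counts Square matrix of non-negative counts, rows = forecast
#'   category, columns = observed category.
#' @param scheme Optional [category_scheme()] with matching `k`.
#' @return A `contingency_table` object.
#' @export
as_contingency_table <- function(counts, scheme = NULL) {
  counts <- as.matrix(counts)
  if (nrow(counts) != ncol(counts)) stop("contingency table must be square")
  if (any(counts < 0) || anyNA(counts)) stop("counts must be non-negative")
  structure(counts, class = c("contingency_table", class(counts)),
            scheme = scheme)
}

table_margins <- function(tab) {
  counts <- unclass(tab)
  list(counts = counts,
       n_forecast = rowSums(counts),
       n_observed = colSums(counts),
       N = sum(counts),
       k = nrow(counts))
}

#' Per-category hit rate
#'
#' Hits / (hits + misses) for each category: the fraction of observed events
#' in a category that were forecast in that category. Undefined (NA) when the
#' category was never observed.
#'
#' @param tab A `contingency_table`.
#' @param i Optional 0-based category index; default returns all categories.
#' @return Numeric in \[0, 1\] or NA; named vector when `i` is NULL.
#' @export
hit_rate <- function(tab, i = NULL) {
  m <- table_margins(tab)
  hr <- ifelse(m$n_observed > 0, diag(m$counts) / m$n_observed, NA_real_)
  names(hr) <- rownames(m$counts)
  if (is.null(i)) hr else unname(hr[i + 1L])
}

#' Per-category false-alarm ratio
#'
#' False alarms / (hits + false alarms) for each category: the fraction of
#' forecasts of a category that did not verify. Undefined (NA) when the
#' category was never forecast (division by zero, which does occur for rare
#' extreme categories).
#'
#' @inheritParams hit_rate
#' @return Numeric in \[0, 1\] or NA; named vector when `i` is NULL.
#' @export
false_alarm_ratio <- function(tab, i = NULL) {
  m <- table_margins(tab)
  far <- ifelse(m$n_forecast > 0,
                (m$n_forecast - diag(m$counts)) / m$n_forecast,
                NA_real_)
  names(far) <- rownames(m$counts)
  if (is.null(i)) far else unname(far[i + 1L])
}

#' Multicategory Heidke skill score
#'
#' Proportion of correct forecasts relative to the proportion expected from a
#' random forecast with the same marginal distributions. 1 is a perfect
#' forecast, 0 no skill; undefined (NA) when all mass sits in a single
#' forecast = observed category.
#'
#' @param tab A `contingency_table` with at least one count.
#' @return Numeric in \[-1, 1\], or NA when undefined.
#' @export
heidke <- function(tab) {
  m <- table_margins(tab)
  if (m$N < 1) stop("empty contingency table")
  pc <- sum(diag(m$counts)) / m$N
  e <- sum(m$n_forecast * m$n_observed) / m$N^2
  if (1 - e == 0) return(NA_real_)
  (pc - e) / (1 - e)
}

#' Multicategory Peirce (Hanssen-Kuipers) skill score
#'
#' Same numerator as the Heidke score but referenced to an unbiased random
#' forecast: the denominator uses the observed marginals only. For two
#' categories it reduces to hit rate minus false-alarm rate.
#'
#' @inheritParams heidke
#' @return Numeric in \[-1, 1\], or NA when undefined.
#' @export
peirce <- function(tab) {
  m <- table_margins(tab)
  if (m$N < 1) stop("empty contingency table")
  pc <- sum(diag(m$counts)) / m$N
  e <- sum(m$n_forecast * m$n_observed) / m$N^2
  d <- 1 - sum(m$n_observed^2) / m$N^2
  if (d == 0) return(NA_real_)
  (pc - e) / d
}

#' Gerrity equitable scoring matrix
#'
#' Builds the Gerrity (1992) scoring matrix from the observed category
#' relative frequencies `p_i = n(O_i) / N`. With `a_i = (1 - sum(p_1..p_i)) /
#' sum(p_1..p_i)` for i = 1..k-1, the symmetric matrix is
#' \deqn{s_{ii} = \frac{1}{k-1}\Big(\sum_{r<i} a_r^{-1} + \sum_{r=i}^{k-1} a_r\Big)}
#' \deqn{s_{ij} = \frac{1}{k-1}\Big(\sum_{r<i} a_r^{-1} - (j-i) + \sum_{r=j}^{k-1} a_r\Big), \quad i<j.}
#' Every row satisfies the equitability identity `sum_j p_j s_ij = 0`, so any
#' constant forecast scores exactly zero.
#'
#' @inheritParams heidke
#' @return A list with `p` (observed frequencies), `a` (odds ratios, length
#'   k - 1) and `s` (symmetric k x k scoring matrix).
#' @export
gerrity_matrix <- function(tab) {
  m <- table_margins(tab)
  if (m$N < 1) stop("empty contingency table")
  k <- m$k
  p <- m$n_observed / m$N
  cum <- cumsum(p)[-k]
  if (any(cum <= 0) || any(cum >= 1)) {
    stop("Gerrity score undefined: an observed category has zero cumulative ",
         "mass at one end of the scale; collapse empty categories and retry")
  }
  a <- (1 - cum) / cum
  s <- matrix(0, k, k)
  for (i in seq_len(k)) {
    for (j in i:k) {
      inv <- if (i > 1) sum(1 / a[seq_len(i - 1L)]) else 0
      tail <- if (j <= k - 1L) sum(a[j:(k - 1L)]) else 0
      s[i, j] <- (inv - (j - i) + tail) / (k - 1L)
      s[j, i] <- s[i, j]
    }
  }
  dimnames(s) <- dimnames(m$counts)
  list(p = p, a = a, s = s)
}

#' Gerrity equitable skill score
#'
#' `(1/N) * sum_ij n(F_i O_j) s_ij` with the scoring matrix of
#' [gerrity_matrix()]. 1 is a perfect forecast; constant and climatological
#' random forecasts score 0 by equitability.
#'
#' @inheritParams heidke
#' @return Numeric in \[-1, 1\].
#' @export
gerrity <- function(tab) {
  m <- table_margins(tab)
  g <- gerrity_matrix(tab)
  sum(m$counts * g$s) / m$N
}

#' Full skill report for one forecast/observation pairing
#'
#' Computes the continuous error summaries and the full categorical
#' verification suite for a set of paired daily maxima. Undefined statistics
#' (never-observed or never-forecast categories, Gerrity with empty tail
#' categories) are reported as NA, never as 0.
#'
#' @inheritParams error_summaries
#' @param scheme A [category_scheme()].
#' @return A list of class `skill_report` with elements `n_days`, `bias`,
#'   `mae`, `rmse`, `hit_rate` and `false_alarm_ratio` (named per-category
#'   vectors), `heidke`, `peirce`, `gerrity` and the underlying `table`.
#' @export
skill_report <- function(pairs, scheme = category_scheme()) {
  err <- error_summaries(pairs)
  tab <- build_table(pairs, scheme)
  structure(list(
    n_days = err$n_days,
    bias = err$bias, mae = err$mae, rmse = err$rmse,
    hit_rate = hit_rate(tab),
    false_alarm_ratio = false_alarm_ratio(tab),
    heidke = heidke(tab),
    peirce = peirce(tab),
    gerrity = tryCatch(gerrity(tab), error = function(e) NA_real_),
    table = tab
  ), class = "skill_report")
}

#' @export
print.skill_report <- function(x, ...) {
  cat(sprintf("Skill report over %d paired days\n", x$n_days))
  cat(sprintf("  bias %+.2f  MAE %.2f  RMSE %.2f degC\n", x$bias, x$mae, x$rmse))
  cat(sprintf("  Heidke %s  Peirce %s  Gerrity %s\n",
              fmt_score(x$heidke), fmt_score(x$peirce), fmt_score(x$gerrity)))
  cat("  hit rate:          ", paste(fmt_score(x$hit_rate), collapse = " "), "\n")
  cat("  false-alarm ratio: ", paste(fmt_score(x$false_alarm_ratio), collapse = " "), "\n")
  invisible(x)
}

fmt_score <- function(v) ifelse(is.na(v), "NA", sprintf("%.2f", v))

#' Flatten a skill report to a one-row tibble
#'
#' Per-category hit rates and false-alarm ratios become columns `hr_0` ...
#' and `far_0` ... indexed by 0-based category.
#'
#' @param x A `skill_report`.
#' @return A one-row tibble.
#' @export
skill_report_row <- function(x) {
  stopifnot(inherits(x, "skill_report"))
  k <- length(x$hit_rate)
  row <- tibble::tibble(n_days = x$n_days, bias = x$bias, mae = x$mae,
                        rmse = x$rmse, heidke = x$heidke, peirce = x$peirce,
                        gerrity = x$gerrity)
  hr <- as.list(unname(x$hit_rate))
  names(hr) <- paste0("hr_", seq_len(k) - 1L)
  far <- as.list(unname(x$false_alarm_ratio))
  names(far) <- paste0("far_", seq_len(k) - 1L)
  dplyr::bind_cols(row, tibble::as_tibble(hr), tibble::as_tibble(far))
}

#' Inter-logger skill baseline
#'
#' Treats each logger at a site as a "forecast" of every other logger, giving
#' a field-variability benchmark: a model whose scores match the inter-logger
#' scores is as useful as deploying one more logger.
#'
#' @param loggers A list of at least two hourly body-temperature tibbles with
#'   columns `time` and `body_temp` on a common time base.
#' @param emersed Logical emersion mask aligned with the common time base.
#' @param utc_offset Hours to add to UTC for the site-local calendar day.
#' @param scheme A [category_scheme()].
#' @return A tibble with one row per ordered logger pair: `forecast_logger`,
#'   `observed_logger`, and the flattened skill-report columns.
#' @export
interlogger_baseline <- function(loggers, emersed, utc_offset = 0,
                                 scheme = category_scheme()) {
  if (length(loggers) < 2L) stop("need at least two loggers")
  ids <- names(loggers)
  if (is.null(ids)) ids <- as.character(seq_along(loggers))
  rows <- list()
  for (i in seq_along(loggers)) {
    for (j in seq_along(loggers)) {
      if (i == j) next
      pairs <- daily_max_pairs(loggers[[i]]$time,
                               loggers[[i]]$body_temp,
                               loggers[[j]]$body_temp,
                               emersed, utc_offset)
      if (nrow(pairs) == 0L) next
      rep_ij <- skill_report(pairs, scheme)
      rows[[length(rows) + 1L]] <- dplyr::bind_cols(
        tibble::tibble(forecast_logger = ids[i], observed_logger = ids[j]),
        skill_report_row(rep_ij))
    }
  }
  dplyr::bind_rows(rows)
}

#' Cross-site summary: unweighted mean and sample SD
#'
#' The summary used for the "Average" and "SD" columns of per-site score
#' tables: plain unweighted mean over sites and the sample (n - 1) standard
#' deviation. NAs are dropped.
#'
#' @param values Numeric per-site values (>= 1 for the mean, >= 2 for the SD).
#' @return Named numeric vector `c(mean = , sd = )`; `sd` is NA with a single
#'   value.
#' @export
summarize_across_sites <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) < 1L) stop("need at least one value")
  c(mean = mean(values),
    sd = if (length(values) >= 2L) stats::sd(values) else NA_real_)
}
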