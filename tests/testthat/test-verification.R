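hand_table <- function() {
  as_contingency_table(matrix(c(3, 1, 0,
                                1, 4, 1,
                                0, 1, 3), 3, 3, byrow = TRUE))
}

test_that("error summaries follow the predicted-minus-observed convention", {
  perfect <- tibble::tibble(forecast_max = c(10, 20), observed_max = c(10, 20))
  expect_equal(unlist(error_summaries(perfect)[, c("bias", "mae", "rmse")]),
               c(bias = 0, mae = 0, rmse = 0))
  pm1 <- tibble::tibble(forecast_max = c(11, 19), observed_max = c(10, 20))
  e <- error_summaries(pm1)
  expect_equal(c(e$bias, e$mae, e$rmse), c(0, 1, 1))
  cold <- tibble::tibble(forecast_max = c(8, 6), observed_max = c(10, 10))
  expect_equal(error_summaries(cold)$bias, -3)  # model runs cold
  expect_error(error_summaries(tibble::tibble(forecast_max = numeric(),
                                              observed_max = numeric())),
               "at least one")
})

test_that("contingency tables count category pairs correctly", {
  sch <- category_scheme()
  empty <- build_table(tibble::tibble(forecast_max = numeric(),
                                      observed_max = numeric()), sch)
  expect_equal(sum(empty), 0)
  expect_equal(dim(empty), c(7L, 7L))

  all3 <- build_table(tibble::tibble(forecast_max = rep(18, 5),
                                     observed_max = rep(19, 5)), sch)
  expect_equal(unclass(all3)[4, 4], 5L)

  # five hand-listed pairs, verified by direct counting
  pairs <- tibble::tibble(forecast_max = c(18, 25, 25, 5, 40),
                          observed_max = c(19, 18, 33, 5, 36))
  tab <- build_table(pairs, sch)
  expect_equal(sum(tab), 5)
  expect_equal(unclass(tab)[4, 4], 1L)  # (18, 19) optimal hit
  expect_equal(unclass(tab)[5, 4], 1L)  # 25 forecast vs 18 observed
  expect_equal(unclass(tab)[5, 6], 1L)  # 25 vs 33
  expect_equal(unclass(tab)[2, 2], 1L)  # 5 vs 5
  expect_equal(unclass(tab)[7, 6], 1L)  # 40 vs 36
})

test_that("hit rate and false-alarm ratio match counting, with NA when undefined", {
  tab <- hand_table()
  expect_equal(hit_rate(tab, 1), 4 / 6, tolerance = 1e-12)
  expect_equal(false_alarm_ratio(tab, 1), 2 / 6, tolerance = 1e-12)

  perfect <- as_contingency_table(diag(c(2, 3, 0)))
  expect_equal(unname(hit_rate(perfect)), c(1, 1, NA))
  expect_equal(unname(false_alarm_ratio(perfect)), c(0, 0, NA))

  # empty forecast row -> undefined false-alarm ratio (division by zero)
  t2 <- as_contingency_table(matrix(c(0, 0, 3, 4), 2, 2, byrow = TRUE))
  expect_true(is.na(false_alarm_ratio(t2, 0)))
  # empty observed column -> undefined hit rate
  expect_true(is.na(hit_rate(as_contingency_table(matrix(c(1, 1, 0, 0), 2, 2)), 1)))
})

test_that("Heidke and Peirce reproduce hand-worked values and limits", {
  tab <- hand_table()
  expect_equal(heidke(tab), 0.5625, tolerance = 1e-12)
  # forecast and observed marginals coincide here, so Peirce equals Heidke
  expect_equal(peirce(tab), 0.5625, tolerance = 1e-12)

  perfect <- as_contingency_table(diag(c(4, 6, 4)))
  expect_equal(heidke(perfect), 1)
  expect_equal(peirce(perfect), 1)

  # exact independence: counts[i,j] = n(F_i) n(O_j) / N
  nf <- c(10, 20, 10); no <- c(8, 24, 8)
  indep <- as_contingency_table(outer(nf, no) / sum(nf))
  expect_equal(heidke(indep), 0, tolerance = 1e-12)
  expect_equal(peirce(indep), 0, tolerance = 1e-12)

  expect_error(heidke(as_contingency_table(matrix(0, 2, 2))), "empty")
  # all mass in one matched category -> undefined
  degenerate <- as_contingency_table(matrix(c(5, 0, 0, 0), 2, 2))
  expect_true(is.na(heidke(degenerate)))
  expect_true(is.na(peirce(degenerate)))
})

test_that("two-category Peirce equals hit rate minus false-alarm rate", {
  set.seed(11)
  for (rep in 1:20) {
    counts <- random_table(k = 2, max_count = 5)
    tab <- as_contingency_table(counts)
    # false-alarm *rate* for the event category (1): forecasts of the event
    # among non-events, divided by non-events
    h <- counts[1, 1] / sum(counts[, 1])
    f <- counts[1, 2] / sum(counts[, 2])
    expect_equal(peirce(tab), h - f, tolerance = 1e-12)
  }
})

test_that("Gerrity matrix matches the hand-worked example and closed forms", {
  tab <- hand_table()  # observed marginal (4, 6, 4) / 14
  g <- gerrity_matrix(tab)
  expect_equal(g$a, c(2.5, 0.4), tolerance = 1e-12)
  expect_equal(diag(g$s), c(1.45, 0.4, 1.45), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(g$s[1, 2], -0.3, tolerance = 1e-12)
  expect_equal(g$s[1, 3], -1, tolerance = 1e-12)
  expect_equal(g$s[2, 3], -0.3, tolerance = 1e-12)
  expect_equal(g$s, t(g$s))

  expect_equal(gerrity(tab), 0.65, tolerance = 1e-12)
  perfect <- as_contingency_table(diag(c(4, 6, 4)))
  expect_equal(gerrity(perfect), 1, tolerance = 1e-12)

  # uniform two-category closed form
  u2 <- as_contingency_table(matrix(c(3, 2, 2, 3), 2, 2))
  g2 <- gerrity_matrix(u2)
  expect_equal(g2$a, 1)
  expect_equal(unname(g2$s), matrix(c(1, -1, -1, 1), 2, 2))
})

test_that("Gerrity is equitable and errors on empty tail categories", {
  set.seed(7)
  for (rep in 1:50) {
    tab <- as_contingency_table(random_table())
    g <- gerrity_matrix(tab)
    expect_equal(max(abs(g$s %*% g$p)), 0, tolerance = 1e-10)
    # any constant forecast scores zero
    k <- nrow(tab); i <- sample(k, 1)
    const <- matrix(0, k, k); const[i, ] <- colSums(unclass(tab))
    expect_equal(gerrity(as_contingency_table(const)), 0, tolerance = 1e-10)
  }
  empty_first <- as_contingency_table(matrix(c(0, 0, 1, 3), 2, 2))
  expect_error(gerrity(empty_first), "collapse")
})

test_that("all five statistics agree with brute-force per-event oracles", {
  set.seed(123)
  for (rep in 1:300) {
    counts <- random_table()
    tab <- as_contingency_table(counts)
    k <- nrow(counts)
    for (i in seq_len(k)) {
      expect_equal(hit_rate(tab, i - 1L), oracle_hit_rate(counts, i),
                   tolerance = 1e-12)
      expect_equal(false_alarm_ratio(tab, i - 1L), oracle_far(counts, i),
                   tolerance = 1e-12)
    }
    expect_equal(heidke(tab), oracle_heidke(counts), tolerance = 1e-12)
    expect_equal(peirce(tab), oracle_peirce(counts), tolerance = 1e-12)
    expect_equal(gerrity(tab), oracle_gerrity(counts), tolerance = 1e-12)
  }
})

test_that("scores stay in [-1, 1] and Heidke = Peirce on matched marginals", {
  set.seed(31)
  for (rep in 1:200) {
    tab <- as_contingency_table(random_table())
    for (s in c(heidke(tab), peirce(tab), gerrity(tab))) {
      if (!is.na(s)) expect_true(s >= -1 - 1e-12 && s <= 1 + 1e-12)
    }
    # symmetrize to force equal forecast and observed marginals
    m <- unclass(tab) + t(unclass(tab))
    mt <- as_contingency_table(m)
    expect_equal(heidke(mt), peirce(mt), tolerance = 1e-12)
  }
})

test_that("interlogger baseline reproduces constant-shift arithmetic and antisymmetry", {
  time <- seq(as.POSIXct("2003-06-01", tz = "UTC"), by = 3600,
              length.out = 24 * 10)
  base <- 15 + 8 * sin(seq_along(time) / 5)
  loggers <- list(a = tibble::tibble(time = time, body_temp = base),
                  b = tibble::tibble(time = time, body_temp = base + 2))
  emersed <- rep(TRUE, length(time))
  out <- interlogger_baseline(loggers, emersed, utc_offset = 0)
  ab <- out[out$forecast_logger == "a", ]
  ba <- out[out$forecast_logger == "b", ]
  expect_equal(ab$bias, -2)
  expect_equal(ab$mae, 2)
  expect_equal(ab$rmse, 2)
  expect_equal(ba$bias, 2)  # role reversal negates bias exactly
  # identical loggers: perfect scores, zero errors
  same <- interlogger_baseline(list(a = loggers$a, b = loggers$a),
                               emersed, utc_offset = 0)
  expect_equal(same$bias, c(0, 0))
  expect_equal(same$heidke, c(1, 1))
  expect_error(interlogger_baseline(loggers[1], emersed), "two loggers")
})

test_that("cross-site summaries are the unweighted mean and sample SD", {
  s <- summarize_across_sites(c(1, 2, 3))
  expect_equal(unname(s), c(2, 1))
  expect_equal(unname(summarize_across_sites(rep(4, 3)))[2], 0)
  expect_true(is.na(summarize_across_sites(5)["sd"]))
  expect_error(summarize_across_sites(NA_real_), "at least one")
})
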