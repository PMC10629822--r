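mat_of <- function(m, ids = sprintf("e%d", seq_len(nrow(m)))) {
  tibble::as_tibble(m, .name_repair = "minimal") |>
    stats::setNames(sprintf("s%d", seq_len(ncol(m)))) |>
    dplyr::mutate(event_id = ids, .before = 1)
}

test_that("log transform applies the pseudocount and keeps missingness", {
  m <- mat_of(matrix(c(0, 0.3, NA, 1), nrow = 2))
  out <- transform_psi(m, x = 1)
  expect_equal(out$s1[1], 0)               # log(0 + 1)
  out2 <- transform_psi(m, x = 0.01)
  expect_equal(out2$s1[2], log(0.31), tolerance = 1e-12)
  expect_true(is.na(out2$s2[1]))
  expect_error(transform_psi(m, x = 0), "positive")
  expect_error(transform_psi(m, x = -1), "positive")
  expect_error(transform_psi(mat_of(matrix(2, 1, 1))), "\\[0, 1\\]")
})

test_that("invariant events are removed and missing values mean-imputed", {
  m <- mat_of(rbind(
    c(0.5, 0.5, 0.5),     # invariant -> dropped
    c(0.1, NA, 0.3),      # NA -> 0.2
    c(NA, NA, NA)         # all missing -> dropped
  ))
  out <- filter_and_impute(m)
  expect_equal(out$event_id, "e2")
  expect_equal(out$s2, 0.2)
})

test_that("standardization yields zero mean and unit population SD per event", {
  m <- mat_of(matrix(c(1, 2, 3), nrow = 1))
  out <- standardize(m)
  expect_equal(unlist(out[1, -1], use.names = FALSE),
               c(-1.2247449, 0, 1.2247449), tolerance = 1e-6)

  set.seed(1)
  r <- mat_of(matrix(runif(50), nrow = 5))
  sr <- as.matrix(standardize(r)[, -1])
  expect_true(all(abs(rowMeans(sr)) < 1e-12))
  expect_true(all(abs(sqrt(rowMeans(sr^2)) - 1) < 1e-12))

  expect_error(standardize(mat_of(matrix(c(1, 1, 1), 1))), "zero-variance")
  expect_error(standardize(mat_of(matrix(c(1, NA, 3), 1))), "complete")
})

test_that("pooled t-test matches the textbook computation", {
  # 3 WT vs 4 MUT, one informative event
  wt <- c(0.10, 0.12, 0.08)
  mut <- c(0.35, 0.42, 0.38, 0.31)
  m <- mat_of(matrix(c(wt, mut), nrow = 1), ids = "ev")
  groups <- stats::setNames(rep(c("WT", "MUT"), c(3, 4)),
                            sprintf("s%d", 1:7))
  fit <- differential_test(m, groups, diff_config())
  res <- tidy(fit)

  z <- log(c(wt, mut) + 0.01)
  z <- (z - mean(z)) / sqrt(mean((z - mean(z))^2))
  oracle <- stats::t.test(z[4:7], z[1:3], var.equal = TRUE)
  expect_equal(res$t, unname(oracle$statistic), tolerance = 1e-12)
  expect_equal(res$p, oracle$p.value, tolerance = 1e-12)
  expect_equal(res$delta_psi, mean(mut) - mean(wt), tolerance = 1e-12)
  expect_equal(res$n_wt, 3L)
  expect_equal(res$n_mut, 4L)

  welch <- tidy(differential_test(m, groups, diff_config(test = "welch")))
  oracle_w <- stats::t.test(z[4:7], z[1:3], var.equal = FALSE)
  expect_equal(welch$p, oracle_w$p.value, tolerance = 1e-12)
})

test_that("classic two-sample example reproduces the closed-form t", {
  # raw two-group t on [1,2,3] vs [4,5,6]: |t| = 3.674, p ~ 0.0212
  tt <- stats::t.test(c(4, 5, 6), c(1, 2, 3), var.equal = TRUE)
  expect_equal(unname(tt$statistic), 3.6742346, tolerance = 1e-6)
  expect_equal(tt$p.value, 2 * stats::pt(-3.6742346, df = 4), tolerance = 1e-6)
  # the pipeline's standardization leaves the t statistic untouched
  z <- c(1, 2, 3, 4, 5, 6)
  z <- (z - mean(z)) / sqrt(mean((z - mean(z))^2))
  tz <- stats::t.test(z[4:6], z[1:3], var.equal = TRUE)
  expect_equal(tz$statistic, tt$statistic, tolerance = 1e-9)
})

test_that("standardization leaves every t statistic unchanged", {
  # the per-event standardization is affine, so t on standardized values
  # equals t on the transformed values
  set.seed(42)
  raw <- matrix(runif(7 * 20, 0, 0.6), nrow = 20)
  m <- mat_of(raw)
  groups <- rep(c("WT", "MUT"), c(3, 4))
  fit <- tidy(differential_test(m, stats::setNames(groups, sprintf("s%d", 1:7))))
  trans <- as.matrix(transform_psi(m, 0.01)[, -1])
  t_direct <- apply(trans, 1, function(row) {
    unname(stats::t.test(row[groups == "MUT"], row[groups == "WT"],
                         var.equal = TRUE)$statistic)
  })
  expect_equal(fit$t, unname(t_direct), tolerance = 1e-9)
})

test_that("events with under two observations per group get missing p", {
  raw <- rbind(
    c(NA, NA, 0.1, 0.4, 0.45, 0.5, 0.2),
    c(0.1, 0.2, 0.15, 0.4, 0.45, 0.5, 0.2)
  )
  m <- mat_of(raw)
  groups <- stats::setNames(rep(c("WT", "MUT"), c(3, 4)), sprintf("s%d", 1:7))
  expect_message(fit <- differential_test(m, groups), "fewer than 2")
  res <- tidy(fit)
  expect_true(is.na(res$p[res$event_id == "e1"]))
  expect_false(res$significant[res$event_id == "e1"])
  expect_false(is.na(res$p[res$event_id == "e2"]))
})

test_that("significance thresholds follow the preset rules", {
  res <- tibble::tibble(
    event_id = c("a", "b", "c"),
    delta_psi = c(0.15, 0.15, 0.05),
    p = c(0.005, 0.02, 1e-12)
  )
  res$p_adj <- stats::p.adjust(res$p, "BH")
  out <- apply_thresholds(res, diff_config())
  expect_equal(out$significant, c(TRUE, FALSE, FALSE))
  # pan-cancer preset: tiny p but small effect still fails the PSI bound
  out2 <- apply_thresholds(res, diff_config(preset = "pan_cancer"))
  expect_equal(out2$significant[3], FALSE)
  expect_equal(diff_config(preset = "pan_cancer")$p_max, 1e-10)
  expect_equal(diff_config(preset = "pan_cancer")$delta_psi_min, 0.05)
})

test_that("BH adjustment matches p.adjust and can gate significance", {
  set.seed(7)
  raw <- matrix(runif(7 * 30, 0, 0.8), nrow = 30)
  m <- mat_of(raw)
  groups <- stats::setNames(rep(c("WT", "MUT"), c(3, 4)), sprintf("s%d", 1:7))
  res <- tidy(differential_test(m, groups, diff_config(adjust = "BH", p_max = 0.05)))
  expect_equal(res$p_adj, stats::p.adjust(res$p, "BH"))
  expect_true(all(res$p_adj[res$significant] < 0.05))
})

test_that("tidy and glance summarize the fit", {
  co <- tiny_cohort()
  ev <- suppressMessages(detect_events(co$junctions, co$models))
  m <- psi_matrix(compute_psi(ev, co$junctions, samples = co$samples$sample_id))
  fit <- differential_test(m, co$samples)
  expect_s3_class(tidy(fit), "tbl_df")
  g <- glance(fit)
  expect_equal(g$n_events, nrow(tidy(fit)))
  expect_equal(g$n_significant, sum(tidy(fit)$significant))
  p <- ggplot2::autoplot(fit)
  expect_s3_class(p, "ggplot")
})
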