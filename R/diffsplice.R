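#' Differential-splicing configuration
#'
#' @param pseudocount Pseudocount `x` of the `log(PSI + x)` transform
#'   (default 0.01).
#' @param min_coverage Total-read floor below which PSI is missing
#'   (default 10).
#' @param delta_psi_min Minimum absolute group difference in mean PSI for a
#'   significant call (default 0.1).
#' @param p_max Maximum p-value for a significant call (default 0.01).
#' @param test `"pooled"` (pooled-variance two-sample t-test, default) or
#'   `"welch"`.
#' @param adjust `"none"` (raw p-values gate significance, default) or
#'   `"BH"` (Benjamini-Hochberg adjusted p-values gate significance;
#'   adjusted values are always reported either way).
#' @param preset Optional threshold preset: `"mouse_kpc"` sets
#'   `(delta_psi_min, p_max) = (0.1, 0.01)`, `"pan_cancer"` sets
#'   `(0.05, 1e-10)`. Explicit arguments win over the preset.
#' @return A list of class `cryptsplice_diff_config`.
#' @export
diff_config <- function(pseudocount = 0.01,
                        min_coverage = 10,
                        delta_psi_min = NULL,
                        p_max = NULL,
                        test = c("pooled", "welch"),
                        adjust = c("none", "BH"),
                        preset = c("mouse_kpc", "pan_cancer")) {
  preset <- match.arg(preset)
  defaults <- switch(preset,
                     mouse_kpc = c(delta = 0.1, p = 0.01),
                     pan_cancer = c(delta = 0.05, p = 1e-10))
  cfg <- list(
    pseudocount = pseudocount,
    min_coverage = as.integer(min_coverage),
    delta_psi_min = delta_psi_min %||% unname(defaults["delta"]),
    p_max = p_max %||% unname(defaults["p"]),
    test = match.arg(test),
    adjust = match.arg(adjust),
    preset = preset
  )
  if (cfg$pseudocount <= 0) {
    stop("pseudocount must be positive", call. = FALSE)
  }
  if (cfg$delta_psi_min <= 0 || cfg$delta_psi_min >= 1 ||
      cfg$p_max <= 0 || cfg$p_max >= 1) {
    stop("thresholds must lie in (0, 1)", call. = FALSE)
  }
  structure(cfg, class = "cryptsplice_diff_config")
}

as_value_matrix <- function(matrix) {
  stopifnot("event_id" %in% names(matrix))
  m <- as.matrix(matrix[, setdiff(names(matrix), "event_id"), drop = FALSE])
  rownames(m) <- matrix$event_id
  storage.mode(m) <- "double"
  m
}

as_psi_tibble <- function(m) {
  tibble::as_tibble(m, rownames = "event_id")
}

#' Log-transform a PSI matrix
#'
#' Applies `value -> log(value + x)` (natural log) cell-wise; missing values
#' stay missing.
#'
#' @param matrix Wide PSI tibble (`event_id` plus sample columns).
#' @param x Positive pseudocount.
#' @return The transformed wide tibble.
#' @export
transform_psi <- function(matrix, x = 0.01) {
  if (!is.numeric(x) || length(x) != 1 || x <= 0) {
    stop("pseudocount x must be a positive number", call. = FALSE)
  }
  m <- as_value_matrix(matrix)
  if (any(m < 0 | m > 1, na.rm = TRUE)) {
    stop("PSI values must lie in [0, 1]", call. = FALSE)
  }
  as_psi_tibble(log(m + x))
}

#' Remove invariant events and mean-impute missing values
#'
#' Events whose observed values are all equal (zero variance) or all missing
#' are removed; remaining missing cells are set to the event-wise mean of the
#' observed values across all samples.
#'
#' @param matrix Wide (transformed) PSI tibble.
#' @return The filtered, imputed wide tibble.
#' @export
filter_and_impute <- function(matrix) {
  m <- as_value_matrix(matrix)
  n_obs <- rowSums(!is.na(m))
  v <- apply(m, 1, stats::var, na.rm = TRUE)
  keep <- n_obs > 0 & !is.na(v) & v > 0
  m <- m[keep, , drop = FALSE]
  if (nrow(m) > 0) {
    means <- rowMeans(m, na.rm = TRUE)
    idx <- which(is.na(m), arr.ind = TRUE)
    if (nrow(idx)) m[idx] <- means[idx[, 1]]
  }
  as_psi_tibble(m)
}

#' Standardize each event row to mean 0 and unit population SD
#'
#' @param matrix Wide tibble with no missing values
#'   (after [filter_and_impute()]).
#' @return The standardized wide tibble.
#' @export
standardize <- function(matrix) {
  m <- as_value_matrix(matrix)
  if (anyNA(m)) {
    stop("standardize() expects a complete matrix; run filter_and_impute() first",
         call. = FALSE)
  }
  mu <- rowMeans(m)
  sdev <- sqrt(rowMeans((m - mu)^2))
  if (any(sdev == 0)) {
    stop("zero-variance row survived filtering: ",
         rownames(m)[sdev == 0][1], call. = FALSE)
  }
  as_psi_tibble((m - mu) / sdev)
}

two_sample_t <- function(x, y, pooled = TRUE) {
  nx <- length(x); ny <- length(y)
  if (pooled) {
    sp2 <- ((nx - 1) * stats::var(x) + (ny - 1) * stats::var(y)) / (nx + ny - 2)
    t <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / nx + 1 / ny))
    df <- nx + ny - 2
  } else {
    vx <- stats::var(x) / nx; vy <- stats::var(y) / ny
    t <- (mean(x) - mean(y)) / sqrt(vx + vy)
    df <- (vx + vy)^2 / (vx^2 / (nx - 1) + vy^2 / (ny - 1))
  }
  c(t = t, p = 2 * stats::pt(-abs(t), df))
}

#' Test events for differential splicing between genotype groups
#'
#' Runs the full statistic: `log(PSI + x)` transform, removal of invariant
#' events, event-wise mean imputation of missing values, per-event
#' standardization, then a two-sided two-sample t-test (WT vs MUT) on the
#' standardized values. The effect size `delta_psi` is computed on the raw
#' PSI scale from observed (non-imputed) values as `mean(MUT) - mean(WT)`.
#' Events with fewer than two observed values in either group get a missing
#' p-value and are never called significant.
#'
#' @param matrix Wide PSI tibble on the raw scale (`event_id` + samples).
#' @param groups Named character vector or sample-sheet tibble mapping
#'   `sample_id` to `"WT"`/`"MUT"`.
#' @param config A [diff_config()].
#' @return An object of class `cryptsplice_diff`: a list with `results`
#'   (tibble: `event_id`, `n_wt`, `n_mut`, `delta_psi`, `t`, `p`, `p_adj`,
#'   `significant`), `config`, and the intermediate `standardized` matrix.
#' @export
differential_test <- function(matrix, groups, config = diff_config()) {
  if (inherits(groups, "data.frame")) {
    groups <- stats::setNames(groups$group, groups$sample_id)
  }
  raw <- as_value_matrix(matrix)
  sample_ids <- colnames(raw)
  if (!all(sample_ids %in% names(groups))) {
    stop("group labels missing for sample(s): ",
         paste(setdiff(sample_ids, names(groups)), collapse = ", "),
         call. = FALSE)
  }
  grp <- unname(groups[sample_ids])
  if (sum(grp == "WT") < 2 || sum(grp == "MUT") < 2) {
    stop("differential testing needs at least 2 samples per group", call. = FALSE)
  }

  std <- matrix |>
    transform_psi(x = config$pseudocount) |>
    filter_and_impute() |>
    standardize()
  sm <- as_value_matrix(std)
  raw <- raw[rownames(sm), , drop = FALSE]

  wt <- grp == "WT"; mut <- grp == "MUT"
  n_wt <- rowSums(!is.na(raw[, wt, drop = FALSE]))
  n_mut <- rowSums(!is.na(raw[, mut, drop = FALSE]))
  delta <- rowMeans(raw[, mut, drop = FALSE], na.rm = TRUE) -
    rowMeans(raw[, wt, drop = FALSE], na.rm = TRUE)

  tp <- t(apply(sm, 1, function(row) {
    two_sample_t(row[mut], row[wt], pooled = config$test == "pooled")
  }))
  p <- tp[, "p"]
  underpowered <- n_wt < 2 | n_mut < 2
  if (any(underpowered)) {
    message(sum(underpowered),
            " event(s) with fewer than 2 observed values in a group; p set missing")
    p[underpowered] <- NA_real_
  }
  res <- tibble::tibble(
    event_id = rownames(sm),
    n_wt = as.integer(n_wt),
    n_mut = as.integer(n_mut),
    delta_psi = unname(delta),
    t = unname(tp[, "t"]),
    p = unname(p),
    p_adj = stats::p.adjust(p, method = "BH")
  )
  res <- apply_thresholds(res, config)
  structure(list(results = res, config = config, standardized = std),
            class = "cryptsplice_diff")
}

#' Apply significance thresholds to differential-splicing results
#'
#' An event is significant when `|delta_psi| > delta_psi_min` and its
#' p-value (BH-adjusted when `adjust = "BH"`) is below `p_max`. The default
#' preset uses the murine cohort thresholds (0.1, 0.01); the pan-cancer
#' preset uses (0.05, 1e-10).
#'
#' @param results Results tibble (from [differential_test()], or its `results`
#'   element).
#' @param config A [diff_config()].
#' @return The results tibble with a recomputed `significant` column.
#' @export
apply_thresholds <- function(results, config = diff_config()) {
  if (inherits(results, "cryptsplice_diff")) results <- results$results
  p_gate <- if (config$adjust == "BH") results$p_adj else results$p
  results$significant <- !is.na(p_gate) &
    abs(results$delta_psi) > config$delta_psi_min &
    p_gate < config$p_max
  results
}

#' @export
print.cryptsplice_diff <- function(x, ...) {
  cat("<cryptsplice differential splicing result>\n")
  cat(sprintf("  %d events tested, %d significant (|dPSI| > %g, p%s < %g, %s t-test)\n",
              nrow(x$results), sum(x$results$significant),
              x$config$delta_psi_min,
              if (x$config$adjust == "BH") "_adj" else "",
              x$config$p_max, x$config$test))
  invisible(x)
}

#' Tidy a differential-splicing fit
#'
#' @param x A `cryptsplice_diff` object.
#' @param ... Unused.
#' @return The per-event results tibble.
#' @export
tidy.cryptsplice_diff <- function(x, ...) x$results

#' One-row summary of a differential-splicing fit
#'
#' @param x A `cryptsplice_diff` object.
#' @param ... Unused.
#' @return A one-row tibble: events tested, significant calls, thresholds.
#' @export
glance.cryptsplice_diff <- function(x, ...) {
  tibble::tibble(
    n_events = nrow(x$results),
    n_significant = sum(x$results$significant),
    delta_psi_min = x$config$delta_psi_min,
    p_max = x$config$p_max,
    test = x$config$test,
    adjust = x$config$adjust
  )
}
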