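mwu_u_from_ranks <- function(pooled, n_a) {
  r <- rank(pooled)  # midranks handle ties
  sum(r[seq_len(n_a)]) - n_a * (n_a + 1) / 2
}

#' Mann-Whitney U test
#'
#' Two-sided Mann-Whitney U (Wilcoxon rank-sum) test for two independent
#' samples, the standard choice for small-cohort comparisons where normality
#' cannot be assumed. Ties contribute 1/2 to the U statistic (midranks).
#'
#' The exact two-sided p-value is computed by full enumeration of the
#' permutation distribution of U over all `choose(n_a + n_b, n_a)` group
#' labelings (valid with ties), used in `"auto"` mode when
#' `n_a + n_b <= exact_limit`; larger samples use the tie-corrected normal
#' approximation with continuity correction. The reported statistic follows
#' the `min(U_A, U_B)` convention.
#'
#' @param a,b Numeric samples (non-empty).
#' @param mode `"auto"` (default), `"exact"` or `"normal_approx"`.
#' @param exact_limit Largest `n_a + n_b` for which auto mode enumerates.
#' @return An object of class `mwu_test`: a list with `statistic`
#'   (min(U_A, U_B)), `u_a`, `u_b`, `p_value`, `n_a`, `n_b`, `mode_used` and
#'   `degenerate` (TRUE when all pooled values are identical, in which case
#'   p = 1). Has [tidy()] and [glance()] methods.
#' @examples
#' mwu_test(c(1, 2, 3), c(4, 5, 6)) # U = 0, exact two-sided p = 0.1
#' @export
mwu_test <- function(a, b, mode = c("auto", "exact", "normal_approx"),
                     exact_limit = 16) {
  mode <- match.arg(mode)
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) == 0 || length(b) == 0) abort("both samples must be non-empty")
  if (any(!is.finite(c(a, b)))) abort("samples must be finite")
  n_a <- length(a); n_b <- length(b); n <- n_a + n_b
  pooled <- c(a, b)
  u_a <- mwu_u_from_ranks(pooled, n_a)
  u_b <- n_a * n_b - u_a
  mu <- n_a * n_b / 2

  degenerate <- length(unique(pooled)) == 1
  use_exact <- switch(mode,
    exact = TRUE,
    normal_approx = FALSE,
    auto = n <= exact_limit
  )

  if (degenerate) {
    p <- 1
    mode_used <- "degenerate"
  } else if (use_exact) {
    labelings <- combn(n, n_a)
    r <- rank(pooled)
    offset <- n_a * (n_a + 1) / 2
    u_all <- colSums(matrix(r[labelings], nrow = n_a)) - offset
    obs <- abs(u_a - mu)
    p <- mean(abs(u_all - mu) >= obs - 1e-9)
    mode_used <- "exact"
  } else {
    ties <- table(pooled)
    tie_term <- sum(ties^3 - ties) / (n * (n - 1))
    sigma2 <- n_a * n_b / 12 * ((n + 1) - tie_term)
    if (sigma2 <= 0) {
      p <- 1
      mode_used <- "degenerate"
    } else {
      z <- (u_a - mu - sign(u_a - mu) * 0.5) / sqrt(sigma2)
      p <- min(1, 2 * pnorm(-abs(z)))
      mode_used <- "normal_approx"
    }
  }

  structure(
    list(
      statistic = min(u_a, u_b), u_a = u_a, u_b = u_b, p_value = p,
      n_a = n_a, n_b = n_b, mode_used = mode_used, degenerate = degenerate,
      method = "Mann-Whitney U test (two-sided)"
    ),
    class = "mwu_test"
  )
}

#' @export
print.mwu_test <- function(x, ...) {
  cat(x$method, "\n")
  cat(sprintf("U = %g (U_A = %g, U_B = %g), n = %d vs %d, p = %.4g [%s]\n",
              x$statistic, x$u_a, x$u_b, x$n_a, x$n_b, x$p_value, x$mode_used))
  if (x$degenerate) cat("note: all pooled values identical (degenerate)\n")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a Mann-Whitney U test
#'
#' @param x An `mwu_test` object.
#' @param ... Unused.
#' @return A one-row tibble with `statistic`, `u_a`, `u_b`, `p.value`,
#'   `n_a`, `n_b`, `method`, `mode`.
#' @method tidy mwu_test
#' @export
tidy.mwu_test <- function(x, ...) {
  tibble(
    statistic = x$statistic, u_a = x$u_a, u_b = x$u_b, p.value = x$p_value,
    n_a = x$n_a, n_b = x$n_b, method = x$method, mode = x$mode_used
  )
}

#' @rdname tidy.mwu_test
#' @method glance mwu_test
#' @export
glance.mwu_test <- function(x, ...) tidy(x, ...)

#' Compare groups on per-image or per-subject metrics
#'
#' Joins per-image metric records with the cohort manifest and compares the
#' two groups with [mwu_test()], either at the image level (each image is an
#' observation) or — the default, appropriate for small cohorts where images
#' within a subject are correlated — at the subject level, where each
#' subject contributes the mean of its images (its "subject vector"
#' average).
#'
#' No multiple-testing correction is applied to `p_value`; a
#' Benjamini-Hochberg-adjusted column `p_bh` across the requested metrics is
#' added for transparency.
#'
#' @param data Tibble of per-image records (e.g. from [summarize_image()] or
#'   [cohort_ratio_table()]); must contain `image_id` and the metric
#'   columns, and `subject_id`/`group` either in `data` or via `manifest`.
#' @param metrics Character vector of metric column names to compare.
#' @param manifest Optional manifest tibble supplying `subject_id` and
#'   `group` for each `image_id`.
#' @param level `"subject"` (default) or `"image"`.
#' @param mode Passed to [mwu_test()].
#' @return A tibble with one row per metric: `metric`, `level`, `u`,
#'   `p_value`, `n_a`, `n_b`, group means and medians, `mode`, `p_bh`.
#' @export
compare_groups <- function(data, metrics, manifest = NULL,
                           level = c("subject", "image"),
                           mode = "auto") {
  level <- match.arg(level)
  data <- as_tibble(data)
  if (!is.null(manifest)) {
    manifest <- validate_manifest(manifest)
    keep <- setdiff(names(data), c("subject_id", "group"))
    data <- left_join(data[, keep, drop = FALSE],
                      distinct(manifest[, c("image_id", "subject_id", "group")]),
                      by = "image_id")
  }
  if (!all(c("subject_id", "group") %in% names(data))) {
    abort("data must have subject_id and group columns (or supply a manifest)")
  }
  missing_metrics <- setdiff(metrics, names(data))
  if (length(missing_metrics) > 0) {
    abort(paste0("metric column(s) not found: ",
                 paste(missing_metrics, collapse = ", ")))
  }
  groups <- sort(unique(data$group))
  if (length(groups) != 2) abort("exactly two groups are required")

  out <- purrr::map_dfr(metrics, function(m) {
    d <- data[is.finite(data[[m]]), c("subject_id", "group", m)]
    if (level == "subject") {
      d <- d |>
        group_by(.data$subject_id, .data$group) |>
        summarise(value = mean(.data[[m]]), .groups = "drop")
    } else {
      d$value <- d[[m]]
    }
    va <- d$value[d$group == groups[1]]
    vb <- d$value[d$group == groups[2]]
    if (length(va) == 0 || length(vb) == 0) {
      abort(paste0("a group has no observations for metric '", m, "'"))
    }
    t <- mwu_test(va, vb, mode = mode)
    tibble(
      metric = m, level = level,
      group_a = groups[1], group_b = groups[2],
      u = t$statistic, p_value = t$p_value,
      n_a = t$n_a, n_b = t$n_b,
      mean_a = mean(va), mean_b = mean(vb),
      median_a = median(va), median_b = median(vb),
      mode = t$mode_used
    )
  })
  out$p_bh <- p.adjust(out$p_value, method = "BH")
  out
}
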