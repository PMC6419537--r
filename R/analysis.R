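#' Normalized ciliation ratio
#'
#' Ratio of the percentage of reporter-expressing cells displaying cilia
#' to the percentage of all cells displaying cilia, expressed in percent
#' and rounded to the nearest integer for reporting.  Values below 100
#' indicate that expression (or the transfection that enabled it) lowered
#' ciliation.
#'
#' @param transfected_ciliated_pct Percentage of expressing cells with
#'   cilia, in `(0, 100]`.
#' @param all_ciliated_pct Percentage of all cells with cilia, in
#'   `(0, 100]`.
#' @return Integer percentage `100 * transfected / all`.
#' @examples
#' normalized_ciliation_ratio(53.7, 75)   # 72
#' @export
normalized_ciliation_ratio <- function(transfected_ciliated_pct,
                                       all_ciliated_pct) {
  if (any(all_ciliated_pct <= 0)) {
    stop("ciliation percentage of all cells must be > 0", call. = FALSE)
  }
  if (any(transfected_ciliated_pct <= 0 | transfected_ciliated_pct > 100) ||
      any(all_ciliated_pct > 100)) {
    stop("percentages must lie in (0, 100]", call. = FALSE)
  }
  round(100 * transfected_ciliated_pct / all_ciliated_pct)
}

#' Replicate-normalized arrival time course
#'
#' Builds the population time course of one statistic (a surface-to-total
#' ratio side or the MCC): cells are averaged per replicate and time
#' point, each replicate's series is divided by its own maximum, and the
#' normalized series are then averaged across replicates with the
#' standard error of the mean over replicates.  Per-replicate
#' normalization makes the result invariant to replicate-specific gains.
#'
#' Cells that failed cilium QC contribute to surface statistics but are
#' excluded from MCC statistics.
#'
#' @param records Quantification records: a data frame from
#'   [quantify_population()] / [read_quant_table()] or a list of
#'   `cell_quant`.
#' @param statistic `"surface_ratio"` or `"mcc"`.
#' @param side For `surface_ratio`, which stained side to use
#'   (`"apical"` or `"basolateral"`).
#' @return A `timecourse_result`: data frame with columns `time`, one
#'   normalized-mean column per replicate, `mean` and `sem` across
#'   replicates; attributes keep the raw per-replicate means.
#' @export
build_timecourse <- function(records, statistic = c("surface_ratio", "mcc"),
                             side = NULL) {
  statistic <- match.arg(statistic)
  df <- quant_records(records)
  if (statistic == "mcc") {
    df <- df[df$qc_pass & !is.na(df$mcc), ]
  } else if (!is.null(side)) {
    df <- df[df$side == side, ]
  }
  if (nrow(df) == 0L) stop("no usable records", call. = FALSE)
  agg <- stats::aggregate(df[[statistic]],
                          by = list(replicate_id = df$replicate_id,
                                    time = df$release_time),
                          FUN = mean)
  names(agg)[3] <- "value"
  reps <- sort(unique(agg$replicate_id))
  times <- sort(unique(agg$time))
  raw <- sapply(reps, function(r) {
    v <- agg$value[match(paste(r, times), paste(agg$replicate_id, agg$time))]
    v
  })
  raw <- matrix(raw, nrow = length(times), dimnames = list(NULL, reps))
  norm <- raw
  for (j in seq_along(reps)) {
    m <- suppressWarnings(max(raw[, j], na.rm = TRUE))
    if (!is.finite(m) || m <= 0) {
      stop("replicate '", reps[j], "' has an all-zero series; cannot normalize",
           call. = FALSE)
    }
    norm[, j] <- raw[, j] / m
  }
  out <- data.frame(time = times)
  for (r in reps) out[[r]] <- norm[, r]
  out$mean <- rowMeans(norm, na.rm = TRUE)
  out$sem <- apply(norm, 1, function(v) {
    v <- v[!is.na(v)]
    if (length(v) > 1) sd(v) / sqrt(length(v)) else 0
  })
  structure(out, class = c("timecourse_result", "data.frame"),
            statistic = statistic, side = side, raw = raw)
}

#' @export
print.timecourse_result <- function(x, ...) {
  side <- attr(x, "side")
  cat(sprintf("Normalized time course of %s%s (%d replicates):\n",
              attr(x, "statistic"),
              if (!is.null(side)) paste0(" [", side, "]") else "",
              ncol(attr(x, "raw"))))
  print.data.frame(x, digits = 4, row.names = FALSE)
  invisible(x)
}

#' @export
plot.timecourse_result <- function(x, ...) {
  graphics::plot(x$time, x$mean, type = "b", pch = 16, ylim = c(0, 1.05),
                 xlab = "time after release (h)",
                 ylab = sprintf("normalized %s", attr(x, "statistic")), ...)
  graphics::arrows(x$time, x$mean - x$sem, x$time, x$mean + x$sem,
                   angle = 90, code = 3, length = 0.03)
  invisible(x)
}

#' Per-cell linear fit of MCC against surface signal
#'
#' Ordinary least-squares fit of the ciliary fraction (MCC) against the
#' side-specific surface-to-total ratio across the QC-passing single
#' cells of one replicate and side.  The slope is the correlation measure
#' compared between sides: lateral ciliary import from the apical
#' membrane predicts a positive apical slope and a negative basolateral
#' slope.
#'
#' @param records Quantification records (data frame or list of
#'   `cell_quant`).
#' @param side `"apical"` or `"basolateral"`.
#' @return A `slope_fit`: list with `slope`, `intercept`, `n`, `side`,
#'   `r_squared` and the underlying `lm` fit.
#' @export
fit_mcc_vs_surface <- function(records, side = c("apical", "basolateral")) {
  side <- match.arg(side)
  df <- quant_records(records)
  df <- df[df$side == side & df$qc_pass & !is.na(df$mcc) &
             !is.na(df$surface_ratio), ]
  if (nrow(df) < 2L) {
    stop("need at least 2 QC-passing cells with both statistics", call. = FALSE)
  }
  if (var(df$surface_ratio) < .Machine$double.eps) {
    stop("surface ratios have zero variance; slope undefined", call. = FALSE)
  }
  fit <- lm(mcc ~ surface_ratio, data = df)
  structure(list(slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 n = nrow(df), side = side,
                 r_squared = summary(fit)$r.squared,
                 fit = fit),
            class = "slope_fit")
}

#' @export
print.slope_fit <- function(x, ...) {
  cat(sprintf("MCC vs %s surface ratio: slope %.4g, intercept %.4g (n = %d cells, R2 = %.3f)\n",
              x$side, x$slope, x$intercept, x$n, x$r_squared))
  invisible(x)
}

#' @export
coef.slope_fit <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

#' Paired comparison of apical and basolateral slopes
#'
#' Two-tailed paired t-test on the per-replicate difference between the
#' apical and basolateral slopes of [fit_mcc_vs_surface()].  Pairing is
#' by replicate: the i-th elements of both lists must come from the same
#' experiment.
#'
#' @param apical List of apical `slope_fit`s (or a numeric vector of
#'   slopes), one per replicate.
#' @param basolateral Matching list for the basolateral side.
#' @return A `slope_comparison`: per-replicate slopes, means, the t
#'   statistic, degrees of freedom and the two-tailed p value.
#' @export
compare_slopes <- function(apical, basolateral) {
  a <- slope_values(apical)
  b <- slope_values(basolateral)
  if (length(a) != length(b)) {
    stop("apical and basolateral replicate lists must be paired (equal length)",
         call. = FALSE)
  }
  n <- length(a)
  if (n < 2L) stop("paired test needs at least 2 replicates", call. = FALSE)
  d <- a - b
  if (sd(d) < .Machine$double.eps) {
    if (abs(mean(d)) < .Machine$double.eps) {
      tt <- list(statistic = c(t = 0), parameter = c(df = n - 1), p.value = 1)
    } else {
      stop("slope differences are constant and nonzero; t undefined", call. = FALSE)
    }
  } else {
    tt <- t.test(a, b, paired = TRUE, alternative = "two.sided")
  }
  structure(list(apical = a, basolateral = b,
                 mean_apical = mean(a), mean_basolateral = mean(b),
                 t = unname(tt$statistic), df = unname(tt$parameter),
                 p_value = tt$p.value, n_replicates = n),
            class = "slope_comparison")
}

slope_values <- function(x) {
  if (inherits(x, "slope_fit")) x <- list(x)
  if (is.list(x)) {
    vapply(x, function(f) if (inherits(f, "slope_fit")) f$slope else as.numeric(f),
           numeric(1))
  } else as.numeric(x)
}

#' @export
print.slope_comparison <- function(x, ...) {
  cat(sprintf("Paired slope comparison over %d replicates:\n", x$n_replicates))
  cat(sprintf("  apical mean slope      %.4g\n", x$mean_apical))
  cat(sprintf("  basolateral mean slope %.4g\n", x$mean_basolateral))
  cat(sprintf("  paired t = %.4g (df = %d), two-tailed p = %.4g%s\n",
              x$t, x$df, x$p_value, if (x$p_value < 0.05) " *" else ""))
  invisible(x)
}

#' @export
summary.slope_comparison <- function(object, ...) {
  data.frame(replicate = seq_along(object$apical),
             apical_slope = object$apical,
             basolateral_slope = object$basolateral,
             difference = object$apical - object$basolateral)
}
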