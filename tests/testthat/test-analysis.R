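quant_df <- function(replicate_id, release_time, side, surface_ratio, mcc,
                     qc_pass = TRUE) {
  n <- max(lengths(list(replicate_id, release_time, side, surface_ratio, mcc)))
  data.frame(cell_id = sprintf("c%03d", seq_len(n)),
             replicate_id = replicate_id, release_time = release_time,
             side = side, surface_ratio = surface_ratio, mcc = mcc,
             cilium_voxels = 40L, qc_pass = qc_pass,
             qc_reason = ifelse(qc_pass, "", "no cilium detected"),
             stringsAsFactors = FALSE)
}

test_that("ciliation ratios reproduce the reported reductions to 72%", {
  expect_equal(normalized_ciliation_ratio(53.7, 75), 72)
  expect_equal(normalized_ciliation_ratio(38.1, 53), 72)
  for (x in c(10, 53, 75, 100)) {
    expect_equal(normalized_ciliation_ratio(x, x), 100)
  }
  expect_error(normalized_ciliation_ratio(50, 0), "> 0")
})

test_that("time courses are max-normalized per replicate before averaging", {
  df <- quant_df("rep1", rep(c(0.5, 1, 2), each = 2), "apical",
                 rep(c(1, 2, 4), each = 2), 0.01)
  tc <- build_timecourse(df, "surface_ratio", side = "apical")
  expect_equal(tc$mean, c(0.25, 0.5, 1.0))
  # two identical replicates: SEM identically zero
  df2 <- rbind(df, transform(df, replicate_id = "rep2"))
  tc2 <- build_timecourse(df2, "surface_ratio", side = "apical")
  expect_equal(tc2$sem, c(0, 0, 0))
  expect_equal(tc2$mean, c(0.25, 0.5, 1.0))
})

test_that("normalization cancels replicate-specific gains", {
  df <- quant_df(rep(c("rep1", "rep2"), each = 3), rep(c(0.5, 1, 2), 2),
                 "apical", c(1, 3, 4, 2, 6, 8), 0.01)
  tc_ref <- build_timecourse(df, "surface_ratio", side = "apical")
  df_scaled <- df
  df_scaled$surface_ratio[df_scaled$replicate_id == "rep2"] <-
    df_scaled$surface_ratio[df_scaled$replicate_id == "rep2"] * 17.3
  tc_scaled <- build_timecourse(df_scaled, "surface_ratio", side = "apical")
  expect_equal(tc_scaled$mean, tc_ref$mean, tolerance = 1e-12)
  expect_true(all(apply(attr(tc_scaled, "raw") / attr(tc_ref, "raw"), 2,
                        function(v) diff(range(v)) < 1e-9)))
})

test_that("QC-failing cells are excluded from MCC but kept for surface series", {
  df <- quant_df("rep1", rep(c(0.5, 1), each = 2), "apical",
                 c(1, 1, 2, 2), c(0.02, NA, 0.04, NA),
                 qc_pass = c(TRUE, FALSE, TRUE, FALSE))
  tc_mcc <- build_timecourse(df, "mcc")
  expect_equal(tc_mcc$mean, c(0.5, 1))
  tc_surf <- build_timecourse(df, "surface_ratio", side = "apical")
  expect_equal(tc_surf$mean, c(0.5, 1))
})

test_that("an all-zero replicate is a normalization error naming the replicate", {
  df <- quant_df("repX", c(0.5, 1), "apical", c(0, 0), 0.01)
  expect_error(build_timecourse(df, "surface_ratio", side = "apical"),
               "repX")
})

test_that("the synthetic time course peaks basolaterally before apically", {
  pr <- fast_profile()
  times <- c(0.25, 0.5, 1, 1.5, 2)
  recs <- list()
  for (rep_i in 1:2) {
    for (t_h in times) {
      pop <- generate_population(6, kinetic_params(), variability_spec(),
                                 time = t_h,
                                 seed = 300 + 17 * rep_i + round(100 * t_h),
                                 geometry = pr$geometry, imaging = pr$imaging,
                                 stained_side = c("apical", "basolateral"),
                                 replicate_id = sprintf("rep%d", rep_i))
      recs[[length(recs) + 1L]] <- quantify_population(pop, pr$settings)
    }
  }
  q <- do.call(rbind, recs)
  tc_bl <- build_timecourse(q, "surface_ratio", side = "basolateral")
  tc_ap <- build_timecourse(q, "surface_ratio", side = "apical")
  expect_equal(tc_bl$time[which.max(tc_bl$mean)], 1)
  expect_gt(tc_ap$time[which.max(tc_ap$mean)], 1)
  # MCC series rises to its late-time saturation
  tc_mcc <- build_timecourse(q, "mcc")
  expect_gt(tc_mcc$time[which.max(tc_mcc$mean)], 1)
  expect_true(all(tc_mcc$mean <= 1 + 1e-12))
})

test_that("OLS slope fits match exact and summation oracles", {
  x <- c(0.1, 0.25, 0.4, 0.6, 0.8)
  df <- quant_df("rep1", 1, "apical", x, 0.02 * x + 0.01)
  fit <- suppressWarnings(fit_mcc_vs_surface(df, "apical"))
  expect_equal(fit$slope, 0.02, tolerance = 1e-12)
  expect_equal(fit$intercept, 0.01, tolerance = 1e-12)
  df2 <- quant_df("rep1", 1, "apical", c(0, 1, 2), c(0, 1, 2))
  expect_equal(suppressWarnings(fit_mcc_vs_surface(df2, "apical"))$slope, 1,
               tolerance = 1e-12)
  set.seed(7)
  for (i in 1:5) {
    xs <- runif(20); ys <- 0.05 * xs + rnorm(20, sd = 0.01)
    dfr <- quant_df("rep1", 1, "basolateral", xs, ys)
    fitr <- fit_mcc_vs_surface(dfr, "basolateral")
    o <- oracle_ols(xs, ys)
    expect_equal(fitr$slope, o[["slope"]], tolerance = 1e-10)
    expect_equal(fitr$intercept, o[["intercept"]], tolerance = 1e-10)
    expect_equal(fitr$slope, cov(xs, ys) / var(xs), tolerance = 1e-10)
  }
  expect_error(fit_mcc_vs_surface(df[1, ], "apical"), "at least 2")
  dfc <- quant_df("rep1", 1, "apical", c(1, 1, 1), c(0.1, 0.2, 0.3))
  expect_error(fit_mcc_vs_surface(dfc, "apical"), "zero variance")
})

test_that("paired slope comparison matches the closed-form t-test", {
  a <- c(0.031, 0.029, 0.0305)
  b <- c(-0.0295, -0.031, -0.030)
  cmp <- compare_slopes(a, b)
  o <- oracle_paired_t(a, b)
  expect_equal(cmp$t, o[["t"]], tolerance = 1e-10)
  expect_equal(cmp$p_value, o[["p"]], tolerance = 1e-10)
  expect_lt(cmp$p_value, 0.05)
  # identical lists: no difference at all
  same <- compare_slopes(c(0.1, 0.2, 0.3), c(0.1, 0.2, 0.3))
  expect_equal(same$t, 0)
  expect_equal(same$p_value, 1)
  expect_error(compare_slopes(0.1, 0.2), "at least 2")
  expect_error(compare_slopes(c(0.1, 0.2), c(0.1, 0.2, 0.3)), "paired")
})
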