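test_that("stack write/read round-trips intensities bit-exactly with metadata", {
  set.seed(21)
  chans <- list(
    gfp = array(as.numeric(sample(0:65535, 4 * 6 * 5, TRUE)), dim = c(4, 6, 5)),
    surface = array(as.numeric(sample(0:65535, 4 * 6 * 5, TRUE)), dim = c(4, 6, 5)))
  s <- voxel_stack(chans, voxel_size = c(0.3, 0.1, 0.1), release_time = 1.5,
                   stained_side = "basolateral", replicate_id = "rep2",
                   meta = list(expression_level = 1.3))
  path <- withr::local_tempfile(fileext = ".tif")
  write_stack(s, path)
  r <- read_stack(path)
  expect_identical(r$channels$gfp, s$channels$gfp)
  expect_identical(r$channels$surface, s$channels$surface)
  expect_equal(r$voxel_size, s$voxel_size)
  expect_equal(r$release_time, 1.5)
  expect_equal(r$stained_side, "basolateral")
  expect_equal(r$replicate_id, "rep2")
  expect_equal(r$meta$expression_level, 1.3)
})

test_that("a single-plane 2D TIFF is promoted to a depth-1 stack", {
  path <- withr::local_tempfile(fileext = ".tif")
  tiff::writeTIFF(matrix(runif(30), 5, 6), path, bits.per.sample = 16)
  expect_warning(s <- read_stack(path), "voxel-size")
  expect_equal(dim(s$channels[[1]]), c(1, 5, 6))
})

test_that("a channel-count mismatch is a named error", {
  path <- withr::local_tempfile(fileext = ".tif")
  tiff::writeTIFF(list(matrix(0, 4, 4), matrix(0, 4, 4), matrix(0, 4, 4),
                       matrix(0, 4, 4)), path, bits.per.sample = 16)
  expect_error(read_stack(path, channel_names = c("a", "b", "c"), nz = 1,
                          voxel_size = c(0.3, 0.1, 0.1)),
               "4 TIFF pages")
})

test_that("a missing file is an I/O error", {
  expect_error(read_stack("no/such/file.tif"), "not found")
})

test_that("quantification tables round-trip, with QC'd-out MCC as empty field", {
  df <- data.frame(cell_id = c("c1", "c2"), replicate_id = "rep1",
                   release_time = 1, side = c("apical", "basolateral"),
                   surface_ratio = c(0.41, 0.39), mcc = c(0.048, NA),
                   cilium_voxels = c(40L, 0L), qc_pass = c(TRUE, FALSE),
                   qc_reason = c("", "no cilium detected"),
                   stringsAsFactors = FALSE)
  path <- withr::local_tempfile(fileext = ".csv")
  write_quant_table(df, path)
  lines <- readLines(path)
  expect_length(lines, 3)             # header + one row per cell
  expect_match(lines[3], ",,", all = FALSE)  # empty mcc field for QC fail
  back <- read_quant_table(path)
  expect_equal(back$mcc, df$mcc)
  expect_equal(back$qc_pass, df$qc_pass)
  expect_equal(back$qc_reason, df$qc_reason)
  expect_equal(back$surface_ratio, df$surface_ratio)
})

test_that("empty regions and unnamed channels are rejected", {
  expect_error(region_set(list(background = array(FALSE, c(2, 2, 2)))),
               "empty")
  expect_error(voxel_stack(list(array(0, c(2, 2, 2)))), "named")
})
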