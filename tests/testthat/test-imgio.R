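test_that("channel_stack normalizes shapes to (channel, z, y, x)", {
  m <- matrix(runif(48), 6, 8)
  cs <- channel_stack(m, "hoechst")
  expect_equal(dim(cs$data), c(1L, 1L, 6L, 8L))
  expect_equal(cs$data[1, 1, , ], m)

  a <- array(runif(4 * 6 * 8), dim = c(4, 6, 8))
  cs4 <- channel_stack(a, c("hoechst", "sytox", "mpo", "cith3"))
  expect_equal(dim(cs4$data), c(4L, 1L, 6L, 8L))
  expect_equal(get_channel(cs4, "mpo"), a[3, , ])

  z <- array(runif(9 * 6 * 8), dim = c(9, 6, 8))
  csz <- channel_stack(z, "hoechst")
  expect_equal(dim(csz$data), c(1L, 9L, 6L, 8L))
  expect_equal(get_channel(csz, "hoechst", z = 5), z[5, , ])

  # normalization is idempotent
  cs2 <- channel_stack(cs4$data, cs4$channel_names)
  expect_identical(cs2$data, cs4$data)
})

test_that("channel_stack rejects invalid inputs", {
  expect_error(channel_stack(matrix(-1, 2, 2), "a"), "nonnegative")
  expect_error(channel_stack(matrix(1, 2, 2), c("a", "b")), "channel")
  expect_error(channel_stack(matrix(1, 2, 2), "a", pixel_size_um = 0),
               "pixel_size_um")
  expect_error(get_channel(channel_stack(matrix(1, 2, 2), "a"), "missing"),
               "not found")
})

test_that("TIFF round trip is bit-exact for integer stacks", {
  withr_like_tmp <- tempfile(fileext = ".tif")
  on.exit(unlink(withr_like_tmp))
  set.seed(7)
  arr <- array(sample(0:65535, 4 * 2 * 16 * 16, replace = TRUE),
               dim = c(4, 2, 16, 16))
  cs <- channel_stack(arr, c("hoechst", "sytox", "mpo", "cith3"))
  write_channel_stack(cs, withr_like_tmp)
  back <- read_channel_stack(withr_like_tmp,
                             c("hoechst", "sytox", "mpo", "cith3"))
  expect_identical(back$data, cs$data + 0)  # numeric compare, bit exact
  expect_equal(back$channel_names, cs$channel_names)
})

test_that("single-channel 9-slice z-stack reads with z-extent 9", {
  tmp <- tempfile(fileext = ".tif")
  on.exit(unlink(tmp))
  set.seed(8)
  arr <- array(sample(0:65535, 9 * 12 * 12, replace = TRUE),
               dim = c(9, 12, 12))
  write_channel_stack(channel_stack(arr, "hoechst"), tmp)
  back <- read_channel_stack(tmp, "hoechst")
  expect_equal(dim(back$data), c(1L, 9L, 12L, 12L))
  expect_equal(back$data[1, , , ], arr + 0)
})

test_that("axis ambiguity and missing files raise explicit errors", {
  tmp <- tempfile(fileext = ".tif")
  on.exit(unlink(tmp))
  arr <- array(0:2, dim = c(3, 4, 4))
  write_channel_stack(channel_stack(arr, "hoechst"), tmp)
  expect_error(read_channel_stack(tmp, c("a", "b")), "ambiguity")
  expect_error(read_channel_stack("nope.tif", "a"), "not found")
  big <- channel_stack(matrix(70000, 2, 2), "a")
  expect_error(write_channel_stack(big, tmp), "16-bit")
})

test_that("persist_table round trips numeric tables to 1e-9", {
  tmp <- tempfile(fileext = ".csv")
  on.exit(unlink(tmp))
  set.seed(21)
  tab <- data.frame(label = 1:1000, area_px = sample(1:500, 1000, TRUE),
                    x = runif(1000, 0, 2048), y = runif(1000, 0, 2048),
                    mfi = rexp(1000, 1e-3))
  persist_table(tab, tmp)
  back <- utils::read.csv(tmp)
  for (col in names(tab))
    expect_lt(max(abs(back[[col]] - tab[[col]])), 1e-9)

  empty <- data.frame(label = integer(), mfi = numeric())
  persist_table(empty, tmp)
  expect_length(readLines(tmp), 1L)  # header only

  persist_table(tab[1:3, ], tmp)
  expect_length(readLines(tmp), 4L)
})

test_that("pipeline configuration validates keys and ranges", {
  good <- validate_pipeline_config(list(min_area_px = 10, watershed = TRUE))
  expect_s3_class(good, "PipelineConfig")
  expect_error(validate_pipeline_config(list(minn_area = 1)), "unknown")
  expect_error(validate_pipeline_config(list(connectivity = 12)), "range")
  expect_error(validate_pipeline_config(list(watershed = "yes")),
               "true/false")
  p <- config_seg_params(good)
  expect_s3_class(p, "SegmentParams")
  expect_true(p$watershed)
  expect_equal(p$min_area_px, 10)
})
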