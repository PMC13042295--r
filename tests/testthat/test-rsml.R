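make_axes <- function() {
  m <- matrix(FALSE, 80, 80)
  m[10:69, 40] <- TRUE          # main
  m[30, 41:55] <- TRUE          # lateral 1
  m[50, 25:39] <- TRUE          # lateral 2
  classify_axes(build_graph(m, c(10, 40)))
}

test_that("a main root with two laterals nests as order-1 / order-2", {
  ax <- make_axes()
  f <- tempfile(fileext = ".rsml")
  write_rsml(ax, f, scale = 0.04, dt = 15)
  sc <- read_rsml(f)
  expect_length(sc$plants, 1L)
  expect_length(sc$plants[[1]]$roots, 1L)
  main <- sc$plants[[1]]$roots[[1]]
  expect_equal(main$order, 1L)
  expect_length(main$children, 2L)
  expect_true(all(vapply(main$children, `[[`, integer(1), "order") == 2L))
  expect_equal(sc$metadata$resolution, 25)  # px per mm at 0.04 mm/px
})

test_that("an empty plant still writes a valid document", {
  empty <- structure(list(id = 1, roots = list()), class = "rsml_scene")
  scene <- structure(list(
    metadata = list(version = "1.0", unit = "mm", resolution = 25,
                    dt_min = 15, software = "rhizolapse"),
    plants = list(list(id = 1, roots = list()))
  ), class = "rsml_scene")
  f <- tempfile(fileext = ".rsml")
  write_rsml(scene, f)
  expect_true(validate_rsml(f))
  sc <- read_rsml(f)
  expect_length(sc$plants[[1]]$roots, 0L)
})

test_that("write -> read -> write is byte-identical", {
  ax <- make_axes()
  f1 <- tempfile(fileext = ".rsml"); f2 <- tempfile(fileext = ".rsml")
  f3 <- tempfile(fileext = ".rsml")
  write_rsml(ax, f1, scale = 0.04, dt = 15)
  write_rsml(read_rsml(f1), f2)
  write_rsml(read_rsml(f2), f3)
  expect_identical(readBin(f1, "raw", file.size(f1) + 10),
                   readBin(f2, "raw", file.size(f2) + 10))
  expect_identical(readBin(f2, "raw", file.size(f2) + 10),
                   readBin(f3, "raw", file.size(f3) + 10))
})

test_that("round trip preserves topology, coordinates and properties", {
  ax <- make_axes()
  f <- tempfile(fileext = ".rsml")
  write_rsml(ax, f, scale = 0.04, dt = 15)
  sc <- read_rsml(f)
  main <- sc$plants[[1]]$roots[[1]]
  # polyline coordinates equal the main path in (x, y) = (col, row)
  expect_equal(main$path[, "x"], ax$main$path[, 2])
  expect_equal(main$path[, "y"], ax$main$path[, 1])
  expect_equal(main$props$length, ax$main$length_px * 0.04,
               tolerance = 1e-4)
  expect_equal(length(main$children), length(ax$laterals))
})

test_that("missing optional properties load as missing without failure", {
  f <- tempfile(fileext = ".rsml")
  writeLines(c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<rsml><metadata><version>1.0</version><unit>mm</unit>',
    '<resolution>25</resolution><software>other-tool</software></metadata>',
    '<scene><plant id="p1"><root id="r1" order="1">',
    '<geometry><polyline><point x="1" y="2"/><point x="1" y="8"/>',
    '</polyline></geometry></root></plant></scene></rsml>'), f)
  sc <- read_rsml(f)
  rt <- sc$plants[[1]]$roots[[1]]
  expect_length(rt$props, 0L)
  expect_null(rt$props$length)
  expect_true(validate_rsml(f))
})

test_that("malformed nesting and empty polylines are rejected", {
  f <- tempfile(fileext = ".rsml")
  writeLines(c(
    '<rsml><metadata><version>1</version><unit>mm</unit>',
    '<resolution>25</resolution></metadata>',
    '<scene><plant id="p1"><root id="r1" order="2">',
    '<geometry><polyline><point x="1" y="2"/></polyline></geometry>',
    '</root></plant></scene></rsml>'), f)
  expect_error(read_rsml(f), "order-2")

  f2 <- tempfile(fileext = ".rsml")
  writeLines(c(
    '<rsml><metadata><version>1</version><unit>mm</unit>',
    '<resolution>25</resolution></metadata>',
    '<scene><plant id="p1"><root id="r1" order="1">',
    '<geometry><polyline></polyline></geometry>',
    '</root></plant></scene></rsml>'), f2)
  expect_error(read_rsml(f2), "empty polyline")
})
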