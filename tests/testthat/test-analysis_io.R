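# Retention counting, suspension statistics, and lossless result I/O.

test_that("retention counting follows the bond-duration-speed criterion", {
  t <- seq(0.01, 0.5, by = 0.01)
  n <- length(t)
  nb <- cbind(rep(5L, n),                                  # always bonded
              c(rep(0L, 10), rep(2L, 3), rep(0L, n - 13)), # transient
              rep(0L, n))                                  # free
  speed <- cbind(rep(2, n), rep(2, n), rep(150, n))
  tr <- toy_trajectory(t, nb, speed)
  crit <- retention_criterion(min_bonds = 1, min_duration = 0.05)
  ser <- count_retained(tr, crit)
  # transient bond (0.03 s) is shorter than the 0.05 s threshold: only the
  # permanently bonded slow cell counts
  expect_identical(ser$retained[n], 1L)
  expect_true(all(ser$retained <= 1L))
  # degenerate criterion counts the whole population
  ser0 <- count_retained(tr, retention_criterion(min_bonds = 0))
  expect_true(all(ser0$retained == 3L))
  # a trajectory without a bond channel errors
  tr2 <- tr; tr2$nb <- NULL
  expect_error(count_retained(tr2), "bond")
})

test_that("the speed gate excludes fast cells even when bonded", {
  t <- seq(0.01, 0.3, by = 0.01)
  n <- length(t)
  nb <- cbind(rep(3L, n), rep(3L, n))
  speed <- cbind(rep(1, n), rep(100, n))  # second cell still moving fast
  tr <- toy_trajectory(t, nb, speed, v_bulk = 150)
  ser <- count_retained(tr)
  expect_identical(ser$retained[n], 1L)
})

test_that("mean suspension velocity equals the hand-computed average", {
  t <- c(0.1, 0.2)
  nb <- matrix(0L, 2, 3)
  speed <- rbind(c(100, 150, 200), c(0, 0, 0))
  tr <- toy_trajectory(t, nb, speed)
  mv <- mean_suspension_velocity(tr)
  expect_equal(mv$mean_velocity, c(150, 0))
  tr2 <- tr; tr2$speed <- tr$speed[, 0, drop = FALSE]
  expect_error(mean_suspension_velocity(tr2), "no cells")
})

test_that("plateau detection flags unconverged series", {
  s1 <- data.frame(time = 1:10, retained = c(0, 1, 2, 3, 3, 3, 3, 3, 3, 3),
                   mean_velocity = 0)
  p1 <- plateau_info(s1)
  expect_true(p1$reached)
  expect_equal(p1$value, 3)
  expect_equal(p1$time_to_plateau, 4)
  s2 <- data.frame(time = 1:10, retained = 1:10, mean_velocity = 0)
  expect_false(plateau_info(s2)$reached)
})

test_that("CSV output round-trips byte-identically", {
  set.seed(1)
  ser <- data.frame(time = cumsum(runif(20)), retained = rpois(20, 2),
                    mean_velocity = rnorm(20, 100))
  d <- tempfile(); dir.create(d)
  res <- structure(list(name = "retention", series = list(ser),
                        seeds = 1L, plateau = 2, reached = TRUE,
                        criterion = retention_criterion(),
                        config_hash = "abc"), class = "assay_result")
  paths <- write_outputs(res, d)
  csv <- paths[grepl("csv$", paths)]
  back <- read_retention_csv(csv)
  expect_equal(back$time, ser$time)          # exact (17 digits)
  expect_identical(back$retained, as.integer(ser$retained))
  expect_equal(back$mean_velocity, ser$mean_velocity)
  d2 <- tempfile(); dir.create(d2)
  res2 <- res; res2$series <- list(back)
  paths2 <- write_outputs(res2, d2)
  expect_identical(readLines(csv), readLines(paths2[grepl("csv$", paths2)]))
  # overwrite protection
  expect_error(write_outputs(res, d), "overwrite")
})

test_that("the JSON summary validates against the shipped schema", {
  ser <- data.frame(time = 1:3, retained = c(0L, 1L, 1L),
                    mean_velocity = c(100, 60, 50))
  d <- tempfile(); dir.create(d)
  res <- structure(list(name = "retention", series = list(ser),
                        seeds = c(1L, 2L), plateau = c(1, 1),
                        reached = c(TRUE, TRUE),
                        criterion = retention_criterion(),
                        config_hash = "ffff"), class = "assay_result")
  res$series <- list(ser, ser)
  write_outputs(res, d)
  expect_true(validate_summary_json(file.path(d, "summary.json")))
  # a truncated summary fails validation
  bad <- file.path(d, "bad.json")
  jsonlite::write_json(list(assay = "retention"), bad, auto_unbox = TRUE)
  expect_error(validate_summary_json(bad), "missing required")
})

test_that("2D snapshots export as parseable legacy VTK polydata", {
  o1 <- make_cell_outline("biconcave", 24)
  o2 <- make_cell_outline("sickle", 24)
  f <- tempfile(fileext = ".vtk")
  write_outlines_vtk(list(o1, o2), macs = matrix(c(30, 2, 9), 1), f)
  lines <- readLines(f)
  expect_identical(lines[1], "# vtk DataFile Version 3.0")
  expect_true(any(grepl("^DATASET POLYDATA", lines)))
  np <- as.integer(strsplit(grep("^POINTS", lines, value = TRUE),
                            " ")[[1]][2])
  expect_identical(np, 24L + 24L + 48L)
  npoly <- as.integer(strsplit(grep("^POLYGONS", lines, value = TRUE),
                               " ")[[1]][2])
  expect_identical(npoly, 3L)
})
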