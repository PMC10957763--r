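test_that("a square matrix file is read back exactly and validated", {
  w <- matrix(c(0, 1, 2,
                1, 0, 3,
                2, 3, 0), 3, 3, byrow = TRUE)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_connectivity_matrix(connectivity_matrix(w, "structural"), path)
  cm <- read_connectivity_matrix(path, "structural")
  expect_equal(unname(cm$weights), w)
  expect_equal(cm$weights[1, 2], 1)
  expect_equal(cm$weights[1, 3], 2)
  expect_equal(cm$weights[2, 3], 3)

  # label round trip
  cm2 <- connectivity_matrix(w / 10, "functional",
                             region_labels = c("Amy", "Hip", "Tha"))
  path2 <- withr::local_tempfile(fileext = ".tsv")
  write_connectivity_matrix(cm2, path2)
  back <- read_connectivity_matrix(path2, "functional")
  expect_equal(back$region_labels, c("Amy", "Hip", "Tha"))
  expect_equal(back$weights, cm2$weights)
})

test_that("malformed matrix inputs are rejected", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("0\t1\t2", "1\t0\t3"), path)  # 2 x 3
  expect_error(read_connectivity_matrix(path, "structural"), "non-square")

  path2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("0\t1", "5\t0"), path2)       # w_12 = 1 but w_21 = 5
  expect_error(read_connectivity_matrix(path2, "structural"),
               "asymmetric beyond tolerance")

  expect_error(connectivity_matrix(matrix(c(0, -1, -1, 0), 2), "structural"),
               "negative")
  expect_error(connectivity_matrix(matrix(c(0, NA, NA, 0), 2), "functional"),
               "NA")
  # tiny asymmetry is averaged away
  w <- matrix(c(0, 1, 1 + 1e-12, 0), 2, byrow = TRUE)
  expect_equal(connectivity_matrix(w, "structural")$weights[1, 2],
               1 + 5e-13)
})

test_that("functional connectivity follows the correlation rules", {
  base <- sin(seq_len(50))
  ts <- rbind(base, 2 * base + 1, -base, stats::rnorm(50))
  fc <- fc_from_timeseries(ts)
  expect_equal(fc$weights[1, 2], 1)           # identical up to affine scale
  expect_equal(fc$weights[1, 3], 0)           # negative clamped to zero
  expect_true(all(diag(fc$weights) == 0))
  expect_true(all(fc$weights >= 0 & fc$weights <= 1))

  # independent long series: all off-diagonal correlations are small and
  # match a direct clamped-correlation computation
  set.seed(7)
  ts2 <- matrix(stats::rnorm(3 * 10000), nrow = 3)
  fc2 <- fc_from_timeseries(ts2)
  expect_true(all(fc2$weights[upper.tri(fc2$weights)] < 0.1))
  direct <- stats::cor(t(ts2))
  direct[direct < 0] <- 0
  diag(direct) <- 0
  expect_equal(unname(fc2$weights), direct, tolerance = 1e-12)

  # constant region: warned, zeroed, does not abort
  ts3 <- rbind(rep(1, 10), stats::rnorm(10), stats::rnorm(10))
  expect_warning(fc3 <- fc_from_timeseries(ts3), "constant")
  expect_true(all(fc3$weights[1, ] == 0) && all(fc3$weights[, 1] == 0))

  expect_error(fc_from_timeseries(matrix(1:4, 2)), "3 timepoints")
})

test_that("structural connectivity is fibers over summed surface areas", {
  fib <- mat_from_edges(3, i = c(1, 2), j = c(2, 3), w = c(50, 7))
  sc <- sc_from_fibers(fib, c(100, 150, 4))
  expect_equal(sc$weights[1, 2], 50 / 250)   # 0.2
  expect_equal(sc$weights[1, 3], 0)          # no fibers, no connection
  fib2 <- mat_from_edges(2, i = 1, j = 2, w = 7)
  expect_equal(sc_from_fibers(fib2, c(3, 4))$weights[1, 2], 1)
  expect_error(sc_from_fibers(fib2, c(3, 0)), "positive")

  # invariance to joint rescaling of fibers and areas
  a <- c(120, 80, 45)
  s1 <- sc_from_fibers(fib, a)
  s2 <- sc_from_fibers(fib * 3.7, a * 3.7)
  expect_equal(s1$weights, s2$weights, tolerance = 1e-12)
})

test_that("cohort manifests are validated and loaded in order", {
  dir <- withr::local_tempdir()
  w <- matrix(c(0, 0.5, 0.5, 0), 2)
  for (id in c("a", "b", "c")) {
    write_connectivity_matrix(connectivity_matrix(w, "structural"),
                              file.path(dir, paste0("sc_", id, ".tsv")))
    write_connectivity_matrix(connectivity_matrix(w, "functional"),
                              file.path(dir, paste0("fc_", id, ".tsv")))
  }
  man <- data.frame(subject_id = c("a", "b", "c"),
                    group = c("HC", "SZ", "HC"),
                    sc_path = paste0("sc_", c("a", "b", "c"), ".tsv"),
                    fc_path = paste0("fc_", c("a", "b", "c"), ".tsv"))
  mpath <- file.path(dir, "manifest.tsv")
  utils::write.table(man, mpath, sep = "\t", quote = FALSE, row.names = FALSE)

  got <- read_cohort_manifest(mpath)
  expect_equal(got$subject_id, c("a", "b", "c"))
  subjects <- load_cohort(mpath)
  expect_length(subjects, 3)
  expect_equal(subjects[[2]]$group, "SZ")

  man_dup <- man
  man_dup$subject_id <- c("a", "a", "c")
  utils::write.table(man_dup, mpath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  expect_error(read_cohort_manifest(mpath), "duplicate")

  man_missing <- man
  man_missing$fc_path[2] <- "fc_nope.tsv"
  utils::write.table(man_missing, mpath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  expect_error(read_cohort_manifest(mpath), "fc_nope")

  man_cols <- man[, c("subject_id", "group", "sc_path")]
  utils::write.table(man_cols, mpath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  expect_error(read_cohort_manifest(mpath), "fc_path")
})
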