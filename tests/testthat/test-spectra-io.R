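test_that("read_spectra_table parses a wide table and normalises column order", {
  path <- withr_tempfile()
  writeLines(c("id,780,782,784,786,ref",
               "a,0.1,0.2,0.3,0.4,20",
               "b,0.5,0.6,0.7,0.8,25",
               "c,0.9,1.0,1.1,1.2,30",
               "d,1.3,1.4,1.5,1.6,35"), path)
  s <- read_spectra_table(path)
  expect_equal(n_wavelengths(s), 4)
  expect_equal(n_samples(s), 4)
  expect_equal(s$wavelengths, c(780, 782, 784, 786))
  expect_equal(s$reference, c(20, 25, 30, 35))

  # shuffled wavelength columns come back sorted, data permuted consistently
  writeLines(c("id,784,780,786,782,ref",
               "a,0.3,0.1,0.4,0.2,20",
               "b,0.7,0.5,0.8,0.6,25",
               "c,1.1,0.9,1.2,1.0,30"), path)
  s2 <- read_spectra_table(path)
  expect_equal(s2$wavelengths, c(780, 782, 784, 786))
  expect_equal(s2$absorbance[1, ], c(0.1, 0.2, 0.3, 0.4), ignore_attr = TRUE)
})

test_that("read_spectra_table reports format problems", {
  path <- withr_tempfile()
  writeLines(c("id,780,782,ref", "a,0.1,0.2,20"), path)
  expect_error(read_spectra_table(path, reference_column = "GLB"),
               "reference column")
  writeLines(c("id,780,peak,ref", "a,0.1,0.2,20"), path)
  expect_error(read_spectra_table(path), "non-numeric wavelength")
  writeLines(c("id,780,782,ref", "a,0.1,oops,20", "b,0.2,0.3,25"), path)
  expect_error(read_spectra_table(path), "non-numeric absorbance")
})

test_that("write/read round trip reproduces the set at stated precision", {
  for (seed in 1:3) {
    s <- random_spectra(n = 6, N = 7, seed = seed)
    path <- withr_tempfile()
    write_spectra_table(s, path)
    s2 <- read_spectra_table(path)
    expect_equal(s2$wavelengths, s$wavelengths)
    expect_equal(s2$absorbance, s$absorbance, ignore_attr = TRUE,
                 tolerance = 1e-12)
    expect_equal(s2$reference, s$reference, tolerance = 1e-12)
    expect_equal(s2$sample_ids, s$sample_ids)
  }
})

test_that("write_spectra_table rejects an empty set and writes one-row sets", {
  s1 <- random_spectra(n = 1, N = 3)
  empty <- s1
  empty$absorbance <- empty$absorbance[0, , drop = FALSE]
  empty$reference <- numeric(0)
  empty$sample_ids <- character(0)
  path <- withr_tempfile()
  expect_error(write_spectra_table(empty, path), "no samples")
  write_spectra_table(s1, path)
  expect_length(readLines(path), 2L)  # header + one data row
})

test_that("subset_wavelengths honours the grid and composes", {
  grid <- seq(780, 2498, by = 2)
  s <- random_spectra(n = 4, N = length(grid), wl = grid)
  expect_equal(subset_wavelengths(s, grid), s)
  expect_equal(n_wavelengths(subset_wavelengths(s, seq(1504, 1820, by = 2))),
               159)
  expect_error(subset_wavelengths(s, 781), "781")
  w1 <- seq(1000, 1500, by = 2)
  w2 <- seq(1200, 1300, by = 4)
  expect_equal(subset_wavelengths(subset_wavelengths(s, w1), w2),
               subset_wavelengths(s, w2))
  expect_equal(subset_wavelengths(s, w1)$reference, s$reference)
})

test_that("average_replicates takes per-group means", {
  s <- random_spectra(n = 6, N = 4)
  # three identical replicate rows collapse to the identical single row
  rep3 <- spectra_set(s$wavelengths, s$absorbance[c(1, 1, 1), ],
                      s$reference[c(1, 1, 1)])
  m <- average_replicates(rep3, c("g", "g", "g"))
  expect_equal(n_samples(m), 1)
  expect_equal(m$absorbance[1, ], s$absorbance[1, ], ignore_attr = TRUE)

  two <- spectra_set(c(780, 782), matrix(c(0, 0, 1, 1), 2, byrow = TRUE),
                     c(0, 1))
  m2 <- average_replicates(two, c("g", "g"))
  expect_equal(m2$absorbance[1, ], c(0.5, 0.5), ignore_attr = TRUE)
  expect_equal(m2$reference, 0.5)

  expect_error(average_replicates(s, c("a", "b")), "one entry per sample")

  # 230 specimens x 3 replicate scans reduce to 230 modeling samples
  big <- random_spectra(n = 690, N = 5, seed = 9)
  expect_equal(n_samples(average_replicates(big, rep(1:230, each = 3))), 230)
})

test_that("spectra_set enforces its invariants", {
  expect_error(spectra_set(c(780, 780), matrix(0, 2, 2), c(1, 2)),
               "strictly increasing")
  expect_error(spectra_set(c(780, 782, 784), matrix(0, 2, 2), c(1, 2)),
               "absorbance columns")
  expect_error(spectra_set(c(780, 782), matrix(0, 2, 2), c(1, 2, 3)),
               "absorbance rows")
})
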