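test_that("MGF round-trip preserves spectra within tolerance", {
  empty <- tempfile(fileext = ".mgf")
  file.create(empty)
  expect_length(read_mgf(empty), 0)

  one <- tempfile(fileext = ".mgf")
  writeLines(c("BEGIN IONS", "TITLE=demo", "PEPMASS=301.1412",
               "CHARGE=1+", "COLLISION_ENERGY=20",
               "100.1 12", "150.2 7.5", "250.9 1", "END IONS"), one)
  ss <- read_mgf(one)
  expect_length(ss, 1)
  expect_equal(n_peaks(ss[[1]]), 3)
  expect_equal(ss[[1]]$precursor_mz, 301.1412)
  expect_equal(ss[[1]]$collision_energy, 20)
  expect_equal(ss[[1]]$id, "demo")

  set.seed(101)
  orig <- lapply(seq_len(50), function(i)
    rand_spectrum(sample(2:12, 1), precursor = runif(1, 100, 900)))
  p <- tempfile(fileext = ".mgf")
  write_mgf(orig, p)
  back <- read_mgf(p)
  expect_length(back, 50)
  for (i in seq_along(orig)) {
    expect_lt(max(abs(back[[i]]$peaks$mz - orig[[i]]$peaks$mz)), 1e-6)
    rel <- abs(back[[i]]$peaks$intensity - orig[[i]]$peaks$intensity) /
      orig[[i]]$peaks$intensity
    expect_lt(max(rel), 1e-6)
    expect_equal(back[[i]]$precursor_mz, orig[[i]]$precursor_mz,
                 tolerance = 1e-8)
  }
})

test_that("malformed MGF blocks raise errors naming the line", {
  bad <- tempfile(fileext = ".mgf")
  writeLines(c("BEGIN IONS", "PEPMASS=100", "50.0 1"), bad)
  expect_error(read_mgf(bad), "never closed")
  bad2 <- tempfile(fileext = ".mgf")
  writeLines(c("BEGIN IONS", "PEPMASS=100", "oops_not_a_peak", "END IONS"),
             bad2)
  expect_error(read_mgf(bad2), "line 3")
})

test_that("MSP records parse into spectra", {
  p <- tempfile(fileext = ".msp")
  writeLines(c("Name: compound_a", "PrecursorMZ: 180.0634",
               "Num Peaks: 2", "60.02 10", "85.03 55", "",
               "Name: compound_b", "PrecursorMZ: 120.1",
               "Num Peaks: 1", "77.04 3", ""), p)
  ss <- read_msp(p)
  expect_length(ss, 2)
  expect_equal(ss[[1]]$id, "compound_a")
  expect_equal(n_peaks(ss[[1]]), 2)
  expect_equal(ss[[2]]$precursor_mz, 120.1)
})

test_that("peak matching is one-to-one, within tolerance and maximal", {
  s <- spectrum(c(100, 200, 300), c(1, 1, 1))
  m <- match_peaks(s, s, 7)
  expect_equal(m[, "index_a"], m[, "index_b"])
  expect_equal(nrow(m), 3)

  a <- spectrum(100.000, 1)
  b <- spectrum(100.001, 1)  # 10 ppm apart, window at 7 ppm is 0.0007 Da
  expect_equal(nrow(match_peaks(a, b, 7)), 0)

  set.seed(202)
  for (i in seq_len(100)) {
    a <- rand_spectrum(5, 50, 500)
    # half the cases share some masses with jitter inside/outside tolerance
    b <- if (i %% 2 == 0) rand_spectrum(5, 50, 500) else {
      mz <- a$peaks$mz * (1 + rnorm(n_peaks(a), 0, 5e-6))
      spectrum(mz, runif(length(mz)))
    }
    m <- match_peaks(a, b, 7)
    expect_equal(anyDuplicated(m[, 1]), 0)
    expect_equal(anyDuplicated(m[, 2]), 0)
    if (nrow(m)) {
      da <- a$peaks$mz[m[, 1]]; db <- b$peaks$mz[m[, 2]]
      expect_true(all(abs(da - db) <= 7e-6 * pmax(da, db)))
    }
    expect_equal(nrow(m),
                 bipartite_max_matching_size(a$peaks$mz, b$peaks$mz, 7))
  }
})

test_that("cosine score matches a hand-computed dot product", {
  a <- spectrum(c(100, 200, 300), c(3, 4, 0.5))
  b <- spectrum(c(100.0001, 250, 300.0001), c(1, 2, 2))
  # matches: (100, 100.0001) and (300, 300.0001)
  expected <- (3 * 1 + 0.5 * 2) /
    (sqrt(3^2 + 4^2 + 0.5^2) * sqrt(1 + 4 + 4))
  expect_equal(cosine_score(a, b, exclude_precursor = FALSE), expected,
               tolerance = 1e-12)
  expect_equal(cosine_score(a, a), 1)
  d <- spectrum(c(120, 220), c(1, 1))
  e <- spectrum(c(150, 260), c(1, 1))
  expect_equal(cosine_score(d, e), 0)
})

test_that("cosine score is symmetric and bounded on random spectra", {
  set.seed(303)
  for (i in seq_len(1000)) {
    a <- rand_spectrum(sample(2:8, 1))
    b <- if (i %% 3 == 0) a else rand_spectrum(sample(2:8, 1))
    sq <- i %% 2 == 0
    ab <- cosine_score(a, b, sqrt_intensities = sq)
    ba <- cosine_score(b, a, sqrt_intensities = sq)
    expect_equal(ab, ba, tolerance = 1e-12)
    expect_gte(ab, 0); expect_lte(ab, 1)
  }
})

test_that("precursor peaks are excluded from the cosine", {
  base <- spectrum(c(100, 150), c(1, 1), precursor_mz = 200)
  with_pre <- spectrum(c(100, 150, 200), c(1, 1, 50), precursor_mz = 200)
  expect_equal(cosine_score(base, with_pre), cosine_score(base, base))
  empty_after <- spectrum(200, 1, precursor_mz = 200)
  expect_error(cosine_score(empty_after, empty_after), "undefined")
})

test_that("merging collision energies produces pseudo-ramp spectra", {
  s <- spectrum(c(100, 200), c(1, 2), precursor_mz = 300,
                collision_energy = 10)
  m1 <- merge_spectra(list(s))
  expect_equal(m1$collision_energy, "merged")
  expect_equal(m1$peaks$mz, s$peaks$mz, tolerance = 1e-9)

  s2 <- spectrum(c(100, 200), c(4, 2), precursor_mz = 300,
                 collision_energy = 40)
  m2 <- merge_spectra(list(s, s2))
  expect_equal(n_peaks(m2), 2)
  # per-input normalization to max 1, then summed
  expect_equal(m2$peaks$intensity, c(0.5 + 1, 1 + 0.5), tolerance = 1e-12)

  set.seed(404)
  for (i in 1:20) {
    parts <- lapply(1:3, function(k) rand_spectrum(6, precursor = 500))
    mm <- merge_spectra(parts)
    all_in <- unlist(lapply(parts, function(p) p$peaks$mz))
    for (mz in mm$peaks$mz)
      expect_true(any(abs(all_in - mz) <= 7e-6 * pmax(all_in, mz)))
  }
  expect_error(merge_spectra(list()), "empty")
  expect_error(merge_spectra(list(
    spectrum(100, 1, precursor_mz = 200),
    spectrum(100, 1, precursor_mz = 300))), "disagree")
})
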