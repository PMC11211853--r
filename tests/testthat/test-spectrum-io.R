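test_that("MGF blocks parse to spectra with sorted peaks", {
  f <- tempfile(fileext = ".mgf")
  writeLines(c("BEGIN IONS", "TITLE=scan=12 demo", "PEPMASS=500.25",
               "CHARGE=2+", "300.1 10", "100.5 5", "200.2 7", "END IONS"), f)
  sp <- read_mgf(f)
  expect_length(sp, 1L)
  expect_equal(sp[[1]]$charge, 2L)
  expect_equal(sp[[1]]$mz, c(100.5, 200.2, 300.1))
  expect_equal(sp[[1]]$intensity, c(5, 7, 10))
  # block without CHARGE is skipped, not guessed
  writeLines(c("BEGIN IONS", "TITLE=a", "PEPMASS=400", "CHARGE=2+",
               "100 1", "END IONS",
               "BEGIN IONS", "TITLE=b", "PEPMASS=500", "100 1", "END IONS"), f)
  expect_message(sp <- read_mgf(f), "without charge")
  expect_length(sp, 1L)
  # unparseable peak line errors with its line number
  writeLines(c("BEGIN IONS", "TITLE=a", "PEPMASS=400", "CHARGE=2+",
               "100 xyz", "END IONS"), f)
  expect_error(read_mgf(f), "line 5")
})

test_that("MGF write-read round trip preserves fields within 1e-6", {
  prot <- simulate_proteome(5, 150, seed = 8)
  sim <- simulate_spectra(prot, n_spectra = 10, seed = 9,
                          scheme = static_scheme())
  f <- tempfile(fileext = ".mgf")
  write_mgf(sim$spectra, f)
  back <- read_mgf(f)
  expect_length(back, 10L)
  for (i in seq_along(back)) {
    expect_equal(back[[i]]$spectrum_id, sim$spectra[[i]]$spectrum_id)
    expect_equal(back[[i]]$charge, sim$spectra[[i]]$charge)
    expect_equal(back[[i]]$precursor_mz, sim$spectra[[i]]$precursor_mz,
                 tolerance = 1e-6)
    expect_equal(back[[i]]$mz, sim$spectra[[i]]$mz, tolerance = 1e-6)
    expect_equal(back[[i]]$intensity, sim$spectra[[i]]$intensity,
                 tolerance = 1e-6)
  }
})

test_that("binning sqrt-transforms and scales each region to max 50", {
  empty <- spectrum("e", 500, 2, numeric(0), numeric(0))
  expect_true(all(bin_spectrum(empty, n_bins = 100)$u == 0))
  one <- spectrum("o", 500, 2, 355.7, 42)
  b <- bin_spectrum(one)
  expect_equal(sum(b$u > 0), 1L)
  expect_equal(max(b$u), 50)
  # independent reimplementation of the stated transform
  set.seed(21)
  s <- spectrum("r", 600, 2, sort(runif(80, 100, 1200)), rexp(80))
  got <- bin_spectrum(s, bin_width = 1.0005079, region_count = 10)
  n_bins <- length(got$u)
  u <- numeric(n_bins)
  for (i in seq_along(s$mz)) {
    k <- floor(s$mz[i] / 1.0005079) + 1
    u[k] <- u[k] + s$intensity[i]
  }
  u <- sqrt(u)
  reg <- ceiling(seq_len(n_bins) / (n_bins / 10))
  reg[reg > 10] <- 10
  for (r in 1:10) {
    ii <- reg == r
    if (max(u[ii]) > 0) u[ii] <- u[ii] / max(u[ii]) * 50
  }
  expect_equal(got$u, u, tolerance = 1e-12)
})

test_that("top-q filtering keeps the q most intense peaks per window", {
  s <- spectrum("t", 500, 2, c(110, 120, 130, 140, 150), c(5, 3, 9, 1, 7))
  f2 <- top_q_filter(s, 2)
  expect_equal(f2$mz, c(130, 150))
  expect_equal(top_q_filter(s, 10)$mz, s$mz)  # q > peaks: identity
  set.seed(31)
  for (trial in 1:20) {
    s <- spectrum("r", 700, 2, runif(60, 100, 900), rexp(60))
    q <- sample(1:10, 1)
    got <- top_q_filter(s, q)
    # oracle: sort-and-slice within each floor(mz/100) window
    keep <- unlist(lapply(split(seq_along(s$mz), floor(s$mz / 100)),
                          function(ii) {
      ii[order(-s$intensity[ii], s$mz[ii])][seq_len(min(q, length(ii)))]
    }))
    expect_setequal(got$mz, s$mz[keep])
    # subset of input and idempotent
    expect_true(all(got$mz %in% s$mz))
    again <- top_q_filter(got, q)
    expect_equal(again$mz, got$mz)
  }
})

test_that("mzTab write-read round trip is field-exact", {
  set.seed(41)
  n <- 100
  psms <- data.frame(
    spectrum_id = sprintf("sp%03d", 1:n),
    peptide = replicate(n, paste(sample(c("A", "K", "M[+15.994915]", "R"),
                                        8, replace = TRUE), collapse = "")),
    score = round(rnorm(n), 6),
    is_decoy = sample(c(TRUE, FALSE), n, replace = TRUE),
    precursor_mz = round(runif(n, 300, 1400), 6),
    charge = sample(2:4, n, replace = TRUE))
  f <- tempfile(fileext = ".mztab")
  write_mztab(psms, f)
  back <- read_mztab(f)
  expect_equal(back$spectrum_id, psms$spectrum_id)
  expect_equal(back$peptide, psms$peptide)
  expect_equal(back$score, psms$score, tolerance = 1e-6)
  expect_equal(back$is_decoy, psms$is_decoy)
  expect_equal(back$precursor_mz, psms$precursor_mz, tolerance = 1e-6)
  expect_equal(back$charge, psms$charge)
  # zero PSMs: header-only file still parses
  write_mztab(psms[0, ], f)
  expect_true(any(grepl("^MTD", readLines(f))))
  expect_equal(nrow(read_mztab(f)), 0L)
  expect_error(write_mztab(rbind(psms, psms[1, ]), f), "one PSM per")
})

test_that("PIN export is column-valid with +/-1 labels", {
  psms <- data.frame(spectrum_id = c("scan=5 t", "d"),
                     peptide = c("PEPTIDEK", "EPTDEPIK"),
                     score = c(1.5, -0.2), is_decoy = c(FALSE, TRUE),
                     precursor_mz = c(450.1, 450.1), charge = c(2L, 3L))
  f <- tempfile(fileext = ".pin")
  write_pin(psms, f)
  lines <- readLines(f)
  expect_length(lines, 3L)
  fields <- strsplit(lines, "\t")
  expect_true(all(lengths(fields) == lengths(fields)[1]))
  expect_equal(vapply(fields[-1], `[`, "", 2), c("1", "-1"))
  expect_equal(fields[[2]][3], "5")  # scan number lifted from the title
  expect_true(validate_pin(f))
  # corrupt label detected
  lines[2] <- sub("\t1\t", "\t9\t", lines[2])
  writeLines(lines, f)
  expect_error(validate_pin(f), "Label")
})
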