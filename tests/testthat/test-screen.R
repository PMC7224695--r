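make_screen_fixture <- function(ppm_sd = 0, n_decoy_spectra = 3,
                                intensities = c(5e3, 1.2e3, 5e2, 2e3),
                                seed = 31) {
  lib <- build_library(3:9, include_unsaturated = TRUE,
                       heads = c("UB", "UP"))
  planted_names <- c("asc-C7", "2'-(asc-C5)-asc-C4", "4'-UB-asc-C5",
                     "4'-UP-asc-C4")
  planted <- lib[match(planted_names, lib$name), ]
  spectra <- simulate_spectra(planted, ppm_sd = ppm_sd, n_decoys = 5,
                              intensity = intensities,
                              n_decoy_spectra = n_decoy_spectra, seed = seed)
  list(lib = lib, planted_names = planted_names, spectra = spectra)
}

test_that("planted compounds are recalled exactly with zero ppm error", {
  fx <- make_screen_fixture()
  res <- screen_spectra(fx$spectra, fx$lib)
  # every planted spectrum matched, with the true name in its isomer set
  for (i in seq_along(fx$planted_names)) {
    rows <- res[res$spectrum_id == sprintf("planted_%03d_%s", i,
                                           fx$planted_names[i]), ]
    expect_gt(nrow(rows), 0)
    expect_true(any(vapply(rows$candidates,
                           function(x) fx$planted_names[i] %in% x,
                           logical(1))))
  }
  # no decoy spectrum matches anything
  expect_identical(sum(grepl("^decoy", res$spectrum_id)), 0L)
})

test_that("a precursor shifted beyond tolerance is not matched", {
  lib <- build_library(c(4, 5))
  mz <- lib$mz_MpNa[match("asc-C5", lib$name)]
  hit <- spectrum("s1", mz, "positive", precursor_intensity = 2e3)
  off <- spectrum("s2", mz * (1 + 50e-6), "positive",
                  precursor_intensity = 2e3)
  cfg <- screen_config(precursor_tol_ppm = 5)
  expect_gt(nrow(match_spectrum(hit, lib, cfg)), 0)
  expect_identical(nrow(match_spectrum(off, lib, cfg)), 0L)
})

test_that("diagnostic fragment peaks flip fragments_confirmed", {
  lib <- build_library(c(4, 5), heads = "UB")
  st <- lib$structure[[match("4'-UB-asc-C5", lib$name)]]
  frag_mz <- ion_mz("C11H18N2O5", "M+H")  # head + sugar - 2 H2O
  prec <- ion_mz(st$formula, "M+Na")
  with_frag <- spectrum("w", prec, "positive",
                        peaks = data.frame(mz = frag_mz, intensity = 500),
                        precursor_intensity = 2e3)
  without <- spectrum("wo", prec, "positive", precursor_intensity = 2e3)
  r1 <- match_spectrum(with_frag, lib)
  r2 <- match_spectrum(without, lib)
  expect_true(any(r1$fragments_confirmed[r1$class == "UBAS"]))
  expect_false(any(r2$fragments_confirmed[r2$class == "UBAS"]))
})

test_that("enlarging tolerances never removes a match", {
  fx <- make_screen_fixture(ppm_sd = 3, seed = 77)
  narrow <- screen_spectra(fx$spectra, fx$lib,
                           screen_config(precursor_tol_ppm = 5,
                                         fragment_tol_ppm = 10))
  wide <- screen_spectra(fx$spectra, fx$lib,
                         screen_config(precursor_tol_ppm = 15,
                                       fragment_tol_ppm = 30))
  key <- function(df) paste(df$spectrum_id, df$formula, df$adduct)
  expect_true(all(key(narrow) %in% key(wide)))
})

test_that("mass-identical isomer sets are never reported as resolved", {
  lib <- build_library(c(4, 5))
  dimer <- lib$structure[[match("2'-(asc-C5)-asc-C4", lib$name)]]
  sp <- spectrum("iso", ion_mz(dimer$formula, "M+Na"), "positive",
                 precursor_intensity = 2e3)
  res <- match_spectrum(sp, lib)
  expect_identical(nrow(res), 1L)
  # 2'/4' linkages x (C5,C4)/(C4,C5) order are all mass-identical
  expect_gte(res$n_isomers, 4L)
})

test_that("targeted fragment screen returns exactly the planted spectra", {
  ub_mz <- ion_mz("C11H18N2O5", "M+H")
  mk <- function(id, peaks_mz) {
    spectrum(id, 400, "positive",
             peaks = data.frame(mz = peaks_mz, intensity = 100))
  }
  spectra <- c(
    lapply(1:3, function(i) mk(paste0("hit", i), c(ub_mz, 150.1))),
    lapply(1:7, function(i) mk(paste0("miss", i), c(150.1, 300.2)))
  )
  expect_setequal(targeted_fragment_screen(spectra, ub_mz),
                  paste0("hit", 1:3))
  expect_identical(
    targeted_fragment_screen(spectra[4:10], ub_mz), character(0))
  # ppm boundary behavior
  at3 <- mk("at3", ub_mz * (1 + 3e-6))
  at30 <- mk("at30", ub_mz * (1 + 30e-6))
  cfg <- screen_config(fragment_tol_ppm = 10)
  expect_identical(
    targeted_fragment_screen(list(at3, at30), ub_mz, config = cfg), "at3")
})

test_that("intensity calls follow the quantifiable/trace threshold", {
  cfg <- screen_config(intensity_threshold = 1e3)
  expect_identical(classify_abundance(1.2e3, cfg), "quantifiable")
  expect_identical(classify_abundance(9.9e2, cfg), "trace")
  expect_identical(classify_abundance(0, cfg), "absent")
  expect_identical(classify_abundance(1e3, cfg), "quantifiable")
  expect_error(classify_abundance(-1, cfg), "negative")
  # raising the threshold never converts absent to quantifiable
  x <- c(0, 500, 1500, 1e4)
  lo <- classify_abundance(x, screen_config(intensity_threshold = 1e3))
  hi <- classify_abundance(x, screen_config(intensity_threshold = 2e3))
  expect_true(all(!(lo == "absent" & hi == "quantifiable")))
  expect_true(all(hi[lo == "absent"] == "absent"))
})
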