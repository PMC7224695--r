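test_that("replicate means treat missing detections as zero", {
  areas <- tibble::tibble(
    species = "sp1", compound = "a", replicate = 1:3,
    area = c(3000, 0, 3000)
  )
  expect_equal(aggregate_replicates(areas)$mean_area, 2000)

  # compound recorded in only 1 of 3 replicates still divides by 3
  areas2 <- dplyr::bind_rows(
    areas,
    tibble::tibble(species = "sp1", compound = "b", replicate = 1,
                   area = 900)
  )
  m <- aggregate_replicates(areas2)
  expect_equal(m$mean_area[m$compound == "b"], 300)

  single <- tibble::tibble(species = "s", compound = "a", replicate = 1,
                           area = 42)
  expect_equal(aggregate_replicates(single)$mean_area, 42)
  expect_error(aggregate_replicates(dplyr::mutate(single, area = -1)),
               "negative")
})

test_that("within-class percentages sum to 100 per nonzero class", {
  fx <- make_test_areas()
  prof <- within_class_percentages(aggregate_replicates(fx$areas),
                                   fx$class_map)
  sums <- prof |>
    dplyr::group_by(species, class) |>
    dplyr::summarise(s = sum(percent), .groups = "drop")
  expect_true(all(abs(sums$s - 100) < 1e-9 | sums$s == 0))
  # the DASC-free species has an all-zero class, not NaN
  dasc3 <- prof$percent[prof$species == "sp3" &
                          prof$class == "DASC"]
  expect_identical(dasc3, c(0, 0))
})

test_that("monomeric and dimeric UBAS are standardized separately", {
  areas <- tibble::tibble(
    species = "sp1", replicate = 1,
    compound = c("ubas#1", "ubas#28"),
    area = c(200, 800)
  )
  cmap <- tibble::tibble(compound = c("ubas#1", "ubas#28"),
                         class = c("UBAS-monomeric", "UBAS-dimeric"))
  prof <- within_class_percentages(aggregate_replicates(areas), cmap)
  expect_equal(prof$percent, c(100, 100))
})

test_that("unmapped compounds are rejected", {
  fx <- make_test_areas()
  expect_error(
    within_class_percentages(aggregate_replicates(fx$areas),
                             fx$class_map[-1, ]),
    "missing from the class map"
  )
})

test_that("closed compositions sum to 100 and reject all-zero species", {
  means <- tibble::tibble(
    species = rep(c("x", "y"), each = 3),
    compound = rep(c("a", "b", "c"), 2),
    mean_area = c(1, 1, 2, 60, 40, 0)
  )
  closed <- close_composition(means)
  expect_equal(closed$percent[closed$species == "x"], c(25, 25, 50))
  expect_equal(closed$percent[closed$species == "y"], c(60, 40, 0))
  sums <- tapply(closed$percent, closed$species, sum)
  expect_true(all(abs(sums - 100) < 1e-9))
  expect_error(
    close_composition(dplyr::mutate(means, mean_area = 0)), "all-zero")
})

test_that("profiles are invariant to per-species rescaling", {
  fx <- make_test_areas()
  m1 <- aggregate_replicates(fx$areas)
  scaled <- fx$areas |>
    dplyr::mutate(area = area * ifelse(species == "sp1", 7.5, 1))
  m2 <- aggregate_replicates(scaled)
  expect_equal(within_class_percentages(m1, fx$class_map)$percent,
               within_class_percentages(m2, fx$class_map)$percent)
  expect_equal(close_composition(m1)$percent, close_composition(m2)$percent)
})

test_that("presence calls use mean >= threshold and are monotone", {
  means <- tibble::tibble(species = "s", compound = c("a", "b", "c"),
                          mean_area = c(1.5e3, 5e2, 0))
  pa <- presence_absence(means, threshold = 1e3)
  expect_identical(pa$present, c(TRUE, FALSE, FALSE))  # trace coded absent
  pa0 <- presence_absence(means, threshold = 0)
  expect_identical(pa0$present, c(TRUE, TRUE, FALSE))
  # monotone non-increasing in threshold
  for (thr in c(10, 600, 2000)) {
    lo <- presence_absence(means, threshold = thr)$present
    hi <- presence_absence(means, threshold = thr * 2)$present
    expect_true(all(lo >= hi))
  }
})

test_that("conservation patterns classify constant/singleton/variable", {
  presence <- tibble::tibble(
    species = rep(paste0("s", 1:6), 3),
    compound = rep(c("const", "single", "var"), each = 6),
    present = c(rep(TRUE, 6),
                c(TRUE, rep(FALSE, 5)),
                c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))
  )
  pat <- conservation_pattern(presence)
  expect_identical(pat$pattern[match(c("const", "single", "var"),
                                     pat$compound)],
                   c("constant", "singleton", "variable"))
})
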