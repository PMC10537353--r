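test_that("spearman_rho handles monotone, reversed, tied and degenerate input", {
  expect_equal(spearman_rho(c(1, 2, 3), c(10, 20, 30)), 1)
  expect_equal(spearman_rho(c(1, 2, 3), c(3, 2, 1)), -1)
  # tied zeros, hand-enumerated mid-rank correlation
  expect_equal(spearman_rho(c(0, 0, 3, 10, 0), c(0, 0, 5, 2, 0)), 0.875)
  # zero-variance series: undefined, caller decides
  expect_true(is.na(spearman_rho(c(2, 2, 2), c(1, 2, 3))))
  expect_error(spearman_rho(1:3, 1:4), "equal length")
  expect_error(spearman_rho(1:2, 2:1), ">= 3")
})

test_that("synchrony is 1 for shared profiles and uses |rho| per pair", {
  profile <- c(0, 2, 8, 1, 0, 4)
  grid <- rbind(profile, 3 * profile, 7 * profile)
  expect_equal(synchrony_ri(floral_calendar(grid))$r_i, 1)

  # two plants in perfect opposition: |rho| = 1 before averaging
  anti <- floral_calendar(rbind(c(1, 2, 3, 4), c(4, 3, 2, 1)))
  res <- synchrony_ri(anti)
  expect_equal(res$r_i, 1)
  expect_equal(res$n_pairs_used, 1L)

  # three plants, brute-force oracle over the three pairs
  grid3 <- rbind(A = c(0, 2, 8, 1), B = c(1, 3, 9, 0), C = c(5, 0, 0, 7))
  expect_equal(synchrony_ri(floral_calendar(grid3))$r_i, naive_ri(grid3))

  expect_error(synchrony_ri(floral_calendar(matrix(1:4, 1))), ">= 2")
})

test_that("undefined pairs are dropped and counted, never imputed", {
  grid <- rbind(c(1, 5, 2), c(3, 3, 3), c(2, 1, 4))
  res <- synchrony_ri(floral_calendar(grid))
  expect_equal(res$n_pairs_used + res$n_pairs_dropped, 3L) # n(n-1)/2
  expect_equal(res$n_pairs_dropped, 2L) # both pairs with the constant plant
  expect_equal(res$r_i, abs(naive_spearman(grid[1, ], grid[3, ])))

  all_const <- floral_calendar(rbind(c(2, 2, 2), c(5, 5, 5)))
  expect_true(is.na(synchrony_ri(all_const)$r_i))
  expect_equal(synchrony_ri(all_const)$n_pairs_dropped, 1L)
})

test_that("individual_cv matches closed forms under both denominators", {
  expect_equal(individual_cv(rep(4, 10)), 0)
  # single spike among n weeks: CV = sqrt(n) under the sample-sd convention
  spike <- c(100, rep(0, 24))
  expect_equal(individual_cv(spike), 5)
  expect_equal(individual_cv(c(2, 0, 6, 0)), sqrt(2))
  # population convention scales by sqrt((n-1)/n)
  expect_equal(individual_cv(spike, "n"), 5 * sqrt(24 / 25))
  expect_error(individual_cv(c(0, 0, 0)), "mean")
  expect_error(individual_cv(3), "length")
})

test_that("temporal variability averages per-plant CVs", {
  const <- floral_calendar(rbind(c(3, 3, 3), c(7, 7, 7)))
  expect_equal(temporal_variability_cvi(const), 0)

  single <- floral_calendar(matrix(c(2, 0, 6, 0), 1))
  expect_equal(temporal_variability_cvi(single), sqrt(2))

  grid <- rbind(c(2, 0, 6, 0), c(1, 1, 1, 5), c(0, 0, 9, 3))
  expect_equal(temporal_variability_cvi(floral_calendar(grid)), naive_cvi(grid))
})

test_that("count_events is the union of flowering weeks and is monotone", {
  expect_equal(count_events(floral_calendar(matrix(0, 2, 5))), 0L)
  full <- floral_calendar(matrix(1, 2, 5))
  expect_equal(count_events(full), 5)

  grid <- matrix(0, 2, 9)
  grid[1, c(1, 5)] <- 3
  grid[2, c(5, 9)] <- 2
  expect_equal(count_events(floral_calendar(grid)), 3)

  # adding counts never decreases the event count
  withr::local_seed(5)
  for (i in 1:20) {
    g <- matrix(sample(0:2, 12, replace = TRUE), 3, 4)
    more <- g
    idx <- sample(length(g), 3)
    more[idx] <- more[idx] + sample(1:3, 3, replace = TRUE)
    expect_gte(
      count_events(floral_calendar(more)),
      count_events(floral_calendar(g))
    )
  }
})

test_that("r_i is invariant under strictly increasing per-plant transforms", {
  withr::local_seed(21)
  for (i in 1:15) {
    cal <- random_small_calendar()
    transformed <- cal$counts
    for (p in seq_len(nrow(transformed))) {
      transformed[p, ] <- if (p %% 2 == 0) {
        transformed[p, ]^2 # strictly increasing on non-negative integers
      } else {
        5 * transformed[p, ] + 1
      }
    }
    expect_equal(
      synchrony_ri(floral_calendar(transformed))$r_i,
      synchrony_ri(cal)$r_i,
      tolerance = 1e-12
    )
  }
})

test_that("cv_i is invariant under positive scaling of any plant's series", {
  withr::local_seed(22)
  for (i in 1:15) {
    cal <- random_small_calendar()
    scaled <- cal$counts
    scaled[1, ] <- 7 * scaled[1, ]
    expect_equal(
      temporal_variability_cvi(floral_calendar(scaled)),
      temporal_variability_cvi(cal),
      tolerance = 1e-12
    )
  }
})

test_that("descriptor_table assembles one labelled row per calendar", {
  cals <- tidyr::expand_grid(
    department = c("Caldas", "Cesar"), semester = c("1st", "2nd")
  ) %>%
    dplyr::mutate(calendar = purrr::map2(
      department, semester,
      ~ floral_calendar(rbind(c(0, 2, 5), c(1, 3, 0)),
        department = .x, semester = .y
      )
    ))
  tab <- descriptor_table(cals)
  expect_equal(nrow(tab), 4L)
  expect_equal(tab$department, rep(c("Caldas", "Cesar"), each = 2))
  expect_true(all(tab$event == 3))
  expect_true(all(tab$n_pairs_used + tab$n_pairs_dropped ==
    tab$n_plants * (tab$n_plants - 1) / 2))

  # single calendar and empty input
  one <- descriptor_table(floral_calendar(rbind(c(1, 0, 2), c(0, 2, 1))))
  expect_equal(nrow(one), 1L)
  expect_equal(nrow(descriptor_table(list())), 0L)
})

test_that("descriptor_table flags undersized populations instead of dropping them", {
  cals <- list(
    floral_calendar(rbind(c(1, 2, 0), c(0, 1, 3)), accession = "ok"),
    floral_calendar(rbind(c(1, 2, 0), c(0, 0, 0)), accession = "one_plant"),
    floral_calendar(matrix(0, 3, 3), accession = "silent")
  )
  tab <- descriptor_table(cals)
  expect_equal(nrow(tab), 3L)
  flagged <- tab[tab$accession != "ok", ]
  expect_true(all(is.na(flagged$r_i)))
  expect_true(all(!is.na(flagged$note)))
  expect_false(is.na(tab$r_i[tab$accession == "ok"]))
  expect_equal(tab$event[tab$accession == "silent"], 0L)
})

test_that("descriptors match the naive oracle on random small calendars", {
  withr::local_seed(99)
  for (i in 1:100) {
    cal <- random_small_calendar()
    expect_equal(synchrony_ri(cal)$r_i, naive_ri(cal$counts),
      tolerance = 1e-12
    )
    expect_equal(temporal_variability_cvi(cal), naive_cvi(cal$counts),
      tolerance = 1e-12
    )
  }
})
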