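# Synthetic glycolysis data generation and split bookkeeping

test_that("noise-free generation returns the truth exactly", {
  ds <- generate_glycolysis_dataset(data_setting(16, 0, seed = 1))
  tr <- ds$truth[ds$truth$window == "train", ]
  joined <- dplyr::inner_join(ds$measurements, tr,
                              by = c("time", "observable"))
  expect_equal(joined$measurement, joined$value, tolerance = 1e-12)
  expect_true(all(ds$sigma == 0))
})

test_that("time grids are uniform and inclusive of both endpoints", {
  ds <- generate_glycolysis_dataset(data_setting(46, 5, seed = 1))
  times <- sort(unique(ds$measurements$time))
  expect_length(times, 46)
  expect_equal(times[1], 0)
  expect_equal(times[46], 1.5)
  expect_equal(diff(times), rep(1.5 / 45, 45), tolerance = 1e-12)
  # 46 points per observable
  expect_equal(unname(table(ds$measurements$observable)), c(46L, 46L),
               ignore_attr = TRUE)
})

test_that("noise realisations are calibrated and independent", {
  # empirical SD of (noisy - truth) matches the configured sigma within 5%
  setting <- data_setting(16, 20, seed = 1)
  base <- generate_glycolysis_dataset(setting)
  truth <- base$truth[base$truth$window == "train", ]
  n_rep <- 1000
  resid <- matrix(NA_real_, nrow(base$measurements), n_rep)
  for (r in seq_len(n_rep)) {
    ds <- generate_glycolysis_dataset(data_setting(16, 20, seed = r),
                                      test_points = 2L)
    m <- dplyr::inner_join(ds$measurements, truth,
                           by = c("time", "observable"))
    resid[, r] <- m$measurement - m$value
  }
  for (o in c("N2", "A3")) {
    sel <- base$measurements$observable == o
    emp <- sd(as.numeric(resid[sel, ]))
    expect_lt(abs(emp - base$sigma[[o]]) / base$sigma[[o]], 0.05)
  }
  # independence across records: neighbouring-record correlation near zero
  cors <- cor(t(resid[1:10, ]))
  off <- cors[upper.tri(cors)]
  expect_lt(max(abs(off)), 0.15)
})

test_that("train/validation bookkeeping reproduces the canonical splits", {
  cases <- list(c(8, 5, 3), c(16, 8, 8), c(31, 16, 15), c(46, 24, 22),
                c(61, 31, 30))
  for (cs in cases) {
    ds <- generate_glycolysis_dataset(data_setting(cs[1], 5, seed = 2),
                                      test_points = 2L)
    m <- ds$measurements
    per_obs <- dplyr::count(m, .data$observable, .data$partition)
    for (o in c("N2", "A3")) {
      expect_equal(per_obs$n[per_obs$observable == o &
                               per_obs$partition == "train"], cs[2],
                   info = paste(cs[1], "points"))
      expect_equal(per_obs$n[per_obs$observable == o &
                               per_obs$partition == "validation"], cs[3],
                   info = paste(cs[1], "points"))
    }
    # the initial condition always trains
    expect_true(all(m$partition[m$time == 0] == "train"))
    expect_true(all(m$is_initial == (m$time == 0)))
    # validation points are spread over the window, not clumped
    vt <- sort(unique(m$time[m$partition == "validation"]))
    expect_gt(max(vt) - min(vt), 0.5 * 1.5)
  }
})

test_that("non-canonical point counts fall back to 1:1 with a warning", {
  d <- tibble::tibble(time = seq(0, 1.5, length.out = 11),
                      observable = "N2", measurement = rnorm(11))
  expect_warning(out <- split_dataset(d, 11), "1:1")
  expect_equal(sum(out$partition == "validation"), 5)
})

test_that("the noise-free test truth is identical across noise settings", {
  a <- generate_glycolysis_dataset(data_setting(16, 5, seed = 1))
  b <- generate_glycolysis_dataset(data_setting(16, 35, seed = 9))
  expect_identical(a$truth[a$truth$window == "test", ],
                   b$truth[b$truth$window == "test", ])
})

test_that("measurement tables round-trip through the TSV dialect", {
  ds <- generate_glycolysis_dataset(data_setting(8, 10, seed = 3),
                                    test_points = 2L)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_measurements(ds$measurements, path)
  back <- read_measurements(path, problem = glycolysis_problem(),
                            split = NULL)
  expect_equal(back$measurement, ds$measurements$measurement,
               tolerance = 1e-12)
  expect_equal(back$time, ds$measurements$time)
  # unknown observables are rejected against a problem
  tab <- readr::read_tsv(path, show_col_types = FALSE)
  tab$observableId[1] <- "mystery"
  readr::write_tsv(tab, path)
  expect_error(read_measurements(path, problem = glycolysis_problem()),
               "unknown observables")
})

test_that("the real-data convention splits 16 time points 4:1", {
  # a 48-record table shaped like the dimerisation dataset
  times <- c(0, 2.5, 5, 10, 15, 20, 30, 40, 50, 60, 80, 100, 120, 160, 200,
             240)
  tab <- tidyr::expand_grid(
    observableId = c("pSTAT5A_rel", "pSTAT5B_rel", "rSTAT5A_rel"),
    time = times
  )
  set.seed(8)
  tab$measurement <- runif(nrow(tab), 0, 100)
  path <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(tab, path)
  out <- read_measurements(path, problem = stat5_problem(), split = "4:1")
  expect_equal(nrow(out), 48)
  val_times <- unique(out$time[out$partition == "validation"])
  expect_length(val_times, 3) # 16 time points at 4:1 -> 3 held out
  expect_equal(length(unique(out$time[out$partition == "train"])), 13)
})

test_that("dataset artifacts are reproducible from their provenance", {
  dir <- withr::local_tempdir()
  ds1 <- generate_glycolysis_dataset(data_setting(8, 10, seed = 7),
                                     test_points = 5L)
  write_dataset(ds1, dir, stem = "g")
  prov <- jsonlite::read_json(file.path(dir, "g_provenance.json"))
  ds2 <- generate_glycolysis_dataset(
    data_setting(prov$n_points, prov$noise_percent, prov$seed),
    test_points = 5L)
  expect_equal(ds1$measurements, ds2$measurements, tolerance = 1e-15)
})
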