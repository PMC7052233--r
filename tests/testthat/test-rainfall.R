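test_that("regime construction conserves the annual total k*A*T = MAP", {
  r6 <- regime_from_MAP(k = 6, MAP = 100)
  expect_equal(r6$A, 100 * 365 / 6)            # 6083.33 mm/y
  expect_equal(r6$A_mm_day, 100 / 6, tolerance = 1e-12)
  r1 <- regime_from_MAP(k = 1, MAP = 100)
  expect_equal(r1$A, 36500)                    # 100 mm in one day
  r0 <- regime_from_MAP(k = 4, MAP = 0)
  expect_equal(r0$A, 0)
  expect_true(all(precip_at(seq(0, 1, by = 1e-3), r0) == 0))
  # events must fit in the first half year
  expect_error(rainfall_regime(k = 200, T_event = 1 / 365, MAP = 100), "half")
  expect_error(rainfall_regime(k = 2, T_event = 1 / 365, MAP = 100,
                               event_starts = c(0, 0.4999)), "half")
  expect_error(rainfall_regime(k = 2, T_event = 2 / 365, MAP = 100,
                               event_starts = c(0, 1 / 365)), "overlap")
})

test_that("the square wave rains only inside first-half-year event windows", {
  reg <- regime_from_MAP(k = 6, MAP = 100)
  # dry second half of the year, in every year
  t2 <- c(seq(0.5, 0.999, by = 0.013), 1.7, 2.5001)
  expect_true(all(precip_at(t2, reg) == 0))
  # inside the first event window
  reg1 <- rainfall_regime(k = 1, T_event = 1 / 365, MAP = 100,
                          event_starts = 0)
  expect_equal(precip_at(0.5 / 365, reg1), reg1$A)
  expect_equal(precip_at(1.5 / 365, reg1), 0)
  # annual periodicity
  tt <- seq(0, 0.999, by = 1 / 1460)
  expect_equal(precip_at(tt + 1, reg), precip_at(tt, reg))
})

test_that("integrated annual precipitation equals MAP", {
  h <- 1 / (8 * 365)
  for (k in c(1, 6, 24)) {
    reg <- regime_from_MAP(k = k, MAP = 100)
    tt <- seq(0, 1 - h, by = h) + h / 2   # midpoint rule on a sub-daily grid
    q <- sum(precip_at(tt, reg)) * h
    expect_equal(q, 100, tolerance = 1e-9)  # day-aligned events: exact sum
  }
})

test_that("hillslope amplification has the printed shape and limits", {
  expect_equal(alpha_runoff(0), 0)
  expect_equal(alpha_runoff(100), 156 / 53)          # ~2.943
  expect_equal(alpha_runoff(1e9), 3.0, tolerance = 1e-6)  # alpha1/alpha2
  P <- seq(0, 200, by = 0.5)
  a <- alpha_runoff(P)
  expect_true(all(diff(a) >= 0))
  expect_true(all(a <= 3.0))
  # cubic low-intensity runoff yield: alpha*P ~ alpha1*P^3
  expect_equal(alpha_runoff(0.01) * 0.01, 0.0156 * 0.01^3, tolerance = 1e-6)
  expect_error(alpha_runoff(-1), ">= 0")
})

test_that("sampled series are periodic, conservative, and resolve events", {
  reg <- regime_from_MAP(k = 1, MAP = 100)
  s1 <- build_series(reg, years = 1)
  expect_equal(sum(s1$P > 0), 4)              # one pulse, dt = T/4
  s2 <- build_series(reg, years = 2)
  half <- length(s2$P) / 2
  expect_equal(s2$P[seq_len(half) + half], s2$P[seq_len(half)])
  dt <- diff(s2$times[1:2])
  expect_equal(sum(s2$P) * dt, 2 * 100, tolerance = 1e-9)
  expect_error(build_series(reg, 1, dt = 2 / 365), "T_event")
})

test_that("drought series swap per-event intensity between blocks", {
  sc <- drought_scenario(spinup_years = 2, drought_years = 3,
                         MAP_normal = 100, MAP_drought = 40,
                         recovery_years = 1)
  s <- build_drought_series(sc, k = 6)
  expect_equal(s$end, 6)
  peak <- function(y) max(series_at(seq(y, y + 0.49, by = 1 / 1460), s))
  expect_equal(peak(0) / 365, 100 / 6, tolerance = 1e-12)   # 16.67 mm/day
  expect_equal(peak(2) / 365, 40 / 6, tolerance = 1e-12)    # 6.67 mm/day
  expect_equal(peak(5) / 365, 100 / 6, tolerance = 1e-12)
  # degenerate scenarios reduce to the constant-MAP series
  for (sc0 in list(drought_scenario(2, 0, 100, 40, 1),
                   drought_scenario(2, 3, 100, 100, 1))) {
    yrs <- sc0$spinup_years + sc0$drought_years + sc0$recovery_years
    s0 <- build_drought_series(sc0, k = 6)
    ref <- build_series(regime_from_MAP(6, MAP = 100), yrs)
    # probe halfway between samples so grid-rounding cannot flip a lookup
    tt <- seq(0, yrs - 1e-3, by = 1 / 1460) + 1 / 2920
    expect_equal(series_at(tt, s0), series_at(tt, ref))
  }
  expect_error(drought_scenario(MAP_normal = 40, MAP_drought = 100), "MAP")
})

test_that("daily precipitation files round trip and conserve MAP", {
  reg <- regime_from_MAP(k = 6, MAP = 100)
  f <- withr::local_tempfile(fileext = ".txt")
  write_precip_file(reg, f, years = 1)
  tab <- read.table(f)
  expect_equal(nrow(tab), 365)
  expect_equal(sum(tab$V2), 100, tolerance = 1e-9)  # day-aligned events
  s <- read_precip_file(f)
  s2 <- build_series(reg, 1, dt = 1 / 365)
  expect_equal(series_at(s2$times, s), s2$P, tolerance = 1e-9)
  # write(read()) is the identity on daily series
  f2 <- withr::local_tempfile(fileext = ".txt")
  write_precip_file(s, f2)
  expect_identical(readLines(f), readLines(f2))
})

test_that("malformed precipitation files fail with a line number", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("1 0.5", "2 oops", "3 1"), f)
  expect_error(read_precip_file(f), "line 2")
  writeLines(c("1 0.5", "2 -3"), f)
  expect_error(read_precip_file(f), "negative.*line 2")
  writeLines(c("1 0.5", "3 1"), f)
  expect_error(read_precip_file(f), "consecutive")
})
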