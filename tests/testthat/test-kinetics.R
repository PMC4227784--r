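make_trace <- function(times, signal) {
  kinetic_trace(times, signal, construct = "M7-Luc-M7", mg_mM = 0.8, k_mM = 60)
}

test_that("trace validation sorts, deduplicates and checks metadata", {
  tr <- make_trace(c(3, 1, 2), c(30, 10, 20))
  expect_equal(tr$times, c(1, 2, 3))
  expect_equal(tr$signal, c(10, 20, 30))
  expect_error(make_trace(c(1, 2, 2), c(1, 2, 3)), "duplicate timestamp.*2")
  expect_error(make_trace(c(1, 2, 3), c(1, -2, 3)), "negative")
  expect_error(make_trace(c(1, 2), c(1, 2)), "at least 3")
  expect_error(kinetic_trace(1:5, 1:5, mg_mM = 0.8, k_mM = 60),
               "missing metadata fields: construct")
  expect_error(kinetic_trace(1:5, 1:5), "construct, mg_mM, k_mM")
  # the standard plate-reader run: 61 one-minute reads
  tr61 <- make_trace(0:60, seq(0, 600, by = 10))
  expect_length(tr61$times, 61)
})

test_that("max rate of linear and constant traces is exact for any window", {
  t <- 0:60
  for (w in c(2, 5, 10, 30)) {
    lin <- max_synthesis_rate(make_trace(t, 7.5 * t + 3), window_minutes = w)
    expect_equal(lin$max_rate, 7.5, tolerance = 1e-12)
    expect_equal(max_synthesis_rate(make_trace(t, rep(42, 61)),
                                    window_minutes = w)$max_rate, 0)
  }
  expect_error(max_synthesis_rate(make_trace(0:3, 1:4), window_minutes = 10),
               "shorter than")
  expect_error(max_synthesis_rate(make_trace(0:10, 0:10), window_minutes = 1),
               "2 sampling intervals")
})

test_that("windowed slope equals brute-force enumeration on a piecewise trace", {
  t <- 0:60
  y <- ifelse(t <= 30, t, 30 + 3 * (t - 30))
  for (w in c(5, 12)) {
    got <- max_synthesis_rate(make_trace(t, y), window_minutes = w)
    # independent oracle: lm() on every complete window
    best <- -Inf; best_start <- NA
    for (i in seq_along(t)) {
      j <- which(t >= t[i] & t <= t[i] + w)
      if (t[max(j)] - t[i] < w) next
      sl <- unname(coef(lm(y[j] ~ t[j]))[2])
      if (sl > best + 1e-12) { best <- sl; best_start <- t[i] }
    }
    expect_equal(got$max_rate, best, tolerance = 1e-9)
    expect_equal(got$window_start, best_start)
  }
})

test_that("max rate is slope-statistic invariant: shifts drop out, scales pass through", {
  withr::with_seed(8, {
    t <- 0:60
    y <- cumsum(runif(61, 0, 5))
    base <- max_synthesis_rate(make_trace(t, y))$max_rate
    expect_equal(max_synthesis_rate(make_trace(t, y + 100))$max_rate, base)
    expect_equal(max_synthesis_rate(make_trace(t, 3.7 * y))$max_rate,
                 3.7 * base)
  })
})

test_that("wide plate-reader exports map onto validated traces", {
  wide <- data.frame(time_min = 0:10, A1 = 2 * (0:10), A2 = 5 * (0:10),
                     check.names = FALSE)
  wmap <- data.frame(well = c("A1", "A2"), construct = "M7-Luc-M7",
                     mg_mM = c(0.4, 0.8), k_mM = 60, replicate = 1)
  traces <- read_trace_wide(wide, wmap)
  expect_length(traces, 2)
  expect_equal(traces[["A2"]]$signal, 5 * (0:10))
  expect_equal(traces[["A1"]]$meta$mg_mM, 0.4)
  expect_error(read_trace_wide(wide, wmap[, -1]), "lacks column")
  wmap_bad <- wmap
  wmap_bad$well[2] <- "B9"
  expect_error(read_trace_wide(wide, wmap_bad), "B9")
  # equivalent long-format input gives identical rates
  long <- rbind(
    data.frame(time_min = 0:10, signal_alu = 2 * (0:10), construct = "M7-Luc-M7",
               mg_mM = 0.4, k_mM = 60, replicate = 1),
    data.frame(time_min = 0:10, signal_alu = 5 * (0:10), construct = "M7-Luc-M7",
               mg_mM = 0.8, k_mM = 60, replicate = 1))
  expect_equal(rate_table(traces, 5)$max_rate, rate_table(long, 5)$max_rate)
})

test_that("trace tables round-trip through the reader and rate_table", {
  tab <- rbind(
    data.frame(time_min = 0:10, signal_alu = 2 * (0:10), construct = "A",
               mg_mM = 0.4, k_mM = 60, replicate = 1),
    data.frame(time_min = 0:10, signal_alu = 5 * (0:10), construct = "A",
               mg_mM = 0.8, k_mM = 60, replicate = 1))
  traces <- read_trace_table(tab)
  expect_length(traces, 2)
  rates <- rate_table(tab, window_minutes = 5)
  expect_equal(nrow(rates), 2)
  expect_equal(sort(rates$max_rate), c(2, 5), tolerance = 1e-10)
  expect_error(read_trace_table(tab[, -1]), "lacks column")
  # file round trip
  f <- tempfile(fileext = ".csv")
  write.csv(tab, f, row.names = FALSE)
  expect_equal(rate_table(f, 5)$max_rate, rates$max_rate)
})
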