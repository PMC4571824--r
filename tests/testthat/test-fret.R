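# Trace segmentation, codon assignment, lifetime fits, survival and stalls.

test_that("toy generator emits the promised levels and ground truth", {
  # one codon, no noise, no bleach: exactly two intensity levels
  ts <- gen_fret_traces(n_traces = 1, n_codons = 1, noise_sd = 0,
                        bleach_mean = 1e9, seed = 2)
  expect_equal(sort(unique(ts$traces[[1]]$intensity)), c(0.3, 1.0))
  expect_equal(length(ts$traces[[1]]$intensity), 6000)  # 10 Hz x 600 s

  # forced stalls report the arrest codon as the final codon
  ts2 <- gen_fret_traces(n_traces = 10, n_codons = 20, arrest_codon = 5,
                         p_stall = 1, seed = 3)
  fc <- vapply(ts2$traces, function(tr) tr$truth$final_codon, integer(1))
  expect_true(all(fc == 5))
  expect_true(all(vapply(ts2$traces, function(tr) tr$truth$stalled,
                         logical(1))))

  # ground-truth dwell means converge to the generating parameters
  ts3 <- gen_fret_traces(n_traces = 1000, n_codons = 3, bleach_mean = 1e9,
                         seed = 4)
  rot <- unlist(lapply(ts3$traces, function(tr) tr$truth$dwell_rot))
  nr <- unlist(lapply(ts3$traces, function(tr) tr$truth$dwell_nonrot))
  nr <- nr[is.finite(nr)]
  expect_lt(abs(mean(rot) - 2.5), 3 * sd(rot) / sqrt(length(rot)))
  expect_lt(abs(mean(nr) - 2.5), 3 * sd(nr) / sqrt(length(nr)))
  cyc <- rot + nr
  expect_lt(abs(mean(cyc) - 5), 3 * sd(cyc) / sqrt(length(cyc)))
})

test_that("noise-free traces segment at the true transition times", {
  ts <- gen_fret_traces(n_traces = 5, n_codons = 8, noise_sd = 0,
                        bleach_mean = 1e9, seed = 11)
  for (tr in ts$traces) {
    path <- segment_trace(tr)
    # boundaries of detected segments vs ground-truth transitions
    tt <- tr$truth$transition_times
    tt <- tt[is.finite(tt)]
    starts <- path$start[-1]
    detectable <- tt[c(diff(c(0, tt)) >= 0.2)]  # >= 2 samples long dwells
    for (b in starts) {
      expect_lte(min(abs(b - tt)), 0.1 + 1e-9)  # within one sample
    }
  }
})

test_that("constant traces yield a one-segment path with a warning", {
  tr <- structure(list(id = 1, t = seq(0, 9.9, by = 0.1),
                       intensity = rep(0.5, 100), rate = 10,
                       duration = 10, truth = NULL), class = "fret_trace")
  expect_warning(path <- segment_trace(tr), "unimodal")
  expect_equal(nrow(path), 1)
  expect_equal(path$duration, 10)
})

test_that("noisy transitions are recovered within two samples", {
  # noise is 10% of the level separation (0.07 on 0.7)
  ts <- gen_fret_traces(n_traces = 200, n_codons = 40, duration = 300,
                        noise_sd = 0.07, bleach_mean = 1e9, seed = 21)
  hits <- 0; total <- 0
  for (tr in ts$traces) {
    path <- suppressWarnings(segment_trace(tr))
    starts <- path$start[-1]
    tt <- tr$truth$transition_times
    tt <- tt[is.finite(tt)]
    tt <- head(tt, -1)  # the final boundary has no intensity change
    tt <- tt[tt < tr$duration - 1]
    # ground-truth transitions flanked by detectable dwells
    durs <- c(tt[1], diff(tt))
    ok <- durs >= 0.3 & c(durs[-1] >= 0.3, TRUE)
    for (i in which(ok)) {
      total <- total + 1
      if (length(starts) > 0 && min(abs(starts - tt[i])) <= 0.2 + 1e-9) {
        hits <- hits + 1
      }
    }
  }
  expect_gt(total, 2000)
  expect_gte(hits / total, 0.95)
})

test_that("codon assignment flags terminal segments and counts cycles", {
  mk_path <- function(states, durs) {
    structure(data.frame(state = states,
                         start = cumsum(c(0, head(durs, -1))),
                         duration = durs),
              class = c("state_path", "data.frame"),
              trace_id = 1)
  }
  # three complete cycles plus a trailing rotated segment
  p3 <- mk_path(rep(c("rotated", "nonrotated"), 3), rep(2, 6))
  tb <- assign_codons(p3)
  expect_equal(attr(tb, "completed"), 2L)  # last nonrotated dwell is terminal
  expect_equal(sort(unique(tb$codon)), 1:3)

  p <- mk_path(c(rep(c("rotated", "nonrotated"), 4), "rotated"),
               c(rep(2, 8), 1.5))
  tb2 <- assign_codons(p)
  expect_equal(attr(tb2, "completed"), 4L)
  expect_equal(attr(tb2, "terminal_codon"), 5L)
  expect_true(tb2$terminal[tb2$codon == 5])
  # a leading non-rotated segment is skipped
  plead <- mk_path(c("nonrotated", rep(c("rotated", "nonrotated"), 2),
                     "rotated"), c(1, rep(2, 4), 9))
  tb3 <- assign_codons(plead)
  expect_equal(attr(tb3, "completed"), 2L)
  expect_equal(tb3$codon[1], 1)
  expect_equal(tb3$state[1], "rotated")
})

test_that("noise-free pipeline reproduces ground-truth dwells", {
  ts <- gen_fret_traces(n_traces = 20, n_codons = 6, noise_sd = 0,
                        bleach_mean = 1e9, seed = 31)
  tables <- lapply(ts$traces, function(tr) assign_codons(segment_trace(tr)))
  checked <- 0
  for (k in seq_along(tables)) {
    truth <- ts$traces[[k]]$truth
    # restrict to traces where every dwell is resolvable at 10 Hz, so
    # detected codons align one-to-one with generated codons
    if (any(c(truth$dwell_rot, head(truth$dwell_nonrot, -1)) < 0.3)) next
    tb <- as.data.frame(tables[[k]])
    done <- attr(tables[[k]], "completed")
    expect_gte(done, 5)
    for (cod in seq_len(done)) {
      rot <- tb$duration[tb$codon == cod & tb$state == "rotated"]
      # sampled at 10 Hz: durations match within one sample each side
      expect_equal(rot, truth$dwell_rot[cod], tolerance = 0.25)
      checked <- checked + 1
    }
  }
  expect_gte(checked, 15)
  surv <- survival_curve(tables)
  expect_true(all(diff(surv$fraction) <= 0))
})

test_that("exponential lifetime fits match the closed-form MLE", {
  f <- fit_lifetimes(c(2, 4))
  expect_equal(f$tau, 3)
  expect_equal(f$se, 3 / sqrt(2))
  f2 <- fit_lifetimes(c(5, 5, 5, 5))
  expect_equal(f2$tau, 5)
  expect_equal(f2$se, 2.5)
  expect_error(fit_lifetimes(3), "at least 2")
  set.seed(5)
  d <- rexp(1000, 1 / 2.5)
  f3 <- fit_lifetimes(d)
  expect_lt(abs(f3$tau - 2.5), 3 * f3$se)
  # dead-time corrected fit recovers tau from shifted dwells
  f4 <- fit_lifetimes(d + 0.2, dead_time = 0.2)
  expect_equal(f4$tau, f3$tau, tolerance = 1e-9)
})

test_that("survival drops by the stall probability around the arrest codon", {
  ts <- gen_fret_traces(n_traces = 120, n_codons = 12, arrest_codon = 8,
                        p_stall = 0.9, bleach_mean = 1e9, duration = 120,
                        seed = 41)
  res <- suppressWarnings(fret_pipeline(ts))
  surv <- res$survival
  # occasional missed sub-sample dwells shift codon numbers down by 1-2,
  # smearing the survival drop around the arrest codon (the same codon
  # uncertainty real traces have), so compare the cumulative drop
  drop <- surv$fraction[surv$codon == 4] - surv$fraction[surv$codon == 9]
  se <- sqrt(0.9 * 0.1 / 120)
  expect_lt(abs(drop - 0.9), 3 * se + 0.05)
  # stall detection: long terminal dwells well inside the ORF are arrest;
  # the rest after the final ORF codon is termination
  st <- detect_stalls(res$tables, max_codon = 10)
  truth_stalled <- vapply(ts$traces, function(tr) tr$truth$stalled,
                          logical(1))
  expect_equal(mean(st$stalled), mean(truth_stalled), tolerance = 0.05)
  # flags sit on truly stalled traces, in the non-rotated state, near the
  # arrest codon
  expect_gte(mean(st$stalled == truth_stalled), 0.9)
  flagged <- st[st$stalled & truth_stalled, ]
  expect_true(all(flagged$state == "nonrotated"))
  # codon numbers slip downward only (missed cycles), never upward
  expect_true(all(flagged$codon >= 5 & flagged$codon <= 8))
  expect_gte(mean(flagged$codon >= 7), 0.7)
})

test_that("all dwells below the cutoff means no stall", {
  ts <- gen_fret_traces(n_traces = 20, n_codons = 10, bleach_mean = 1e9,
                        seed = 51)
  tables <- suppressWarnings(lapply(ts$traces, function(tr)
    assign_codons(segment_trace(tr))))
  tables <- lapply(tables, function(tb) {
    tb2 <- tb[tb$duration < 25, , drop = FALSE]
    attributes(tb2)[c("trace_id", "completed", "terminal_codon")] <-
      attributes(tb)[c("trace_id", "completed", "terminal_codon")]
    class(tb2) <- class(tb)
    tb2
  })
  st <- detect_stalls(tables, dwell_cutoff = 30)
  expect_false(any(st$stalled))
  expect_error(detect_stalls(tables, dwell_cutoff = -1), "> 0")
})

test_that("FRET trace CSV + JSON round trip", {
  ts <- gen_fret_traces(n_traces = 2, n_codons = 3, duration = 30, seed = 6)
  path <- tempfile(fileext = ".csv")
  write_fret_csv(ts, path)
  back <- read_fret_csv(path)
  expect_equal(length(back$traces), 2)
  expect_equal(back$traces[[1]]$intensity, ts$traces[[1]]$intensity,
               tolerance = 1e-9)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  expect_equal(meta$params$rate, 10)
})
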