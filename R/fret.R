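# Two-state segmentation of single-ribosome fluorescence traces, codon
# assignment, dwell-time fits, survival curves and stall detection.
#
# One elongation cycle = one transition from the non-rotated state (low
# donor intensity, high FRET) to the rotated state (high intensity, low
# FRET) and back; each completed cycle advances the ribosome by one codon.

#' Segment a fluorescence trace into rotated/non-rotated dwells
#'
#' Median-filters the trace (window 3), fits a Gaussian mixture to the
#' intensity histogram (EM with deterministic initialization and a
#' variance floor so noise-free traces stay well-posed) to locate the two
#' state levels and, when present, a third photobleached level below both.
#' A terminal fall below both state levels is taken as the photobleach and
#' the trace is truncated there. States are then called with hysteresis
#' thresholds: the state switches high only above `mu_high - sigma_high`
#' and low only below `mu_low + sigma_low`. Segments shorter than
#' `min_samples` are merged into their neighbours.
#'
#' @param trace A `fret_trace` (elements `t`, `intensity`, `rate`).
#' @param min_samples Minimum segment length in samples (default 2).
#' @return A `state_path`: data frame with columns `state` (`"rotated"` /
#'   `"nonrotated"`), `start` (s) and `duration` (s), with attributes
#'   `trace_id`, `levels`, `bleach_time` (`NA` if none detected) and
#'   `single_state` (TRUE when the histogram is effectively unimodal).
#' @export
segment_trace <- function(trace, min_samples = 2) {
  x <- trace$intensity
  rate <- trace$rate
  if (length(x) < 10) stop("trace too short to segment (need >= 10 samples)")
  y <- as.numeric(stats::runmed(x, 3))
  n0 <- length(y)

  # levels and widths come from the raw intensity histogram; the median
  # filter narrows the apparent noise, which would push the 1-sigma
  # hysteresis thresholds too close to the levels
  gm <- .fit_levels(x)
  if (gm$unimodal) {
    warning("intensity histogram is effectively unimodal; single-state path")
    out <- data.frame(state = "nonrotated", start = trace$t[1],
                      duration = n0 / rate)
    attr(out, "trace_id") <- trace$id
    attr(out, "levels") <- gm
    attr(out, "bleach_time") <- NA_real_
    attr(out, "single_state") <- TRUE
    class(out) <- c("state_path", "data.frame")
    return(out)
  }

  # photobleach truncation: last sample still above the bleach/low midpoint
  bleach_time <- NA_real_
  if (!is.na(gm$mu_bleach)) {
    t_sig <- (gm$mu_bleach + gm$mu_low) / 2
    j <- max(which(y >= t_sig))
    if (n0 - j >= 5) {
      bleach_time <- trace$t[j + 1L]
      y <- y[seq_len(j)]
    }
  }

  # hysteresis state calling on the raw series: the median filter delays
  # threshold crossings by 1-2 samples and swallows sub-0.5 s dwells,
  # while at working separations (many sigma between levels) raw noise
  # cannot produce false switches past the 1-sigma hysteresis margins
  xr <- x[seq_len(length(y))]
  thr_hi <- gm$mu_high - gm$sd_high
  thr_lo <- gm$mu_low + gm$sd_low
  n <- length(y)
  st <- integer(n) # 1 = low (non-rotated), 2 = high (rotated)
  st[1] <- if (y[1] >= (gm$mu_low + gm$mu_high) / 2) 2L else 1L
  for (i in seq_len(n)[-1]) {
    st[i] <- if (st[i - 1] == 1L && xr[i] >= thr_hi) 2L
             else if (st[i - 1] == 2L && xr[i] <= thr_lo) 1L
             else st[i - 1]
  }
  # merge segments shorter than min_samples into the previous segment
  r <- rle(st)
  while (any(r$lengths < min_samples) && length(r$lengths) > 1) {
    k <- which(r$lengths < min_samples)[1]
    into <- if (k == 1) 2L else k - 1L
    r$lengths[into] <- r$lengths[into] + r$lengths[k]
    r$lengths <- r$lengths[-k]; r$values <- r$values[-k]
    r <- rle(inverse.rle(r))
  }
  ends <- cumsum(r$lengths)
  starts <- c(1L, head(ends, -1) + 1L)

  out <- data.frame(
    state = ifelse(r$values == 2L, "rotated", "nonrotated"),
    start = trace$t[starts],
    duration = r$lengths / rate,
    stringsAsFactors = FALSE)
  attr(out, "trace_id") <- trace$id
  attr(out, "levels") <- gm
  attr(out, "bleach_time") <- bleach_time
  attr(out, "single_state") <- FALSE
  class(out) <- c("state_path", "data.frame")
  out
}

# Gaussian mixture over the intensity histogram: up to three components
# (photobleached, non-rotated, rotated), deterministic init, variance floor.
.fit_levels <- function(y, max_iter = 100, floor_sd = 1e-3) {
  rng <- range(y)
  if (diff(rng) < 1e-9) {
    return(list(unimodal = TRUE, mu_bleach = NA_real_, mu_low = rng[1],
                mu_high = rng[2], sd_low = floor_sd, sd_high = floor_sd))
  }
  K <- 3L
  mu <- c(rng[1], mean(rng), rng[2])
  sdv <- rep(max(floor_sd, diff(rng) / 8), K)
  w <- rep(1 / K, K)
  dens <- matrix(0, length(y), K)
  for (it in seq_len(max_iter)) {
    for (k in seq_len(K)) dens[, k] <- w[k] * stats::dnorm(y, mu[k], sdv[k])
    tot <- pmax(rowSums(dens), 1e-300)
    g <- dens / tot
    wk <- colSums(g)
    alive <- wk > 1e-9
    mu_new <- mu; sd_new <- sdv
    mu_new[alive] <- colSums(g[, alive, drop = FALSE] * y) / wk[alive]
    for (k in which(alive)) {
      sd_new[k] <- max(floor_sd, sqrt(sum(g[, k] * (y - mu_new[k])^2) / wk[k]))
    }
    conv <- max(abs(mu_new - mu)) < 1e-9
    mu <- mu_new; sdv <- sd_new; w <- wk / length(y)
    if (conv) break
  }
  keep <- which(w > 0.01)
  o <- keep[order(mu[keep])]
  mu <- mu[o]; sdv <- sdv[o]; w <- w[o]
  # merge components that are not separated by > 2 pooled s.d.
  i <- 1L
  while (i < length(mu)) {
    pooled <- sqrt((sdv[i]^2 + sdv[i + 1]^2) / 2)
    if ((mu[i + 1] - mu[i]) <= 2 * max(floor_sd, pooled)) {
      wt <- w[i] + w[i + 1]
      m <- (w[i] * mu[i] + w[i + 1] * mu[i + 1]) / wt
      v <- (w[i] * (sdv[i]^2 + (mu[i] - m)^2) +
              w[i + 1] * (sdv[i + 1]^2 + (mu[i + 1] - m)^2)) / wt
      mu <- c(mu[-c(i, i + 1)], m); o2 <- order(mu)
      sdv <- c(sdv[-c(i, i + 1)], sqrt(v))[o2]
      w <- c(w[-c(i, i + 1)], wt)[o2]
      mu <- mu[o2]
      i <- 1L
    } else {
      i <- i + 1L
    }
  }
  if (length(mu) == 1L) {
    return(list(unimodal = TRUE, mu_bleach = NA_real_, mu_low = mu,
                mu_high = mu, sd_low = sdv, sd_high = sdv))
  }
  if (length(mu) == 2L) {
    list(unimodal = FALSE, mu_bleach = NA_real_,
         mu_low = mu[1], mu_high = mu[2],
         sd_low = sdv[1], sd_high = sdv[2])
  } else {
    list(unimodal = FALSE, mu_bleach = mu[1],
         mu_low = mu[2], mu_high = mu[3],
         sd_low = sdv[2], sd_high = sdv[3])
  }
}

#' Assign elongation cycles to codons
#'
#' The k-th completed rotated-to-non-rotated cycle is codon
#' `start_codon + k - 1`; each completed codon contributes one rotated and
#' one non-rotated dwell. The final segment of the path (truncated by
#' bleaching or the end of observation) is flagged terminal and not
#' counted as a completed codon; a leading non-rotated segment before the
#' first cycle is skipped.
#'
#' @param path A `state_path` from [segment_trace()].
#' @param start_codon Codon number of the first cycle (default 1).
#' @return A `dwell_table`: data frame with columns `codon`, `state`,
#'   `duration` (s) and `terminal` (logical), with attributes `trace_id`,
#'   `completed` (number of completed codons) and `terminal_codon`.
#' @export
assign_codons <- function(path, start_codon = 1) {
  stopifnot(inherits(path, "state_path"))
  start_codon <- as.integer(start_codon)
  n <- nrow(path)
  rows <- list()
  completed <- 0L
  terminal_codon <- NA_integer_
  first_rot <- which(path$state == "rotated")[1]
  if (!is.na(first_rot)) {
    k <- first_rot
    codon <- start_codon
    while (k <= n) {
      rot_terminal <- (k == n)
      rows[[length(rows) + 1L]] <- data.frame(
        codon = codon, state = "rotated", duration = path$duration[k],
        terminal = rot_terminal)
      if (rot_terminal) { terminal_codon <- codon; break }
      nonrot_terminal <- (k + 1L == n)
      rows[[length(rows) + 1L]] <- data.frame(
        codon = codon, state = "nonrotated",
        duration = path$duration[k + 1L], terminal = nonrot_terminal)
      if (nonrot_terminal) { terminal_codon <- codon; break }
      completed <- codon - start_codon + 1L
      codon <- codon + 1L
      k <- k + 2L
    }
  }
  out <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(codon = integer(0), state = character(0),
               duration = numeric(0), terminal = logical(0))
  attr(out, "trace_id") <- attr(path, "trace_id")
  attr(out, "completed") <- completed
  attr(out, "terminal_codon") <- terminal_codon
  class(out) <- c("dwell_table", "data.frame")
  out
}

#' Single-exponential lifetime fit
#'
#' Maximum-likelihood fit of an exponential dwell distribution: the MLE is
#' `tau_hat` = sample mean, with standard error `tau_hat / sqrt(n)`.
#'
#' Segmented dwells carry a detection dead time: dwells shorter than the
#' segmenter's minimum (2 samples) are never observed, and because the
#' exponential is memoryless the observed dwells are distributed as
#' `dead_time + Exp(tau)`. Passing the dead time applies the standard
#' correction `tau_hat = mean - dead_time` (the MLE of the shifted
#' exponential).
#'
#' @param dwells Numeric vector of dwell durations in seconds (n >= 2).
#' @param dead_time Detection dead time in seconds (default 0: plain MLE).
#' @return List with `tau` (mean lifetime, s), `se` and `n`.
#' @export
#' @examples
#' fit_lifetimes(c(2, 4))  # tau = 3, se = 3/sqrt(2)
fit_lifetimes <- function(dwells, dead_time = 0) {
  dwells <- dwells[is.finite(dwells)]
  if (length(dwells) < 2) stop("need at least 2 dwells")
  if (any(dwells <= 0)) stop("dwell durations must be positive")
  tau <- max(mean(dwells) - dead_time, .Machine$double.eps)
  list(tau = tau, se = tau / sqrt(length(dwells)), n = length(dwells))
}

#' Per-codon lifetimes across a batch of dwell tables
#'
#' @param tables List of `dwell_table` objects.
#' @param by_codon Fit per codon (`TRUE`) or pooled over codons (default).
#' @param dead_time Detection dead time passed to [fit_lifetimes()]
#'   (default 0).
#' @return Data frame with columns `codon` (`NA` when pooled), `state`,
#'   `tau`, `se`, `n`.
#' @export
codon_lifetimes <- function(tables, by_codon = FALSE, dead_time = 0) {
  all <- do.call(rbind, lapply(tables, function(tb) {
    tb <- as.data.frame(tb)
    tb[!tb$terminal, , drop = FALSE]
  }))
  if (nrow(all) == 0) stop("no completed dwells")
  grp <- if (by_codon) interaction(all$codon, all$state, drop = TRUE)
         else all$state
  rows <- lapply(split(all, grp), function(d) {
    ft <- fit_lifetimes(d$duration, dead_time = dead_time)
    data.frame(codon = if (by_codon) d$codon[1] else NA_integer_,
               state = d$state[1], tau = ft$tau, se = ft$se, n = ft$n)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Survival curve over codons
#'
#' Fraction of traces whose ribosome completed at least codon i, for every
#' codon i observed in the batch. The denominator is all traces; the curve
#' is monotone non-increasing by construction.
#'
#' @param tables List of `dwell_table` objects (one per trace).
#' @param start_codon First codon (default 1).
#' @return Data frame with columns `codon` and `fraction`.
#' @export
survival_curve <- function(tables, start_codon = 1) {
  if (length(tables) == 0) stop("need at least one trace")
  comp <- vapply(tables, function(tb) attr(tb, "completed"), integer(1))
  max_c <- max(c(comp, start_codon))
  codons <- seq.int(start_codon, max_c)
  frac <- vapply(codons, function(ci) mean(comp >= ci), numeric(1))
  data.frame(codon = codons, fraction = frac)
}

#' Detect stalled traces
#'
#' A trace is stalled when any dwell (terminal dwells included: a stalled
#' ribosome's last dwell ends only by photobleaching) exceeds the cutoff.
#' The default cutoff, 30 s, is six times the typical 5 s elongation
#' cycle.
#'
#' @param tables List of `dwell_table` objects.
#' @param dwell_cutoff Stall cutoff in seconds (default 30).
#' @param max_codon Ignore dwells beyond this codon (default `NULL`: no
#'   bound). A ribosome resting after the last codon of the open reading
#'   frame produces a long terminal dwell that reflects termination, not
#'   arrest; when the ORF length is known, bound the stall search below
#'   it.
#' @return Data frame with one row per trace: `trace_id`, `stalled`,
#'   `codon`, `state`, `dwell` (the longest qualifying dwell, `NA` if not
#'   stalled).
#' @export
detect_stalls <- function(tables, dwell_cutoff = 30, max_codon = NULL) {
  if (dwell_cutoff <= 0) stop("dwell_cutoff must be > 0")
  rows <- lapply(seq_along(tables), function(k) {
    tb <- as.data.frame(tables[[k]])
    id <- attr(tables[[k]], "trace_id")
    if (is.null(id)) id <- k
    long <- which(tb$duration > dwell_cutoff &
                    (if (is.null(max_codon)) TRUE else tb$codon <= max_codon))
    if (length(long) == 0) {
      data.frame(trace_id = id, stalled = FALSE, codon = NA_integer_,
                 state = NA_character_, dwell = NA_real_)
    } else {
      j <- long[which.max(tb$duration[long])]
      data.frame(trace_id = id, stalled = TRUE, codon = tb$codon[j],
                 state = tb$state[j], dwell = tb$duration[j])
    }
  })
  do.call(rbind, rows)
}

#' Run the full dwell-time pipeline on a trace set
#'
#' Segments every trace, assigns codons and returns the dwell tables plus
#' pooled per-state lifetimes.
#'
#' @param ts A `fret_trace_set`.
#' @param start_codon First codon (default 1).
#' @return List with `tables` (list of `dwell_table`), `lifetimes`
#'   (pooled, from [codon_lifetimes()]), `survival` and
#'   `mean_cycle` (sum of the two pooled lifetimes, s/codon).
#' @export
fret_pipeline <- function(ts, start_codon = 1) {
  stopifnot(inherits(ts, "fret_trace_set"))
  tables <- lapply(ts$traces, function(tr) {
    assign_codons(segment_trace(tr), start_codon = start_codon)
  })
  # the segmenter cannot see dwells shorter than 2 samples
  rate <- ts$traces[[1]]$rate
  lt <- codon_lifetimes(tables, dead_time = 2 / rate)
  surv <- survival_curve(tables, start_codon = start_codon)
  list(tables = tables, lifetimes = lt, survival = surv,
       mean_cycle = sum(lt$tau))
}
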