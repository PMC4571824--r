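# Seeded generators for the tabular inputs: gel-lane intensities around a
# true f_FL(L) profile, ligand titration points, and two-state fluorescence
# traces with exponential dwells, noise, photobleaching and optional stalls.

#' Generate synthetic gel-lane intensities around a true force profile
#'
#' The true profile is a Gaussian peak on a baseline,
#' `f(L) = b + (A - b) * exp(-(L - L0)^2 / (2 w^2))`. Each lane draws a
#' total loaded amount from LogNormal(0, `amount_sd`^2) and splits it into
#' full-length and arrested band intensities with multiplicative Gaussian
#' noise, clipped at zero:
#' `I_FL = amount * f * (1 + e)`, `I_A = amount * (1 - f) * (1 + e')`.
#'
#' Defaults mirror a sharp folding peak at L0 = 25 on a 0.1 baseline with
#' three replicates per tether length.
#'
#' @param profile List with elements `b` (baseline), `A` (peak amplitude),
#'   `L0` (peak center) and `w` (peak width); `0 <= b <= A <= 1`.
#' @param L_list Integer vector of tether lengths.
#' @param n_rep Replicates per length (default 3).
#' @param noise_sd S.d. of the multiplicative band noise (default 0.05).
#' @param amount_sd Log-s.d. of the lane loading amount (default 0.1).
#' @param condition Condition label (default `"+Zn"`).
#' @param construct Construct label.
#' @param seed Integer seed.
#' @return A data frame of class `gel_lanes` with columns `construct`, `L`,
#'   `condition`, `replicate`, `I_FL`, `I_A`.
#' @export
#' @examples
#' lanes <- gen_gel_lanes(L_list = 17:41, seed = 7)
#' head(lanes)
gen_gel_lanes <- function(profile = list(b = 0.1, A = 0.8, L0 = 25, w = 1.5),
                          L_list, n_rep = 3, noise_sd = 0.05,
                          amount_sd = 0.1, condition = "+Zn",
                          construct = "domain-AP", seed = 1) {
  b <- profile$b; A <- profile$A; L0 <- profile$L0; w <- profile$w
  if (is.null(b) || is.null(A) || is.null(L0) || is.null(w) ||
      b < 0 || A > 1 || b > A || w <= 0) {
    stop("invalid profile parameters: need 0 <= b <= A <= 1 and w > 0")
  }
  set.seed(seed)
  rows <- expand.grid(replicate = seq_len(n_rep), L = L_list,
                      KEEP.OUT.ATTRS = FALSE)
  f_true <- b + (A - b) * exp(-(rows$L - L0)^2 / (2 * w^2))
  n <- nrow(rows)
  amount <- if (amount_sd > 0) rlnorm(n, 0, amount_sd) else rep(1, n)
  e1 <- if (noise_sd > 0) rnorm(n, 0, noise_sd) else numeric(n)
  e2 <- if (noise_sd > 0) rnorm(n, 0, noise_sd) else numeric(n)
  out <- data.frame(
    construct = construct,
    L = rows$L,
    condition = condition,
    replicate = rows$replicate,
    I_FL = pmax(0, amount * f_true * (1 + e1)),
    I_A = pmax(0, amount * (1 - f_true) * (1 + e2)),
    stringsAsFactors = FALSE
  )
  attr(out, "true_profile") <- profile
  class(out) <- c("gel_lanes", "data.frame")
  out
}

#' Generate synthetic ligand-titration points
#'
#' Draws f_FL values from a Hill binding isotherm
#' `f(c) = f_min + (f_max - f_min) * c^h / (K_half^h + c^h)` with additive
#' Gaussian noise. Defaults mimic a Zn2+ titration with half-maximal
#' response at 1 uM.
#'
#' @param conc Concentrations in uM (default 8 points log-spaced over
#'   0.01-100 uM).
#' @param f_min,f_max Plateau values (defaults 0.1 and 0.8).
#' @param K_half Half-maximal concentration in uM (default 1).
#' @param h Hill coefficient (default 1).
#' @param noise_sd Additive Gaussian noise s.d. (default 0.03).
#' @param seed Integer seed.
#' @return Data frame with columns `conc` (uM) and `f_FL`.
#' @export
gen_titration_points <- function(conc = 10^seq(-2, 2, length.out = 8),
                                 f_min = 0.1, f_max = 0.8, K_half = 1,
                                 h = 1, noise_sd = 0.03, seed = 1) {
  stopifnot(K_half > 0, h > 0, all(conc >= 0))
  set.seed(seed)
  f <- f_min + (f_max - f_min) * conc^h / (K_half^h + conc^h)
  if (noise_sd > 0) f <- f + rnorm(length(conc), 0, noise_sd)
  data.frame(conc = conc, f_FL = pmin(1, pmax(0, f)))
}

#' Generate synthetic single-ribosome fluorescence traces
#'
#' Emulates inter-subunit FRET reporters of the ribosome's rotated and
#' non-rotated states sampled at `rate` Hz for `duration` seconds. Each
#' codon contributes one rotated dwell (emitted at `I_high`; the rotated
#' state has low FRET, hence high donor intensity) drawn from
#' Exp(`tau_rot`) and one non-rotated dwell at `I_low` from
#' Exp(`tau_nonrot`); the default 2.5 s + 2.5 s means a 5 s elongation
#' cycle per codon. With `arrest_codon` set, a trace stalls with
#' probability `p_stall` at that codon: after its rotated dwell it enters
#' a terminal non-rotated dwell that ends only by photobleaching. After
#' the last codon the trace rests in the non-rotated state. A single-step
#' photobleach at Exp(`bleach_mean`) drops the intensity to zero, and
#' Gaussian noise is added throughout. Ground-truth dwells, transition
#' times, stall flags and bleach times are stored per trace.
#'
#' @param n_traces Number of traces.
#' @param n_codons Codons per open reading frame (default 54).
#' @param tau_rot,tau_nonrot Mean dwell times in s (defaults 2.5 and 2.5).
#' @param arrest_codon Stall codon index, or `NULL` for none.
#' @param p_stall Per-trace stall probability at `arrest_codon`.
#' @param I_high,I_low Emission levels of the rotated and non-rotated
#'   states (defaults 1.0 and 0.3; bleached level is 0).
#' @param noise_sd Additive Gaussian noise s.d. (default 0.07).
#' @param bleach_mean Mean photobleach time in s (default 300).
#' @param rate Sampling rate in Hz (default 10).
#' @param duration Trace duration in s (default 600).
#' @param seed Integer seed.
#' @return A `fret_trace_set`: list with `traces` (list of `fret_trace`
#'   objects, each with `t`, `intensity`, `rate`, `duration` and a `truth`
#'   list) and `params`.
#' @export
#' @examples
#' ts <- gen_fret_traces(n_traces = 2, n_codons = 5, seed = 1)
#' ts$traces[[1]]$truth$final_codon
gen_fret_traces <- function(n_traces, n_codons = 54, tau_rot = 2.5,
                            tau_nonrot = 2.5, arrest_codon = NULL,
                            p_stall = 0, I_high = 1.0, I_low = 0.3,
                            noise_sd = 0.07, bleach_mean = 300,
                            rate = 10, duration = 600, seed = 1) {
  stopifnot(tau_rot > 0, tau_nonrot > 0, I_low < I_high,
            p_stall >= 0, p_stall <= 1, bleach_mean > 0)
  n_samp <- floor(rate * duration)
  if (n_samp < 1) stop("duration shorter than one sample")
  set.seed(seed)
  params <- list(n_codons = n_codons, tau_rot = tau_rot,
                 tau_nonrot = tau_nonrot, arrest_codon = arrest_codon,
                 p_stall = p_stall, I_high = I_high, I_low = I_low,
                 noise_sd = noise_sd, bleach_mean = bleach_mean,
                 rate = rate, duration = duration, seed = seed)
  traces <- vector("list", n_traces)
  tgrid <- (seq_len(n_samp) - 1) / rate
  for (tr in seq_len(n_traces)) {
    stalled <- !is.null(arrest_codon) && runif(1) < p_stall
    last_codon <- as.integer(if (stalled) min(arrest_codon, n_codons)
                             else n_codons)
    rot <- rexp(last_codon, 1 / tau_rot)
    nonrot <- rexp(last_codon, 1 / tau_nonrot)
    if (stalled) nonrot[last_codon] <- Inf  # terminal stall dwell
    # dwell schedule: rot_1, nonrot_1, rot_2, ...; then terminal non-rotated
    durs <- as.numeric(rbind(rot, nonrot))
    states <- rep(c("rotated", "nonrotated"), last_codon)
    if (!stalled) { # post-termination rest in the non-rotated state
      durs <- c(durs, Inf)
      states <- c(states, "nonrotated")
    }
    ends <- cumsum(durs)
    bleach <- rexp(1, 1 / bleach_mean)
    level <- ifelse(states == "rotated", I_high, I_low)
    seg_idx <- findInterval(tgrid, c(0, ends), rightmost.closed = FALSE)
    seg_idx[seg_idx > length(level)] <- length(level)
    intensity <- level[seg_idx]
    intensity[tgrid >= bleach] <- 0
    if (noise_sd > 0) intensity <- intensity + rnorm(n_samp, 0, noise_sd)
    truth <- list(
      dwell_rot = rot, dwell_nonrot = nonrot,
      transition_times = ends[seq_len(length(ends) - 1)],
      stalled = stalled,
      stall_codon = if (stalled) last_codon else NA_integer_,
      final_codon = last_codon,
      bleach_time = bleach
    )
    traces[[tr]] <- structure(
      list(id = tr, t = tgrid, intensity = intensity, rate = rate,
           duration = duration, truth = truth),
      class = "fret_trace")
  }
  structure(list(traces = traces, params = params),
            class = "fret_trace_set")
}

#' @export
print.fret_trace_set <- function(x, ...) {
  cat("FRET trace set:", length(x$traces), "traces,",
      x$params$rate, "Hz x", x$params$duration, "s\n")
  ns <- sum(vapply(x$traces, function(tr) isTRUE(tr$truth$stalled),
                   logical(1)))
  cat("Stalled traces (ground truth):", ns, "\n")
  invisible(x)
}

#' Write a FRET trace set to long-format CSV plus a JSON sidecar
#'
#' The CSV has columns `trace_id`, `t`, `intensity`; generator parameters
#' and per-trace ground truth go to `<path>.json`.
#'
#' @param ts A `fret_trace_set`.
#' @param path CSV output path.
#' @return `path`, invisibly.
#' @export
write_fret_csv <- function(ts, path) {
  stopifnot(inherits(ts, "fret_trace_set"))
  long <- do.call(rbind, lapply(ts$traces, function(tr) {
    data.frame(trace_id = tr$id, t = tr$t, intensity = tr$intensity)
  }))
  write.csv(long, path, row.names = FALSE)
  truth <- lapply(ts$traces, function(tr) tr$truth)
  jsonlite::write_json(list(params = ts$params, truth = truth),
                       paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' Read a long-format FRET trace CSV
#'
#' @param path CSV with columns `trace_id`, `t`, `intensity`.
#' @return A `fret_trace_set` (without ground-truth annotations).
#' @export
read_fret_csv <- function(path) {
  long <- read.csv(path)
  ids <- unique(long$trace_id)
  traces <- lapply(ids, function(id) {
    d <- long[long$trace_id == id, , drop = FALSE]
    rate <- if (nrow(d) > 1) 1 / (d$t[2] - d$t[1]) else 1
    structure(list(id = id, t = d$t, intensity = d$intensity,
                   rate = rate, duration = max(d$t) + 1 / rate,
                   truth = NULL),
              class = "fret_trace")
  })
  structure(list(traces = traces, params = list()),
            class = "fret_trace_set")
}

#' Write gel lanes to CSV
#' @param lanes A `gel_lanes` data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gel_csv <- function(lanes, path) {
  write.csv(as.data.frame(lanes), path, row.names = FALSE)
  invisible(path)
}

#' Read gel lanes from CSV
#' @param path CSV with columns `construct`, `L`, `condition`, `replicate`,
#'   `I_FL`, `I_A`.
#' @return A `gel_lanes` data frame.
#' @export
read_gel_csv <- function(path) {
  out <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("L", "I_FL", "I_A")
  if (!all(need %in% names(out))) {
    stop("gel lane CSV must have columns L, I_FL, I_A")
  }
  if (is.null(out$condition)) out$condition <- "default"
  if (is.null(out$replicate)) out$replicate <- seq_len(nrow(out))
  class(out) <- c("gel_lanes", "data.frame")
  out
}
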