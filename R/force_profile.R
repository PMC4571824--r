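# Arrest-peptide force profiles: f_FL statistics, peak location and
# ligand titration fits.

#' Fraction full-length protein from band intensities
#'
#' `f_FL = I_FL / (I_FL + I_A)`: the fraction of ribosomes that read
#' through the arrest peptide, a proxy for the tension on the nascent
#' chain when the arrest codon is decoded.
#'
#' @param I_FL Full-length band intensity (>= 0). Vectorized.
#' @param I_A Arrested band intensity (>= 0).
#' @return f_FL in \[0, 1\].
#' @export
#' @examples
#' compute_ffl(100, 100)  # 0.5
compute_ffl <- function(I_FL, I_A) {
  if (any(I_FL < 0) || any(I_A < 0)) {
    stop("band intensities must be non-negative")
  }
  if (any(I_FL + I_A == 0)) {
    stop("undefined lane: both band intensities are zero")
  }
  I_FL / (I_FL + I_A)
}

#' Assemble a force profile from gel lanes
#'
#' Per (L, condition) group: the mean of the per-lane f_FL values, the SEM
#' (s.d. with n-1 denominator over sqrt(n); `NA` for single replicates)
#' and the replicate count. Lanes whose two bands are both below the
#' detection floor are dropped with a warning.
#'
#' @param lanes A `gel_lanes` data frame (columns `L`, `condition`,
#'   `I_FL`, `I_A`).
#' @param detection_floor Lanes with `I_FL + I_A` below this are dropped
#'   (default 1e-6).
#' @return A `force_profile` data frame with columns `L`, `condition`,
#'   `mean_fFL`, `SEM`, `n`, ordered by `L` within condition.
#' @export
assemble_profile <- function(lanes, detection_floor = 1e-6) {
  stopifnot(all(c("L", "I_FL", "I_A") %in% names(lanes)))
  if (is.null(lanes$condition)) lanes$condition <- "default"
  bad <- (lanes$I_FL + lanes$I_A) < detection_floor
  if (any(bad)) {
    warning(sum(bad), " lane(s) below the detection floor dropped")
    lanes <- lanes[!bad, , drop = FALSE]
  }
  if (nrow(lanes) == 0) stop("no usable lanes")
  f <- compute_ffl(lanes$I_FL, lanes$I_A)
  key <- interaction(lanes$L, lanes$condition, drop = TRUE)
  rows <- lapply(split(seq_along(f), key), function(ii) {
    data.frame(L = lanes$L[ii[1]],
               condition = lanes$condition[ii[1]],
               mean_fFL = mean(f[ii]),
               SEM = if (length(ii) > 1) sd(f[ii]) / sqrt(length(ii))
                     else NA_real_,
               n = length(ii),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$condition, out$L), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("force_profile", "data.frame")
  out
}

#' Locate the force-profile peak
#'
#' Returns the tether length of maximal mean f_FL. Exact ties are reported
#' as the full tied interval (the experimental profiles themselves report
#' interval peaks such as 24-26 residues). A profile whose range is below
#' twice the median SEM triggers a no-peak warning; a peak on the profile
#' boundary triggers a boundary warning.
#'
#' @param profile A `force_profile`.
#' @param condition Condition to use (default: the first present).
#' @param tie_tol Absolute tolerance for calling means tied (default 0).
#' @return Numeric vector: length 1 for a unique peak, or `c(L_lo, L_hi)`
#'   for a tied interval, with attribute `tied`.
#' @export
find_lmax <- function(profile, condition = NULL, tie_tol = 0) {
  stopifnot(inherits(profile, "force_profile") || is.data.frame(profile))
  if (is.null(condition)) condition <- profile$condition[1]
  p <- profile[profile$condition == condition, , drop = FALSE]
  p <- p[order(p$L), , drop = FALSE]
  if (length(unique(p$L)) < 3) stop("need at least 3 distinct L values")
  rng <- diff(range(p$mean_fFL))
  med_sem <- median(p$SEM, na.rm = TRUE)
  if (is.finite(med_sem) && rng < 2 * med_sem) {
    warning("no peak: profile range below twice the median SEM")
  }
  mx <- max(p$mean_fFL)
  tied <- which(p$mean_fFL >= mx - tie_tol)
  Ls <- p$L[tied]
  if (max(Ls) == max(p$L) || min(Ls) == min(p$L)) {
    warning("peak on the profile boundary; L_max may lie outside the ",
            "sampled range")
  }
  if (length(Ls) > 1) {
    structure(c(min(Ls), max(Ls)), tied = TRUE)
  } else {
    structure(Ls, tied = FALSE)
  }
}

#' Fit a ligand titration with a Hill isotherm
#'
#' Least-squares fit of
#' `f(c) = f_min + (f_max - f_min) * c^h / (K_half^h + c^h)`. The Hill
#' coefficient is fixed at 1 unless `fit_h = TRUE`. `K_half` is reported
#' with a Wald confidence interval from the fit covariance.
#'
#' @param points Data frame with columns `conc` (concentration, uM) and
#'   `f_FL`.
#' @param fit_h Also fit the Hill coefficient? Default `FALSE`.
#' @param conf_level Confidence level for the K_half interval (default
#'   0.95).
#' @return List with `f_min`, `f_max`, `K_half`, `h`, `K_half_ci`
#'   (length 2), `se` (named), and the `fit` object.
#' @export
#' @examples
#' pts <- gen_titration_points(seed = 3)
#' fit_titration(pts)$K_half
fit_titration <- function(points, fit_h = FALSE, conf_level = 0.95) {
  stopifnot(all(c("conc", "f_FL") %in% names(points)))
  if (length(unique(points$conc)) < 4) {
    stop("need at least 4 distinct concentrations")
  }
  if (diff(range(points$f_FL)) < 1e-9) {
    stop("fit failure: no signal (all f_FL values equal)")
  }
  d <- points
  start <- list(f_min = min(d$f_FL), f_max = max(d$f_FL),
                K_half = exp(mean(log(pmax(d$conc, 1e-6)))))
  fml <- if (fit_h) {
    start$h <- 1
    f_FL ~ f_min + (f_max - f_min) * conc^h / (K_half^h + conc^h)
  } else {
    f_FL ~ f_min + (f_max - f_min) * conc / (K_half + conc)
  }
  fit <- tryCatch(
    minpack.lm::nlsLM(fml, data = d, start = start,
                      lower = c(0, 0, 1e-9, if (fit_h) 0.1),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) {
      stop("fit failure: ", conditionMessage(e),
           "; residual range ", signif(diff(range(d$f_FL)), 3))
    })
  cf <- coef(fit)
  se <- tryCatch(sqrt(diag(vcov(fit))), error = function(e)
    setNames(rep(NA_real_, length(cf)), names(cf)))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  list(f_min = unname(cf["f_min"]), f_max = unname(cf["f_max"]),
       K_half = unname(cf["K_half"]),
       h = if (fit_h) unname(cf["h"]) else 1,
       K_half_ci = unname(cf["K_half"] + c(-1, 1) * z * se["K_half"]),
       se = se, fit = fit)
}

#' Write a force profile to CSV
#' @param profile A `force_profile`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_force_profile_csv <- function(profile, path) {
  write.csv(as.data.frame(profile), path, row.names = FALSE)
  invisible(path)
}
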