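# Navigation statistics: regressions, thermal phases, turn rates, sweep
# sizes, binned summaries, speeds, and phase comparisons.

#' Ordinary least squares regression of intensity vs length change
#'
#' Closed-form simple OLS for per-frame (fractional length change,
#' fractional intensity change) pairs of one segment. The slope standard
#' error follows the usual convention `s_resid / (s_x * sqrt(n - 1))`.
#'
#' @param x,y numeric vectors (e.g. x = dL/L, y = dI/I)
#' @return list `slope`, `slope_se`, `intercept`, `r_squared`, `n`
#' @export
regressIntensityVsLength <- function(x, y) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3) stopc("larvagram_invalid_argument", "need at least 3 finite pairs")
  sxx <- sum((x - mean(x))^2)
  if (sxx == 0) stopc("larvagram_degenerate_regression", "zero variance in x")
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  slope <- sxy / sxx
  intercept <- mean(y) - slope * mean(x)
  resid <- y - intercept - slope * x
  syy <- sum((y - mean(y))^2)
  r2 <- if (syy == 0) 1 else 1 - sum(resid^2) / syy
  sResid <- if (n > 2) sqrt(sum(resid^2) / (n - 2)) else 0
  sx <- sqrt(sxx / (n - 1))
  list(slope = slope, slope_se = sResid / (sx * sqrt(n - 1)),
       intercept = intercept, r_squared = r2, n = n)
}

#' Classify warming/cooling/neutral phases of a temperature trace
#'
#' dT/dt is estimated by central differences after boxcar smoothing;
#' warming where dT/dt exceeds the threshold, cooling where it is below
#' its negative, neutral in between.
#'
#' @param temperature data.frame `time_s`, `temp_C` (regularly sampled)
#' @param threshold phase threshold (degC/s)
#' @param smoothSec boxcar smoothing window (s)
#' @return data.frame `time_s`, `dTdt`, `phase`
#' @export
classifyPhases <- function(temperature, threshold = 0.001, smoothSec = 1) {
  t <- temperature$time_s
  dt <- median(diff(t))
  if (max(t) - min(t) < smoothSec)
    stopc("larvagram_invalid_argument", "trace shorter than the smoothing window")
  d <- traceRate(temperature, smoothSec)
  data.frame(time_s = t, dTdt = d,
             phase = ifelse(d > threshold, "warming",
                            ifelse(d < -threshold, "cooling", "neutral")))
}

phaseMinutes <- function(phases) {
  dt <- median(diff(phases$time_s))
  tapply(rep(dt / 60, nrow(phases)), phases$phase, sum)
}

#' Reorientation frequency per thermal phase
#'
#' Counts maneuvers per phase (at maneuver onset) divided by total phase
#' time, with Poisson standard errors.
#'
#' @param maneuvers data.frame with `onset_s` (and optionally `phase`)
#' @param phases data.frame from [classifyPhases()]
#' @return data.frame `phase`, `n`, `minutes`, `rate_min`, `se_min`
#' @export
turnFrequency <- function(maneuvers, phases) {
  mins <- phaseMinutes(phases)
  if (any(mins == 0) || !length(mins))
    mins <- mins[mins > 0]
  if (!length(mins)) stopc("larvagram_undefined_rate", "no phase time")
  lab <- vapply(maneuvers$onset_s, function(tt)
    phases$phase[which.min(abs(phases$time_s - tt))], character(1))
  out <- lapply(names(mins), function(p) {
    n <- sum(lab == p)
    data.frame(phase = p, n = n, minutes = as.numeric(mins[p]),
               rate_min = n / mins[p], se_min = sqrt(n) / mins[p])
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Mean size of the first head sweep per thermal phase
#'
#' @param maneuvers data.frame with `first_sweep_peak_deg` and `onset_s`
#' @param phases data.frame from [classifyPhases()]
#' @return data.frame `phase`, `n`, `mean_deg`, `se_deg` (`se_deg` NA when
#'   a phase has a single maneuver)
#' @export
firstSweepSize <- function(maneuvers, phases) {
  lab <- vapply(maneuvers$onset_s, function(tt)
    phases$phase[which.min(abs(phases$time_s - tt))], character(1))
  out <- lapply(unique(lab), function(p) {
    v <- maneuvers$first_sweep_peak_deg[lab == p]
    data.frame(phase = p, n = length(v), mean_deg = mean(v),
               se_deg = if (length(v) > 1) sd(v) / sqrt(length(v)) else NA_real_)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Probability of within-bend wave initiation, binned by sweep size
#'
#' For each bend-angle bin: p = m/n with binomial standard error
#' `sqrt(p(1-p)/n)`, where n counts classified maneuvers and m those whose
#' first post-sweep wave initiated within the bent region. Ambiguous
#' initiations are excluded from n and reported separately.
#'
#' @param maneuvers data.frame with `accepted_peak_deg` and `init_class`
#' @param binWidth bin width (deg)
#' @return data.frame `bin_lo`, `bin_hi`, `bin_mid`, `n`, `m`, `p`, `se`,
#'   `ambiguous`
#' @export
initiationProbabilityByAngle <- function(maneuvers, binWidth = 30) {
  keep <- !is.na(maneuvers$init_class)
  m <- maneuvers[keep, , drop = FALSE]
  if (!nrow(m)) return(data.frame(bin_lo = numeric(0)))
  lo <- floor(min(m$accepted_peak_deg) / binWidth) * binWidth
  bins <- seq(lo, max(m$accepted_peak_deg) + binWidth, by = binWidth)
  idx <- findInterval(m$accepted_peak_deg, bins, rightmost.closed = TRUE)
  out <- lapply(sort(unique(idx)), function(b) {
    sel <- m[idx == b, , drop = FALSE]
    amb <- sum(sel$init_class == "ambiguous")
    sel <- sel[sel$init_class != "ambiguous", , drop = FALSE]
    n <- nrow(sel)
    mm <- sum(sel$init_class == "within_bend")
    p <- if (n > 0) mm / n else NA_real_
    data.frame(bin_lo = bins[b], bin_hi = bins[b + 1],
               bin_mid = bins[b] + binWidth / 2, n = n, m = mm, p = p,
               se = if (n > 0) sqrt(p * (1 - p) / n) else NA_real_,
               ambiguous = amb)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Waves needed to straighten, binned by sweep size
#'
#' @param maneuvers data.frame with `accepted_peak_deg` and
#'   `waves_to_straighten`
#' @param binWidth bin width (deg)
#' @return data.frame `bin_lo`, `bin_hi`, `bin_mid`, `n`, `mean_waves`,
#'   `sd_waves`
#' @export
straighteningWavesByAngle <- function(maneuvers, binWidth = 30) {
  keep <- !is.na(maneuvers$waves_to_straighten)
  m <- maneuvers[keep, , drop = FALSE]
  if (!nrow(m)) return(data.frame(bin_lo = numeric(0)))
  lo <- floor(min(m$accepted_peak_deg) / binWidth) * binWidth
  bins <- seq(lo, max(m$accepted_peak_deg) + binWidth, by = binWidth)
  idx <- findInterval(m$accepted_peak_deg, bins, rightmost.closed = TRUE)
  out <- lapply(sort(unique(idx)), function(b) {
    v <- m$waves_to_straighten[idx == b]
    data.frame(bin_lo = bins[b], bin_hi = bins[b + 1],
               bin_mid = bins[b] + binWidth / 2, n = length(v),
               mean_waves = mean(v), sd_waves = if (length(v) > 1) sd(v) else 0)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Mean forward speed excluding turning intervals
#'
#' Frame-to-frame centroid speed averaged over frames outside maneuver
#' intervals.
#'
#' @param track data.frame with `time_s`, `x_mm`, `y_mm`
#' @param maneuvers data.frame with `onset_s` and `offset_s` (or
#'   `offset_frame` + frameRate-consistent `onset_s`); may be empty
#' @return list `speed_mm_s`, `se`, `n`
#' @export
forwardSpeed <- function(track, maneuvers = NULL) {
  dt <- diff(track$time_s)
  sp <- sqrt(diff(track$x_mm)^2 + diff(track$y_mm)^2) / dt
  t0 <- track$time_s[-nrow(track)]
  t1 <- track$time_s[-1]
  excl <- rep(FALSE, length(sp))
  if (!is.null(maneuvers) && nrow(maneuvers)) {
    offs <- if ("offset_s" %in% names(maneuvers)) maneuvers$offset_s
            else maneuvers$onset_s + 8
    ## exclude any step that overlaps a maneuver interval
    for (k in seq_len(nrow(maneuvers)))
      excl <- excl | (t1 > maneuvers$onset_s[k] & t0 < offs[k])
  }
  sp <- sp[!excl & is.finite(sp)]
  if (!length(sp)) stopc("larvagram_undefined", "no frames outside maneuvers")
  list(speed_mm_s = mean(sp), se = sd(sp) / sqrt(length(sp)), n = length(sp))
}

#' Population thermotaxis speed
#'
#' OLS slope of the population mean gradient-axis position versus time,
#' truncated at stabilization: the first time the windowed mean drift
#' falls below 10% of its initial value.
#'
#' @param positions matrix (time x animals) of gradient-axis positions
#'   (mm), or data.frame in long format `time_s`, `animal`, `pos_mm`
#' @param times time vector (s) when `positions` is a matrix
#' @param window drift-estimation window (s)
#' @return list `speed_mm_s`, `se`, `stabilized_at_s` (NA when never),
#'   `n_times`
#' @export
thermotaxisSpeed <- function(positions, times = NULL, window = 60) {
  if (is.data.frame(positions)) {
    tt <- sort(unique(positions$time_s))
    m <- tapply(positions$pos_mm, positions$time_s, mean)
    mp <- as.numeric(m); times <- tt
  } else {
    if (is.null(times)) stopc("larvagram_invalid_argument", "times required")
    if (ncol(positions) < 2) stopc("larvagram_invalid_argument", "need >= 2 tracks")
    mp <- rowMeans(positions)
  }
  dt <- median(diff(times))
  wN <- max(2L, round(window / dt))
  nW <- floor(length(mp) / wN)
  stabAt <- NA_real_
  if (nW >= 2) {
    drift <- vapply(seq_len(nW), function(k) {
      i0 <- (k - 1) * wN + 1; i1 <- min(length(mp), k * wN)
      (mp[i1] - mp[i0]) / (times[i1] - times[i0])
    }, numeric(1))
    ref <- drift[1]
    below <- which(abs(drift) < 0.1 * abs(ref))
    if (abs(ref) < 1e-12) {
      stabAt <- times[1]
    } else if (length(below)) {
      stabAt <- times[(min(below) - 1) * wN + 1]
    }
  }
  keep <- if (is.na(stabAt)) seq_along(mp) else which(times <= stabAt)
  if (length(keep) < 3) {
    if (all(abs(diff(mp)) < 1e-12))
      return(list(speed_mm_s = 0, se = 0, stabilized_at_s = stabAt,
                  n_times = length(mp)))
    stopc("larvagram_undefined_slope", "stabilized immediately; no drift to fit")
  }
  fit <- lm(mp[keep] ~ times[keep])
  sm <- suppressWarnings(summary(fit))$coefficients
  list(speed_mm_s = unname(sm[2, 1]), se = unname(sm[2, 2]),
       stabilized_at_s = stabAt, n_times = length(keep))
}

#' Two-group comparison of phase statistics
#'
#' Welch's unequal-variance t-test by default; optionally a permutation
#' test of the difference in means.
#'
#' @param a,b numeric samples
#' @param method `"welch"` or `"permutation"`
#' @param nPerm permutations
#' @param seed seed for the permutation stream
#' @return list `p_value`, `method`, `estimate` (mean difference a - b)
#' @export
phaseComparisonTest <- function(a, b, method = c("welch", "permutation"),
                                nPerm = 2000, seed = 1) {
  method <- match.arg(method)
  if (length(a) < 2 || length(b) < 2)
    stopc("larvagram_invalid_argument", "each group needs n >= 2")
  est <- mean(a) - mean(b)
  if (sd(a) == 0 && sd(b) == 0 && est == 0)
    return(list(p_value = 1, method = method, estimate = 0))
  if (method == "welch") {
    p <- t.test(a, b, var.equal = FALSE)$p.value
  } else {
    set.seed(as.integer(seed))
    pool <- c(a, b); na <- length(a)
    d0 <- abs(est)
    cnt <- 0
    for (i in seq_len(nPerm)) {
      idx <- sample(length(pool), na)
      if (abs(mean(pool[idx]) - mean(pool[-idx])) >= d0 - 1e-12) cnt <- cnt + 1
    }
    p <- (cnt + 1) / (nPerm + 1)
  }
  list(p_value = p, method = method, estimate = est)
}
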