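#' Construct a sweep trace
#'
#' A single whole-cell sweep: time and current samples with the two
#' annotations the analysis needs, a baseline window (for baseline level and
#' noise) and the pulse onset (start of the low-pH application). Inward
#' currents are conventionally negative; the analysis works on the
#' baseline-subtracted magnitude, so the sign never needs flipping by hand.
#'
#' @param time_s Strictly increasing sample times (s).
#' @param current Current samples, same length (pA or any consistent unit).
#' @param baseline_window Length-2 window `[t0, t1]` (s) of agonist-free
#'   baseline; must precede `pulse_onset_s`.
#' @param pulse_onset_s Time (s) at which the activating solution arrives.
#' @param sweep_id,condition Optional identifiers carried through.
#' @return A `sweep_trace` tibble (`time_s`, `current`) with annotation
#'   attributes.
#' @export
sweep_trace <- function(time_s, current, baseline_window, pulse_onset_s,
                        sweep_id = NA_character_, condition = NA_character_) {
  if (length(time_s) != length(current)) {
    stop("sweep_trace(): time and current lengths differ", call. = FALSE)
  }
  if (any(diff(time_s) <= 0)) {
    stop("sweep_trace(): time must be strictly increasing", call. = FALSE)
  }
  if (length(baseline_window) != 2 || baseline_window[2] > pulse_onset_s) {
    stop("sweep_trace(): baseline window must be [t0, t1] with t1 <= pulse ",
         "onset", call. = FALSE)
  }
  out <- tibble::tibble(time_s = as.numeric(time_s),
                        current = as.numeric(current))
  attr(out, "baseline_window") <- as.numeric(baseline_window)
  attr(out, "pulse_onset_s") <- as.numeric(pulse_onset_s)
  attr(out, "sweep_id") <- sweep_id
  attr(out, "condition") <- condition
  class(out) <- c("sweep_trace", class(out))
  out
}

#' Read a sweep CSV with a JSON annotation sidecar
#'
#' Sweep files are two-column CSVs (`time_s`, `current_pA`); annotations
#' (baseline window, pulse onset, pH, sweep id, condition) live in
#' `<path>.json` or are passed explicitly.
#'
#' @param path CSV path.
#' @param annotations Optional named list overriding/replacing the sidecar:
#'   `baseline_window`, `pulse_onset_s`, `sweep_id`, `condition`, `pH`.
#' @return A `sweep_trace`; the pH (if annotated) is attribute `"pH"`.
#' @export
read_sweep_csv <- function(path, annotations = NULL) {
  tbl <- readr::read_csv(path, show_col_types = FALSE)
  cur_col <- intersect(c("current_pA", "current"), names(tbl))[1]
  if (!"time_s" %in% names(tbl) || is.na(cur_col)) {
    stop("read_sweep_csv(): need columns time_s and current_pA", call. = FALSE)
  }
  side <- paste0(path, ".json")
  meta <- if (file.exists(side)) jsonlite::read_json(side,
                                                     simplifyVector = TRUE)
  else list()
  meta[names(annotations)] <- annotations
  if (is.null(meta$baseline_window) || is.null(meta$pulse_onset_s)) {
    stop("read_sweep_csv(): baseline_window and pulse_onset_s must be ",
         "annotated (sidecar JSON or `annotations`)", call. = FALSE)
  }
  tr <- sweep_trace(tbl$time_s, tbl[[cur_col]], meta$baseline_window,
                    meta$pulse_onset_s,
                    sweep_id = meta$sweep_id %||% NA_character_,
                    condition = meta$condition %||% NA_character_)
  attr(tr, "pH") <- meta$pH %||% NA_real_
  tr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Time to 1/e decay of a desensitizing current
#'
#' Quantifies desensitization the way patch-clamp work reports it: the time
#' from the current peak to the point where 1/e (~63%) of the peak has
#' decayed, i.e. where the baseline-subtracted magnitude first falls to
#' `peak / e`. The crossing is linearly interpolated between the bracketing
#' samples so the estimate is not quantised to the sampling interval.
#'
#' @param trace A `sweep_trace`.
#' @param noise_mult Peak must exceed `noise_mult` times the baseline SD
#'   (default 3) or a no-peak error is raised.
#' @return A `decay_result` (one-row tibble): `sweep_id`, `peak_time_s`,
#'   `peak_amplitude` (baseline-subtracted magnitude), `t_1e_s` (time from
#'   peak to the 1/e crossing; `NA` when not crossed), `crossed`.
#' @export
decay_time <- function(trace, noise_mult = 3) {
  stopifnot(inherits(trace, "sweep_trace"))
  bw <- attr(trace, "baseline_window")
  onset <- attr(trace, "pulse_onset_s")
  in_base <- trace$time_s >= bw[1] & trace$time_s <= bw[2]
  if (!any(in_base)) stop("decay_time(): empty baseline window",
                          call. = FALSE)
  baseline <- mean(trace$current[in_base])
  noise_sd <- stats::sd(trace$current[in_base])
  after <- which(trace$time_s >= onset)
  if (length(after) < 3) stop("decay_time(): too few samples after pulse ",
                              "onset", call. = FALSE)
  mag <- abs(trace$current[after] - baseline)
  t <- trace$time_s[after]
  ipk <- which.max(mag)
  peak <- mag[ipk]
  if (is.finite(noise_sd) && noise_sd > 0 && peak < noise_mult * noise_sd) {
    stop("decay_time(): no peak above noise (peak ", signif(peak, 3),
         " < ", noise_mult, " x baseline SD ", signif(noise_sd, 3), ")",
         call. = FALSE)
  }
  target <- peak / exp(1)
  post <- mag[ipk:length(mag)]
  tpost <- t[ipk:length(t)]
  below <- which(post <= target)
  crossed <- length(below) > 0 && length(post) >= 2
  t_1e <- NA_real_
  if (crossed) {
    j <- below[1]
    if (j == 1) {
      t_1e <- 0
    } else {
      # linear interpolation between the bracketing samples
      f <- (post[j - 1] - target) / (post[j - 1] - post[j])
      t_cross <- tpost[j - 1] + f * (tpost[j] - tpost[j - 1])
      t_1e <- t_cross - tpost[1]
    }
  }
  out <- tibble::tibble(
    sweep_id = attr(trace, "sweep_id"),
    peak_time_s = tpost[1],
    peak_amplitude = peak,
    t_1e_s = t_1e,
    crossed = crossed
  )
  class(out) <- c("decay_result", class(out))
  out
}

#' Measure a peak amplitude robust to sampling noise
#'
#' Peak magnitude estimator for dose-response and wash-on work: the
#' baseline-subtracted magnitude is boxcar-smoothed over `window_s`, and the
#' peak is the maximum of the smoothed series after pulse onset. Smoothing
#' mimics the low-pass filtering of real acquisition chains and removes the
#' max-of-noise bias a raw `max()` suffers; because it scales the underlying
#' signal by the same factor at every pH, the bias cancels exactly when
#' responses are normalized to the reference pH. (The desensitization
#' metric in [decay_time()] deliberately keeps the raw peak: its 1/e
#' threshold is defined from the unsmoothed trace.)
#'
#' @param trace A `sweep_trace`.
#' @param window_s Boxcar width in seconds (default 0.001, i.e. 1 ms).
#' @return Peak magnitude (baseline subtracted), a single number.
#' @export
measure_peak <- function(trace, window_s = 0.001) {
  stopifnot(inherits(trace, "sweep_trace"))
  bw <- attr(trace, "baseline_window")
  onset <- attr(trace, "pulse_onset_s")
  in_base <- trace$time_s >= bw[1] & trace$time_s <= bw[2]
  baseline <- mean(trace$current[in_base])
  after <- which(trace$time_s >= onset)
  mag <- abs(trace$current[after] - baseline)
  dt <- stats::median(diff(trace$time_s))
  k <- max(1L, as.integer(round(window_s / dt)))
  if (k %% 2 == 0) k <- k + 1L
  if (k > 1 && length(mag) > k) {
    mag <- stats::filter(mag, rep(1 / k, k), sides = 2)
  }
  max(mag, na.rm = TRUE)
}

#' Average decay times over the sweeps of one experiment
#'
#' @param results One or more `decay_result` rows ([decay_time()] output),
#'   stacked with `dplyr::bind_rows()` or supplied as a list.
#' @return One-row tibble: `mean_t_1e_s` (arithmetic mean over crossed
#'   sweeps; `NA` when none crossed), `n_sweeps`, `n_excluded` (uncrossed).
#' @export
average_sweeps <- function(results) {
  if (is.list(results) && !is.data.frame(results)) {
    results <- dplyr::bind_rows(results)
  }
  crossed <- results[results$crossed & !is.na(results$t_1e_s), ]
  tibble::tibble(
    mean_t_1e_s = if (nrow(crossed) > 0) mean(crossed$t_1e_s) else NA_real_,
    n_sweeps = nrow(results),
    n_excluded = nrow(results) - nrow(crossed)
  )
}

#' Normalize peak responses to the reference pH
#'
#' Dose-response construction: per-pH peak responses (already averaged over
#' their sweeps) are divided by the response at the maximally activating
#' reference pH (5.5 by convention), which is therefore 1 by construction.
#'
#' @param peaks Data frame with columns `pH` and `peak` (mean peak
#'   magnitude per pH).
#' @param reference_pH Reference pH (default 5.5).
#' @return A `dose_response` tibble: `pH`, `normalized_response`, with
#'   attribute `reference_pH`.
#' @export
normalize_dose_response <- function(peaks, reference_pH = 5.5) {
  if (!all(c("pH", "peak") %in% names(peaks))) {
    stop("normalize_dose_response(): need columns pH and peak", call. = FALSE)
  }
  iref <- which(abs(peaks$pH - reference_pH) < 1e-9)
  if (length(iref) == 0) {
    stop("normalize_dose_response(): reference pH ", reference_pH,
         " not present", call. = FALSE)
  }
  ref <- mean(peaks$peak[iref])
  if (!is.finite(ref) || ref <= 0) {
    stop("normalize_dose_response(): reference response must be positive",
         call. = FALSE)
  }
  out <- tibble::tibble(pH = peaks$pH,
                        normalized_response = peaks$peak / ref)
  attr(out, "reference_pH") <- reference_pH
  class(out) <- c("dose_response", class(out))
  out
}

#' The Hill-type pH-activation curve
#'
#' `I(pH) = 1 / (1 + 10^((pH05 - pH) * n))`, with asymptotes fixed at 0 and
#' 1. As printed, a *negative* `n` gives a response that grows with acidity
#' (the physiological direction for an acid-activated channel); the sign of
#' `n` is left free and `abs(n)` is reported as the Hill number.
#'
#' @param pH pH values.
#' @param pH05 Half-maximal activating pH.
#' @param n Hill exponent (sign free, see Details).
#' @return Predicted normalized response in `[0,1]`.
#' @export
hill_curve <- function(pH, pH05, n) {
  1 / (1 + 10^((pH05 - pH) * n))
}

#' Fit the Hill pH-activation curve
#'
#' Least-squares fit of [hill_curve()] to a normalized dose-response, with
#' the asymptotes restrained to 0 and 1 (only `pH05` and `n` are free, so
#' the fitted curve is bounded in `[0,1]` by construction). Both signs of
#' the initial Hill exponent are tried (`n = +n0` and `-n0`) and the fit
#' with the lower SSE is kept, ties broken toward smaller `|n|`; given the
#' same data and guesses the result is deterministic. `pH05` is reported as
#' the pH where the fitted curve equals 0.5, which for this
#' parameterisation is the `pH05` parameter itself.
#'
#' @param dr A `dose_response` (or data frame with `pH` and
#'   `normalized_response`).
#' @param pH05_init Initial midpoint (default: midpoint of the pH range).
#' @param n_init Initial Hill exponent magnitude (default 1; both signs
#'   tried).
#' @return A `hill_fit` object: `pH05`, `n` (signed), `hill_n` (`= |n|`),
#'   `residual_sse`, `converged`, `n_points`, plus the data for plotting.
#' @export
fit_hill <- function(dr, pH05_init = NULL, n_init = 1) {
  pH <- dr$pH
  y <- dr$normalized_response
  ok <- is.finite(pH) & is.finite(y)
  pH <- pH[ok]; y <- y[ok]
  if (length(unique(pH)) < 4) {
    stop("fit_hill(): need at least 4 distinct pH points", call. = FALSE)
  }
  if (stats::sd(y) < 1e-12) {
    stop("fit_hill(): degenerate data (responses all equal)", call. = FALSE)
  }
  if (is.null(pH05_init)) pH05_init <- mean(range(pH))
  sse <- function(par) {
    r <- y - hill_curve(pH, par[1], par[2])
    sum(r * r)
  }
  fits <- lapply(c(n_init, -n_init), function(n0) {
    stats::optim(c(pH05_init, n0), sse, method = "BFGS",
                 control = list(maxit = 500, reltol = 1e-14))
  })
  val <- vapply(fits, function(f) f$value, numeric(1))
  absn <- vapply(fits, function(f) abs(f$par[2]), numeric(1))
  best <- order(val, absn)[1]
  fit <- fits[[best]]
  out <- list(
    pH05 = fit$par[1], n = fit$par[2], hill_n = abs(fit$par[2]),
    residual_sse = fit$value, converged = fit$convergence == 0,
    n_points = length(pH),
    data = tibble::tibble(pH = pH, normalized_response = y)
  )
  class(out) <- "hill_fit"
  if (!out$converged) {
    warning("fit_hill(): optimizer did not converge (code ",
            fit$convergence, ")", call. = FALSE)
  }
  out
}

#' @export
print.hill_fit <- function(x, ...) {
  cat(sprintf(
    "<hill_fit> pH0.5 = %.3f, Hill n = %.2f (signed %.2f), SSE = %.3g, %s\n",
    x$pH05, x$hill_n, x$n, x$residual_sse,
    if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' Wash-on time course
#'
#' Normalizes per-sweep peak currents to the first sweep of the experiment,
#' the standard way slow lipid wash-on is displayed.
#'
#' @param peaks Numeric vector of per-sweep peak magnitudes (in sweep
#'   order), or a data frame with columns `sweep` and `peak`.
#' @return Tibble: `sweep` (1-based), `normalized_peak` (first sweep = 1).
#' @export
washon_timecourse <- function(peaks) {
  if (is.data.frame(peaks)) {
    peaks <- peaks$peak[order(peaks$sweep)]
  }
  if (length(peaks) < 1) stop("washon_timecourse(): no sweeps", call. = FALSE)
  if (!is.finite(peaks[1]) || peaks[1] <= 0) {
    stop("washon_timecourse(): first-sweep peak must be positive",
         call. = FALSE)
  }
  tibble::tibble(sweep = seq_along(peaks),
                 normalized_peak = peaks / peaks[1])
}
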