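#' Binned multi-trial spike trains with unit metadata
#'
#' Container for a recording session: a trials x bins x units binary array of
#' spike counts, a stimulus label per trial, the bin width, and a unit table
#' (area, optional 3-D position in micrometres).
#'
#' @param spikes Integer array with dim (trials M, bins N, units U), all values
#'   0 or 1.
#' @param units Data frame with columns `unit` and `area` (optional `x`, `y`,
#'   `z`); one row per unit, in the order of the array's third dimension.
#' @param stimulus Character/factor of length M: stimulus label per trial.
#' @param bin_ms Bin width in milliseconds (default 1).
#' @return An object of class `spike_train_set`.
#' @export
spike_train_set <- function(spikes, units, stimulus = NULL, bin_ms = 1) {
  d <- dim(spikes)
  if (length(d) != 3) stop_ccgnet("spikes must be a trials x bins x units array")
  if (!all(spikes %in% c(0L, 1L))) stop_ccgnet("spike counts must be binary per bin")
  units <- as.data.frame(units)
  if (nrow(units) != d[3]) stop_ccgnet("units table must match the array's unit dimension")
  units$unit <- as.character(units$unit)
  if (is.null(stimulus)) stimulus <- rep("stim", d[1])
  if (length(stimulus) != d[1]) stop_ccgnet("one stimulus label per trial required")
  structure(list(spikes = spikes, units = units,
                 stimulus = as.character(stimulus), bin_ms = bin_ms,
                 M = d[1], N = d[2]),
            class = "spike_train_set")
}

#' @export
print.spike_train_set <- function(x, ...) {
  cat(sprintf("spike_train_set: %d units, %d trials x %d bins (%.1f ms bins)\n",
              nrow(x$units), x$M, x$N, x$bin_ms))
  cat("  stimulus labels:", paste(unique(x$stimulus), collapse = ", "), "\n")
  r <- firing_rates(x)
  cat(sprintf("  firing rates: %.2f-%.2f spikes/s (median %.2f)\n",
              min(r), max(r), stats::median(r)))
  invisible(x)
}

#' Firing rates in spikes per second
#'
#' @param data A `spike_train_set`.
#' @param stimulus Optional stimulus label; default uses all trials.
#' @return Named numeric vector, one rate per unit.
#' @export
firing_rates <- function(data, stimulus = NULL) {
  sel <- if (is.null(stimulus)) rep(TRUE, data$M) else data$stimulus == stimulus
  if (!any(sel)) stop_ccgnet("no trials with stimulus label ", stimulus)
  counts <- apply(data$spikes[sel, , , drop = FALSE], 3, sum)
  r <- counts / (sum(sel) * data$N * data$bin_ms / 1000)
  names(r) <- data$units$unit
  r
}

# Mean spike count per bin (the rate entering the CCG normalization).
mean_count_per_bin <- function(data, sel = rep(TRUE, data$M)) {
  apply(data$spikes[sel, , , drop = FALSE], 3, sum) / (sum(sel) * data$N)
}

#' Generate a ground-truth population with planted signed couplings
#'
#' Defines the synthetic study conditions: a multi-area population of units
#' with Poisson-like baseline rates, a set of planted directed couplings
#' (sign, lag, duration, transmission probability) and an optional shared
#' slow rate modulation. Defaults reflect the conditions the downstream
#' detection stage is designed for: 1 ms bins, 20 Hz baselines, short
#' monosynaptic/polysynaptic lags (2-4 bins) and a 200-bin sinusoidal
#' envelope of relative amplitude 0.5 when modulation is enabled.
#'
#' @param config A list; recognized entries (with defaults):
#'   `n_units` (60), `areas` (labels recycled over units, default 3 areas),
#'   `baseline_hz` (20, scalar or per unit), `n_couplings` (10),
#'   `frac_positive` (0.6), `lag_range` (c(2, 4) bins), `duration_range`
#'   (c(1, 2) bins), `transmission` (0.5), `modulation` (`NULL` or a list
#'   with `period` bins and `amplitude`), `positions` (`TRUE`: draw 3-D unit
#'   positions with 400 um between area centroids), `tau_max` (12).
#' @param seed Integer seed; output is deterministic given (config, seed).
#' @return An object of class `ground_truth` with elements `units` (data
#'   frame: unit, area, rate, x, y, z), `couplings` (data frame: source,
#'   target, sign, lag, duration, transmission) and `modulation`.
#' @export
make_ground_truth <- function(config = list(), seed = 1) {
  cfg <- utils::modifyList(list(
    n_units = 60L, areas = NULL, baseline_hz = 20, n_couplings = 10L,
    frac_positive = 0.6, lag_range = c(2L, 4L), duration_range = c(1L, 2L),
    transmission = 0.5, modulation = NULL, positions = TRUE, tau_max = 12L
  ), config)
  n <- as.integer(cfg$n_units)
  if (n < 1) stop_ccgnet("make_ground_truth: need at least one unit")
  if (any(cfg$baseline_hz <= 0)) stop_ccgnet("make_ground_truth: rates must be positive")
  if (max(cfg$lag_range) > cfg$tau_max)
    stop_ccgnet("make_ground_truth: lags must not exceed tau_max")
  if (min(cfg$lag_range) < 1) stop_ccgnet("make_ground_truth: lags must be >= 1")
  if (cfg$n_couplings > n * (n - 1))
    stop_ccgnet("make_ground_truth: more couplings than ordered pairs")
  if (any(cfg$transmission <= 0 | cfg$transmission > 1))
    stop_ccgnet("make_ground_truth: transmission probabilities must be in (0, 1]")

  areas <- cfg$areas %||% paste0("area", rep(1:3, length.out = n))
  if (length(areas) != n) areas <- rep(areas, length.out = n)
  rate <- rep(cfg$baseline_hz, length.out = n)
  units <- data.frame(unit = sprintf("u%03d", seq_len(n)), area = areas,
                      rate = rate, stringsAsFactors = FALSE)

  with_seed(seed, {
    if (isTRUE(cfg$positions)) {
      centroid <- match(units$area, unique(units$area)) - 1
      units$x <- centroid * 400 + stats::rnorm(n, 0, 100)
      units$y <- stats::rnorm(n, 0, 100)
      units$z <- stats::rnorm(n, 0, 100)
    }
    k <- as.integer(cfg$n_couplings)
    if (k > 0) {
      # distinct ordered pairs, no self-couplings
      pair_idx <- sample(n * (n - 1), k)
      src <- (pair_idx - 1L) %/% (n - 1L) + 1L
      off <- (pair_idx - 1L) %% (n - 1L) + 1L
      tgt <- ifelse(off >= src, off + 1L, off)
      n_pos <- round(k * cfg$frac_positive)
      sign <- rep(c(1L, -1L), c(n_pos, k - n_pos))
      couplings <- data.frame(
        source = units$unit[src], target = units$unit[tgt], sign = sign,
        lag = sample(seq(cfg$lag_range[1], cfg$lag_range[2]), k, replace = TRUE),
        duration = sample(seq(cfg$duration_range[1], cfg$duration_range[2]),
                          k, replace = TRUE),
        transmission = rep(cfg$transmission, length.out = k),
        stringsAsFactors = FALSE)
    } else {
      couplings <- data.frame(source = character(0), target = character(0),
                              sign = integer(0), lag = integer(0),
                              duration = integer(0), transmission = numeric(0))
    }
    structure(list(units = units, couplings = couplings,
                   modulation = cfg$modulation, tau_max = cfg$tau_max),
              class = "ground_truth")
  })
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("ground_truth: %d units, %d planted couplings (%d+, %d-)\n",
              nrow(x$units), nrow(x$couplings),
              sum(x$couplings$sign == 1), sum(x$couplings$sign == -1)))
  if (!is.null(x$modulation))
    cat(sprintf("  shared modulation: period %d bins, amplitude %.2f\n",
                x$modulation$period, x$modulation$amplitude))
  invisible(x)
}

#' Simulate a session of binned spike trains from planted ground truth
#'
#' Baseline trains are Bernoulli-per-bin approximations of Poisson processes
#' at each unit's configured rate, optionally multiplied by a shared
#' sinusoidal envelope (random phase per trial). A positive coupling then
#' adds, for each source spike, one target spike at a lag drawn uniformly
#' from `[lag, lag + duration - 1]` with the coupling's transmission
#' probability; a negative coupling deletes target spikes in that lag window
#' with the same probability.
#'
#' @param truth A `ground_truth` object.
#' @param M Number of trials.
#' @param N Bins per trial; must exceed the largest lag + duration.
#' @param bin_ms Bin width in ms (default 1).
#' @param stimulus Stimulus label attached to all trials (default "stim").
#' @param seed Integer seed.
#' @return A `spike_train_set`.
#' @export
simulate_session <- function(truth, M, N, bin_ms = 1, stimulus = "stim", seed = 1) {
  stopifnot(inherits(truth, "ground_truth"))
  M <- as.integer(M); N <- as.integer(N)
  if (nrow(truth$couplings) > 0 &&
      N <= max(truth$couplings$lag + truth$couplings$duration))
    stop_ccgnet("simulate_session: N must exceed max lag + duration")
  n <- nrow(truth$units)
  p_bin <- truth$units$rate * bin_ms / 1000
  amp <- if (is.null(truth$modulation)) 0 else truth$modulation$amplitude
  if (any(p_bin * (1 + amp) > 1))
    stop_ccgnet("simulate_session: per-bin probability exceeds 1; rate too high for bin width")

  with_seed(seed, {
    spikes <- array(0L, dim = c(M, N, n))
    env <- matrix(1, M, N)
    if (!is.null(truth$modulation)) {
      phase <- stats::runif(M, 0, 2 * pi)
      t_axis <- seq_len(N)
      env <- 1 + amp * sin(outer(phase, 2 * pi * t_axis / truth$modulation$period, "+"))
    }
    for (u in seq_len(n)) {
      spikes[, , u] <- (matrix(stats::runif(M * N), M, N) < p_bin[u] * env) + 0L
    }
    cp <- truth$couplings
    if (nrow(cp) > 0) {
      uid <- truth$units$unit
      for (ci in seq_len(nrow(cp))) {
        s <- match(cp$source[ci], uid); t <- match(cp$target[ci], uid)
        sp <- which(spikes[, , s] == 1L, arr.ind = TRUE)  # (trial, bin)
        if (nrow(sp) == 0) next
        go <- stats::runif(nrow(sp)) < cp$transmission[ci]
        sp <- sp[go, , drop = FALSE]
        if (nrow(sp) == 0) next
        if (cp$sign[ci] == 1) {
          lag <- cp$lag[ci] + sample.int(cp$duration[ci], nrow(sp), replace = TRUE) - 1L
          tb <- sp[, 2] + lag
          ok <- tb <= N
          if (any(ok)) spikes[cbind(sp[ok, 1], tb[ok], t)] <- 1L
        } else {
          for (off in seq(cp$lag[ci], cp$lag[ci] + cp$duration[ci] - 1L)) {
            tb <- sp[, 2] + off
            ok <- tb <= N
            if (any(ok)) spikes[cbind(sp[ok, 1], tb[ok], t)] <- 0L
          }
        }
      }
    }
    spike_train_set(spikes, truth$units, rep(stimulus, M), bin_ms)
  })
}

#' Score a detected network against planted ground truth
#'
#' A detection matches a planted coupling when source, target and sign agree
#' and the detected onset lag lies within one bin of the planted lag window
#' `[lag, lag + duration - 1]`.
#'
#' @param truth A `ground_truth`.
#' @param detected A `functional_network` over the same unit id space.
#' @return A list: `sensitivity` (matched planted / planted), `precision`
#'   (true detections / all detections; `NA` when nothing was detected),
#'   `sign_accuracy` (among detections matching a planted source-target-lag,
#'   the fraction with the planted sign; `NA` if none), `lag_error` (detected
#'   onset minus planted lag for matched couplings) and the `matches` table.
#' @export
evaluate_recovery <- function(truth, detected) {
  stopifnot(inherits(truth, "ground_truth"), inherits(detected, "functional_network"))
  if (!all(detected$nodes$unit %in% truth$units$unit))
    stop_ccgnet("evaluate_recovery: unit id spaces do not match")
  cp <- truth$couplings
  ed <- detected$edges
  if (nrow(cp) == 0) {
    return(list(sensitivity = NA_real_,
                precision = if (nrow(ed) == 0) NA_real_ else 0,
                sign_accuracy = NA_real_, lag_error = integer(0),
                matches = data.frame()))
  }
  if (nrow(ed) == 0) {
    return(list(sensitivity = 0, precision = NA_real_,
                sign_accuracy = NA_real_, lag_error = integer(0),
                matches = data.frame()))
  }
  pair_hit <- logical(nrow(cp))       # lag window + endpoints agree
  full_hit <- logical(nrow(cp))       # and sign agrees
  edge_true <- logical(nrow(ed))
  lag_err <- integer(0)
  matches <- NULL
  for (i in seq_len(nrow(cp))) {
    j <- which(ed$source == cp$source[i] & ed$target == cp$target[i])
    if (length(j) == 0) next
    j <- j[1]
    in_window <- !is.na(ed$lag[j]) &&
      ed$lag[j] >= cp$lag[i] - 1L &&
      ed$lag[j] <= cp$lag[i] + cp$duration[i]
    if (in_window) {
      pair_hit[i] <- TRUE
      if (ed$sign[j] == cp$sign[i]) {
        full_hit[i] <- TRUE
        edge_true[j] <- TRUE
        lag_err <- c(lag_err, ed$lag[j] - cp$lag[i])
        matches <- rbind(matches, data.frame(
          source = cp$source[i], target = cp$target[i], sign = cp$sign[i],
          planted_lag = cp$lag[i], detected_lag = ed$lag[j],
          significance = ed$significance[j]))
      }
    }
  }
  list(sensitivity = mean(full_hit),
       precision = sum(edge_true) / nrow(ed),
       sign_accuracy = if (any(pair_hit)) sum(full_hit) / sum(pair_hit) else NA_real_,
       lag_error = lag_err,
       matches = matches %||% data.frame())
}
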