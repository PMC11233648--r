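#' Detection parameters for CCG-based functional connections
#'
#' @param tau_max Maximum candidate onset lag in bins (default 12; with 1 ms
#'   bins, 12 ms).
#' @param n_sigma Significance multiplier on the moving-average spread
#'   (default 4: a window must deviate by 4 standard deviations).
#' @param jitter_window Jitter window size in bins (default 25).
#' @param entropy_threshold Minimum normalized entropy of the raw CCG for a
#'   pair to be considered reliable (default 0.9).
#' @param min_rate_hz Minimum firing rate per stimulus type for a unit to be
#'   retained (default 2 spikes/s).
#' @param lag_axis Length of the lag axis used to form the moving-average
#'   reference set C(D) (default 100 bins; lags 0..lag_axis).
#' @return A list of class `detection_params`.
#' @export
detection_params <- function(tau_max = 12L, n_sigma = 4, jitter_window = 25L,
                             entropy_threshold = 0.9, min_rate_hz = 2,
                             lag_axis = 100L) {
  stopifnot(tau_max >= 1, n_sigma > 0, jitter_window >= 1,
            entropy_threshold >= 0, entropy_threshold <= 1,
            lag_axis >= tau_max + 1)
  structure(list(tau_max = as.integer(tau_max), n_sigma = n_sigma,
                 jitter_window = as.integer(jitter_window),
                 entropy_threshold = entropy_threshold,
                 min_rate_hz = min_rate_hz, lag_axis = as.integer(lag_axis)),
            class = "detection_params")
}

#' Drop units whose firing rate falls below threshold under any stimulus
#'
#' Retains exactly the units whose rate is at least `min_rate_hz` during
#' every stimulus type in the session, so the unit set is identical across
#' stimulus types afterwards.
#'
#' @param data A `spike_train_set`.
#' @param min_rate_hz Rate threshold in spikes/s (default 2).
#' @return The filtered `spike_train_set`.
#' @export
filter_units_by_rate <- function(data, min_rate_hz = 2) {
  stopifnot(inherits(data, "spike_train_set"))
  labs <- unique(data$stimulus)
  ok <- rep(TRUE, nrow(data$units))
  for (s in labs) ok <- ok & (firing_rates(data, s) >= min_rate_hz)
  if (!any(ok)) stop_ccgnet("filter_units_by_rate: no units survive the rate filter")
  spike_train_set(data$spikes[, , ok, drop = FALSE],
                  data$units[ok, , drop = FALSE],
                  data$stimulus, data$bin_ms)
}

# Sparse concatenation of trials (with `pad` zero-bins after each trial) as a
# (M * (N + pad)) x U sparse matrix; padding prevents cross-trial coincidences
# for lags up to `pad`.
concat_sparse <- function(spikes, pad) {
  d <- dim(spikes)
  idx <- which(spikes == 1L, arr.ind = TRUE)   # (trial, bin, unit)
  row <- (idx[, 1] - 1L) * (d[2] + pad) + idx[, 2]
  Matrix::sparseMatrix(i = row, j = idx[, 3], x = 1,
                       dims = c(d[1] * (d[2] + pad), d[3]))
}

# Dense concatenation of the window-smoothed trains: each spike replaced by a
# uniform mass 1/w over the bins of its jitter window (per trial).  The
# cross-correlation of two such smoothed trains is the exact expectation of
# the CCG under independent interval jitter of both trains.
concat_smoothed <- function(spikes, pad, w) {
  d <- dim(spikes)
  n_win <- ceiling(d[2] / w)
  out <- matrix(0, d[1] * (d[2] + pad), d[3])
  win_id <- rep(seq_len(n_win), each = w)[seq_len(d[2])]
  win_len <- tabulate(win_id, n_win)
  for (u in seq_len(d[3])) {
    tr <- spikes[, , u, drop = TRUE]
    if (d[1] == 1) tr <- matrix(tr, 1)
    # per-trial window counts -> per-bin expected value
    counts <- t(apply(tr, 1, function(v) tapply(v, win_id, sum)))
    if (n_win == 1) counts <- matrix(counts, ncol = 1)
    sm <- counts[, win_id, drop = FALSE] / rep(win_len[win_id], each = d[1])
    full <- cbind(sm, matrix(0, d[1], pad))
    out[, u] <- as.vector(t(full))
  }
  out
}

# One Monte-Carlo jitter resample: spikes uniformly redistributed within their
# jitter window, per trial and unit, preserving window counts.
jitter_resample <- function(spikes, w) {
  d <- dim(spikes)
  n_win <- ceiling(d[2] / w)
  win_id <- rep(seq_len(n_win), each = w)[seq_len(d[2])]
  out <- array(0L, d)
  for (u in seq_len(d[3])) for (m in seq_len(d[1])) {
    v <- spikes[m, , u]
    for (wi in seq_len(n_win)) {
      bins <- which(win_id == wi)
      k <- sum(v[bins])
      if (k > 0) out[m, bins[sample.int(length(bins), k)], u] <- 1L
    }
  }
  out
}

# All-pairs CCG: raw, jitter expectation and corrected curves for every
# ordered unit pair, lags 0..lag_axis.  Returns arrays [U, U, L + 1].
ccg_all_pairs <- function(data, params, sel = rep(TRUE, data$M),
                          jitter_method = c("analytic", "montecarlo"),
                          n_jitter = 50, seed = 1) {
  jitter_method <- match.arg(jitter_method)
  spikes <- data$spikes[sel, , , drop = FALSE]
  d <- dim(spikes)
  L <- params$lag_axis
  if (d[2] <= L) stop_ccgnet("ccg: trains shorter than the lag axis")
  lam <- apply(spikes, 3, sum) / (d[1] * d[2])
  if (any(lam == 0))
    stop_ccgnet("ccg: zero-rate unit(s); the CCG normalization is undefined")

  X <- concat_sparse(spikes, pad = L)
  Ttot <- nrow(X)
  U <- d[3]
  norm <- outer(sqrt(lam), sqrt(lam))
  raw <- array(0, c(U, U, L + 1))
  for (tau in 0:L) {
    num <- as.matrix(Matrix::crossprod(X[seq_len(Ttot - tau), , drop = FALSE],
                                       X[seq_len(Ttot - tau) + tau, , drop = FALSE]))
    raw[, , tau + 1] <- num / (d[1] * (d[2] - tau) * norm)
  }

  jit <- array(0, c(U, U, L + 1))
  if (jitter_method == "analytic") {
    S <- concat_smoothed(spikes, pad = L, w = params$jitter_window)
    for (tau in 0:L) {
      num <- crossprod(S[seq_len(Ttot - tau), , drop = FALSE],
                       S[seq_len(Ttot - tau) + tau, , drop = FALSE])
      jit[, , tau + 1] <- num / (d[1] * (d[2] - tau) * norm)
    }
  } else {
    with_seed(seed, {
      for (r in seq_len(n_jitter)) {
        Xj <- concat_sparse(jitter_resample(spikes, params$jitter_window), pad = L)
        for (tau in 0:L) {
          num <- as.matrix(Matrix::crossprod(Xj[seq_len(Ttot - tau), , drop = FALSE],
                                             Xj[seq_len(Ttot - tau) + tau, , drop = FALSE]))
          jit[, , tau + 1] <- jit[, , tau + 1] +
            num / (n_jitter * d[1] * (d[2] - tau) * norm)
        }
      }
    })
  }
  list(raw = raw, jitter = jit, corrected = raw - jit, lambda = lam,
       lags = 0:L, units = data$units$unit)
}

#' Jitter-corrected cross-correlogram for one ordered unit pair
#'
#' Computes the trial-averaged, rate-normalized cross-correlogram
#' `raw[tau] = (1/M) sum_i sum_t x_A(t) x_B(t + tau) / (theta(tau) *
#' sqrt(lambda_A lambda_B))` with `theta(tau) = N - tau` correcting the
#' shrinking overlap, over non-negative lags 0..`lag_axis`; the jitter
#' expectation (spikes uniformly redistributed within `jitter_window`-bin
#' windows, per trial) is subtracted to remove slow shared rate fluctuations.
#'
#' @param trainA,trainB Binary M x N matrices (trials x bins) for the source
#'   and target unit, with equal dimensions.
#' @param params A `detection_params`.
#' @param jitter_method `"analytic"` (exact expectation of the jitter null,
#'   default) or `"montecarlo"` (seeded resampling average).
#' @param n_jitter Number of Monte-Carlo resamples (default 50).
#' @param seed Seed for the Monte-Carlo mode.
#' @return An object of class `ccg_curve`: list with `lags`, `raw`,
#'   `jitter_expectation`, `corrected`, `lambda` and `T` (train length).
#' @export
compute_ccg <- function(trainA, trainB, params = detection_params(),
                        jitter_method = c("analytic", "montecarlo"),
                        n_jitter = 50, seed = 1) {
  trainA <- as.matrix(trainA); trainB <- as.matrix(trainB)
  if (!all(dim(trainA) == dim(trainB)))
    stop_ccgnet("compute_ccg: trains need equal trial counts and lengths")
  arr <- array(0L, c(nrow(trainA), ncol(trainA), 2))
  arr[, , 1] <- trainA; arr[, , 2] <- trainB
  dat <- spike_train_set(arr, data.frame(unit = c("A", "B"), area = "-"))
  res <- ccg_all_pairs(dat, params, jitter_method = match.arg(jitter_method),
                       n_jitter = n_jitter, seed = seed)
  structure(list(lags = res$lags, raw = res$raw[1, 2, ],
                 jitter_expectation = res$jitter[1, 2, ],
                 corrected = res$corrected[1, 2, ],
                 lambda = res$lambda, T = ncol(trainA)),
            class = "ccg_curve")
}

#' @export
print.ccg_curve <- function(x, ...) {
  cat(sprintf("ccg_curve: lags 0..%d, peak corrected %.4g at lag %d\n",
              max(x$lags), max(x$corrected),
              x$lags[which.max(x$corrected)]))
  invisible(x)
}

#' Normalized Shannon entropy of a CCG lag distribution
#'
#' The raw (non-negative) CCG values are normalized to a probability
#' distribution over lags; its Shannon entropy divided by `log(n_lags)`
#' quantifies how concentrated the correlogram is. Pairs with too few spikes
#' give low-entropy, unreliable correlograms and are excluded from the
#' network below the threshold. An all-zero curve returns 0.
#'
#' @param curve A `ccg_curve`, or a numeric vector of non-negative raw CCG
#'   values.
#' @return A value in \[0, 1\].
#' @export
normalized_entropy <- function(curve) {
  v <- if (inherits(curve, "ccg_curve")) curve$raw else curve
  if (length(v) < 2) stop_ccgnet("normalized_entropy: need at least 2 lag bins")
  if (any(v < 0)) stop_ccgnet("normalized_entropy: raw CCG values must be non-negative")
  s <- sum(v)
  if (s == 0) return(0)
  p <- v / s
  p <- p[p > 0]
  -sum(p * log(p)) / log(length(v))
}

# Scan a corrected CCG for the most significant sharp peak / interval.
# For each duration D in 1..tau_max+1, the reference set C(D) holds the
# moving averages over the whole lag axis; a candidate window starting at
# t0 in 0..tau_max-D+1 is significant when its mean crosses mu +/- n*sigma.
# The smallest qualifying D is reported.  `restrict_t0min` re-runs the scan
# with onsets >= 1 (used by the zero-lag resolution rule).
scan_windows <- function(cc, params, t0_min = 0L) {
  L1 <- length(cc)
  for (D in seq_len(params$tau_max + 1L)) {
    cs <- cumsum(c(0, cc))
    mov <- (cs[(D + 1):(L1 + 1)] - cs[seq_len(L1 - D + 1)]) / D
    sigma <- stats::sd(mov)
    if (!is.finite(sigma) || sigma == 0) next
    mu <- mean(mov)
    t0s <- seq.int(t0_min, params$tau_max - D + 1L)
    t0s <- t0s[t0s >= 0 & t0s <= L1 - D]
    if (length(t0s) == 0) next
    m <- mov[t0s + 1L]
    z <- (m - mu) / sigma
    hit <- which(z > params$n_sigma | z < -params$n_sigma)
    if (length(hit) > 0) {
      best <- hit[which.max(abs(z[hit]))]
      t0 <- t0s[best]
      win <- cc[(t0 + 1):(t0 + D)]
      sign <- if (z[best] > 0) 1L else -1L
      weight <- if (sign == 1) max(win) else min(win)
      return(list(sign = sign, lag = t0, duration = D,
                  significance = z[best], weight = weight))
    }
  }
  NULL
}

#' Detect a signed sharp-peak / sharp-interval connection in a CCG
#'
#' Searches durations `D = 1..tau_max + 1` in increasing order; for each, the
#' moving averages of the corrected CCG over the whole lag axis form the
#' reference set whose mean and standard deviation gate candidate windows
#' with onsets in `0..tau_max - D + 1` at `n_sigma`-fold significance. The
#' smallest qualifying duration is reported (it carries the highest
#' significance); within it, the window with the largest |Z|. A constant
#' curve (zero spread) yields no detection for that duration.
#'
#' @param curve A `ccg_curve`.
#' @param params A `detection_params`.
#' @return `NULL` if nothing is significant, else a list of class
#'   `ccg_detection` with `sign`, `lag` (onset t0), `duration`,
#'   `significance` (Z of the winning window mean) and `weight` (signed
#'   corrected-CCG extremum within the window), plus `nonzero`: the best
#'   candidate restricted to onsets > 0 (or `NULL`).
#' @export
detect_connection <- function(curve, params = detection_params()) {
  cc <- if (inherits(curve, "ccg_curve")) curve$corrected else curve
  if (any(!is.finite(cc))) stop_ccgnet("detect_connection: corrected CCG must be finite")
  best <- scan_windows(cc, params, t0_min = 0L)
  if (is.null(best)) return(NULL)
  best$nonzero <- if (best$lag > 0) best[c("sign", "lag", "duration",
                                           "significance", "weight")]
                  else scan_windows(cc, params, t0_min = 1L)
  class(best) <- "ccg_detection"
  best
}

#' Resolve zero-lag detections between the two orderings of a pair
#'
#' Zero-lag peaks are treated as a single primary direction of communication:
#' when both orderings are significant only at lag 0, the direction with the
#' higher significance is kept; the other direction survives only if it also
#' has a significant window at a non-zero lag (in which case that window is
#' used). Exact ties are broken lexicographically by (source, target) id.
#'
#' @param candAB,candBA Results of [detect_connection()] for A->B and B->A
#'   (`NULL` when not significant).
#' @param idA,idB Unit ids of A and B (used for the deterministic tie-break).
#' @return A list with elements `AB` and `BA`, each `NULL` or a detection.
#' @export
resolve_zero_lag <- function(candAB, candBA, idA = "A", idB = "B") {
  if (is.null(candAB) || is.null(candBA) || candAB$lag > 0 || candBA$lag > 0)
    return(list(AB = candAB, BA = candBA))
  sAB <- abs(candAB$significance); sBA <- abs(candBA$significance)
  ab_wins <- if (sAB != sBA) sAB > sBA else idA < idB
  if (ab_wins) {
    list(AB = candAB, BA = if (!is.null(candBA$nonzero)) {
      d <- candBA$nonzero; class(d) <- "ccg_detection"; d
    })
  } else {
    list(AB = if (!is.null(candAB$nonzero)) {
      d <- candAB$nonzero; class(d) <- "ccg_detection"; d
    }, BA = candBA)
  }
}

#' Build the signed functional network of a session
#'
#' Evaluates every ordered unit pair for one stimulus label: computes all
#' jitter-corrected CCGs, excludes unreliable pairs by normalized entropy,
#' detects signed sharp peaks / intervals, and resolves zero-lag conflicts.
#' Connection weights are the signed corrected-CCG extremum within the
#' winning window.
#'
#' @param data A rate-filtered `spike_train_set` (see
#'   [filter_units_by_rate()]).
#' @param params A `detection_params`.
#' @param stimulus Stimulus label selecting the trials (default: all trials
#'   regardless of label).
#' @param jitter_method,n_jitter,seed Passed to the CCG stage.
#' @param correct If `FALSE`, detection runs on the raw (uncorrected) CCG —
#'   useful for quantifying how much slow-comodulation structure the jitter
#'   correction removes.
#' @return A `functional_network` with an `exclusions` attribute counting
#'   pairs removed by the entropy filter.
#' @export
build_network <- function(data, params = detection_params(), stimulus = NULL,
                          jitter_method = "analytic", n_jitter = 50, seed = 1,
                          correct = TRUE) {
  stopifnot(inherits(data, "spike_train_set"))
  sel <- if (is.null(stimulus)) rep(TRUE, data$M) else data$stimulus == stimulus
  if (!any(sel)) stop_ccgnet("build_network: no trials with that stimulus label")
  res <- ccg_all_pairs(data, params, sel, jitter_method = jitter_method,
                       n_jitter = n_jitter, seed = seed)
  U <- length(res$units)
  det <- vector("list", U * U)
  entropy_dropped <- 0L
  for (a in seq_len(U)) for (b in seq_len(U)) {
    if (a == b) next
    raw <- res$raw[a, b, ]
    if (normalized_entropy(raw) < params$entropy_threshold) {
      entropy_dropped <- entropy_dropped + 1L
      next
    }
    cand <- detect_connection(
      if (correct) res$corrected[a, b, ] else res$raw[a, b, ], params)
    if (!is.null(cand)) det[[(a - 1L) * U + b]] <- cand
  }
  edges <- NULL
  for (a in seq_len(U - 1L)) for (b in seq.int(a + 1L, U)) {
    cAB <- det[[(a - 1L) * U + b]]
    cBA <- det[[(b - 1L) * U + a]]
    r <- resolve_zero_lag(cAB, cBA, res$units[a], res$units[b])
    if (!is.null(r$AB))
      edges <- rbind(edges, data.frame(
        source = res$units[a], target = res$units[b], sign = r$AB$sign,
        weight = r$AB$weight, lag = r$AB$lag, duration = r$AB$duration,
        significance = r$AB$significance))
    if (!is.null(r$BA))
      edges <- rbind(edges, data.frame(
        source = res$units[b], target = res$units[a], sign = r$BA$sign,
        weight = r$BA$weight, lag = r$BA$lag, duration = r$BA$duration,
        significance = r$BA$significance))
  }
  net <- functional_network(data$units, edges)
  attr(net, "exclusions") <- c(entropy = entropy_dropped)
  net
}
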