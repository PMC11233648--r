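# Cross-correlogram computation and sharp peak / interval detection.

test_that("raw CCG matches hand-forced single-spike cases", {
  p <- detection_params(tau_max = 3, lag_axis = 9)
  A <- matrix(0L, 1, 10); A[1, 5] <- 1L
  self <- compute_ccg(A, A, p)
  expect_equal(self$raw[1], 1 / (10 * 0.1))          # = 1.0

  B <- matrix(0L, 1, 10); B[1, 7] <- 1L
  pair <- compute_ccg(A, B, p)
  expect_equal(pair$raw[3], 1 / ((10 - 2) * 0.1))    # = 1.25
  expect_equal(pair$raw[1], 0)
  # corrected = raw - jitter expectation elementwise
  expect_equal(pair$corrected, pair$raw - pair$jitter_expectation)
})

test_that("raw CCG equals the naive triple-loop coincidence count exactly", {
  set.seed(31)
  p <- detection_params(tau_max = 5, lag_axis = 20)
  for (rep in 1:5) {
    A <- matrix(rbinom(4 * 60, 1, 0.15), 4, 60)
    B <- matrix(rbinom(4 * 60, 1, 0.15), 4, 60)
    if (sum(A) == 0 || sum(B) == 0) next
    cv <- compute_ccg(A, B, p)
    counts <- oracle_ccg_counts(A, B, 20)
    lamA <- sum(A) / length(A); lamB <- sum(B) / length(B)
    denorm <- cv$raw * (4 * (60 - 0:20) * sqrt(lamA * lamB))
    expect_equal(denorm, as.numeric(counts), tolerance = 1e-9)
  }
})

test_that("zero-rate units are rejected and short trains refused", {
  p <- detection_params(tau_max = 3, lag_axis = 9)
  Z <- matrix(0L, 1, 10); A <- matrix(0L, 1, 10); A[1, 2] <- 1L
  expect_error(compute_ccg(A, Z, p), "zero-rate")
  expect_error(compute_ccg(A[, 1:5, drop = FALSE], A[, 1:5, drop = FALSE], p),
               "shorter than")
})

test_that("independent stationary pairs give unbiased, lag-flat corrected CCGs", {
  p <- detection_params()
  means <- matrix(NA_real_, 50, 2)
  lagmean <- matrix(NA_real_, 50, 101)
  for (s in 1:50) {
    dat <- mk_poisson_set(U = 2, M = 15, N = 600, rate_hz = 25, seed = 400 + s)
    cv <- compute_ccg(dat$spikes[, , 1], dat$spikes[, , 2], p)
    means[s, ] <- c(mean(cv$corrected), NA)
    lagmean[s, ] <- cv$raw
  }
  gm <- mean(means[, 1])
  se <- stats::sd(means[, 1]) / sqrt(50)
  expect_lt(abs(gm), 3 * se)

  # theta(tau) overlap correction: no triangular bias in the raw CCG
  avg <- colMeans(lagmean)
  fit <- stats::lm(avg ~ seq_along(avg))
  slope_t <- summary(fit)$coefficients[2, "t value"]
  expect_lt(abs(slope_t), 3)
})

test_that("analytic jitter expectation agrees with Monte-Carlo resampling", {
  set.seed(33)
  dat <- mk_poisson_set(U = 2, M = 10, N = 400, rate_hz = 40, seed = 77)
  p <- detection_params(lag_axis = 50)
  an <- compute_ccg(dat$spikes[, , 1], dat$spikes[, , 2], p)
  mc <- compute_ccg(dat$spikes[, , 1], dat$spikes[, , 2], p,
                    jitter_method = "montecarlo", n_jitter = 200, seed = 3)
  expect_identical(an$raw, mc$raw)
  expect_lt(mean(abs(an$jitter_expectation - mc$jitter_expectation)),
            0.05 * mean(an$jitter_expectation))
})

test_that("sharp peak and sharp interval detection follow the window rules", {
  p <- detection_params()
  expect_null(detect_connection(rep(0.3, 101), p))   # constant: sigma = 0

  set.seed(35)
  base <- rnorm(101, 0, 1)
  base <- base / sd(base)
  curve <- base
  curve[5] <- mean(base) + 10 * sd(base)             # lag 4 (0-based)
  d <- detect_connection(curve, p)
  expect_identical(d$sign, 1L)
  expect_identical(d$lag, 4L)
  expect_identical(d$duration, 1L)
  expect_gt(d$significance, 4)

  # three consecutive bins at +3 sigma: invisible at D = 1, found at D >= 2
  curve2 <- base
  curve2[6:8] <- mean(base) + 3 * sd(base)
  # brute-force over all (D, t0): D = 1 must fail, some D >= 2 must succeed
  d1_hits <- FALSE
  for (t0 in 0:12) {
    mov <- curve2[t0 + 1]
    z <- (mov - mean(curve2)) / sd(curve2)
    if (abs(z) > 4) d1_hits <- TRUE
  }
  d2 <- detect_connection(curve2, p)
  expect_false(d1_hits)
  expect_false(is.null(d2))
  expect_gte(d2$duration, 2L)
  expect_identical(d2$sign, 1L)

  # negative interval detection
  curve3 <- base
  curve3[3:5] <- mean(base) - 3.5 * sd(base)
  d3 <- detect_connection(curve3, p)
  expect_identical(d3$sign, -1L)
  expect_lt(d3$weight, mean(base))
})

test_that("zero-lag conflicts keep the primary direction", {
  cand <- function(lag, z, nonzero = NULL)
    structure(list(sign = 1L, lag = lag, duration = 1L, significance = z,
                   weight = 0.5, nonzero = nonzero), class = "ccg_detection")

  # both only at zero lag: higher significance wins
  r <- resolve_zero_lag(cand(0L, 6), cand(0L, 5), "a", "b")
  expect_false(is.null(r$AB))
  expect_null(r$BA)

  # loser has a non-zero significant window: both kept
  nz <- list(sign = 1L, lag = 3L, duration = 1L, significance = 4.5, weight = 0.4)
  r2 <- resolve_zero_lag(cand(0L, 6), cand(0L, 5, nonzero = nz), "a", "b")
  expect_false(is.null(r2$AB))
  expect_identical(r2$BA$lag, 3L)
  expect_equal(r2$BA$significance, 4.5)

  # only one direction significant: passthrough
  r3 <- resolve_zero_lag(cand(0L, 6), NULL, "a", "b")
  expect_identical(r3$AB$lag, 0L)
  expect_null(r3$BA)

  # exact tie: lexicographic (source, target) order
  r4 <- resolve_zero_lag(cand(0L, 5), cand(0L, 5), "a", "b")
  expect_false(is.null(r4$AB))
  expect_null(r4$BA)
})

test_that("normalized entropy has the stated closed forms", {
  expect_equal(normalized_entropy(rep(1, 8)), 1)
  expect_equal(normalized_entropy(c(0, 0, 7, 0)), 0)
  expect_equal(normalized_entropy(c(1, 1, rep(0, 6))), log(2) / log(8))
  expect_equal(normalized_entropy(rep(0, 10)), 0)
  expect_error(normalized_entropy(c(-1, 2)), "non-negative")
})

test_that("rate filtering drops a unit that is slow under any stimulus", {
  set.seed(37)
  M <- 20; N <- 500
  arr <- array(0L, c(M, N, 3))
  arr[, , 1] <- rbinom(M * N, 1, 0.02)      # 20 Hz everywhere
  arr[, , 2] <- rbinom(M * N, 1, 0.02)
  arr[1:10, , 3] <- matrix(rbinom(10 * N, 1, 0.02), 10)   # fast in stim A
  arr[11:20, , 3] <- matrix(rbinom(10 * N, 1, 0.001), 10) # ~1 Hz in stim B
  dat <- spike_train_set(arr, data.frame(unit = c("a", "b", "c"), area = "x"),
                         stimulus = rep(c("A", "B"), each = 10))
  filt <- filter_units_by_rate(dat, 2)
  expect_identical(filt$units$unit, c("a", "b"))

  # survivor set equals brute-force recomputation from the raw arrays
  brute <- sapply(1:3, function(u) {
    all(sapply(c("A", "B"), function(s) {
      sel <- dat$stimulus == s
      sum(dat$spikes[sel, , u]) / (sum(sel) * N / 1000) >= 2
    }))
  })
  expect_identical(which(brute), 1:2)
  expect_error(filter_units_by_rate(dat, 1e6), "no units")
})

test_that("swapping source and target respects the lag convention", {
  gt <- make_ground_truth(list(n_units = 2, n_couplings = 0), seed = 41)
  gt$couplings <- data.frame(source = "u001", target = "u002", sign = 1L,
                             lag = 3L, duration = 1L, transmission = 0.8)
  dat <- simulate_session(gt, M = 80, N = 1500, seed = 42)
  p <- detection_params()
  ab <- compute_ccg(dat$spikes[, , 1], dat$spikes[, , 2], p)
  ba <- compute_ccg(dat$spikes[, , 2], dat$spikes[, , 1], p)
  expect_equal(ab$raw[1], ba$raw[1], tolerance = 1e-12)  # zero lag symmetric
  dab <- detect_connection(ab, p)
  expect_identical(dab$lag, 3L)
  dba <- detect_connection(ba, p)
  # the reversed ordering must not see a positive peak at a positive lag
  expect_true(is.null(dba) || dba$lag == 0L || dba$sign == -1L)
})

test_that("build_network assembles, filters, and is deterministic", {
  gt <- make_ground_truth(list(n_units = 8, n_couplings = 3,
                               frac_positive = 1), seed = 51)
  dat <- simulate_session(gt, M = 60, N = 1200, seed = 52)
  n1 <- build_network(dat, detection_params(), seed = 53)
  n2 <- build_network(dat, detection_params(), seed = 53)
  expect_identical(n1$edges, n2$edges)
  expect_true(all(n1$edges$lag >= 0))
  expect_true(all(n1$edges$duration >= 1 & n1$edges$duration <= 13))
  expect_true(all(abs(n1$edges$significance) > 4))
})
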