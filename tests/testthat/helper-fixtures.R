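# Fixture generators and independent oracles shared across the test suite.
# Oracles are deliberately naive (triple loops, exhaustive enumeration) and
# never reuse package internals.

# Random signed directed network (uniform edge placement).
mk_random_net <- function(V, E, frac_pos = 0.7, seed = 1, areas = NULL,
                          weights = TRUE) {
  set.seed(seed)
  units <- data.frame(unit = sprintf("u%03d", seq_len(V)),
                      area = areas %||% rep("a", V))
  slot <- sample(V * (V - 1), E)
  s <- (slot - 1) %/% (V - 1) + 1
  off <- (slot - 1) %% (V - 1) + 1
  t <- ifelse(off >= s, off + 1, off)
  sign <- ifelse(stats::runif(E) < frac_pos, 1L, -1L)
  w <- if (weights) stats::runif(E, 0.2, 1) else rep(1, E)
  functional_network(units, data.frame(source = units$unit[s],
                                       target = units$unit[t],
                                       sign = sign, weight = sign * w))
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# Planted 3-block signed network: positive within blocks, negative between.
mk_block_net <- function(n_per = 20, blocks = 3, p_in = 0.25, p_out = 0.1,
                         seed = 1) {
  set.seed(seed)
  V <- n_per * blocks
  blk <- rep(seq_len(blocks), each = n_per)
  units <- data.frame(unit = sprintf("u%03d", seq_len(V)),
                      area = paste0("a", blk))
  src <- rep(seq_len(V), each = V); tgt <- rep(seq_len(V), V)
  keep <- src != tgt
  src <- src[keep]; tgt <- tgt[keep]
  same <- blk[src] == blk[tgt]
  u <- stats::runif(length(src))
  on <- (same & u < p_in) | (!same & u < p_out)
  src <- src[on]; tgt <- tgt[on]; same <- same[on]
  e <- data.frame(source = units$unit[src], target = units$unit[tgt],
                  sign = ifelse(same, 1L, -1L),
                  weight = ifelse(same, 1, -1) * stats::runif(length(src), 0.5, 1))
  list(net = functional_network(units, e),
       blocks = stats::setNames(blk, units$unit))
}

# --- oracles --------------------------------------------------------------

# Raw CCG numerator by naive triple loop (integer coincidence counts).
oracle_ccg_counts <- function(trainA, trainB, lag_max) {
  M <- nrow(trainA); N <- ncol(trainA)
  counts <- integer(lag_max + 1)
  for (tau in 0:lag_max) {
    tot <- 0L
    for (i in seq_len(M)) for (t in seq_len(N - tau)) {
      tot <- tot + trainA[i, t] * trainB[i, t + tau]
    }
    counts[tau + 1] <- tot
  }
  counts
}

# Triad classification oracle: match the 3-node subgraph against canonical
# representatives by explicit permutation search over edge lists.
oracle_classify <- function(adj, sgn) {
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1),
                c(3, 1, 2), c(3, 2, 1))
  arcs <- rbind(c(1, 2), c(2, 1), c(1, 3), c(3, 1), c(2, 3), c(3, 2))
  enc <- function(a, s) {
    bits <- mapply(function(i, j) a[i, j], arcs[, 1], arcs[, 2])
    trit <- mapply(function(i, j) {
      if (a[i, j] == 0) 0 else if (s[i, j] > 0) 1 else 2
    }, arcs[, 1], arcs[, 2])
    c(sum(bits * 2^(0:5)), sum(trit * 3^(0:5)))
  }
  best <- NULL
  for (p in perms) {
    a2 <- adj[p, p]; s2 <- sgn[p, p]
    key <- enc(a2, s2)
    if (is.null(best) || key[1] < best[1] ||
        (key[1] == best[1] && key[2] < best[2])) best <- key
  }
  best   # canonical (pattern code, sign code)
}

# Full motif census by naive O(V^3) loop over triples.
oracle_census <- function(net) {
  units <- net$nodes$unit
  V <- length(units)
  A <- matrix(0, V, V); S <- matrix(0, V, V); W <- matrix(0, V, V)
  idx <- cbind(match(net$edges$source, units), match(net$edges$target, units))
  A[idx] <- 1; S[idx] <- net$edges$sign; W[idx] <- abs(net$edges$weight)
  out <- list()
  for (i in 1:(V - 2)) for (j in (i + 1):(V - 1)) for (k in (j + 1):V) {
    tr <- c(i, j, k)
    a <- A[tr, tr]
    pairs_conn <- sum((a[1, 2] | a[2, 1]), (a[1, 3] | a[3, 1]),
                      (a[2, 3] | a[3, 2]))
    if (pairs_conn < 2) next
    key <- paste(oracle_classify(a, S[tr, tr]), collapse = "_")
    w <- W[tr, tr][a == 1]
    I <- prod(w)^(1 / length(w))
    if (is.null(out[[key]])) out[[key]] <- c(0, 0)
    out[[key]] <- out[[key]] + c(1, I)
  }
  out  # named list: canonical key -> (count, intensity)
}

# Pair-counting ARI oracle: count agreeing node pairs directly.
oracle_ari <- function(x, y) {
  n <- length(x)
  same_x <- outer(x, x, "==")[upper.tri(diag(n))]
  same_y <- outer(y, y, "==")[upper.tri(diag(n))]
  a <- sum(same_x & same_y); b <- sum(same_x & !same_y)
  c_ <- sum(!same_x & same_y); d <- sum(!same_x & !same_y)
  tot <- a + b + c_ + d
  expected <- (a + b) * (a + c_) / tot
  ((a - expected) / ((2 * a + b + c_) / 2 - expected))
}

# Signed modularity oracle: literal double loop over all ordered pairs
# (including i = j null terms) per the modularity definition.
oracle_modularity <- function(net, assignment, gamma_pos = 1, gamma_neg = 1,
                              weighted = FALSE) {
  units <- net$nodes$unit
  V <- length(units)
  Apos <- matrix(0, V, V); Aneg <- matrix(0, V, V)
  idx <- cbind(match(net$edges$source, units), match(net$edges$target, units))
  val <- if (weighted) abs(net$edges$weight) else rep(1, nrow(net$edges))
  pos <- net$edges$sign == 1
  Apos[idx[pos, , drop = FALSE]] <- val[pos]
  Aneg[idx[!pos, , drop = FALSE]] <- val[!pos]
  mp <- sum(Apos); mn <- sum(Aneg)
  q <- 0
  for (i in 1:V) for (j in 1:V) {
    if (assignment[i] != assignment[j]) next
    pp <- if (mp > 0) sum(Apos[i, ]) * sum(Apos[, j]) / mp else 0
    pn <- if (mn > 0) sum(Aneg[i, ]) * sum(Aneg[, j]) / mn else 0
    q <- q + (Apos[i, j] - Aneg[i, j]) - (gamma_pos * pp - gamma_neg * pn)
  }
  q / (mp + mn)
}

# All set partitions of 1..n (for exhaustive modularity optimization).
all_partitions <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in all_partitions(n - 1)) {
    for (b in seq_len(max(p) + 1L)) out[[length(out) + 1L]] <- c(p, b)
  }
  out
}

# Poisson-like independent spike session without structure.
mk_poisson_set <- function(U, M, N, rate_hz = 20, seed = 1) {
  gt <- make_ground_truth(list(n_units = U, n_couplings = 0, positions = FALSE,
                               baseline_hz = rate_hz), seed = seed)
  simulate_session(gt, M = M, N = N, seed = seed + 10000)
}
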