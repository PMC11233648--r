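#' Topological summary statistics of a signed functional network
#'
#' Density (edges over ordered pairs), fraction of positive edges, fraction
#' of within-area edges, the mean directed clustering coefficient of the
#' unsigned binarized graph, and the signed degree sequences.
#'
#' The clustering coefficient is the directed all-motif generalization: for
#' node i with binarized adjacency A, `C_i = ((A + A')^3)_ii / (2 *
#' (d_tot_i (d_tot_i - 1) - 2 d_bi_i))` where `d_tot` is total (in + out)
#' degree and `d_bi` the number of reciprocal neighbours; the network value
#' averages over nodes with a defined denominator.
#'
#' @param net A `functional_network`.
#' @return A list with `density`, `frac_positive`, `frac_within_area`,
#'   `clustering`, and a `degrees` data frame (per node signed in/out degrees
#'   and strengths). With zero edges the fractions and clustering are `NA`.
#' @export
summary_metrics <- function(net) {
  stopifnot(inherits(net, "functional_network"))
  V <- nrow(net$nodes)
  if (V == 0) stop_ccgnet("summary_metrics: empty node set")
  E <- nrow(net$edges)
  deg <- signed_degrees(net, weighted = FALSE)
  str <- signed_degrees(net, weighted = TRUE)
  degrees <- data.frame(unit = net$nodes$unit,
                        in_pos = deg$in_pos, in_neg = deg$in_neg,
                        out_pos = deg$out_pos, out_neg = deg$out_neg,
                        s_in_pos = str$in_pos, s_in_neg = str$in_neg,
                        s_out_pos = str$out_pos, s_out_neg = str$out_neg,
                        row.names = NULL)
  if (E == 0) {
    return(list(density = 0, frac_positive = NA_real_,
                frac_within_area = NA_real_, clustering = NA_real_,
                degrees = degrees))
  }
  frac_within <- if ("area" %in% names(net$nodes)) {
    area <- stats::setNames(net$nodes$area, net$nodes$unit)
    mean(area[net$edges$source] == area[net$edges$target])
  } else NA_real_

  A <- adjacency_matrix(net, "binary")
  S <- A + t(A)
  tri <- diag(S %*% S %*% S)
  d_tot <- rowSums(A) + colSums(A)
  d_bi <- rowSums(A * t(A))
  denom <- 2 * (d_tot * (d_tot - 1) - 2 * d_bi)
  cl <- ifelse(denom > 0, tri / denom, NA_real_)

  list(density = E / (V * (V - 1)),
       frac_positive = mean(net$edges$sign == 1),
       frac_within_area = frac_within,
       clustering = if (all(is.na(cl))) NA_real_ else mean(cl, na.rm = TRUE),
       degrees = degrees)
}

#' Signal correlation: tuning similarity between unit pairs
#'
#' For each unit, a tuning vector of condition-averaged spike counts (total
#' count in the trial window, averaged over the trials of each condition);
#' the signal correlation of two units is the Pearson correlation of their
#' tuning vectors. At least 3 distinct conditions are required (with 2, the
#' correlation is trivially +/-1). Units with zero variance across
#' conditions yield `NA` rows/columns.
#'
#' @param data A `spike_train_set`.
#' @param conditions Vector of condition labels, one per trial.
#' @return A symmetric U x U correlation matrix with unit dimnames and unit
#'   diagonal where defined.
#' @export
signal_correlation <- function(data, conditions) {
  stopifnot(inherits(data, "spike_train_set"))
  if (length(conditions) != data$M)
    stop_ccgnet("signal_correlation: one condition label per trial required")
  conds <- unique(conditions)
  if (length(conds) < 3)
    stop_ccgnet("signal_correlation: need at least 3 distinct conditions")
  counts <- apply(data$spikes, c(1, 3), sum)        # trials x units
  tuning <- apply(counts, 2, function(v) tapply(v, conditions, mean))
  keep <- apply(tuning, 2, stats::sd) > 0
  out <- matrix(NA_real_, ncol(tuning), ncol(tuning),
                dimnames = list(data$units$unit, data$units$unit))
  if (any(keep)) out[keep, keep] <- stats::cor(tuning[, keep, drop = FALSE])
  out
}

#' Euclidean distances between unit positions
#'
#' @param net A `functional_network` whose nodes carry `x`, `y`, `z`.
#' @return Symmetric matrix of pairwise distances (micrometres); `NA` where a
#'   position is missing.
#' @export
unit_distances <- function(net) {
  nd <- net$nodes
  if (!all(c("x", "y", "z") %in% names(nd)))
    stop_ccgnet("unit_distances: nodes lack 3-D positions")
  m <- as.matrix(stats::dist(nd[, c("x", "y", "z")]))
  dimnames(m) <- list(nd$unit, nd$unit)
  m
}

#' Connection probability against a pair covariate, with trend test
#'
#' Bins unordered node pairs by a covariate (e.g. distance or signal
#' correlation), tabulates the empirical probability of being connected (in
#' either direction) and of being positive given connected, and tests for a
#' monotone trend in connection probability with the Cochran-Armitage
#' statistic.
#'
#' @param net A `functional_network`.
#' @param values Symmetric matrix of covariate values over units (dimnames
#'   matching unit ids); pairs with `NA` are excluded.
#' @param breaks Number of equal-width bins (default 5) or a vector of break
#'   points covering the covariate range.
#' @return A list with `table` (bin, n_pairs, n_connected, p_connect,
#'   n_positive, p_positive_given_connected) and `trend` (from
#'   [trend_test()]; `NA`s when fewer than 2 bins are occupied).
#' @export
connection_probability_profile <- function(net, values, breaks = 5) {
  units <- net$nodes$unit
  values <- values[units, units]
  pairs <- which(upper.tri(values), arr.ind = TRUE)
  v <- values[pairs]
  ok <- is.finite(v)
  pairs <- pairs[ok, , drop = FALSE]; v <- v[ok]
  if (length(v) == 0) stop_ccgnet("connection_probability_profile: no pairs with covariate")
  if (length(breaks) == 1) breaks <- seq(min(v), max(v), length.out = breaks + 1)
  bin <- cut(v, breaks, include.lowest = TRUE)

  conn_key <- unique(ifelse(net$edges$source < net$edges$target,
                            paste(net$edges$source, net$edges$target),
                            paste(net$edges$target, net$edges$source)))
  pos_units <- net$edges$sign == 1
  # an unordered pair is 'positive' if any of its edges is positive
  pos_key <- unique(ifelse(net$edges$source[pos_units] < net$edges$target[pos_units],
                           paste(net$edges$source[pos_units], net$edges$target[pos_units]),
                           paste(net$edges$target[pos_units], net$edges$source[pos_units])))
  key <- paste(pmin(units[pairs[, 1]], units[pairs[, 2]]),
               pmax(units[pairs[, 1]], units[pairs[, 2]]))
  connected <- key %in% conn_key
  positive <- key %in% pos_key

  n_pairs <- as.vector(table(bin))
  n_conn <- as.vector(tapply(connected, bin, sum, default = 0))
  n_pos <- as.vector(tapply(positive & connected, bin, sum, default = 0))
  tab <- data.frame(bin = levels(bin), n_pairs = n_pairs, n_connected = n_conn,
                    p_connect = ifelse(n_pairs > 0, n_conn / n_pairs, NA),
                    n_positive = n_pos,
                    p_positive_given_connected =
                      ifelse(n_conn > 0, n_pos / n_conn, NA))
  occ <- which(n_pairs > 0)
  trend <- if (length(occ) >= 2)
    trend_test(n_conn[occ], n_pairs[occ], scores = occ)
  else list(statistic = NA_real_, p.value = NA_real_, estimate = NA_real_)
  list(table = tab, trend = trend)
}
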