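#' Specification of a randomized reference (null) model ensemble
#'
#' Four nested models, each preserving strictly more of the original network:
#' `erdos_renyi` (node count, edge count, weight multiset), `degree_preserving`
#' (plus every node's in/out degree), `pair_preserving` (plus the multiset of
#' unordered-pair states: null / unidirectional / bidirectional) and
#' `signed_pair_preserving` (plus the signed pair states, e.g. +->, -->,
#' +<->+, +<->-, -<->-). Signs and weights are reassigned at random in the
#' first three models; the signed model keeps them attached to their pair
#' state category.
#'
#' @param model One of `"erdos_renyi"`, `"degree_preserving"`,
#'   `"pair_preserving"`, `"signed_pair_preserving"`.
#' @param preserve_distance If `TRUE`, randomization is additionally
#'   restricted to preserve the discretized distribution of pairwise
#'   distances (requires node positions).
#' @param n_distance_bins Number of equal-count distance bins (default 10).
#' @param ensemble Ensemble size (default 200).
#' @param seed Integer master seed; replicate i is a deterministic function
#'   of (seed, i).
#' @return A list of class `surrogate_spec`.
#' @export
surrogate_spec <- function(model = c("signed_pair_preserving", "pair_preserving",
                                     "degree_preserving", "erdos_renyi"),
                           preserve_distance = FALSE, n_distance_bins = 10,
                           ensemble = 200, seed = 1) {
  model <- match.arg(model)
  stopifnot(ensemble >= 1)
  structure(list(model = model, preserve_distance = preserve_distance,
                 n_distance_bins = n_distance_bins,
                 ensemble = as.integer(ensemble), seed = seed),
            class = "surrogate_spec")
}

# Discretized distance bin per unordered pair (equal-count bins).
distance_bins <- function(net, n_bins) {
  dm <- unit_distances(net)
  v <- dm[upper.tri(dm)]
  br <- unique(stats::quantile(v, probs = seq(0, 1, length.out = n_bins + 1),
                               na.rm = TRUE))
  B <- matrix(NA_integer_, nrow(dm), ncol(dm), dimnames = dimnames(dm))
  B[] <- as.integer(cut(dm, br, include.lowest = TRUE))
  B
}

# Directed double-edge swaps within one category of edges.
# edges: 2-column integer matrix (src, tgt).  occ: V x V logical matrix of
# occupied unordered pairs (TRUE blocks placement).  undirected: swap treats
# edges as unordered pairs.  bins: optional pair-bin matrix; a swap must keep
# each edge in its distance bin.  Returns the updated edges + occ.
swap_edges <- function(edges, occ, undirected = FALSE, bins = NULL,
                       n_accept_per_edge = 10, label = "edges") {
  ne <- nrow(edges)
  if (ne < 2) return(list(edges = edges, occ = occ, accepted = 0L))
  target <- n_accept_per_edge * ne
  max_attempts <- 100 * target
  accepted <- 0L; attempts <- 0L
  batch <- 512L
  prop1 <- prop2 <- integer(0); flip <- logical(0); bi <- batch
  while (accepted < target && attempts < max_attempts) {
    attempts <- attempts + 1L
    bi <- bi + 1L
    if (bi > batch) {
      prop1 <- sample.int(ne, batch, replace = TRUE)
      prop2 <- sample.int(ne, batch, replace = TRUE)
      flip <- stats::runif(batch) < 0.5
      bi <- 1L
    }
    if (prop1[bi] == prop2[bi]) next
    ij <- c(prop1[bi], prop2[bi])
    a <- edges[ij[1], 1]; b <- edges[ij[1], 2]
    c_ <- edges[ij[2], 1]; d <- edges[ij[2], 2]
    if (undirected && flip[bi]) { tmp <- c_; c_ <- d; d <- tmp }
    # propose (a,b),(c,d) -> (a,d),(c,b)
    # require 4 distinct endpoints: degenerate proposals are either
    # self-pairs or no-op identities
    if (a == d || c_ == b || a == c_ || b == d) next
    if (occ[a, d] || occ[c_, b]) next
    if (!is.null(bins) &&
        (bins[a, d] != bins[a, b] || bins[c_, b] != bins[c_, d])) next
    occ[a, b] <- occ[b, a] <- FALSE
    occ[c_, d] <- occ[d, c_] <- FALSE
    occ[a, d] <- occ[d, a] <- TRUE
    occ[c_, b] <- occ[b, c_] <- TRUE
    edges[ij[1], ] <- c(a, d)
    edges[ij[2], ] <- c(c_, b)
    accepted <- accepted + 1L
  }
  # A category where no swap is ever valid is simply frozen: its constraints
  # admit (essentially) only the original placement.
  list(edges = edges, occ = occ, accepted = accepted)
}

#' Generate one randomized surrogate network
#'
#' @param net A `functional_network` with at least 2 nodes.
#' @param spec A [surrogate_spec()].
#' @param replicate Replicate index; combined with `spec$seed` it fully
#'   determines the draw.
#' @return A `functional_network` with the properties of `spec$model`
#'   preserved; detection attributes (lag, duration, significance) are not
#'   carried into surrogates.
#' @export
make_surrogate <- function(net, spec = surrogate_spec(), replicate = 1) {
  stopifnot(inherits(net, "functional_network"))
  V <- nrow(net$nodes)
  if (V < 2) stop_ccgnet("make_surrogate: need at least 2 nodes")
  e <- net$edges
  if (nrow(e) == 0) return(functional_network(net$nodes))
  units <- net$nodes$unit
  src <- match(e$source, units); tgt <- match(e$target, units)
  bins <- if (spec$preserve_distance) {
    B <- distance_bins(net, spec$n_distance_bins)
    dimnames(B) <- NULL
    B
  } else NULL

  with_seed(child_seed(spec$seed, paste0("surrogate", replicate)), {
    new_edges <- switch(spec$model,
      erdos_renyi = surrogate_er(V, src, tgt, e, bins),
      degree_preserving = surrogate_swap_all(V, src, tgt, e, bins),
      pair_preserving = surrogate_pairs(V, src, tgt, e, bins, signed = FALSE),
      signed_pair_preserving = surrogate_pairs(V, src, tgt, e, bins, signed = TRUE))
    new_edges$source <- units[new_edges$src]
    new_edges$target <- units[new_edges$tgt]
    functional_network(net$nodes,
                       new_edges[, c("source", "target", "sign", "weight")])
  })
}

# Erdos-Renyi placement: E distinct ordered pairs (within distance bins when
# required), then the original (sign, weight) labels in random order.
surrogate_er <- function(V, src, tgt, e, bins) {
  E <- length(src)
  if (is.null(bins)) {
    slot <- sample(V * (V - 1), E)
    s <- (slot - 1L) %/% (V - 1L) + 1L
    off <- (slot - 1L) %% (V - 1L) + 1L
    t <- ifelse(off >= s, off + 1L, off)
  } else {
    pair_bin <- bins[cbind(pmin(src, tgt), pmax(src, tgt))]
    s <- integer(0); t <- integer(0)
    all_pairs <- which(upper.tri(matrix(0, V, V)), arr.ind = TRUE)
    ap_bin <- bins[all_pairs]
    for (b in unique(pair_bin)) {
      k <- sum(pair_bin == b)
      cand <- which(ap_bin == b)
      # ordered slots: each unordered pair offers two directions
      slots <- sample(2L * length(cand), k)
      ci <- cand[(slots - 1L) %/% 2L + 1L]
      fwd <- slots %% 2L == 1L
      s <- c(s, ifelse(fwd, all_pairs[ci, 1], all_pairs[ci, 2]))
      t <- c(t, ifelse(fwd, all_pairs[ci, 2], all_pairs[ci, 1]))
    }
  }
  lab <- sample(E)
  data.frame(src = s, tgt = t, sign = e$sign[lab], weight = e$weight[lab])
}

# Degree-preserving: double swaps over the full directed edge set; labels
# reassigned randomly.
surrogate_swap_all <- function(V, src, tgt, e, bins) {
  edges <- cbind(src, tgt)
  occ <- matrix(FALSE, V, V)
  # occupancy must be per directed edge here, pairs may be bidirectional
  occ_dir <- matrix(FALSE, V, V)
  occ_dir[edges] <- TRUE
  ne <- nrow(edges)
  target <- 10L * ne
  max_attempts <- 100L * target
  accepted <- 0L; attempts <- 0L
  while (accepted < target && attempts < max_attempts && ne >= 2) {
    attempts <- attempts + 1L
    ij <- sample.int(ne, 2)
    if (ij[1] == ij[2]) next
    a <- edges[ij[1], 1]; b <- edges[ij[1], 2]
    c_ <- edges[ij[2], 1]; d <- edges[ij[2], 2]
    if (a == d || c_ == b || a == c_ || b == d) next
    if (occ_dir[a, d] || occ_dir[c_, b]) next
    if (!is.null(bins) &&
        (bins[a, d] != bins[a, b] || bins[c_, b] != bins[c_, d])) next
    occ_dir[a, b] <- FALSE; occ_dir[c_, d] <- FALSE
    occ_dir[a, d] <- TRUE; occ_dir[c_, b] <- TRUE
    edges[ij[1], ] <- c(a, d)
    edges[ij[2], ] <- c(c_, b)
    accepted <- accepted + 1L
  }
  lab <- sample(nrow(edges))
  data.frame(src = edges[, 1], tgt = edges[, 2],
             sign = e$sign[lab], weight = e$weight[lab])
}

# Pair-state categories of the network: unidirectional directed edges and
# bidirectional unordered pairs, optionally split by sign pattern.
pair_categories <- function(src, tgt, e) {
  key <- paste(pmin(src, tgt), pmax(src, tgt))
  dup <- key %in% key[duplicated(key)]
  uni <- which(!dup)
  bi_keys <- unique(key[dup])
  bi <- lapply(bi_keys, function(k) which(key == k))
  list(uni = uni, bi = bi)
}

surrogate_pairs <- function(V, src, tgt, e, bins, signed) {
  cats <- pair_categories(src, tgt, e)
  occ <- matrix(FALSE, V, V)
  occ[cbind(pmin(src, tgt), pmax(src, tgt))] <- TRUE
  occ[cbind(pmax(src, tgt), pmin(src, tgt))] <- TRUE

  out <- NULL
  if (!signed) {
    # unidirectional edges: one directed category
    if (length(cats$uni) > 0) {
      sw <- swap_edges(cbind(src[cats$uni], tgt[cats$uni]), occ,
                       undirected = FALSE, bins = bins, label = "unidirectional")
      occ <- sw$occ
      out <- rbind(out, data.frame(src = sw$edges[, 1], tgt = sw$edges[, 2],
                                   sign = NA, weight = NA))
    }
    if (length(cats$bi) > 0) {
      bp <- t(vapply(cats$bi, function(ix) c(min(src[ix[1]], tgt[ix[1]]),
                                             max(src[ix[1]], tgt[ix[1]])),
                     integer(2)))
      sw <- swap_edges(bp, occ, undirected = TRUE, bins = bins,
                       label = "bidirectional")
      occ <- sw$occ
      out <- rbind(out,
                   data.frame(src = c(sw$edges[, 1], sw$edges[, 2]),
                              tgt = c(sw$edges[, 2], sw$edges[, 1]),
                              sign = NA, weight = NA))
    }
    lab <- sample(nrow(out))
    out$sign <- e$sign[lab]; out$weight <- e$weight[lab]
    return(out)
  }

  # signed: categories by signed pair state, labels travel with the category
  uni_sign <- e$sign[cats$uni]
  for (sgn in c(1L, -1L)) {
    ix <- cats$uni[uni_sign == sgn]
    if (length(ix) == 0) next
    sw <- swap_edges(cbind(src[ix], tgt[ix]), occ, undirected = FALSE,
                     bins = bins, label = paste0("uni sign ", sgn))
    occ <- sw$occ
    w <- sample(abs(e$weight[ix]))
    out <- rbind(out, data.frame(src = sw$edges[, 1], tgt = sw$edges[, 2],
                                 sign = sgn, weight = w))
  }
  if (length(cats$bi) > 0) {
    bi_state <- vapply(cats$bi, function(ix) {
      s <- sort(e$sign[ix])
      if (all(s == 1)) "pp" else if (all(s == -1)) "nn" else "pn"
    }, character(1))
    for (st in c("pp", "nn", "pn")) {
      sel <- which(bi_state == st)
      if (length(sel) == 0) next
      if (st == "pn") {
        # orient by the positive edge so the mixed state keeps its structure
        ep <- t(vapply(cats$bi[sel], function(ix) {
          pos <- ix[e$sign[ix] == 1]
          c(src[pos], tgt[pos])
        }, integer(2)))
        wts <- t(vapply(cats$bi[sel], function(ix) {
          c(abs(e$weight[ix[e$sign[ix] == 1]]), abs(e$weight[ix[e$sign[ix] == -1]]))
        }, numeric(2)))
        sw <- swap_edges(ep, occ, undirected = FALSE, bins = bins,
                         label = "mixed bidirectional")
        occ <- sw$occ
        perm <- sample(nrow(wts))
        out <- rbind(out,
          data.frame(src = c(sw$edges[, 1], sw$edges[, 2]),
                     tgt = c(sw$edges[, 2], sw$edges[, 1]),
                     sign = rep(c(1L, -1L), each = nrow(ep)),
                     weight = c(wts[perm, 1], wts[perm, 2])))
      } else {
        bp <- t(vapply(cats$bi[sel], function(ix) c(min(src[ix[1]], tgt[ix[1]]),
                                                    max(src[ix[1]], tgt[ix[1]])),
                       integer(2)))
        wts <- t(vapply(cats$bi[sel], function(ix) abs(e$weight[ix]), numeric(2)))
        sw <- swap_edges(bp, occ, undirected = TRUE, bins = bins,
                         label = paste0("bidirectional ", st))
        occ <- sw$occ
        perm <- sample(nrow(wts))
        sgn <- if (st == "pp") 1L else -1L
        flip <- stats::runif(nrow(bp)) < 0.5
        w1 <- ifelse(flip, wts[perm, 2], wts[perm, 1])
        w2 <- ifelse(flip, wts[perm, 1], wts[perm, 2])
        out <- rbind(out,
          data.frame(src = c(sw$edges[, 1], sw$edges[, 2]),
                     tgt = c(sw$edges[, 2], sw$edges[, 1]),
                     sign = sgn, weight = c(w1, w2)))
      }
    }
  }
  out
}

#' Generate a seeded ensemble of surrogate networks
#'
#' @inheritParams make_surrogate
#' @return A list of `spec$ensemble` independent surrogate
#'   `functional_network`s; replicate i depends only on (`spec$seed`, i).
#' @export
surrogate_ensemble <- function(net, spec = surrogate_spec()) {
  lapply(seq_len(spec$ensemble), function(i) make_surrogate(net, spec, i))
}
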