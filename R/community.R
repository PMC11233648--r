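#' Parameters for signed modularity and module detection
#'
#' @param gamma_pos,gamma_neg Resolution parameters for the positive and
#'   negative parts of the modularity (both default 1; larger `gamma_pos`
#'   favours smaller modules).
#' @param weighted If `TRUE`, positive/negative degrees and edge masses use
#'   absolute connection strengths instead of counts.
#' @param min_size Minimum module size; smaller modules are marked
#'   unassigned after optimization (default 4).
#' @return A list of class `modularity_params`.
#' @export
modularity_params <- function(gamma_pos = 1, gamma_neg = 1, weighted = FALSE,
                              min_size = 4L) {
  stopifnot(gamma_pos > 0, gamma_neg > 0, min_size >= 1)
  structure(list(gamma_pos = gamma_pos, gamma_neg = gamma_neg,
                 weighted = weighted, min_size = as.integer(min_size)),
            class = "modularity_params")
}

# Signed modularity matrix B with B_ij = A_ij - (g+ p+_ij - g- p-_ij), where
# A = A+ - A- and p+-_ij = k_out_i^{+-} k_in_j^{+-} / m^{+-}; the scale
# 1/(m+ + m-) turns sum(B[within modules]) into Q.  The sum runs over all
# ordered pairs including i = j (A_ii = 0; the diagonal null term is
# partition-independent).
modularity_matrix <- function(net, params) {
  deg <- signed_degrees(net, weighted = params$weighted)
  if (deg$m_pos + deg$m_neg == 0)
    stop_ccgnet("signed_modularity: network has no edges, Q undefined")
  if (params$weighted) {
    A <- adjacency_matrix(net, "signed")
  } else {
    A <- adjacency_matrix(net, "sign")
  }
  Ppos <- if (deg$m_pos > 0) outer(deg$out_pos, deg$in_pos) / deg$m_pos else 0 * A
  Pneg <- if (deg$m_neg > 0) outer(deg$out_neg, deg$in_neg) / deg$m_neg else 0 * A
  list(B = A - (params$gamma_pos * Ppos - params$gamma_neg * Pneg),
       scale = 1 / (deg$m_pos + deg$m_neg))
}

#' Signed modularity of a partition
#'
#' `Q = 1/(m+ + m-) * sum_ij [A_ij - (gamma+ p+_ij - gamma- p-_ij)]
#' delta(sigma_i, sigma_j)` with `A = A+ - A-` and degree-based null terms
#' `p+-_ij = k_out_i^{+-} k_in_j^{+-} / m^{+-}`. In weighted mode, counts are
#' replaced by absolute strength sums throughout.
#'
#' @param net A `functional_network` with at least one edge.
#' @param assignment Module label per node (in node-table order, or a named
#'   vector over unit ids); no `NA`s.
#' @param params A [modularity_params()].
#' @return The modularity value Q.
#' @export
signed_modularity <- function(net, assignment, params = modularity_params()) {
  units <- net$nodes$unit
  if (!is.null(names(assignment))) assignment <- assignment[units]
  if (length(assignment) != length(units) || anyNA(assignment))
    stop_ccgnet("signed_modularity: every node needs a module label")
  mm <- modularity_matrix(net, params)
  same <- outer(assignment, assignment, "==")
  mm$scale * sum(mm$B[same])
}

#' Signed-modularity Louvain community detection
#'
#' Greedy node-move sweeps followed by aggregation phases, optimizing the
#' signed modularity of [signed_modularity()]: positive connections are
#' pulled inside modules, negative connections pushed between them. Node
#' visiting order is randomized from `seed`, so the optimum found is
#' stochastic but reproducible. Modules smaller than `params$min_size` are
#' marked unassigned (`NA`) in the returned membership; `Q` refers to the
#' full partition before the size filter.
#'
#' @param net A `functional_network` with at least one edge.
#' @param params A [modularity_params()].
#' @param seed Integer seed for the node visiting order.
#' @param max_iter Cap on move sweeps per phase (default 100).
#' @return An object of class `module_partition`: list with `membership`
#'   (named over units; `NA` for nodes in dropped small modules),
#'   `membership_full` (before the size filter, ids contiguous by decreasing
#'   module size), `Q`, `params`, `seed`, `converged`.
#' @export
louvain_signed <- function(net, params = modularity_params(), seed = 1,
                           max_iter = 100L) {
  stopifnot(inherits(net, "functional_network"))
  if (nrow(net$edges) == 0) stop_ccgnet("louvain_signed: network has no edges")
  mm <- modularity_matrix(net, params)
  B0 <- mm$B
  n0 <- nrow(B0)

  with_seed(seed, {
    # `groups` maps original nodes -> current super-node
    groups <- seq_len(n0)
    B <- B0
    converged <- TRUE
    repeat {
      n <- nrow(B)
      comm <- seq_len(n)
      improved_phase <- FALSE
      iter <- 0L
      repeat {
        iter <- iter + 1L
        moved <- FALSE
        for (v in sample.int(n)) {
          cur <- comm[v]
          # gain of joining community c: sum over members j of B[v,j] + B[j,v]
          link <- B[v, ] + B[, v]
          gain <- tapply(link, comm, sum)
          gain[as.character(cur)] <- gain[as.character(cur)] - 2 * B[v, v]
          # staying contributes gain[cur] (v excluded); moving to c adds gain[c]
          best <- names(gain)[which.max(gain)]
          if (gain[[best]] > gain[[as.character(cur)]] + 1e-12) {
            comm[v] <- as.integer(best)
            moved <- TRUE
            improved_phase <- TRUE
          }
        }
        if (!moved) break
        if (iter >= max_iter) { converged <- FALSE; break }
      }
      if (!improved_phase) break
      # aggregate communities into super-nodes
      ids <- sort(unique(comm))
      comm <- match(comm, ids)
      groups <- comm[groups]
      k <- max(comm)
      M <- matrix(0, nrow(B), k)
      M[cbind(seq_len(nrow(B)), comm)] <- 1
      B <- t(M) %*% B %*% M
      if (k == nrow(B0) || k == 1) break
    }

    # contiguous ids by decreasing size
    sizes <- table(groups)
    ord <- order(-as.integer(sizes), as.integer(names(sizes)))
    relabel <- stats::setNames(seq_along(ord), names(sizes)[ord])
    full <- as.integer(relabel[as.character(groups)])
    names(full) <- net$nodes$unit
    Q <- mm$scale * sum(B0[outer(full, full, "==")])
    keep <- table(full)
    membership <- full
    membership[keep[as.character(full)] < params$min_size] <- NA_integer_
    structure(list(membership = membership, membership_full = full,
                   Q = Q, params = params, seed = seed, converged = converged),
              class = "module_partition")
  })
}

#' @export
print.module_partition <- function(x, ...) {
  sizes <- table(x$membership_full)
  cat(sprintf("module_partition: %d nodes, %d modules (sizes %s), Q = %.4f\n",
              length(x$membership_full), length(sizes),
              paste(sort(as.integer(sizes), decreasing = TRUE), collapse = ", "),
              x$Q))
  n_un <- sum(is.na(x$membership))
  if (n_un > 0)
    cat(sprintf("  %d nodes unassigned (modules below size %d)\n",
                n_un, x$params$min_size))
  invisible(x)
}

#' Select resolution parameters by maximizing the modularity difference map
#'
#' At every (`gamma_pos`, `gamma_neg`) grid point, the empirical modularity
#' (best of `n_runs` seeded Louvain runs) is compared with the mean
#' modularity of surrogate networks (one run each); the grid point
#' maximizing the difference — where the network deviates most from the null
#' — is returned together with the full map.
#'
#' @param net A `functional_network`.
#' @param gamma_pos_grid,gamma_neg_grid Numeric grids (defaults: 13
#'   log-spaced points in \[0.5, 2\] and a narrow band around 1).
#' @param spec A [surrogate_spec()] for the reference ensemble per grid point
#'   (default signed-pair-preserving, ensemble 20).
#' @param n_runs Louvain restarts for the empirical network per grid point
#'   (default 200; smaller values trade optimization quality for speed).
#' @param params Base [modularity_params()] (its resolutions are overridden
#'   by the grid).
#' @param seed Integer master seed.
#' @return A list with `best` (gamma_pos, gamma_neg, difference), `map`
#'   (data frame over the grid: Q_emp, Q_null, difference) and `flagged`
#'   (`TRUE` when the map is constant and the smallest grid point was
#'   returned by convention).
#' @export
resolution_sweep <- function(net, gamma_pos_grid = exp(seq(log(0.5), log(2),
                                                           length.out = 13)),
                             gamma_neg_grid = c(0.9, 1, 1.1),
                             spec = surrogate_spec(ensemble = 20),
                             n_runs = 200, params = modularity_params(),
                             seed = 1) {
  if (length(gamma_pos_grid) == 0 || length(gamma_neg_grid) == 0)
    stop_ccgnet("resolution_sweep: empty grid")
  surr <- surrogate_ensemble(net, spec)
  rows <- NULL
  for (gp in gamma_pos_grid) for (gn in gamma_neg_grid) {
    pr <- modularity_params(gp, gn, params$weighted, params$min_size)
    q_emp <- max(vapply(seq_len(n_runs), function(r)
      louvain_signed(net, pr, seed = child_seed(seed, paste0("emp", gp, gn, r)))$Q,
      numeric(1)))
    q_null <- mean(vapply(seq_along(surr), function(r)
      louvain_signed(surr[[r]], pr,
                     seed = child_seed(seed, paste0("null", gp, gn, r)))$Q,
      numeric(1)))
    rows <- rbind(rows, data.frame(gamma_pos = gp, gamma_neg = gn,
                                   Q_emp = q_emp, Q_null = q_null,
                                   difference = q_emp - q_null))
  }
  flagged <- (max(rows$difference) - min(rows$difference)) < 1e-12
  best <- if (flagged) rows[1, ] else rows[which.max(rows$difference), ]
  list(best = best[, c("gamma_pos", "gamma_neg", "difference")],
       map = rows, flagged = flagged)
}

#' Modularity Z-score against a surrogate ensemble
#'
#' `Z_Q = (Q - mean(q)) / sd(q)` where `q` are modularities of surrogate
#' networks obtained by the same optimization protocol.
#'
#' @param net A `functional_network`.
#' @param params A [modularity_params()].
#' @param ensemble List of surrogate networks (>= 2).
#' @param n_runs Louvain restarts for the empirical network (default 200;
#'   surrogates use a single run each).
#' @param seed Integer seed.
#' @return A list with `Q`, `q` (ensemble values), `z` (`NA` and `flagged =
#'   TRUE` when the ensemble variance is zero).
#' @export
modularity_zscore <- function(net, params = modularity_params(), ensemble,
                              n_runs = 200, seed = 1) {
  if (length(ensemble) < 2) stop_ccgnet("modularity_zscore: ensemble size must be >= 2")
  Q <- max(vapply(seq_len(n_runs), function(r)
    louvain_signed(net, params, seed = child_seed(seed, paste0("emp", r)))$Q,
    numeric(1)))
  q <- vapply(seq_along(ensemble), function(r)
    louvain_signed(ensemble[[r]], params,
                   seed = child_seed(seed, paste0("sur", r)))$Q, numeric(1))
  s <- sqrt(mean(q^2) - mean(q)^2)
  if (s == 0) return(list(Q = Q, q = q, z = NA_real_, flagged = TRUE))
  list(Q = Q, q = q, z = (Q - mean(q)) / s, flagged = FALSE)
}

#' Consensus partition over repeated stochastic runs
#'
#' Voting over module appearances: starting with all nodes unassigned, the
#' module (node set) appearing most often across runs is assigned (its
#' still-unassigned nodes become one consensus module), votes are recounted
#' over the remaining unassigned nodes, and the procedure iterates until all
#' nodes are assigned. Ties are broken by larger module size, then by
#' lexicographic node-set order.
#'
#' @param runs List of `module_partition`s (or membership vectors) over the
#'   same node set.
#' @return A named membership vector (consensus module ids, contiguous).
#' @export
consensus_partition <- function(runs) {
  if (length(runs) == 0) stop_ccgnet("consensus_partition: empty run list")
  mem <- lapply(runs, function(r) if (inherits(r, "module_partition"))
    r$membership_full else r)
  nodes <- names(mem[[1]])
  if (is.null(nodes)) stop_ccgnet("consensus_partition: memberships must be named")
  for (m in mem) if (!identical(sort(names(m)), sort(nodes)))
    stop_ccgnet("consensus_partition: runs cover mismatched node sets")
  # tally distinct modules (node sets) across runs
  sets <- list(); votes <- integer(0)
  for (m in mem) {
    for (lab in unique(m[!is.na(m)])) {
      key <- paste(sort(names(m)[!is.na(m) & m == lab]), collapse = "|")
      hit <- match(key, names(votes))
      if (is.na(hit)) { votes[key] <- 1L; sets[[key]] <- strsplit(key, "|", fixed = TRUE)[[1]] }
      else votes[key] <- votes[key] + 1L
    }
  }
  unassigned <- nodes
  out <- stats::setNames(rep(NA_integer_, length(nodes)), nodes)
  next_id <- 1L
  while (length(unassigned) > 0) {
    # votes restricted to modules with at least one unassigned node
    live <- vapply(sets, function(s) any(s %in% unassigned), logical(1))
    if (!any(live)) {
      # nodes never seen in any module become singletons
      for (nd in unassigned) { out[nd] <- next_id; next_id <- next_id + 1L }
      break
    }
    cand <- which(live)
    v <- votes[cand]
    sz <- vapply(sets[cand], length, integer(1))
    keyord <- names(votes)[cand]
    ord <- order(-v, -sz, keyord)
    pick <- cand[ord[1]]
    members <- intersect(sets[[pick]], unassigned)
    out[members] <- next_id
    next_id <- next_id + 1L
    unassigned <- setdiff(unassigned, members)
  }
  out
}

#' Module-id inheritance across resolutions, with two-opt node ordering
#'
#' For comparing partitions across a resolution sweep: modules of the
#' highest (finest) resolution get unique ids; each module at a coarser
#' resolution inherits the id of its maximum-overlap submodule from the
#' previous (finer) resolution (overlap ties broken by the larger submodule
#' id). Nodes are then ordered within each area by a seeded two-opt search
#' minimizing the summed Hamming distance between the module-id sequences of
#' nodes within a 10-node adjacency window.
#'
#' @param partitions List of membership vectors (or `module_partition`s)
#'   ordered from highest (finest) resolution to lowest.
#' @param areas Optional named area vector; ordering is computed within each
#'   area (default: one area).
#' @param window Adjacency window for the ordering objective (default 10).
#' @param seed Seed for the two-opt search.
#' @param max_sweeps Two-opt improvement sweeps cap (default 50).
#' @return A list with `ids` (nodes x resolutions matrix of inherited module
#'   ids) and `order` (character vector of node ids).
#' @export
multires_id_assignment <- function(partitions, areas = NULL, window = 10L,
                                   seed = 1, max_sweeps = 50L) {
  if (length(partitions) == 0) stop_ccgnet("multires_id_assignment: no partitions")
  mem <- lapply(partitions, function(r) if (inherits(r, "module_partition"))
    r$membership_full else r)
  nodes <- names(mem[[1]])
  ids <- matrix(NA_integer_, length(nodes), length(mem),
                dimnames = list(nodes, NULL))
  # finest resolution: unique ids
  ids[, 1] <- match(mem[[1]][nodes], unique(mem[[1]][nodes]))
  if (length(mem) > 1) {
    for (r in 2:length(mem)) {
      prev <- ids[, r - 1]
      cur <- mem[[r]][nodes]
      for (lab in unique(cur)) {
        members <- which(cur == lab)
        ov <- table(prev[members])
        best <- as.integer(names(ov)[ov == max(ov)])
        ids[members, r] <- max(best)  # tie-break: larger submodule id
      }
    }
  }
  areas <- areas %||% stats::setNames(rep("all", length(nodes)), nodes)
  ord <- character(0)
  with_seed(seed, {
    for (a in unique(areas[nodes])) {
      sub <- nodes[areas[nodes] == a]
      if (length(sub) <= 2) { ord <- c(ord, sub); next }
      H <- matrix(0, length(sub), length(sub))
      for (u in seq_along(sub)) for (v in seq_along(sub))
        H[u, v] <- sum(ids[sub[u], ] != ids[sub[v], ])
      cost <- function(p) {
        tot <- 0
        for (d in 1:min(window - 1L, length(p) - 1L))
          tot <- tot + sum(H[cbind(p[seq_len(length(p) - d)],
                                   p[seq_len(length(p) - d) + d])])
        tot
      }
      p <- sample(length(sub))
      cur <- cost(p)
      for (sweep in seq_len(max_sweeps)) {
        improved <- FALSE
        for (i in seq_len(length(p) - 1)) for (j in seq(i + 1, length(p))) {
          q <- p; q[i:j] <- rev(q[i:j])
          cq <- cost(q)
          if (cq < cur - 1e-9) { p <- q; cur <- cq; improved <- TRUE }
        }
        if (!improved) break
      }
      ord <- c(ord, sub[p])
    }
  })
  list(ids = ids, order = ord)
}
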