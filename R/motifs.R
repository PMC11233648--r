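# Signed two- and three-node motif catalog, census, intensities and Z-scores.
#
# Three-node digraphs are encoded over the fixed arc order
# (1->2, 2->1, 1->3, 3->1, 2->3, 3->2): a 6-bit pattern code for the unsigned
# structure and a base-3 code (0 absent, 1 positive, 2 negative per arc) for
# the signed structure.  Canonical forms minimize (pattern code, sign code)
# over the 6 node permutations.  Unsigned class ids 1..13 order the weakly
# connected classes by (edge count, connected pairs, mutual pairs, canonical
# code), which places the feedforward loop at id 6 and the fully reciprocal
# triangle at id 13.

.motif_cache <- new.env(parent = emptyenv())

.triad_arcs <- rbind(c(1, 2), c(2, 1), c(1, 3), c(3, 1), c(2, 3), c(3, 2))
.triad_perms <- rbind(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                      c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))

# arc index permutation tables: row r gives, for each arc slot m, the slot it
# maps to under permutation r.
triad_arc_perm <- function() {
  arc_index <- matrix(0L, 3, 3)
  for (m in 1:6) arc_index[.triad_arcs[m, 1], .triad_arcs[m, 2]] <- m
  t(apply(.triad_perms, 1, function(p)
    vapply(1:6, function(m)
      arc_index[p[.triad_arcs[m, 1]], p[.triad_arcs[m, 2]]], integer(1))))
}

triad_tables <- function() {
  if (!is.null(.motif_cache$tables)) return(.motif_cache$tables)
  ap <- triad_arc_perm()
  pow2 <- 2^(0:5); pow3 <- 3^(0:5)

  code_bits <- t(vapply(0:63, function(code) as.integer(intToBits(code))[1:6],
                        integer(6)))
  # permuting arcs of a signed trit vector
  perm_scode <- function(trits, r) sum(trits[ap[r, ]] * pow3)
  perm_code <- function(bits, r) sum(bits[ap[r, ]] * pow2)

  conn <- vapply(0:63, function(code) {
    b <- code_bits[code + 1, ]
    sum((b[1] | b[2]), (b[3] | b[4]), (b[5] | b[6])) >= 2
  }, logical(1))

  canon_code <- vapply(0:63, function(code) {
    min(vapply(1:6, function(r) perm_code(code_bits[code + 1, ], r), numeric(1)))
  }, numeric(1))

  cls_codes <- sort(unique(canon_code[conn]))
  info <- t(vapply(cls_codes, function(code) {
    b <- code_bits[code + 1, ]
    c(code = code, n_edges = sum(b),
      n_pairs = sum((b[1] | b[2]), (b[3] | b[4]), (b[5] | b[6])),
      n_mutual = sum(b[1] & b[2], b[3] & b[4], b[5] & b[6]))
  }, numeric(4)))
  o <- order(info[, "n_edges"], info[, "n_pairs"], info[, "n_mutual"], info[, "code"])
  info <- info[o, , drop = FALSE]
  unsigned_id_of_canon <- integer(64)
  unsigned_id_of_canon[info[, "code"] + 1] <- seq_len(nrow(info))
  unsigned_lookup <- ifelse(conn, unsigned_id_of_canon[canon_code + 1], NA_integer_)

  # contains-FFL flag per unsigned class: some permutation exposes arcs
  # 1->2, 2->3, 1->3 (bits 1, 5, 3 -> code mask 1 + 16 + 4 = 21)
  has_ffl <- vapply(info[, "code"], function(code) {
    b <- code_bits[code + 1, ]
    any(vapply(1:6, function(r) {
      pb <- integer(6); pb[ap[r, ]] <- b
      all(pb[c(1, 5, 3)] == 1)
    }, logical(1)))
  }, logical(1))

  # signed classes: enumerate all consistent sign codes of connected patterns
  scode_of <- function(trits) sum(trits * pow3)
  signed_canon <- new.env(parent = emptyenv())
  signed_rows <- list()
  for (ci in seq_len(nrow(info))) {
    code <- info[ci, "code"]
    b <- code_bits[code + 1, ]
    arcs_on <- which(b == 1)
    n_e <- length(arcs_on)
    for (assign in 0:(2^n_e - 1)) {
      trits <- integer(6)
      trits[arcs_on] <- 1L + as.integer(intToBits(assign))[seq_len(n_e)]
      # canonicalize over permutations: minimize (pattern code, sign code)
      best <- NULL
      for (r in 1:6) {
        pb <- integer(6); pb[ap[r, ]] <- b
        pt <- integer(6); pt[ap[r, ]] <- trits
        key <- c(sum(pb * pow2), scode_of(pt))
        if (is.null(best) || key[1] < best[1] ||
            (key[1] == best[1] && key[2] < best[2])) best <- key
      }
      kname <- as.character(best[2])
      if (is.null(signed_canon[[kname]])) {
        canon_trits <- integer(6)
        # recover canonical trit vector from canonical scode
        s <- best[2]
        for (m in 1:6) { canon_trits[m] <- s %% 3; s <- s %/% 3 }
        sgn_str <- paste(c("", "+", "-")[canon_trits[canon_trits > 0] + 1],
                         collapse = "")
        uid <- unsigned_id_of_canon[best[1] + 1]
        label <- if (all(canon_trits[canon_trits > 0] == 1)) paste0("p", uid)
                 else if (all(canon_trits[canon_trits > 0] == 2)) paste0("n", uid)
                 else paste0(uid, ":", sgn_str)
        # all-positive FFL contained: some permutation has arcs (1,5,3)
        # present and positive
        pffl <- any(vapply(1:6, function(r) {
          pt <- integer(6); pt[ap[r, ]] <- canon_trits
          all(pt[c(1, 5, 3)] == 1)
        }, logical(1)))
        signed_canon[[kname]] <- label
        signed_rows[[length(signed_rows) + 1]] <- data.frame(
          label = label, unsigned_id = uid, scode = best[2],
          n_edges = n_e, pfflb = pffl)
      }
    }
  }
  signed_df <- do.call(rbind, signed_rows)
  signed_df <- signed_df[order(signed_df$unsigned_id, signed_df$scode), ]
  rownames(signed_df) <- NULL

  # full signed lookup: canonical label per raw (valid, connected) scode
  signed_lookup <- rep(NA_character_, 3^6)
  for (code in 0:63) {
    if (!conn[code + 1]) next
    b <- code_bits[code + 1, ]
    arcs_on <- which(b == 1)
    n_e <- length(arcs_on)
    for (assign in 0:(2^n_e - 1)) {
      trits <- integer(6)
      trits[arcs_on] <- 1L + as.integer(intToBits(assign))[seq_len(n_e)]
      best <- NULL
      for (r in 1:6) {
        pb <- integer(6); pb[ap[r, ]] <- b
        pt <- integer(6); pt[ap[r, ]] <- trits
        key <- c(sum(pb * pow2), scode_of(pt))
        if (is.null(best) || key[1] < best[1] ||
            (key[1] == best[1] && key[2] < best[2])) best <- key
      }
      signed_lookup[scode_of(trits) + 1] <- signed_canon[[as.character(best[2])]]
    }
  }

  unsigned_df <- data.frame(id = seq_len(nrow(info)), code = info[, "code"],
                            n_edges = info[, "n_edges"],
                            n_pairs = info[, "n_pairs"],
                            n_mutual = info[, "n_mutual"],
                            contains_ffl = has_ffl)
  .motif_cache$tables <- list(unsigned = unsigned_df, signed = signed_df,
                              unsigned_lookup = unsigned_lookup,
                              signed_lookup = signed_lookup,
                              connected = conn)
  .motif_cache$tables
}

#' Catalog of connected two- or three-node motif classes
#'
#' Exhaustively enumerates all labeled digraphs without self-loops on 2 or 3
#' nodes, restricts to weakly connected ones and groups them by isomorphism
#' (respecting edge signs when `signed = TRUE`). Three-node unsigned classes
#' carry the conventional ids 1..13 (feedforward loop = 6, fully reciprocal
#' triangle = 13); signed classes are labeled `p<k>` (all positive), `n<k>`
#' (all negative) or `<k>:<sign string>` over the canonical representative's
#' arcs.
#'
#' @param n_nodes 2 or 3.
#' @param signed If `TRUE`, classes distinguish edge-sign patterns.
#' @return A data frame, one row per class. Three-node rows carry `n_edges`,
#'   `n_mutual` and `contains_ffl` (unsigned) or `pfflb` (signed: contains an
#'   all-positive feedforward loop).
#' @examples
#' nrow(motif_catalog(3))              # 13
#' nrow(motif_catalog(2, signed = TRUE))  # 5
#' @export
motif_catalog <- function(n_nodes = 3, signed = FALSE) {
  if (!n_nodes %in% c(2, 3)) stop_ccgnet("motif_catalog: n_nodes must be 2 or 3")
  if (n_nodes == 2) {
    if (!signed) {
      return(data.frame(label = c("uni", "bi"), n_edges = c(1L, 2L),
                        bidirectional = c(FALSE, TRUE)))
    }
    return(data.frame(label = c("uni_pos", "uni_neg", "bi_pos_pos",
                                "bi_pos_neg", "bi_neg_neg"),
                      n_edges = c(1L, 1L, 2L, 2L, 2L),
                      bidirectional = c(FALSE, FALSE, TRUE, TRUE, TRUE)))
  }
  tabs <- triad_tables()
  if (signed) tabs$signed else tabs$unsigned
}

#' Classify a 3-node sub-network into its motif classes
#'
#' @param edges Data frame with columns `source`, `target` and (optionally)
#'   `sign`, describing the induced subgraph on exactly 3 named nodes.
#' @param nodes Optional character vector of the 3 node names (needed when
#'   some node is isolated in `edges`).
#' @return A list with `unsigned_id` (1..13) and `signed_label`, or an error
#'   for a disconnected triple.
#' @export
classify_triad <- function(edges, nodes = NULL) {
  edges <- as.data.frame(edges)
  nodes <- nodes %||% unique(c(edges$source, edges$target))
  if (length(nodes) != 3) stop_ccgnet("classify_triad: need exactly 3 nodes")
  if (is.null(edges$sign)) edges$sign <- 1L
  tabs <- triad_tables()
  i <- match(edges$source, nodes); j <- match(edges$target, nodes)
  if (anyNA(i) || anyNA(j)) stop_ccgnet("classify_triad: edge endpoints not in nodes")
  arc_index <- matrix(0L, 3, 3)
  for (m in 1:6) arc_index[.triad_arcs[m, 1], .triad_arcs[m, 2]] <- m
  trits <- integer(6)
  trits[arc_index[cbind(i, j)]] <- ifelse(edges$sign == 1, 1L, 2L)
  code <- sum((trits > 0) * 2^(0:5))
  if (!tabs$connected[code + 1])
    stop_ccgnet("classify_triad: triple is not weakly connected (not a motif)")
  scode <- sum(trits * 3^(0:5))
  list(unsigned_id = tabs$unsigned_lookup[code + 1],
       signed_label = tabs$signed_lookup[scode + 1])
}

# Vectorized census over all weakly connected triples.  Returns per-triple
# assignments (internal work-horse for the census, Z-scores and pFFLb sets).
triad_instances <- function(net) {
  tabs <- triad_tables()
  units <- net$nodes$unit
  V <- length(units)
  if (V < 3 || nrow(net$edges) == 0) {
    return(data.frame(i = integer(0), j = integer(0), k = integer(0),
                      unsigned_id = integer(0), signed_label = character(0),
                      intensity = numeric(0)))
  }
  Sg <- adjacency_matrix(net, "sign")
  W <- abs(adjacency_matrix(net, "signed"))
  tri <- utils::combn(V, 3)
  i <- tri[1, ]; j <- tri[2, ]; k <- tri[3, ]
  ends <- list(cbind(i, j), cbind(j, i), cbind(i, k),
               cbind(k, i), cbind(j, k), cbind(k, j))
  trits <- vapply(ends, function(ix) {
    s <- Sg[ix]
    ifelse(s == 0, 0L, ifelse(s > 0, 1L, 2L))
  }, integer(length(i)))
  if (length(i) == 1) trits <- matrix(trits, nrow = 1)
  code <- matrix(as.numeric(trits > 0), ncol = 6) %*% 2^(0:5)
  scode <- trits %*% 3^(0:5)
  keep <- tabs$connected[code + 1]
  if (!any(keep)) {
    return(data.frame(i = integer(0), j = integer(0), k = integer(0),
                      unsigned_id = integer(0), signed_label = character(0),
                      intensity = numeric(0)))
  }
  logw <- vapply(ends, function(ix) {
    w <- W[ix]
    ifelse(w > 0, log(w), 0)
  }, numeric(length(i)))
  if (length(i) == 1) logw <- matrix(logw, nrow = 1)
  n_e <- rowSums(trits > 0)
  intensity <- exp(rowSums(logw) / n_e)
  data.frame(i = units[i[keep]], j = units[j[keep]], k = units[k[keep]],
             unsigned_id = tabs$unsigned_lookup[code[keep] + 1],
             signed_label = tabs$signed_lookup[scode[keep] + 1],
             intensity = intensity[keep])
}

#' Signed motif census: counts and intensities per class
#'
#' Iterates over all weakly connected node triples; the intensity of a
#' subgraph is the geometric mean of the absolute strengths of its edges,
#' and a class's intensity is the sum over its subgraphs (with unit weights
#' it equals the count).
#'
#' @param net A `functional_network`.
#' @param instances If `TRUE`, also return the per-triple instance table.
#' @return A data frame with one row per signed class present (columns
#'   `signed_label`, `unsigned_id`, `count`, `intensity`), with the instance
#'   table as attribute `"instances"` when requested.
#' @export
motif_intensity_census <- function(net, instances = FALSE) {
  inst <- triad_instances(net)
  if (nrow(inst) == 0) {
    out <- data.frame(signed_label = character(0), unsigned_id = integer(0),
                      count = integer(0), intensity = numeric(0))
  } else {
    agg <- stats::aggregate(inst$intensity, by = list(signed_label = inst$signed_label),
                            FUN = sum)
    cnt <- table(inst$signed_label)
    uid <- tapply(inst$unsigned_id, inst$signed_label, function(x) x[1])
    out <- data.frame(signed_label = agg$signed_label,
                      unsigned_id = as.integer(uid[agg$signed_label]),
                      count = as.integer(cnt[agg$signed_label]),
                      intensity = agg$x)
    out <- out[order(out$unsigned_id, out$signed_label), ]
    rownames(out) <- NULL
  }
  if (instances) attr(out, "instances") <- inst
  out
}

#' Motif intensity Z-scores against a surrogate ensemble
#'
#' `Z_M = (I_M - mean(i_M)) / sd(i_M)` per signed class, where `i_M` are the
#' class intensities in the surrogate replicates. Classes whose ensemble
#' intensity does not vary are flagged (`NA` Z) rather than scored, except
#' when the constant ensemble equals the empirical intensity (Z = 0).
#'
#' @param net A `functional_network`.
#' @param ensemble A list of surrogate networks (e.g. from
#'   [surrogate_ensemble()]); at least 2.
#' @return A data frame per signed class: `signed_label`, `unsigned_id`,
#'   `count`, `intensity`, `ensemble_mean`, `ensemble_sd`, `z`, `pfflb`.
#' @export
motif_zscores <- function(net, ensemble) {
  if (length(ensemble) < 2) stop_ccgnet("motif_zscores: ensemble size must be >= 2")
  emp <- motif_intensity_census(net)
  cat_signed <- motif_catalog(3, signed = TRUE)
  labels <- unique(c(emp$signed_label,
                     unlist(lapply(ensemble, function(s) motif_intensity_census(s)$signed_label))))
  # intensity per label per replicate (0 when absent)
  ens <- matrix(0, length(ensemble), length(labels),
                dimnames = list(NULL, labels))
  for (r in seq_along(ensemble)) {
    cs <- motif_intensity_census(ensemble[[r]])
    if (nrow(cs) > 0) ens[r, cs$signed_label] <- cs$intensity
  }
  I_emp <- stats::setNames(rep(0, length(labels)), labels)
  I_emp[emp$signed_label] <- emp$intensity
  cnt <- stats::setNames(rep(0L, length(labels)), labels)
  cnt[emp$signed_label] <- emp$count
  mu <- colMeans(ens)
  # population spread over the ensemble, per the Z definition
  sdv <- sqrt(colMeans(ens^2) - mu^2)
  z <- ifelse(sdv > 0, (I_emp - mu) / sdv, ifelse(I_emp == mu, 0, NA_real_))
  uid <- cat_signed$unsigned_id[match(labels, cat_signed$label)]
  out <- data.frame(signed_label = labels, unsigned_id = uid,
                    count = as.integer(cnt), intensity = unname(I_emp),
                    ensemble_mean = unname(mu), ensemble_sd = unname(sdv),
                    z = unname(z),
                    pfflb = cat_signed$pfflb[match(labels, cat_signed$label)])
  out <- out[order(out$unsigned_id, out$signed_label), ]
  rownames(out) <- NULL
  out
}

#' Mask outliers of motif Z-scores across analysis replicates
#'
#' When aggregating motif Z-scores across replicate sessions ("mice"), values
#' beyond `threshold` standard deviations of the replicate set (per class)
#' are masked.
#'
#' @param z_matrix Replicates x classes matrix of Z values.
#' @param threshold SD threshold (default 2).
#' @return A logical matrix, `TRUE` where the value is retained.
#' @export
mask_outliers <- function(z_matrix, threshold = 2) {
  apply(z_matrix, 2, function(v) {
    m <- mean(v, na.rm = TRUE); s <- stats::sd(v, na.rm = TRUE)
    if (!is.finite(s) || s == 0) return(!is.na(v))
    !is.na(v) & abs(v - m) <= threshold * s
  })
}

#' Relative counts of signed two-node motifs against an Erdos-Renyi ensemble
#'
#' Ratio of the empirical count of each signed pair state to its mean count
#' over the ensemble.
#'
#' @param net A `functional_network`.
#' @param ensemble List of surrogate networks (normally Erdos-Renyi).
#' @return Data frame with `class`, `count`, `ensemble_mean`, `ratio`
#'   (`Inf` flagged when the ensemble mean is 0 but the count positive).
#' @export
pair_relative_counts <- function(net, ensemble) {
  if (length(ensemble) < 1) stop_ccgnet("pair_relative_counts: empty ensemble")
  emp <- signed_pair_census(net)
  ens <- vapply(ensemble, signed_pair_census, numeric(5))
  mu <- rowMeans(ens)
  data.frame(class = names(emp), count = as.integer(emp),
             ensemble_mean = unname(mu),
             ratio = unname(ifelse(mu > 0, emp / mu,
                                   ifelse(emp > 0, Inf, NA_real_))),
             row.names = NULL)
}

#' Instance sets and regional composition of pFFLb motifs
#'
#' pFFLb classes are the signed three-node classes containing at least one
#' all-positive feedforward loop. For each class present in the network,
#' returns its node triples, the fraction of instances with at least one /
#' all three nodes in a designated area, and the sets of within-motif and
#' other connected unordered pairs (inputs for tuning-similarity and distance
#' comparisons).
#'
#' @param net A `functional_network` with area labels.
#' @param area The designated area label (default: the most common area).
#' @return A list keyed by signed class label, each with `triples` (data
#'   frame), `frac_any_area`, `frac_all_area`, `within_pairs` and
#'   `other_connected_pairs` (2-column matrices of unit ids).
#' @export
pfflb_sets <- function(net, area = NULL) {
  if (!"area" %in% names(net$nodes)) stop_ccgnet("pfflb_sets: nodes lack area labels")
  area <- area %||% names(sort(table(net$nodes$area), decreasing = TRUE))[1]
  cat_signed <- motif_catalog(3, signed = TRUE)
  pffl_labels <- cat_signed$label[cat_signed$pfflb]
  inst <- attr(motif_intensity_census(net, instances = TRUE), "instances")
  node_area <- stats::setNames(net$nodes$area, net$nodes$unit)
  e <- net$edges
  all_conn_pairs <- unique(paste(pmin(e$source, e$target), pmax(e$source, e$target)))
  out <- list()
  for (lab in intersect(pffl_labels, unique(inst$signed_label))) {
    sub <- inst[inst$signed_label == lab, , drop = FALSE]
    in_area <- cbind(node_area[sub$i] == area, node_area[sub$j] == area,
                     node_area[sub$k] == area)
    wp <- unique(do.call(rbind, lapply(seq_len(nrow(sub)), function(r) {
      tr <- c(sub$i[r], sub$j[r], sub$k[r])
      prs <- t(utils::combn(tr, 2))
      prs <- cbind(pmin(prs[, 1], prs[, 2]), pmax(prs[, 1], prs[, 2]))
      prs[paste(prs[, 1], prs[, 2]) %in% all_conn_pairs, , drop = FALSE]
    })))
    wkeys <- paste(wp[, 1], wp[, 2])
    other <- setdiff(all_conn_pairs, wkeys)
    om <- do.call(rbind, strsplit(other, " "))
    out[[lab]] <- list(
      triples = sub[, c("i", "j", "k")],
      frac_any_area = mean(rowSums(in_area) >= 1),
      frac_all_area = mean(rowSums(in_area) == 3),
      within_pairs = wp,
      other_connected_pairs = om %||% matrix(character(0), 0, 2))
  }
  out
}

#' Overlap of unique motif instances across conditions
#'
#' A unique motif is a signed class together with a specific unordered node
#' triple. For every non-empty subset of conditions, counts the unique motifs
#' present in exactly that subset of condition-wise instance sets.
#'
#' @param instance_sets Named list (one entry per condition) of instance data
#'   frames with columns `i`, `j`, `k`, `signed_label` (e.g. the `triples` of
#'   [pfflb_sets()] plus label, or `attr(motif_intensity_census(net, TRUE),
#'   "instances")`).
#' @param min_size Drop subsets with fewer motifs than this (default 0).
#' @return Data frame: `subset` (condition names joined by `+`), `count`.
#' @export
motif_overlap <- function(instance_sets, min_size = 0) {
  stopifnot(length(instance_sets) >= 1, !is.null(names(instance_sets)))
  keys <- lapply(instance_sets, function(df) {
    if (nrow(df) == 0) return(character(0))
    trip <- apply(cbind(df$i, df$j, df$k), 1, function(v) paste(sort(v), collapse = "|"))
    unique(paste(trip, df$signed_label %||% "", sep = ":"))
  })
  all_keys <- unique(unlist(keys))
  member <- vapply(keys, function(k) all_keys %in% k, logical(length(all_keys)))
  if (length(all_keys) == 1) member <- matrix(member, nrow = 1)
  pattern <- apply(member, 1, function(row)
    paste(names(instance_sets)[row], collapse = "+"))
  tab <- table(pattern)
  out <- data.frame(subset = names(tab), count = as.integer(tab))
  out <- out[out$count >= min_size & out$subset != "", , drop = FALSE]
  out[order(-out$count), , drop = FALSE]
}
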