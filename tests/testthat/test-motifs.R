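# Motif catalog, triad classification, census, intensities, Z-scores, overlap.

test_that("catalog enumeration matches the known class counts", {
  expect_identical(nrow(motif_catalog(2)), 2L)
  expect_identical(nrow(motif_catalog(2, signed = TRUE)), 5L)
  expect_identical(sum(motif_catalog(2, signed = TRUE)$bidirectional), 3L)

  u3 <- motif_catalog(3)
  expect_identical(nrow(u3), 13L)
  expect_identical(u3$id, 1:13)
  # feedforward-loop-containing classes and their mutual-pair grouping
  expect_identical(sum(u3$contains_ffl), 6L)
  expect_identical(sort(u3$n_mutual[u3$contains_ffl]), c(0, 1, 1, 1, 2, 3))
  expect_identical(u3$id[u3$contains_ffl], c(6L, 9L, 10L, 11L, 12L, 13L))
  # catalog is deterministic (cached canonical forms)
  expect_identical(motif_catalog(3, signed = TRUE), motif_catalog(3, signed = TRUE))
})

test_that("triad classification is isomorphism-invariant and flags pFFLb", {
  ffl <- data.frame(source = c("A", "B", "A"), target = c("B", "C", "C"),
                    sign = 1L)
  cl <- classify_triad(ffl)
  expect_identical(cl$unsigned_id, 6L)
  expect_identical(cl$signed_label, "p6")
  # every relabeling of the three nodes maps to the same ids
  for (perm in list(c("C", "A", "B"), c("B", "C", "A"), c("C", "B", "A"))) {
    relab <- ffl
    relab$source <- perm[match(ffl$source, c("A", "B", "C"))]
    relab$target <- perm[match(ffl$target, c("A", "B", "C"))]
    expect_identical(classify_triad(relab), cl)
  }
  # signed variant distinct from the all-positive one
  mixed <- ffl; mixed$sign <- c(1L, 1L, -1L)
  expect_identical(classify_triad(mixed)$unsigned_id, 6L)
  expect_false(classify_triad(mixed)$signed_label == "p6")

  expect_error(classify_triad(data.frame(source = "A", target = "B", sign = 1L),
                              nodes = c("A", "B", "C")), "not weakly connected")
})

test_that("intensities follow the geometric-mean definition", {
  u <- data.frame(unit = c("A", "B", "C"), area = "x")
  ffl <- functional_network(u, data.frame(
    source = c("A", "B", "A"), target = c("B", "C", "C"),
    sign = 1L, weight = c(1, 2, 4)))
  cs <- motif_intensity_census(ffl)
  expect_identical(nrow(cs), 1L)
  expect_identical(cs$signed_label, "p6")
  expect_equal(cs$intensity, (1 * 2 * 4)^(1 / 3))   # = 2
  expect_identical(cs$count, 1L)

  # unit weights: intensity equals count for every class
  net <- mk_random_net(12, 40, seed = 91, weights = FALSE)
  cs2 <- motif_intensity_census(net)
  expect_equal(cs2$intensity, as.numeric(cs2$count))
})

test_that("census equals the naive O(V^3) oracle on a random 30-node network", {
  net <- mk_random_net(30, 140, frac_pos = 0.6, seed = 92)
  cs <- motif_intensity_census(net)
  oracle <- oracle_census(net)
  # classes are compared through their (count, intensity) content
  mine <- cs[order(cs$count, cs$intensity), c("count", "intensity")]
  theirs <- do.call(rbind, unname(oracle))
  theirs <- theirs[order(theirs[, 1], theirs[, 2]), , drop = FALSE]
  expect_identical(nrow(mine), nrow(theirs))
  expect_equal(unname(as.matrix(mine)), unname(theirs), tolerance = 1e-9)

  # census conservation: total count = number of weakly connected triples
  units <- net$nodes$unit
  A <- adjacency_matrix(net, "binary")
  P <- (A + t(A)) > 0
  n_conn <- 0L
  tri <- utils::combn(length(units), 3)
  for (c_ in seq_len(ncol(tri))) {
    i <- tri[1, c_]; j <- tri[2, c_]; k <- tri[3, c_]
    if (P[i, j] + P[i, k] + P[j, k] >= 2) n_conn <- n_conn + 1L
  }
  expect_identical(sum(cs$count), n_conn)
})

test_that("degenerate ensembles yield zero or flagged Z-scores", {
  net <- mk_random_net(10, 30, seed = 93)
  ens <- replicate(10, net, simplify = FALSE)
  mz <- motif_zscores(net, ens)
  expect_true(all(mz$z == 0 | is.na(mz$z)))
  expect_error(motif_zscores(net, ens[1]), ">= 2")
})

test_that("reciprocal-rich networks show two-node over-representation vs ER", {
  set.seed(94)
  units <- data.frame(unit = sprintf("u%02d", 1:20), area = "x")
  # 15 reciprocal pairs: far above the ER expectation at this density
  all_pairs <- t(utils::combn(20, 2))
  pairs <- all_pairs[sample(nrow(all_pairs), 15), , drop = FALSE]
  e <- NULL
  for (i in 1:15) {
    a <- units$unit[pairs[i, 1]]; b <- units$unit[pairs[i, 2]]
    e <- rbind(e, data.frame(source = c(a, b), target = c(b, a),
                             sign = 1L, weight = 0.5))
  }
  net <- functional_network(units, e)
  ens <- surrogate_ensemble(net, surrogate_spec("erdos_renyi", ensemble = 100,
                                                seed = 17))
  rc <- pair_relative_counts(net, ens)
  expect_gt(rc$ratio[rc$class == "bi_pos_pos"], 1)
  # closed-form ER expectation: E[bi pairs] = n(n-1)/2 * p^2 with p = density
  p_dens <- nrow(net$edges) / (20 * 19)
  expect_equal(rc$ensemble_mean[rc$class == "bi_pos_pos"],
               (20 * 19 / 2) * p_dens^2, tolerance = 0.25)

  none <- mk_random_net(10, 12, seed = 95)   # sparse: likely no reciprocals
  if (signed_pair_census(none)[["bi_pos_pos"]] == 0) {
    rc2 <- pair_relative_counts(none,
      surrogate_ensemble(none, surrogate_spec("erdos_renyi", ensemble = 20,
                                              seed = 18)))
    expect_identical(rc2$count[rc2$class == "bi_pos_pos"], 0L)
  }
})

test_that("planted all-positive feedforward loops surface as top p6 Z-scores", {
  hits <- 0L
  for (s in 1:10) {
    net <- mk_random_net(30, 40, frac_pos = 0.7, seed = 960 + s)
    # plant 10 disjoint all-positive FFLs over fresh node triples
    set.seed(970 + s)
    nodes <- sample(net$nodes$unit, 30)
    add <- NULL
    for (i in 1:10) {
      tr <- nodes[(3 * i - 2):(3 * i)]
      add <- rbind(add, data.frame(source = tr[c(1, 2, 1)],
                                   target = tr[c(2, 3, 3)],
                                   sign = 1L, weight = 0.8))
    }
    key <- paste(add$source, add$target)
    e <- net$edges[!(paste(net$edges$source, net$edges$target) %in% key),
                   c("source", "target", "sign", "weight")]
    planted <- functional_network(net$nodes, rbind(e, add))
    ens <- surrogate_ensemble(planted,
      surrogate_spec("signed_pair_preserving", ensemble = 50, seed = 980 + s))
    mz <- motif_zscores(planted, ens)
    mz <- mz[!is.na(mz$z), ]
    top <- mz$signed_label[order(-mz$z)][1:3]
    if ("p6" %in% top) hits <- hits + 1L
  }
  expect_gte(hits, 6L)   # majority of seeds
})

test_that("pFFLb instance sets and regional composition are tallied correctly", {
  units <- data.frame(unit = sprintf("u%02d", 1:9),
                      area = rep(c("V1", "LM", "AL"), each = 3))
  # one all-positive FFL entirely in V1, one spanning areas
  e <- data.frame(source = c("u01", "u02", "u01",  "u04", "u07", "u04"),
                  target = c("u02", "u03", "u03",  "u07", "u02", "u02"),
                  sign = 1L, weight = 0.5)
  net <- functional_network(units, e)
  ps <- pfflb_sets(net, area = "V1")
  expect_true("p6" %in% names(ps))
  p6 <- ps[["p6"]]
  expect_identical(nrow(p6$triples), 2L)
  expect_equal(p6$frac_all_area, 0.5)
  expect_equal(p6$frac_any_area, 1)       # both instances touch V1

  neg <- net
  neg$edges$sign <- -1L
  expect_identical(length(pfflb_sets(neg, area = "V1")), 0L)
})

test_that("motif overlap counts exact subset membership", {
  mk <- function(trips) data.frame(i = trips[, 1], j = trips[, 2],
                                   k = trips[, 3], signed_label = "p6")
  s1 <- mk(rbind(c("a", "b", "c"), c("a", "b", "d"), c("b", "c", "d")))
  s2 <- mk(rbind(c("a", "b", "d"), c("b", "c", "d"), c("c", "d", "e")))
  ov <- motif_overlap(list(A = s1, B = s2))
  get <- function(sub) ov$count[ov$subset == sub]
  expect_identical(get("A+B"), 2L)
  expect_identical(get("A"), 1L)
  expect_identical(get("B"), 1L)

  ident <- motif_overlap(list(A = s1, B = s1))
  expect_identical(ident$subset, "A+B")
  expect_identical(ident$count, 3L)

  disj <- motif_overlap(list(A = s1, B = mk(rbind(c("x", "y", "z")))))
  expect_true(all(disj$subset %in% c("A", "B")))
})

test_that("outlier masking works per class across replicates", {
  z <- cbind(c(0.1, -0.2, 0.3, 0.05, -0.1, 0.2, 10),
             c(1, 1.2, 0.8, 1.1, 0.9, 1.0, 1.05))
  m <- mask_outliers(z, threshold = 2)
  expect_false(m[7, 1])
  expect_true(all(m[1:6, 1]))
  expect_true(all(m[, 2]))
})
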