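#' Contingency table between a module partition and area labels
#'
#' Cross-tabulates `n_ij = |M_i intersect A_j|` for module i and area j.
#' Nodes with `NA` module labels (unassigned, e.g. dropped by the minimum
#' module-size filter) are excluded by default, or included as singleton
#' modules for sensitivity analysis.
#'
#' @param modules Vector of module labels per node (`NA` = unassigned).
#' @param areas Vector of area labels per node, same length.
#' @param include_unassigned If `TRUE`, each unassigned node enters the table
#'   as its own singleton module. Default `FALSE`.
#' @return A matrix of counts with modules as rows and areas as columns.
#' @export
contingency_table <- function(modules, areas, include_unassigned = FALSE) {
  stopifnot(length(modules) == length(areas))
  if (anyNA(areas)) stop_ccgnet("contingency_table: every node needs an area label")
  modules <- as.vector(modules)
  if (include_unassigned && anyNA(modules)) {
    idx <- which(is.na(modules))
    modules[idx] <- paste0(".singleton", seq_along(idx))
  }
  keep <- !is.na(modules)
  if (!any(keep)) stop_ccgnet("contingency_table: no assigned nodes")
  tab <- table(module = modules[keep], area = areas[keep])
  unclass(tab)
}

#' Per-module coverage and purity, with module-size-weighted averages
#'
#' Coverage of module `M_i` is `max_j |M_i ∩ A_j| / |A_j|`: how completely the
#' module covers its best-matching area. Purity is `max_j |M_i ∩ A_j| / |M_i|`:
#' how much of the module comes from a single area. The network-level weighted
#' averages (WA) weight modules by size:
#' `WA coverage = sum_i |M_i| * cov_i / sum_i |M_i|` and
#' `WA purity = sum_i max_j n_ij / sum_i |M_i|`.
#'
#' Area sizes `|A_j|` are computed over the nodes in the table, i.e. after any
#' exclusion of unassigned nodes.
#'
#' @inheritParams contingency_table
#' @return A list with `per_module` (data frame: module, size, coverage,
#'   purity), `wa_coverage` and `wa_purity`.
#' @export
coverage_purity <- function(modules, areas, include_unassigned = FALSE) {
  tab <- contingency_table(modules, areas, include_unassigned)
  a <- rowSums(tab)             # module sizes
  b <- colSums(tab)             # area sizes
  if (any(a == 0)) stop_ccgnet("coverage_purity: empty module in table")
  cov_i <- apply(sweep(tab, 2, b, "/"), 1, max)
  max_n <- apply(tab, 1, max)
  pur_i <- max_n / a
  list(per_module = data.frame(module = rownames(tab), size = as.integer(a),
                               coverage = unname(cov_i), purity = unname(pur_i),
                               row.names = NULL),
       wa_coverage = sum(a * cov_i) / sum(a),
       wa_purity = sum(max_n) / sum(a))
}

#' Adjusted Rand index from a contingency table
#'
#' Pair-counting chance-corrected agreement between two partitions:
#' `ARI = (S_ij - S_a S_b / C(n,2)) / ((S_a + S_b)/2 - S_a S_b / C(n,2))`
#' where `S_ij = sum_ij C(n_ij, 2)`, `S_a = sum_i C(a_i, 2)`,
#' `S_b = sum_j C(b_j, 2)`. Equals 1 iff the partitions are identical up to
#' relabeling; values below -0.5 are possible only for unusual partition
#' shapes and are reported with an attribute `anomaly = TRUE`.
#'
#' @param table A contingency matrix of counts (e.g. from
#'   [contingency_table()]), or `NULL` if `modules`/`areas` are given.
#' @param modules,areas Optional label vectors used to build the table when
#'   `table` is `NULL`.
#' @return The ARI as a single number; `NA` with a warning when the
#'   chance-correction denominator is zero (both partitions degenerate).
#' @export
adjusted_rand_index <- function(table = NULL, modules = NULL, areas = NULL) {
  if (is.null(table)) table <- contingency_table(modules, areas)
  n <- sum(table)
  if (n < 2) stop_ccgnet("adjusted_rand_index: need at least 2 nodes")
  ch2 <- function(x) x * (x - 1) / 2
  S_ij <- sum(ch2(table))
  S_a <- sum(ch2(rowSums(table)))
  S_b <- sum(ch2(colSums(table)))
  expected <- S_a * S_b / ch2(n)
  denom <- (S_a + S_b) / 2 - expected
  if (denom == 0) {
    warning("adjusted_rand_index: degenerate partitions, ARI undefined")
    return(NA_real_)
  }
  ari <- (S_ij - expected) / denom
  if (ari < -0.5) attr(ari, "anomaly") <- TRUE
  ari
}
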