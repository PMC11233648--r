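#' Construct a signed, directed functional network
#'
#' The central container for detected functional connectivity: a set of nodes
#' (units) with area / position metadata and a set of signed, weighted,
#' directed edges carrying the detection attributes (lag, duration,
#' significance). At most one edge per ordered pair; no self-edges.
#'
#' @param nodes Data frame with at least a `unit` column (unique ids); optional
#'   `area`, `x`, `y`, `z`, `rate` columns.
#' @param edges Data frame with columns `source`, `target`, `sign` (+1 / -1)
#'   and `weight`; optional `lag`, `duration`, `significance`. May have zero
#'   rows.
#' @return An object of class `functional_network`: a list with `nodes` and
#'   `edges`.
#' @examples
#' nodes <- data.frame(unit = c("a", "b", "c"), area = c("V1", "V1", "LM"))
#' edges <- data.frame(source = "a", target = "b", sign = 1, weight = 0.5)
#' functional_network(nodes, edges)
#' @export
functional_network <- function(nodes, edges = NULL) {
  nodes <- as.data.frame(nodes)
  if (!"unit" %in% names(nodes)) stop_ccgnet("nodes must have a 'unit' column")
  nodes$unit <- as.character(nodes$unit)
  if (anyDuplicated(nodes$unit)) stop_ccgnet("duplicate unit ids in nodes")
  if (is.null(edges) || nrow(as.data.frame(edges)) == 0) {
    edges <- data.frame(source = character(0), target = character(0),
                        sign = integer(0), weight = numeric(0),
                        lag = integer(0), duration = integer(0),
                        significance = numeric(0))
  } else {
    edges <- as.data.frame(edges)
    req <- c("source", "target", "sign", "weight")
    if (!all(req %in% names(edges)))
      stop_ccgnet("edges must have columns source, target, sign, weight")
    edges$source <- as.character(edges$source)
    edges$target <- as.character(edges$target)
    for (col in c("lag", "duration", "significance"))
      if (!col %in% names(edges)) edges[[col]] <- NA
    edges <- edges[c("source", "target", "sign", "weight",
                     "lag", "duration", "significance")]
    if (!all(edges$sign %in% c(-1L, 1L))) stop_ccgnet("edge signs must be +1 or -1")
    if (any(edges$source == edges$target)) stop_ccgnet("self-edges are not allowed")
    if (!all(c(edges$source, edges$target) %in% nodes$unit))
      stop_ccgnet("edge endpoints must be listed in nodes")
    if (anyDuplicated(paste(edges$source, edges$target)))
      stop_ccgnet("at most one edge per ordered pair")
  }
  structure(list(nodes = nodes, edges = edges), class = "functional_network")
}

#' @export
print.functional_network <- function(x, ...) {
  V <- nrow(x$nodes); E <- nrow(x$edges)
  cat(sprintf("functional_network: %d nodes, %d directed signed edges\n", V, E))
  if (E > 0) {
    cat(sprintf("  positive: %d, negative: %d; density: %.4f\n",
                sum(x$edges$sign == 1), sum(x$edges$sign == -1),
                E / (V * (V - 1))))
  }
  if ("area" %in% names(x$nodes))
    cat("  areas:", paste(names(table(x$nodes$area)), table(x$nodes$area),
                          sep = ":", collapse = ", "), "\n")
  invisible(x)
}

#' Signed and unsigned adjacency matrices of a functional network
#'
#' @param net A `functional_network`.
#' @param what One of `"signed"` (signed weights), `"weight"` (absolute
#'   weights with sign applied), `"binary"` (0/1 presence),
#'   `"sign"` (+1/-1/0).
#' @return A dense V x V matrix with unit ids as dimnames; `A[i, j]` refers to
#'   the edge i -> j.
#' @export
adjacency_matrix <- function(net, what = c("signed", "binary", "sign")) {
  what <- match.arg(what)
  units <- net$nodes$unit
  A <- matrix(0, length(units), length(units), dimnames = list(units, units))
  if (nrow(net$edges) > 0) {
    idx <- cbind(match(net$edges$source, units), match(net$edges$target, units))
    A[idx] <- switch(what,
      signed = net$edges$sign * abs(net$edges$weight),
      binary = 1,
      sign = net$edges$sign)
  }
  A
}

#' Census of signed two-node (pair) states of a network
#'
#' Classifies every connected unordered node pair into one of the five signed
#' pair states: unidirectional positive (`uni_pos`), unidirectional negative
#' (`uni_neg`), bidirectional with both edges positive (`bi_pos_pos`), mixed
#' (`bi_pos_neg`) or both negative (`bi_neg_neg`).
#'
#' @param net A `functional_network`.
#' @return Named integer vector of the five counts.
#' @export
signed_pair_census <- function(net) {
  out <- c(uni_pos = 0L, uni_neg = 0L,
           bi_pos_pos = 0L, bi_pos_neg = 0L, bi_neg_neg = 0L)
  e <- net$edges
  if (nrow(e) == 0) return(out)
  key <- ifelse(e$source < e$target, paste(e$source, e$target),
                paste(e$target, e$source))
  for (k in unique(key)) {
    sub <- e[key == k, ]
    if (nrow(sub) == 1) {
      out[if (sub$sign == 1) "uni_pos" else "uni_neg"] <-
        out[if (sub$sign == 1) "uni_pos" else "uni_neg"] + 1L
    } else {
      s <- sort(sub$sign)
      cls <- if (all(s == 1)) "bi_pos_pos" else if (all(s == -1)) "bi_neg_neg" else "bi_pos_neg"
      out[cls] <- out[cls] + 1L
    }
  }
  out
}

# In/out degree vectors (counts or strengths), split by sign.  Used by the
# modularity null term and by the surrogate conservation checks.
signed_degrees <- function(net, weighted = FALSE) {
  units <- net$nodes$unit
  e <- net$edges
  val <- if (weighted) abs(e$weight) else rep(1, nrow(e))
  deg <- function(ids, mask) {
    v <- numeric(length(units)); names(v) <- units
    if (any(mask)) {
      s <- tapply(val[mask], ids[mask], sum)
      v[names(s)] <- s
    }
    v
  }
  pos <- e$sign == 1; neg <- e$sign == -1
  list(out_pos = deg(e$source, pos), in_pos = deg(e$target, pos),
       out_neg = deg(e$source, neg), in_neg = deg(e$target, neg),
       m_pos = sum(val[pos]), m_neg = sum(val[neg]))
}
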