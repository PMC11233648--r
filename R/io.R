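# Plain-text serialization of the pipeline's data objects.  All tables are
# tab-delimited with a single '# ccgnet <object> v1' header line.

write_ccgnet_table <- function(df, path, what) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# ccgnet %s v1", what), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
}

read_ccgnet_table <- function(path, what) {
  header <- readLines(path, n = 1)
  if (!startsWith(header, sprintf("# ccgnet %s", what)))
    stop_ccgnet("unexpected header in ", path, ": ", header)
  utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                    stringsAsFactors = FALSE)
}

#' Write / read a spike-train session as delimited text
#'
#' Three tables: `spikes.tsv` (trial, unit, bin — one row per spike),
#' `units.tsv` (unit, area, optional x/y/z, rate) and `trials.tsv` (trial,
#' stimulus, n_bins, bin_ms).
#'
#' @param data A `spike_train_set`.
#' @param dir Output directory (created if missing).
#' @return `write_spike_data` returns `dir` invisibly; `read_spike_data`
#'   returns the reconstructed `spike_train_set`.
#' @export
write_spike_data <- function(data, dir) {
  stopifnot(inherits(data, "spike_train_set"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  idx <- which(data$spikes == 1L, arr.ind = TRUE)
  spikes <- data.frame(trial = idx[, 1], unit = data$units$unit[idx[, 3]],
                       bin = idx[, 2])
  spikes <- spikes[order(spikes$trial, spikes$unit, spikes$bin), ]
  write_ccgnet_table(spikes, file.path(dir, "spikes.tsv"), "spikes")
  units <- data$units
  units$rate <- firing_rates(data)
  write_ccgnet_table(units, file.path(dir, "units.tsv"), "units")
  trials <- data.frame(trial = seq_len(data$M), stimulus = data$stimulus,
                       n_bins = data$N, bin_ms = data$bin_ms)
  write_ccgnet_table(trials, file.path(dir, "trials.tsv"), "trials")
  invisible(dir)
}

#' @rdname write_spike_data
#' @export
read_spike_data <- function(dir) {
  spikes <- read_ccgnet_table(file.path(dir, "spikes.tsv"), "spikes")
  units <- read_ccgnet_table(file.path(dir, "units.tsv"), "units")
  trials <- read_ccgnet_table(file.path(dir, "trials.tsv"), "trials")
  arr <- array(0L, dim = c(nrow(trials), trials$n_bins[1], nrow(units)))
  arr[cbind(spikes$trial, spikes$bin, match(spikes$unit, units$unit))] <- 1L
  units$rate <- NULL
  spike_train_set(arr, units, trials$stimulus, trials$bin_ms[1])
}

#' Write / read a functional network as delimited edge and node tables
#'
#' @param net A `functional_network`.
#' @param dir Output directory.
#' @param prefix Optional file-name prefix (e.g. the stimulus label).
#' @return `write_network` returns the paths invisibly; `read_network`
#'   returns the `functional_network`.
#' @export
write_network <- function(net, dir, prefix = "network") {
  stopifnot(inherits(net, "functional_network"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  nodes_path <- file.path(dir, paste0(prefix, "_nodes.tsv"))
  edges_path <- file.path(dir, paste0(prefix, "_edges.tsv"))
  write_ccgnet_table(net$nodes, nodes_path, "nodes")
  write_ccgnet_table(net$edges, edges_path, "edges")
  invisible(c(nodes = nodes_path, edges = edges_path))
}

#' @rdname write_network
#' @export
read_network <- function(dir, prefix = "network") {
  nodes <- read_ccgnet_table(file.path(dir, paste0(prefix, "_nodes.tsv")), "nodes")
  edges <- read_ccgnet_table(file.path(dir, paste0(prefix, "_edges.tsv")), "edges")
  functional_network(nodes, edges)
}

#' Write / read a ground-truth coupling table
#'
#' @param truth A `ground_truth`.
#' @param dir Output directory.
#' @return `read_couplings` returns the `ground_truth` (without modulation
#'   settings, which live in the run configuration).
#' @export
write_couplings <- function(truth, dir) {
  stopifnot(inherits(truth, "ground_truth"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_ccgnet_table(truth$couplings, file.path(dir, "couplings.tsv"), "couplings")
  write_ccgnet_table(truth$units, file.path(dir, "truth_units.tsv"), "units")
  invisible(dir)
}

#' @rdname write_couplings
#' @export
read_couplings <- function(dir) {
  couplings <- read_ccgnet_table(file.path(dir, "couplings.tsv"), "couplings")
  units <- read_ccgnet_table(file.path(dir, "truth_units.tsv"), "units")
  structure(list(units = units, couplings = couplings, modulation = NULL,
                 tau_max = 12L), class = "ground_truth")
}
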