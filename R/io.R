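## Connectivity-matrix input/output and a synthetic connectome generator.
## Two plain-text formats are supported: a header-free dense CSV (row i =
## outgoing weights of node i) and a 3-column weighted edge list with
## header `source,target,weight` and 0-based node ids. Real connectome
## files (e.g. from public connectome databases) are supplied by the user
## in either format; nothing is downloaded.

#' Read a connectivity matrix
#'
#' Reads a square weight matrix from a dense CSV or a weighted edge list,
#' auto-detecting the format from the first line when `format = "auto"`.
#' Edge lists are materialized to a dense matrix with absent pairs set
#' to 0; the node count is `max(id) + 1` unless `n_nodes` is given.
#'
#' @param path Path to the file.
#' @param format `"auto"` (default), `"dense_csv"` or `"edge_list"`.
#' @param label Optional label stored with the record (defaults to the
#'   file name).
#' @param node_kind `"region"` or `"neuron"`; metadata only.
#' @param n_nodes Optional node count for edge lists whose highest ids are
#'   unconnected.
#' @return Object of class `connectome_record`: list with `matrix`,
#'   `label`, `node_kind` and `is_binary` (`TRUE` when all entries are 0
#'   or 1).
#' @export
read_connectome <- function(path, format = c("auto", "dense_csv", "edge_list"),
                            label = NULL, node_kind = c("region", "neuron"),
                            n_nodes = NULL) {
  format <- match.arg(format)
  node_kind <- match.arg(node_kind)
  if (!file.exists(path))
    stop(sprintf("file not found: %s", path), call. = FALSE)
  first <- readLines(path, n = 1L, warn = FALSE)
  if (length(first) == 0 || !nzchar(trimws(first)))
    stop(sprintf("empty file: %s", path), call. = FALSE)
  if (format == "auto")
    format <- if (grepl("^\\s*source\\s*,\\s*target\\s*,\\s*weight\\s*$", first))
      "edge_list" else "dense_csv"
  W <- if (format == "edge_list")
    read_edge_list(path, n_nodes)
  else
    read_dense_csv(path)
  structure(list(matrix = W,
                 label = if (is.null(label)) basename(path) else label,
                 node_kind = node_kind,
                 is_binary = all(W %in% c(0, 1))),
            class = "connectome_record")
}

read_dense_csv <- function(path) {
  df <- utils::read.csv(path, header = FALSE, colClasses = "character",
                        strip.white = TRUE)
  M <- suppressWarnings(apply(as.matrix(df), c(1, 2), as.numeric))
  if (anyNA(M)) {
    bad <- which(is.na(M), arr.ind = TRUE)[1, ]
    stop(sprintf("non-numeric cell at row %d, column %d of %s",
                 bad[1], bad[2], path), call. = FALSE)
  }
  if (nrow(M) != ncol(M))
    stop(sprintf("dense matrix in %s is not square: %d rows x %d columns",
                 path, nrow(M), ncol(M)), call. = FALSE)
  dimnames(M) <- NULL
  M
}

read_edge_list <- function(path, n_nodes = NULL) {
  df <- utils::read.csv(path, header = TRUE, strip.white = TRUE)
  if (ncol(df) != 3)
    stop(sprintf("edge list %s must have exactly 3 columns (source,target,weight)",
                 path), call. = FALSE)
  names(df) <- c("source", "target", "weight")
  if (!is.numeric(df$source) || !is.numeric(df$target) || !is.numeric(df$weight))
    stop(sprintf("non-numeric cells in edge list %s", path), call. = FALSE)
  if (any(df$source < 0) || any(df$target < 0)) {
    bad <- which(df$source < 0 | df$target < 0)[1]
    stop(sprintf("negative node id at row %d of %s", bad, path), call. = FALSE)
  }
  if (any(df$source != floor(df$source)) || any(df$target != floor(df$target)))
    stop(sprintf("non-integer node ids in %s", path), call. = FALSE)
  N <- max(df$source, df$target) + 1
  if (!is.null(n_nodes)) {
    if (n_nodes < N)
      stop(sprintf("`n_nodes` = %d smaller than largest id + 1 = %d",
                   n_nodes, N), call. = FALSE)
    N <- n_nodes
  }
  W <- matrix(0, N, N)
  W[cbind(df$source + 1, df$target + 1)] <- df$weight
  W
}

#' Write a weight matrix as header-free dense CSV
#'
#' Row `i` of the file holds the outgoing weights of node `i`. The
#' round-trip through [read_connectome()] reproduces the values to full
#' printed precision.
#'
#' @inheritParams propagate
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_dense_csv <- function(W, path) {
  check_weights(W)
  utils::write.table(format(W, digits = 17, trim = TRUE, scientific = TRUE),
                     path, sep = ",", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Write a weight matrix as a weighted edge list
#'
#' Emits the nonzero entries as `source,target,weight` rows with 0-based
#' ids.
#'
#' @inheritParams write_dense_csv
#' @export
write_edge_list <- function(W, path) {
  check_weights(W)
  ij <- which(W != 0, arr.ind = TRUE)
  df <- data.frame(source = ij[, 1] - 1, target = ij[, 2] - 1,
                   weight = W[ij])
  df <- df[order(df$source, df$target), ]
  utils::write.csv(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Generate a synthetic connectome-like matrix
#'
#' Builds a weighted random network whose node strengths range from nearly
#' uniform (`hubness = 0`) to heavy-tailed with pronounced hubs (larger
#' `hubness`), at a chosen connection density. Each node receives a
#' log-normal propensity `u_i = exp(hubness * z_i)`, `z_i ~ N(0, 1)`;
#' off-diagonal connections exist independently with probability `density`
#' and carry weight `u_i * u_j * |e|` with half-normal noise `e`. The
#' result is a stand-in fixture for real connectome matrices, not a
#' biological model.
#'
#' @param n_nodes Number of nodes.
#' @param hubness Nonnegative tail-heaviness control; 0 gives near-uniform
#'   strengths.
#' @param density Probability that an off-diagonal connection exists, in
#'   `(0, 1]`.
#' @param binary If `TRUE`, return the 0/1 existence matrix instead of
#'   weights (for degree-based pipelines).
#' @param seed Optional integer seed.
#' @param label Label stored in the record.
#' @return A `connectome_record` (see [read_connectome()]).
#' @export
synth_connectome <- function(n_nodes, hubness = 1, density = 0.3,
                             binary = FALSE, seed = NULL,
                             label = "synthetic") {
  if (!is.numeric(n_nodes) || n_nodes < 2)
    stop("`n_nodes` must be an integer >= 2", call. = FALSE)
  if (!is.numeric(hubness) || hubness < 0)
    stop("`hubness` must be nonnegative", call. = FALSE)
  if (!is.numeric(density) || density <= 0 || density > 1)
    stop("`density` must lie in (0, 1]", call. = FALSE)
  if (!is.null(seed)) {
    old <- rng_state()
    on.exit(restore_rng(old), add = TRUE)
    set.seed(seed)
  }
  N <- as.integer(n_nodes)
  u <- exp(hubness * stats::rnorm(N))
  exists <- matrix(stats::runif(N * N) < density, N, N)
  diag(exists) <- FALSE
  W <- outer(u, u) * abs(matrix(stats::rnorm(N * N), N, N))
  W[!exists] <- 0
  if (binary) W <- (W > 0) * 1
  structure(list(matrix = W, label = label, node_kind = "region",
                 is_binary = binary),
            class = "connectome_record")
}

#' @export
print.connectome_record <- function(x, ...) {
  cat(sprintf("Connectome '%s': %d %s nodes, %s, density %.3f\n",
              x$label, nrow(x$matrix), x$node_kind,
              if (x$is_binary) "binary" else "weighted",
              mean(x$matrix[!diag(TRUE, nrow(x$matrix))] != 0)))
  invisible(x)
}
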