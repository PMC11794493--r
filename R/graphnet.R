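# Weighted graph metrics on WPLI matrices. The network is analyzed as the
# full weighted complete graph (no thresholding or binarization); distances
# use the reciprocal-weight rule (edge length 1/w; -log(w) available), and
# clustering uses the Onnela normalization by the network-wide maximum
# weight (Barrat variant available).

asWeightMatrix <- function(g) {
  W <- if (is(g, "ConnectivityMatrix")) g@W else as.matrix(g)
  if (nrow(W) != ncol(W)) stop("weight matrix must be square")
  if (max(abs(W - t(W))) > 1e-9) stop("weight matrix must be symmetric")
  if (any(W < 0)) stop("weights must be non-negative")
  diag(W) <- 0
  W
}

#' Node strength
#'
#' Sum of each node's edge weights; the network-level "connection strength"
#' is the mean over nodes.
#'
#' @param g a \code{\linkS4class{ConnectivityMatrix}} or symmetric
#'   non-negative matrix with zero diagonal.
#' @return named numeric vector of per-node strengths.
#' @export
nodeStrength <- function(g) {
  W <- asWeightMatrix(g)
  rowSums(W)
}

#' Onnela weighted clustering coefficient
#'
#' Per node i: \code{C_i = (1 / (k_i (k_i - 1))) * sum_{j,h} (w'_ij w'_ih
#' w'_jh)^(1/3)} with weights normalized by the network maximum (\code{w' =
#' w / max(W)}); nodes with fewer than 2 neighbors get 0. The Barrat variant
#' (weight-proportional triangle counting on the binarized triple count) is
#' available for comparison.
#'
#' @inheritParams nodeStrength
#' @param variant \code{"onnela"} (default) or \code{"barrat"}.
#' @return named numeric vector of per-node clustering coefficients in [0, 1].
#' @export
clusteringCoefficient <- function(g, variant = c("onnela", "barrat")) {
  variant <- match.arg(variant)
  W <- asWeightMatrix(g)
  n <- nrow(W)
  k <- rowSums(W > 0)
  out <- numeric(n)
  if (max(W) == 0) return(setNames(out, rownames(W)))
  if (variant == "onnela") {
    A <- (W / max(W))^(1 / 3)
    cyc <- diag(A %*% A %*% A)
    denom <- k * (k - 1)
    out <- ifelse(denom > 0, cyc / denom, 0)
  } else {
    B <- (W > 0) * 1
    s <- rowSums(W)
    for (i in seq_len(n)) {
      if (k[i] < 2) next
      tri <- 0
      nb <- which(W[i, ] > 0)
      for (j in nb) for (h in nb) if (h != j && W[j, h] > 0)
        tri <- tri + (W[i, j] + W[i, h]) / 2
      out[i] <- tri / (s[i] * (k[i] - 1))
    }
  }
  setNames(as.numeric(out), rownames(W))
}

#' Shortest-path distance matrix
#'
#' Converts weights to lengths (\code{1/w} by default, \code{-log(w)} as an
#' alternative; zero weight = no edge) and runs Dijkstra over the resulting
#' graph. Unreachable pairs get \code{Inf}; the diagonal is 0.
#'
#' @inheritParams nodeStrength
#' @param distance \code{"reciprocal"} (default) or \code{"neglog"}.
#' @return numeric distance matrix.
#' @export
graphDistances <- function(g, distance = c("reciprocal", "neglog")) {
  distance <- match.arg(distance)
  W <- asWeightMatrix(g)
  L <- W
  pos <- W > 0
  L[pos] <- if (distance == "reciprocal") 1 / W[pos] else -log(W[pos])
  L[!pos] <- 0
  gr <- igraph::graph_from_adjacency_matrix(L, mode = "undirected",
                                            weighted = TRUE, diag = FALSE)
  d <- igraph::distances(gr, algorithm = "dijkstra")
  dimnames(d) <- dimnames(W)
  d
}

#' Characteristic path length
#'
#' Mean shortest-path distance over ordered pairs i != j that are reachable;
#' the number of unreachable ordered pairs is reported alongside.
#'
#' @param d a distance matrix from \code{\link{graphDistances}}.
#' @return list with \code{L} (scalar) and \code{nUnreachable} (count of
#'   unreachable ordered pairs).
#' @export
characteristicPathLength <- function(d) {
  off <- d[row(d) != col(d)]
  finite <- is.finite(off)
  if (!any(finite)) stop("no reachable pair: characteristic path length undefined")
  list(L = mean(off[finite]), nUnreachable = sum(!finite))
}

#' Global efficiency
#'
#' \code{E = mean over ordered pairs i != j of 1/d_ij}, with \code{1/Inf = 0}
#' for unreachable pairs.
#'
#' @param d a distance matrix from \code{\link{graphDistances}}.
#' @return scalar efficiency.
#' @export
globalEfficiency <- function(d) {
  if (nrow(d) < 2L) stop("global efficiency undefined for fewer than 2 nodes")
  off <- d[row(d) != col(d)]
  inv <- ifelse(is.finite(off) & off > 0, 1 / off, 0)
  mean(inv)
}

#' Local efficiency
#'
#' Mean over nodes of the global efficiency of each node's neighborhood
#' subgraph (neighbors: \code{w_ij > threshold}); nodes with fewer than 2
#' neighbors contribute 0.
#'
#' @inheritParams nodeStrength
#' @param threshold weight above which an edge defines neighborhood
#'   membership (default 0).
#' @param distance distance rule passed to \code{\link{graphDistances}}.
#' @return scalar local efficiency.
#' @export
localEfficiency <- function(g, threshold = 0, distance = "reciprocal") {
  W <- asWeightMatrix(g)
  n <- nrow(W)
  eff <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(W[i, ] > threshold)
    if (length(nb) < 2L) next
    sub <- W[nb, nb, drop = FALSE]
    eff[i] <- globalEfficiency(graphDistances(sub, distance))
  }
  mean(eff)
}

#' Bundle all network metrics for one connectivity matrix
#'
#' Computes node strength, Onnela clustering, characteristic path length,
#' global and local efficiency, and records the conventions used together
#' with the matrix's band/condition/subject metadata.
#'
#' @param g a \code{\linkS4class{ConnectivityMatrix}} or weight matrix.
#' @param distance distance rule (\code{"reciprocal"} or \code{"neglog"}).
#' @param clusteringVariant \code{"onnela"} or \code{"barrat"}.
#' @return a \code{\linkS4class{NetworkMetrics}}.
#' @export
#' @examples
#' W <- matrix(0.5, 4, 4); diag(W) <- 0
#' networkSummary(W)
networkSummary <- function(g, distance = "reciprocal",
                           clusteringVariant = "onnela") {
  W <- asWeightMatrix(g)
  s <- nodeStrength(W)
  cc <- clusteringCoefficient(W, clusteringVariant)
  d <- graphDistances(W, distance)
  cpl <- characteristicPathLength(d)
  meta <- list(distance = distance, clustering = clusteringVariant,
               unreachable = "excluded from L, contribute 0 to efficiency")
  if (is(g, "ConnectivityMatrix"))
    meta <- c(meta, list(band = g@band$name, condition = g@condition,
                         subject = g@subject))
  new("NetworkMetrics",
      strength = s, meanStrength = mean(s),
      clustering = cc, meanClustering = mean(cc),
      charPathLength = cpl$L, nUnreachable = as.integer(cpl$nUnreachable),
      globalEfficiency = globalEfficiency(d),
      localEfficiency = localEfficiency(W, distance = distance),
      meta = meta)
}

#' Flatten network metrics to a one-row data.frame
#'
#' @param m a \code{\linkS4class{NetworkMetrics}}.
#' @return one-row data.frame of the scalar summaries plus metadata.
#' @export
metricsRow <- function(m) {
  data.frame(
    band = if (!is.null(m@meta$band)) m@meta$band else NA_character_,
    condition = if (length(m@meta$condition)) paste(m@meta$condition, collapse = "/") else NA_character_,
    subject = if (!is.null(m@meta$subject)) m@meta$subject else NA_character_,
    strength = m@meanStrength,
    clustering = m@meanClustering,
    char_path_length = m@charPathLength,
    global_efficiency = m@globalEfficiency,
    local_efficiency = m@localEfficiency,
    n_unreachable = m@nUnreachable,
    stringsAsFactors = FALSE
  )
}
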