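#' Layer graph of a multilayer brain network
#'
#' A layer is an undirected weighted graph over the n regions, stored as an
#' edge table with canonical keys i < j and strictly positive weights.
#'
#' @param n node count.
#' @param edges data frame with columns `i`, `j` (1-based node ids, i < j)
#'   and `w` (> 0).
#' @param modality `"structural"` or `"functional"`.
#' @return object of class `layer_graph`.
#' @export
layer_graph <- function(n, edges, modality) {
  stopifnot(n >= 0)
  edges <- as.data.frame(edges)
  if (nrow(edges)) {
    stopifnot(all(c("i", "j", "w") %in% names(edges)))
    if (any(edges$i == edges$j)) stop("self-loops are not allowed")
    swap <- edges$i > edges$j
    tmp <- edges$i[swap]; edges$i[swap] <- edges$j[swap]; edges$j[swap] <- tmp
    if (anyDuplicated(edges[c("i", "j")])) stop("duplicate edges")
    if (any(edges$w <= 0)) stop("edge weights must be > 0")
    if (any(edges$i < 1 | edges$j > n)) stop("node ids out of range")
    edges <- edges[order(edges$i, edges$j), , drop = FALSE]
    rownames(edges) <- NULL
  } else {
    edges <- data.frame(i = integer(), j = integer(), w = numeric())
  }
  structure(list(n = n, edges = edges, modality = modality),
            class = "layer_graph")
}

#' @export
print.layer_graph <- function(x, ...) {
  cat(sprintf("<layer_graph> %s, %d nodes, %d edges\n",
              x$modality, x$n, nrow(x$edges)))
  invisible(x)
}

#' Build the structural layer from a refined structural matrix
#'
#' Every strictly positive off-diagonal entry of the beta-mapped structural
#' matrix becomes an undirected edge with that weight; the structural layer
#' is therefore as sparse as the underlying tractography.
#'
#' @param bw_s refined structural [connectivity_matrix()].
#' @return a [layer_graph()].
#' @export
build_structural_layer <- function(bw_s) {
  w <- bw_s$weights
  idx <- which(upper.tri(w) & w > 0, arr.ind = TRUE)
  layer_graph(nrow(w),
              data.frame(i = idx[, 1], j = idx[, 2], w = w[idx]),
              "structural")
}

#' Average degree of a layer
#'
#' For an undirected layer, `avg_s = 2 |E| / n`: the mean number of incident
#' edges per node.  This sets the scale for functional-layer sparsification.
#'
#' @param layer a [layer_graph()].
#' @return numeric average degree (0 for an empty layer).
#' @export
structural_average_degree <- function(layer) {
  if (layer$n == 0) stop("layer has no nodes")
  2 * nrow(layer$edges) / layer$n
}

#' Build the functional layer, scale-guided by the structural layer
#'
#' The functional matrix is near-dense, so only the strongest connections are
#' kept: each node nominates its `k* = max(1, round(theta * avg_s))`
#' strongest incident entries (zeros never nominated; ties broken by
#' ascending node index), and an undirected edge is retained when either
#' endpoint nominated it.  With `theta = 0.5` the functional layer is about
#' half the network scale of the structural layer.
#'
#' @param bw_f refined functional [connectivity_matrix()].
#' @param avg_s structural average degree (see
#'   [structural_average_degree()]).
#' @param theta network-scale parameter > 0 (default 0.5).
#' @return a [layer_graph()].
#' @export
build_functional_layer <- function(bw_f, avg_s, theta = 0.5) {
  stopifnot(theta > 0, avg_s >= 0)
  w <- bw_f$weights
  n <- nrow(w)
  kstar <- max(1L, as.integer(floor(theta * avg_s + 0.5)))  # round half up
  keep <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    row <- w[i, ]
    row[i] <- 0
    pos <- which(row > 0)
    if (!length(pos)) next
    ord <- pos[order(-row[pos], pos)]  # strongest first, ties by index
    nom <- ord[seq_len(min(kstar, length(ord)))]
    keep[i, nom] <- TRUE
  }
  keep <- keep | t(keep)  # union of nominations
  idx <- which(upper.tri(keep) & keep, arr.ind = TRUE)
  layer_graph(n, data.frame(i = idx[, 1], j = idx[, 2], w = w[idx]),
              "functional")
}

#' Count a node's weak neighbours
#'
#' `|T_i|` is the number of neighbours of node i connected by an edge whose
#' weight does not exceed the mean edge weight of the layer (each undirected
#' edge counted once in the mean).  A node similar to only few neighbours --
#' all its links strong -- has a small `|T_i|`.
#'
#' @param layer a [layer_graph()].
#' @param i node id (1-based).
#' @return integer count (0 for an isolated node or an empty layer).
#' @export
weak_neighbor_count <- function(layer, i) {
  e <- layer$edges
  if (!nrow(e)) return(0L)
  mw <- mean(e$w)
  inc <- e$i == i | e$j == i
  sum(e$w[inc] <= mw)
}

#' Node informativeness of a layer
#'
#' `I_i = ln(e + |T_i|)`, where `|T_i|` is the weak-neighbour count: the more
#' neighbours a node is weakly tied to, the more informative stepping through
#' it is for the diffusion.  Always >= 1 (`ln e`).
#'
#' @param layer a [layer_graph()].
#' @return numeric vector of length n.
#' @export
informativeness <- function(layer) {
  e <- layer$edges
  tcount <- integer(layer$n)
  if (nrow(e)) {
    mw <- mean(e$w)
    weak <- e$w <= mw
    tcount <- tabulate(c(e$i[weak], e$j[weak]), nbins = layer$n)
  }
  log(exp(1) + tcount)
}

#' Assemble the two-layer brain network
#'
#' Couples the structural and functional layers through directed inter-layer
#' edges between corresponding nodes, weighted by node informativeness: the
#' transition into the structural layer at node i is weighted `I_i^s`, into
#' the functional layer `I_i^f`.  The informativeness vectors are stored
#' directly (they are all the diffusion consumes).
#'
#' @param structural structural [layer_graph()].
#' @param functional functional [layer_graph()].
#' @param theta network-scale parameter used to build the functional layer
#'   (recorded for provenance).
#' @return object of class `multilayer_network` with elements `structural`,
#'   `functional`, `info_s`, `info_f`, `theta`, `avg_s`, `n`.
#' @export
assemble_multilayer <- function(structural, functional, theta = 0.5) {
  if (structural$n != functional$n)
    stop("layer size mismatch: ", structural$n, " vs ", functional$n)
  structure(list(structural = structural, functional = functional,
                 info_s = informativeness(structural),
                 info_f = informativeness(functional),
                 theta = theta,
                 avg_s = structural_average_degree(structural),
                 n = structural$n),
            class = "multilayer_network")
}

#' @export
print.multilayer_network <- function(x, ...) {
  cat(sprintf(paste0("<multilayer_network> %d nodes; structural %d edges, ",
                     "functional %d edges (theta = %g)\n"),
              x$n, nrow(x$structural$edges), nrow(x$functional$edges),
              x$theta))
  invisible(x)
}

#' Build a subject's multilayer network from refined matrices
#'
#' Convenience composition: structural layer from `bw_s`, functional layer
#' scale-guided by the structural average degree, then assembly with
#' informativeness-based inter-layer weights.
#'
#' @param bw_s,bw_f refined structural and functional matrices.
#' @param theta network-scale parameter (default 0.5).
#' @return a `multilayer_network`.
#' @export
build_multilayer <- function(bw_s, bw_f, theta = 0.5) {
  s <- build_structural_layer(bw_s)
  f <- build_functional_layer(bw_f, structural_average_degree(s), theta)
  assemble_multilayer(s, f, theta)
}

# adjacency list (0-based, neighbours ascending) for the C++ engine
layer_adjacency <- function(layer) {
  n <- layer$n
  nbr <- vector("list", n)
  wts <- vector("list", n)
  for (k in seq_len(n)) { nbr[[k]] <- integer(); wts[[k]] <- numeric() }
  e <- layer$edges
  if (nrow(e)) {
    all_i <- c(e$i, e$j)
    all_j <- c(e$j, e$i)
    all_w <- c(e$w, e$w)
    ord <- order(all_i, all_j)
    all_i <- all_i[ord]; all_j <- all_j[ord]; all_w <- all_w[ord]
    split_j <- split(all_j, all_i)
    split_w <- split(all_w, all_i)
    for (nm in names(split_j)) {
      k <- as.integer(nm)
      nbr[[k]] <- as.integer(split_j[[nm]]) - 1L
      wts[[k]] <- as.numeric(split_w[[nm]])
    }
  }
  list(nbr = nbr, w = wts)
}
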