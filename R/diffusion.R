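#' Walk configuration for multilayer informativeness diffusion
#'
#' @param p return parameter > 0; small p favours revisiting the previous
#'   node (default 0.1).
#' @param q in-out parameter > 0; q > 1 keeps the walk near the previous
#'   node, q < 1 pushes it outward (default 1.6).
#' @param walk_length number of diffusion steps per walk (lambda, default
#'   10); a walk emits up to `walk_length + 1` node ids including its start.
#' @param walks_per_node walks started from each node (default 10).
#' @param seed RNG seed for the sampler.
#' @return list of class `walk_config`.
#' @export
walk_config <- function(p = 0.1, q = 1.6, walk_length = 10,
                        walks_per_node = 10, seed = 1) {
  if (p <= 0 || q <= 0) stop("p and q must be > 0")
  if (walk_length < 1 || walks_per_node < 1)
    stop("walk_length and walks_per_node must be >= 1")
  structure(list(p = p, q = q, walk_length = as.integer(walk_length),
                 walks_per_node = as.integer(walks_per_node),
                 seed = as.numeric(seed)),
            class = "walk_config")
}

#' Inter-layer transition probabilities at a node
#'
#' The diffusion chooses its next layer in proportion to the node's
#' informativeness in each layer:
#' `P(structural) = I_s / (I_s + I_f)`, `P(functional) = I_f / (I_s + I_f)`.
#'
#' @param info_s,info_f informativeness of the node in the structural and
#'   functional layer (both >= 1).
#' @return named numeric vector `c(structural = ..., functional = ...)`
#'   summing to 1.
#' @export
layer_choice_probs <- function(info_s, info_f) {
  if (info_s <= 0 || info_f <= 0) stop("informativeness must be positive")
  tot <- info_s + info_f
  c(structural = info_s / tot, functional = info_f / tot)
}

#' Intra-layer transition distribution of the biased second-order walk
#'
#' Distribution over the neighbours of `current` in the chosen layer.  When
#' the edge (previous, current) is absent from that layer (including the
#' first step), the next node is drawn proportionally to edge weight.
#' Otherwise the second-order biases apply: mass `w/p` for stepping back to
#' `previous`, `w` for a common neighbour of `previous`, and `w/q` for a
#' node at distance 2 from `previous`.
#'
#' @param net a `multilayer_network`.
#' @param layer `"structural"` or `"functional"`.
#' @param current current node id.
#' @param previous previous node id or `NULL`.
#' @param p,q bias parameters.
#' @return named numeric vector of probabilities over the neighbours of
#'   `current` in `layer`, summing to 1.
#' @export
intra_layer_distribution <- function(net, layer = c("structural", "functional"),
                                     current, previous = NULL,
                                     p = 0.1, q = 1.6) {
  layer <- match.arg(layer)
  lg <- net[[layer]]
  e <- lg$edges
  inc <- e$i == current | e$j == current
  if (!any(inc)) stop("node ", current, " is isolated in the ", layer, " layer")
  nb <- ifelse(e$i[inc] == current, e$j[inc], e$i[inc])
  w <- e$w[inc]
  has_edge <- function(a, b) any((e$i == min(a, b)) & (e$j == max(a, b)))
  mass <- w
  if (!is.null(previous) && has_edge(previous, current)) {
    for (t in seq_along(nb)) {
      x <- nb[t]
      if (x == previous) mass[t] <- w[t] / p
      else if (has_edge(previous, x)) mass[t] <- w[t]
      else mass[t] <- w[t] / q
    }
  }
  out <- mass / sum(mass)
  names(out) <- nb
  out
}

net_adjacency <- function(net) {
  s <- layer_adjacency(net$structural)
  f <- layer_adjacency(net$functional)
  list(s_idx = s$nbr, s_w = s$w, f_idx = f$nbr, f_w = f$w)
}

#' Simulate diffusion walks from one start node
#'
#' Each step first samples the next layer by [layer_choice_probs()] at the
#' current node (switching to the other layer if the node is isolated in the
#' chosen one, and terminating early if isolated in both), then samples the
#' next node by the biased second-order rule via alias tables.  Layer tags
#' are discarded: the emitted sequence contains node ids only.
#'
#' @param net a `multilayer_network`.
#' @param start start node id (1-based).
#' @param config a [walk_config()].
#' @param n_walks how many walks to draw (default 1).
#' @return list of integer vectors (node ids, each of length at most
#'   `walk_length + 1`, beginning with `start`); a single vector when
#'   `n_walks = 1`.
#' @export
simulate_walk <- function(net, start, config = walk_config(), n_walks = 1) {
  stopifnot(start >= 1, start <= net$n)
  adj <- net_adjacency(net)
  res <- cpp_simulate_walks(adj$s_idx, adj$s_w, adj$f_idx, adj$f_w,
                            net$info_s, net$info_f, config$p, config$q,
                            as.integer(start - 1), config$walk_length,
                            as.integer(n_walks), config$seed)
  res <- lapply(res, function(v) v + 1L)
  if (n_walks == 1) res[[1]] else res
}

#' Generate the walk corpus of a multilayer network
#'
#' Starts `walks_per_node` walks from every node, with the start order
#' reshuffled on each repetition; fully reproducible for a given seed.
#'
#' @param net a `multilayer_network`.
#' @param config a [walk_config()].
#' @return object of class `walk_corpus`: list with `walks` (list of
#'   integer node-id vectors), `n` and `config`.
#' @export
generate_corpus <- function(net, config = walk_config()) {
  adj <- net_adjacency(net)
  walks <- cpp_generate_corpus(adj$s_idx, adj$s_w, adj$f_idx, adj$f_w,
                               net$info_s, net$info_f, config$p, config$q,
                               config$walk_length, config$walks_per_node,
                               config$seed)
  walks <- lapply(walks, function(v) v + 1L)
  structure(list(walks = walks, n = net$n, config = config),
            class = "walk_corpus")
}

#' @export
print.walk_corpus <- function(x, ...) {
  lens <- lengths(x$walks)
  cat(sprintf("<walk_corpus> %d walks over %d nodes (lengths %d-%d)\n",
              length(x$walks), x$n, min(lens), max(lens)))
  invisible(x)
}

#' Write a walk corpus as whitespace-delimited node-id lines
#'
#' @param corpus a `walk_corpus`.
#' @param path output path (one walk per line).
#' @return `path`, invisibly.
#' @export
write_corpus <- function(corpus, path) {
  writeLines(vapply(corpus$walks, paste, character(1), collapse = " "), path)
  invisible(path)
}

#' Alias table for O(1) discrete sampling
#'
#' Vose's construction: from K nonnegative masses, a table that draws one
#' category with exactly two uniforms per sample regardless of K.  This is
#' the primitive behind every diffusion step.
#'
#' @param w nonnegative weights (at least one positive).
#' @return list of class `alias_table` with `prob` and `alias` (1-based).
#' @export
alias_table <- function(w) {
  if (length(w) < 1 || any(w < 0) || sum(w) <= 0)
    stop("need nonnegative weights with positive sum")
  t <- cpp_alias_build(as.numeric(w))
  structure(list(prob = t$prob, alias = t$alias + 1L, k = length(w)),
            class = "alias_table")
}

#' Draw from an alias table
#'
#' @param tab an [alias_table()].
#' @param n number of draws.
#' @param seed RNG seed.
#' @return integer vector of category indices (1-based), with attribute
#'   `rng_draws` giving the number of uniforms consumed (always `2 n`).
#' @export
alias_sample <- function(tab, n, seed = 1) {
  res <- cpp_alias_sample(tab$prob, tab$alias - 1L, as.integer(n),
                          as.numeric(seed))
  out <- res$sample + 1L
  attr(out, "rng_draws") <- res$rng_draws
  out
}
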