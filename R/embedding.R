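#' Train node embeddings from a walk corpus
#'
#' Maximises the skip-gram objective with negative sampling by stochastic
#' gradient ascent: each node's representation is trained to predict the
#' nodes co-occurring within `window` positions in the walks, against
#' `negatives` noise nodes drawn from the unigram distribution raised to
#' 3/4.  Under the conditional-independence and feature-space-symmetry
#' assumptions the objective factorises over context pairs, which is exactly
#' how the loss is computed.  Training is single-threaded and bit
#' reproducible for a given seed.
#'
#' @param corpus a `walk_corpus` (see [generate_corpus()]), or a plain list
#'   of integer node-id vectors together with `n`.
#' @param d embedding dimension (default 80).
#' @param window context radius (default 10).
#' @param negatives negative samples per context pair (default 5).
#' @param epochs passes over the corpus (default 5).
#' @param lr initial learning rate, decayed linearly (default 0.025).
#' @param seed RNG seed.
#' @param n node count (taken from the corpus when available).
#' @return numeric n x d matrix of node representations (the input vectors),
#'   of class `embedding_matrix`, with the output vectors in attribute
#'   `context_vectors` and the unigram counts in attribute `counts`.
#' @export
train_embeddings <- function(corpus, d = 80, window = 10, negatives = 5,
                             epochs = 5, lr = 0.025, seed = 1, n = NULL) {
  if (inherits(corpus, "walk_corpus")) {
    n <- corpus$n
    walks <- corpus$walks
  } else {
    walks <- corpus
    if (is.null(n)) n <- max(unlist(walks))
  }
  if (!length(walks)) stop("empty corpus")
  seen <- sort(unique(unlist(walks)))
  if (!identical(seen, seq_len(n)))
    stop("corpus must contain every node id in 1..n at least once")
  walks0 <- lapply(walks, function(v) as.integer(v) - 1L)
  res <- cpp_sgns_train(walks0, as.integer(n), as.integer(d),
                        as.integer(window), as.integer(negatives),
                        as.integer(epochs), lr, as.numeric(seed))
  out <- res$input
  rownames(out) <- paste0("V", seq_len(n))
  attr(out, "context_vectors") <- res$output
  attr(out, "counts") <- res$counts
  class(out) <- c("embedding_matrix", class(out))
  out
}

#' @export
print.embedding_matrix <- function(x, ...) {
  cat(sprintf("<embedding_matrix> %d nodes x %d dimensions\n",
              nrow(x), ncol(x)))
  invisible(x)
}

#' Expected negative-sampling loss of an embedding on a corpus
#'
#' Deterministic evaluation of the skip-gram negative-sampling objective
#' (negated, so smaller is better): over all fixed-window context pairs
#' (u, v) of the corpus,
#' `-log sigma(in_u . out_v) - negatives * E_j~noise[log sigma(-in_u . out_j)]`,
#' with the noise expectation taken in full over the unigram^(3/4)
#' distribution rather than sampled.  Used to verify that training descends.
#'
#' @param emb an `embedding_matrix` from [train_embeddings()] (needs the
#'   `context_vectors` attribute).
#' @param corpus the corpus it was (or is to be) trained on.
#' @param window context radius.
#' @param negatives negative-sample count.
#' @return scalar loss.
#' @export
sgns_loss <- function(emb, corpus, window = 10, negatives = 5) {
  walks <- if (inherits(corpus, "walk_corpus")) corpus$walks else corpus
  n <- nrow(emb)
  syn0 <- unclass(emb); attributes(syn0) <- list(dim = dim(emb))
  syn1 <- attr(emb, "context_vectors")
  cnt <- numeric(n)
  pair_cnt <- matrix(0, n, n)  # pair_cnt[u, v]: input u, target v
  for (wk in walks) {
    len <- length(wk)
    for (pos in seq_len(len)) {
      lo <- max(1, pos - window); hi <- min(len, pos + window)
      ctx <- wk[setdiff(lo:hi, pos)]
      for (u in ctx) pair_cnt[u, wk[pos]] <- pair_cnt[u, wk[pos]] + 1
    }
  }
  cnt <- tabulate(unlist(walks), n)
  noise <- cnt^0.75
  noise <- noise / sum(noise)
  S <- syn0 %*% t(syn1)
  logsig <- function(x) ifelse(x > -30, -log1p(exp(-x)), x)
  pos_term <- sum(pair_cnt * logsig(S))
  # expected negative term: for each input u weighted by its pair count
  u_weight <- rowSums(pair_cnt)
  neg_term <- negatives * sum(u_weight * (logsig(-S) %*% noise))
  -(pos_term + neg_term)
}
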