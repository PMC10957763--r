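#' Fit multilayer brain-network embeddings for a cohort
#'
#' The central fitting function.  For every subject it (1) refines the
#' structural and functional connectivity matrices with the beta mapping,
#' (2) builds the two-layer network with informativeness-weighted
#' inter-layer transitions, (3) samples a walk corpus by biased multilayer
#' diffusion, (4) trains skip-gram embeddings with negative sampling, and
#' (5) reconfigures the embedding by per-subject PCA.  The result carries
#' the per-subject reconfigured representations from which node and network
#' distances, nodewise statistics and classification are computed.
#'
#' Defaults follow the published parameter study: `alpha = 10`, `beta = 1`,
#' `theta = 0.5`, `p = 0.1`, `q = 1.6`, `walk_length = 10`, `dim = 80`,
#' `k = dim / 2`.  Walks per node (10), window (10), negatives (5) and
#' epochs (5) are the standard conventions of this embedding family.
#'
#' @param subjects a cohort: list of `list(id, group, sc, fc)` (as returned
#'   by [load_cohort()] or [simulate_cohort()]), or a manifest path.
#' @param alpha,beta beta-mapping shape parameters.
#' @param theta functional-layer network-scale parameter.
#' @param p,q diffusion bias parameters.
#' @param walk_length steps per walk (lambda).
#' @param walks_per_node walks started from each node.
#' @param dim embedding dimension d.
#' @param window,negatives,epochs skip-gram training parameters.
#' @param k retained principal components (default `dim / 2`, must be < dim
#'   and at most the PCA rank, i.e. < number of regions).
#' @param seed master seed; per-subject walk and training seeds are derived
#'   from it.
#' @param keep_embeddings retain the raw n x d embeddings (default TRUE).
#' @return object of class `mbne`: list with `A` (per-subject
#'   `reconfigured_matrix` list, named by subject id), `groups`, `ids`,
#'   `region_labels`, `params`, and optionally `embeddings`.
#' @export
mbne <- function(subjects, alpha = 10, beta = 1, theta = 0.5, p = 0.1,
                 q = 1.6, walk_length = 10, walks_per_node = 10, dim = 80,
                 window = 10, negatives = 5, epochs = 5,
                 k = floor(dim / 2), seed = 1, keep_embeddings = TRUE) {
  if (is.character(subjects)) subjects <- load_cohort(subjects)
  if (!length(subjects)) stop("empty cohort")
  bp <- beta_params(alpha, beta)
  ids <- vapply(subjects, `[[`, character(1), "id")
  groups <- vapply(subjects, `[[`, character(1), "group")
  region_labels <- subjects[[1]]$sc$region_labels
  A <- vector("list", length(subjects))
  emb <- if (keep_embeddings) vector("list", length(subjects)) else NULL
  # cohort-wide structural scale: identical edge strengths must map
  # identically across subjects
  sc_scale <- max(vapply(subjects, function(s) max(s$sc$weights), numeric(1)))
  for (i in seq_along(subjects)) {
    s <- subjects[[i]]
    bw_s <- refine_matrix(s$sc, bp, sc_scale = sc_scale)
    bw_f <- refine_matrix(s$fc, bp)
    net <- build_multilayer(bw_s, bw_f, theta)
    sub_seed <- derive_seed(seed, i)
    corpus <- generate_corpus(net, walk_config(p, q, walk_length,
                                               walks_per_node, sub_seed))
    F <- train_embeddings(corpus, d = dim, window = window,
                          negatives = negatives, epochs = epochs,
                          seed = sub_seed)
    A[[i]] <- pca_reconfigure(F, k)
    if (keep_embeddings) emb[[i]] <- F
  }
  names(A) <- ids
  if (keep_embeddings) names(emb) <- ids
  structure(list(A = A, groups = groups, ids = ids,
                 region_labels = region_labels,
                 params = list(alpha = alpha, beta = beta, theta = theta,
                               p = p, q = q, walk_length = walk_length,
                               walks_per_node = walks_per_node, dim = dim,
                               window = window, negatives = negatives,
                               epochs = epochs, k = k, seed = seed),
                 embeddings = emb),
            class = "mbne")
}

#' @export
print.mbne <- function(x, ...) {
  tab <- table(x$groups)
  cat(sprintf("<mbne> %d subjects (%s), %d regions, d = %d, k = %d\n",
              length(x$ids),
              paste(sprintf("%s: %d", names(tab), tab), collapse = ", "),
              length(x$region_labels), x$params$dim, x$params$k))
  invisible(x)
}

#' Node distances of every subject to a group template
#'
#' @param fit an [mbne()] fit.
#' @param template_group the group whose centroid template is the reference.
#' @param subjects_idx optional subject subset used to build the template
#'   (defaults to all subjects of `template_group`).
#' @return subjects x regions [node_distance_matrix()].
#' @export
node_distances <- function(fit, template_group, subjects_idx = NULL) {
  if (is.null(subjects_idx)) subjects_idx <- which(fit$groups == template_group)
  if (!length(subjects_idx)) stop("no subjects in group ", template_group)
  tmpl <- build_node_template(fit$A[subjects_idx], template_group)
  L <- node_distance_matrix(fit$A, tmpl)
  colnames(L) <- fit$region_labels
  rownames(L) <- fit$ids
  L
}

#' Network distances of every subject to two group templates
#'
#' @param fit an [mbne()] fit.
#' @param positive,negative group labels defining the positive and negative
#'   templates.
#' @return m x 2 matrix (columns `d_pos`, `d_neg`).
#' @export
network_distances <- function(fit, positive, negative) {
  tmpl <- build_network_templates(fit$A[fit$groups == positive],
                                  fit$A[fit$groups == negative])
  H <- network_distance_matrix(fit$A, tmpl$C_plus, tmpl$C_minus)
  rownames(H) <- fit$ids
  H
}

#' @export
summary.mbne <- function(object, ...) {
  grps <- unique(object$groups)
  D <- matrix(NA_real_, length(grps), length(grps),
              dimnames = list(group = grps, template = grps))
  for (g in grps) {
    L <- node_distances(object, g)
    for (h in grps)
      D[h, g] <- mean(L[object$groups == h, ])
  }
  out <- list(n_subjects = length(object$ids),
              groups = table(object$groups),
              n_regions = length(object$region_labels),
              params = object$params,
              mean_node_distance = D)
  class(out) <- "summary.mbne"
  out
}

#' @export
print.summary.mbne <- function(x, ...) {
  cat(sprintf("mbne fit: %d subjects, %d regions\n",
              x$n_subjects, x$n_regions))
  print(x$groups)
  cat("\nMean node distance (rows: group, cols: reference template):\n")
  print(round(x$mean_node_distance, 4))
  cat(sprintf("\nparameters: alpha=%g beta=%g theta=%g p=%g q=%g lambda=%d d=%d k=%d seed=%g\n",
              x$params$alpha, x$params$beta, x$params$theta, x$params$p,
              x$params$q, x$params$walk_length, x$params$dim, x$params$k,
              x$params$seed))
  invisible(x)
}

#' Plot the network-distance plane of a fitted cohort
#'
#' Scatter of each subject's distances to the positive (x) and negative (y)
#' group template, coloured by group -- the two-dimensional feature space
#' the SVM classifies.
#'
#' @param x an [mbne()] fit.
#' @param positive,negative group labels (defaults: first two groups).
#' @param ... passed to [graphics::plot()].
#' @return the H matrix, invisibly.
#' @export
plot.mbne <- function(x, positive = NULL, negative = NULL, ...) {
  grps <- unique(x$groups)
  if (is.null(positive)) positive <- grps[1]
  if (is.null(negative)) negative <- if (length(grps) > 1) grps[2] else grps[1]
  H <- network_distances(x, positive, negative)
  col <- as.integer(factor(x$groups)) + 1L
  graphics::plot(H[, 1], H[, 2], col = col, pch = 19,
                 xlab = paste("distance to", positive, "template"),
                 ylab = paste("distance to", negative, "template"), ...)
  graphics::legend("topleft", legend = levels(factor(x$groups)),
                   col = seq_along(levels(factor(x$groups))) + 1L, pch = 19,
                   bty = "n")
  invisible(H)
}
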