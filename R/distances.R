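#' Reconfigure an embedding by per-subject PCA
#'
#' A given embedding dimension can encode different latent concepts in
#' different subjects' networks, so raw dimensions are not comparable across
#' subjects.  Each subject's n x d representation is therefore rotated onto
#' its own principal axes (columns centred over nodes) and the top k
#' component scores are retained, ordered by explained variance.  The
#' eigenvector sign ambiguity is removed with a rotation-invariant
#' convention on the scores: each component is flipped so that the third
#' moment of its score vector is positive (falling back to making the
#' largest-magnitude score positive when the scores are unskewed).  A
#' loading-based convention would be expressed in the embedding's own
#' arbitrary rotated basis and therefore assign effectively random signs
#' across subjects; the scores are invariant to that rotation, which is
#' precisely why the reconfiguration makes subjects comparable.
#'
#' @param F an n x d embedding matrix.
#' @param k retained components, `k < d` (default `ncol(F) / 2`).
#' @return object of class `reconfigured_matrix`: list with `A` (n x k
#'   scores), `explained_variance` (nonincreasing, length k) and `k`.
#' @export
pca_reconfigure <- function(F, k = floor(ncol(F) / 2)) {
  F <- as.matrix(unclass(F))
  attributes(F) <- list(dim = dim(F), dimnames = dimnames(F))
  n <- nrow(F); d <- ncol(F)
  if (n < 2) stop("need at least 2 nodes for PCA")
  if (k >= d) stop("k must be smaller than the embedding dimension d")
  if (k < 1) stop("k must be >= 1")
  pr <- stats::prcomp(F, center = TRUE, scale. = FALSE)
  avail <- ncol(pr$rotation)
  if (k > avail)
    stop("k = ", k, " exceeds the ", avail, " available components")
  scores <- pr$x[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    s <- scores[, j]
    m3 <- sum(s^3)
    flip <- if (abs(m3) > 1e-12 * sum(s^2)^1.5) m3 < 0
            else s[which.max(abs(s))] < 0
    if (flip) scores[, j] <- -s
  }
  structure(list(A = scores, explained_variance = pr$sdev[seq_len(k)]^2,
                 k = k),
            class = "reconfigured_matrix")
}

#' Cosine distance between two vectors
#'
#' `CosDist(a, b) = 1 - cos(a, b) = 1 - (a . b) / (||a|| ||b||)`, in
#' \[0, 2\]: 0 for parallel vectors, 1 for orthogonal, 2 for anti-parallel.
#' Undefined (an error) for a zero vector.
#'
#' @param a,b numeric vectors of equal length, both nonzero.
#' @return scalar distance in \[0, 2\].
#' @export
cosine_distance <- function(a, b) {
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0)
    stop("cosine distance is undefined for a zero vector")
  d <- 1 - sum(a * b) / (na * nb)
  min(max(d, 0), 2)  # clamp fp noise
}

# cosine distance that maps zero-vector operands to the maximum 2 with a
# warning, for use inside cohort loops
cosine_distance_safe <- function(a, b, warned = FALSE) {
  if (sum(a^2) == 0 || sum(b^2) == 0) {
    if (!warned) warning("zero vector in distance computation; recording 2")
    return(2)
  }
  cosine_distance(a, b)
}

get_A <- function(x) if (inherits(x, "reconfigured_matrix")) x$A else as.matrix(x)

#' Build a node-level group template
#'
#' The template is the centroid node representation of a group: row i is the
#' mean of the i-th reconfigured rows over the group's subjects.
#'
#' @param group_matrices nonempty list of `reconfigured_matrix` objects (or
#'   plain n x k matrices) sharing dimensions.
#' @param group_label label recorded on the template.
#' @return object of class `node_template`: list with `tau` (n x k),
#'   `group_label`, `support`.
#' @export
build_node_template <- function(group_matrices, group_label = NA_character_) {
  if (!length(group_matrices)) stop("empty group")
  mats <- lapply(group_matrices, get_A)
  dm <- dim(mats[[1]])
  for (m in mats)
    if (!identical(dim(m), dm)) stop("shape mismatch across group matrices")
  tau <- Reduce(`+`, mats) / length(mats)
  structure(list(tau = tau, group_label = group_label,
                 support = length(mats)),
            class = "node_template")
}

#' Node distance matrix against a template
#'
#' `L[r, i]` is the cosine distance between subject r's node-i row and the
#' template's row `tau_i`.  A zero row in either operand yields the maximum
#' distance 2 with a warning (strict mode errors instead).
#'
#' @param subjects list of `reconfigured_matrix` objects (or n x k matrices).
#' @param template a [build_node_template()] result (or an n x k matrix).
#' @param strict error on zero vectors instead of recording 2.
#' @return m x n numeric matrix of class `node_distance_matrix`, with
#'   attribute `template_label`.
#' @export
node_distance_matrix <- function(subjects, template, strict = FALSE) {
  tau <- if (inherits(template, "node_template")) template$tau else as.matrix(template)
  mats <- lapply(subjects, get_A)
  n <- nrow(tau)
  L <- matrix(NA_real_, length(mats), n)
  warned <- FALSE
  for (r in seq_along(mats)) {
    A <- mats[[r]]
    if (!identical(dim(A), dim(tau))) stop("subject ", r, ": shape mismatch")
    for (i in seq_len(n)) {
      if (!strict && (sum(A[i, ]^2) == 0 || sum(tau[i, ]^2) == 0)) {
        L[r, i] <- cosine_distance_safe(A[i, ], tau[i, ], warned)
        warned <- TRUE
      } else {
        L[r, i] <- cosine_distance(A[i, ], tau[i, ])
      }
    }
  }
  rownames(L) <- names(subjects)
  attr(L, "template_label") <-
    if (inherits(template, "node_template")) template$group_label else NA_character_
  class(L) <- c("node_distance_matrix", class(L))
  L
}

#' Concatenate a reconfigured matrix into a network representation
#'
#' Row-major flattening: the rows of A (one per node) laid end to end into a
#' single vector of length n * k.
#'
#' @param A a `reconfigured_matrix` or n x k matrix.
#' @return numeric vector of length n * k.
#' @export
concat_representation <- function(A) as.vector(t(get_A(A)))

#' Build network-level positive and negative templates
#'
#' Each subject's reconfigured matrix is concatenated row-major into a
#' network representation; the templates are the group means of those
#' vectors.
#'
#' @param positive,negative nonempty lists of `reconfigured_matrix` objects
#'   for the positive and negative group.
#' @return list with `C_plus` and `C_minus` (length n * k vectors).
#' @export
build_network_templates <- function(positive, negative) {
  if (!length(positive) || !length(negative)) stop("empty group")
  cp <- rowMeans(vapply(positive, concat_representation,
                        numeric(length(concat_representation(positive[[1]])))))
  cm <- rowMeans(vapply(negative, concat_representation,
                        numeric(length(concat_representation(negative[[1]])))))
  list(C_plus = cp, C_minus = cm)
}

#' Network distance matrix against the two templates
#'
#' `H[a, 1]` is the cosine distance of subject a's concatenated
#' representation to the positive template, `H[a, 2]` to the negative one.
#'
#' @param subjects list of `reconfigured_matrix` objects.
#' @param C_plus,C_minus template vectors (see [build_network_templates()]).
#' @return m x 2 matrix with columns `d_pos`, `d_neg`.
#' @export
network_distance_matrix <- function(subjects, C_plus, C_minus) {
  if (sum(C_plus^2) == 0 || sum(C_minus^2) == 0)
    stop("zero template vector")
  H <- t(vapply(subjects, function(s) {
    v <- concat_representation(s)
    c(cosine_distance(v, C_plus), cosine_distance(v, C_minus))
  }, numeric(2)))
  colnames(H) <- c("d_pos", "d_neg")
  rownames(H) <- names(subjects)
  H
}
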