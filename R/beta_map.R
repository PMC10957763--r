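#' Beta-distribution parameters for connectivity refinement
#'
#' The refinement maps an edge strength x in \[0, 1\] to
#' `psi(x) = x * dbeta(x, alpha, beta)`.  With `alpha >= 1` and `beta = 1`
#' the map is monotone increasing with maximum `psi(1) = alpha`, so strong
#' connections are expanded and weak ones squeezed toward zero.  Outside the
#' monotone regime (`alpha < 1` or `beta > 1`) a warning is emitted; with
#' `beta < 1` the density diverges as x approaches 1, which produces
#' implausibly large refined weights.
#'
#' Defaults: `alpha = 10`, `beta = 1` (the configuration found optimal in the
#' parameter study the method was developed with).
#'
#' @param alpha shape parameter, > 0.
#' @param beta shape parameter, > 0.
#' @return list of class `beta_params`.
#' @export
beta_params <- function(alpha = 10, beta = 1) {
  if (!is.numeric(alpha) || alpha <= 0 || !is.numeric(beta) || beta <= 0)
    stop("alpha and beta must be positive")
  if (alpha < 1 || beta > 1)
    warning("outside the monotone mapping regime (needs alpha >= 1, beta <= 1)")
  structure(list(alpha = alpha, beta = beta), class = "beta_params")
}

#' Beta mapping of a connection strength
#'
#' Computes `psi(x) = x * dbeta(x, alpha, beta)`, the refinement applied to
#' every edge weight before network construction.  A worked contrast: with
#' `alpha = 2, beta = 1`, a strong connection of 0.9 maps to 1.62 while a
#' typical 0.5 maps to 0.5 -- a 224% gap where the raw strengths differ by
#' only 80%.  (Some descriptions of this example state beta = 2, but only
#' beta = 1 reproduces the value 1.62; the monotone beta = 1 family is the
#' one used throughout.)
#'
#' @param x numeric vector of strengths in \[0, 1\].
#' @param params a [beta_params()] object (or a list with `alpha`, `beta`).
#' @return `psi(x)`, same length as `x`; `psi(0) = 0`, and for `beta = 1`
#'   the maximum is `psi(1) = alpha`.
#' @export
beta_map <- function(x, params = beta_params()) {
  if (any(x < 0 | x > 1, na.rm = TRUE))
    stop("beta_map inputs must lie in [0, 1]")
  out <- x * stats::dbeta(x, params$alpha, params$beta)
  # x = 0 with alpha = 1 gives dbeta = 1 (psi = 0 via the x factor); for
  # alpha > 1 dbeta(0) = 0.  Either way psi(0) = 0 exactly.
  out[x == 0] <- 0
  out
}

#' Refine a connectivity matrix with the beta mapping
#'
#' Applies [beta_map()] elementwise.  Functional matrices are already in
#' \[0, 1\]; structural matrices (fibers / summed surface areas) are not
#' bounded by 1 and are first rescaled by their own maximum entry
#' (`sc_rescale = TRUE`), which preserves each subject's rank order of edge
#' strengths while placing the weights on the beta density's support.
#'
#' When refining a whole cohort, pass the cohort-wide maximum as `sc_scale`
#' so that every subject is mapped on a common scale; a subject-specific
#' maximum would make identical edge strengths map differently across
#' subjects and corrupt group comparisons (see the methods vignette).
#'
#' @param cm a [connectivity_matrix()].
#' @param params a [beta_params()] object.
#' @param sc_rescale rescale structural matrices before mapping (default
#'   TRUE).
#' @param sc_scale positive scalar to divide structural weights by; default
#'   `NULL` uses the matrix's own maximum (appropriate for a single
#'   subject in isolation).
#' @return A refined [connectivity_matrix()] of the same modality.  Zeros and
#'   symmetry are preserved.
#' @export
refine_matrix <- function(cm, params = beta_params(), sc_rescale = TRUE,
                          sc_scale = NULL) {
  w <- cm$weights
  if (cm$modality == "structural" && sc_rescale) {
    mx <- if (is.null(sc_scale)) max(w) else sc_scale
    if (mx < 0 || (mx == 0 && max(w) > 0)) stop("invalid sc_scale")
    if (mx > 0) w <- w / mx
  }
  if (any(w > 1 + 1e-9))
    stop("entries outside [0, 1] after rescaling; cannot apply beta mapping")
  w[w > 1] <- 1
  bw <- matrix(beta_map(as.vector(w), params), nrow(w), ncol(w),
               dimnames = dimnames(w))
  bw <- (bw + t(bw)) / 2  # guard against fp asymmetry
  connectivity_matrix(bw, cm$modality, cm$region_labels, refined = TRUE)
}
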