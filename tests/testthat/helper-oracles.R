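# Fixtures and independent oracles.  The oracles recompute expected values
# from raw weight matrices with plain arithmetic; they deliberately do not
# call the package's own layer/diffusion code.

cm_from_matrix <- function(w, modality = "structural") {
  connectivity_matrix(w, modality, refined = TRUE)
}

# undirected weighted matrix from an edge list (1-based, i, j, w)
mat_from_edges <- function(n, i, j, w) {
  m <- matrix(0, n, n)
  for (t in seq_along(i)) {
    m[i[t], j[t]] <- w[t]
    m[j[t], i[t]] <- w[t]
  }
  m
}

# 6-node two-layer toy with hand-specified weights; no node is isolated in
# either layer
toy_weights <- function() {
  Ws <- mat_from_edges(6,
                       i = c(1, 1, 2, 2, 3, 4, 5),
                       j = c(2, 3, 3, 4, 5, 5, 6),
                       w = c(1.0, 2.0, 0.5, 1.5, 1.0, 2.5, 0.8))
  Wf <- mat_from_edges(6,
                       i = c(1, 1, 2, 3, 4, 4, 5),
                       j = c(2, 4, 5, 4, 5, 6, 6),
                       w = c(0.9, 1.2, 2.0, 0.7, 1.1, 0.4, 1.6))
  list(s = Ws, f = Wf)
}

toy_multilayer <- function() {
  W <- toy_weights()
  s <- build_structural_layer(cm_from_matrix(W$s))
  f <- build_structural_layer(cm_from_matrix(W$f))
  f$modality <- "functional"
  assemble_multilayer(s, f, theta = 0.5)
}

# --- oracle: informativeness from a weight matrix ------------------------
oracle_info <- function(W) {
  ew <- W[upper.tri(W)]
  ew <- ew[ew > 0]
  mw <- mean(ew)
  n <- nrow(W)
  vapply(seq_len(n), function(i) {
    nb <- which(W[i, ] > 0)
    log(exp(1) + sum(W[i, nb] <= mw))
  }, numeric(1))
}

# layer-choice probability of the structural layer at each node
oracle_p_struct <- function(Ws, Wf) {
  Is <- oracle_info(Ws)
  If <- oracle_info(Wf)
  Is / (Is + If)
}

# unnormalised second-order mass over neighbours of `cur` in layer W, given
# `prev` (biased cases apply only when the edge (prev, cur) is in W)
oracle_step_mass <- function(W, cur, prev, p, q) {
  nb <- which(W[cur, ] > 0)
  mass <- W[cur, nb]
  if (!is.null(prev) && W[prev, cur] > 0) {
    for (t in seq_along(nb)) {
      x <- nb[t]
      if (x == prev) mass[t] <- W[cur, x] / p
      else if (W[prev, x] > 0) mass[t] <- W[cur, x]
      else mass[t] <- W[cur, x] / q
    }
  }
  out <- numeric(nrow(W))
  out[nb] <- mass
  out
}

# exact distribution of the first emitted node for a walk from `start`
oracle_first_step <- function(Ws, Wf, start, p, q) {
  ps <- oracle_p_struct(Ws, Wf)[start]
  n <- nrow(Ws)
  out <- numeric(n)
  for (lay in 1:2) {
    W <- if (lay == 1) Ws else Wf
    prob <- if (lay == 1) ps else 1 - ps
    if (sum(W[start, ]) == 0) {        # isolated: forced switch
      W <- if (lay == 1) Wf else Ws
      if (sum(W[start, ]) == 0) next   # isolated in both: walk ends
    }
    m <- oracle_step_mass(W, start, NULL, p, q)
    out <- out + prob * m / sum(m)
  }
  out
}

# exact joint distribution of the first two emitted nodes (v1, v2)
oracle_two_step <- function(Ws, Wf, start, p, q) {
  n <- nrow(Ws)
  ps <- oracle_p_struct(Ws, Wf)
  P <- matrix(0, n, n)
  for (l1 in 1:2) {
    W1 <- if (l1 == 1) Ws else Wf
    pr1 <- if (l1 == 1) ps[start] else 1 - ps[start]
    if (sum(W1[start, ]) == 0) next  # toy has no isolated nodes
    m1 <- oracle_step_mass(W1, start, NULL, p, q)
    m1 <- m1 / sum(m1)
    for (v1 in which(m1 > 0)) {
      for (l2 in 1:2) {
        W2 <- if (l2 == 1) Ws else Wf
        pr2 <- if (l2 == 1) ps[v1] else 1 - ps[v1]
        if (sum(W2[v1, ]) == 0) {
          W2 <- if (l2 == 1) Wf else Ws
          if (sum(W2[v1, ]) == 0) next
        }
        m2 <- oracle_step_mass(W2, v1, start, p, q)
        m2 <- m2 / sum(m2)
        P[v1, ] <- P[v1, ] + pr1 * m1[v1] * pr2 * m2
      }
    }
  }
  P
}

# exact two-step distribution of a plain single-layer (p, q)-biased
# second-order walk (the node2vec reduction target)
oracle_node2vec_two_step <- function(W, start, p, q) {
  n <- nrow(W)
  P <- matrix(0, n, n)
  m1 <- oracle_step_mass(W, start, NULL, p, q)
  m1 <- m1 / sum(m1)
  for (v1 in which(m1 > 0)) {
    m2 <- oracle_step_mass(W, v1, start, p, q)
    P[v1, ] <- m1[v1] * m2 / sum(m2)
  }
  P
}

# textbook pooled-variance two-sample t statistic
oracle_pooled_t <- function(x, y) {
  sp2 <- ((length(x) - 1) * stats::var(x) + (length(y) - 1) * stats::var(y)) /
    (length(x) + length(y) - 2)
  (mean(x) - mean(y)) / sqrt(sp2 * (1 / length(x) + 1 / length(y)))
}

# chi-square goodness-of-fit p-value; cells with expected count < 10 are
# pooled into one bucket
chisq_gof_p <- function(obs, probs) {
  stopifnot(length(obs) == length(probs))
  n <- sum(obs)
  expd <- probs * n
  keep <- expd >= 10
  o <- obs[keep]
  e <- expd[keep]
  if (any(!keep) && sum(expd[!keep]) > 0) {
    o <- c(o, sum(obs[!keep]))
    e <- c(e, sum(expd[!keep]))
  }
  stat <- sum((o - e)^2 / e)
  stats::pchisq(stat, df = length(o) - 1, lower.tail = FALSE)
}

cos_sim <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))

# empirical (v1, v2) counts from walks of length >= 3 nodes
pair_counts <- function(walks, n) {
  cnt <- matrix(0, n, n)
  for (wk in walks) {
    if (length(wk) >= 3) cnt[wk[2], wk[3]] <- cnt[wk[2], wk[3]] + 1
  }
  cnt
}

# the synthetic study conditions used by the recovery and calibration tests
study_config <- function(seed, delta, n_per_group = 20) {
  synth_config(n_regions = 30,
               n_per_group = c(control = n_per_group, patient = n_per_group),
               affected_regions = c(3, 8, 15, 22, 27),
               effect_size = delta, seed = seed)
}

run_study <- function(seed, delta, r = 30, d = 8, k = 4, alpha = 2,
                      n_per_group = 20, classify = TRUE) {
  cfg <- study_config(seed, delta, n_per_group)
  subs <- simulate_cohort(cfg)
  fit <- mbne(subs, alpha = alpha, dim = d, k = k, walks_per_node = r,
              seed = derive_study_seed(seed))
  L <- node_distances(fit, "control")
  st <- suppressWarnings(
    nodewise_ttests(L, fit$groups, "control", "patient"))
  sig <- which(st$significant)
  aff <- cfg$affected_regions
  out <- list(sig = sig,
              recall = length(intersect(sig, aff)) / length(aff),
              precision = if (length(sig))
                length(intersect(sig, aff)) / length(sig) else NA_real_,
              n_sig = length(sig))
  if (classify) {
    cls <- cross_validated_classify(fit$A, fit$groups, positive = "patient",
                                    seed = seed)
    out$acc <- cls$ACC
    out$auc <- cls$AUC
  }
  out
}

derive_study_seed <- function(seed) (seed * 131 + 7) %% 100000
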