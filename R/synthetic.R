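# deterministic sub-seed derivation, kept well below 2^31
derive_seed <- function(seed, idx) {
  ((seed %% 100000) * 7919 + idx * 104729) %% 2147483646 + 1
}

#' Configuration of a synthetic multimodal cohort
#'
#' The generator emulates a case/control connectome study: every subject
#' shares a cohort-level structural backbone (a weighted stochastic-block
#' graph, minimum degree 2 -- human anatomy is strongly conserved across
#' subjects, and template-referenced group comparison presupposes that),
#' with per-subject multiplicative weight jitter; functional time series
#' arise from community-shared latent signals mixed through the subject's
#' structural backbone plus independent observation noise.
#'
#' In the patient group the designated affected regions undergo a
#' connectivity *dedifferentiation*: each affected region's coupling is
#' redistributed from its strong connections to its weak ones -- incident
#' edges at or below the region's backbone-median weight are scaled by
#' `(1 + effect_size)` and those above it by `1 / (1 + effect_size)`.  With
#' `effect_modality = "both"` (default) the perturbed weights are both
#' observed as the subject's SC and used as the latent mixing backbone that
#' generates the time series, so the functional effect is coupled to the
#' structural one; `"sc"` perturbs only the observed SC, `"fc"` only the
#' latent mixing.  A profile perturbation of this kind expresses for any
#' connected region and mimics the loss of connectional specificity
#' reported in psychotic disorders; a uniform gain on all incident edges
#' would instead be largely invisible to walk-based embeddings, whose
#' per-node transition probabilities are normalised (see the methods
#' vignette).  `effect_size = 0` reproduces the control distribution
#' exactly.
#'
#' @param n_regions number of regions (default 30).
#' @param n_per_group named integer vector of group sizes (default 20
#'   control, 20 patient).
#' @param communities community id per region.  The default carves the
#'   regions into four blocks of unequal size (40/30/17/13% of regions):
#'   brain networks have heterogeneous module sizes, and the resulting
#'   eigenvalue gaps keep the per-subject principal axes stably matched
#'   across subjects, which equal-sized blocks (a degenerate eigenspace)
#'   would not.
#' @param sc_density target structural edge density in (0, 1\] (default
#'   0.25).
#' @param affected_regions region ids perturbed in patients (default none).
#' @param effect_size multiplicative perturbation delta >= 0 (default 0).
#' @param noise_sd observation noise SD on the time series (default 0.5).
#' @param t_len time-series length (default 200, a short resting-state-like
#'   regime).
#' @param effect_modality `"both"`, `"sc"` or `"fc"`: where the perturbation
#'   is injected.
#' @param patient_group name of the perturbed group (default `"patient"`).
#' @param seed cohort seed.
#' @return list of class `synth_config`.
#' @export
synth_config <- function(n_regions = 30,
                         n_per_group = c(control = 20, patient = 20),
                         communities = NULL, sc_density = 0.25,
                         affected_regions = integer(0), effect_size = 0,
                         noise_sd = 0.5, t_len = 200,
                         effect_modality = c("both", "sc", "fc"),
                         patient_group = "patient", seed = 1) {
  effect_modality <- match.arg(effect_modality)
  if (is.null(communities)) {
    cuts <- round(n_regions * cumsum(c(0, 0.40, 0.30, 0.17, 0.13)))
    communities <- rep(seq_len(4), diff(cuts))
  }
  stopifnot(length(communities) == n_regions,
            sc_density > 0, sc_density <= 1,
            effect_size >= 0, noise_sd >= 0, t_len >= 3)
  if (length(affected_regions) &&
      (min(affected_regions) < 1 || max(affected_regions) > n_regions))
    stop("affected_regions out of range")
  if (is.null(names(n_per_group)))
    stop("n_per_group must be named by group label")
  if (effect_size > 0 && !(patient_group %in% names(n_per_group)))
    stop("patient_group not among group labels")
  structure(list(n_regions = n_regions, n_per_group = n_per_group,
                 communities = communities, sc_density = sc_density,
                 affected_regions = as.integer(affected_regions),
                 effect_size = effect_size, noise_sd = noise_sd,
                 t_len = as.integer(t_len),
                 effect_modality = effect_modality,
                 patient_group = patient_group, seed = seed),
            class = "synth_config")
}

# cohort-level structural backbone: SBM topology + base edge weights,
# deterministic in config$seed
cohort_backbone <- function(config) {
  set.seed(derive_seed(config$seed, 0))
  n <- config$n_regions
  comm <- config$communities
  same <- outer(comm, comm, `==`)
  ut <- upper.tri(same)
  f_within <- mean(same[ut])
  # within-community edges 4x more probable than between
  p_between <- config$sc_density / (4 * f_within + (1 - f_within))
  p_within <- min(1, 4 * p_between)
  prob <- ifelse(same, p_within, p_between)
  adj <- matrix(FALSE, n, n)
  adj[ut] <- stats::runif(sum(ut)) < prob[ut]
  adj <- adj | t(adj)
  # minimum degree 2, so every region participates in the diffusion
  for (i in seq_len(n)) {
    need <- 2 - sum(adj[i, ])
    if (need > 0) {
      cand <- setdiff(sample(n), c(i, which(adj[i, ])))
      add <- cand[seq_len(need)]
      adj[i, add] <- TRUE; adj[add, i] <- TRUE
    }
  }
  base_w <- matrix(0, n, n)
  wvals <- exp(stats::rnorm(sum(ut), 0, 0.4)) * ifelse(same[ut], 1.5, 1)
  base_w[ut] <- ifelse(adj[ut], wvals, 0)
  base_w <- base_w + t(base_w)

  # cohort-stable dedifferentiation masks: per affected region, its incident
  # backbone edges at or below that region's median weight are the "weak"
  # set (strengthened in patients), the rest the "strong" set (weakened)
  aff <- config$affected_regions
  n_up <- matrix(FALSE, n, n); n_dn <- matrix(FALSE, n, n)
  for (i in aff) {
    nb <- which(adj[i, ])
    med <- stats::median(base_w[i, nb])
    weak <- nb[base_w[i, nb] <= med]
    strong <- setdiff(nb, weak)
    n_up[i, weak] <- TRUE
    n_dn[i, strong] <- TRUE
  }
  list(adj = adj, base_w = base_w, up = n_up, dn = n_dn)
}

#' Generate one synthetic subject
#'
#' @param config a [synth_config()].
#' @param group the subject's group label.
#' @param subject_seed RNG seed for this subject's noise draws.
#' @return list with `sc` and `fc` ([connectivity_matrix()] objects).
#' @export
generate_subject <- function(config, group,
                             subject_seed = derive_seed(config$seed, 1)) {
  bk <- cohort_backbone(config)
  set.seed(subject_seed)
  n <- config$n_regions
  delta <- config$effect_size
  patient <- identical(group, config$patient_group) && delta > 0
  up_s <- bk$up | t(bk$up)
  dn_s <- (bk$dn | t(bk$dn)) & !up_s

  # structural weights: backbone with per-subject lognormal jitter, and the
  # dedifferentiation applied for patients
  ut <- upper.tri(bk$base_w)
  w_clean <- matrix(0, n, n)
  w_clean[ut] <- bk$base_w[ut] * exp(stats::rnorm(sum(ut), 0, 0.15))
  w_clean <- w_clean + t(w_clean)
  w_pert <- w_clean
  if (patient) {
    w_pert[up_s] <- w_pert[up_s] * (1 + delta)
    w_pert[dn_s] <- w_pert[dn_s] / (1 + delta)
  }
  # the observed SC carries the perturbation for "both"/"sc"; the latent
  # coupling that generates the time series carries it for "both"/"fc" --
  # the functional effect is thus coupled to the structural one through the
  # generative mixing rather than injected separately
  w_sc <- if (config$effect_modality %in% c("both", "sc")) w_pert else w_clean
  w_mix <- if (config$effect_modality %in% c("both", "fc")) w_pert else w_clean
  sc <- connectivity_matrix(w_sc, "structural")

  # functional matrix: community latents mixed through the SC backbone
  Tt <- config$t_len
  comm <- config$communities
  Z <- matrix(stats::rnorm(length(unique(comm)) * Tt), ncol = Tt)
  S0 <- Z[match(comm, sort(unique(comm))), , drop = FALSE]
  Wn <- w_mix
  rs <- rowSums(Wn)
  rs[rs == 0] <- 1
  Wn <- Wn / rs
  mix <- 0.4
  C <- (1 - mix) * diag(n) + mix * Wn
  S <- C %*% S0 + config$noise_sd * matrix(stats::rnorm(n * Tt), n, Tt)
  fc <- fc_from_timeseries(S)
  list(sc = sc, fc = fc)
}

#' Simulate a cohort in memory
#'
#' @param config a [synth_config()].
#' @return list of subjects, each `list(id, group, sc, fc)`, groups in
#'   manifest order.
#' @export
simulate_cohort <- function(config) {
  out <- list()
  counter <- 0
  for (g in names(config$n_per_group)) {
    for (i in seq_len(config$n_per_group[[g]])) {
      counter <- counter + 1
      sub <- generate_subject(config, g, derive_seed(config$seed, counter))
      out[[counter]] <- list(id = sprintf("%s%02d", g, i), group = g,
                             sc = sub$sc, fc = sub$fc)
    }
  }
  out
}

#' Write a synthetic cohort to disk
#'
#' Writes per-subject SC and FC matrices as TSV plus a manifest consumable
#' by [read_cohort_manifest()].
#'
#' @param config a [synth_config()].
#' @param dir output directory (created if needed).
#' @return the manifest path, invisibly; the manifest data frame as
#'   attribute `manifest`.
#' @export
generate_cohort <- function(config, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (file.access(dir, 2) != 0) stop("output directory not writable: ", dir)
  subjects <- simulate_cohort(config)
  rows <- lapply(subjects, function(s) {
    scp <- paste0("sc_", s$id, ".tsv")
    fcp <- paste0("fc_", s$id, ".tsv")
    write_connectivity_matrix(s$sc, file.path(dir, scp))
    write_connectivity_matrix(s$fc, file.path(dir, fcp))
    data.frame(subject_id = s$id, group = s$group,
               sc_path = scp, fc_path = fcp)
  })
  manifest <- do.call(rbind, rows)
  mpath <- file.path(dir, "manifest.tsv")
  utils::write.table(manifest, mpath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  out <- invisible(mpath)
  attr(out, "manifest") <- manifest
  out
}
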