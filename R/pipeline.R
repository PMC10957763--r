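#' Run the full analysis pipeline and persist every stage
#'
#' Orchestrates: read cohort -> beta refinement -> multilayer construction ->
#' diffusion walks -> skip-gram embedding -> PCA reconfiguration -> group
#' templates and distances -> nodewise t-tests + cross-validated
#' classification.  All tabular outputs are written as TSV under `out_dir`,
#' together with the resolved configuration and a plain-text log, so a run
#' is auditable and reproducible from its seed.
#'
#' @param subjects cohort manifest path, `cohort_manifest`, or in-memory
#'   subject list (see [mbne()]).
#' @param out_dir output directory, created if needed.
#' @param group_a reference (negative/control) group label.
#' @param group_b positive (patient) group label.
#' @param folds,repeats cross-validation protocol (default 10 x 10).
#' @param test `"welch"` (default) or `"student"` t-test variant.
#' @param seed master seed.
#' @param ... embedding and network parameters forwarded to [mbne()]
#'   (`alpha`, `beta`, `theta`, `p`, `q`, `walk_length`, `walks_per_node`,
#'   `dim`, `window`, `negatives`, `epochs`, `k`).
#' @return invisibly, list with `fit`, `L`, `H`, `stats`, `classification`
#'   and `paths`.
#' @export
run_pipeline <- function(subjects, out_dir, group_a, group_b,
                         folds = 10, repeats = 10,
                         test = c("welch", "student"), seed = 1, ...) {
  test <- match.arg(test)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "run.log")
  logf <- function(...) cat(sprintf(...), "\n", sep = "", file = log_path,
                            append = TRUE)
  cat("", file = log_path)

  stage <- "read"
  result <- tryCatch({
    if (is.character(subjects) || inherits(subjects, "cohort_manifest"))
      subjects <- load_cohort(subjects)
    logf("read: %d subjects", length(subjects))

    stage <- "fit"
    fit <- mbne(subjects, seed = seed, ...)
    logf("fit: d=%d k=%d alpha=%g theta=%g p=%g q=%g lambda=%d r=%d window=%d negatives=%d epochs=%d",
         fit$params$dim, fit$params$k, fit$params$alpha, fit$params$theta,
         fit$params$p, fit$params$q, fit$params$walk_length,
         fit$params$walks_per_node, fit$params$window, fit$params$negatives,
         fit$params$epochs)

    cfg <- c(fit$params, list(group_a = group_a, group_b = group_b,
                              folds = folds, repeats = repeats, test = test,
                              master_seed = seed))
    cfg_path <- file.path(out_dir, "config.txt")
    writeLines(paste(names(cfg), vapply(cfg, format, character(1)),
                     sep = " = "), cfg_path)

    stage <- "reconfigure"
    adir <- file.path(out_dir, "reconfigured")
    dir.create(adir, showWarnings = FALSE)
    for (id in fit$ids)
      utils::write.table(fit$A[[id]]$A, file.path(adir, paste0(id, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE,
                         col.names = FALSE)

    stage <- "distances"
    L <- node_distances(fit, group_a)
    L_path <- file.path(out_dir,
                        sprintf("node_distances_%s_template.tsv", group_a))
    utils::write.table(cbind(subject_id = rownames(L), as.data.frame(L)),
                       L_path, sep = "\t", quote = FALSE, row.names = FALSE)
    H <- network_distances(fit, group_b, group_a)
    H_path <- file.path(out_dir, "network_distances.tsv")
    utils::write.table(cbind(subject_id = rownames(H), group = fit$groups,
                             as.data.frame(H)),
                       H_path, sep = "\t", quote = FALSE, row.names = FALSE)

    stage <- "stats"
    st <- nodewise_ttests(L, fit$groups, group_a, group_b,
                          var_equal = (test == "student"))
    st_path <- file.path(out_dir,
                         sprintf("node_stats_%s_vs_%s.tsv", group_a, group_b))
    utils::write.table(st, st_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    logf("stats: %d of %d regions significant (threshold %.3g)",
         sum(st$significant, na.rm = TRUE), nrow(st), attr(st, "threshold"))

    stage <- "classify"
    cls <- cross_validated_classify(fit$A, fit$groups, positive = group_b,
                                    negative = group_a, folds = folds,
                                    repeats = repeats,
                                    seed = derive_seed(seed, 9999))
    cls_path <- file.path(out_dir, "classification.txt")
    writeLines(c(sprintf("positive = %s", group_b),
                 sprintf("negative = %s", group_a),
                 sprintf("folds = %d", folds),
                 sprintf("repeats = %d", repeats),
                 sprintf("cv_seed = %d", derive_seed(seed, 9999)),
                 sprintf("ACC = %.6f", cls$ACC),
                 sprintf("SEN = %.6f", cls$SEN),
                 sprintf("SPE = %.6f", cls$SPE),
                 sprintf("AUC = %.6f", cls$AUC)),
               cls_path)
    utils::write.table(cls$per_repeat,
                       file.path(out_dir, "classification_per_repeat.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    logf("classify: ACC=%.4f SEN=%.4f SPE=%.4f AUC=%.4f",
         cls$ACC, cls$SEN, cls$SPE, cls$AUC)

    list(fit = fit, L = L, H = H, stats = st, classification = cls,
         paths = list(config = cfg_path, log = log_path, L = L_path,
                      H = H_path, stats = st_path,
                      classification = cls_path))
  }, error = function(e) {
    logf("ERROR at stage '%s': %s", stage, conditionMessage(e))
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  invisible(result)
}
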