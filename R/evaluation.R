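#' Nodewise two-sample t-tests on node distances
#'
#' For each region (column of the node distance matrix L), a two-tailed
#' two-sample t-test compares the two groups' distances to the reference
#' template, with Bonferroni control of the family-wise error: a region is
#' flagged significant when its raw p-value falls below `0.05 / n`.
#'
#' @param L node distance matrix (subjects x regions).
#' @param labels group label per subject (length `nrow(L)`).
#' @param group_a,group_b the two labels to compare (each needs >= 2
#'   subjects).
#' @param var_equal `FALSE` (default) for Welch's unequal-variance test,
#'   `TRUE` for the pooled-variance Student test.
#' @param alpha family-wise error level (default 0.05).
#' @return data frame of class `node_stats_report` with columns `region`,
#'   `t`, `p` and `significant`; regions where both groups have zero
#'   variance get `p = 1` with a warning.
#' @export
nodewise_ttests <- function(L, labels, group_a, group_b, var_equal = FALSE,
                            alpha = 0.05) {
  L <- as.matrix(L)
  if (length(labels) != nrow(L))
    stop("labels length does not match rows of L")
  ia <- labels == group_a
  ib <- labels == group_b
  if (sum(ia) < 2 || sum(ib) < 2)
    stop("both groups need at least 2 subjects")
  n <- ncol(L)
  tt <- rep(NA_real_, n); pp <- rep(NA_real_, n)
  degenerate <- FALSE
  for (i in seq_len(n)) {
    xa <- L[ia, i]; xb <- L[ib, i]
    if (stats::sd(xa) == 0 && stats::sd(xb) == 0) {
      degenerate <- TRUE
      pp[i] <- 1
      next
    }
    ans <- tryCatch(stats::t.test(xa, xb, var.equal = var_equal),
                    error = function(e) NULL)
    if (is.null(ans)) { degenerate <- TRUE; pp[i] <- 1; next }
    tt[i] <- unname(ans$statistic)
    pp[i] <- ans$p.value
  }
  if (degenerate)
    warning("zero within-group variance at some region(s); p recorded as 1")
  out <- data.frame(region = if (!is.null(colnames(L))) colnames(L)
                             else seq_len(n),
                    t = tt, p = pp,
                    significant = pp < alpha / n)
  attr(out, "threshold") <- alpha / n
  attr(out, "groups") <- c(group_a, group_b)
  class(out) <- c("node_stats_report", "data.frame")
  out
}

#' Classification metrics from confusion counts
#'
#' `ACC = (TP + TN) / (TP + FN + TN + FP)`, `SEN = TP / (TP + FN)`,
#' `SPE = TN / (TN + FP)`.  A zero denominator yields `NaN` with a warning.
#'
#' @param TP,TN,FP,FN nonnegative confusion counts.
#' @return named numeric vector `c(ACC, SEN, SPE)`.
#' @export
classification_metrics <- function(TP, TN, FP, FN) {
  TP <- unname(TP); TN <- unname(TN); FP <- unname(FP); FN <- unname(FN)
  if (any(c(TP, TN, FP, FN) < 0)) stop("confusion counts must be nonnegative")
  total <- TP + FN + TN + FP
  safe <- function(num, den, what) {
    if (den == 0) { warning(what, " undefined (zero denominator)"); NaN }
    else num / den
  }
  c(ACC = safe(TP + TN, total, "ACC"),
    SEN = safe(TP, TP + FN, "SEN"),
    SPE = safe(TN, TN + FP, "SPE"))
}

# Mann-Whitney identity: P(score_pos > score_neg) + 0.5 P(tie)
rank_auc <- function(scores, is_pos) {
  np <- sum(is_pos); nn <- sum(!is_pos)
  if (np == 0 || nn == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[is_pos]) - np * (np + 1) / 2) / (np * nn)
}

stratified_folds <- function(labels, folds) {
  assign <- integer(length(labels))
  for (g in unique(labels)) {
    idx <- sample(which(labels == g))
    assign[idx] <- rep_len(seq_len(folds), length(idx))
  }
  assign
}

#' Cross-validated classification from network distances
#'
#' Repeated stratified k-fold classification of two groups.  Within each
#' training fold the network templates (positive/negative group centroids)
#' are rebuilt from training subjects only, the m x 2 network distance
#' matrix H is computed for train and test subjects against those templates,
#' and a linear SVM (C = 1, features standardised by the SVM's default
#' scaling) is fit on the training H.  Metrics are pooled
#' over folds within a repeat and averaged over repeats; AUC comes from the
#' SVM decision values.  Setting `paper_protocol = TRUE` instead computes
#' the templates once from the whole cohort (no leakage guard).
#'
#' @param subjects list of `reconfigured_matrix` objects (one per subject).
#' @param labels group label per subject.
#' @param positive label of the positive class; `negative` defaults to the
#'   other label present.
#' @param folds,repeats cross-validation folds (default 10) and repeats
#'   (default 10).
#' @param seed RNG seed for the fold shuffling.
#' @param paper_protocol use whole-cohort templates (default FALSE).
#' @return object of class `classification_report`: list with `ACC`, `SEN`,
#'   `SPE`, `AUC` (means over repeats), `per_repeat` data frame, pooled
#'   `confusion` counts, and the call parameters.
#' @export
cross_validated_classify <- function(subjects, labels, positive,
                                     negative = NULL, folds = 10,
                                     repeats = 10, seed = 1,
                                     paper_protocol = FALSE) {
  labels <- as.character(labels)
  if (is.null(negative)) {
    others <- setdiff(unique(labels), positive)
    if (length(others) != 1)
      stop("specify `negative`: found labels ", paste(others, collapse = ", "))
    negative <- others
  }
  keep <- labels %in% c(positive, negative)
  subjects <- subjects[keep]
  labels <- labels[keep]
  npos <- sum(labels == positive); nneg <- sum(labels == negative)
  if (min(npos, nneg) < folds)
    stop("smallest class (", min(npos, nneg),
         ") is smaller than the fold count (", folds, ")")
  set.seed(seed)
  per_repeat <- data.frame()
  conf_total <- c(TP = 0, TN = 0, FP = 0, FN = 0)
  for (rep_i in seq_len(repeats)) {
    fold_of <- stratified_folds(labels, folds)
    conf <- c(TP = 0, TN = 0, FP = 0, FN = 0)
    scores <- numeric(length(labels))
    for (f in seq_len(folds)) {
      test <- fold_of == f
      train <- !test
      if (paper_protocol) {
        tmpl <- build_network_templates(subjects[labels == positive],
                                        subjects[labels == negative])
      } else {
        tmpl <- build_network_templates(
          subjects[train & labels == positive],
          subjects[train & labels == negative])
      }
      H_train <- network_distance_matrix(subjects[train],
                                         tmpl$C_plus, tmpl$C_minus)
      H_test <- network_distance_matrix(subjects[test],
                                        tmpl$C_plus, tmpl$C_minus)
      y_train <- factor(labels[train], levels = c(negative, positive))
      fit <- e1071::svm(H_train, y_train, kernel = "linear", cost = 1)
      pred <- stats::predict(fit, H_test, decision.values = TRUE)
      dv <- attr(pred, "decision.values")
      # decision values are signed toward the class named first in the
      # "A/B" column label
      first <- sub("/.*$", "", colnames(dv)[1])
      s <- if (first == positive) dv[, 1] else -dv[, 1]
      scores[test] <- s
      truth <- labels[test]
      is_p <- truth == positive
      conf["TP"] <- conf["TP"] + sum(pred == positive & is_p)
      conf["FN"] <- conf["FN"] + sum(pred != positive & is_p)
      conf["TN"] <- conf["TN"] + sum(pred != positive & !is_p)
      conf["FP"] <- conf["FP"] + sum(pred == positive & !is_p)
    }
    m <- classification_metrics(conf["TP"], conf["TN"], conf["FP"], conf["FN"])
    auc <- rank_auc(scores, labels == positive)
    per_repeat <- rbind(per_repeat,
                        data.frame(repeat_i = rep_i, ACC = m["ACC"],
                                   SEN = m["SEN"], SPE = m["SPE"], AUC = auc,
                                   row.names = NULL))
    conf_total <- conf_total + conf
  }
  structure(list(ACC = mean(per_repeat$ACC), SEN = mean(per_repeat$SEN),
                 SPE = mean(per_repeat$SPE), AUC = mean(per_repeat$AUC),
                 per_repeat = per_repeat, confusion = conf_total,
                 positive = positive, negative = negative, folds = folds,
                 repeats = repeats, seed = seed,
                 paper_protocol = paper_protocol),
            class = "classification_report")
}

#' @export
print.classification_report <- function(x, ...) {
  cat(sprintf("<classification_report> %s vs %s (%d-fold x %d)\n",
              x$positive, x$negative, x$folds, x$repeats))
  cat(sprintf("  ACC %.4f  SEN %.4f  SPE %.4f  AUC %.4f\n",
              x$ACC, x$SEN, x$SPE, x$AUC))
  invisible(x)
}
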