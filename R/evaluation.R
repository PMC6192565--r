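#' Ground-truth-driven benchmarking
#'
#' ROC/AUC analysis of same-vs-different pair discrimination and
#' leave-one-out nearest-neighbor domain classification at each level of
#' the 4-level classification hierarchy (1 = class, 2 = fold,
#' 3 = superfamily, 4 = family).
#'
#' @name evaluation
#' @keywords internal
NULL

#' Hierarchy-level label match
#'
#' Two 4-level dotted labels match at level k iff their first k
#' components are equal.
#'
#' @param labelA,labelB character label(s), e.g. "a.1.1.1" (vectorized).
#' @param level k in 1..4.
#' @return logical.
#' @export
level_match <- function(labelA, labelB, level) {
  stopifnot(level >= 1, level <= 4)
  pre <- function(x) vapply(strsplit(x, ".", fixed = TRUE),
                            function(p) paste(p[seq_len(level)], collapse = "."), "")
  pre(labelA) == pre(labelB)
}

#' ROC curve and AUC for same-vs-different pair discrimination
#'
#' A similarity threshold sweeps from above the maximum score down to
#' below the minimum (the observed unique scores serve as thresholds —
#' an exact, resolution-independent version of a dense grid sweep).
#' Pairs with similarity strictly greater than the threshold are called
#' positive; a pair is truly positive when its two domains match at the
#' chosen hierarchy level. TPR = TP/(TP+FN) and FPR = FP/(FP+TN) per
#' threshold; AUC by the trapezoidal rule.
#'
#' @param similarity numeric similarity scores, one per pair (NAs
#'   dropped with their pairs).
#' @param positive logical truth per pair, or use `labels1`/`labels2` +
#'   `level`.
#' @param labels1,labels2 pair label vectors (alternative to
#'   `positive`).
#' @param level hierarchy level for the label interface.
#' @return list with `points` (data.frame `fpr`, `tpr`, `threshold`) and
#'   `auc`.
#' @export
roc_points <- function(similarity, positive = NULL, labels1 = NULL,
                       labels2 = NULL, level = 3) {
  if (is.null(positive)) positive <- level_match(labels1, labels2, level)
  keep <- !is.na(similarity)
  similarity <- similarity[keep]
  positive <- positive[keep]
  nP <- sum(positive); nN <- sum(!positive)
  if (nP == 0 || nN == 0) stop("ROC undefined: need both classes at this level")
  thr <- c(Inf, sort(unique(similarity), decreasing = TRUE), -Inf)
  ord <- order(similarity, decreasing = TRUE)
  s <- similarity[ord]; y <- positive[ord]
  # counts of scores > t for each threshold
  tp <- vapply(thr, function(t) sum(y & s > t), 0L)
  fp <- vapply(thr, function(t) sum(!y & s > t), 0L)
  tpr <- tp / nP
  fpr <- fp / nN
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  list(points = data.frame(fpr = fpr, tpr = tpr, threshold = thr), auc = auc)
}

#' Leave-one-out nearest-neighbor classification
#'
#' Every domain in turn is treated as a query and assigned the label of
#' its nearest non-self neighbor in the distance matrix; the prediction
#' is correct when it matches the query's own label at the chosen level.
#' Distance ties are broken by the lexicographically smallest neighbor
#' id, making the procedure deterministic.
#'
#' @param D square distance matrix with domain ids as dimnames.
#' @param labels named character vector: domain id -> 4-level label.
#' @param level hierarchy level (1-4).
#' @return list with `fraction_correct`, `predictions` (data.frame:
#'   `domain_id`, `neighbor`, `predicted`, `truth`, `correct`).
#' @export
nn_classify_loo <- function(D, labels, level = 1) {
  ids <- rownames(D)
  stopifnot(!is.null(ids), length(ids) >= 2)
  ord <- order(ids)          # lexicographic candidate order for tie-breaks
  nn <- character(length(ids))
  for (i in seq_along(ids)) {
    cand <- ord[ord != i]
    d <- D[i, cand]
    nn[i] <- ids[cand[which.min(d)]]   # first minimum in lexicographic order
  }
  truth <- labels[ids]
  pred <- labels[nn]
  correct <- level_match(pred, truth, level)
  list(fraction_correct = mean(correct),
       predictions = data.frame(domain_id = ids, neighbor = nn,
                                predicted = unname(pred),
                                truth = unname(truth),
                                correct = correct,
                                stringsAsFactors = FALSE))
}

#' Benchmark every method and consensus scheme on all three views
#'
#' For each data view (original / common / imputed) and each score
#' column (every comparison method, M1-M5 and the median consensus),
#' computes the leave-one-out nearest-neighbor fraction correct at
#' hierarchy levels 1-4 and the ROC AUC at the chosen level. Missing
#' similarities become maximal distance (1) in the nearest-neighbor
#' matrices and are dropped from ROC input; ROC positives are evaluated
#' on unordered pairs (the mirrored orientation carries no extra
#' information).
#'
#' @param result an `mcpsc_result` from [run_consensus()].
#' @param records ground-truth data.frame from [read_ground_truth()].
#' @param roc_level hierarchy level for ROC/AUC (default 3,
#'   superfamily).
#' @param nn_levels hierarchy levels for nearest-neighbor evaluation.
#' @return list with `nn` (data.frame: view, column, level,
#'   fraction_correct) and `auc` (data.frame: view, column, level, auc).
#' @export
evaluate_all <- function(result, records, roc_level = 3, nn_levels = 1:4) {
  labels <- stats::setNames(records$label, records$domain_id)
  columns <- c(result$methods, "m1", "m2", "m3", "m4", "m5", "median")
  nn_rows <- list(); auc_rows <- list()
  for (view in names(result$views)) {
    v <- result$views[[view]]
    unordered <- v$domain1 < v$domain2
    pos <- level_match(labels[v$domain1[unordered]],
                       labels[v$domain2[unordered]], roc_level)
    for (col in columns) {
      D <- build_distance_matrix(v, col, domains = result$domains)
      for (lev in nn_levels) {
        r <- nn_classify_loo(D, labels, lev)
        nn_rows[[length(nn_rows) + 1L]] <-
          data.frame(view = view, column = col, level = lev,
                     fraction_correct = r$fraction_correct,
                     stringsAsFactors = FALSE)
      }
      sim <- v[[col]][unordered]
      auc <- tryCatch(roc_points(sim, positive = pos)$auc,
                      error = function(e) NA_real_)
      auc_rows[[length(auc_rows) + 1L]] <-
        data.frame(view = view, column = col, level = roc_level, auc = auc,
                   stringsAsFactors = FALSE)
    }
  }
  list(nn = do.call(rbind, nn_rows), auc = do.call(rbind, auc_rows))
}
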