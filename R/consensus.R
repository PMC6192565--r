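#' Consensus score calculation
#'
#' The fusion core of the package. Raw pairwise scores are converted to
#' dissimilarities, autoscaled and squashed through a logistic sigmoid to
#' commensurable similarities in (0,1), missing pairs are filled by a
#' local-average scheme, and five consensus schemes plus their median are
#' computed per domain pair:
#'
#' * M1 — generalized mean (q = 1: plain average) of available scores;
#' * M2 — coverage-weighted average (fraction of pairs each method scored);
#' * M3 — M2 with expert multipliers (e.g. structure-agnostic
#'   compression methods down-weighted to one half);
#' * M4 — divergence-weighted: each method weighted by the mean RMS
#'   distance of its scores from the other methods' scores;
#' * M5 — user-supplied weights, or weights learned by a seeded logistic
#'   regression of same-vs-different classification on a small training
#'   fraction of pairs.
#'
#' Per pair, the weights of the m available methods are renormalized to
#' sum to one before averaging; the median consensus is the middle order
#' statistic of M1..M5.
#'
#' @name consensus
#' @keywords internal
NULL

# run expr with a fixed RNG seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Convert a raw score to a dissimilarity
#'
#' Methods reporting similarities are negated (any strictly decreasing
#' transform is equivalent after autoscaling, and negation needs no range
#' assumption); dissimilarity methods pass through.
#'
#' @param raw numeric score(s).
#' @param polarity `"similarity"` or `"dissimilarity"`.
#' @return dissimilarity value(s) X, higher = more different.
#' @export
to_dissimilarity <- function(raw, polarity = c("similarity", "dissimilarity")) {
  polarity <- match.arg(polarity)
  if (polarity == "similarity") -raw else raw
}

#' Fit per-method scaling parameters
#'
#' Mean and population standard deviation of a method's non-missing
#' dissimilarities, the location/scale used by [logistic_scale()].
#'
#' @param x numeric dissimilarities (NAs ignored).
#' @param method optional method name carried in the result.
#' @return list with `method`, `mu`, `sigma`.
#' @export
fit_scaling_params <- function(x, method = NA_character_) {
  x <- x[!is.na(x)]
  if (!length(x)) stop("method has no scores", if (!is.na(method)) paste0(": ", method))
  mu <- mean(x)
  sigma <- sqrt(mean((x - mu)^2))  # population sd
  list(method = method, mu = mu, sigma = sigma)
}

#' Logistic-sigmoid score scaling
#'
#' `S = 1 - 1 / (1 + exp(-(X - mu) / sigma))`: dissimilarities are
#' autoscaled then squashed to similarities in (0,1), strictly decreasing
#' in X. A degenerate method with sigma = 0 (constant scores) maps to the
#' sigmoid midpoint 0.5 everywhere.
#'
#' @param x dissimilarity value(s).
#' @param params list with `mu` and `sigma` from [fit_scaling_params()].
#' @return scaled similarity in (0, 1).
#' @export
logistic_scale <- function(x, params) {
  if (params$sigma < 0) stop("sigma must be >= 0")
  if (params$sigma == 0) return(ifelse(is.na(x), NA_real_, 0.5))
  1 - 1 / (1 + exp(-(x - params$mu) / params$sigma))
}

# vectorized local-average fill of one method's column over the full
# ordered-pair frame: mean of {scores with same first domain} union
# {scores with same second domain}; fallback = global mean
impute_column <- function(s, d1, d2) {
  obs <- !is.na(s)
  if (!any(obs)) stop("method has no scores anywhere; cannot impute")
  sum1 <- tapply(s[obs], d1[obs], sum)
  cnt1 <- tapply(s[obs], d1[obs], length)
  sum2 <- tapply(s[obs], d2[obs], sum)
  cnt2 <- tapply(s[obs], d2[obs], length)
  g <- mean(s[obs])
  miss <- which(!obs)
  a1 <- sum1[d1[miss]]; n1 <- cnt1[d1[miss]]
  a2 <- sum2[d2[miss]]; n2 <- cnt2[d2[miss]]
  a1[is.na(a1)] <- 0; n1[is.na(n1)] <- 0
  a2[is.na(a2)] <- 0; n2[is.na(n2)] <- 0
  tot <- n1 + n2
  fill <- ifelse(tot > 0, (a1 + a2) / tot, g)
  s[miss] <- fill
  s
}

#' Local-average fill of missing pairwise scores
#'
#' For every ordered pair (d_i, d_j) missing for the given method, the
#' scores of all records whose first domain is d_i are merged with the
#' scores of all records whose second domain is d_j, and the mean of that
#' multiset union is imputed; when both sets are empty the method's
#' global mean is used. Only pre-imputation values feed the fill, so the
#' result is deterministic and independent of pair order. Present values
#' are never modified.
#'
#' @param table a mirrored [score_table()] with `scaled` populated.
#' @param method method name to impute.
#' @return the `score_table` with the method's records covering every
#'   ordered pair, `imputed` flag set on filled records.
#' @export
impute_local_average <- function(table, method) {
  full <- full_pair_frame(table$domains)
  rec <- table$records
  mrec <- rec[rec$method == method, , drop = FALSE]
  idx <- match(paste(full$domain1, full$domain2, sep = "\r"),
               paste(mrec$domain1, mrec$domain2, sep = "\r"))
  s <- mrec$scaled[idx]
  filled <- impute_column(s, full$domain1, full$domain2)
  out <- data.frame(domain1 = full$domain1, domain2 = full$domain2,
                    method = method,
                    raw = mrec$raw[idx],
                    dissimilarity = mrec$dissimilarity[idx],
                    scaled = filled,
                    imputed = is.na(s),
                    stringsAsFactors = FALSE)
  score_table(rbind(rec[rec$method != method, , drop = FALSE], out),
              methods = table$methods, domains = table$domains)
}

# all N^2 - N ordered pairs, sorted by domain1 then domain2
full_pair_frame <- function(domains) {
  domains <- sort(domains)
  g <- expand.grid(domain2 = domains, domain1 = domains,
                   stringsAsFactors = FALSE)[, c("domain1", "domain2")]
  g <- g[g$domain1 != g$domain2, , drop = FALSE]
  g <- g[order(g$domain1, g$domain2), , drop = FALSE]
  rownames(g) <- NULL
  g
}

#' Generalized mean of available scores (consensus scheme M1)
#'
#' `((1/m) * sum(S_i^q))^(1/q)`; with the default q = 1 this is the
#' arithmetic mean of the available scaled scores.
#'
#' @param scores numeric vector (NAs = unavailable methods, dropped).
#' @param q exponent, non-zero.
#' @return consensus value.
#' @export
m1_generalized_mean <- function(scores, q = 1) {
  if (q == 0) stop("q must be non-zero")
  s <- scores[!is.na(scores)]
  if (!length(s)) stop("no available scores")
  (sum(s^q) / length(s))^(1 / q)
}

#' Coverage-based method weights (consensus scheme M2)
#'
#' Weight_i = s_i / P: the fraction of the N^2 - N ordered pairs the
#' method scored before imputation.
#'
#' @param table a mirrored [score_table()] (pre-imputation missingness).
#' @return named numeric weight vector over `table$methods`.
#' @export
m2_coverage_weights <- function(table) {
  cov <- method_coverage(table)
  stats::setNames(cov$coverage, cov$method)
}

#' Expert-adjusted coverage weights (consensus scheme M3)
#'
#' M2's coverage weights multiplied by each method's expert prior
#' (default 1; the convention for structure-agnostic compression-based
#' scorers is one half).
#'
#' @param table a mirrored [score_table()].
#' @param specs list of [psc_method()] objects (source of
#'   `expert_weight`), or a named numeric vector of expert weights.
#' @return named numeric weight vector.
#' @export
m3_expert_weights <- function(table, specs) {
  ew <- expert_weight_vector(specs, table$methods)
  if (any(ew <= 0)) stop("expert weights must be > 0")
  m2_coverage_weights(table) * ew[table$methods]
}

expert_weight_vector <- function(specs, methods) {
  if (is.numeric(specs)) {
    ew <- specs
  } else {
    ew <- stats::setNames(vapply(specs, `[[`, 0, "expert_weight"),
                          vapply(specs, `[[`, "", "name"))
  }
  out <- stats::setNames(rep(1, length(methods)), methods)
  out[intersect(names(ew), methods)] <- ew[intersect(names(ew), methods)]
  out
}

#' Divergence-driven method weights (consensus scheme M4)
#'
#' Pairwise method divergence `RMSD_ij = sqrt(mean((S_ki - S_kj)^2))`
#' over the pairs k where both methods have pre-imputation scores;
#' `r_i = (1/M) * sum_j RMSD_ij`; `w_i = r_i / max(r_i)`. When all
#' methods agree exactly (all r_i = 0) the scheme degenerates to equal
#' weights.
#'
#' @param S numeric matrix, ordered pairs x methods, of pre-imputation
#'   scaled scores (NA = missing), or a mirrored [score_table()].
#' @return named numeric weight vector; also carries the divergence
#'   matrix as attribute `rmsd` and the per-method means as `r`.
#' @export
m4_divergence_weights <- function(S) {
  if (inherits(S, "score_table")) S <- score_matrix(S)$S
  M <- ncol(S)
  if (M < 2) stop("divergence weighting needs at least 2 methods")
  methods <- colnames(S)
  rmsd <- matrix(0, M, M, dimnames = list(methods, methods))
  for (i in seq_len(M - 1)) {
    for (j in (i + 1):M) {
      both <- !is.na(S[, i]) & !is.na(S[, j])
      if (!any(both))
        stop("method shares no scored pairs with another method: ",
             methods[i], " / ", methods[j])
      v <- sqrt(mean((S[both, i] - S[both, j])^2))
      rmsd[i, j] <- v
      rmsd[j, i] <- v
    }
  }
  r <- rowSums(rmsd) / M
  w <- if (max(r) == 0) stats::setNames(rep(1, M), methods) else r / max(r)
  attr(w, "rmsd") <- rmsd
  attr(w, "r") <- r
  w
}

#' User-supplied or learned method weights (consensus scheme M5)
#'
#' Explicit mode passes the supplied relative weights through
#' (non-negative, at least one positive). Learn mode fits a logistic
#' regression of same-vs-different classification (at the chosen
#' hierarchy level) on the scaled score matrix, using a seeded random
#' sample of pairs as the training set (default 10%), and returns the
#' normalized absolute coefficients as weights.
#'
#' @param weights named numeric vector of explicit weights (explicit
#'   mode).
#' @param S ordered-pairs x methods scaled score matrix with complete
#'   cases for training (learn mode; the imputed matrix).
#' @param pairs data.frame of `domain1`, `domain2` matching rows of `S`.
#' @param labels named character vector: domain id -> 4-level label.
#' @param level hierarchy level (1-4) defining the positive class.
#' @param train_fraction fraction of pairs sampled for training.
#' @param seed RNG seed for the training sample.
#' @return named numeric weight vector.
#' @export
m5_user_weights <- function(weights = NULL, S = NULL, pairs = NULL,
                            labels = NULL, level = 1,
                            train_fraction = 0.1, seed = 1) {
  if (!is.null(weights)) {
    if (any(weights < 0)) stop("explicit M5 weights must be non-negative")
    if (all(weights == 0)) stop("at least one M5 weight must be positive")
    return(weights)
  }
  stopifnot(!is.null(S), !is.null(pairs), !is.null(labels))
  y <- level_match(labels[pairs$domain1], labels[pairs$domain2], level)
  n <- nrow(S)
  ntrain <- max(2L, round(train_fraction * n))
  idx <- if (train_fraction >= 1) seq_len(n) else
    with_seed(seed, sample.int(n, ntrain))
  ytr <- y[idx]
  if (length(unique(ytr)) < 2)
    stop("training sample contains a single class; increase train_fraction")
  df <- as.data.frame(S[idx, , drop = FALSE])
  df$.y <- as.integer(ytr)
  fit <- suppressWarnings(stats::glm(.y ~ ., data = df, family = stats::binomial()))
  co <- stats::coef(fit)[-1]
  co[is.na(co)] <- 0
  w <- abs(co)
  names(w) <- colnames(S)
  if (sum(w) == 0) stop("degenerate M5 fit: all coefficients zero")
  w / sum(w)
}

#' Weighted consensus of one pair's available scores
#'
#' Renormalizes the weights of the available (non-missing) methods to sum
#' to one and returns the weighted average (schemes M2-M5).
#'
#' @param scores numeric vector of scaled scores (NA = unavailable).
#' @param weights numeric weights aligned with `scores`.
#' @return consensus value.
#' @export
weighted_consensus <- function(scores, weights) {
  avail <- !is.na(scores)
  if (!any(avail)) stop("no available scores")
  w <- weights[avail]
  if (sum(w) == 0) stop("all available methods have zero weight")
  sum(w / sum(w) * scores[avail])
}

#' Median consensus score
#'
#' The middle order statistic of the five consensus scheme values.
#'
#' @param m numeric vector of the five per-pair consensus values.
#' @return the median.
#' @export
median_mcpsc <- function(m) stats::median(m)

# pre-imputation scaled score matrix (ordered pairs x methods) of a
# mirrored table; rows follow full_pair_frame(table$domains)
score_matrix <- function(table, column = "scaled") {
  full <- full_pair_frame(table$domains)
  rec <- table$records
  S <- matrix(NA_real_, nrow(full), length(table$methods),
              dimnames = list(NULL, table$methods))
  fkey <- paste(full$domain1, full$domain2, sep = "\r")
  for (m in table$methods) {
    mrec <- rec[rec$method == m, , drop = FALSE]
    idx <- match(fkey, paste(mrec$domain1, mrec$domain2, sep = "\r"))
    S[, m] <- mrec[[column]][idx]
  }
  list(pairs = full, S = S)
}

# row-wise weighted consensus over an availability mask
consensus_column <- function(S, avail, w) {
  W <- matrix(w[colnames(S)], nrow(S), ncol(S), byrow = TRUE) * avail
  tot <- rowSums(W)
  num <- rowSums(W * ifelse(avail, S, 0))
  m <- rowSums(avail)
  bad <- m > 0 & tot == 0
  if (any(bad)) stop("pair(s) whose available methods all have zero weight")
  out <- num / tot
  out[m == 0] <- NA_real_
  out
}

# row-wise generalized mean over an availability mask
m1_column <- function(S, avail, q = 1) {
  m <- rowSums(avail)
  Sq <- ifelse(avail, S, 0)^q
  Sq[!avail] <- 0
  out <- (rowSums(Sq) / m)^(1 / q)
  out[m == 0] <- NA_real_
  out
}

#' Run the full consensus pipeline
#'
#' Executes, in order: dissimilarity conversion, per-method sigmoid
#' autoscaling, mirroring to the full ordered-pair matrix, local-average
#' imputation per method, consensus schemes M1-M5 and the median. Three
#' evaluation views of the data are emitted:
#'
#' * `original` — pre-imputation scores with missing values retained;
#'   per-pair weights renormalize over the methods actually available;
#' * `common` — the subset of pairs scored by every method;
#' * `imputed` — the fully filled table (all methods treated available).
#'
#' @param table a [score_table()] with `raw` populated (one or both
#'   orientations per pair).
#' @param specs list of [psc_method()] objects for the table's methods
#'   (polarity and expert weights); alternatively a named character
#'   vector of polarities, in which case expert weights default to 1.
#' @param q exponent of the M1 generalized mean.
#' @param m5_weights optional named numeric vector of explicit M5
#'   weights; default equal weights.
#' @param m5_learn optional list(`labels`, `level`, `train_fraction`,
#'   `seed`) activating learned M5 weights (`labels` = named character
#'   vector domain -> label).
#' @return an object of class `mcpsc_result`: list with `views` (each a
#'   wide data.frame: domain1, domain2, per-method scaled scores,
#'   m1..m5, median, per-method imputed flags), `weights`, `scaling`,
#'   `coverage`, `methods`, `domains`.
#' @export
run_consensus <- function(table, specs, q = 1, m5_weights = NULL,
                          m5_learn = NULL) {
  methods <- table$methods
  reserved <- c("domain1", "domain2", paste0("m", 1:5), "median")
  clash <- intersect(methods, reserved)
  if (length(clash))
    stop("method name(s) collide with consensus output columns: ",
         paste(clash, collapse = ", "))
  if (is.character(specs)) {
    pol <- specs
    ew <- stats::setNames(rep(1, length(methods)), methods)
  } else {
    nm <- vapply(specs, `[[`, "", "name")
    pol <- stats::setNames(vapply(specs, `[[`, "", "polarity"), nm)
    ew <- expert_weight_vector(specs, methods)
  }
  missing_pol <- setdiff(methods, names(pol))
  if (length(missing_pol))
    stop("no polarity declared for method(s): ", paste(missing_pol, collapse = ", "))

  rec <- table$records
  rec$dissimilarity <- ifelse(pol[rec$method] == "similarity", -rec$raw, rec$raw)

  scaling <- lapply(methods, function(m)
    fit_scaling_params(rec$dissimilarity[rec$method == m], m))
  names(scaling) <- methods
  rec$scaled <- NA_real_
  for (m in methods) {
    sel <- rec$method == m
    rec$scaled[sel] <- logistic_scale(rec$dissimilarity[sel], scaling[[m]])
  }
  tab <- mirror_symmetric(score_table(rec, methods = methods,
                                      domains = table$domains))

  sm <- score_matrix(tab)
  pairs <- sm$pairs
  S0 <- sm$S                               # pre-imputation
  Simp <- S0
  for (m in methods) Simp[, m] <- impute_column(S0[, m], pairs$domain1, pairs$domain2)

  coverage <- method_coverage(tab)
  w_m2 <- m2_coverage_weights(tab)
  w_m3 <- w_m2 * ew[methods]
  w_m4 <- if (length(methods) >= 2) m4_divergence_weights(S0) else
    stats::setNames(1, methods)
  w_m5 <- if (!is.null(m5_learn)) {
    m5_user_weights(S = Simp, pairs = pairs, labels = m5_learn$labels,
                    level = if (is.null(m5_learn$level)) 1 else m5_learn$level,
                    train_fraction = if (is.null(m5_learn$train_fraction)) 0.1
                                     else m5_learn$train_fraction,
                    seed = if (is.null(m5_learn$seed)) 1 else m5_learn$seed)
  } else if (!is.null(m5_weights)) {
    m5_user_weights(weights = m5_weights)
  } else stats::setNames(rep(1, length(methods)), methods)

  make_view <- function(S, avail, keep) {
    v <- data.frame(pairs[keep, , drop = FALSE],
                    S[keep, , drop = FALSE],
                    check.names = FALSE, stringsAsFactors = FALSE)
    Sk <- S[keep, , drop = FALSE]
    Ak <- avail[keep, , drop = FALSE]
    v$m1 <- m1_column(Sk, Ak, q)
    v$m2 <- consensus_column(Sk, Ak, w_m2)
    v$m3 <- consensus_column(Sk, Ak, w_m3)
    v$m4 <- consensus_column(Sk, Ak, w_m4)
    v$m5 <- consensus_column(Sk, Ak, w_m5)
    cm <- cbind(v$m1, v$m2, v$m3, v$m4, v$m5)
    v$median <- apply(cm, 1, function(r) if (anyNA(r)) NA_real_ else stats::median(r))
    imp_flags <- is.na(S0[keep, , drop = FALSE]) & !is.na(Sk)
    colnames(imp_flags) <- paste0(methods, "_imputed")
    v <- cbind(v, as.data.frame(imp_flags))
    rownames(v) <- NULL
    v
  }
  avail0 <- !is.na(S0)
  all_rows <- rep(TRUE, nrow(pairs))
  views <- list(
    original = make_view(S0, avail0, all_rows),
    common = make_view(S0, avail0, rowSums(avail0) == length(methods)),
    imputed = make_view(Simp, matrix(TRUE, nrow(S0), ncol(S0),
                                     dimnames = dimnames(S0)), all_rows))
  structure(list(views = views,
                 weights = list(m2 = w_m2, m3 = w_m3,
                                m4 = as.numeric(w_m4) |> stats::setNames(methods),
                                m5 = w_m5),
                 scaling = data.frame(
                   method = methods,
                   mu = vapply(scaling, `[[`, 0, "mu"),
                   sigma = vapply(scaling, `[[`, 0, "sigma"),
                   row.names = NULL),
                 coverage = coverage,
                 q = q,
                 methods = methods,
                 domains = sort(table$domains)),
            class = "mcpsc_result")
}

#' @export
print.mcpsc_result <- function(x, ...) {
  cat(sprintf("mcpsc_result: %d domains, methods: %s\n",
              length(x$domains), paste(x$methods, collapse = ", ")))
  cat(sprintf("  views: original (%d pairs), common (%d), imputed (%d)\n",
              nrow(x$views$original), nrow(x$views$common),
              nrow(x$views$imputed)))
  invisible(x)
}
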