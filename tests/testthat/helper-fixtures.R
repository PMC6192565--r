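# Shared fixture builders and independent oracles.

# random small score table: n_dom domains, methods with random polarity,
# ~miss_rate of the unordered pairs dropped per method (the first pair is
# always kept for every method so pairwise method overlap is never empty)
random_small_table <- function(seed, n_dom = NULL, n_meth = NULL,
                               miss_rate = 0.2) {
  set.seed(seed)
  if (is.null(n_dom)) n_dom <- sample(3:5, 1)
  if (is.null(n_meth)) n_meth <- sample(2:3, 1)
  domains <- paste0("d", seq_len(n_dom))
  methods <- paste0("meth", seq_len(n_meth))
  pairs <- t(combn(domains, 2))
  rec <- do.call(rbind, lapply(methods, function(m) {
    keep <- c(TRUE, runif(nrow(pairs) - 1) > miss_rate)
    data.frame(domain1 = pairs[keep, 1], domain2 = pairs[keep, 2],
               method = m, raw = rnorm(sum(keep)),
               stringsAsFactors = FALSE)
  }))
  polarity <- setNames(sample(c("similarity", "dissimilarity"), n_meth,
                              replace = TRUE), methods)
  expert <- setNames(runif(n_meth, 0.5, 2), methods)
  m5w <- setNames(runif(n_meth, 0.1, 1), methods)
  list(table = score_table(rec, methods = methods, domains = domains),
       polarity = polarity, expert = expert, m5w = m5w)
}

specs_from <- function(fix) {
  lapply(names(fix$polarity), function(m)
    psc_method(m, polarity = fix$polarity[[m]], runner = "builtin:usm",
               expert_weight = fix$expert[[m]]))
}

# ---------------------------------------------------------------------------
# Independent brute-force transcription of the consensus mathematics:
# direct per-pair loops over the dissimilarity conversion, sigmoid
# autoscaling, mirroring, local-average imputation, the five weighting
# schemes and the median. Shares no code with the pipeline.
naive_consensus <- function(fix, q = 1) {
  rec <- fix$table$records
  methods <- fix$table$methods
  domains <- sort(fix$table$domains)

  # dissimilarity conversion + per-method autoscaled sigmoid
  X <- numeric(nrow(rec))
  for (i in seq_len(nrow(rec)))
    X[i] <- if (fix$polarity[[rec$method[i]]] == "similarity") -rec$raw[i] else rec$raw[i]
  S <- numeric(nrow(rec))
  for (m in methods) {
    sel <- which(rec$method == m)
    mu <- mean(X[sel])
    sigma <- sqrt(mean((X[sel] - mu)^2))
    for (i in sel)
      S[i] <- if (sigma == 0) 0.5 else 1 - 1 / (1 + exp(-(X[i] - mu) / sigma))
  }
  rec$scaled <- S

  # mirror
  key <- paste(rec$domain1, rec$domain2, rec$method)
  extra <- list()
  for (i in seq_len(nrow(rec))) {
    if (!(paste(rec$domain2[i], rec$domain1[i], rec$method[i]) %in% key)) {
      extra[[length(extra) + 1]] <-
        data.frame(domain1 = rec$domain2[i], domain2 = rec$domain1[i],
                   method = rec$method[i], scaled = rec$scaled[i],
                   stringsAsFactors = FALSE)
    }
  }
  rec <- rbind(rec[, c("domain1", "domain2", "method", "scaled")],
               do.call(rbind, extra))

  # full ordered-pair score matrix, pre-imputation
  full <- expand.grid(domain2 = domains, domain1 = domains,
                      stringsAsFactors = FALSE)[, c("domain1", "domain2")]
  full <- full[full$domain1 != full$domain2, ]
  full <- full[order(full$domain1, full$domain2), ]
  P <- nrow(full)
  S0 <- matrix(NA_real_, P, length(methods), dimnames = list(NULL, methods))
  for (i in seq_len(nrow(rec))) {
    r <- which(full$domain1 == rec$domain1[i] & full$domain2 == rec$domain2[i])
    S0[r, rec$method[i]] <- rec$scaled[i]
  }

  # local average fill: first-domain set union second-domain set
  Simp <- S0
  for (m in methods) {
    g <- mean(S0[, m], na.rm = TRUE)
    for (r in which(is.na(S0[, m]))) {
      set1 <- S0[full$domain1 == full$domain1[r], m]
      set1 <- set1[!is.na(set1)]
      set2 <- S0[full$domain2 == full$domain2[r], m]
      set2 <- set2[!is.na(set2)]
      n_u <- length(set1) + length(set2)
      Simp[r, m] <- if (n_u) (sum(set1) + sum(set2)) / n_u else g
    }
  }

  # scheme weights
  w2 <- colSums(!is.na(S0)) / P
  w3 <- w2 * fix$expert[methods]
  M <- length(methods)
  if (M >= 2) {
    rmsd <- matrix(0, M, M)
    for (i in 1:M) for (j in 1:M) if (i != j) {
      both <- which(!is.na(S0[, i]) & !is.na(S0[, j]))
      rmsd[i, j] <- sqrt(mean((S0[both, i] - S0[both, j])^2))
    }
    r <- numeric(M)
    for (i in 1:M) r[i] <- sum(rmsd[i, ]) / M
    w4 <- if (max(r) == 0) rep(1, M) else r / max(r)
  } else w4 <- 1
  names(w4) <- methods
  w5 <- fix$m5w[methods]

  wavg <- function(s, w) {
    a <- !is.na(s)
    sum((w[a] / sum(w[a])) * s[a])
  }
  consensus_of <- function(Smat, avail) {
    out <- data.frame(full, m1 = NA_real_, m2 = NA_real_, m3 = NA_real_,
                      m4 = NA_real_, m5 = NA_real_, median = NA_real_)
    for (r in seq_len(P)) {
      s <- ifelse(avail[r, ], Smat[r, ], NA_real_)
      if (all(is.na(s))) next
      sv <- s[!is.na(s)]
      out$m1[r] <- (sum(sv^q) / length(sv))^(1 / q)
      out$m2[r] <- wavg(s, w2)
      out$m3[r] <- wavg(s, w3)
      out$m4[r] <- wavg(s, w4)
      out$m5[r] <- wavg(s, w5)
      out$median[r] <- median(c(out$m1[r], out$m2[r], out$m3[r],
                                out$m4[r], out$m5[r]))
    }
    out
  }
  all_avail <- matrix(TRUE, P, M)
  list(pairs = full,
       imputed = consensus_of(Simp, all_avail),
       original = consensus_of(S0, !is.na(S0)),
       S0 = S0, Simp = Simp,
       weights = list(m2 = w2, m3 = w3, m4 = w4, m5 = w5))
}

# brute-force RMSD minimization over proper rotations (Euler angles,
# multi-start Nelder-Mead); independent of the SVD route
rmsd_bruteforce <- function(A, B, n_starts = 24) {
  A <- sweep(A, 2, colMeans(A))
  B <- sweep(B, 2, colMeans(B))
  rotmat <- function(ang) {
    ca <- cos(ang); sa <- sin(ang)
    Rz <- rbind(c(ca[1], -sa[1], 0), c(sa[1], ca[1], 0), c(0, 0, 1))
    Ry <- rbind(c(ca[2], 0, sa[2]), c(0, 1, 0), c(-sa[2], 0, ca[2]))
    Rx <- rbind(c(1, 0, 0), c(0, ca[3], -sa[3]), c(0, sa[3], ca[3]))
    Rz %*% Ry %*% Rx
  }
  obj <- function(ang) sqrt(mean(rowSums((B %*% rotmat(ang) - A)^2)))
  best <- Inf
  set.seed(42)
  for (k in seq_len(n_starts)) {
    res <- optim(runif(3, -pi, pi), obj, method = "Nelder-Mead",
                 control = list(maxit = 2000, reltol = 1e-14))
    best <- min(best, res$value)
  }
  best
}

# AUC via the rank-sum identity: P(score_pos > score_neg) + 0.5 P(equal),
# an independent closed form equal to the trapezoidal ROC area
auc_ranksum <- function(sim, positive) {
  sp <- sim[positive]; sn <- sim[!positive]
  tot <- 0
  for (a in sp) for (b in sn) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(sp) * length(sn))
}

# tiny planted fixture shortcut
small_planted <- function(seed = 1, noise = c(A = 0.05, B = 0.05),
                          coverage = NULL, dpf = 2) {
  cfg <- planted_config(domains_per_family = dpf, method_noise = noise,
                        method_coverage = coverage, seed = seed)
  rec <- generate_labels(cfg)
  list(cfg = cfg, records = rec,
       table = generate_planted_scores(rec, cfg),
       specs = planted_method_specs(cfg))
}

toy_pdb_lines <- function(xyz) {
  vapply(seq_len(nrow(xyz)), function(i)
    sprintf("ATOM  %5d  CA  ALA A%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
            i, i, xyz[i, 1], xyz[i, 2], xyz[i, 3]), "")
}
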