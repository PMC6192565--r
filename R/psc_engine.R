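#' Pluggable pairwise structure-comparison scoring
#'
#' Two self-contained scorers ship with the package: a compression-based
#' universal-similarity-metric (USM) distance over C-alpha contact maps,
#' and a Kabsch-superposition RMSD similarity. Any external comparison
#' program that prints its score to stdout can be plugged in through
#' [psc_method()] with a command template and an extraction regex.
#'
#' @name psc_engine
#' @keywords internal
NULL

#' Declare a pairwise structure-comparison method
#'
#' @param name unique method name.
#' @param polarity whether the raw score grows with similarity
#'   (`"similarity"`) or with difference (`"dissimilarity"`).
#' @param runner `"builtin:usm"`, `"builtin:kabsch"`, or for an external
#'   program a list with `command` (template containing `{pdb1}` and
#'   `{pdb2}` placeholders) and `pattern` (regex whose first capture
#'   group, or first numeric token of the first match, is the score).
#' @param expert_weight prior weight (> 0) used by the expert-weighted
#'   consensus scheme; the convention for structure-agnostic
#'   compression-based methods is 0.5, all others 1.
#' @param timeout seconds allowed per external invocation.
#' @return an object of class `psc_method`.
#' @export
psc_method <- function(name,
                       polarity = c("similarity", "dissimilarity"),
                       runner = "builtin:kabsch",
                       expert_weight = 1.0,
                       timeout = 120) {
  polarity <- match.arg(polarity)
  if (!is.numeric(expert_weight) || expert_weight <= 0)
    stop("expert_weight must be > 0")
  if (is.character(runner)) {
    if (!runner %in% c("builtin:usm", "builtin:kabsch"))
      stop("unknown builtin runner: ", runner)
  } else if (is.list(runner)) {
    if (is.null(runner$command) || is.null(runner$pattern))
      stop("external runner needs 'command' and 'pattern'")
    if (!grepl("{pdb1}", runner$command, fixed = TRUE) ||
        !grepl("{pdb2}", runner$command, fixed = TRUE))
      stop("external command template must contain {pdb1} and {pdb2} placeholders")
  } else stop("runner must be a builtin id or an external command list")
  structure(list(name = name, polarity = polarity, runner = runner,
                 expert_weight = expert_weight, timeout = timeout),
            class = "psc_method")
}

#' Built-in method set
#'
#' The two self-contained scorers: `usm` (compression distance over
#' contact maps, dissimilarity, expert weight 0.5 since it is
#' structure-representation agnostic) and `kabsch` (superposition RMSD
#' similarity, expert weight 1).
#'
#' @return list of [psc_method()] objects.
#' @export
builtin_methods <- function() {
  list(
    psc_method("usm", polarity = "dissimilarity", runner = "builtin:usm",
               expert_weight = 0.5),
    psc_method("kabsch", polarity = "similarity", runner = "builtin:kabsch",
               expert_weight = 1.0))
}

#' Read method specifications from a config file
#'
#' Plain-text blocks, one key=value pair per line, blank-line separated:
#' `name`, `polarity`, `command` (with `{pdb1}`/`{pdb2}`), `pattern`,
#' `expert_weight`, `timeout`; or `builtin=usm|kabsch`. `#` comments
#' allowed.
#'
#' @param path config file path.
#' @return list of [psc_method()] objects.
#' @export
read_method_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("^\\s*#.*$", "", lines)
  blocks <- split(lines, cumsum(!nzchar(trimws(lines))))
  specs <- list()
  for (blk in blocks) {
    blk <- blk[nzchar(trimws(blk))]
    if (!length(blk)) next
    kv <- do.call(rbind, regmatches(blk, regexec("^\\s*([^=]+?)\\s*=\\s*(.*)$", blk)))
    vals <- stats::setNames(kv[, 3], kv[, 2])
    if (!is.na(vals["builtin"])) {
      spec <- psc_method(
        name = if (is.na(vals["name"])) vals[["builtin"]] else vals[["name"]],
        polarity = if (vals[["builtin"]] == "usm") "dissimilarity" else "similarity",
        runner = paste0("builtin:", vals[["builtin"]]),
        expert_weight = if (is.na(vals["expert_weight"])) {
          if (vals[["builtin"]] == "usm") 0.5 else 1.0
        } else as.numeric(vals[["expert_weight"]]))
    } else {
      spec <- psc_method(
        name = vals[["name"]],
        polarity = if (is.na(vals["polarity"])) "similarity" else vals[["polarity"]],
        runner = list(command = vals[["command"]], pattern = vals[["pattern"]]),
        expert_weight = if (is.na(vals["expert_weight"])) 1.0
                        else as.numeric(vals[["expert_weight"]]),
        timeout = if (is.na(vals["timeout"])) 120 else as.numeric(vals[["timeout"]]))
    }
    specs[[spec$name]] <- spec
  }
  unname(specs)
}

#' Enumerate domain pairs for an experiment
#'
#' All-to-all mode returns the N(N-1)/2 unordered pairs as canonically
#' (lexicographically) ordered pairs; pair-list mode filters a supplied
#' pair list to known domains, erroring on unknown ids.
#'
#' @param domains character vector of domain ids (or a data.frame with a
#'   `domain_id` column).
#' @param mode `"all_to_all"` or `"pair_list"`.
#' @param pair_list data.frame with columns `domain1`, `domain2`
#'   (required in pair-list mode).
#' @return data.frame with columns `domain1`, `domain2`.
#' @export
enumerate_pairs <- function(domains, mode = c("all_to_all", "pair_list"),
                            pair_list = NULL) {
  mode <- match.arg(mode)
  if (is.data.frame(domains)) domains <- domains$domain_id
  domains <- as.character(domains)
  if (length(domains) < 2) stop("need at least 2 domains")
  if (mode == "all_to_all") {
    ids <- sort(domains)
    cmb <- utils::combn(ids, 2)
    data.frame(domain1 = cmb[1, ], domain2 = cmb[2, ], stringsAsFactors = FALSE)
  } else {
    if (is.null(pair_list)) stop("pair_list mode requires a pair_list")
    unknown <- setdiff(unique(c(pair_list$domain1, pair_list$domain2)), domains)
    if (length(unknown))
      stop("pair list names unknown domains: ", paste(unknown, collapse = ", "))
    data.frame(domain1 = as.character(pair_list$domain1),
               domain2 = as.character(pair_list$domain2),
               stringsAsFactors = FALSE)
  }
}

#' C-alpha contact map
#'
#' Binary symmetric matrix with entry (i, j) = 1 iff the Euclidean
#' distance between C-alpha atoms i and j is at most `cutoff` and the
#' residues are non-adjacent in sequence (|i - j| >= 2); diagonal 0.
#'
#' @param coords n x 3 coordinate matrix (Angstrom).
#' @param cutoff contact distance cutoff in Angstrom (default 8).
#' @return n x n 0/1 integer matrix.
#' @export
contact_map <- function(coords, cutoff = 8.0) {
  coords <- as.matrix(coords)
  if (nrow(coords) < 2) stop("need at least 2 coordinates")
  if (cutoff <= 0) stop("cutoff must be > 0")
  d <- as.matrix(stats::dist(coords))
  n <- nrow(d)
  seqsep <- abs(outer(seq_len(n), seq_len(n), `-`))
  m <- (d <= cutoff) & (seqsep >= 2)
  storage.mode(m) <- "integer"
  dimnames(m) <- NULL
  m
}

# compressed length in bytes of a contact map's canonical serialization
# (row-major, one byte per cell)
compressed_size <- function(bytes, type) {
  length(memCompress(bytes, type = type))
}

map_bytes <- function(map) {
  as.raw(as.integer(t(map)) + 0x30)  # '0'/'1' characters, row-major
}

#' Compression-based structural distance between two contact maps
#'
#' An approximation of the universal similarity metric using real
#' compressor lengths: with C(x) the compressed byte length of map x's
#' canonical serialization and ab the concatenation,
#' `max(C(ab) - C(a), C(ba) - C(b)) / max(C(a), C(b))`, clamped to >= 0.
#' Values are compressor-dependent; the compressor is fixed per run and
#' recorded in run metadata. Polarity: dissimilarity.
#'
#' @param mapA,mapB binary contact matrices from [contact_map()].
#' @param compressor one of `"gzip"`, `"bzip2"`, `"xz"` (see
#'   [memCompress()]).
#' @return non-negative distance (near 0 for identical maps).
#' @export
usm_distance <- function(mapA, mapB, compressor = "gzip") {
  a <- map_bytes(mapA); b <- map_bytes(mapB)
  ca <- compressed_size(a, compressor)
  cb <- compressed_size(b, compressor)
  cab <- compressed_size(c(a, b), compressor)
  cba <- compressed_size(c(b, a), compressor)
  max(0, max(cab - ca, cba - cb) / max(ca, cb))
}

# optimal rotation (proper, det +1) aligning centered B onto centered A:
# maximizes tr(R' H) for H = B'A, so R = U diag(1,1,d) V' from H = U S V'
kabsch_rotation <- function(A, B) {
  s <- svd(crossprod(B, A))
  d <- sign(det(s$u %*% t(s$v)))
  if (d == 0) d <- 1
  s$u %*% diag(c(1, 1, d)) %*% t(s$v)
}

#' Superposition-based similarity of two C-alpha traces
#'
#' Truncates both traces to their common leading length L, finds the
#' optimal least-squares rigid superposition (Kabsch algorithm,
#' reflection-corrected rotation with determinant +1), and maps the
#' resulting RMSD to a bounded similarity `1 / (1 + RMSD / R0)` with
#' R0 = 3 Angstrom. Polarity: similarity, in (0, 1].
#'
#' @param coordsA,coordsB coordinate matrices (>= 3 rows each).
#' @param r0 RMSD scale constant in Angstrom.
#' @return similarity in (0, 1]; 1 for identical (or rigidly moved)
#'   structures.
#' @export
kabsch_similarity <- function(coordsA, coordsB, r0 = 3.0) {
  A <- as.matrix(coordsA); B <- as.matrix(coordsB)
  if (nrow(A) < 3 || nrow(B) < 3) stop("need at least 3 residues per structure")
  L <- min(nrow(A), nrow(B))
  A <- A[seq_len(L), , drop = FALSE]
  B <- B[seq_len(L), , drop = FALSE]
  A <- sweep(A, 2, colMeans(A))
  B <- sweep(B, 2, colMeans(B))
  R <- kabsch_rotation(A, B)
  diff <- B %*% R - A
  rmsd <- sqrt(sum(diff^2) / L)
  1 / (1 + rmsd / r0)
}

#' Run an external comparison program on one structure pair
#'
#' Substitutes the two PDB paths into the command template, runs it with
#' a timeout, and extracts the score as the first match of the method's
#' stdout pattern (first capture group if the regex has one, otherwise
#' the first numeric token of the match). Non-zero exit, timeout, or no
#' pattern match yield a missing score rather than an error; per-method
#' failures surface downstream as reduced coverage.
#'
#' @param spec a [psc_method()] with an external runner.
#' @param pdb1,pdb2 structure file paths.
#' @return numeric score, or NA on failure.
#' @export
run_external_method <- function(spec, pdb1, pdb2) {
  stopifnot(is.list(spec$runner))
  cmd <- gsub("{pdb1}", shQuote(pdb1), spec$runner$command, fixed = TRUE)
  cmd <- gsub("{pdb2}", shQuote(pdb2), cmd, fixed = TRUE)
  out <- tryCatch(
    suppressWarnings(system(cmd, intern = TRUE, ignore.stderr = TRUE,
                            timeout = spec$timeout)),
    error = function(e) NULL)
  status <- attr(out, "status")
  if (is.null(out) || (!is.null(status) && status != 0)) return(NA_real_)
  m <- regexec(spec$runner$pattern, out)
  hit <- which(vapply(m, function(x) x[1] != -1L, TRUE))
  if (!length(hit)) return(NA_real_)
  groups <- regmatches(out[hit[1]], m[hit[1]])[[1]]
  token <- if (length(groups) >= 2) groups[2] else {
    num <- regmatches(groups[1], regexpr("[-+]?[0-9]*\\.?[0-9]+([eE][-+]?[0-9]+)?", groups[1]))
    if (!length(num)) return(NA_real_)
    num
  }
  val <- suppressWarnings(as.numeric(token))
  if (is.na(val)) NA_real_ else val
}

#' Score all domain pairs with all methods
#'
#' Executes the |pairs| x |methods| fine-grained comparison jobs across
#' `threads` concurrent workers (forked; `threads = 1` runs serially).
#' Results are keyed by (pair, method), never by completion order, so the
#' returned table is identical for any thread count. Failed jobs yield
#' missing scores and reduce that method's coverage; a method whose
#' external binary cannot run is simply absent from the non-missing
#' records.
#'
#' For built-in scorers each structure is read (and its contact map
#' built) once, up front.
#'
#' @param records data.frame from [read_ground_truth()]; `structure_path`
#'   must point at readable PDB files for the domains being compared.
#' @param specs list of [psc_method()] objects.
#' @param pairs data.frame from [enumerate_pairs()]; defaults to
#'   all-to-all over `records`.
#' @param threads worker count p >= 1.
#' @param compressor compressor id for the USM-style scorer.
#' @param contact_cutoff contact-map cutoff in Angstrom.
#' @return a [score_table()] with one record per (pair, method), `raw`
#'   filled (NA = failed job).
#' @export
distribute_jobs <- function(records, specs, pairs = NULL, threads = 1L,
                            compressor = "gzip", contact_cutoff = 8.0) {
  stopifnot(threads >= 1)
  if (is.null(pairs)) pairs <- enumerate_pairs(records)
  names(specs) <- vapply(specs, `[[`, "", "name")
  need_builtin <- any(vapply(specs, function(s) is.character(s$runner), TRUE))
  used <- unique(c(pairs$domain1, pairs$domain2))
  struct <- list()
  if (need_builtin) {
    paths <- stats::setNames(records$structure_path, records$domain_id)
    for (id in used) {
      struct[[id]] <- tryCatch(read_pdb_ca(paths[[id]]), error = function(e) NULL)
    }
  }
  need_usm <- any(vapply(specs, function(s)
    is.character(s$runner) && s$runner == "builtin:usm", TRUE))
  maps <- list()
  if (need_usm) {
    for (id in used) {
      maps[[id]] <- if (is.null(struct[[id]])) NULL else
        tryCatch(contact_map(struct[[id]]$xyz, contact_cutoff),
                 error = function(e) NULL)
    }
  }
  path_of <- stats::setNames(records$structure_path, records$domain_id)

  jobs <- expand.grid(pair = seq_len(nrow(pairs)), method = names(specs),
                      stringsAsFactors = FALSE)
  run_job <- function(i) {
    p <- jobs$pair[i]
    spec <- specs[[jobs$method[i]]]
    d1 <- pairs$domain1[p]; d2 <- pairs$domain2[p]
    if (is.character(spec$runner)) {
      if (spec$runner == "builtin:usm") {
        if (is.null(maps[[d1]]) || is.null(maps[[d2]])) return(NA_real_)
        usm_distance(maps[[d1]], maps[[d2]], compressor)
      } else {
        if (is.null(struct[[d1]]) || is.null(struct[[d2]])) return(NA_real_)
        tryCatch(kabsch_similarity(struct[[d1]]$xyz, struct[[d2]]$xyz),
                 error = function(e) NA_real_)
      }
    } else {
      run_external_method(spec, path_of[[d1]], path_of[[d2]])
    }
  }
  raw <- if (threads == 1L) {
    vapply(seq_len(nrow(jobs)), run_job, 0)
  } else {
    unlist(parallel::mclapply(seq_len(nrow(jobs)), run_job,
                              mc.cores = threads, mc.preschedule = TRUE))
  }
  score_table(
    data.frame(domain1 = pairs$domain1[jobs$pair],
               domain2 = pairs$domain2[jobs$pair],
               method = jobs$method, raw = as.numeric(raw),
               stringsAsFactors = FALSE),
    methods = names(specs),
    domains = sort(unique(records$domain_id)))
}

#' Per-method coverage of a score table
#'
#' Fraction of the N^2 - N ordered pairs with a non-missing raw score,
#' per method (the Table-1-style coverage accounting).
#'
#' @param table a mirrored [score_table()].
#' @return data.frame with `method`, `pairs_scored`, `coverage`.
#' @export
method_coverage <- function(table) {
  n <- length(table$domains)
  P <- n * n - n
  rec <- table$records
  scored <- tapply(!is.na(rec$raw), rec$method, sum)
  scored <- scored[table$methods]
  scored[is.na(scored)] <- 0
  data.frame(method = table$methods,
             pairs_scored = as.integer(scored),
             coverage = as.numeric(scored) / P,
             stringsAsFactors = FALSE, row.names = NULL)
}
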