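#' Domain records, pairwise score tables, and file I/O
#'
#' A dataset of protein domains is described by a ground-truth file mapping
#' each domain identifier to a 4-level hierarchical classification label
#' (class.fold.superfamily.family, SCOP-style, e.g. "a.1.1.1") and,
#' optionally, to a structure file in PDB format. Pairwise comparison
#' results are exchanged between all pipeline stages as a long-format
#' score table.
#'
#' @name score_model
#' @keywords internal
NULL

#' Construct a long-format pairwise score table
#'
#' The central exchange object between scoring, consensus and analysis
#' stages: one row per (domain1, domain2, method) with the raw score, its
#' dissimilarity conversion, the sigmoid-scaled similarity in (0,1) and an
#' imputation flag. Self pairs are excluded by construction, so a fully
#' covered method has at most P = N^2 - N rows after mirroring.
#'
#' @param records data.frame with columns `domain1`, `domain2`, `method`,
#'   and optionally `raw`, `dissimilarity`, `scaled`, `imputed`.
#' @param methods character vector of method names, in presentation order.
#'   Defaults to the methods present in `records`.
#' @param domains character vector of domain ids. Defaults to the ids seen
#'   in `records`.
#' @return An object of class `score_table`: a list with elements
#'   `records`, `methods`, `domains`.
#' @export
score_table <- function(records, methods = NULL, domains = NULL) {
  stopifnot(is.data.frame(records))
  needed <- c("domain1", "domain2", "method")
  missing_cols <- setdiff(needed, names(records))
  if (length(missing_cols))
    stop("score table records lack columns: ", paste(missing_cols, collapse = ", "))
  for (col in c("raw", "dissimilarity", "scaled")) {
    if (is.null(records[[col]])) records[[col]] <- NA_real_
  }
  if (is.null(records$imputed)) records$imputed <- FALSE
  records$domain1 <- as.character(records$domain1)
  records$domain2 <- as.character(records$domain2)
  records$method <- as.character(records$method)
  if (any(records$domain1 == records$domain2))
    stop("self pairs (domain1 == domain2) are not allowed in a score table")
  key <- paste(records$domain1, records$domain2, records$method, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate (domain1, domain2, method) records in score table")
  if (is.null(methods)) methods <- unique(records$method)
  if (is.null(domains)) domains <- sort(unique(c(records$domain1, records$domain2)))
  structure(
    list(records = records[, c("domain1", "domain2", "method", "raw",
                               "dissimilarity", "scaled", "imputed")],
         methods = as.character(methods),
         domains = as.character(domains)),
    class = "score_table")
}

#' @export
print.score_table <- function(x, ...) {
  cat(sprintf("score_table: %d domains, %d methods, %d records\n",
              length(x$domains), length(x$methods), nrow(x$records)))
  invisible(x)
}

#' Read a ground-truth domain classification file
#'
#' One domain per line: whitespace-delimited fields `domain_id`,
#' `dotted 4-level label`, and optionally a structure filename. Lines
#' starting with `#` and blank lines are ignored. The label must have
#' exactly four dot-separated non-empty components
#' (class.fold.superfamily.family).
#'
#' @param path path to the ground-truth file.
#' @param pdb_dir optional directory prepended to relative structure
#'   filenames.
#' @return data.frame with columns `domain_id`, `label`, `structure_path`
#'   (NA when absent), one row per domain.
#' @export
read_ground_truth <- function(path, pdb_dir = NULL) {
  if (!file.exists(path)) stop("ground-truth file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  lines <- lines[keep]
  lineno <- which(keep)
  if (!length(lines)) stop("ground-truth file has no data lines: ", path)
  fields <- strsplit(trimws(lines), "\\s+")
  nf <- lengths(fields)
  if (any(nf < 2))
    stop("ground-truth line ", lineno[which(nf < 2)[1]],
         " has fewer than 2 fields")
  ids <- vapply(fields, `[[`, "", 1L)
  labels <- vapply(fields, `[[`, "", 2L)
  paths <- vapply(fields, function(f) if (length(f) >= 3) f[[3]] else NA_character_, "")
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stop("duplicate domain id in ground truth: ", paste(unique(dup), collapse = ", "))
  parts <- strsplit(labels, ".", fixed = TRUE)
  bad <- which(lengths(parts) != 4L | vapply(parts, function(p) any(!nzchar(p)), TRUE))
  if (length(bad))
    stop("label '", labels[bad[1]], "' on line ", lineno[bad[1]],
         " does not have 4 non-empty dot-separated components")
  if (!is.null(pdb_dir)) {
    rel <- !is.na(paths) & !grepl("^/", paths)
    paths[rel] <- file.path(pdb_dir, paths[rel])
  }
  data.frame(domain_id = ids, label = labels, structure_path = paths,
             stringsAsFactors = FALSE)
}

#' Write a ground-truth classification file
#'
#' Inverse of [read_ground_truth()]: whitespace-delimited
#' `domain_id label [structure_file]` lines.
#'
#' @param records data.frame with `domain_id`, `label`, optionally
#'   `structure_path`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(records, path) {
  lines <- ifelse(is.na(records$structure_path) | !nzchar(records$structure_path),
                  paste(records$domain_id, records$label),
                  paste(records$domain_id, records$label,
                        basename(records$structure_path)))
  writeLines(lines, path)
  invisible(path)
}

#' Read C-alpha coordinates from a PDB file
#'
#' Extracts the C-alpha trace of the first model and first chain
#' encountered: ATOM records with atom name "CA", keeping the first
#' alternate location per residue, in residue order. Coordinates are in
#' Angstrom.
#'
#' @param path path to a PDB-format file.
#' @return list with `xyz` (n x 3 numeric matrix) and `aa` (one-letter
#'   residue codes, "X" for non-standard residues).
#' @export
read_pdb_ca <- function(path) {
  pdb <- suppressWarnings(bio3d::read.pdb(path, multi = FALSE, verbose = FALSE))
  atoms <- pdb$atom
  ca <- atoms[atoms$type == "ATOM" & atoms$elety == "CA", , drop = FALSE]
  if (!nrow(ca)) stop("empty structure (no CA atoms): ", path)
  first_chain <- ca$chain[1]
  ca <- ca[is.na(ca$chain) == is.na(first_chain) &
             (is.na(ca$chain) | ca$chain == first_chain), , drop = FALSE]
  # first altLoc kept per residue
  ca <- ca[!duplicated(paste(ca$resno, ca$insert)), , drop = FALSE]
  xyz <- as.matrix(ca[, c("x", "y", "z")])
  dimnames(xyz) <- NULL
  list(xyz = xyz, aa = bio3d::aa321(ca$resid))
}

#' Mirror a score table to full ordered-pair form
#'
#' Pairwise structural scores are computed once per unordered pair but all
#' downstream bookkeeping uses the full ordered-pair matrix. For every
#' record (a, b, method) lacking its (b, a, method) counterpart, the
#' mirrored record is added with identical scores; existing counterparts
#' are never overwritten. Both orientations carrying different raw scores
#' (possible with asymmetric external methods) are kept with a warning.
#'
#' @param table a [score_table()].
#' @return the mirrored `score_table`. Idempotent.
#' @export
mirror_symmetric <- function(table) {
  rec <- table$records
  key <- paste(rec$domain1, rec$domain2, rec$method, sep = "\r")
  rkey <- paste(rec$domain2, rec$domain1, rec$method, sep = "\r")
  have_rev <- rkey %in% key
  if (any(have_rev)) {
    idx <- match(rkey[have_rev], key)
    fwd <- rec$raw[have_rev]
    rev_ <- rec$raw[idx]
    conflict <- !is.na(fwd) & !is.na(rev_) & fwd != rev_
    if (any(conflict))
      warning(sum(conflict)/2, " record(s) have conflicting scores in the two ",
              "orientations; both kept")
  }
  add <- rec[!have_rev, , drop = FALSE]
  if (nrow(add)) {
    tmp <- add$domain1; add$domain1 <- add$domain2; add$domain2 <- tmp
    rec <- rbind(rec, add)
  }
  score_table(rec, methods = table$methods, domains = table$domains)
}

#' Read a long-format pairwise score CSV
#'
#' Columns: `domain1, domain2, method, score`. Empty score fields denote
#' missing values. This is the precomputed-score entry point that lets the
#' consensus and analysis stages run without any structure files.
#'
#' @param path CSV path.
#' @param methods optional method ordering.
#' @return a [score_table()] with `raw` filled.
#' @export
read_score_csv <- function(path, methods = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("domain1", "domain2", "method", "score")
  if (!all(needed %in% names(df)))
    stop("score CSV must have columns: ", paste(needed, collapse = ", "))
  score_table(data.frame(domain1 = df$domain1, domain2 = df$domain2,
                         method = df$method, raw = as.numeric(df$score),
                         stringsAsFactors = FALSE),
              methods = methods)
}

#' Write a long-format pairwise score CSV
#'
#' @param table a [score_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_score_csv <- function(table, path) {
  rec <- table$records
  out <- data.frame(domain1 = rec$domain1, domain2 = rec$domain2,
                    method = rec$method, score = rec$raw)
  out <- out[order(out$domain1, out$domain2, out$method), ]
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Write a consensus score table to CSV
#'
#' Wide format, one row per ordered domain pair, sorted by domain1 then
#' domain2: the sigmoid-scaled similarity per comparison method, the five
#' consensus scores m1..m5, the median consensus, and one imputation flag
#' per method. Missing values (pre-imputation tables) serialize as empty
#' fields. This is the schema of the pipeline's
#' `processed.imputed.mcpsc.csv` artifact.
#'
#' @param wide data.frame with columns `domain1`, `domain2`, one column
#'   per method, optionally `m1`..`m5`, `median`, and `<method>_imputed`
#'   flags (as produced by [run_consensus()] views).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_consensus_csv <- function(wide, path) {
  stopifnot(all(c("domain1", "domain2") %in% names(wide)))
  out <- wide[order(wide$domain1, wide$domain2), , drop = FALSE]
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a consensus score CSV written by [write_consensus_csv()]
#'
#' @param path CSV path.
#' @return data.frame in the same wide schema.
#' @export
read_consensus_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("domain1", "domain2") %in% names(df)))
    stop("not a consensus CSV (needs domain1, domain2 columns): ", path)
  df
}
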