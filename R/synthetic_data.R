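#' Synthetic fixtures: planted hierarchies, score tables, toy structures
#'
#' Everything the pipeline consumes can be fabricated: a 4-level label
#' hierarchy, multi-method pairwise score tables with planted class
#' structure (dissimilarity gaps growing with the level of label
#' divergence, per-method Gaussian noise and coverage thinning), and toy
#' single-chain PDB files whose C-alpha traces are ideal helices or
#' strands, jittered within families. Every generator is a pure function
#' of (config, seed).
#'
#' @name synthetic_data
#' @keywords internal
NULL

#' Configuration of a planted-hierarchy fixture
#'
#' @param n_classes,folds_per_class,superfams_per_fold,families_per_superfam,domains_per_family
#'   counts (>= 1) at each hierarchy level; total domains is their
#'   product. Defaults give 2x2x2x2x4 = 64 domains.
#' @param level_separations dissimilarity gap contributed by a label
#'   mismatch at each of the four levels (class, fold, superfamily,
#'   family). A pair diverging at level k accumulates the separations of
#'   levels k..4. Defaults (4, 2, 1, 0.5) put same-family pairs at true
#'   dissimilarity 0 and different-class pairs at 7.5.
#' @param method_noise named numeric: per-method Gaussian noise sd on the
#'   true dissimilarity (default 0.25 for unlisted methods).
#' @param method_coverage named numeric in (0, 1\]: per-method fraction
#'   of unordered pairs retained (independent uniform thinning).
#' @param seed RNG seed.
#' @return a `planted_config` list.
#' @export
planted_config <- function(n_classes = 2, folds_per_class = 2,
                           superfams_per_fold = 2, families_per_superfam = 2,
                           domains_per_family = 4,
                           level_separations = c(4, 2, 1, 0.5),
                           method_noise = c(methodA = 0.25, methodB = 0.25,
                                            methodC = 0.25),
                           method_coverage = NULL,
                           seed = 1) {
  counts <- c(n_classes, folds_per_class, superfams_per_fold,
              families_per_superfam, domains_per_family)
  stopifnot(all(counts >= 1), length(level_separations) == 4,
            all(level_separations >= 0))
  if (is.null(method_coverage))
    method_coverage <- stats::setNames(rep(1, length(method_noise)),
                                       names(method_noise))
  stopifnot(all(method_coverage > 0), all(method_coverage <= 1))
  structure(list(n_classes = n_classes, folds_per_class = folds_per_class,
                 superfams_per_fold = superfams_per_fold,
                 families_per_superfam = families_per_superfam,
                 domains_per_family = domains_per_family,
                 level_separations = level_separations,
                 method_noise = method_noise,
                 method_coverage = method_coverage,
                 seed = seed),
            class = "planted_config")
}

#' Enumerate the planted label hierarchy
#'
#' Deterministic enumeration of the configured hierarchy with synthetic
#' ids d0001, d0002, ... and dotted labels (classes a, b, c, ...;
#' numeric fold/superfamily/family components).
#'
#' @param config a [planted_config()].
#' @return data.frame with `domain_id`, `label`, `structure_path` (NA).
#' @export
generate_labels <- function(config) {
  g <- expand.grid(dom = seq_len(config$domains_per_family),
                   fam = seq_len(config$families_per_superfam),
                   sf = seq_len(config$superfams_per_fold),
                   fold = seq_len(config$folds_per_class),
                   cls = seq_len(config$n_classes))
  g <- g[order(g$cls, g$fold, g$sf, g$fam, g$dom), ]
  n <- nrow(g)
  cls_names <- if (config$n_classes <= 26) letters[g$cls] else paste0("c", g$cls)
  data.frame(domain_id = sprintf("d%04d", seq_len(n)),
             label = paste(cls_names, g$fold, g$sf, g$fam, sep = "."),
             structure_path = NA_character_,
             stringsAsFactors = FALSE)
}

# true planted dissimilarity between two labels: sum of the separations
# of every level at which the label prefixes diverge
planted_dissimilarity <- function(labelA, labelB, separations) {
  diverge <- vapply(1:4, function(k) !level_match(labelA, labelB, k),
                    logical(length(labelA)))
  if (is.null(dim(diverge))) diverge <- matrix(diverge, nrow = 1)
  as.numeric(diverge %*% separations)
}

#' Generate a planted multi-method score table
#'
#' For each unordered pair, the true dissimilarity is the sum of the
#' level separations over the levels at which the two labels diverge;
#' each method observes it plus Gaussian noise with its own sd, and its
#' records are then independently thinned to the configured coverage
#' fraction. All draws are seeded. Raw scores carry dissimilarity
#' polarity.
#'
#' @param records label data.frame from [generate_labels()].
#' @param config a [planted_config()].
#' @return a [score_table()] (one canonical orientation per pair).
#' @export
generate_planted_scores <- function(records, config) {
  pairs <- enumerate_pairs(records)
  truth <- planted_dissimilarity(
    records$label[match(pairs$domain1, records$domain_id)],
    records$label[match(pairs$domain2, records$domain_id)],
    config$level_separations)
  methods <- names(config$method_noise)
  out <- with_seed(config$seed, {
    do.call(rbind, lapply(methods, function(m) {
      raw <- truth + stats::rnorm(length(truth), 0, config$method_noise[[m]])
      keep <- stats::runif(length(truth)) <= config$method_coverage[[m]]
      data.frame(domain1 = pairs$domain1[keep], domain2 = pairs$domain2[keep],
                 method = m, raw = raw[keep], stringsAsFactors = FALSE)
    }))
  })
  score_table(out, methods = methods, domains = records$domain_id)
}

#' Method specifications matching a planted score table
#'
#' All planted methods carry dissimilarity polarity and unit expert
#' weight; runners are irrelevant for precomputed tables (a builtin
#' placeholder is used).
#'
#' @param config a [planted_config()].
#' @return list of [psc_method()] objects.
#' @export
planted_method_specs <- function(config) {
  lapply(names(config$method_noise), function(m)
    psc_method(m, polarity = "dissimilarity", runner = "builtin:usm"))
}

# ideal CA traces: alpha-helix (rise 1.5 A/residue, 100 degree turn,
# radius 2.3 A) or extended strand (3.5 A spacing, slight zigzag)
backbone_trace <- function(n, geometry = c("helix", "strand")) {
  geometry <- match.arg(geometry)
  i <- seq_len(n)
  if (geometry == "helix") {
    ang <- (i - 1) * 100 * pi / 180
    cbind(2.3 * cos(ang), 2.3 * sin(ang), (i - 1) * 1.5)
  } else {
    cbind((i - 1) * 3.3, 1.0 * (i %% 2), 0.5 * ((i %/% 2) %% 2))
  }
}

format_pdb_atom <- function(serial, resno, xyz) {
  sprintf("ATOM  %5d  CA  ALA A%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
          serial, resno, xyz[1], xyz[2], xyz[3])
}

#' Write a minimal C-alpha-only PDB file
#'
#' @param xyz n x 3 coordinate matrix.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pdb_ca <- function(xyz, path) {
  lines <- vapply(seq_len(nrow(xyz)), function(i)
    format_pdb_atom(i, i, xyz[i, ]), "")
  writeLines(c(lines, "TER", "END"), path)
  invisible(path)
}

#' Generate toy PDB structures and the matching ground-truth file
#'
#' Each class alternates between helix and strand geometry with its own
#' length regime; each family perturbs the class backbone with a
#' family-specific seeded deformation; domains within a family add small
#' coordinate jitter (sd 0.15 A). Structures are written as minimal
#' single-chain CA-only PDB files alongside a ground-truth file naming
#' them.
#'
#' @param records label data.frame from [generate_labels()].
#' @param outdir output directory (created if needed).
#' @param seed RNG seed.
#' @return the records data.frame with `structure_path` filled; the
#'   ground-truth file is written as `ground_truth.txt` in `outdir`.
#' @export
generate_toy_structures <- function(records, outdir, seed = 1) {
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  if (file.access(outdir, 2) != 0) stop("output directory not writable: ", outdir)
  parts <- strsplit(records$label, ".", fixed = TRUE)
  cls <- vapply(parts, `[[`, "", 1)
  famkey <- vapply(parts, function(p) paste(p, collapse = "."), "")
  cls_ids <- sort(unique(cls))
  records$structure_path <- NA_character_
  with_seed(seed, {
    fam_base <- list()
    for (i in seq_len(nrow(records))) {
      fk <- famkey[i]
      if (is.null(fam_base[[fk]])) {
        ci <- match(cls[i], cls_ids)
        geometry <- if (ci %% 2 == 1) "helix" else "strand"
        len <- 30 + ((ci * 13 + match(fk, sort(unique(famkey))) * 7) %% 51)
        base <- backbone_trace(len, geometry)
        # family-specific smooth deformation distinguishes families
        base <- base + 0.6 * sin(outer(seq_len(len) / len * 2 * pi,
                                       stats::runif(3, 1, 3)))
        fam_base[[fk]] <- base
      }
      base <- fam_base[[fk]]
      xyz <- base + matrix(stats::rnorm(length(base), 0, 0.15), nrow(base), 3)
      path <- file.path(outdir, paste0(records$domain_id[i], ".pdb"))
      write_pdb_ca(xyz, path)
      records$structure_path[i] <- path
    }
  })
  write_ground_truth(records, file.path(outdir, "ground_truth.txt"))
  records
}
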