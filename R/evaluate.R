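# Agreement metrics between an observed and a known module collection.
#
# Relevance is the mean, over observed modules, of the best Jaccard
# index against any known module; recovery is the same with the two
# collections switched.  Precision walks over every gene g of the
# universe and its co-clustered partners g' (the genes sharing at least
# one observed module with g), scoring each pair by
#   min(|M'_gg'|, |M_gg'|) / |M'_gg'|  *  Phi(g, g')
# where M'_gg' / M_gg' are the observed / known modules containing both
# genes and Phi is the mean, over the shared observed modules, of the
# best Jaccard against the shared known modules.  The printed form of
# the pair score leaves the grouping of min(.), Phi and the
# denominator ambiguous; this implementation multiplies Phi by the
# min-overlap ratio.  Empty-set conventions: Phi = 0 when no known
# module contains both genes; a pair with no shared observed module
# contributes 0; a gene in no observed module contributes 0.  Recall is
# precision with the collections switched.

#' Relevance of observed modules to known modules
#'
#' Mean over observed modules of the best Jaccard index against any
#' known module.
#'
#' @param observed,known \code{clam_modules} objects (or named lists of
#'   gene vectors).
#' @return A number in [0, 1].
#' @export
module_relevance <- function(observed, known) {
  O <- as_module_list(observed); K <- as_module_list(known)
  if (length(O) == 0L || length(K) == 0L) stopf("both module sets must be nonempty")
  mean(vapply(O, function(m) max(vapply(K, jaccard, numeric(1L), m)), numeric(1L)))
}

#' Recovery of known modules by observed modules
#'
#' Mean over known modules of the best Jaccard index against any
#' observed module; relevance with the roles switched.
#'
#' @inheritParams module_relevance
#' @return A number in [0, 1].
#' @export
module_recovery <- function(observed, known) module_relevance(known, observed)

as_module_list <- function(x) {
  if (inherits(x, "clam_modules")) x$modules
  else if (is.list(x)) lapply(x, as.character)
  else stopf("expected a clam_modules object or a named list of gene vectors")
}

# Jaccard matrix between two module lists (rows = first argument).
jaccard_matrix <- function(A, B) {
  out <- matrix(0, length(A), length(B), dimnames = list(names(A), names(B)))
  for (i in seq_along(A)) for (j in seq_along(B)) out[i, j] <- jaccard(A[[i]], B[[j]])
  out
}

#' Precision of observed modules against known modules
#'
#' Gene-centric co-clustering agreement; see the file-level notes for
#' the exact pair score and empty-set conventions.
#'
#' @inheritParams module_relevance
#' @param universe Character vector of genes to average over; defaults
#'   to the union of all module members on both sides.  Must contain
#'   every module member.
#' @return A number in [0, 1].
#' @export
module_precision <- function(observed, known, universe = NULL) {
  O <- as_module_list(observed); K <- as_module_list(known)
  if (length(O) == 0L || length(K) == 0L) stopf("both module sets must be nonempty")
  members <- union(unlist(O, use.names = FALSE), unlist(K, use.names = FALSE))
  universe <- universe %||% members
  if (!all(members %in% universe)) stopf("'universe' must contain every module member")
  J <- jaccard_matrix(O, K)
  o_idx <- gene_module_index(O, universe)
  k_idx <- gene_module_index(K, universe)
  partners <- lapply(seq_along(O), function(i) O[[i]])
  total <- 0
  for (g in universe) {
    og <- o_idx[[g]]
    if (length(og) == 0L) next                       # E = {g}, self-pair term is 0
    Eg <- unique(unlist(partners[og], use.names = FALSE))
    acc <- 0
    for (gp in Eg) {
      mo <- intersect(og, o_idx[[gp]])
      if (length(mo) == 0L) next
      mk <- intersect(k_idx[[g]], k_idx[[gp]])
      if (length(mk) == 0L) next                     # Phi = 0
      Jsub <- J[mo, mk, drop = FALSE]
      phi <- mean(apply(Jsub, 1L, max))
      acc <- acc + min(length(mo), length(mk)) / length(mo) * phi
    }
    total <- total + acc / length(Eg)
  }
  total / length(universe)
}

# Named list: gene -> integer indices of modules containing it.
gene_module_index <- function(mods, universe) {
  idx <- stats::setNames(vector("list", length(universe)), universe)
  for (i in seq_along(mods)) {
    for (g in mods[[i]]) idx[[g]] <- c(idx[[g]], i)
  }
  idx
}

#' Recall of observed modules against known modules
#'
#' Precision with the observed and known collections switched.
#'
#' @inheritParams module_precision
#' @return A number in [0, 1].
#' @export
module_recall <- function(observed, known, universe = NULL)
  module_precision(known, observed, universe = universe)

# One permuted version of a module collection: a random relabelling of
# the union of its member genes, preserving module count, sizes and
# overlap structure.
permute_module_set <- function(mods, pool = NULL) {
  mods <- as_module_list(mods)
  genes <- unique(unlist(mods, use.names = FALSE))
  pool <- pool %||% genes
  relab <- stats::setNames(sample(pool, length(genes)), genes)
  lapply(mods, function(m) unname(relab[m]))
}

#' Score observed modules against a known collection
#'
#' Computes the four raw agreement scores (precision, recall,
#' relevance, recovery), normalises each by its mean over \code{B}
#' permuted versions of the known modules (random relabellings of the
#' known member genes that preserve module count, sizes and overlaps),
#' and summarises the normalised scores by their harmonic mean.
#'
#' @inheritParams module_precision
#' @param B Number of permutations, default 500.
#' @param seed Seed for the permutation draw.
#' @return An object of class \code{clam_eval}: list with \code{raw},
#'   \code{normalized}, \code{overall}, \code{permuted_means},
#'   \code{B} and \code{seed}.  A normalised score whose permutation
#'   baseline is 0 is reported as \code{Inf} and flagged.
#' @export
evaluate_modules <- function(observed, known, universe = NULL, B = 500, seed = 1) {
  if (B < 1) stopf("'B' must be >= 1")
  O <- as_module_list(observed); K <- as_module_list(known)
  members <- union(unlist(O, use.names = FALSE), unlist(K, use.names = FALSE))
  universe <- universe %||% members
  raw <- c(precision = module_precision(O, K, universe),
           recall = module_recall(O, K, universe),
           relevance = module_relevance(O, K),
           recovery = module_recovery(O, K))
  if (!is.null(seed)) set.seed(seed)
  perm <- matrix(NA_real_, B, 4L, dimnames = list(NULL, names(raw)))
  for (b in seq_len(B)) {
    Kp <- permute_module_set(K)
    uni_b <- union(universe, unlist(Kp, use.names = FALSE))
    perm[b, ] <- c(module_precision(O, Kp, uni_b),
                   module_recall(O, Kp, uni_b),
                   module_relevance(O, Kp),
                   module_recovery(O, Kp))
  }
  pm <- colMeans(perm)
  normalized <- ifelse(pm == 0, Inf, raw / pm)
  overall <- if (any(!is.finite(normalized))) Inf else harmonic_mean(normalized)
  structure(list(raw = raw, normalized = normalized, overall = overall,
                 permuted_means = pm, B = B, seed = seed,
                 degenerate_baseline = any(pm == 0)),
            class = "clam_eval")
}

#' @export
print.clam_eval <- function(x, digits = 3, ...) {
  cat(sprintf("Module evaluation (B = %d permutations)\n", x$B))
  tab <- rbind(raw = x$raw, normalized = x$normalized)
  print(round(tab, digits))
  cat(sprintf("overall (harmonic mean of normalized): %s\n",
              format(round(x$overall, digits))))
  if (isTRUE(x$degenerate_baseline))
    cat("note: at least one permutation baseline was 0; normalized score reported as Inf\n")
  invisible(x)
}

#' Harmonic-mean summary of normalised scores
#'
#' @param normalized Numeric vector of non-negative normalised scores.
#' @return Their harmonic mean; 0 if any score is 0.
#' @export
overall_score <- function(normalized) harmonic_mean(normalized)

#' Cross-validated evaluation of an interaction-assisted pipeline
#'
#' Splits the known modules at the module level into \code{folds}
#' folds, so held-out modules are fully unseen.  For each fold the
#' \code{runner} receives the training-fold module set (e.g. to derive
#' training-only interaction priors) and must return an observed module
#' set, which is scored against the held-out fold.
#'
#' @param known A \code{clam_modules} collection of known modules.
#' @param runner Function taking the training \code{clam_modules} and
#'   returning an observed module set.
#' @param folds Number of folds, default 5.
#' @param seed Seed for the fold split.
#' @param B Permutations per fold evaluation, default 50.
#' @param universe Optional gene universe passed to
#'   [evaluate_modules()].
#' @return List with per-fold \code{clam_eval} reports, the fold
#'   assignment and the mean overall score.
#' @export
clam_crossvalidate <- function(known, runner, folds = 5, seed = 1, B = 50,
                               universe = NULL) {
  K <- as_module_list(known)
  if (folds < 2) stopf("'folds' must be >= 2")
  if (length(K) < folds) stopf("fewer modules (%d) than folds (%d)", length(K), folds)
  if (!is.null(seed)) set.seed(seed)
  shuffled <- sample(names(K))
  fold_of <- stats::setNames(rep(seq_len(folds), length.out = length(K)), shuffled)
  fold_of <- fold_of[names(K)]
  reports <- vector("list", folds)
  for (f in seq_len(folds)) {
    train <- module_set(K[fold_of != f])
    heldout <- module_set(K[fold_of == f])
    observed <- runner(train)
    reports[[f]] <- evaluate_modules(observed, heldout, universe = universe,
                                     B = B, seed = if (is.null(seed)) NULL else seed + f)
  }
  list(folds = reports, fold_assignment = fold_of,
       mean_overall = mean(vapply(reports, `[[`, numeric(1L), "overall")))
}
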