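# The top-level model fit: preprocess each omics layer, build and fuse
# the neighbourhood graphs, adjust by interaction priors, seed and
# propagate membership vectors, and return a classed fit object.

#' Detect co-expressed gene modules across omics layers
#'
#' Fits the full trans-omics module model to one or more expression
#' matrices.  The pipeline is deterministic: per-dataset similarity and
#' k-nearest-neighbour weights, fusion over the union of genes,
#' optional reweighting by interaction-derived prior correlation
#' probabilities, density-based centre/outlier detection, and local
#' approximation of membership vectors to a fixed point.
#'
#' @param datasets A genes-x-samples expression matrix or a list of
#'   them (one per omics layer); \code{NA} entries are allowed and are
#'   handled by [filter_missing()] and [impute_knn()].
#' @param interactions Optional \code{clam_interactions} database; when
#'   supplied (and \code{prior = TRUE}) edge weights are adjusted by
#'   co-regulation priors.
#' @param k Neighbours per object within each dataset, default 10.
#'   Larger k yields fewer, larger modules.
#' @param measure Similarity measure, see [similarity()].
#' @param absolute For Pearson similarity, use |r| (default).
#' @param prior Apply the interaction prior; defaults to \code{TRUE}
#'   whenever \code{interactions} is supplied.
#' @param prior_temperature Softmax temperature of the prior.
#' @param prior_include_pathways Treat pathway co-membership as an
#'   interaction, see [coregulation_scores()].
#' @param prior_renormalize Rescale weights to sum to 1 after the
#'   prior, see [apply_prior()].
#' @param merge_identifiers If \code{TRUE} (default) the same gene
#'   identifier measured in several layers is one object, as the fusion
#'   step assumes; if \code{FALSE} each layer's measurement becomes a
#'   distinct object named \code{<gene>@<dataset_id>}.
#' @param max_missing,impute_k Preprocessing parameters, see
#'   [filter_missing()] and [impute_knn()].
#' @param outlier_threshold Density bound for outlier seeds, see
#'   [find_centers_outliers()].
#' @param tol,max_iter Convergence controls, see
#'   [iterate_membership()].
#' @param min_module_size Optional floor below which modules are folded
#'   into the outlier set; \code{NULL} keeps all modules.
#' @param verbose Emit per-stage progress messages.
#' @return An object of class \code{"clam"} with components
#'   \code{modules} (a [module_set()]), \code{membership},
#'   \code{density}, \code{roles}, \code{centers}, \code{graph} (the
#'   fused, prior-adjusted graph), \code{E} (objective trace),
#'   \code{iterations}, \code{converged} and \code{config}.
#' @seealso [evaluate_modules()], [clam_survival()], [clam_simulate()]
#' @examples
#' sim <- clam_simulate(n_modules = 3, module_size = 8, n_background = 20,
#'                      n_samples = 30, seed = 1)
#' fit <- clam(sim$datasets, sim$interactions, k = 5)
#' fit
#' @export
clam <- function(datasets, interactions = NULL, k = 10,
                 measure = c("pearson", "euclidean", "mutual_information"),
                 absolute = TRUE,
                 prior = !is.null(interactions), prior_temperature = 1,
                 prior_include_pathways = TRUE, prior_renormalize = TRUE,
                 merge_identifiers = TRUE,
                 max_missing = 0.20, impute_k = 10,
                 outlier_threshold = "mean",
                 tol = 1e-6, max_iter = 500, min_module_size = NULL,
                 verbose = FALSE) {
  cl <- match.call()
  measure <- match.arg(measure)
  if (is.matrix(datasets)) datasets <- list(datasets)
  if (length(datasets) == 0L) stopf("need at least one dataset")
  say <- function(...) if (verbose) message(sprintf(...))
  ids <- vapply(seq_along(datasets), function(i) {
    attr(datasets[[i]], "dataset_id") %||% names(datasets)[i] %||% paste0("dataset", i)
  }, character(1L))
  if (anyDuplicated(ids)) stopf("dataset ids must be unique")
  graphs <- vector("list", length(datasets))
  for (i in seq_along(datasets)) {
    mat <- expression_matrix(unclass(datasets[[i]]), ids[i])
    if (anyNA(mat)) {
      mat <- filter_missing(mat, max_missing)
      mat <- impute_knn(mat, impute_k)
    }
    if (!merge_identifiers)
      rownames(mat) <- paste0(rownames(mat), "@", ids[i])
    say("[%s] %d genes x %d samples: similarity (%s) + %d-NN graph",
        ids[i], nrow(mat), ncol(mat), measure, k)
    sim <- similarity(mat, measure, absolute = absolute)
    graphs[[i]] <- knn_weights(sim, k, source = ids[i])
  }
  fused <- fuse(graphs)
  say("fused graph: %d objects, %d edges", length(fused$objects), nrow(fused$edges))
  if (prior) {
    if (is.null(interactions)) stopf("'prior = TRUE' requires an interaction database")
    fused <- apply_prior(fused, interactions, temperature = prior_temperature,
                         include_pathways = prior_include_pathways,
                         renormalize = prior_renormalize)
    say("interaction prior applied")
  }
  density <- compute_density(fused)
  roles <- find_centers_outliers(density, fused, outlier_threshold = outlier_threshold)
  say("roles: %d centres, %d outliers, %d ordinary",
      sum(roles == "center"), sum(roles == "outlier"), sum(roles == "ordinary"))
  P0 <- init_membership(roles)
  it <- iterate_membership(P0, fused, roles, tol = tol, max_iter = max_iter)
  say("converged in %d iterations (E = %.4g)", it$iterations, it$E[length(it$E)])
  modules <- assign_modules(it$membership, min_module_size = min_module_size)
  structure(list(
    modules = modules,
    membership = it$membership,
    density = density,
    roles = roles,
    centers = attr(it$membership, "centers"),
    graph = fused,
    E = it$E,
    iterations = it$iterations,
    converged = it$converged,
    config = list(k = k, measure = measure, absolute = absolute, prior = prior,
                  prior_temperature = prior_temperature,
                  prior_include_pathways = prior_include_pathways,
                  prior_renormalize = prior_renormalize,
                  merge_identifiers = merge_identifiers,
                  outlier_threshold = outlier_threshold,
                  max_missing = max_missing, impute_k = impute_k,
                  tol = tol, max_iter = max_iter,
                  min_module_size = min_module_size,
                  datasets = ids),
    call = cl), class = "clam")
}

#' @export
print.clam <- function(x, ...) {
  cat("Trans-omics co-expression module fit\n")
  cat(sprintf("  datasets: %s; k = %d; similarity = %s; prior %s\n",
              paste(x$config$datasets, collapse = ", "), x$config$k,
              x$config$measure, if (x$config$prior) "on" else "off"))
  cat(sprintf("  %d objects -> %d modules + %d outliers (%d iterations, E = %.4g)\n",
              nrow(x$membership), length(x$modules$modules),
              length(x$modules$outliers), x$iterations, x$E[length(x$E)]))
  invisible(x)
}

#' @export
summary.clam <- function(object, ...) {
  sizes <- lengths(object$modules$modules)
  structure(list(
    n_objects = nrow(object$membership),
    n_modules = length(sizes),
    sizes = sizes,
    n_outliers = length(object$modules$outliers),
    roles = table(object$roles),
    iterations = object$iterations,
    converged = object$converged,
    E_final = object$E[length(object$E)],
    config = object$config), class = "summary.clam")
}

#' @export
print.summary.clam <- function(x, ...) {
  cat(sprintf("Module fit over %d objects (%s)\n", x$n_objects,
              paste(x$config$datasets, collapse = " + ")))
  cat(sprintf("  %d modules (sizes %s), %d outliers\n", x$n_modules,
              paste(range(x$sizes), collapse = "-"), x$n_outliers))
  rc <- function(role) if (role %in% names(x$roles)) x$roles[[role]] else 0L
  cat(sprintf("  roles: %d centres / %d outliers / %d ordinary\n",
              rc("center"), rc("outlier"), rc("ordinary")))
  cat(sprintf("  %s after %d iterations, E = %.4g\n",
              if (x$converged) "converged" else "NOT converged",
              x$iterations, x$E_final))
  invisible(x)
}

#' Hard module assignments of a fit
#'
#' @param object A \code{clam} fit.
#' @param ... Unused.
#' @return Named factor: module id per gene, with level
#'   \code{"outlier"} for unassigned genes.
#' @export
fitted.clam <- function(object, ...) {
  ms <- object$modules
  lab <- stats::setNames(rep("outlier", nrow(object$membership)),
                         rownames(object$membership))
  for (m in names(ms$modules)) lab[ms$modules[[m]]] <- m
  factor(lab, levels = c(names(ms$modules), "outlier"))
}

#' Per-object local approximation residuals
#'
#' The Euclidean norm of \eqn{p_x - \sum_y w_{xy} p_y} at the fitted
#' state; the sum of its squares is the final objective E.
#'
#' @param object A \code{clam} fit.
#' @param ... Unused.
#' @return Named numeric vector.
#' @export
residuals.clam <- function(object, ...) {
  W <- graph_matrices(object$graph, rownames(object$membership))$W
  approx <- as.matrix(W %*% object$membership)
  stats::setNames(sqrt(rowSums((object$membership - approx)^2)),
                  rownames(object$membership))
}

#' Membership vectors of a fit
#' @param object A \code{clam} fit.
#' @param ... Unused.
#' @return Objects x (M+1) membership matrix (last column = outlier
#'   slot).
#' @export
coef.clam <- function(object, ...) object$membership

#' Diagnostic plots for a module fit
#'
#' Left: the objective E across iterations.  Right: the density of
#' every object coloured by role, centres highlighted.
#'
#' @param x A \code{clam} fit.
#' @param ... Passed to \code{plot}.
#' @export
plot.clam <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  graphics::plot(seq_along(x$E) - 1L, x$E, type = "b", pch = 16, cex = 0.6,
                 xlab = "iteration", ylab = "E", main = "approximation objective", ...)
  cols <- c(center = "firebrick", outlier = "grey50", ordinary = "steelblue")
  graphics::plot(seq_along(x$density), sort(x$density, decreasing = TRUE),
                 type = "n", xlab = "rank", ylab = "density", main = "object densities")
  ord <- order(-x$density)
  graphics::points(seq_along(ord), x$density[ord], pch = 16, cex = 0.6,
                   col = cols[x$roles[ord]])
  graphics::legend("topright", legend = names(cols), col = cols, pch = 16, bty = "n")
  invisible(x)
}

#' Write the per-gene assignment table of a fit
#'
#' TSV with the gene, its module (or outlier), its role, density and
#' the full membership vector.
#'
#' @param fit A \code{clam} fit.
#' @param path Output path.
#' @export
write_assignments <- function(fit, path) {
  lab <- fitted(fit)
  df <- data.frame(gene = names(lab), module = as.character(lab),
                   role = fit$roles[names(lab)],
                   density = fit$density[names(lab)],
                   round(fit$membership[names(lab), , drop = FALSE], 6),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
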