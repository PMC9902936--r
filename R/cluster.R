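# Density-based seeding and local approximation of membership vectors.
#
# Each object's density is the mean similarity to its neighbours in the
# fused graph.  Objects strictly denser than every neighbour become
# cluster centres, objects strictly less dense than every neighbour
# become outliers.  Centres and outliers are pinned to one-hot
# membership vectors; every other object starts uniform over the M+1
# slots (M clusters plus an outlier slot) and is updated synchronously
# by the weighted average of its neighbours' vectors until the vectors
# stop changing.  The objective E = sum_x ||p_x - sum_y w_xy p_y||^2 is
# recorded along the way.

#' Local density of every object in a neighbourhood graph
#'
#' Density of an object is the arithmetic mean of the (possibly fused)
#' similarity values along its neighbour list.
#'
#' @param graph A \code{clam_graph}.
#' @return Named numeric vector of densities.
#' @export
compute_density <- function(graph) {
  s <- rowsum(graph$edges$similarity, graph$edges$object, reorder = FALSE)
  n <- rowsum(rep(1, nrow(graph$edges)), graph$edges$object, reorder = FALSE)
  rho <- stats::setNames((s / n)[, 1L], rownames(s))
  rho[graph$objects]
}

#' Classify objects as cluster centres, outliers or ordinary
#'
#' A centre has density strictly greater than all objects in its
#' neighbour list; an outlier has density strictly lower than all of
#' them and, by default, below the mean density.  Ties leave an object
#' ordinary.  The extra threshold follows the local-approximation
#' clustering scheme this procedure is built on: without it every
#' dense module would contain one outlier (its internal density
#' minimum) acting as an absorbing sink that erodes the module from
#' within.  Raising k merges neighbourhoods and can only reduce the
#' number of local density maxima, so fewer centres (hence fewer
#' modules) are found at larger k.
#'
#' @param density Named density vector from [compute_density()].
#' @param graph The graph the densities were computed on.
#' @param outlier_threshold Upper density bound for outliers:
#'   \code{"mean"} (default, the mean density), a number, or
#'   \code{"none"} to label every local density minimum an outlier.
#' @return Named character vector with values \code{"center"},
#'   \code{"outlier"} or \code{"ordinary"}.
#' @export
find_centers_outliers <- function(density, graph, outlier_threshold = "mean") {
  thr <- if (identical(outlier_threshold, "mean")) mean(density)
         else if (identical(outlier_threshold, "none")) Inf
         else as.numeric(outlier_threshold)
  idx <- split(graph$edges$neighbor, graph$edges$object)
  roles <- stats::setNames(rep("ordinary", length(graph$objects)), graph$objects)
  for (x in names(idx)) {
    nb <- density[idx[[x]]]
    if (all(density[x] > nb)) roles[x] <- "center"
    else if (all(density[x] < nb) && density[x] < thr) roles[x] <- "outlier"
  }
  if (!any(roles == "center"))
    stopf("no cluster centres found; densities may be too uniform -- try a smaller k")
  roles
}

#' Initial membership state
#'
#' Centres are one-hot on their own cluster (clusters numbered by the
#' lexicographic order of their centre genes), outliers one-hot on the
#' final slot, and ordinary objects uniform at 1/(M+1).
#'
#' @param roles Role vector from [find_centers_outliers()].
#' @return Numeric matrix, objects x (M+1); attribute \code{centers}
#'   records the centre gene of each cluster.
#' @export
init_membership <- function(roles) {
  centers <- sort(names(roles)[roles == "center"])
  M <- length(centers)
  if (M < 1L) stopf("need at least one cluster centre")
  P <- matrix(1 / (M + 1), nrow = length(roles), ncol = M + 1L,
              dimnames = list(names(roles), c(centers, ".outlier")))
  for (i in seq_along(centers)) P[centers[i], ] <- c(tabulate(i, M), 0)
  out <- names(roles)[roles == "outlier"]
  P[out, ] <- rep(c(numeric(M), 1), each = length(out))
  attr(P, "centers") <- centers
  P
}

#' Iterate membership vectors to their fixed point
#'
#' Synchronous (Jacobi) updates: every ordinary object's vector is
#' replaced by the weighted average of its neighbours' vectors,
#' \eqn{p_x \leftarrow \sum_{y} w_{xy} p_y}; centres and outliers stay
#' fixed.  When the weight rows do not sum to 1 (prior applied without
#' renormalisation) each updated vector is projected back to the
#' simplex by L1 normalisation.  Iteration stops when the largest
#' absolute per-entry change falls below \code{tol}.
#'
#' @param P Membership matrix from [init_membership()].
#' @param graph The fused, prior-adjusted \code{clam_graph}.
#' @param roles Role vector.
#' @param tol Convergence tolerance on the max absolute change,
#'   default 1e-6.
#' @param max_iter Iteration cap, default 500; non-convergence is a
#'   warning, not an error.
#' @return List with the final membership matrix, the objective trace
#'   \code{E} (initial state first), the iteration count and a
#'   convergence flag.
#' @export
iterate_membership <- function(P, graph, roles, tol = 1e-6, max_iter = 500) {
  W <- graph_matrices(graph, rownames(P))$W
  rs <- Matrix::rowSums(W)
  renormalized <- max(abs(rs - 1)) < 1e-8
  fixed <- roles[rownames(P)] != "ordinary"
  objective <- function(P) {
    approx <- as.matrix(W %*% P)
    sum((P - approx)^2)
  }
  E <- objective(P)
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    Pn <- as.matrix(W %*% P)
    if (!renormalized) Pn <- Pn / rowSums(Pn)
    Pn[fixed, ] <- P[fixed, , drop = FALSE]
    if (min(Pn) < -1e-12 || max(abs(rowSums(Pn) - 1)) > 1e-8)
      stopf("membership vectors left the probability simplex (internal error)")
    delta <- max(abs(Pn - P))
    P <- Pn
    E <- c(E, objective(P))
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warnf("membership iteration did not converge in %d iterations (E = %.3g)",
          max_iter, E[length(E)])
  list(membership = P, E = E, iterations = iter, converged = converged)
}

#' Hard module assignment from converged membership vectors
#'
#' Every object joins the cluster with the highest membership score;
#' ties go to the lowest cluster index (the outlier slot is last, so a
#' cluster wins a tie against it).  Objects whose argmax is the outlier
#' slot form the outlier set.
#'
#' @param P Converged membership matrix.
#' @param min_module_size Modules smaller than this are folded into the
#'   outlier set; \code{NULL} (default) keeps all modules.
#' @return A \code{clam_modules} object; module ids \code{M1, M2, ...}
#'   follow cluster order and descriptions record the centre genes.
#' @export
assign_modules <- function(P, min_module_size = NULL) {
  M <- ncol(P) - 1L
  slot <- apply(P, 1L, which.max)
  centers <- attr(P, "centers") %||% colnames(P)[seq_len(M)]
  ids <- sprintf("M%d", seq_len(M))
  mods <- lapply(seq_len(M), function(i) sort(rownames(P)[slot == i]))
  names(mods) <- ids
  outliers <- sort(rownames(P)[slot == M + 1L])
  keep <- rep(TRUE, M)
  if (!is.null(min_module_size)) {
    keep <- lengths(mods) >= min_module_size
    outliers <- sort(c(outliers, unlist(mods[!keep], use.names = FALSE)))
  }
  module_set(mods[keep], outliers = outliers,
             descriptions = stats::setNames(paste0("center:", centers[keep]), ids[keep]))
}
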