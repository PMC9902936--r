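# Per-dataset k-nearest-neighbour graphs and their fusion into the
# trans-omics neighbourhood matrix.  A neighbourhood graph is directed:
# y being among x's k nearest neighbours does not imply the converse.

#' Pairwise gene similarity
#'
#' Computes a symmetric gene-by-gene similarity table from an imputed
#' expression matrix.  Pearson similarity is the absolute correlation
#' |r| by default, so strongly anti-correlated genes are admitted as
#' neighbours (their sign is re-derived where it matters, in the
#' survival orientation step); set \code{absolute = FALSE} to keep only
#' positive correlations.  Euclidean similarity is 1/(1+d).  Mutual
#' information uses equal-frequency binning with
#' max(2, floor(sqrt(n_samples))) bins.
#'
#' @param mat Expression matrix (genes x samples), fully imputed.
#' @param measure One of \code{"pearson"}, \code{"euclidean"},
#'   \code{"mutual_information"}.
#' @param absolute For Pearson: use |r| (default) rather than
#'   max(r, 0).
#' @return Symmetric numeric matrix with zero diagonal and a
#'   \code{dataset_id} attribute.
#' @export
similarity <- function(mat, measure = c("pearson", "euclidean", "mutual_information"),
                       absolute = TRUE) {
  measure <- match.arg(measure)
  if (anyNA(mat)) stopf("similarity requires a fully imputed matrix")
  if (nrow(mat) < 2L) stopf("need at least 2 genes")
  sim <- switch(measure,
    pearson = {
      if (ncol(mat) < 3L) stopf("pearson similarity needs >= 3 samples")
      r <- suppressWarnings(stats::cor(t(mat)))
      if (anyNA(r)) {
        nzv <- rownames(mat)[apply(mat, 1L, stats::sd) == 0]
        warnf("%d zero-variance gene(s); their correlations set to 0", length(nzv))
        r[is.na(r)] <- 0
      }
      if (absolute) abs(r) else pmax(r, 0)
    },
    euclidean = 1 / (1 + as.matrix(stats::dist(mat))),
    mutual_information = mi_table(mat))
  diag(sim) <- 0
  attr(sim, "dataset_id") <- dataset_id(mat)
  sim
}

# Mutual information between all gene pairs from equal-frequency binned
# profiles (natural log).
mi_table <- function(mat) {
  n <- ncol(mat)
  B <- max(2L, floor(sqrt(n)))
  bins <- t(apply(mat, 1L, function(x) {
    as.integer(cut(rank(x, ties.method = "first"), breaks = B, labels = FALSE))
  }))
  G <- nrow(mat)
  out <- matrix(0, G, G, dimnames = list(rownames(mat), rownames(mat)))
  marg <- lapply(seq_len(G), function(i) tabulate(bins[i, ], B) / n)
  for (i in seq_len(G - 1L)) {
    for (j in (i + 1L):G) {
      joint <- tabulate((bins[i, ] - 1L) * B + bins[j, ], B * B) / n
      pij <- matrix(joint, B, B, byrow = TRUE)  # [bin_i, bin_j]
      expected <- outer(marg[[i]], marg[[j]])
      nz <- pij > 0
      out[i, j] <- out[j, i] <- sum(pij[nz] * log(pij[nz] / expected[nz]))
    }
  }
  out
}

#' Build a k-nearest-neighbour weight graph
#'
#' For every object the k most similar other objects are selected (ties
#' at the k-th rank broken by lexicographic identifier) and given
#' weights proportional to their similarity, \eqn{w_{xy} = S_{xy} /
#' \sum_{z \in KNN(x)} S_{xz}}, so each object's weights sum to 1.
#' Objects whose selected neighbours all have non-positive similarity
#' receive uniform weights over those neighbours, with a warning;
#' neighbours with non-positive similarity alongside positive ones are
#' dropped from the list.
#'
#' @param sim Symmetric similarity matrix (as from [similarity()]).
#' @param k Number of neighbours per object.
#' @param source Label for the graph's provenance; defaults to the
#'   similarity table's \code{dataset_id}.
#' @return An object of class \code{clam_graph}: a list with an edge
#'   table (object, neighbor, weight, similarity), the gene set, k and
#'   the source label.
#' @export
knn_weights <- function(sim, k, source = NULL) {
  if (k < 1) stopf("'k' must be >= 1")
  genes <- rownames(sim)
  n <- length(genes)
  if (n < 2L) stopf("need at least 2 objects")
  kk <- min(k, n - 1L)
  src <- source %||% attr(sim, "dataset_id") %||% "dataset"
  uniform_fallback <- 0L
  res <- vector("list", n)
  for (i in seq_len(n)) {
    s <- sim[i, ]
    ord <- order(-s, genes)
    ord <- ord[ord != i][seq_len(kk)]
    sv <- s[ord]
    if (all(sv <= 0)) {
      w <- rep(1 / kk, kk)
      uniform_fallback <- uniform_fallback + 1L
    } else {
      if (any(sv <= 0)) {
        ord <- ord[sv > 0]
        sv <- sv[sv > 0]
      }
      w <- sv / sum(sv)
    }
    res[[i]] <- data.frame(object = genes[i], neighbor = genes[ord],
                           weight = w, similarity = s[ord],
                           stringsAsFactors = FALSE)
  }
  if (uniform_fallback > 0L)
    warnf("%d object(s) had no positive-similarity neighbour; uniform weights assigned",
          uniform_fallback)
  edges <- do.call(rbind, res)
  rownames(edges) <- NULL
  new_graph(edges, objects = genes, k = k, source = src)
}

new_graph <- function(edges, objects, k, source) {
  structure(list(edges = edges, objects = objects, k = k, source = source),
            class = "clam_graph")
}

#' @export
print.clam_graph <- function(x, ...) {
  cat(sprintf("Neighbourhood graph [%s]: %d objects, %d edges, k = %d\n",
              x$source, length(x$objects), nrow(x$edges), x$k))
  invisible(x)
}

#' Fuse per-dataset neighbourhood graphs
#'
#' Combines k-nearest-neighbour graphs from different omics layers into
#' one trans-omics neighbourhood graph over the union of their objects.
#' For an object measured in m datasets, each of its incoming neighbour
#' weights is divided by that object's own m, and duplicated (object,
#' neighbor) pairs are then merged by summing, so duplicated neighbours
#' end up with higher weight and every object's weights still sum to 1.
#' Per-edge similarities are carried along under the same 1/m weighting
#' for use in the density computation.
#'
#' @param graphs List of \code{clam_graph} objects.
#' @return A fused \code{clam_graph} with \code{source = "fused"}.
#' @export
fuse <- function(graphs) {
  if (inherits(graphs, "clam_graph")) graphs <- list(graphs)
  if (length(graphs) == 0L) stopf("need at least one graph")
  m <- table(unlist(lapply(graphs, `[[`, "objects")))
  edges <- do.call(rbind, lapply(graphs, function(g) {
    e <- g$edges
    div <- as.numeric(m[e$object])
    e$weight <- e$weight / div
    e$similarity <- e$similarity / div
    e
  }))
  key <- paste(edges$object, edges$neighbor, sep = "\r")
  if (anyDuplicated(key)) {
    w <- rowsum(edges$weight, key, reorder = FALSE)
    s <- rowsum(edges$similarity, key, reorder = FALSE)
    first <- !duplicated(key)
    edges <- edges[first, , drop = FALSE]
    edges$weight <- w[match(key[first], rownames(w)), 1L]
    edges$similarity <- s[match(key[first], rownames(s)), 1L]
  }
  edges <- edges[order(edges$object, edges$neighbor), , drop = FALSE]
  rownames(edges) <- NULL
  new_graph(edges, objects = sort(names(m)), k = max(vapply(graphs, `[[`, numeric(1L), "k")),
            source = "fused")
}

#' Write a neighbourhood graph as a 3-column TSV
#' @param graph A \code{clam_graph}.
#' @param path Output path.
#' @export
write_graph <- function(graph, path) {
  utils::write.table(graph$edges[c("object", "neighbor", "weight")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Per-object weight sums (used by invariant checks).
weight_sums <- function(graph) {
  s <- rowsum(graph$edges$weight, graph$edges$object, reorder = FALSE)
  stats::setNames(s[, 1L], rownames(s))
}

# Sparse weight / similarity matrices over a fixed object ordering.
graph_matrices <- function(graph, objects = graph$objects) {
  i <- match(graph$edges$object, objects)
  j <- match(graph$edges$neighbor, objects)
  if (anyNA(i) || anyNA(j)) stopf("graph refers to objects outside the given ordering")
  n <- length(objects)
  list(W = Matrix::sparseMatrix(i = i, j = j, x = graph$edges$weight, dims = c(n, n),
                                dimnames = list(objects, objects)),
       S = Matrix::sparseMatrix(i = i, j = j, x = graph$edges$similarity, dims = c(n, n),
                                dimnames = list(objects, objects)))
}
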