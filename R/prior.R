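# Prior correlation probabilities from known molecular interactions.
#
# For a gene g1, a co-regulatory network is built from the interaction
# database: neighbours that interact with g1 directly (PPI, optionally
# pathway co-membership) or share a transcriptional regulator (TF or
# miRNA) with g1.  With n1 miRNAs and n2 TFs targeting g1 and n3 direct
# partners, every edge leaving g1 carries weight 1/(n1+n2+n3); a shared
# regulator that targets n4 of g1's neighbours splits its mass 1/n4
# among them, so a neighbour reached through it scores
# 1/(n1+n2+n3) * 1/n4.  Contributions over multiple connecting paths
# sum.  Neighbours absent from the network score zero.

#' Co-regulation scores between a gene and its neighbours
#'
#' @param g1 Gene identifier.
#' @param neighbors Character vector of g1's neighbours in the fused
#'   graph.
#' @param db A \code{clam_interactions} object.
#' @param include_pathways Treat pathway co-membership as a
#'   regulator-like interaction: each pathway containing g1 counts in
#'   the denominator and splits its mass over the neighbours it
#'   contains.  Default \code{TRUE}.
#' @return Named numeric vector of scores in [0, 1], one per neighbour.
#' @export
coregulation_scores <- function(g1, neighbors, db, include_pathways = TRUE) {
  if (length(neighbors) == 0L) stopf("neighbour list is empty")
  scores <- stats::setNames(numeric(length(neighbors)), neighbors)
  regulating <- function(map) names(map)[vapply(map, function(t) g1 %in% t, logical(1L))]
  mirnas <- regulating(db$mirna_targets)
  tfs <- regulating(db$tf_targets)
  partners <- db$ppi[[g1]] %||% character()
  pws <- if (include_pathways) regulating(db$pathways) else character()
  denom <- length(mirnas) + length(tfs) + length(partners) + length(pws)
  if (denom == 0L) return(scores)
  share_out <- function(targets) {
    hit <- intersect(targets, neighbors)
    n4 <- length(hit)
    if (n4 > 0L) scores[hit] <<- scores[hit] + (1 / denom) * (1 / n4)
  }
  for (r in mirnas) share_out(setdiff(db$mirna_targets[[r]], g1))
  for (r in tfs) share_out(setdiff(db$tf_targets[[r]], g1))
  for (p in pws) share_out(setdiff(db$pathways[[p]], g1))
  direct <- intersect(partners, neighbors)
  scores[direct] <- scores[direct] + 1 / denom
  scores
}

#' Prior correlation probabilities from co-regulation scores
#'
#' Softmax transform with temperature \eqn{\tau}: \eqn{p_i =
#' \exp(c_i/\tau) / \sum_j \exp(c_j/\tau)}.  All-zero scores give a
#' uniform prior, which leaves relative edge weights untouched
#' downstream.
#'
#' @param scores Numeric vector of co-regulation scores.
#' @param temperature Softmax temperature, default 1.
#' @return Numeric vector summing to 1.
#' @export
prior_probabilities <- function(scores, temperature = 1) {
  if (temperature <= 0) stopf("'temperature' must be positive")
  z <- scores / temperature
  e <- exp(z - max(z))
  e / sum(e)
}

#' Reweight a neighbourhood graph by interaction priors
#'
#' Replaces each edge weight \eqn{w_{xy}} with \eqn{w_{xy} \times
#' prior_{xy}}, where the prior is the softmax of x's co-regulation
#' scores over its neighbour list.  With \code{renormalize = TRUE}
#' (default) every object's weights are rescaled to sum to 1 so that
#' membership propagation stays on the probability simplex.
#'
#' @param graph A \code{clam_graph}.
#' @param db A \code{clam_interactions} object.
#' @param temperature Softmax temperature.
#' @param include_pathways Passed to [coregulation_scores()].
#' @param renormalize Rescale each object's weights to sum to 1.
#' @return The reweighted \code{clam_graph}.
#' @export
apply_prior <- function(graph, db, temperature = 1, include_pathways = TRUE,
                        renormalize = TRUE) {
  edges <- graph$edges
  idx <- split(seq_len(nrow(edges)), edges$object)
  for (rows in idx) {
    nbrs <- edges$neighbor[rows]
    sc <- coregulation_scores(edges$object[rows][1L], nbrs, db,
                              include_pathways = include_pathways)
    pr <- prior_probabilities(sc, temperature = temperature)
    w <- edges$weight[rows] * pr
    if (renormalize) w <- w / sum(w)
    edges$weight[rows] <- w
  }
  new_graph(edges, objects = graph$objects, k = graph$k, source = graph$source)
}
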