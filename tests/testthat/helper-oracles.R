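# Independent brute-force oracles.  These re-derive expected values by
# direct enumeration / literal formula evaluation, separately from the
# package's (vectorised, index-based) implementations.

# Literal Jaccard on two sets.
o_jaccard <- function(a, b) {
  u <- unique(c(a, b))
  if (length(u) == 0L) return(0)
  length(intersect(a, b)) / length(u)
}

# Relevance: mean over observed modules of the best Jaccard against any
# known module, by exhaustive pairwise evaluation.
oracle_relevance <- function(O, K) {
  vals <- numeric(length(O))
  for (i in seq_along(O)) {
    best <- 0
    for (j in seq_along(K)) best <- max(best, o_jaccard(O[[i]], K[[j]]))
    vals[i] <- best
  }
  mean(vals)
}

# Precision: literal term-by-term evaluation of the gene-centric
# co-clustering formula (see the package docs for the conventions).
oracle_precision <- function(O, K, universe) {
  mods_with <- function(mods, g) names(mods)[vapply(mods, function(m) g %in% m, logical(1L))]
  total <- 0
  for (g in universe) {
    og <- mods_with(O, g)
    E <- if (length(og) == 0L) g else unique(c(g, unlist(O[og], use.names = FALSE)))
    inner <- 0
    for (g2 in E) {
      Mo <- intersect(og, mods_with(O, g2))
      if (length(Mo) == 0L) next
      Mk <- intersect(mods_with(K, g), mods_with(K, g2))
      if (length(Mk) == 0L) next
      phis <- numeric(length(Mo))
      for (a in seq_along(Mo)) {
        best <- 0
        for (b in seq_along(Mk)) best <- max(best, o_jaccard(O[[Mo[a]]], K[[Mk[b]]]))
        phis[a] <- best
      }
      inner <- inner + min(length(Mo), length(Mk)) / length(Mo) * mean(phis)
    }
    total <- total + inner / length(E)
  }
  total / length(universe)
}

# KNN imputation by exhaustive pairwise-distance evaluation, following
# the documented convention: Euclidean over co-observed samples scaled
# by sqrt(observed fraction), donors observed in the gap's sample,
# inverse-distance weights, exact copies (d = 0) take precedence.
oracle_impute <- function(mat, k) {
  out <- mat
  genes <- rownames(mat)
  for (g in genes) {
    for (s in colnames(mat)) {
      if (!is.na(mat[g, s])) next
      cand <- character(); dist <- numeric()
      for (h in setdiff(genes, g)) {
        if (is.na(mat[h, s])) next
        co <- which(!is.na(mat[g, ]) & !is.na(mat[h, ]))
        if (length(co) == 0L) next
        d <- sqrt(sum((mat[g, co] - mat[h, co])^2)) / sqrt(length(co) / ncol(mat))
        cand <- c(cand, h); dist <- c(dist, d)
      }
      if (length(cand) == 0L) stop("no donor")
      ord <- order(dist, cand)
      pick <- ord[seq_len(min(k, length(ord)))]
      dd <- dist[pick]
      out[g, s] <- if (any(dd == 0)) mean(mat[cand[pick][dd == 0], s])
                   else sum((1 / dd) * mat[cand[pick], s]) / sum(1 / dd)
    }
  }
  out
}

# Co-regulation scores by explicit path enumeration over the
# co-regulatory network of g1.
oracle_coreg <- function(g1, neighbors, db, include_pathways = TRUE) {
  sc <- setNames(numeric(length(neighbors)), neighbors)
  regs_of <- function(map) {
    out <- character()
    for (r in names(map)) if (g1 %in% map[[r]]) out <- c(out, r)
    out
  }
  mir <- regs_of(db$mirna_targets); tf <- regs_of(db$tf_targets)
  pw <- if (include_pathways) regs_of(db$pathways) else character()
  partners <- if (g1 %in% names(db$ppi)) db$ppi[[g1]] else character()
  D <- length(mir) + length(tf) + length(partners) + length(pw)
  if (D == 0L) return(sc)
  paths <- list()
  for (r in mir) paths[[length(paths) + 1L]] <- setdiff(db$mirna_targets[[r]], g1)
  for (r in tf) paths[[length(paths) + 1L]] <- setdiff(db$tf_targets[[r]], g1)
  for (p in pw) paths[[length(paths) + 1L]] <- setdiff(db$pathways[[p]], g1)
  for (tgts in paths) {
    n4 <- sum(neighbors %in% tgts)
    if (n4 == 0L) next
    for (gi in neighbors) if (gi %in% tgts) sc[gi] <- sc[gi] + (1 / D) * (1 / n4)
  }
  for (gi in neighbors) if (gi %in% partners) sc[gi] <- sc[gi] + 1 / D
  sc
}

# Two-group log-rank chi-square by hand tabulation of observed vs
# expected events (hypergeometric variance) at every distinct event
# time.
oracle_logrank <- function(time, event, group) {
  g1 <- levels(factor(group))[1L]
  OmE <- 0; V <- 0
  for (t in sort(unique(time[event == 1]))) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & group == g1)
    d <- sum(event == 1 & time == t)
    d1 <- sum(event == 1 & time == t & group == g1)
    OmE <- OmE + d1 - d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  OmE^2 / V
}

# Adjusted Rand index from the contingency-table formula.
oracle_ari <- function(a, b) {
  tab <- table(a, b)
  ch2 <- function(x) x * (x - 1) / 2
  sij <- sum(ch2(tab)); sa <- sum(ch2(rowSums(tab))); sb <- sum(ch2(colSums(tab)))
  N <- ch2(sum(tab))
  (sij - sa * sb / N) / ((sa + sb) / 2 - sa * sb / N)
}

# Fixed point of the membership propagation by direct linear solve:
# (I - W_OO) P_O = W_OF P_F for the ordinary block.
oracle_fixed_point <- function(P0, W, roles) {
  W <- as.matrix(W)
  ord <- which(roles[rownames(P0)] == "ordinary")
  fx <- which(roles[rownames(P0)] != "ordinary")
  P <- P0
  if (length(ord)) {
    A <- diag(length(ord)) - W[ord, ord, drop = FALSE]
    B <- W[ord, fx, drop = FALSE] %*% P0[fx, , drop = FALSE]
    P[ord, ] <- solve(A, as.matrix(B))
  }
  P
}

# --- fixture builders -------------------------------------------------

rand_expr <- function(n_genes, n_samples, seed, id = "d1") {
  set.seed(seed)
  m <- matrix(rnorm(n_genes * n_samples), n_genes,
              dimnames = list(sprintf("g%02d", seq_len(n_genes)),
                              sprintf("s%02d", seq_len(n_samples))))
  expression_matrix(m, id)
}

# Random symmetric positive similarity table.
rand_sim <- function(n, seed) {
  set.seed(seed)
  s <- abs(cor(matrix(rnorm(n * (n + 3)), ncol = n)))
  dimnames(s) <- list(sprintf("g%02d", 1:n), sprintf("g%02d", 1:n))
  diag(s) <- 0
  s
}

# Random toy interaction database over genes g01..gNN.
rand_db <- function(n_genes, seed) {
  set.seed(seed)
  genes <- sprintf("g%02d", seq_len(n_genes))
  pick <- function() sample(genes, sample(1:4, 1))
  ntf <- sample(0:3, 1); nmir <- sample(0:3, 1); npw <- sample(0:2, 1)
  tf <- setNames(lapply(seq_len(ntf), function(i) pick()), sprintf("tf%d", seq_len(ntf)))
  mir <- setNames(lapply(seq_len(nmir), function(i) pick()), sprintf("mir%d", seq_len(nmir)))
  pw <- setNames(lapply(seq_len(npw), function(i) sample(genes, sample(2:5, 1))),
                 sprintf("pw%d", seq_len(npw)))
  nppi <- sample(0:5, 1)
  ppi <- if (nppi > 0) data.frame(a = sample(genes, nppi, replace = TRUE),
                                  b = sample(genes, nppi, replace = TRUE))
         else NULL
  interaction_db(tf_targets = tf, mirna_targets = mir, ppi_edges = ppi, pathways = pw)
}

# A two-cluster planted fixture: two tight clumps in sample space.
planted_two_cluster <- function(n_per = 6, n_samples = 12, seed = 7) {
  set.seed(seed)
  f1 <- rnorm(n_samples); f2 <- rnorm(n_samples)
  vals <- rbind(
    t(vapply(1:n_per, function(i) f1 + 0.3 * rnorm(n_samples), numeric(n_samples))),
    t(vapply(1:n_per, function(i) f2 + 0.3 * rnorm(n_samples), numeric(n_samples))))
  dimnames(vals) <- list(c(sprintf("a%02d", 1:n_per), sprintf("b%02d", 1:n_per)),
                         sprintf("s%02d", 1:n_samples))
  expression_matrix(vals, "toy")
}

# All set partitions of a small gene vector (for exhaustive metric
# suites).
all_partitions <- function(genes) {
  if (length(genes) == 1L) return(list(list(genes)))
  rest <- all_partitions(genes[-1L])
  out <- list()
  for (p in rest) {
    for (i in seq_along(p)) {
      q <- p; q[[i]] <- c(genes[1L], q[[i]])
      out[[length(out) + 1L]] <- q
    }
    out[[length(out) + 1L]] <- c(list(genes[1L]), p)
  }
  out
}

named_partition <- function(p) setNames(p, sprintf("m%d", seq_along(p)))
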