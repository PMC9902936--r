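# Similarity measures, KNN weighting and graph fusion.

test_that("pearson similarity: identical and anti-correlated profiles score 1 under |r|", {
  vals <- rbind(g1 = c(1, 2, 3), g2 = c(2, 4, 6), g3 = c(3, 2, 1))
  colnames(vals) <- c("s1", "s2", "s3")
  m <- expression_matrix(vals, "d")
  s <- similarity(m, "pearson")
  expect_equal(s["g1", "g2"], 1)
  expect_equal(s["g1", "g3"], 1)      # perfect anticorrelation, absolute value
  s2 <- similarity(m, "pearson", absolute = FALSE)
  expect_equal(s2["g1", "g3"], 0)     # clamped under positive-only mode
})

test_that("pearson similarity equals the textbook formula on a toy matrix", {
  m <- rand_expr(6, 8, seed = 3)
  s <- similarity(m, "pearson")
  pear <- function(x, y) {
    sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  }
  for (i in 1:5) for (j in (i + 1):6)
    expect_equal(s[i, j], abs(pear(m[i, ], m[j, ])), tolerance = 1e-12)
})

test_that("euclidean and mutual-information similarities behave as documented", {
  m <- rand_expr(4, 25, seed = 4)
  se <- similarity(m, "euclidean")
  d12 <- sqrt(sum((m[1, ] - m[2, ])^2))
  expect_equal(se[1, 2], 1 / (1 + d12))

  # a dependent pair carries more mutual information than independent noise
  dep <- rbind(m, g99 = m[1, ] + 0.01 * rnorm(25))
  dep <- expression_matrix(dep, "d")
  smi <- similarity(dep, "mutual_information")
  expect_true(smi["g01", "g99"] > max(smi["g01", c("g02", "g03", "g04")]))
  expect_equal(smi, t(smi))
})

test_that("zero-variance genes are zeroed with a warning under pearson", {
  m <- rand_expr(4, 6, seed = 9)
  m[2, ] <- 5
  expect_warning(s <- similarity(m, "pearson"), "zero-variance")
  expect_true(all(s[2, ] == 0))
})

test_that("knn weights follow the similarity-share formula", {
  sim <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  sim["a", c("b", "c", "d")] <- c(0.9, 0.6, 0.5)
  sim[c("b", "c", "d"), "a"] <- c(0.9, 0.6, 0.5)
  sim["b", "c"] <- sim["c", "b"] <- 0.2
  sim["b", "d"] <- sim["d", "b"] <- 0.2
  sim["c", "d"] <- sim["d", "c"] <- 0.2
  g <- knn_weights(sim, k = 3)
  e <- g$edges[g$edges$object == "a", ]
  expect_equal(setNames(e$weight, e$neighbor),
               c(b = 0.45, c = 0.30, d = 0.25))

  # equal similarities give uniform 1/k
  sim2 <- matrix(0.5, 4, 4, dimnames = dimnames(sim)); diag(sim2) <- 0
  g2 <- knn_weights(sim2, k = 3)
  expect_true(all(abs(g2$edges$weight - 1 / 3) < 1e-12))
})

test_that("neighbour selection matches an exhaustive sort oracle, ties lexicographic", {
  set.seed(11)
  sim <- rand_sim(8, seed = 11)
  sim[1, 3] <- sim[3, 1] <- sim[1, 5]   # force a tie at the boundary
  g <- knn_weights(sim, k = 3)
  for (i in 1:8) {
    x <- rownames(sim)[i]
    s <- sim[i, -i]
    expected <- names(s)[order(-s, names(s))][1:3]
    got <- g$edges$neighbor[g$edges$object == x]
    expect_identical(sort(got), sort(expected))
    # monotonicity: higher similarity => higher weight
    e <- g$edges[g$edges$object == x, ]
    expect_true(all(diff(e$weight[order(-e$similarity)]) <= 1e-12))
  }
  # per-object weight sums and exact neighbour counts
  expect_true(all(abs(clam:::weight_sums(g) - 1) < 1e-9))
  expect_true(all(table(g$edges$object) == 3))
})

test_that("fusion halves per-dataset weights and merges duplicated neighbours", {
  e1 <- data.frame(object = "g", neighbor = c("a", "b"), weight = c(0.6, 0.4),
                   similarity = c(0.6, 0.4))
  e2 <- data.frame(object = "g", neighbor = c("a", "c"), weight = c(0.7, 0.3),
                   similarity = c(0.7, 0.3))
  g1 <- clam:::new_graph(e1, objects = "g", k = 2, source = "d1")
  g2 <- clam:::new_graph(e2, objects = "g", k = 2, source = "d2")
  f <- fuse(list(g1, g2))
  w <- setNames(f$edges$weight, f$edges$neighbor)
  expect_equal(w[c("a", "b", "c")], c(a = 0.65, b = 0.20, c = 0.15))
})

test_that("fusion is an identity on one graph and order-invariant", {
  sim <- rand_sim(7, seed = 21)
  g <- knn_weights(sim, k = 3)
  f1 <- fuse(list(g))
  expect_equal(f1$edges[order(f1$edges$object, f1$edges$neighbor), ],
               g$edges[order(g$edges$object, g$edges$neighbor), ],
               ignore_attr = TRUE)

  gs <- lapply(1:3, function(i) knn_weights(rand_sim(6 + i, seed = 30 + i), k = 3))
  fa <- fuse(gs); fb <- fuse(rev(gs))
  expect_equal(fa$edges, fb$edges)
})

test_that("weight conservation holds across fusion of partially overlapping graphs", {
  for (seed in 1:5) {
    gs <- lapply(1:3, function(i) {
      s <- rand_sim(5 + i + seed %% 3, seed = seed * 10 + i)
      rownames(s) <- colnames(s) <- sprintf("g%02d", seq_len(nrow(s)) + i)  # overlap shift
      knn_weights(s, k = 3)
    })
    f <- fuse(gs)
    expect_true(all(abs(clam:::weight_sums(f) - 1) < 1e-9))
  }
})
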