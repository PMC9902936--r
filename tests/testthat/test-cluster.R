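# Density seeding, membership propagation and the full fit.

# Small handmade graph: helper to build a clam_graph from an edge table.
mk_graph <- function(edges, k = 3) {
  clam:::new_graph(edges, objects = sort(unique(c(edges$object, edges$neighbor))),
                   k = k, source = "toy")
}

test_that("density is the mean neighbour similarity", {
  e <- data.frame(object = c("a", "a", "a", "b"), neighbor = c("b", "c", "d", "a"),
                  weight = c(0.45, 0.30, 0.25, 1), similarity = c(0.9, 0.6, 0.5, 0.9))
  g <- mk_graph(e)
  rho <- compute_density(g)
  expect_equal(unname(rho["a"]), 2 / 3)
  expect_equal(unname(rho["b"]), 0.9)

  g10 <- knn_weights(rand_sim(10, seed = 6), k = 4)
  rho10 <- compute_density(g10)
  for (x in g10$objects) {
    expect_equal(unname(rho10[x]),
                 mean(g10$edges$similarity[g10$edges$object == x]))
  }
})

test_that("centres and outliers follow the strict density comparisons", {
  m <- planted_two_cluster()
  s <- similarity(m)
  g <- knn_weights(s, k = 4)
  rho <- compute_density(g)
  roles <- find_centers_outliers(rho, g, outlier_threshold = "none")
  # brute-force role oracle
  for (x in g$objects) {
    nb <- g$edges$neighbor[g$edges$object == x]
    expected <- if (all(rho[x] > rho[nb])) "center"
                else if (all(rho[x] < rho[nb])) "outlier" else "ordinary"
    expect_identical(unname(roles[x]), expected)
  }
  # two well-separated clumps give exactly two centres
  expect_identical(sum(roles == "center"), 2L)
  expect_identical(sort(unique(substr(names(roles)[roles == "center"], 1, 1))),
                   c("a", "b"))
})

test_that("density ties and uniform densities are handled", {
  e <- data.frame(object = c("a", "b"), neighbor = c("b", "a"),
                  weight = c(1, 1), similarity = c(0.5, 0.5))
  g <- mk_graph(e)
  rho <- compute_density(g)     # both 0.5: tied, neither centre nor outlier
  expect_error(find_centers_outliers(rho, g), "no cluster centres")
})

test_that("the outlier density threshold spares dense-region local minima", {
  # a, b, c dense clique (a is its minimum); d, e sparse pair below mean
  e <- data.frame(object = c("a", "b", "c", "d", "e"),
                  neighbor = c("b", "c", "b", "e", "d"),
                  weight = 1, similarity = c(0.90, 0.95, 0.92, 0.10, 0.20))
  g <- mk_graph(e, k = 1)
  rho <- compute_density(g)
  r_none <- find_centers_outliers(rho, g, outlier_threshold = "none")
  r_mean <- find_centers_outliers(rho, g)
  expect_identical(unname(r_none["a"]), "outlier")   # local minimum of the dense clique
  expect_identical(unname(r_mean["a"]), "ordinary")  # spared: density above the mean
  expect_identical(unname(r_mean["d"]), "outlier")   # sparse local minimum stays
})

test_that("membership initialisation pins centres and outliers", {
  roles <- c(a = "center", b = "center", c = "center", x = "ordinary", y = "outlier")
  P <- init_membership(roles)
  expect_equal(unname(P["x", ]), rep(1 / 4, 4))
  expect_equal(unname(P["b", ]), c(0, 1, 0, 0))
  expect_equal(unname(P["y", ]), c(0, 0, 0, 1))
})

test_that("propagation absorbs into a one-hot neighbourhood and respects symmetry", {
  roles <- c(c1 = "center", c2 = "center", x = "ordinary")
  e <- data.frame(object = c("x", "c1", "c2"), neighbor = c("c1", "x", "x"),
                  weight = 1, similarity = 0.9)
  g <- mk_graph(e)
  out <- iterate_membership(init_membership(roles), g, roles)
  expect_equal(unname(out$membership["x", ]), c(1, 0, 0))

  # symmetric barbell: weight mass split evenly between two centres
  e2 <- data.frame(object = c("x", "x", "c1", "c2"), neighbor = c("c1", "c2", "x", "x"),
                   weight = c(0.5, 0.5, 1, 1), similarity = 0.9)
  out2 <- iterate_membership(init_membership(roles), mk_graph(e2), roles)
  expect_equal(out2$membership["x", "c1"], out2$membership["x", "c2"], tolerance = 1e-9)
})

test_that("the fixed point equals a direct linear solve on planted fixtures", {
  m <- planted_two_cluster(n_per = 6, n_samples = 12, seed = 13)
  g <- knn_weights(similarity(m), k = 4)
  rho <- compute_density(g)
  roles <- find_centers_outliers(rho, g)
  P0 <- init_membership(roles)
  it <- iterate_membership(P0, g, roles, tol = 1e-10)
  W <- clam:::graph_matrices(g, rownames(P0))$W
  expect_lt(max(abs(it$membership - oracle_fixed_point(P0, W, roles))), 1e-6)
  # E decreases to its fixed-point plateau.  The pinned centre/outlier
  # terms are not themselves minimised, so E may rise by a numerically
  # negligible amount while settling; require near-monotonicity and an
  # overall decrease.
  expect_true(all(diff(it$E[-1]) <= 1e-4 * it$E[length(it$E)]))
  expect_lt(it$E[length(it$E)], it$E[1])
  expect_true(all(abs(rowSums(it$membership) - 1) < 1e-9))
})

test_that("hard assignment takes the argmax with documented tie-breaks", {
  P <- rbind(g1 = c(0.7, 0.2, 0.1), g2 = c(0.2, 0.2, 0.6), g3 = c(0.5, 0.5, 0))
  colnames(P) <- c("c1", "c2", ".outlier")
  attr(P, "centers") <- c("c1", "c2")
  ms <- assign_modules(P)
  expect_identical(ms$modules$M1, c("g1", "g3"))   # tie goes to the lowest index
  expect_identical(ms$outliers, "g2")

  # min_module_size folds small modules into the outlier set
  ms2 <- assign_modules(P, min_module_size = 3)
  expect_length(ms2$modules, 0L)
  expect_setequal(ms2$outliers, c("g1", "g2", "g3"))
})

test_that("the full fit is deterministic and composes the documented stages", {
  sim <- clam_simulate(n_modules = 3, module_size = 10, n_background = 30,
                       n_samples = 30, n_datasets = 1, seed = 5)
  f1 <- clam(sim$datasets, sim$interactions, k = 5)
  f2 <- clam(sim$datasets, sim$interactions, k = 5)
  expect_identical(f1$modules, f2$modules)
  expect_identical(f1$membership, f2$membership)

  # single dataset without prior equals the manually composed stages
  f0 <- clam(sim$datasets, k = 5)
  g <- knn_weights(similarity(sim$datasets[[1]]), k = 5)
  fused <- fuse(list(g))
  rho <- compute_density(fused)
  roles <- find_centers_outliers(rho, fused)
  it <- iterate_membership(init_membership(roles), fused, roles)
  expect_equal(unclass(f0$membership), unclass(it$membership), ignore_attr = TRUE)
  expect_identical(f0$modules$modules, assign_modules(it$membership)$modules)
})

test_that("fit methods expose assignments, residuals and membership", {
  sim <- clam_simulate(n_modules = 2, module_size = 8, n_background = 15,
                       n_samples = 25, n_datasets = 1, seed = 3)
  fit <- clam(sim$datasets, k = 5)
  lab <- fitted(fit)
  expect_identical(length(lab), nrow(fit$membership))
  expect_true(all(levels(lab) == c(names(fit$modules$modules), "outlier")))
  r <- residuals(fit)
  expect_equal(sum(r^2), fit$E[length(fit$E)], tolerance = 1e-8)
  expect_identical(coef(fit), fit$membership)
  expect_output(print(fit), "modules")
  expect_output(print(summary(fit)), "roles")
})

test_that("namespaced mode keeps layers distinct; merged mode unifies identifiers", {
  sim <- clam_simulate(n_modules = 2, module_size = 8, n_background = 10,
                       n_samples = 25, n_datasets = 2, gene_overlap = 1,
                       seed = 8)
  f_ns <- clam(sim$datasets, k = 4, merge_identifiers = FALSE)
  expect_true(all(grepl("@omics", rownames(f_ns$membership))))
  expect_identical(nrow(f_ns$membership), 52L)
  f_m <- clam(sim$datasets, k = 4)
  expect_identical(nrow(f_m$membership), 26L)
})
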