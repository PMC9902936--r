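# Orientation, per-patient co-expression SD, median split and log-rank.

toy_expr <- function(vals, genes, samples) {
  dimnames(vals) <- list(genes, samples)
  vals
}

test_that("orientation flips anti-correlated members and nothing else", {
  s <- sprintf("s%d", 1:6)
  base <- c(1, 3, 2, 5, 4, 6)
  expr <- toy_expr(rbind(base + 0.1 * (1:6), base * 2, base + c(0, .2, 0, .1, 0, 0)),
                   c("g1", "g2", "g3"), s)
  expect_true(all(orient_genes(expr) == 1))

  expr2 <- rbind(expr, g4 = -base)
  sg <- orient_genes(expr2)
  expect_equal(unname(sg["g4"]), -1)
  # post-condition: every gene correlates non-negatively with the reference
  flipped <- expr2 * sg
  r <- cor(t(flipped))
  ref <- names(which.max(rowSums(abs(cor(t(expr2)))) - 1))
  expect_true(all(r[ref, ] >= 0))
})

test_that("orientation excludes zero-variance genes with a warning", {
  s <- sprintf("s%d", 1:5)
  expr <- toy_expr(rbind(c(1, 2, 3, 4, 5), c(2, 4, 6, 8, 10), rep(7, 5)),
                   c("g1", "g2", "flat"), s)
  expect_warning(sg <- orient_genes(expr), "zero-variance")
  expect_identical(names(sg), c("g1", "g2"))
})

test_that("per-patient SD of oriented z-scores matches hand computation", {
  # identical transformed values give sigma 0; a (1, -1) pair gives 1
  s <- sprintf("s%d", 1:6)
  g1 <- c(1, 2, 3, 4, 5, 6)
  expr <- toy_expr(rbind(g1, g1, g1), c("a", "b", "c"), s)
  expr <- expr + rep(c(0, 0, 0), each = 6) # keep identical rows
  cx <- coexpression_sd(expr)
  expect_true(all(abs(cx$sigma) < 1e-12))

  # two-gene module, one the negative of the other: after orientation the
  # z-scores coincide, sigma is identically 0 (degenerate co-expression)
  expr2 <- toy_expr(rbind(g1, -g1), c("a", "b"), s)
  cx2 <- coexpression_sd(expr2)
  expect_true(all(abs(cx2$sigma) < 1e-12))

  # population-denominator convention on a hand-computed 3 x 6 toy
  set.seed(4)
  expr3 <- toy_expr(matrix(rnorm(18), 3), c("a", "b", "c"), s)
  cx3 <- coexpression_sd(expr3)
  zs <- t(apply(expr3, 1, function(x) (x - mean(x)) / sqrt(mean((x - mean(x))^2))))
  zs <- zs * cx3$signs[rownames(zs)]
  manual <- apply(zs, 2, function(v) sqrt(mean((v - mean(v))^2)))
  expect_equal(cx3$sigma, manual, tolerance = 1e-12)

  # flipping a raw profile is absorbed by the orientation step
  expr4 <- expr3; expr4["b", ] <- -expr4["b", ]
  expect_equal(coexpression_sd(expr4)$sigma, cx3$sigma, tolerance = 1e-12)
})

test_that("log-rank split matches the hand-tabulated worked example exactly", {
  clin <- data.frame(sample_id = sprintf("p%d", 1:6),
                     time = c(2, 4, 6, 1, 3, 5), event = 1L)
  stat <- setNames(c(0, 0, 0, 1, 1, 1), clin$sample_id)  # median split: 3 vs 3
  res <- logrank_split(stat, clin)
  expect_equal(res$chisq, 0.484876260311641, tolerance = 1e-10)
  expect_equal(res$chisq, oracle_logrank(clin$time, clin$event,
                                         ifelse(stat > median(stat), "high", "low")),
               tolerance = 1e-12)
  expect_identical(c(res$n_low, res$n_high), c(3L, 3L))
})

test_that("log-rank split agrees with brute-force tabulation on random small cohorts", {
  for (seed in 1:10) {
    set.seed(seed)
    n <- sample(6:10, 1)
    clin <- data.frame(sample_id = sprintf("p%d", 1:n),
                       time = sample(1:20, n), event = rbinom(n, 1, 0.8))
    stat <- setNames(rnorm(n), clin$sample_id)
    if (sum(clin$event) == 0) next
    res <- logrank_split(stat, clin)
    grp <- ifelse(stat > median(stat), "high", "low")
    if (length(unique(grp)) < 2) next
    expect_equal(res$chisq, oracle_logrank(clin$time, clin$event, grp),
                 tolerance = 1e-10)
  }
})

test_that("identical survival in both groups gives a null log-rank result", {
  clin <- data.frame(sample_id = sprintf("p%d", 1:8),
                     time = rep(c(1, 2, 3, 4), 2), event = 1L)
  stat <- setNames(rep(c(0, 1), each = 4), clin$sample_id)
  res <- logrank_split(stat, clin)
  expect_lt(res$chisq, 1e-10)
  expect_gt(res$p, 0.99)
})

test_that("a constant statistic takes the degenerate path: all patients in one group", {
  clin <- data.frame(sample_id = sprintf("p%d", 1:6),
                     time = 1:6, event = 1L)
  stat <- setNames(rep(2.5, 6), clin$sample_id)  # ties go to the <= median group
  res <- logrank_split(stat, clin)
  expect_true(res$degenerate)
  expect_identical(res$p, 1)
  expect_identical(res$n_high, 0L)
})

test_that("the module screen reports every mode, adjusts p-values and ranks by p", {
  sim <- clam_simulate(n_modules = 2, module_size = 6, n_background = 4,
                       n_samples = 40, n_datasets = 1, seed = 11)
  scr <- clam_survival(sim$truth, sim$datasets[[1]], sim$clinical)
  expect_s3_class(scr, "clam_survival")
  expect_identical(sort(unique(scr$mode)), c("mean", "sd", "single_gene"))
  expect_identical(nrow(scr), 6L)           # 2 modules x 3 modes
  expect_true(all(!is.na(scr$p_adj)))
  for (m in unique(scr$mode)) expect_false(is.unsorted(scr$p[scr$mode == m]))
  # single-gene rows name their best gene, module rows do not
  expect_true(all(!is.na(scr$gene[scr$mode == "single_gene"])))
  expect_true(all(is.na(scr$gene[scr$mode != "single_gene"])))
})

test_that("SD-linked hazard is detected best by the sd statistic on the causal module", {
  hits <- 0L
  for (seed in 1:3) {
    sim <- clam_simulate(n_modules = 2, module_size = 15, n_background = 5,
                         n_samples = 60, n_datasets = 1, seed = seed)
    scr <- clam_survival(sim$truth, sim$datasets[[1]], sim$clinical,
                         modes = c("sd", "mean"))
    p_sd <- scr$p[scr$module == sim$causal_module & scr$mode == "sd"]
    p_mean <- scr$p[scr$module == sim$causal_module & scr$mode == "mean"]
    if (p_sd < p_mean) hits <- hits + 1L
    expect_lt(p_sd, 0.05)
  }
  expect_gte(hits, 2L)
})
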