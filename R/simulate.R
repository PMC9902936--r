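# Seeded synthetic multi-omics generator.
#
# Each planted module is driven by one latent factor per sample: a
# member gene's profile is sqrt(rho_w) * factor + sqrt(1 - rho_w) *
# noise, which makes the population correlation between any two members
# exactly rho_w (at noise_sd = 1).  Background genes are independent
# noise.  Datasets share a configurable fraction of genes and samples;
# shared samples share their factor values, so the same biology is seen
# through both layers with layer-specific noise.  Interactions plant
# one TF and one miRNA per module, each covering a configurable
# fraction of the module's genes, plus decoy regulators targeting
# random genes.  Survival times are exponential with log-hazard
# proportional to the per-patient co-expression standard deviation of
# one designated causal module, with independent exponential censoring.

#' Generate a synthetic multi-omics study with planted modules
#'
#' @param n_modules Number of planted modules.
#' @param module_size Genes per module; scalar or length-2 range to
#'   sample from.
#' @param n_background Independent background genes.
#' @param n_samples Samples per dataset.
#' @param n_datasets Number of omics layers.
#' @param gene_overlap Fraction of all genes measured in each dataset
#'   beyond the first (dataset 1 measures every gene).
#' @param sample_overlap Fraction of samples shared by all datasets.
#' @param rho_w Target within-module pairwise correlation, in (0, 1).
#' @param noise_sd Scale of the gene-level noise; at 1 the realised
#'   within-module correlation is calibrated to \code{rho_w}.
#' @param interaction_fidelity Fraction of each module's genes covered
#'   by its planted TF and by its planted miRNA.
#' @param decoy_rate Decoy interaction edges as a multiple of the
#'   planted ones.
#' @param baseline_hazard Event rate for a patient with average
#'   co-expression.
#' @param survival_effect Log-hazard increase per standard deviation of
#'   the per-patient co-expression statistic of the causal module.
#' @param censoring_rate Rate of the independent exponential censoring
#'   time.
#' @param missing_rate Optional missing-completely-at-random rate to
#'   exercise the filter/impute path.
#' @param causal_module Index of the module whose co-expression drives
#'   survival.
#' @param seed Integer seed; the output is fully reproducible.
#' @return List with \code{datasets} (named list of expression
#'   matrices), \code{interactions} (a \code{clam_interactions}),
#'   \code{truth} (a \code{clam_modules} with background genes as
#'   outliers), \code{clinical} (survival table over dataset 1's
#'   samples), \code{sigma} (the true per-patient statistic of the
#'   causal module) and \code{config}.
#' @export
clam_simulate <- function(n_modules = 5, module_size = 20, n_background = 200,
                          n_samples = 50, n_datasets = 2,
                          gene_overlap = 0.7, sample_overlap = 0.5,
                          rho_w = 0.8, noise_sd = 1,
                          interaction_fidelity = 0.5, decoy_rate = 1,
                          baseline_hazard = 0.1, survival_effect = 1.5,
                          censoring_rate = 0.025, missing_rate = 0,
                          causal_module = 1, seed = 1) {
  stopifnot(n_modules >= 1, n_background >= 1, n_samples >= 3, n_datasets >= 1,
            rho_w > 0, rho_w < 1)
  for (f in c(gene_overlap, sample_overlap, interaction_fidelity, missing_rate))
    if (f < 0 || f > 1) stopf("fractions must be in [0, 1]")
  if (causal_module > n_modules) stopf("'causal_module' exceeds 'n_modules'")
  set.seed(seed)
  sizes <- if (length(module_size) == 2L)
    sample(module_size[1L]:module_size[2L], n_modules, replace = TRUE)
  else rep(module_size, n_modules)
  mod_ids <- sprintf("M%d", seq_len(n_modules))
  mod_genes <- lapply(seq_len(n_modules), function(m)
    sprintf("g%04d", sum(sizes[seq_len(m - 1L)]) + seq_len(sizes[m])))
  names(mod_genes) <- mod_ids
  bg_genes <- sprintf("b%04d", seq_len(n_background))
  genes <- c(unlist(mod_genes, use.names = FALSE), bg_genes)
  gene_module <- stats::setNames(rep(c(mod_ids, NA), c(sizes, n_background)), genes)

  n_shared <- round(sample_overlap * n_samples)
  shared <- sprintf("s%03d", seq_len(n_shared))
  sample_sets <- lapply(seq_len(n_datasets), function(d)
    c(shared, sprintf("d%d.s%03d", d, seq_len(n_samples - n_shared))))
  all_samples <- unique(unlist(sample_sets))
  factors <- matrix(stats::rnorm(length(all_samples) * n_modules),
                    nrow = length(all_samples),
                    dimnames = list(all_samples, mod_ids))

  bg_scale <- sqrt(rho_w + noise_sd^2 * (1 - rho_w))  # match module-gene variance
  datasets <- vector("list", n_datasets)
  for (d in seq_len(n_datasets)) {
    gset <- if (d == 1L) genes else sort(sample(genes, round(gene_overlap * length(genes))))
    smp <- sample_sets[[d]]
    vals <- matrix(NA_real_, length(gset), length(smp), dimnames = list(gset, smp))
    for (g in gset) {
      m <- gene_module[[g]]
      vals[g, ] <- if (is.na(m)) bg_scale * stats::rnorm(length(smp))
      else sqrt(rho_w) * factors[smp, m] +
           noise_sd * sqrt(1 - rho_w) * stats::rnorm(length(smp))
    }
    if (missing_rate > 0)
      vals[stats::runif(length(vals)) < missing_rate] <- NA_real_
    datasets[[d]] <- expression_matrix(vals, sprintf("omics%d", d))
  }
  names(datasets) <- sprintf("omics%d", seq_len(n_datasets))

  tf_targets <- list(); mirna_targets <- list()
  n_true <- 0L
  if (interaction_fidelity > 0) {
    for (m in seq_len(n_modules)) {
      cover <- max(1L, round(interaction_fidelity * sizes[m]))
      tf_targets[[sprintf("TF%d", m)]] <- sort(sample(mod_genes[[m]], cover))
      mirna_targets[[sprintf("miR%d", m)]] <- sort(sample(mod_genes[[m]], cover))
      n_true <- n_true + 2L * cover
    }
  }
  n_decoy <- round(decoy_rate * max(n_true, 2L * n_modules))
  if (n_decoy > 0L) {
    per_reg <- 5L
    n_reg <- ceiling(n_decoy / per_reg)
    for (i in seq_len(n_reg)) {
      tgt <- sort(sample(genes, min(per_reg, n_decoy - (i - 1L) * per_reg)))
      if (i %% 2L == 1L) tf_targets[[sprintf("dTF%d", i)]] <- tgt
      else mirna_targets[[sprintf("dmiR%d", i)]] <- tgt
    }
  }
  interactions <- interaction_db(tf_targets = tf_targets, mirna_targets = mirna_targets)

  patients <- sample_sets[[1L]]
  causal <- mod_genes[[causal_module]]
  expr1 <- datasets[[1L]][causal, patients, drop = FALSE]
  if (anyNA(expr1)) expr1 <- impute_knn(expression_matrix(expr1, "omics1"), 10)
  sigma <- coexpression_sd(expr1)$sigma
  sig_std <- (sigma - mean(sigma)) / stats::sd(sigma)
  t_event <- stats::rexp(length(patients),
                         rate = baseline_hazard * exp(survival_effect * sig_std))
  t_cens <- stats::rexp(length(patients), rate = censoring_rate)
  clinical <- data.frame(sample_id = patients,
                         time = pmin(t_event, t_cens),
                         event = as.integer(t_event <= t_cens),
                         stringsAsFactors = FALSE)

  list(datasets = datasets,
       interactions = interactions,
       truth = module_set(mod_genes, outliers = bg_genes),
       clinical = clinical,
       sigma = sigma,
       causal_module = mod_ids[causal_module],
       config = list(n_modules = n_modules, sizes = sizes,
                     n_background = n_background, n_samples = n_samples,
                     n_datasets = n_datasets, gene_overlap = gene_overlap,
                     sample_overlap = sample_overlap, rho_w = rho_w,
                     noise_sd = noise_sd,
                     interaction_fidelity = interaction_fidelity,
                     decoy_rate = decoy_rate, baseline_hazard = baseline_hazard,
                     survival_effect = survival_effect,
                     censoring_rate = censoring_rate,
                     missing_rate = missing_rate, seed = seed))
}

#' Compare detected modules with the planted truth
#'
#' Computes the adjusted Rand index between the two hard assignments
#' (every gene labelled by its module, with unassigned/outlier genes as
#' one extra class, over the union of genes covered by either side)
#' together with the relevance and recovery agreement scores.
#'
#' @param detected,truth \code{clam_modules} objects.
#' @return List with \code{ari}, \code{relevance}, \code{recovery}.
#' @export
truth_comparison <- function(detected, truth) {
  lab <- function(ms, genes) {
    l <- stats::setNames(rep(".outlier", length(genes)), genes)
    for (m in names(ms$modules)) {
      g <- intersect(ms$modules[[m]], genes)
      l[g] <- m
    }
    l
  }
  genes <- union(union(unlist(detected$modules), detected$outliers),
                 union(unlist(truth$modules), truth$outliers))
  ari <- mclust::adjustedRandIndex(lab(detected, genes), lab(truth, genes))
  list(ari = ari,
       relevance = module_relevance(detected, truth),
       recovery = module_recovery(detected, truth))
}
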