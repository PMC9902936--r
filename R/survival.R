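# Module-based survival analysis.
#
# For a module's genes, expression profiles are sign-aligned (so that
# anti-correlated members point the same way), z-scored per gene across
# patients, and summarised per patient by the standard deviation across
# the module genes.  A low standard deviation means the genes are
# tightly co-expressed in that patient.  Patients are split at the
# median of the statistic (ties to the "low" group) and the two
# survival curves compared by the log-rank test.  Alternative
# per-patient statistics -- the mean of the oriented z-scores, or a
# single gene's expression -- serve as comparison modes.

#' Orientation signs for a module's genes
#'
#' Chooses a sign (+1/-1) per gene so that all genes correlate
#' non-negatively with a reference member.  The reference is the gene
#' with the largest summed absolute correlation to the others (ties by
#' lexicographic gene id); each other gene takes the sign of its
#' Pearson correlation with the reference.  Zero-variance genes are
#' excluded with a warning.
#'
#' @param expr Numeric genes-x-samples matrix restricted to the
#'   module's genes (>= 2 genes, >= 3 samples).
#' @return Named numeric vector of +1/-1 signs over the retained
#'   genes.
#' @export
orient_genes <- function(expr) {
  if (nrow(expr) < 2L) stopf("need at least 2 genes to orient")
  if (ncol(expr) < 3L) stopf("need at least 3 shared samples to orient")
  v <- apply(expr, 1L, stats::sd)
  if (any(v == 0)) {
    warnf("excluding %d zero-variance gene(s) from the module", sum(v == 0))
    expr <- expr[v > 0, , drop = FALSE]
    if (nrow(expr) < 2L) stopf("fewer than 2 genes left after excluding zero variance")
  }
  r <- stats::cor(t(expr))
  tot <- rowSums(abs(r)) - 1   # exclude the self-correlation
  ref <- rownames(expr)[order(-tot, rownames(expr))][1L]
  s <- sign(r[ref, ])
  s[s == 0] <- 1
  s[ref] <- 1
  s
}

#' Per-patient co-expression standard deviation
#'
#' Applies population-denominator z-scoring per gene across patients,
#' flips genes by their orientation signs, and returns for each patient
#' the population standard deviation of the transformed values across
#' the module's genes.  Low values mean high co-expression.
#'
#' @param expr Genes-x-samples matrix restricted to the module.
#' @param signs Optional orientation signs (computed by
#'   [orient_genes()] if missing).
#' @return List with \code{sigma} (named per-patient statistic),
#'   \code{signs} and \code{z} (the oriented z-score matrix).
#' @export
coexpression_sd <- function(expr, signs = NULL) {
  signs <- signs %||% orient_genes(expr)
  expr <- expr[names(signs), , drop = FALSE]
  if (nrow(expr) < 2L) stopf("module has fewer than 2 usable genes")
  z <- zscore_rows(expr) * signs
  sigma <- apply(z, 2L, sd_pop)
  list(sigma = sigma, signs = signs, z = z)
}

#' Median split and log-rank test on a per-patient statistic
#'
#' Patients with statistic strictly greater than the median form the
#' "high" group; those at or below it form the "low" group.  The two
#' groups' survival curves are compared with the log-rank test.  A
#' constant statistic (one group empty) or a cohort without events
#' yields a degenerate result with chi-square 0 and p = 1, flagged.
#'
#' @param statistic Named per-patient values (names = sample ids).
#' @param clinical Data frame with \code{sample_id}, \code{time},
#'   \code{event}; intersected with the statistic's names.
#' @return List with \code{chisq}, \code{p}, group sizes, the group
#'   factor, Kaplan-Meier coordinates per group and a
#'   \code{degenerate} flag.
#' @export
logrank_split <- function(statistic, clinical) {
  common <- intersect(names(statistic), clinical$sample_id)
  if (length(common) < 4L) stopf("need at least 4 patients with clinical data")
  dropped <- length(statistic) - length(common)
  if (dropped > 0L) message(sprintf("%d patient(s) without clinical data dropped", dropped))
  st <- statistic[common]
  cl <- clinical[match(common, clinical$sample_id), ]
  med <- stats::median(st)
  grp <- factor(ifelse(st > med, "high", "low"), levels = c("low", "high"))
  n_low <- sum(grp == "low"); n_high <- sum(grp == "high")
  km <- function(idx) {
    if (!length(idx)) return(NULL)
    f <- survival::survfit(survival::Surv(cl$time[idx], cl$event[idx]) ~ 1)
    data.frame(time = f$time, surv = f$surv, n_risk = f$n.risk)
  }
  degenerate <- n_low == 0L || n_high == 0L || sum(cl$event) == 0L
  if (degenerate) {
    return(list(chisq = 0, p = 1, n_low = n_low, n_high = n_high,
                group = stats::setNames(grp, common),
                km = list(low = km(which(grp == "low")), high = km(which(grp == "high"))),
                degenerate = TRUE))
  }
  sd_ <- survival::survdiff(survival::Surv(cl$time, cl$event) ~ grp)
  chisq <- unname(sd_$chisq)
  list(chisq = chisq, p = stats::pchisq(chisq, df = 1, lower.tail = FALSE),
       n_low = n_low, n_high = n_high,
       group = stats::setNames(grp, common),
       km = list(low = km(which(grp == "low")), high = km(which(grp == "high"))),
       degenerate = FALSE)
}

#' Screen modules for survival-associated co-expression
#'
#' Runs the module-based survival analysis for every module and each
#' requested per-patient statistic: \code{"sd"} (standard deviation of
#' the oriented z-scores; the co-expression statistic), \code{"mean"}
#' (mean of the oriented z-scores) and \code{"single_gene"} (each
#' member gene's raw expression separately, reporting the gene with the
#' smallest log-rank p).  Raw log-rank p-values are
#' Benjamini-Hochberg-adjusted within each mode across modules.
#'
#' @param modules A \code{clam_modules} object or named list of gene
#'   vectors.
#' @param expr Genes-x-samples expression matrix.
#' @param clinical Clinical table (\code{sample_id}, \code{time},
#'   \code{event}).
#' @param modes Character subset of \code{c("sd", "mean",
#'   "single_gene")}.
#' @param alpha Significance threshold recorded in the result, default
#'   0.05.
#' @return An object of class \code{clam_survival}: a results data
#'   frame (one row per module x mode, ranked by p within mode) with
#'   attributes carrying the per-module Kaplan-Meier coordinates and
#'   orientation signs.
#' @export
clam_survival <- function(modules, expr, clinical,
                          modes = c("sd", "mean", "single_gene"), alpha = 0.05) {
  mods <- as_module_list(modules)
  modes <- match.arg(modes, several.ok = TRUE)
  rows <- list(); km_store <- list(); sign_store <- list()
  skipped <- character()
  for (nm in names(mods)) {
    genes <- intersect(mods[[nm]], rownames(expr))
    common <- intersect(colnames(expr), clinical$sample_id)
    if (length(genes) < 2L || length(common) < 4L) { skipped <- c(skipped, nm); next }
    sub <- expr[genes, common, drop = FALSE]
    cx <- tryCatch(coexpression_sd(sub), error = function(e) NULL)
    if (is.null(cx)) { skipped <- c(skipped, nm); next }
    sign_store[[nm]] <- cx$signs
    for (mode in modes) {
      if (mode == "single_gene") {
        best <- NULL
        for (g in rownames(sub)) {
          r <- logrank_split(sub[g, ], clinical)
          if (is.null(best) || r$p < best$p) { best <- r; best$gene <- g }
        }
        res <- best
      } else {
        stat <- if (mode == "sd") cx$sigma else colMeans(cx$z)
        res <- logrank_split(stat, clinical)
        res$gene <- NA_character_
      }
      rows[[length(rows) + 1L]] <- data.frame(
        module = nm, mode = mode, n_genes = nrow(sub),
        gene = res$gene, chisq = res$chisq, p = res$p,
        n_low = res$n_low, n_high = res$n_high,
        degenerate = res$degenerate, stringsAsFactors = FALSE)
      km_store[[paste(nm, mode, sep = ".")]] <- res$km
    }
  }
  if (length(rows) == 0L) stopf("no module could be analysed")
  df <- do.call(rbind, rows)
  df$p_adj <- NA_real_
  for (mode in modes) {
    i <- df$mode == mode
    df$p_adj[i] <- stats::p.adjust(df$p[i], method = "BH")
  }
  df <- df[order(df$mode, df$p), ]
  rownames(df) <- NULL
  structure(df, km = km_store, signs = sign_store, alpha = alpha,
            skipped = skipped, class = c("clam_survival", "data.frame"))
}

#' @export
print.clam_survival <- function(x, ...) {
  cat(sprintf("Module-based survival screen: %d result(s), alpha = %g\n",
              nrow(x), attr(x, "alpha")))
  sk <- attr(x, "skipped")
  if (length(sk)) cat(sprintf("  skipped module(s): %s\n", paste(sk, collapse = ", ")))
  print.data.frame(x, digits = 4)
  invisible(x)
}

#' Kaplan-Meier curves for one screened module
#'
#' @param x A \code{clam_survival} object.
#' @param module Module id to plot.
#' @param mode Statistic mode, default \code{"sd"}.
#' @param ... Passed to \code{plot}.
#' @export
plot.clam_survival <- function(x, module = x$module[1L], mode = "sd", ...) {
  km <- attr(x, "km")[[paste(module, mode, sep = ".")]]
  if (is.null(km)) stopf("no Kaplan-Meier curves stored for module '%s', mode '%s'", module, mode)
  step_xy <- function(d) list(x = c(0, rep(d$time, each = 2)),
                              y = c(1, 1, rep(d$surv, each = 2)[-(2 * nrow(d))]))
  lo <- step_xy(km$low); hi <- step_xy(km$high)
  graphics::plot(range(c(lo$x, hi$x)), c(0, 1), type = "n",
                 xlab = "time", ylab = "survival",
                 main = sprintf("%s (%s split)", module, mode), ...)
  graphics::lines(lo$x, lo$y, col = "steelblue", lwd = 2)
  graphics::lines(hi$x, hi$y, col = "firebrick", lwd = 2)
  graphics::legend("bottomleft", c("low statistic", "high statistic"),
                   col = c("steelblue", "firebrick"), lwd = 2, bty = "n")
  invisible(x)
}

#' Write a survival screen as TSV
#' @param x A \code{clam_survival} object.
#' @param path Output path.
#' @export
write_survival <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
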