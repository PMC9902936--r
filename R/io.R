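# Readers/writers for the plain-text formats the pipeline consumes
# (expression TSV, GMT gene sets, interaction edge lists, clinical tables)
# and the expression preprocessing steps: missing-value filtering and
# KNN imputation.

MISSING_MARKERS <- c("", "na", "nan", "null")

#' Read an expression matrix from TSV
#'
#' Expects a header row of sample identifiers and a first column of gene
#' identifiers; remaining cells are numeric expression values.  Empty
#' fields and the markers \code{NA}, \code{NaN}, \code{null}
#' (case-insensitive) denote missing values.  Duplicate gene rows are
#' collapsed by their per-sample mean (over non-missing values).
#'
#' @param path Path to a tab-separated file.
#' @param dataset_id Short identifier for the omics layer this matrix
#'   represents; defaults to the file name without extension.
#' @return A numeric matrix (genes x samples) with a \code{dataset_id}
#'   attribute.  Missing entries are \code{NA}.
#' @export
read_expression <- function(path, dataset_id = NULL) {
  lines <- readLines(path)
  if (length(lines) < 2L) stopf("expression file '%s': need a header and at least one gene row", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1L]]
  samples <- header[-1L]
  if (length(samples) == 0L) stopf("expression file '%s': header has no sample columns", path)
  if (anyDuplicated(samples)) stopf("expression file '%s': duplicate sample id '%s'", path,
                                    samples[duplicated(samples)][1L])
  body <- fields[-1L]
  nf <- lengths(body)
  if (any(nf != length(header))) {
    stopf("expression file '%s': row %d has %d fields, expected %d", path,
          which(nf != length(header))[1L] + 1L, nf[nf != length(header)][1L], length(header))
  }
  genes <- vapply(body, `[`, character(1L), 1L)
  cells <- t(vapply(body, function(f) f[-1L], character(length(samples))))
  if (length(samples) == 1L) cells <- matrix(cells, ncol = 1L)
  low <- tolower(trimws(cells))
  miss <- low %in% MISSING_MARKERS
  vals <- suppressWarnings(as.numeric(cells))
  bad <- !miss & is.na(vals)
  if (any(bad)) {
    idx <- which(bad, arr.ind = FALSE)[1L]
    stopf("expression file '%s': non-numeric value '%s' for gene '%s'", path,
          cells[idx], genes[(idx - 1L) %% length(genes) + 1L])
  }
  vals[miss] <- NA_real_
  mat <- matrix(vals, nrow = length(genes), dimnames = list(genes, samples))
  if (anyDuplicated(genes)) {
    mat <- collapse_duplicate_genes(mat)
  }
  expression_matrix(mat, dataset_id %||% sub("\\.[^.]*$", "", basename(path)))
}

# Mean-collapse duplicate gene rows, ignoring missing entries.
collapse_duplicate_genes <- function(mat) {
  grp <- rownames(mat)
  out <- rowsum(ifelse(is.na(mat), 0, mat), grp, reorder = FALSE)
  cnt <- rowsum((!is.na(mat)) * 1, grp, reorder = FALSE)
  res <- out / cnt                       # 0/0 -> NaN where all copies missing
  res[cnt == 0] <- NA_real_
  res[, , drop = FALSE]
}

#' Construct an expression matrix object
#'
#' Validates and tags a genes-x-samples numeric matrix with its dataset
#' identity.  Used by the readers and the synthetic generator; accepts
#' any numeric matrix with unique dimnames.
#'
#' @param values Numeric matrix, genes in rows, samples in columns.
#' @param dataset_id Short string naming the omics layer.
#' @return The matrix with a \code{dataset_id} attribute.
#' @export
expression_matrix <- function(values, dataset_id) {
  if (!is.matrix(values) || !is.numeric(values)) stopf("'values' must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stopf("expression matrix needs gene rownames and sample colnames")
  if (anyDuplicated(rownames(values))) stopf("duplicate gene identifiers")
  if (anyDuplicated(colnames(values))) stopf("duplicate sample identifiers")
  attr(values, "dataset_id") <- as.character(dataset_id)
  values
}

dataset_id <- function(mat) attr(mat, "dataset_id") %||% "dataset"

#' Write an expression matrix to TSV
#'
#' @param mat Numeric genes-x-samples matrix.
#' @param path Output path.
#' @export
write_expression <- function(mat, path) {
  df <- data.frame(gene = rownames(mat), mat, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Remove genes with too many missing values
#'
#' Drops every gene whose fraction of missing entries is strictly
#' greater than \code{max_missing_fraction}; a gene exactly at the
#' threshold is retained.
#'
#' @param mat Expression matrix (genes x samples), \code{NA} = missing.
#' @param max_missing_fraction Highest tolerated missing fraction,
#'   default 0.20.
#' @return The filtered matrix.
#' @export
filter_missing <- function(mat, max_missing_fraction = 0.20) {
  if (max_missing_fraction < 0 || max_missing_fraction > 1)
    stopf("'max_missing_fraction' must be in [0, 1]")
  frac <- rowMeans(is.na(mat))
  keep <- frac <= max_missing_fraction
  if (!any(keep)) stopf("all genes exceed the missing-value threshold %.2f", max_missing_fraction)
  id <- dataset_id(mat)
  expression_matrix(mat[keep, , drop = FALSE], id)
}

#' Impute missing expression values by k-nearest-neighbour averaging
#'
#' Each missing entry of a gene is replaced by the inverse-distance
#' weighted mean of the k genes nearest to it.  Distances are Euclidean
#' over the samples observed in both genes, rescaled by the square root
#' of the observed fraction so that genes compared over few samples are
#' not spuriously close.  Only genes observed in the sample holding the
#' gap are candidate donors; exact-copy donors (distance zero) take
#' precedence.
#'
#' @param mat Expression matrix with \code{NA} marking missing entries.
#' @param k Number of donor genes, default 10.
#' @return The matrix with all missing entries filled.
#' @export
impute_knn <- function(mat, k = 10) {
  if (k < 1) stopf("'k' must be >= 1")
  if (!anyNA(mat)) return(mat)
  id <- dataset_id(mat)
  n_samp <- ncol(mat)
  obs <- !is.na(mat)
  out <- mat
  for (g in which(rowSums(!obs) > 0L)) {
    d <- impute_distances(mat, obs, g)
    for (s in which(!obs[g, ])) {
      cand <- which(obs[, s] & is.finite(d))
      if (length(cand) == 0L)
        stopf("gene '%s' has no co-observed donor gene for sample '%s'",
              rownames(mat)[g], colnames(mat)[s])
      cand <- cand[order(d[cand], rownames(mat)[cand])]
      cand <- cand[seq_len(min(k, length(cand)))]
      dd <- d[cand]
      if (any(dd == 0)) {
        out[g, s] <- mean(mat[cand[dd == 0], s])
      } else {
        w <- 1 / dd
        out[g, s] <- sum(w * mat[cand, s]) / sum(w)
      }
    }
  }
  expression_matrix(out, id)
}

# Scaled Euclidean distance from gene g to every other gene over
# co-observed samples; Inf where no sample is co-observed.
impute_distances <- function(mat, obs, g) {
  co <- obs & rep(obs[g, ], each = nrow(mat))
  n_co <- rowSums(co)
  diff2 <- (mat - rep(mat[g, ], each = nrow(mat)))^2
  diff2[!co] <- 0
  d <- sqrt(rowSums(diff2)) / sqrt(n_co / ncol(mat))
  d[n_co == 0L] <- Inf
  d[g] <- Inf
  d
}

#' Construct a module set
#'
#' A module set maps module identifiers to gene sets, with an optional
#' set of outlier genes that belong to no module.
#'
#' @param modules Named list of character vectors (gene identifiers).
#' @param outliers Character vector of unassigned genes.
#' @param descriptions Optional named character vector of module
#'   descriptions (second GMT column).
#' @return An object of class \code{clam_modules}.
#' @export
module_set <- function(modules, outliers = character(), descriptions = NULL) {
  if (length(modules) > 0L && (is.null(names(modules)) || any(names(modules) == "")))
    stopf("all modules must be named")
  if (anyDuplicated(names(modules))) stopf("duplicate module names")
  modules <- lapply(modules, function(g) unique(as.character(g)))
  structure(list(modules = modules,
                 outliers = unique(as.character(outliers)),
                 descriptions = descriptions),
            class = "clam_modules")
}

#' @export
print.clam_modules <- function(x, ...) {
  sizes <- lengths(x$modules)
  cat(sprintf("Module set: %d modules over %d genes (%d outliers)\n",
              length(x$modules), length(unique(unlist(x$modules))), length(x$outliers)))
  if (length(sizes)) {
    cat(sprintf("  module sizes: min %d, median %g, max %d\n",
                min(sizes), stats::median(sizes), max(sizes)))
  }
  invisible(x)
}

#' @export
length.clam_modules <- function(x) length(x$modules)

#' Read gene sets in GMT format
#'
#' One module per line: name, description, then tab-separated members.
#' Duplicate members within a line are dropped.
#'
#' @param path Path to a GMT file.
#' @return A \code{clam_modules} object.
#' @export
read_gene_sets <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L))
    stopf("GMT file '%s': line %d has %d fields, need at least 3", path,
          which(nf < 3L)[1L], min(nf))
  nm <- vapply(fields, `[`, character(1L), 1L)
  if (anyDuplicated(nm)) stopf("GMT file '%s': duplicate module name '%s'", path,
                               nm[duplicated(nm)][1L])
  desc <- vapply(fields, `[`, character(1L), 2L)
  names(desc) <- nm
  mods <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(mods) <- nm
  module_set(mods, descriptions = desc)
}

#' Write gene sets in GMT format
#'
#' @param modules A \code{clam_modules} object or named list of gene
#'   vectors.
#' @param path Output path.
#' @export
write_gene_sets <- function(modules, path) {
  if (inherits(modules, "clam_modules")) {
    desc <- modules$descriptions
    modules <- modules$modules
  } else desc <- NULL
  lines <- vapply(names(modules), function(nm) {
    d <- if (!is.null(desc) && nm %in% names(desc)) desc[[nm]] else "."
    paste(c(nm, d, modules[[nm]]), collapse = "\t")
  }, character(1L))
  writeLines(lines, path)
  invisible(path)
}

#' Construct an interaction database
#'
#' Holds the known molecular interactions used to compute co-regulation
#' priors: TF targets, miRNA targets, protein-protein interaction (PPI)
#' edges and pathway gene sets.  PPI edges are stored symmetrically and
#' self-edges are dropped.
#'
#' @param tf_targets Named list: TF -> character vector of target genes.
#' @param mirna_targets Named list: miRNA -> target genes.
#' @param ppi_edges Two-column matrix or data frame of undirected gene
#'   pairs, or \code{NULL}.
#' @param pathways Named list: pathway id -> gene set.
#' @return An object of class \code{clam_interactions}.
#' @export
interaction_db <- function(tf_targets = list(), mirna_targets = list(),
                           ppi_edges = NULL, pathways = list()) {
  norm_map <- function(m) {
    m <- lapply(m, function(x) unique(as.character(x)))
    m[lengths(m) > 0L]
  }
  ppi <- list()
  if (!is.null(ppi_edges) && NROW(ppi_edges) > 0L) {
    if (!is.data.frame(ppi_edges)) ppi_edges <- as.data.frame(ppi_edges, stringsAsFactors = FALSE)
    a <- as.character(ppi_edges[[1L]])
    b <- as.character(ppi_edges[[2L]])
    keep <- a != b
    a2 <- c(a[keep], b[keep]); b2 <- c(b[keep], a[keep])
    ppi <- split(b2, a2)
    ppi <- lapply(ppi, function(x) sort(unique(x)))
  }
  structure(list(tf_targets = norm_map(tf_targets),
                 mirna_targets = norm_map(mirna_targets),
                 ppi = ppi,
                 pathways = norm_map(pathways)),
            class = "clam_interactions")
}

#' @export
print.clam_interactions <- function(x, ...) {
  cat(sprintf("Interaction database: %d TFs, %d miRNAs, %d genes with PPI partners, %d pathways\n",
              length(x$tf_targets), length(x$mirna_targets), length(x$ppi), length(x$pathways)))
  invisible(x)
}

#' Read interaction resources from edge lists and GMT
#'
#' TF and miRNA files are two-column TSVs (regulator, target); the PPI
#' file is a two-column TSV of undirected pairs; pathways are GMT.  Any
#' argument may be \code{NULL}.  Malformed lines are skipped and their
#' count reported as a message.
#'
#' @param tf_path,mirna_path,ppi_path Paths to edge-list TSVs or
#'   \code{NULL}.
#' @param pathway_path Path to a pathway GMT file or \code{NULL}.
#' @return A \code{clam_interactions} object.
#' @export
read_interactions <- function(tf_path = NULL, mirna_path = NULL,
                              ppi_path = NULL, pathway_path = NULL) {
  read_edges <- function(path) {
    if (is.null(path)) return(NULL)
    lines <- readLines(path)
    lines <- lines[nzchar(lines)]
    fields <- strsplit(lines, "\t", fixed = TRUE)
    ok <- lengths(fields) >= 2L
    if (any(!ok)) message(sprintf("%s: skipped %d malformed line(s)", basename(path), sum(!ok)))
    fields <- fields[ok]
    data.frame(from = vapply(fields, `[`, character(1L), 1L),
               to = vapply(fields, `[`, character(1L), 2L),
               stringsAsFactors = FALSE)
  }
  edges_to_map <- function(df) {
    if (is.null(df) || nrow(df) == 0L) return(list())
    lapply(split(df$to, df$from), unique)
  }
  pathways <- if (is.null(pathway_path)) list() else read_gene_sets(pathway_path)$modules
  interaction_db(tf_targets = edges_to_map(read_edges(tf_path)),
                 mirna_targets = edges_to_map(read_edges(mirna_path)),
                 ppi_edges = read_edges(ppi_path),
                 pathways = pathways)
}

#' Read a clinical survival table
#'
#' TSV with columns \code{sample_id}, \code{time} (non-negative, study
#' time units) and \code{event} (1 = event observed, 0 = censored).
#'
#' @param path Path to the TSV file.
#' @return A data frame with one row per sample.
#' @export
read_clinical <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "time", "event")
  if (!all(need %in% names(df)))
    stopf("clinical file '%s': need columns %s", path, paste(need, collapse = ", "))
  df <- df[need]
  if (anyDuplicated(df$sample_id)) stopf("clinical file '%s': duplicate sample ids", path)
  if (any(df$time < 0)) stopf("clinical file '%s': negative survival times", path)
  if (!all(df$event %in% c(0, 1))) stopf("clinical file '%s': event must be 0 or 1", path)
  df
}

#' Write a clinical survival table
#' @param clinical Data frame with sample_id, time, event.
#' @param path Output path.
#' @export
write_clinical <- function(clinical, path) {
  utils::write.table(clinical, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
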