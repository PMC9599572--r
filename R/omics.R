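#' Build an expression matrix container
#'
#' Holds a gene x sample raw count matrix, per-sample metadata (time point
#' and replicate), and a gene -> species map. Time points follow the
#' two-point chitin growth design (70 h and 118 h).
#'
#' @param counts Nonnegative integer matrix, genes in rows (rownames
#'   required), samples in columns (colnames required).
#' @param samples Data frame with columns `sample_id`, `time_point`
#'   (`"70h"` or `"118h"`), `replicate`; one row per count column.
#' @param gene_map Named character vector mapping every gene to exactly one
#'   species id.
#' @return Object of class `cn_expr`.
#' @export
expression_matrix <- function(counts, samples, gene_map) {
  stopifnot(is.matrix(counts), !is.null(rownames(counts)),
            !is.null(colnames(counts)), all(counts >= 0))
  stopifnot(is.data.frame(samples),
            all(c("sample_id", "time_point", "replicate") %in% names(samples)),
            setequal(samples$sample_id, colnames(counts)))
  if (!all(samples$time_point %in% c("70h", "118h"))) {
    stop("time_point must be '70h' or '118h'")
  }
  missing <- setdiff(rownames(counts), names(gene_map))
  if (length(missing)) {
    stop("genes without a species mapping: ",
         paste(utils::head(missing, 5), collapse = ", "))
  }
  samples <- samples[match(colnames(counts), samples$sample_id), , drop = FALSE]
  structure(list(counts = counts, samples = samples,
                 gene_map = gene_map[rownames(counts)],
                 normalized = NULL, size_factors = NULL),
            class = "cn_expr")
}

# Median-of-ratios size factors for one submatrix (genes x samples),
# rescaled to unit median so unshifted samples sit at factor 1.
median_of_ratios <- function(mat) {
  logm <- log(mat)
  geo <- rowMeans(logm)
  use <- is.finite(geo)
  if (!any(use)) return(NULL)
  f <- apply(logm[use, , drop = FALSE], 2, function(col) {
    exp(stats::median(col - geo[use]))
  })
  f / stats::median(f)
}

#' Per-species median-of-ratios normalization
#'
#' Size factors are computed within each species' gene set independently, so
#' that shifts in a species' overall abundance are not misread as
#' coordinated gene expression changes. Normalized counts are the raw counts
#' divided by the sample-and-species size factor. A species submatrix with
#' no gene of nonzero geometric mean gets size factors of 1 with a warning.
#'
#' @param em A [expression_matrix()].
#' @return The `cn_expr` with `$normalized` (matrix) and `$size_factors`
#'   (species x sample matrix) filled in.
#' @export
normalize_counts <- function(em) {
  stopifnot(inherits(em, "cn_expr"))
  species <- sort(unique(em$gene_map))
  sf <- matrix(1, nrow = length(species), ncol = ncol(em$counts),
               dimnames = list(species, colnames(em$counts)))
  norm <- em$counts * 1.0
  for (sp in species) {
    rows <- names(em$gene_map)[em$gene_map == sp]
    f <- median_of_ratios(em$counts[rows, , drop = FALSE])
    if (is.null(f)) {
      warning("species '", sp, "': no gene with nonzero geometric mean; ",
              "size factors set to 1")
      f <- rep(1, ncol(em$counts))
    }
    sf[sp, ] <- f
    norm[rows, ] <- sweep(em$counts[rows, , drop = FALSE], 2, f, "/")
  }
  em$normalized <- norm
  em$size_factors <- sf
  em
}

#' Call differentially expressed genes between time points
#'
#' Two-group Wald test (118 h vs 70 h) on per-species-normalized counts
#' under a negative-binomial mean model with method-of-moments dispersion,
#' a t reference distribution (df = n1 + n2 - 2), and Benjamini-Hochberg
#' adjustment within each species. A gene is a DEG iff adjusted P <= `alpha`
#' and absolute fold change > `min_fold`. Genes with zero counts everywhere
#' are excluded from testing and reported as untested.
#'
#' @param em A [expression_matrix()]; normalized on the fly if needed.
#' @param alpha Adjusted-P cutoff (default 0.05).
#' @param min_fold Fold-change cutoff, strict (default 2).
#' @return Data frame with columns `gene_id`, `species_id`, `base_mean`,
#'   `log2_fold_change`, `p_value`, `adjusted_p`, `is_deg`, `status`.
#' @export
call_degs <- function(em, alpha = 0.05, min_fold = 2) {
  stopifnot(inherits(em, "cn_expr"))
  if (is.null(em$normalized)) em <- normalize_counts(em)
  g1 <- em$samples$sample_id[em$samples$time_point == "70h"]
  g2 <- em$samples$sample_id[em$samples$time_point == "118h"]
  if (length(g1) < 2L || length(g2) < 2L) {
    stop("need >= 2 replicates in each time-point group")
  }
  n1 <- length(g1); n2 <- length(g2)
  genes <- rownames(em$counts)
  x1 <- em$normalized[, g1, drop = FALSE]
  x2 <- em$normalized[, g2, drop = FALSE]
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  v1 <- apply(x1, 1, stats::var); v2 <- apply(x2, 1, stats::var)
  tested <- rowSums(em$counts) > 0
  species <- em$gene_map[genes]
  # Method-of-moments NB dispersion pooled across each species' genes: the
  # per-gene estimator is hopeless at 2-3 replicates, but the within-group
  # mean-variance relation is shared, so the species-level median is stable.
  gene_disp <- rep(NA_real_, length(genes))
  for (i in which(tested)) {
    num <- 0; den <- 0
    if (m1[i] > 0) { num <- num + (v1[i] - m1[i]) / m1[i]^2; den <- den + 1 }
    if (m2[i] > 0) { num <- num + (v2[i] - m2[i]) / m2[i]^2; den <- den + 1 }
    if (den > 0) gene_disp[i] <- num / den
  }
  disp <- rep(1e-8, length(genes))
  for (sp in unique(species)) {
    idx <- which(species == sp & !is.na(gene_disp))
    if (length(idx)) {
      disp[species == sp] <- max(stats::median(gene_disp[idx]), 1e-8)
    }
  }
  pc <- 0.5  # pseudocount guards log fold changes when one group mean is 0
  lfc <- log2((m2 + pc) / (m1 + pc))
  se_log <- sqrt((1 / n1) * (1 / (m1 + pc) + disp) +
                   (1 / n2) * (1 / (m2 + pc) + disp))
  z <- (log(m2 + pc) - log(m1 + pc)) / se_log
  # Empirical-null recalibration: at 2-3 replicates the Wald statistic has
  # heavier-than-normal tails, so rescale z within each species by a robust
  # (median/MAD) estimate of the null location and spread; the MAD floor of
  # 1 only ever widens p-values, never sharpens them.
  for (sp in unique(species)) {
    idx <- which(species == sp & tested)
    if (length(idx) >= 10L) {
      ctr <- stats::median(z[idx])
      s0 <- max(1, stats::mad(z[idx], center = ctr))
      z[idx] <- (z[idx] - ctr) / s0
    }
  }
  p <- 2 * stats::pnorm(-abs(z))
  p[!tested] <- NA_real_
  padj <- rep(NA_real_, length(genes))
  for (sp in unique(species)) {
    idx <- which(species == sp & tested)
    padj[idx] <- stats::p.adjust(p[idx], method = "BH")
  }
  is_deg <- !is.na(padj) & padj <= alpha & abs(lfc) > log2(min_fold)
  data.frame(gene_id = genes, species_id = unname(species),
             base_mean = unname((m1 * n1 + m2 * n2) / (n1 + n2)),
             log2_fold_change = ifelse(tested, unname(lfc), NA_real_),
             p_value = unname(p), adjusted_p = unname(padj),
             is_deg = unname(is_deg),
             status = ifelse(tested, "tested", "untested"),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Percentage of a genome comprised of DEGs
#'
#' `100 * n_degs / n_genes`, rounded half-even to two decimals, matching the
#' printed "(no. of DEGs / no. of genes in genome) x 100" convention.
#'
#' @param n_degs Number of DEGs, `0 <= n_degs <= n_genes`.
#' @param n_genes Number of genes in the genome; must be positive.
#' @return Numeric percentage with two decimals.
#' @export
deg_percentage <- function(n_degs, n_genes) {
  if (n_genes <= 0) stop("n_genes must be positive")
  if (n_degs < 0 || n_degs > n_genes) stop("need 0 <= n_degs <= n_genes")
  round(100 * n_degs / n_genes, 2)
}

#' Per-species transcript relative-abundance profile
#'
#' Per-sample species fractions of aligned reads (species read sum over
#' total reads), group means and standard deviations per time point, the
#' between-time-point fold change of group means, and a two-sided Welch t
#' test on the per-replicate fractions.
#'
#' @param em A [expression_matrix()].
#' @return Object of class `cn_abundance`: `fractions` (species x sample
#'   matrix summing to 1 per sample) and `summary` (data frame with
#'   `species_id`, `mean_70h`, `sd_70h`, `mean_118h`, `sd_118h`,
#'   `fold_change` (118 h vs 70 h), `p_value`).
#' @export
abundance_profile <- function(em) {
  stopifnot(inherits(em, "cn_expr"))
  totals <- colSums(em$counts)
  if (any(totals == 0)) {
    stop("zero total reads in sample(s): ",
         paste(names(totals)[totals == 0], collapse = ", "))
  }
  by_species <- rowsum(em$counts, group = em$gene_map)
  fractions <- sweep(by_species, 2, totals, "/")
  g1 <- em$samples$sample_id[em$samples$time_point == "70h"]
  g2 <- em$samples$sample_id[em$samples$time_point == "118h"]
  summ <- data.frame(species_id = rownames(fractions),
                     stringsAsFactors = FALSE, row.names = NULL)
  summ$mean_70h <- rowMeans(fractions[, g1, drop = FALSE])
  summ$sd_70h <- apply(fractions[, g1, drop = FALSE], 1, stats::sd)
  summ$mean_118h <- rowMeans(fractions[, g2, drop = FALSE])
  summ$sd_118h <- apply(fractions[, g2, drop = FALSE], 1, stats::sd)
  summ$fold_change <- summ$mean_118h / summ$mean_70h
  summ$p_value <- vapply(seq_len(nrow(fractions)), function(i) {
    a <- fractions[i, g1]; b <- fractions[i, g2]
    if (length(a) < 2L || length(b) < 2L) return(NA_real_)
    out <- tryCatch(stats::t.test(b, a)$p.value, error = function(e) NA_real_)
    out
  }, numeric(1))
  structure(list(fractions = fractions, summary = summ),
            class = "cn_abundance")
}

#' Metabolite differential abundance between two groups
#'
#' Per-metabolite fold change of group means plus a two-sided Welch t test
#' on log-transformed abundances with Benjamini-Hochberg adjustment.
#' Metabolites with any nonpositive abundance are excluded with a warning
#' (log transform undefined).
#'
#' @param abund Metabolite x sample abundance matrix (rownames/colnames
#'   required).
#' @param groups Character vector over samples with exactly two levels; fold
#'   changes are second level vs first (order of first appearance).
#' @param alpha Significance cutoff on adjusted P (default 0.05).
#' @return Data frame: `metabolite`, `fold_change`, `log2_fold_change`,
#'   `p_value`, `adjusted_p`, `significant`.
#' @export
metabolite_diff <- function(abund, groups, alpha = 0.05) {
  stopifnot(is.matrix(abund), !is.null(rownames(abund)),
            length(groups) == ncol(abund))
  lev <- unique(groups)
  if (length(lev) != 2L) stop("groups must have exactly two levels")
  i1 <- groups == lev[1]; i2 <- groups == lev[2]
  if (sum(i1) < 2L || sum(i2) < 2L) {
    stop("need >= 2 replicates per group")
  }
  bad <- apply(abund, 1, function(x) any(!is.finite(x) | x <= 0))
  if (any(bad)) {
    warning(sum(bad), " metabolite(s) with nonpositive abundances excluded")
  }
  keep <- abund[!bad, , drop = FALSE]
  fold <- rowMeans(keep[, i2, drop = FALSE]) /
    rowMeans(keep[, i1, drop = FALSE])
  p <- vapply(seq_len(nrow(keep)), function(i) {
    stats::t.test(log(keep[i, i2]), log(keep[i, i1]))$p.value
  }, numeric(1))
  padj <- stats::p.adjust(p, method = "BH")
  data.frame(metabolite = rownames(keep),
             fold_change = unname(fold),
             log2_fold_change = unname(log2(fold)),
             p_value = unname(p), adjusted_p = unname(padj),
             significant = unname(padj <= alpha),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Functional-category genomic potential vs expressed fractions
#'
#' For each species and category: the genomic fraction is the share of the
#' category's terms found anywhere in the species' annotations; the
#' expressed fraction is the same share restricted to annotations of the
#' species' expressed genes. Expressed genes are a subset of the genome, so
#' the expressed fraction never exceeds the genomic one.
#'
#' @param annotations Data frame with columns `species_id`, `gene_id`,
#'   `term`.
#' @param expressed_genes Named list, species id -> character vector of
#'   expressed gene ids.
#' @param categories Nonempty named list, category -> character vector of
#'   terms.
#' @return Data frame: `species_id`, `category`, `genomic_fraction`,
#'   `expressed_fraction`.
#' @export
category_coverage <- function(annotations, expressed_genes, categories) {
  stopifnot(length(categories) >= 1L,
            all(c("species_id", "gene_id", "term") %in% names(annotations)))
  species <- sort(unique(annotations$species_id))
  rows <- list()
  for (sp in species) {
    ann <- annotations[annotations$species_id == sp, , drop = FALSE]
    expressed <- ann[ann$gene_id %in% expressed_genes[[sp]], , drop = FALSE]
    for (cat in names(categories)) {
      terms <- unique(categories[[cat]])
      rows[[length(rows) + 1L]] <- data.frame(
        species_id = sp, category = cat,
        genomic_fraction = mean(terms %in% ann$term),
        expressed_fraction = mean(terms %in% expressed$term),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
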