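toy_expr <- function(counts, species = NULL) {
  n <- ncol(counts)
  stopifnot(n %% 2 == 0)
  colnames(counts) <- c(sprintf("t70_r%d", seq_len(n / 2)),
                        sprintf("t118_r%d", seq_len(n / 2)))
  samples <- data.frame(
    sample_id = colnames(counts),
    time_point = rep(c("70h", "118h"), each = n / 2),
    replicate = rep(seq_len(n / 2), 2), stringsAsFactors = FALSE)
  if (is.null(species)) species <- rep("spA", nrow(counts))
  gene_map <- stats::setNames(species, rownames(counts))
  expression_matrix(counts, samples, gene_map)
}

test_that("median-of-ratios normalization has the expected closed forms", {
  counts <- matrix(c(10, 20, 30, 40, 50), ncol = 1)[, c(1, 1, 1, 1)]
  rownames(counts) <- paste0("g", 1:5)
  # identical samples: factors 1, identity normalization
  em <- normalize_counts(toy_expr(counts))
  expect_equal(unname(em$size_factors["spA", ]), rep(1, 4))
  expect_equal(em$normalized, em$counts * 1.0, ignore_attr = TRUE)
  # one sample exactly doubled: its factor 2, normalized columns equal
  counts2 <- counts
  counts2[, 3] <- counts2[, 3] * 2
  em2 <- normalize_counts(toy_expr(counts2))
  expect_equal(unname(em2$size_factors["spA", ]), c(1, 1, 2, 1))
  expect_equal(em2$normalized[, 3], em2$normalized[, 1])
})

test_that("normalization is independent across species", {
  set.seed(5)
  counts <- matrix(rpois(40 * 6, 100), nrow = 40)
  rownames(counts) <- paste0("g", 1:40)
  species <- rep(c("spA", "spB"), each = 20)
  em0 <- normalize_counts(toy_expr(counts, species))
  # triple one species' genes in one sample; the other species' factors
  # must not move
  shifted <- counts
  shifted[1:20, 2] <- shifted[1:20, 2] * 3
  em1 <- normalize_counts(toy_expr(shifted, species))
  expect_equal(em1$size_factors["spB", ], em0$size_factors["spB", ])
  # the shifted sample's own factor moves by ~3 (exactly 3 up to the
  # unit-median renormalization across samples)
  expect_equal(unname(em1$size_factors["spA", 2] /
                        em0$size_factors["spA", 2]), 3,
               tolerance = 0.05)
})

test_that("size factors agree with the DESeq reference implementation", {
  set.seed(11)
  counts <- matrix(rnbinom(50 * 6, mu = 80, size = 10), nrow = 50)
  rownames(counts) <- paste0("g", 1:50)
  em <- normalize_counts(toy_expr(counts))
  ref <- DESeq2::estimateSizeFactorsForMatrix(counts)
  ours <- em$size_factors["spA", ]
  # DESeq2 rescales to geometric mean 1; compare shapes
  expect_equal(unname(ours / exp(mean(log(ours)))),
               unname(ref / exp(mean(log(ref)))), tolerance = 1e-8)
})

test_that("an all-zero species gets unit factors with a warning", {
  counts <- matrix(c(rpois(12, 50), rep(0, 12)), nrow = 4, byrow = TRUE)
  rownames(counts) <- paste0("g", 1:4)
  expect_warning(
    em <- normalize_counts(toy_expr(counts, rep(c("live", "dead"), each = 2))),
    "dead")
  expect_equal(unname(em$size_factors["dead", ]), rep(1, 6))
})

test_that("planted DEGs are recovered with controlled FDR", {
  g <- gen_counts(seed = 7, n_planted_degs = 30, effect_fold = 4,
                  dispersion = 0.1)
  degs <- call_degs(g$em, alpha = 0.05, min_fold = 2)
  called <- degs$gene_id[degs$is_deg]
  planted <- g$truth$planted$gene_id
  fp <- sum(!(called %in% planted))
  expect_gt(length(called), 10)
  expect_lte(fp / max(1, length(called)), 0.1)
  # DEG filter equals brute-force row filtering of the result table
  manual <- !is.na(degs$adjusted_p) & degs$adjusted_p <= 0.05 &
    abs(degs$log2_fold_change) > 1
  expect_identical(degs$is_deg, manual)
})

test_that("the DEG definition excludes sub-threshold fold changes", {
  degs_ok <- data.frame(adjusted_p = 0.001, log2_fold_change = log2(1.9))
  # filter semantics: significant but |FC| <= 2 is not a DEG
  expect_false(degs_ok$adjusted_p <= 0.05 &&
                 abs(degs_ok$log2_fold_change) > log2(2))
  # and on real output the invariant holds everywhere, including adjusted_p
  # never below the raw p
  g <- gen_counts(seed = 21, n_planted_degs = 10, n_genes_per_species = 60)
  degs <- call_degs(g$em)
  tested <- degs[degs$status == "tested", ]
  expect_true(all(tested$adjusted_p >= tested$p_value - 1e-12))
  expect_true(all(tested$adjusted_p <= 1))
  expect_false(any(degs$is_deg & abs(degs$log2_fold_change) <= 1,
                   na.rm = TRUE))
})

test_that("BH adjustment is monotone within species", {
  g <- gen_counts(seed = 22, n_planted_degs = 10, n_genes_per_species = 80)
  degs <- call_degs(g$em)
  for (sp in unique(degs$species_id)) {
    d <- degs[degs$species_id == sp & degs$status == "tested", ]
    ord <- order(d$p_value)
    expect_true(!is.unsorted(d$adjusted_p[ord]))
  }
})

test_that("near-null matrices produce almost no DEG calls", {
  false_calls <- vapply(c(11, 12, 13, 14, 15), function(s) {
    g0 <- gen_counts(seed = s, n_planted_degs = 0,
                     n_genes_per_species = 125)
    sum(call_degs(g0$em)$is_deg, na.rm = TRUE)
  }, numeric(1))
  expect_lte(mean(false_calls), 2)
})

test_that("genes with zero counts everywhere are reported untested", {
  counts <- matrix(c(rpois(6, 60), rep(0L, 6)), nrow = 2, byrow = TRUE)
  rownames(counts) <- c("expressed", "silent")
  degs <- call_degs(toy_expr(counts))
  expect_identical(degs$status[degs$gene_id == "silent"], "untested")
  expect_true(is.na(degs$p_value[degs$gene_id == "silent"]))
  expect_false(degs$is_deg[degs$gene_id == "silent"])
})

test_that("DEG percentages reproduce the printed two-decimal arithmetic", {
  expect_identical(deg_percentage(3909, 7526), 51.94)
  expect_identical(deg_percentage(0, 6281), 0)
  expect_identical(deg_percentage(48, 7143), 0.67)
  # half-even rounding at the second decimal
  expect_identical(deg_percentage(5, 4000), 0.12)
  expect_identical(deg_percentage(15, 4000), 0.38)
  expect_error(deg_percentage(1, 0), "positive")
  expect_error(deg_percentage(10, 5))
})

test_that("abundance fractions, folds and tests have closed forms", {
  one <- abundance_profile(toy_expr(matrix(rpois(6, 50), nrow = 1,
                                           dimnames = list("g1", NULL))))
  expect_equal(unname(one$fractions[1, ]), rep(1, 6))
  # 3:1 split in every sample
  split <- matrix(rep(c(75, 25), 6), nrow = 2,
                  dimnames = list(c("gA", "gB"), NULL))
  ab <- abundance_profile(toy_expr(split, c("spA", "spB")))
  expect_equal(unname(ab$fractions["spA", ]), rep(0.75, 6))
  expect_equal(ab$summary$fold_change, c(1, 1))
  expect_true(all(abs(colSums(ab$fractions) - 1) < 1e-9))
})

test_that("a planted abundance shift in a rare species is recovered", {
  folds <- numeric(0)
  ps <- numeric(0)
  abund <- c(major = 0.795, minor = 0.2, rare = 0.005)
  for (s in 1:10) {
    g <- gen_counts(seed = s, n_planted_degs = 0, n_genes_per_species = 150,
                    species = names(abund), abundances = abund,
                    abundance_shifts = c(rare = 8))
    ab <- abundance_profile(g$em)
    row <- ab$summary[ab$summary$species_id == "rare", ]
    folds <- c(folds, row$fold_change)
    ps <- c(ps, row$p_value)
  }
  expect_gte(mean(folds), 6)
  expect_lte(mean(folds), 10)
  expect_lt(mean(ps < 0.05), 1.01)  # p-values defined
  expect_gte(mean(ps < 0.05), 0.8)
})

test_that("metabolite differences recover planted folds and stay null-quiet", {
  # identical groups: folds exactly 1, nothing significant
  base <- matrix(rep(c(100, 200, 300), each = 10), nrow = 3, byrow = TRUE)
  base <- base * matrix(rep(c(0.9, 0.95, 1, 1.05, 1.1), 6), nrow = 3,
                        byrow = TRUE)
  ident <- cbind(base[, 1:5], base[, 1:5])
  rownames(ident) <- paste0("m", 1:3)
  md0 <- metabolite_diff(ident, rep(c("70h", "118h"), each = 5))
  expect_equal(md0$fold_change, rep(1, 3))
  expect_false(any(md0$significant))
  # planted 6.5-fold shift
  sim <- gen_metabolites(seed = 3, n_diff = 1, fold = 6.5, sigma = 0.1,
                         n_reps = 5)
  md <- metabolite_diff(sim$abund, sim$groups)
  hit <- md[md$metabolite %in% sim$truth$planted, ]
  expect_true(hit$significant)
  expect_gt(hit$fold_change, 5.5)
  expect_lt(hit$fold_change, 7.5)
  # single-replicate groups are a hard error
  expect_error(metabolite_diff(ident[, c(1, 6)], c("70h", "118h")),
               "replicates")
  # nonpositive rows are excluded with a warning
  bad <- ident
  bad[2, 3] <- 0
  expect_warning(mdb <- metabolite_diff(bad, rep(c("70h", "118h"), each = 5)),
                 "nonpositive")
  expect_false("m2" %in% mdb$metabolite)
})

test_that("null metabolite tables stay below one call on average", {
  calls <- vapply(c(31, 32, 33, 34), function(s) {
    sim <- gen_metabolites(seed = s, n_diff = 0, fold = 2, sigma = 0.1,
                           n_metabolites = 100)
    sum(metabolite_diff(sim$abund, sim$groups)$significant)
  }, numeric(1))
  expect_lte(mean(calls), 1)
})

test_that("category coverage counts term fractions per species", {
  ann <- data.frame(
    species_id = "spA",
    gene_id = c("g1", "g2", "g3", "g4"),
    term = c("t1", "t2", "t3", "t4"), stringsAsFactors = FALSE)
  cats <- list(catX = paste0("t", 1:10))
  cc <- category_coverage(ann, list(spA = c("g1", "g2")), cats)
  expect_equal(cc$genomic_fraction, 0.4)
  expect_equal(cc$expressed_fraction, 0.2)
  # expressed genes are a subset of the genome, so never a larger fraction
  expect_true(all(cc$expressed_fraction <= cc$genomic_fraction))
  full <- category_coverage(ann, list(spA = ann$gene_id),
                            list(all4 = paste0("t", 1:4)))
  expect_equal(c(full$genomic_fraction, full$expressed_fraction), c(1, 1))
})
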