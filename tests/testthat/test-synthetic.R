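test_that("generators are deterministic given the seed", {
  d <- default_consortium_design()
  c1 <- gen_consortium(d)
  c2 <- gen_consortium(d)
  f1 <- tempfile(); f2 <- tempfile()
  write_model_json(c1$models$ensifer_like, f1)
  write_model_json(c2$models$ensifer_like, f2)
  expect_identical(readLines(f1), readLines(f2))
  g1 <- gen_counts(seed = 5, n_genes_per_species = 50)
  g2 <- gen_counts(seed = 5, n_genes_per_species = 50)
  g3 <- gen_counts(seed = 6, n_genes_per_species = 50)
  expect_identical(g1$em$counts, g2$em$counts)
  expect_false(identical(g1$em$counts, g3$em$counts))
  m1 <- gen_metabolites(seed = 9)
  m2 <- gen_metabolites(seed = 9)
  expect_identical(m1$abund, m2$abund)
})

test_that("every generated model passes validation and recovers its design", {
  design <- consortium_design(
    niches = list(degrader_sp = c("chitin", "nag", "glucose"),
                  consumer_sp = c("nag", "glucose")),
    degraders = "degrader_sp",
    abundances = c(degrader_sp = 0.5, consumer_sp = 0.5))
  cons <- gen_consortium(design)
  for (m in cons$models) expect_silent(validate_model(m))
  for (sp in names(cons$models)) {
    expect_setequal(fundamental_niche(cons$models[[sp]], unname(cons$media)),
                    design$niches[[sp]])
  }
})

test_that("single species, single substrate reduces to a chain", {
  design <- consortium_design(niches = list(solo = "glucose"))
  cons <- gen_consortium(design)
  expect_setequal(fundamental_niche(cons$models$solo, unname(cons$media)),
                  "glucose")
  expect_identical(cons$truth$realized, "glucose")
})

test_that("infeasible designs fail loudly naming the broken dependency", {
  expect_error(
    consortium_design(niches = list(lonely = c("chitin", "nag"))),
    "not a degrader")
  expect_error(
    consortium_design(niches = list(d = c("chitin", "glucose")),
                      degraders = "d"),
    "cannot consume NAG")
  expect_error(
    consortium_design(niches = list(d = c("nag", "glucose")),
                      degraders = "d"),
    "would grow on chitin")
  expect_error(
    consortium_design(niches = list(sp = c("glucose", "unobtainium"))),
    "not a subset")
})

test_that("draft generation deletes repairable reactions into the universal", {
  d <- default_consortium_design()
  cons <- gen_consortium(d)
  bench <- gen_draft_and_universal(cons$models, d, seed = 1L)
  for (sp in names(bench$drafts)) {
    dels <- bench$truth[[sp]]
    expect_gte(length(dels), 1)
    expect_lte(length(dels), 3)
    expect_true(all(dels %in% names(bench$universal$reactions)))
    draft_ids <- vapply(bench$drafts[[sp]]$reactions, `[[`, character(1),
                        "id")
    expect_false(any(dels %in% draft_ids))
  }
  # zero deletions: drafts are the models, gapfilling adds nothing
  bench0 <- gen_draft_and_universal(cons$models, d,
                                    deletions_per_model = 0, seed = 1L)
  expect_identical(bench0$drafts, cons$models)
  ph <- gen_phenotypes(d, seed = 1L)
  gf <- gapfill_model(bench0$drafts$dyadobacter_like, bench0$universal, ph,
                      unname(cons$media))
  expect_length(gf$report$added_reaction_ids, 0)
})

test_that("decoy reactions never rescue growth", {
  d <- default_consortium_design()
  cons <- gen_consortium(d)
  bench <- gen_draft_and_universal(cons$models, d, seed = 3L)
  decoys <- names(bench$universal$provenance)[
    bench$universal$provenance == "decoy"]
  expect_gte(length(decoys), 1)
  sp <- names(bench$truth)[vapply(bench$truth, length, integer(1)) > 0][1]
  draft <- bench$drafts[[sp]]
  broken_src <- sub("^(T_|CHIT_)", "", bench$truth[[sp]][1])
  if (broken_src == "chitin") broken_src <- "chitin"
  med <- cons$media[[broken_src]]
  expect_false(predicts_growth(draft, med))
  with_decoys <- commniche:::add_reactions(draft, decoys, bench$universal)
  expect_false(predicts_growth(with_decoys, med))
})

test_that("a positive phenotype beyond the universal set is unresolvable", {
  design <- consortium_design(niches = list(solo = "glucose"))
  cons <- gen_consortium(design)
  bench <- gen_draft_and_universal(cons$models, design,
                                   deletions_per_model = 0, n_decoys = 3,
                                   seed = 2L)
  ph <- phenotype_matrix(data.frame(
    species_id = "solo", carbon_source = c("glucose", "xylose"),
    phenotype = "growth", stringsAsFactors = FALSE))
  gf <- gapfill_model(cons$models$solo, bench$universal, ph,
                      unname(panel_media(c("glucose", "xylose"))))
  res <- gf$report$resolution
  expect_identical(res$status[res$carbon_source == "xylose"], "unresolvable")
})

test_that("count simulation concentrates on the designed folds", {
  # near-zero dispersion and large depth: empirical planted folds within 5%
  g <- gen_counts(seed = 101, n_genes_per_species = 100,
                  n_planted_degs = 10, effect_fold = 4, dispersion = 1e-4,
                  depth = 2e7, species = c("spA", "spB", "spC"))
  em <- normalize_counts(g$em)
  g70 <- em$samples$sample_id[em$samples$time_point == "70h"]
  g118 <- em$samples$sample_id[em$samples$time_point == "118h"]
  for (i in seq_len(nrow(g$truth$planted))) {
    gene <- g$truth$planted$gene_id[i]
    emp <- mean(em$normalized[gene, g118]) / mean(em$normalized[gene, g70])
    expect_equal(emp, g$truth$planted$fold[i], tolerance = 0.05)
  }
})

test_that("metabolite simulation plants exactly the advertised signals", {
  sim <- gen_metabolites(seed = 12, n_metabolites = 1, n_diff = 1,
                         fold = 6.55, sigma = 0.1)
  md <- metabolite_diff(sim$abund, sim$groups)
  expect_true(md$significant[1])
  expect_identical(sim$truth$planted, rownames(sim$abund)[1])
})
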