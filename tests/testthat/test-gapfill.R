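# Small universal set: the chain model's reactions plus decoys.
chain_universal <- function() {
  m <- chain_model()
  decoy_mets <- list(
    metabolite("dA_c", compartment = "cytosol"),
    metabolite("dB_c", compartment = "cytosol"))
  decoys <- list(
    reaction("DECOY_1", c(dA_c = -1, dB_c = 1), kind = "internal"),
    reaction("DECOY_2", c(dB_c = -1, dA_c = 1), kind = "internal"))
  universal_reaction_set(
    c(Filter(function(r) r$kind != "biomass", m$reactions), decoys),
    c(m$metabolites, decoy_mets))
}

toy_phenotypes <- function(species, growth_sources, no_growth = character()) {
  phenotype_matrix(data.frame(
    species_id = species,
    carbon_source = c(growth_sources, no_growth),
    phenotype = c(rep("growth", length(growth_sources)),
                  rep("no_growth", length(no_growth))),
    stringsAsFactors = FALSE))
}

test_that("a single missing transport is restored by exactly one addition", {
  draft <- chain_model()
  draft$reactions <- Filter(function(r) r$id != "T_glc", draft$reactions)
  draft <- validate_model(draft)
  uni <- chain_universal()
  ph <- toy_phenotypes("toy", "glc")
  gf <- gapfill_model(draft, uni, ph, list(glc_medium(10)))
  expect_identical(gf$report$added_reaction_ids, "T_glc")
  expect_true(predicts_growth(gf$model, glc_medium(10)))
  # brute force over all universal subsets confirms 1 is minimal
  expect_identical(brute_force_min_additions(draft, glc_medium(10), uni), 1L)
})

test_that("a draft already growing on all positive media gets no additions", {
  m <- chain_model()
  gf <- gapfill_model(m, chain_universal(), toy_phenotypes("toy", "glc"),
                      list(glc_medium(10)))
  expect_length(gf$report$added_reaction_ids, 0)
  expect_identical(gf$report$resolution$status[
    gf$report$resolution$carbon_source == "glc"], "already_growing")
})

test_that("an unresolvable positive phenotype is reported, not fatal", {
  draft <- chain_model()
  uni <- chain_universal()
  # positive phenotype on a substrate no universal reaction can reach
  ph <- toy_phenotypes("toy", c("glc", "xyl"))
  med_xyl <- medium_spec("xyl_e", 10)
  gf <- gapfill_model(draft, uni, ph, list(glc_medium(10), med_xyl))
  res <- gf$report$resolution
  expect_identical(res$status[res$carbon_source == "xyl"], "unresolvable")
  # model unchanged for that medium
  expect_false(predicts_growth(gf$model, med_xyl))
})

test_that("minimal addition cardinality matches brute force on small universes", {
  draft <- chain_model()
  draft$reactions <- Filter(function(r) !(r$id %in% c("T_glc", "CONV_glc")),
                            draft$reactions)
  draft <- validate_model(draft)
  uni <- chain_universal()
  expect_lte(length(uni$reactions), 12)
  bf <- brute_force_min_additions(draft, glc_medium(10), uni)
  expect_identical(bf, 2L)
  gf <- gapfill_model(draft, uni, toy_phenotypes("toy", "glc"),
                      list(glc_medium(10)))
  expect_length(gf$report$added_reaction_ids, bf)
  expect_true(predicts_growth(gf$model, glc_medium(10)))
})

test_that("phenotype concordance counts matches over non-untested entries", {
  m <- chain_model()
  media <- list(glc_medium(10), medium_spec("xyl_e", 10))
  ph <- toy_phenotypes("toy", "glc", no_growth = "xyl")
  expect_equal(phenotype_concordance(list(m), ph, media), 1.0)
  inverted <- ph
  inverted$phenotype <- ifelse(inverted$phenotype == "growth",
                               "no_growth", "growth")
  expect_equal(phenotype_concordance(list(m), inverted, media), 0.0)
  all_untested <- ph
  all_untested$phenotype <- "untested"
  expect_error(phenotype_concordance(list(m), all_untested, media),
               "non-untested")
})

test_that("gapfilling the seeded 8x12 benchmark restores high concordance", {
  d <- default_consortium_design()
  cons <- gen_consortium(d)
  bench <- gen_draft_and_universal(cons$models, d, seed = 42L)
  ph <- gen_phenotypes(d, noise = 0, seed = 42L)
  pre <- phenotype_concordance(unname(bench$drafts), ph, unname(cons$media))
  models <- bench$drafts
  pos_pre <- 0
  for (sp in names(models)) {
    gf <- gapfill_model(models[[sp]], bench$universal, ph,
                        unname(cons$media))
    models[[sp]] <- gf$model
    # every addition is drawn from the universal set
    expect_true(all(gf$report$added_reaction_ids %in%
                      names(bench$universal$reactions)))
  }
  post <- phenotype_concordance(unname(models), ph, unname(cons$media))
  expect_gte(post, 0.95)
  # gapfilling never reduces concordance on positive phenotypes
  pos <- ph[ph$phenotype == "growth", , drop = FALSE]
  expect_gte(phenotype_concordance(unname(models), pos, unname(cons$media)),
             phenotype_concordance(unname(bench$drafts), pos,
                                   unname(cons$media)))
  expect_gte(post, pre)
})

test_that("mixed-bag merge is idempotent and keeps the identity", {
  m <- chain_model()
  expect_identical(merge_mixed_bag(list(m)), m)
  mm <- merge_mixed_bag(list(m, m))
  expect_setequal(vapply(mm$reactions, `[[`, character(1), "id"),
                  vapply(m$reactions, `[[`, character(1), "id"))
  expect_equal(run_fba(mm, glc_medium(10))$objective,
               run_fba(m, glc_medium(10))$objective)
})

test_that("conflicting stoichiometry under one reaction id is a hard error", {
  a <- chain_model("A")
  b <- chain_model("B")
  b$reactions[[3]]$stoichiometry <- c(glc_c = -1, prec_c = 3)
  b$biomass_id <- "BIO"
  expect_error(merge_mixed_bag(list(a, b)), "collision")
})

test_that("merged bounds are the widest of the members", {
  a <- chain_model("A")
  b <- chain_model("B")
  b$reactions[[2]]$upper_bound <- 2000
  mm <- merge_mixed_bag(list(a, b))
  tg <- Filter(function(r) r$id == "T_glc", mm$reactions)[[1]]
  expect_equal(tg$upper_bound, 2000)
})

test_that("community growth on chitin emerges from degrader/consumer merge", {
  deg <- chitin_degrader()
  con <- chitin_consumer()
  med <- chitin_medium(10)
  expect_false(predicts_growth(deg, med))
  expect_false(predicts_growth(con, med))
  comm <- merge_mixed_bag(list(deg, con))
  expect_true(predicts_growth(comm, med))
  # oracle confirmation of all three LP calls
  expect_lt(brute_force_growth(deg, med), 1e-9)
  expect_lt(brute_force_growth(con, med), 1e-9)
  expect_gt(brute_force_growth(comm, med), 1e-6)
})
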