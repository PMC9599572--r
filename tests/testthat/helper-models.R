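# Hand-built toy models used across tests (independent of the synthetic
# generator).

# Linear chain: glucose uptake -> transport -> conversion to 2 precursor ->
# biomass. With uptake ceiling 10 the LP optimum is 20.
chain_model <- function(species_id = "toy") {
  mets <- list(
    metabolite("glc_e", compartment = "extracellular", carbon_atoms = 6L),
    metabolite("glc_c", compartment = "cytosol", carbon_atoms = 6L),
    metabolite("prec_c", compartment = "cytosol", carbon_atoms = 3L))
  rxns <- list(
    reaction("EX_glc_e", c(glc_e = -1), lower_bound = -1000,
             upper_bound = 1000, kind = "exchange"),
    reaction("T_glc", c(glc_e = -1, glc_c = 1), kind = "transport"),
    reaction("CONV_glc", c(glc_c = -1, prec_c = 2), kind = "internal"),
    reaction("BIO", c(prec_c = -1), kind = "biomass"))
  stoich_model(species_id, mets, rxns, biomass_id = "BIO")
}

glc_medium <- function(uptake = 10) medium_spec("glc_e", uptake)

# Sucrose/glucose toy: sucrose hydrolyzes to glucose + fructose, both feed
# the same precursor pool, so the sucrose yield is exactly twice glucose's.
sucrose_toy <- function() {
  mets <- list(
    metabolite("suc_e", compartment = "extracellular", carbon_atoms = 12L),
    metabolite("suc_c", compartment = "cytosol", carbon_atoms = 12L),
    metabolite("glc_e", compartment = "extracellular", carbon_atoms = 6L),
    metabolite("glc_c", compartment = "cytosol", carbon_atoms = 6L),
    metabolite("fru_c", compartment = "cytosol", carbon_atoms = 6L),
    metabolite("prec_c", compartment = "cytosol", carbon_atoms = 6L))
  rxns <- list(
    reaction("EX_suc_e", c(suc_e = -1), -1000, 1000, kind = "exchange"),
    reaction("EX_glc_e", c(glc_e = -1), -1000, 1000, kind = "exchange"),
    reaction("T_suc", c(suc_e = -1, suc_c = 1), kind = "transport"),
    reaction("T_glc", c(glc_e = -1, glc_c = 1), kind = "transport"),
    reaction("HYD_suc", c(suc_c = -1, glc_c = 1, fru_c = 1),
             kind = "internal"),
    reaction("CAT_glc", c(glc_c = -1, prec_c = 1), kind = "internal"),
    reaction("CAT_fru", c(fru_c = -1, prec_c = 1), kind = "internal"),
    reaction("BIO", c(prec_c = -1), kind = "biomass"))
  stoich_model("disacch_toy", mets, rxns, biomass_id = "BIO")
}

# Two-species chitin toy: the degrader cleaves chitin extracellularly but
# cannot take NAG up; the consumer catabolizes NAG but cannot cleave
# chitin. Only the mixed-bag merge grows on chitin.
chitin_degrader <- function() {
  mets <- list(
    metabolite("chitin_e", compartment = "extracellular", carbon_atoms = 32L),
    metabolite("chitobiose_e", compartment = "extracellular",
               carbon_atoms = 16L),
    metabolite("nag_e", compartment = "extracellular", carbon_atoms = 8L),
    metabolite("glc_e", compartment = "extracellular", carbon_atoms = 6L),
    metabolite("glc_c", compartment = "cytosol", carbon_atoms = 6L),
    metabolite("prec_A_c", compartment = "cytosol", carbon_atoms = 6L))
  rxns <- list(
    reaction("EX_chitin_e", c(chitin_e = -1), -1000, 1000, kind = "exchange"),
    reaction("EX_chitobiose_e", c(chitobiose_e = -1), -1000, 1000,
             kind = "exchange"),
    reaction("EX_nag_e", c(nag_e = -1), -1000, 1000, kind = "exchange"),
    reaction("EX_glc_e", c(glc_e = -1), -1000, 1000, kind = "exchange"),
    reaction("CHIT", c(chitin_e = -1, chitobiose_e = 2),
             genes = "degrader_chiA", kind = "internal"),
    reaction("CHITOB", c(chitobiose_e = -1, nag_e = 2),
             genes = "degrader_hex", kind = "internal"),
    reaction("T_glc", c(glc_e = -1, glc_c = 1), kind = "transport"),
    reaction("CAT_glc", c(glc_c = -1, prec_A_c = 1), kind = "internal"),
    reaction("BIO_degrader", c(prec_A_c = -1), kind = "biomass"))
  stoich_model("degrader", mets, rxns, biomass_id = "BIO_degrader")
}

chitin_consumer <- function() {
  mets <- list(
    metabolite("nag_e", compartment = "extracellular", carbon_atoms = 8L),
    metabolite("nag_c", compartment = "cytosol", carbon_atoms = 8L),
    metabolite("prec_B_c", compartment = "cytosol", carbon_atoms = 6L))
  rxns <- list(
    reaction("EX_nag_e", c(nag_e = -1), -1000, 1000, kind = "exchange"),
    reaction("T_nag", c(nag_e = -1, nag_c = 1), kind = "transport"),
    reaction("CAT_nag", c(nag_c = -1, prec_B_c = 4 / 3), kind = "internal"),
    reaction("BIO_consumer", c(prec_B_c = -1), kind = "biomass"))
  stoich_model("consumer", mets, rxns, biomass_id = "BIO_consumer")
}

chitin_medium <- function(uptake = 10) medium_spec("chitin_e", uptake)

# Random chain-style model with nr extra random conversions, for property
# tests. Always feasible, bounded, and solvable by the brute-force oracle.
random_toy_model <- function(seed, n_extra = 2) {
  set.seed(seed)
  mets <- list(
    metabolite("s_e", compartment = "extracellular", carbon_atoms = 6L),
    metabolite("s_c", compartment = "cytosol", carbon_atoms = 6L),
    metabolite("p_c", compartment = "cytosol", carbon_atoms = 6L))
  rxns <- list(
    reaction("EX_s_e", c(s_e = -1), -1000, 1000, kind = "exchange"),
    reaction("T_s", c(s_e = -1, s_c = 1), kind = "transport"),
    # carbon-conserving (lossy) catabolism: yield coefficient <= 1
    reaction("MAIN", c(s_c = -1, p_c = round(stats::runif(1, 0.3, 1), 2)),
             kind = "internal"),
    reaction("BIO", c(p_c = -1), kind = "biomass"))
  for (i in seq_len(n_extra)) {
    rid <- paste0("ALT_", i)
    rxns[[length(rxns) + 1L]] <- reaction(
      rid, c(s_c = -1, p_c = round(stats::runif(1, 0.2, 1), 2)),
      kind = "internal")
  }
  stoich_model(paste0("rand", seed), mets, rxns, biomass_id = "BIO")
}

s_medium <- function(uptake = 10) medium_spec("s_e", uptake)
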