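{
  "name": "chitin_nag_core",
  "version": "1.0",
  "description": "Eight-step chitin/NAG breakdown and assimilation pathway. Early steps act on the polymer and oligomers, mid steps on the dimer/monomer at the cell surface, late steps assimilate NAG into central metabolism. Accepted terms are EC numbers (trailing-field wildcards honored), KEGG orthologs, and glycoside hydrolase / carbohydrate esterase families.",
  "steps": [
    {
      "step_id": "chitin_binding",
      "stage": "early",
      "terms": [{"type": "KO", "term": "K03933"}]
    },
    {
      "step_id": "chitinase_gh18",
      "stage": "early",
      "terms": [{"type": "GH", "term": "GH18"}, {"type": "EC", "term": "3.2.1.14"}]
    },
    {
      "step_id": "chitinase_gh19",
      "stage": "early",
      "terms": [{"type": "GH", "term": "GH19"}, {"type": "KO", "term": "K03791"}]
    },
    {
      "step_id": "chitooligosaccharide_deacetylase_ce4",
      "stage": "early",
      "terms": [{"type": "CE", "term": "CE4"}, {"type": "EC", "term": "3.5.1.104"}]
    },
    {
      "step_id": "beta_hexosaminidase_gh20_gh3",
      "stage": "mid",
      "terms": [{"type": "GH", "term": "GH20"}, {"type": "EC", "term": "3.2.1.52"}]
    },
    {
      "step_id": "nag_pts_transport",
      "stage": "mid",
      "terms": [{"type": "EC", "term": "2.7.1.193"}]
    },
    {
      "step_id": "nag6p_deacetylase",
      "stage": "late",
      "terms": [{"type": "EC", "term": "3.5.1.25"}]
    },
    {
      "step_id": "glucosamine_kinase",
      "stage": "late",
      "terms": [{"type": "EC", "term": "2.7.1.8"}]
    }
  ]
}
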