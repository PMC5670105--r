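cfg <- rule_config()

test_that("the lipophilicity criterion scores the printed examples", {
  expect_equal(score_lipophilicity(1.53, cfg = cfg)$score, 1L)
  tmz <- score_lipophilicity(-1.1, cfg = cfg)
  expect_equal(tmz$score, 0L)
  expect_equal(tmz$reason, "too_hydrophilic")
  tam <- score_lipophilicity(6.70, cfg = cfg)
  expect_equal(tam$score, 0L)
  expect_equal(tam$reason, "too_lipophilic")
  # platinum complexes: partitioning not assessable (aquation in vivo)
  carb <- score_lipophilicity(-0.19, flags = "platinum_complex", cfg = cfg)
  expect_equal(carb$score, 0L)
  expect_equal(carb$reason, "not_assessable")
  # ... unless the platinum rule is configured off
  cfg_off <- rule_config(platinum_logp_not_assessable = FALSE)
  expect_equal(score_lipophilicity(-0.19, flags = "platinum_complex",
                                   cfg = cfg_off)$score, 1L)
  expect_equal(score_lipophilicity(NA_real_, cfg = cfg)$reason, "missing")
  # lower bound is exclusive: exactly -0.5 is too hydrophilic
  expect_equal(score_lipophilicity(-0.5, cfg = cfg)$score, 0L)
  # upper bound is inclusive
  expect_equal(score_lipophilicity(5.0, cfg = cfg)$score, 1L)
})

test_that("the molecular weight and charge criteria honor inclusive bounds", {
  expect_equal(score_molecular_weight(214.10, cfg)$score, 1L)
  expect_equal(score_molecular_weight(588.56, cfg)$score, 0L)
  expect_equal(score_molecular_weight(500.0, cfg)$score, 1L)
  expect_equal(score_molecular_weight(NA_real_, cfg)$reason, "missing")

  expect_equal(score_charge(8, cfg)$score, 1L)
  expect_equal(score_charge(12, cfg)$reason, "partially_charged")
  expect_equal(score_charge(10, cfg)$score, 1L)
  expect_equal(score_charge(90, cfg)$reason, "fully_charged")
  expect_equal(score_charge(NA_real_, cfg)$score, 0L)
})

test_that("systemic classification sums criteria and maps labels", {
  carm <- classify_systemic(rec("Carmustine", 1.53, 214.10, 0), cfg)
  expect_equal(carm$total_score, 3L)
  expect_equal(carm$label, "likely")

  dasa <- classify_systemic(rec("Dasatinib", 3.60, 488.01, 40), cfg)
  expect_equal(dasa$total_score, 2L)
  expect_equal(dasa$label, "intermediate")

  vinc <- classify_systemic(rec("Vincristine", 2.82, 824.96, 98), cfg)
  expect_equal(vinc$total_score, 1L)
  expect_equal(vinc$label, "unlikely")
})

test_that("systemic overrides fire for prodrugs, heavy drugs and biologics", {
  # prodrug: label fixed at intermediate, in either direction, because the
  # active metabolite (not the tabulated parent) determines permeation
  cyc <- classify_systemic(rec("Cyclophosphamide", 0.20, 277.09, 0, prodrug = TRUE), cfg)
  expect_equal(cyc$total_score, 3L)
  expect_equal(cyc$label, "intermediate")
  expect_true("prodrug_cap" %in% cyc$overrides_applied)
  iri <- classify_systemic(
    rec("Irinotecan", 3.50, 586.70, 100, sign = "positive", prodrug = TRUE), cfg)
  expect_equal(iri$total_score, 1L)
  expect_equal(iri$label, "intermediate")

  # molecular-weight hard cap demotes regardless of score
  sir <- classify_systemic(rec("Sirolimus", 4.81, 914.17, 0), cfg)
  expect_equal(sir$total_score, 2L)
  expect_equal(sir$label, "unlikely")
  expect_true("mw_hard_cap" %in% sir$overrides_applied)

  # unknown log P and charge: unlikely for want of evidence
  bev <- classify_systemic(rec("Bevacizumab", mw = 149000, flags = "biologic"), cfg)
  expect_equal(bev$label, "unlikely")
  expect_true("unknown_properties" %in% bev$overrides_applied)

  # the cap can be disabled
  cfg_nocap <- rule_config(prodrug_systemic_cap = "none")
  cyc2 <- classify_systemic(rec("Cyclophosphamide", 0.20, 277.09, 0, prodrug = TRUE),
                            cfg_nocap)
  expect_equal(cyc2$label, "likely")
})

test_that("non-prodrug overrides only ever demote", {
  spec <- fixture_spec(300, seed = 11, boundary_emphasis = 0.3,
                       include_flags = c(prodrug = FALSE, oral_only = TRUE,
                                         platinum = TRUE, biologic = TRUE))
  records <- generate_drug_records(spec, cfg)
  rank <- c(likely = 1L, intermediate = 2L, unlikely = 3L)
  for (i in seq_len(nrow(records))) {
    cls <- classify_systemic(records[i, ], cfg)
    base <- c("unlikely", "unlikely", "intermediate", "likely")[cls$total_score + 1L]
    expect_gte(rank[[cls$label]], rank[[base]])
    expect_true(cls$total_score %in% 0:3)
  }
})

test_that("CED classification applies the charge, prodrug and formulation rules", {
  expect_equal(classify_ced(rec("Carmustine", 1.53, 214.10, 0), cfg)$label, "suitable")
  topo <- classify_ced(rec("Topotecan", -0.88, 412.45, 100, sign = "positive"), cfg)
  expect_equal(topo$label, "unsuitable")
  expect_true("positive_charge" %in% topo$reasons)
  mtx <- classify_ced(rec("Methotrexate", -1.85, 454.44, 100, sign = "negative"), cfg)
  expect_equal(mtx$label, "speculative")
  expect_equal(mtx$reasons, "negative_charge_high")
  lom <- classify_ced(rec("Lomustine", 2.83, 233.70, 0, oral = TRUE), cfg)
  expect_equal(lom$label, "unsuitable")
  expect_equal(lom$reasons, "oral_only_needs_reformulation")
  iri <- classify_ced(
    rec("Irinotecan", 3.50, 586.70, 100, sign = "positive", prodrug = TRUE), cfg)
  expect_equal(iri$label, "unsuitable")
  expect_true("prodrug" %in% iri$reasons)
  mel <- classify_ced(rec("Melphalan", -0.5, 305.20, 99, sign = "zwitterionic"), cfg)
  expect_equal(mel$label, "unsuitable")
  expect_true("zwitterionic" %in% mel$reasons)
  bev <- classify_ced(rec("Bevacizumab", mw = 149000, flags = "biologic"), cfg)
  expect_equal(bev$label, "unsuitable")
  expect_equal(bev$reasons, "unknown_properties")
  # all applicable exclusions are reported together
  cap <- classify_ced(rec("Capecitabine", 0.56, 359.35, 12, sign = "negative",
                          prodrug = TRUE, oral = TRUE), cfg)
  expect_setequal(cap$reasons, c("prodrug", "oral_only_needs_reformulation"))
  # a suitable drug carries the neutral_charge reason and nothing else
  expect_equal(classify_ced(rec("Cisplatin", -2.19, 300.05, 0,
                                flags = "platinum_complex"), cfg)$reasons,
               "neutral_charge")
})

test_that("rule-of-five evaluation reports per-rule verdicts with indeterminates", {
  all_pass <- evaluate_rule_of_five(1.53, 214.10, 1, 4)
  expect_true(all(all_pass$pass))
  tam <- evaluate_rule_of_five(6.7, 371.51, NA, NA)
  expect_false(tam$pass[tam$rule == "log_p"])
  expect_true(tam$pass[tam$rule == "molecular_weight"])
  expect_true(all(is.na(tam$pass[tam$rule %in% c("h_bond_donors", "h_bond_acceptors")])))
  expect_true(all(evaluate_rule_of_five(0, 0, 0, 0)$pass))
})

test_that("classification is deterministic and monotone in the MW threshold", {
  records <- generate_drug_records(fixture_spec(200, seed = 5, boundary_emphasis = 0.2), cfg)
  a <- screen_drugs(records, cfg)
  b <- screen_drugs(records, cfg)
  expect_identical(a, b)
  # raising mw_max_da never decreases any total score
  cfg_wide <- rule_config(mw_max_da = 700)
  wide <- screen_drugs(records, cfg_wide)
  expect_true(all(wide$systemic_score >= a$systemic_score))
})
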