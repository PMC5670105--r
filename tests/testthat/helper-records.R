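# terse record builder for rule tests
rec <- function(name = "X", log_p = NA_real_, mw = NA_real_,
                charge = NA_real_, sign = NULL, prodrug = FALSE,
                oral = FALSE, flags = character(), class = "other_drug",
                sys = NA_character_, ced = NA_character_) {
  if (is.null(sign)) {
    sign <- if (is.na(charge)) "unknown" else if (charge == 0) "neutral" else "positive"
  }
  drug_record(name, class, log_p = log_p, molecular_weight_g_per_mol = mw,
              charge_percent = charge, charge_sign = sign,
              is_prodrug = prodrug, oral_only = oral, compound_flags = flags,
              published_systemic = sys, published_ced = ced)
}
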