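# Independent, table-driven restatement of the classification rules, coded
# flat from the rule text with hard-wired default thresholds. Deliberately
# shares no code with the package implementation; used to cross-check
# classify_systemic()/classify_ced() on generated records.

oracle_systemic <- function(log_p, mw, charge, is_prodrug, is_platinum) {
  lip <- if (is_platinum) 0L
    else if (is.na(log_p)) 0L
    else if (log_p > -0.5 && log_p <= 5) 1L
    else 0L
  wt <- if (!is.na(mw) && mw <= 500) 1L else 0L
  ch <- if (!is.na(charge) && charge <= 10) 1L else 0L
  score <- lip + wt + ch
  label <- c("unlikely", "unlikely", "intermediate", "likely")[score + 1L]
  if (is_prodrug) label <- "intermediate"
  if (!is.na(mw) && mw >= 900) label <- "unlikely"
  if (is.na(log_p) && is.na(charge)) label <- "unlikely"
  list(score = score, label = label)
}

oracle_ced <- function(charge, sign, is_prodrug, oral_only) {
  if (is.na(charge) || sign == "unknown") return("unsuitable")
  if (is_prodrug) return("unsuitable")
  if (oral_only) return("unsuitable")
  if (charge > 10 && sign == "positive") return("unsuitable")
  if (charge > 10 && sign == "zwitterionic") return("unsuitable")
  if (charge > 10 && sign == "negative") return("speculative")
  "suitable"
}

# apply the oracle to every row of a drug-record tibble
oracle_labels <- function(records) {
  sys <- character(nrow(records))
  ced <- character(nrow(records))
  score <- integer(nrow(records))
  for (i in seq_len(nrow(records))) {
    r <- records[i, ]
    is_platinum <- grepl("platinum_complex", r$compound_flags)
    o <- oracle_systemic(r$log_p, r$molecular_weight_g_per_mol,
                         r$charge_percent, r$is_prodrug, is_platinum)
    sys[i] <- o$label
    score[i] <- o$score
    ced[i] <- oracle_ced(r$charge_percent, r$charge_sign, r$is_prodrug,
                         r$oral_only)
  }
  tibble::tibble(name = records$name, oracle_score = score,
                 oracle_systemic = sys, oracle_ced = ced)
}
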