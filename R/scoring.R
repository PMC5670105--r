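#' Score the lipophilicity criterion
#'
#' Scores 1 (optimal) when log P lies in the configured window
#' `(logp_lower, logp_upper]`: lipophilic enough to partition into the
#' endothelial membrane, but within the rule-of-five bound of 5. Platinum
#' coordination complexes are scored 0 with reason `not_assessable` when
#' `cfg$platinum_logp_not_assessable` is set, since aquation in vivo yields
#' charged species whose octanol/water partitioning is not meaningful.
#'
#' @param log_p log P value or `NA`.
#' @param flags character vector of compound flags (see [drug_record()]).
#' @param cfg a [rule_config()].
#' @return a one-row tibble with columns `criterion`, `score`, `reason`.
#' @export
#' @examples
#' score_lipophilicity(1.53)                 # optimal
#' score_lipophilicity(-1.1)                 # too hydrophilic
score_lipophilicity <- function(log_p, flags = character(), cfg = rule_config()) {
  if (cfg$platinum_logp_not_assessable && "platinum_complex" %in% flags) {
    score <- 0L; reason <- "not_assessable"
  } else if (is.na(log_p)) {
    score <- 0L; reason <- "missing"
  } else if (log_p <= cfg$logp_lower) {
    score <- 0L; reason <- "too_hydrophilic"
  } else if (log_p > cfg$logp_upper) {
    score <- 0L; reason <- "too_lipophilic"
  } else {
    score <- 1L; reason <- "within_range"
  }
  tibble::tibble(criterion = "lipophilicity", score = score, reason = reason)
}

#' Score the molecular-weight criterion
#'
#' Scores 1 when the molecular weight is present and at most `cfg$mw_max_da`
#' (inclusive), the size bound for paracellular-scale passive diffusion.
#'
#' @param mw molecular weight in g/mol or `NA`.
#' @inheritParams score_lipophilicity
#' @return a one-row tibble with columns `criterion`, `score`, `reason`.
#' @export
score_molecular_weight <- function(mw, cfg = rule_config()) {
  if (is.na(mw)) {
    score <- 0L; reason <- "missing"
  } else if (mw <= cfg$mw_max_da) {
    score <- 1L; reason <- "within_limit"
  } else {
    score <- 0L; reason <- "too_heavy"
  }
  tibble::tibble(criterion = "molecular_weight", score = score, reason = reason)
}

#' Score the molecular-charge criterion
#'
#' Scores 1 when at most `cfg$charge_neutral_max_percent` (inclusive) of the
#' molecules carry a net charge at physiological pH — the effectively-neutral
#' band able to passively diffuse. Drugs at or above
#' `cfg$charge_full_min_percent` are fully charged (reason `fully_charged`);
#' those in between are partly charged and unlikely to reach therapeutic
#' concentrations (reason `partially_charged`). Both score 0.
#'
#' @param charge_percent percent of molecules charged at pH 7.4, or `NA`.
#' @inheritParams score_lipophilicity
#' @return a one-row tibble with columns `criterion`, `score`, `reason`.
#' @export
score_charge <- function(charge_percent, cfg = rule_config()) {
  if (is.na(charge_percent)) {
    score <- 0L; reason <- "missing"
  } else if (charge_percent <= cfg$charge_neutral_max_percent) {
    score <- 1L; reason <- "effectively_neutral"
  } else if (charge_percent >= cfg$charge_full_min_percent) {
    score <- 0L; reason <- "fully_charged"
  } else {
    score <- 0L; reason <- "partially_charged"
  }
  tibble::tibble(criterion = "charge", score = score, reason = reason)
}

#' Classify a drug's likelihood of passive diffusion across an intact BBB
#'
#' The three binary criteria (lipophilicity, molecular weight, charge) are
#' summed to a 0-3 score mapped to a label: 3 is likely (`+`, green), 2 is
#' intermediate (`+/-`, yellow; some diffusion, but presumably below
#' therapeutic concentration), 0-1 is unlikely (`-`, red). Three overrides
#' then adjust the label:
#'
#' * `prodrug_cap`: a prodrug's permeation is determined by its active
#'   metabolite, whose properties are not tabulated; the label is fixed at
#'   intermediate (when `cfg$prodrug_systemic_cap == "intermediate"`).
#' * `mw_hard_cap`: at or above `cfg$mw_hard_cap_da` the drug is demoted to
#'   unlikely whatever its other criteria.
#' * `unknown_properties`: with both log P and charge unknown (biologics) the
#'   drug is unlikely for want of evidence rather than by arithmetic.
#'
#' `platinum_flag` is recorded in `overrides_applied` when the lipophilicity
#' criterion was voided for a platinum complex.
#'
#' @param record a one-row drug-record tibble (see [drug_record()]).
#' @param cfg a [rule_config()].
#' @return an object of class `bbbced_systemic` with fields `name`,
#'   `total_score` (sum of the three criteria, before overrides), `label`,
#'   `criteria` (3-row tibble), `overrides_applied` (character vector) and
#'   `published_label`.
#' @export
#' @examples
#' cls <- classify_systemic(drug_record("Carmustine", "alkylating",
#'   log_p = 1.53, molecular_weight_g_per_mol = 214.10, charge_percent = 0))
#' cls$total_score
classify_systemic <- function(record, cfg = rule_config()) {
  r <- as.list(record)
  flags <- split_set(r$compound_flags %||% "")
  criteria <- dplyr::bind_rows(
    score_lipophilicity(r$log_p, flags, cfg),
    score_molecular_weight(r$molecular_weight_g_per_mol, cfg),
    score_charge(r$charge_percent, cfg)
  )
  total <- sum(criteria$score)
  label <- if (total == 3L) "likely" else if (total == 2L) "intermediate" else "unlikely"
  overrides <- character()
  if (criteria$reason[criteria$criterion == "lipophilicity"] == "not_assessable") {
    overrides <- c(overrides, "platinum_flag")
  }
  if (isTRUE(r$is_prodrug) && cfg$prodrug_systemic_cap == "intermediate") {
    label <- "intermediate"
    overrides <- c(overrides, "prodrug_cap")
  }
  mw <- r$molecular_weight_g_per_mol
  if (!is.na(mw) && mw >= cfg$mw_hard_cap_da) {
    label <- "unlikely"
    overrides <- c(overrides, "mw_hard_cap")
  }
  if (is.na(r$log_p) && is.na(r$charge_percent)) {
    label <- "unlikely"
    overrides <- c(overrides, "unknown_properties")
  }
  structure(
    list(
      name = r$name,
      total_score = total,
      label = label,
      criteria = criteria,
      overrides_applied = overrides,
      published_label = r$published_systemic %||% NA_character_
    ),
    class = "bbbced_systemic"
  )
}

#' @export
print.bbbced_systemic <- function(x, ...) {
  cat(sprintf("<systemic classification: %s>\n", x$name))
  cat(sprintf("  score %d/3 -> %s (%s)\n", x$total_score, x$label,
              label_symbol(x$label)))
  for (i in seq_len(nrow(x$criteria))) {
    cat(sprintf("  %-17s %d  (%s)\n", x$criteria$criterion[i],
                x$criteria$score[i], x$criteria$reason[i]))
  }
  if (length(x$overrides_applied)) {
    cat("  overrides:", paste(x$overrides_applied, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Classify a drug's suitability for convection-enhanced delivery
#'
#' CED infuses the drug directly into the tumor under a positive pressure
#' gradient, so distribution depends on molecular charge rather than on
#' permeability. The rules, in order of precedence:
#'
#' * unknown charge (biologics) — unsuitable, `unknown_properties`;
#' * prodrug — unsuitable (`prodrug`): CED bypasses the first-pass metabolism
#'   that would activate it;
#' * oral-only formulation — unsuitable
#'   (`oral_only_needs_reformulation`): no infusable liquid form exists,
#'   though reformulation could change this;
#' * predominantly positive charge (above the neutral band) — unsuitable
#'   (`positive_charge`): cationic species complex with anionic membrane
#'   components, collapsing the distribution volume;
#' * zwitterionic above the neutral band — unsuitable (`zwitterionic`), since
#'   its cationic moiety raises the same concern;
#' * negative charge above the neutral band — speculative
#'   (`negative_charge_high`): anionic drugs have only been studied up to 10%
#'   charge, so better distribution is plausible but unproven;
#' * otherwise — suitable (`neutral_charge`).
#'
#' All applicable exclusion reasons are reported, so an oral-only prodrug
#' lists both.
#'
#' @inheritParams classify_systemic
#' @return an object of class `bbbced_ced` with fields `name`, `label`
#'   (`suitable`, `speculative` or `unsuitable`), `reasons` (character
#'   vector) and `published_label`.
#' @export
classify_ced <- function(record, cfg = rule_config()) {
  r <- as.list(record)
  charge <- r$charge_percent
  sign <- r$charge_sign %||% "unknown"
  reasons <- character()
  if (is.na(charge) || sign == "unknown") reasons <- c(reasons, "unknown_properties")
  if (isTRUE(r$is_prodrug)) reasons <- c(reasons, "prodrug")
  if (isTRUE(r$oral_only)) reasons <- c(reasons, "oral_only_needs_reformulation")
  charged <- !is.na(charge) && charge > cfg$charge_neutral_max_percent
  if (charged && sign == "positive") reasons <- c(reasons, "positive_charge")
  if (charged && sign == "zwitterionic") reasons <- c(reasons, "zwitterionic")
  if (length(reasons)) {
    label <- "unsuitable"
  } else if (charged && sign == "negative") {
    label <- "speculative"
    reasons <- "negative_charge_high"
  } else {
    label <- "suitable"
    reasons <- "neutral_charge"
  }
  structure(
    list(
      name = r$name,
      label = label,
      reasons = reasons,
      published_label = r$published_ced %||% NA_character_
    ),
    class = "bbbced_ced"
  )
}

#' @export
print.bbbced_ced <- function(x, ...) {
  cat(sprintf("<CED classification: %s>\n", x$name))
  cat(sprintf("  %s (%s); reasons: %s\n", x$label, label_symbol(x$label),
              paste(x$reasons, collapse = ", ")))
  invisible(x)
}

#' Evaluate the four rule-of-five permeability heuristics
#'
#' Reports each rule separately: molecular weight at most 500 Da, log P at
#' most 5, at most 5 hydrogen-bond donors, at most 10 hydrogen-bond
#' acceptors. Donor/acceptor counts are not part of the packaged table and
#' must be supplied by the caller; a missing input yields an indeterminate
#' (`NA`) verdict rather than a failure.
#'
#' @param log_p log P or `NA`.
#' @param mw molecular weight (g/mol) or `NA`.
#' @param h_donors,h_acceptors hydrogen-bond donor/acceptor counts or `NA`.
#' @return a tibble with columns `rule`, `value`, `threshold`, `pass`
#'   (logical, `NA` = indeterminate).
#' @export
#' @examples
#' evaluate_rule_of_five(1.53, 214.10, 1, 4)
evaluate_rule_of_five <- function(log_p, mw, h_donors = NA, h_acceptors = NA) {
  tibble::tibble(
    rule = c("molecular_weight", "log_p", "h_bond_donors", "h_bond_acceptors"),
    value = as.double(c(mw, log_p, h_donors, h_acceptors)),
    threshold = c(500, 5, 5, 10),
    pass = c(
      if (is.na(mw)) NA else mw <= 500,
      if (is.na(log_p)) NA else log_p <= 5,
      if (is.na(h_donors)) NA else h_donors <= 5,
      if (is.na(h_acceptors)) NA else h_acceptors <= 10
    )
  )
}

#' Classify every record in a drug table on both delivery routes
#'
#' Row-wise application of [classify_systemic()] and [classify_ced()],
#' returned as one tidy table suitable for reports and reconciliation.
#'
#' @param records tibble of drug records.
#' @param cfg a [rule_config()].
#' @return a tibble with one row per record: the input properties plus
#'   per-criterion scores, `systemic_score`, `systemic_label`,
#'   `systemic_reasons`, `systemic_overrides`, `ced_label`, `ced_reasons`,
#'   and the published labels (as `+`/`+/-`/`-` symbols) where present.
#' @export
#' @examples
#' kb <- load_knowledge_base()
#' scr <- screen_drugs(kb$drugs)
#' table(scr$systemic_label)
screen_drugs <- function(records, cfg = rule_config()) {
  rows <- lapply(seq_len(nrow(records)), function(i) {
    rec <- records[i, ]
    sys <- classify_systemic(rec, cfg)
    ced <- classify_ced(rec, cfg)
    tibble::tibble(
      name = rec$name,
      drug_class = rec$drug_class,
      log_p = rec$log_p,
      molecular_weight_g_per_mol = rec$molecular_weight_g_per_mol,
      charge_percent = rec$charge_percent,
      charge_sign = rec$charge_sign,
      is_prodrug = rec$is_prodrug,
      oral_only = rec$oral_only,
      lipophilicity_score = sys$criteria$score[1],
      molecular_weight_score = sys$criteria$score[2],
      charge_score = sys$criteria$score[3],
      systemic_score = sys$total_score,
      systemic_label = sys$label,
      systemic_reasons = paste(sys$criteria$reason, collapse = ";"),
      systemic_overrides = paste(sys$overrides_applied, collapse = ";"),
      ced_label = ced$label,
      ced_reasons = paste(ced$reasons, collapse = ";"),
      published_systemic = sys$published_label,
      published_ced = ced$published_label
    )
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0L) {
    out <- tibble::tibble(
      name = character(), drug_class = character(), log_p = double(),
      molecular_weight_g_per_mol = double(), charge_percent = double(),
      charge_sign = character(), is_prodrug = logical(), oral_only = logical(),
      lipophilicity_score = integer(), molecular_weight_score = integer(),
      charge_score = integer(), systemic_score = integer(),
      systemic_label = character(), systemic_reasons = character(),
      systemic_overrides = character(), ced_label = character(),
      ced_reasons = character(), published_systemic = character(),
      published_ced = character()
    )
  }
  out
}
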