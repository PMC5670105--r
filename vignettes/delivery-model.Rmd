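---
title: "A rule-based delivery model for chemotherapeutics in DIPG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A rule-based delivery model for chemotherapeutics in DIPG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bbbced)
```

## The problem

Diffuse intrinsic pontine glioma (DIPG) infiltrates brainstem tissue whose
blood–brain barrier (BBB) is largely intact, so systemically administered
drugs reach the tumor mainly by **passive diffusion** across tight endothelial
junctions. Whether a small molecule can do that is, to a first approximation,
a function of three physicochemical properties:

* **lipophilicity** (log P, the octanol/water partition coefficient) — the
  molecule must partition into the endothelial membrane, but extreme
  lipophilicity (log P > 5, the rule-of-five bound) predicts poor
  permeability and the far hydrophilic end cannot enter the membrane at all;
* **molecular weight** — at most ~500 Da for meaningful transcellular
  diffusion;
* **molecular charge at pH 7.4** — charged species prefer the aqueous phase
  and do not diffuse passively. Because ionization is an equilibrium, charge
  is expressed as the *percent of molecules* carrying a net charge at
  physiological pH, not as a formal charge.

The alternative route, **convection-enhanced delivery (CED)**, infuses drug
directly into the tumor under a pressure gradient, bypassing the BBB
entirely. There, distribution through tissue is governed by charge
(cationic species complex with anionic membrane components and stall near
the catheter) and by practical constraints: a prodrug never meets the
hepatic metabolism that would activate it, and a drug sold only as an oral
solid has no infusable formulation.

`bbbced` encodes both rule sets, ships the reference table of drugs
historically given to DIPG patients, and reconciles its own output against
the published labels so that any change to the rules is immediately visible.

## The systemic score

Each of the three properties is scored binary — optimal (1) or poor (0) —
and summed:

| criterion | scores 1 when | default thresholds |
|---|---|---|
| lipophilicity | `logp_lower < log P <= logp_upper` | (−0.5, 5.0] |
| molecular weight | `MW <= mw_max_da` | 500 Da, inclusive |
| charge | `charge_percent <= charge_neutral_max_percent` | 10%, inclusive |

The sum maps to a label: **3 → likely** ("+", green), **2 → intermediate**
("+/−", yellow: some diffusion, presumably below therapeutic concentration),
**0–1 → unlikely** ("−", red). Drugs between 10% and 90% charge diffuse
partially; at or above 90% they are treated as fully retained in blood —
both score 0 on the charge criterion, and the distinction is kept in the
reason code (`partially_charged` vs `fully_charged`).

Three overrides adjust the label after summation:

* **Prodrugs** are judged by their active metabolite, whose properties the
  reference table does not list (it prints parent-drug values). With no
  metabolite data the model fixes every prodrug at *intermediate* — in both
  directions. Cyclophosphamide (score 3 on parent properties) comes down to
  intermediate; irinotecan (score 1 on parent properties, but its metabolite
  SN-38 is the active, permeant species) comes up to intermediate. This is
  the one override that can promote; the configuration can disable it
  (`prodrug_systemic_cap = "none"`).
* **Molecular-weight hard cap** (`mw_hard_cap_da`, default 900 Da): at or
  above it a drug is demoted to unlikely regardless of its other criteria.
  The reference labels require such a cap: the neutral macrolides at
  914–1030 Da are labelled unlikely although two of the three would
  otherwise score 2, while tacrolimus (804 Da) and cabazitaxel (836 Da) keep
  their intermediate label. Any cap in (836, 914] reproduces all five rows;
  900 is the round value in that interval.
* **Unknown properties**: a record with neither log P nor charge (the
  monoclonal antibodies) is unlikely for want of evidence, flagged
  `unknown_properties` rather than scored arithmetically.

Two further calibration choices are worth spelling out, because the
reference table forces them:

* **The lower lipophilicity bound is −0.5, exclusive.** The rule text only
  bounds log P above (≤ 5), yet the table labels temozolomide (−1.1),
  cytarabine (−2.46) and gemcitabine (−2.01) intermediate as "too
  hydrophilic" while lenalidomide (−0.4) is fully suitable and melphalan
  (exactly −0.5) is not. An exclusive bound at −0.5 reproduces every such
  row. The often-quoted *optimal* log P window of 2.0–3.5 is deliberately
  **not** a scoring cutoff — it would contradict the lenalidomide,
  thalidomide and veliparib rows.
* **Platinum complexes have no assessable log P.** Carboplatin (−0.19,
  371 Da, 0% charged) would score 3, but coordination complexes aquate in
  vivo into charged species, so their octanol/water partitioning is not
  predictive; the lipophilicity criterion is voided (configurable off).

## The CED rules

In precedence order: unknown charge → unsuitable; prodrug → unsuitable;
oral-only formulation → unsuitable (though reformulation into a liquid would
make these drugs candidates — their charge is favorable); predominantly
positive charge above the 10% band → unsuitable; zwitterionic above the band
→ unsuitable (the cationic moiety raises the same membrane-complexation
concern); negative charge above the band → **speculative**, because anionic
drugs have only been studied up to 10% charge; otherwise suitable. All
applicable exclusions are reported, not just the first.

One edge the reference table never exercises: a zwitterion whose charged
fraction is *within* the 10% band is treated like a neutral drug (suitable),
since the band, not the sign, defines effective neutrality.

## Charge from pKa: the ionization module

The packaged table stores charge percentages as printed; they are never
silently recomputed. For user drugs without a charge value the ionization
module derives one from per-group pKa annotations under an
**independent-sites Henderson–Hasselbalch model**: an acid's deprotonated
fraction is $1/(1+10^{pK_a-pH})$, a base's protonated fraction is
$1/(1+10^{pH-pK_a})$, and each of the $2^n$ protonation microspecies has the
product probability of its groups' states. Microspecies are binned by net
charge (protonated bases +1, deprotonated acids −1); zwitterionic species
(≥1 of each) are reported as an overlapping percentage, since a balanced
zwitterion is net-neutral. The dominant sign is the largest of the positive,
negative and zwitterionic percentages, with an exact positive/negative tie
reported as zwitterionic.

The model ignores microstate coupling and tautomerism — the reference data
are single per-drug percentages, against which coupled-site corrections
could not be validated. Enumeration is bounded at 20 groups (about 10⁶
states); beyond that only the closed-form net average charge
$\sum_b f_b - \sum_a f_a$ is available, which the tests verify equals the
enumeration expectation to 10⁻⁹ within the bound.

```{r}
charge_summary(ionization_profile(c("acid", "base"), c(2.3, 9.2)), ph = 7.4)
```

## Reconciliation and the discrepancy whitelist

`reconcile()` recomputes both labels for every packaged drug and compares
them with the published column. Two systemic rows — **mitoxantrone** (log P
1.19, 444 Da, 99% charged; printed unlikely but scoring 2) and
**cobimetinib** (3.90, 531 Da, 100%; printed intermediate but scoring 1) —
cannot be reproduced by any single threshold set consistent with the other
rows, and are carried as a documented whitelist. The tests pin the mismatch
set *exactly*, so a rule change that silently "fixes" or worsens agreement
fails the suite. All CED rows reconcile.

```{r}
kb <- load_knowledge_base()
reconcile(kb$drugs)
```

Note the drug count: the reference table contains **53 rows**, although the
source text's summary arithmetic quotes 51; the package keeps every printed
row, and the headline fraction (8 qualified, truncated to 15%) is unchanged.

## The synthetic record generator

Property tests run on records from `generate_drug_records()`: log P uniform
on [−4, 8], molecular weight on [100, 1300] Da, integer charge on 0–100 with
sign strata (45% positive, 45% negative, 10% zwitterionic among charged
records), and independent 10% strata for the prodrug, oral-only, platinum
and biologic flags. A configurable fraction of records is pinned *exactly*
on the decision thresholds to exercise boundary inclusivity, and biologic
records get missing log P and charge, as real biologics do. Generation is a
pure function of (spec, config): one master seed, per-stream derived seeds
so adding a stratum never shifts another stream, and no effect on the
caller's RNG state.

What the generator does not emulate: correlations between properties (heavy
drugs tend to be more lipophilic), chemically realistic structures, or the
class composition of real pipelines. Passing the oracle-equivalence test on
these records therefore demonstrates that the implementation matches the
*stated rules* everywhere in property space including the boundaries — not
that the rules themselves generalize beyond the reference table.

## Numerical and interface choices

* Thresholds are compared with plain floating-point `<=`/`<` on values as
  printed (two decimals); no epsilon is introduced, and boundary records in
  the fixtures are placed at exactly the configured values.
* Charge percentages from the ionization module are exact products of
  closed-form fractions; rounding happens only at presentation.
* Labels are rendered "+", "+/−", "−" with an ASCII fallback ("+/-", "-")
  for diff-stable CSV; the headline percentage is a *truncated* integer
  (8/53 → 15%), matching the source arithmetic.
* Reports can suppress provenance (timestamp, version) to be byte-identical
  across reruns.
* Test problem sizes: 1000 synthetic records for oracle equivalence, 100
  random ionization profiles for the probability invariants — both complete
  in seconds and cover every rule branch and boundary.

## Limitations

Efflux-transporter affinity (P-gp, BCRP, MRP1) strongly influences actual
brain uptake but is concentration-dependent and too sparsely measured for a
uniform rule; the packaged annotations are attached to reports for context
and never enter the classification. CED suitability here is a charge and
formulation screen only — infusion physics (pressure gradients, volume of
distribution) is out of scope. The model is theoretical triage: it flags
drugs that *cannot plausibly work* systemically, not drugs guaranteed to
work.
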