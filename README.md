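# bbbced

Rule-based triage of chemotherapeutics for **blood–brain barrier (BBB)
passage** and **convection-enhanced delivery (CED)**, built around the drugs
historically administered to patients with diffuse intrinsic pontine glioma
(DIPG).

DIPG tumors infiltrate brainstem tissue behind a largely intact BBB, so a
systemically given drug only reaches the tumor if it can passively diffuse
across tight endothelial junctions. `bbbced` scores that likelihood from
three physicochemical properties — each binary, optimal (1) or poor (0),
then summed:

| criterion | optimal when (defaults) |
|---|---|
| lipophilicity | −0.5 < log *P* ≤ 5 |
| molecular weight | MW ≤ 500 Da |
| molecular charge at pH 7.4 | ≤ 10% of molecules charged |

Score 3 → **likely** ("+", green), 2 → **intermediate** ("+/−", yellow),
0–1 → **unlikely** ("−", red), with overrides for prodrugs (judged by their
active metabolite, hence fixed at intermediate), very heavy drugs (≥ 900 Da
→ unlikely) and biologics with unknown properties. A second rule set
classifies CED suitability, where molecular charge and formulation, not
permeability, are what matter: positively charged, zwitterionic, prodrug and
oral-only drugs are excluded, strongly negative drugs are speculative.

The package ships the reference knowledge base (53 drugs with published
labels, plus P-gp/BCRP/MRP1 efflux annotations), a Henderson–Hasselbalch
microspecies module for computing percent ionization from pKa values, a
deterministic synthetic record generator for property testing, and
reconciliation tooling that pins computed labels against the published
classification (two documented, whitelisted discrepancies; everything else
matches).

## Worked example

```r
library(bbbced)

kb <- load_knowledge_base()
classify_systemic(kb$drugs[1, ])       # carmustine
#> <systemic classification: Carmustine>
#>   score 3/3 -> likely (+)
#>   lipophilicity     1  (within_range)
#>   molecular_weight  1  (within_limit)
#>   charge            1  (effectively_neutral)

classify_ced(kb$drugs[tolower(kb$drugs$name) == "methotrexate", ])
#> <CED classification: Methotrexate>
#>   speculative (+/−); reasons: negative_charge_high

run_screen(provenance = FALSE)
#> <delivery screen: 53 drugs>
#>   systemic likely: 8 / 53 (15%), intermediate: 25, unlikely: 20
#>   CED suitable: 9 / 53 (16%), speculative: 2, unsuitable: 42
```

Carmustine passes all three criteria, so it is one of only eight drugs
(15%, truncated) qualified for systemic administration; the CED screen
qualifies nine drugs, with methotrexate and valproic acid speculative
because strongly anionic drugs have only been studied up to 10% charge.

Percent ionization can be derived from pKa annotations when a drug's charge
is not tabulated:

```r
charge_summary(ionization_profile("base", 9.4), ph = 7.4)
#> <charge summary at pH 7.40>
#>   positive: 99.0099%  negative: 0.0000%  neutral: 0.9901%
#>   zwitterionic: 0.0000%
#>   net average charge: +0.9901 e
#>   dominant: positive (99.0099%)
```

A command-line driver with `screen`, `table`, `reconcile` and `titrate`
subcommands lives at `inst/cli/bbbced.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli", "bbbced.R", package = "bbbced"))')" reconcile
```

See `vignettes/delivery-model.Rmd` for the full model account: threshold
calibration, override semantics, the ionization model and its assumptions,
and what the synthetic-record tests do and do not demonstrate.

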