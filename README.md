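# ChemLibDesign

Ligand-based design of multi-target focused compound libraries in R.

Medicinal-chemistry programs expand the chemical space around validated hit
compounds by applying *transformation rules* — small structural rewrites such
as "replace a phenyl ring with cyclohexyl" or "replace a carboxylic acid with
a thiazolidine-2,4-dione" — encoded in SMIRKS notation. ChemLibDesign is for
computational and medicinal chemists who want to run that workflow end to
end: parse and audit a rule compendium, enumerate a virtual library from seed
compounds, standardize and deduplicate it, score drug-likeness and synthetic
accessibility, filter on medicinal-chemistry criteria, and characterize the
result's diversity in several chemical spaces.

## The method

* **Rule engine.** A SMIRKS string `pattern >> template` is compiled into a
  substructure query (SMARTS subset: element/aromaticity/degree/ring
  primitives, logical operators, recursive environments, atom maps) and a
  product template. The pattern is matched at every site of a molecule and
  the rewrite applied once per site: mapped atoms are kept and updated,
  matched-but-unmapped atoms leave with their bonds, product-only atoms are
  created. Products are kekulized, valence-checked, re-aromatized, and
  deduplicated on stereo-agnostic canonical SMILES.
* **Enumeration.** Iterative frontier expansion (default two iterations)
  with property gates after each pass: MW < 630 Da and 40 ≤ TPSA ≤ 150 Å².
  Each product carries provenance (seed, ordered rule chain, iteration),
  and every chain replays to its product — a tested invariant.
* **Curation.** Largest component, a 13-element whitelist
  (H B C N O F Si P S Cl Se Br I), neutralize/reionize, a deterministic
  rule-based canonical tautomer, and stereo-stripped canonical SMILES keys.
* **Scores.** QED — the weighted geometric mean of eight asymmetric
  double-sigmoid desirabilities over MW, logP, HBA, HBD, PSA, rotatable
  bonds, aromatic rings and structural alerts (published parameters;
  QED ≥ 0.67 marks attractive compounds). SA score — fragment-frequency
  contributions plus size/stereo/spiro/bridge/macrocycle complexity
  penalties, mapped to [1, 10] (≤ 6 means synthesizable in principle).
* **Filter cascade.** SA → (optional synthetic-feasibility plug-in) → QED →
  structural alerts, with per-stage attrition reporting; the survivor set is
  order-invariant by construction.
* **Chemical multiverse.** The same libraries viewed in several spaces:
  PCA and exact t-SNE over six standardized properties (HBD, HBA, logP, MW,
  RotB, TPSA), a minimum-spanning-tree map over ECFP4 Tanimoto distances,
  and the PMI shape triangle (npr1 = I1/I3, npr2 = I2/I3 between the rod
  (0,1), disc (0.5,0.5) and sphere (1,1) vertices).

Canonical SMILES, Wildman–Crippen logP, Ertl TPSA and 3-D conformers come
from OpenBabel (via ChemmineOB); everything else is implemented natively.

## Worked example

```r
library(ChemLibDesign)

rules <- builtinRules()                      # 7 literature rules
length(rules)                                # 7
groupCounts(rules)["Phenyl"]                 # 3

applyRule(rules[["phenyl_to_cyclohexyl"]], "Cc1ccccc1")
#> MoleculeSet with 1 molecules
#>   CC1CCCCC1

seeds <- curateLibrary(c("Cc1ccc(O)cc1C(=O)O", "CCc1ccccc1CC(=O)O"))$set
lib <- enumerateLibrary(seeds, rules, enumerationConfig())
lib
#> EnumeratedLibrary with 17 molecules over 2 iteration(s)
#>   accepted per iteration: 9, 8
#>   gate-rejected per iteration: 1, 0

res <- runFilterCascade(lib, filterSpec())
res$report
#> FilterCascadeReport
#>   input                        17
#>   sascore                      17
#>   qed                          12
#>   alerts                       11
```

The 17 products are everything the seven rules generate from the two seeds
in two passes that sits inside the MW/TPSA gates; the cascade then keeps the
eleven products with QED > 0.67, SA score ≤ 6 and no structural-alert hits.
(The QED/alert attrition depends on the packaged alert catalogs; your counts
will shift if you configure others.)

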