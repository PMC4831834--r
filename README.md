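# gliobayes

Hybrid Bayesian networks for preoperative glioma grading from multimodal
MRI features.

## What problem this solves

Deciding whether a cerebral glioma is low grade (WHO I–II) or high grade
(WHO III–IV) guides therapy, but biopsy is invasive and samples only part
of a heterogeneous tumor. Several MRI modalities carry complementary
grading signal — a 3-state contrast-enhancement category from T1W+C, five
normalized perfusion parameters from PWI (nrCBV, nMTT, nrCBF, nT0, nTTP),
and four metabolite ratios from MRSI (Cho/Cr, NAA/Cr, Lac/Cr, Lip13/Cr) —
and, crucially, different patients have different modalities available.
`gliobayes` is for methodologists and imaging researchers who want a
probabilistic grader that fuses whatever evidence a patient has and can be
learned from such block-incomplete feature tables.

## The model

The grader is a **conditional linear Gaussian (CLG) Bayesian network**.
Grade G (2 states) and enhancement E (3 states) are discrete; every
continuous feature X with discrete parents D and continuous parents U is

    X | D = d, U = u  ~  N(β₀,d + βdᵀu, σ²d)

with parameters per discrete-parent configuration. Structure is learned by
the **K2** greedy search (fixed grade-first ordering, BIC score over the
CLG likelihood), run separately on the perfusion-complete and
MRSI-complete subsets and merged on the shared grade node; parameters are
maximum-likelihood (relative frequencies; per-configuration least squares
with n-denominator variance), fitted available-case per family. Grade is
predicted as argmax of the exact posterior
P(G | observed evidence), with unobserved discrete nodes summed out and
unobserved Gaussian nodes marginalized analytically. Features are screened
beforehand with a tie-corrected two-group Kruskal–Wallis test (drop if
p > 0.05). Evaluation is leave-one-out cross-validation (parameters
refitted per fold) with per-pattern accuracy and trapezoidal-ROC AUC.

Because the emulated 56-patient cohort is not publicly available, the
package ships a synthetic cohort generator whose per-grade feature
means/SDs, group sizes (30 high / 26 low) and modality-availability
pattern (51 PWI / 26 MRSI / 21 both) match the published summary table
exactly; heavy-tailed ratios (Lac/Cr, Lip13/Cr) are moment-matched
log-normals, the rest Gaussian. See the vignette
(`vignettes/clg-glioma-grading.Rmd`) for assumptions and limitations.

## Worked example

```r
library(gliobayes)

tab <- generate_cohort(default_cohort_spec(seed = 1))
gn  <- build_two_part_network(tab, alpha = 0.05)
print(gn)
#> Two-part grading network (part A: 51 rows, part B: 26 rows)
#> CLG network structure: 10 nodes (2 discrete, 8 gaussian), 9 edges
#>   grade [discrete]
#>   T1WC [discrete] <- grade
#>   nrCBV [gaussian] <- grade
#>   nrCBF [gaussian] <- grade
#>   ...
```

Part A was learned on the 51 perfusion-complete rows, part B on the 26
MRSI-complete rows. The screening table shows why nT0 is absent from the
network — it is the one feature whose high/low distributions barely
differ:

```r
subset(gn$screening, select = c(feature, p_value, retained))
#>    feature      p_value retained
#> 1    nrCBV 1.041953e-04     TRUE
#> 4      nT0 5.701070e-01    FALSE
#> 8   Lac_Cr 1.854341e-05     TRUE
#> ...
```

Leave-one-out evaluation under two observation patterns — enhancement
alone versus everything a patient has:

```r
loocv_evaluate(tab, gn$structure, pattern = "T1WC")
#> LOOCV evaluation | evidence: T1WC | n = 56
#>   accuracy 0.8393 (9 wrong), AUC 0.7000

loocv_evaluate(tab, gn$structure,
               pattern = c("T1WC", "perfusion", "MRSI"), require = "T1WC")
#> LOOCV evaluation | evidence: T1WC + perfusion + MRSI | n = 56
#>   accuracy 0.9821 (1 wrong), AUC 0.9744
```

Reading: with enhancement alone, 9 of 56 synthetic patients are
misgraded (ambiguous slight-enhancement cases and atypical enhancers);
adding each patient's available perfusion and spectroscopy evidence
removes all but one error and lifts the AUC from 0.70 to 0.97. The same
run is available end-to-end, with every artifact and a hashed manifest
written to disk, via `run_pipeline(run_config(seed = 1))`, or from a shell
through the thin CLI at `inst/cli/gliobayes.R`
(`simulate | screen | learn-structure | fit | predict | evaluate | sweep | run`).

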