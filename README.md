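# magscan

Quantitative analysis of magnesium-dependent translational control by
upstream open reading frames (uORFs).

The 5'-leader of vertebrate TRPM7 mRNA — the mRNA of the channel-kinase
that imports Mg²⁺ into cells — carries two conserved uORFs that turn
translation of the main reading frame into a magnesium sensor: uORF1
(strong Kozak context, overlapping the main ORF) sequesters most scanning
ribosomes outright, and uORF2 (suboptimal context, U at −3) captures the
remainder preferentially at *high* Mg²⁺, so the main ORF is translated best
when magnesium is scarce. magscan is for researchers studying uORF-mediated
translational control who want this system — and reporter experiments built
on it — as computable, testable objects.

The package provides:

* **Leader annotation** — upstream AUG discovery, uORF geometry (length,
  frame, overlap with the main ORF, gap to the main AUG), Kozak context
  classification from the −3/+4 positions, GC content
  (`annotate_leader()`).
* **A leaky-scanning/reinitiation model** — reporter synthesis flux
  factorises as cap-dependent 43S loading × leader transmission:

  `flux(Mg, K) = L(Mg, K) · Π_i [1 − p_i(Mg)·loss_i] · p_reporter(Mg)`

  where loading `L` is a two-sided Gaussian bell in added Mg whose center
  shifts affinely with added K, each AUG's initiation probability `p_i` is
  a context-class logistic in Mg (strong contexts flat, suboptimal contexts
  rising), overlapping uORFs sequester ribosomes (`loss = 1`), and
  non-overlapping uORFs lose ribosomes except a reinitiating fraction `q`
  (`closed_form_flux()`, with a Monte-Carlo twin `simulate_scanning()` and
  construct mutation operators `aug_knockout()`, `stop_knockout()`,
  `fuse_reporter()`).
* **Kinetic analysis** — plate-reader luminescence curves → maximal
  synthesis rate (windowed OLS slope, ALU/min; `max_synthesis_rate()`).
* **Dose–response analysis** — Gaussian bell fits of rate vs added Mg,
  magnesium optima, extract calibration and reference normalisation
  (`fit_bell()`, `mg_optimum()`, `calibrate_extract()`,
  `compare_optima()`).
* **A synthetic-data generator** — leader fixtures with exact prescribed
  geometry and complete simulated translation experiments with ground
  truth (`make_leader_fixture()`, `simulate_experiment()`), so everything
  above runs with no external data.
* **A fitted parameter set** — `scanning_preset("paper2014")`, obtained by
  `fit_scanning_params()` from the published quantitative observations
  (fold changes, optimum shifts, potassium invariance) so that one point in
  parameter space reproduces them jointly.

## Worked example

Simulate the reference experiment (TRPM7-like and β-globin-like reporters
at 60 mM added K, noise off), run the analysis pipeline, and compare
magnesium optima:

```r
library(magscan)

params <- scanning_preset("paper2014")
design <- experiment_design(constructs = c("M7-Luc-M7", "beta-Luc-M7"),
                            k_levels = 60, replicates = 1, noise_sd = 0,
                            seed = 1)
sim <- simulate_experiment(design, params)
res <- analyze_traces(sim$traces, reference = NULL)
print(res$optima[, c("construct", "k_mM", "optimum")], row.names = FALSE)
#>    construct k_mM optimum
#> beta-Luc-M7   60     1.0
#>   M7-Luc-M7   60     0.8
```

The TRPM7-like leader's optimum sits at 0.8 mM added Mg; the uORF-free
β-globin-like leader peaks 0.2 mM higher — at 120 mM K the same comparison
gives +0.4 mM, and at the wild-type optimum the uAUG1 knockout construct
(`1AUC-Luc-M7`) translates ~2.6× better than wild type:

```r
wt_opt <- flux_optimum(paper_constructs()[["M7-Luc-M7"]], params, K = 60)  # 0.8
constraint_residuals(params)  # shipped preset vs every printed observation
```

Annotating a leader FASTA from the shell:

```sh
Rscript inst/cli/magscan annotate --fasta leaders.fasta --out annotation.tsv
```

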