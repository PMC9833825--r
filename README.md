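# dupdiv

Simulation and assay toolkit for the early dynamics of gene
duplication–amplification–divergence in bacterial populations.

## The problem

When selection favours higher expression of a weakly expressed gene, two very
different kinds of adaptive mutations compete: **copy-number mutations**
(tandem duplication and further amplification of the locus, raising expression
by dosage) and **point mutations** (here, SNPs that strengthen a weak random
promoter). Duplications arise orders of magnitude more often than point
mutations (10⁻⁶–10⁻² vs ~10⁻⁹–10⁻⁷ per cell per generation) but are unstable —
arrays expand and contract by recombination between the repeats at 10⁻³–10⁻¹
per cell per generation — and each extra copy carries a fitness cost. Whether a
population adapts by amplification, by promoter divergence, or by a
combination depends on the **expression demand** of the environment: the
expression level at which growth rate saturates. Past that plateau, an extra
mutation adds cost without benefit, so dosage and promoter mutations interact
with *negative epistasis*; frequent amplification can then pre-empt and hinder
promoter divergence ("amplification hindrance").

`dupdiv` provides:

* a seeded stochastic simulator of a 12-day serial-dilution evolution
  experiment over genotype classes *(k copies, m mutant copies)*, with a
  deterministic infinite-population oracle;
* a virtual dual-fluorophore readout (YFP reports total expression of the
  selected locus, CFP reports copy number) with population- and single-cell
  classification into the four canonical fractions (ancestral, YFP+,
  YFP+CFP+, mixed);
* the three accompanying measurement procedures: steepest 20-point
  sliding-window growth rate from log(OD) time series, efficiency-corrected
  (Pfaffl) relative copy number from qPCR Cq tables, and a 39-bp-motif
  allele-fraction divergence metric for amplicon reads with contaminant
  exclusion;
* synthetic-data generators for all four real-data shapes (plate-reader CSV,
  flow-cytometry-like event CSV, amplicon FASTQ, Cq CSV) with known ground
  truth.

## The model

A genotype is a tandem array state *(k, m)*: *k* copies of the reporter locus
(1 ≤ k ≤ kmax), *m* of them carrying the evolved promoter allele. Expression is
pure dosage,

    E(k, m) = (k − m)·β_anc + m·β_mut ,

and growth rate follows a piecewise-linear saturating map with per-copy cost,

    r(k, m) = max{ 0,  r0 + (rmax − r0)·min(E/D, 1) − c·(k − 1) } ,

with demand *D* setting the regime: low demand (D = 4) is satisfied by either
a single point mutation (β_mut = 20) or amplification to four copies;
high demand (D = 60) is unreachable by either route alone and requires a
combination. Mutational moves per generation: duplication (1, m) → (2, 2m) at
μ_dup; array expansion/contraction (k, m) → (k ± 1, ·) at μ_step·(k − 1), the
affected copy being a mutant one with probability m/k; point mutation
(k, m) → (k, m + 1) at μ_pm·(k − m). Days are simulated by solving the growth
time to carrying capacity, tau-leaping Poisson mutation flows over ten
sub-intervals, and sampling the 1:820 daily bottleneck multinomially
(≈ 10 generations per transfer).

## Worked example

```r
library(dupdiv)

cfg <- sim_config(env = demand_preset("low"), rates = rate_preset("IS+"),
                  protocol = serial_protocol(k_cap = 1e6))
ex <- run_experiment(cfg, n_replicates = 8, base_seed = 1)
glance(ex)
#> # A tibble: 8 × 5
#>   replicate final_day amplified_freq combination_freq point_mutant_freq
#>       <int>     <int>          <dbl>            <dbl>             <dbl>
#> 1         1        12          1.000       0.00000612        0.00000612
#> 2         2        12          1.000       0                 0
#> 3         3        12          1.000       0.00000709        0.00000709
#> # ... 8 replicates: amplification fixed everywhere, no combination mutants

ft <- fraction_table(ex)
ft[ft$day == 12 & ft$n_replicates > 0, ]
#>     day label        n_replicates
#> 1    12 YFP_CFP_PLUS            8
```

Under low demand every replicate ends amplified (normalized YFP and CFP rise
together: the YFP+CFP+ fraction) and combination mutants stay at the
10⁻⁶-frequency mutation–selection floor — copy-number adaptation pre-empts
promoter divergence.

The assays round-trip their generators:

```r
estimate_copy_number(gen_qpcr_run(true_copies = 4, noise_sd = 0, seed = 1))
#>   sample e_target e_ref dcq_target dcq_ref copy_number
#> 1 sample     2.00  2.00          2       0        4.00

ms <- build_motif_set(synthetic_p0_reference(), start_codon_at = 61)
reads <- gen_amplicon_reads(population_state(k = 4, m = 1, n = 1e5), ms,
                            n_reads = 10000, error_rate = 0, seed = 1)
divergence_fractions(count_motifs(reads, ms))
#>   motif  count fraction
#> 1 -30T>A     0    0
#> 2 -37C>T     0    0
#> 3 double  2529    0.339
```

The last number embodies the template-dilution argument: cells with one
evolved copy in a four-copy array contribute one evolved per three ancestral
templates, so the evolved/ancestral read fraction is 1/3, not 1 — a diverged
copy inside an amplified array also has only a 1-in-4 chance of being the copy
that survives array contraction.

## File formats

| file | columns |
|---|---|
| plate CSV | `well, day, od, yfp, cfp` |
| event CSV | `event, yfp, cfp` |
| Cq CSV | `sample, channel, replicate, cq, dilution` (dilution-series rows have `sample = "dilution"`) |
| trajectory CSV | `replicate, day, k, m, count` |
| FASTQ | strict 4-line records, qualities carried but ignored |

All CSVs are UTF-8, comma-separated, dot-decimal, with a mandatory header.
`read_run_config()` reads TOML-style `[section] key = value` files; every
artifact-producing command writes a JSON manifest with the package version,
the full configuration and its MD5 hash, and all seeds.

A thin command-line wrapper over these functions ships at
`inst/cli/dupdiv.R` (subcommands `simulate`, `synth`, `assay-growth`,
`assay-pfaffl`, `assay-amplicon`, `report`).

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes the protocol's analytic acceptance quantity — the generations per
daily transfer implied by the 1:820 dilution, `round(log2(820))` — after
running the main pipeline end to end (both demand regimes, fraction
classification, pooled amplicon divergence, qPCR copy-number round-trip), and
writes it as JSON. The simulation-based acceptance properties (mutual
exclusivity, combination regime, amplification hindrance, oracle equivalence,
monotonicity) run as `tests/testthat/test-acceptance.R`.
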