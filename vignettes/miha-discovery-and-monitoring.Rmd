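---
title: "From nonsynonymous SNPs to decoded multimer screens: the mihakit pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From nonsynonymous SNPs to decoded multimer screens: the mihakit pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mihakit)
library(dplyr)
```

## The problem

After HLA-identical allogeneic stem cell transplantation, donor CD8+ T cells
can attack recipient hematopoiesis through minor histocompatibility antigens
(MiHA): peptides arising from nonsynonymous SNPs at which recipient and donor
differ. Monitoring these responses — and discovering new MiHA — requires
(i) predicting which SNP-derived peptides bind a given HLA molecule,
(ii) restricting attention to SNPs whose population frequency makes a
donor–recipient disparity likely, (iii) verifying peptide–HLA binding in
vitro, and (iv) detecting many antigen specificities at once in small blood
samples by combinatorially encoded MHC multimers. `mihakit` implements the
computational side of each step, plus seeded generators that fabricate every
input with known ground truth.

## Candidate enumeration and binding prediction

A nonsynonymous SNP at protein position $v$ can be presented in any 9- or
10-mer window covering $v$: an interior variant therefore yields 9 + 10 = 19
candidate allelic peptide pairs. `enumerate_windows()` emits them all
(1-based coordinates, ordered by length then start), pairing the reference
and alternate peptide that differ at exactly one offset. Both allelic
peptides are emitted because downstream policy — not the enumeration — should
decide which allele must bind. Windows containing residues outside the
20-letter alphabet are skipped with a warning, since binding coefficients are
undefined there.

Binding is predicted with the classical position-coefficient model: the
half-time of dissociation of peptide $x_1 \dots x_L$ from the allele is

$$ T_{1/2}(x) = c \prod_{i=1}^{L} M[i, x_i], $$

with $M$ a per-position, per-residue coefficient matrix and $c$ an
allele-specific constant in seconds. `filter_binders()` applies an inclusive
threshold, 30 s by default — a value calibrated against known HLA-A2 binders
at which a peptide of moderate affinity passes. The default policy
(`alt_only`) requires the MiHA-positive peptide to pass; `either` and `both`
are available because screening campaigns have discarded candidates whose
*other* allelic peptide bound poorly, suggesting alleles are sometimes judged
independently. Published coefficient matrices are licensed data we do not
redistribute: the package defines a plain-text matrix format
(`read_coefficient_table()`, bit-exact on round trip) for user-supplied
tables and seeded synthetic tables (`simulate_coefficient_table()`) for
testing. Synthetic coefficients are log-normal with `sdlog = 0.8`, so random
9-mer log half-times spread with standard deviation $0.8\sqrt{9} = 2.4$
around `log(constant)` and a 30 s threshold splits candidates rather than
passing or failing them en bloc.

## Clinical applicability and the frequency band

Under Hardy–Weinberg proportions and donor–recipient independence, a MiHA
whose positive allele has frequency $p$ (write $q = 1-p$) is exploitable in a
random HLA-matched pair with probability

$$ A(p) = \underbrace{(1 - q^2)}_{\text{recipient carries it}}
          \cdot \underbrace{q^2}_{\text{donor does not}} , $$

which peaks at $0.25$ when $q^2 = 1/2$ ($p \approx 0.293$).
`frequency_band()` inverts $A(p) \ge t$ in closed form via the quadratic
$y^2 - y + t = 0$, $y = q^2$; for $t = 0.20$ the exact band is
$(0.1494,\,0.4743)$. The default operational band in
`filter_by_frequency()` is the rounded $[0.15, 0.46]$ window actually used
to shortlist candidates, inclusive at both ends; the exact solution band is
available when wanted. Both assumptions (HWE, unrelated-donor independence)
are stated, not tested: sibling-donor transplants violate independence, but
the criterion is defined by the formula regardless.

```{r}
clinical_applicability(c(0.15, 0.46))
frequency_band(0.20)
```

`is_disparate()` applies the graft-versus-tumor-direction rule at the
genotype level — recipient carries ≥ 1 positive allele, donor none — which is
what SNP genotyping of screened donor–recipient pairs checks.

## ELISA triage

UV-exchange ELISA optical densities are classified `low` (< 0.4),
`intermediate` ([0.4, 1.25)) or `high` (≥ 1.25); low binders are discarded
before multimerization. The 0.4 boundary is genuinely ambiguous in common
usage ("≤ 0.4 discarded" versus "0.4–1.24 intermediate" describe the same
screen); we resolve it by making 0.4 itself intermediate and retained, and
document the choice here rather than hiding it. ODs are consumed pre-averaged; `read_od_table()`
averages `od_rep*` replicate columns when present.

## Panel design

With $k$ fluorochromes and unordered two-color codes, $\binom{k}{2}$
specificities are resolvable: 15 with six colors, 10 with five.
`assign_codes()` hands codes to peptides deterministically (lexicographic in
channel index, peptides in input order) so a panel is reproducible from its
inputs; the shipped 10-MiHA kit fixture uses all ten codes of five
fluorochromes exactly once. `pack_pools()` reproduces the screening layout
rule: controls one per pool from the first pool, candidates filling to
capacity, remainder in the last pool — 75 candidates plus 4 known-MiHA
controls at capacity 15 give five pools of 15 and one of 4, controls in
pools A–D. Code order and control placement are our own deterministic
conventions; published pool tables are one valid instance, not a constraint.
Codes need only be unique within a pool, so the same channels serve every
pool. Spectral-intensity-aware pairing (low-intensity Qdots) is out of
scope.

## Event decoding

`gate_cd8()` applies the standard pre-gate (viability dye negative, lineage
dump channel negative, CD8 positive) as a pure conjunction, logging per-gate
counts. `decode_events()` then computes each event's set of positive
multimer channels: exactly two positives matching a panel code assigns the
event; single positives, three-or-more positives, and unmatched pairs are
excluded and counted — the correction-by-exclusion that suppresses
single-fluorochrome artifacts without modeling compensation. Frequencies are
percentages of CD8-gated events, formatted to two decimals with values below
0.01% shown as `<0.01%` (exact values retained in machine output).
`dual_color_frequency()` gives the conventional single-specificity readout,
which is always ≥ the decoded frequency of the same code since decoding
additionally excludes events positive elsewhere.

Positivity is judged on transformed intensity against per-channel
thresholds. Defaults: inverse hyperbolic sine with cofactor 150 (linear near
zero, logarithmic for bright signal) and a single threshold at 500 intensity
units; any channel can override, and `quantile_thresholds()` derives
thresholds from an unstained control at a chosen quantile (default 99.9%).
Cytometer operators gate manually, so any automatic rule here is explicit
and overridable. Compensation, doublet discrimination and clustering-based
auto-gating are not modeled.

## The synthetic-data generators

Every pipeline input can be fabricated with known truth
(`simulate_variants()`, `simulate_od()`, `simulate_events()`,
`simulate_genotypes()`, `simulate_coefficient_table()`), each byte-identical
under a fixed seed (default 20110624, memorable and arbitrary) and each
emitting a truth table sufficient to score the downstream stage.

The event generator draws, per event: dead (5%), lineage-dump positive
(10%), CD8 positive (70% of the rest), and — among gateable events — a label:
a panel specificity at its spike frequency, single-positive noise (1%),
triple-positive noise (0.2%), or negative. Intensities are two-component
log-normal per channel: negatives around 40 a.u. (`sdlog` 0.45), positives
around 5000 a.u. (`sdlog` 0.4). That decade of separation mirrors a
well-compensated channel where manual gates are unambiguous, and makes
threshold gating exact by construction — which is the point: it lets tests
attribute every decoding error to the decoder, not the gate. What the
generator deliberately does *not* emulate: spectral spillover, acquisition
drift, doublets, debris, or enrichment/expansion kinetics (enrichment is
represented only as elevated spike frequencies). Passing tests therefore
demonstrate the correctness of the windowing/scoring/decoding logic, not
robustness to instrument-level artifacts on real FCS data, where threshold
placement is the user's responsibility.

Problem sizes used in the shipped tests were chosen to make binomial checks
sharp while keeping the suite quick: 20 replicate acquisitions of $10^5$
events for decoder recovery, $10^5$ genotype pairs per allele frequency for
disparity rates, 1000 random peptide pairs for the scoring oracle.

## A worked example

```{r}
sim <- simulate_variants(n_proteins = 40, seed = 7)
pairs <- enumerate_windows(sim$variants, sim$sequences)
tabs <- list(simulate_coefficient_table(9, seed = 1),
             simulate_coefficient_table(10, seed = 2))
shortlist <- pairs |>
  filter_binders(tabs, min_t_half = 30) |>
  filter_by_frequency(band = c(0.15, 0.46))
nrow(pairs); nrow(shortlist)

panel <- miha_kit_panel()
acq <- simulate_events(panel, n_events = 5e4,
                       spike_freqs = setNames(seq(0.001, 0.01, length.out = 10),
                                              panel$peptide_id),
                       seed = 11)
dec <- acq$events |> gate_cd8() |> decode_events(panel)
tidy(dec)
glance(dec)
```

## Numerical choices and edge cases

- Thresholds are inclusive where the motivating criteria read inclusively:
  half-time ≥ 30 s, frequency band endpoints, OD class boundaries
  (`od = 1.25` is high, `od = 0.4` is intermediate).
- A peptide with any zero coefficient on its path scores exactly 0 and can
  never pass a positive threshold.
- `frequency_band()` refuses thresholds ≥ 0.25 (no solution exists) and its
  endpoints satisfy $A(p) = t$ to well below $10^{-9}$.
- Empty inputs (no variants, no events, empty pools) return empty tibbles or
  all-zero summaries rather than erroring.
- Degenerate decodes: a dual-positive pair matching no code is excluded and
  counted with the multi-positive events, never raised as an error — real
  screens see such events routinely.
- Coefficient files are written with 17 significant digits and parsed with
  base R's correctly-rounded reader, so write/read is bit-exact.

## Limitations

Transcript-level annotation, splice variants, cryptic translation products
and proteasome-spliced peptides are outside the enumeration model; live
database retrieval is deliberately not performed (inputs are files);
patient-specific screening percentages depend on raw cytometry data and are
not reproducible from summary tables, so the decoder is validated on
synthetic acquisitions instead.
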