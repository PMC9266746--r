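---
title: "Profiling dinucleotide-specific ribonuclease cleavage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profiling dinucleotide-specific ribonuclease cleavage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rnasespec)
```

## The problem

Endoribonucleases described as "base-specific" are usually specific to a
*dinucleotide*: RNase MC1 cleaves 5′ of uridine but leaves GpU intact;
cusativin cleaves 3′ of cytidine but not CpC. Because these enzymes are
used to fragment RNA for modification mapping by LC-MS/MS, an incomplete
picture of their preferences translates directly into misassigned or
missed cleavage sites. `rnasespec` implements a complete, testable
computational counterpart of the experimental workflow that measures
these preferences: a single probe substrate exposing all 16 ordered
dinucleotides, enumeration and mass annotation of digestion products,
inference of cut bonds from identified products, and a per-bond cleavage
efficiency statistic with replicate aggregation.

## The generative model

Digestion is modelled as **independent cuts**: every scissile bond $i$
(between residues $i$ and $i+1$, $1 \le i \le n-1$) of every molecule is
cut independently with probability $p_i$, a function of the ordered pair
of flanking bases, with exact-code overrides for modified residues. A
product occupying $[i, j]$ requires a cut at both boundaries (molecule
ends count as cut) and no cut inside:

$$P(i,j) \;=\; c_{i-1}\, c_j \prod_{i \le k < j} (1 - c_k),
\qquad c_0 = c_n = 1 .$$

This is the simplest model consistent with the observation that each
product is delimited by two endonucleolytic cuts. Whether real missed
cleavages arise from per-molecule independence or from processivity is
an open biochemical question; independence is the declared, testable
choice here, and it is what makes the efficiency estimator below exactly
unbiased. The model deliberately has no time axis: a digestion endpoint
is treated as a single partial-digest snapshot, and kinetic modelling is
out of scope.

Cleavage chemistry: internal products receive a 5′-hydroxyl and a
2′,3′-cyclic phosphate (`>p`), the direct transesterification product,
which is one water (18.0106 Da) lighter than a linear 3′-phosphate. A
linear-phosphate mode is a model switch
(`product_terminus3 = "phosphate"`), and mass matching can tolerate both
forms since they differ by exactly one water.

## The efficiency statistic

For bond $i$, with product abundances $A(\cdot)$:

* $x_i = \tfrac12\left(\sum_{\text{end}=i} A + \sum_{\text{start}=i+1} A\right)$ —
  each cut generates one product ending at $i$ and one starting at
  $i+1$; averaging the two sums uses both observations without double
  counting.
* $y_i = \sum_{\text{start}\le i < \text{end}} A$ — undercut (spanning)
  abundance.
* $\text{efficiency}_i = 100\, x_i / (x_i + y_i)$.

Under the model, the total expected abundance of products ending at $i$
is $n_{\text{mol}} p_i$ (the sum over start positions telescopes to 1),
and likewise for products starting at $i+1$; spanning products total
$n_{\text{mol}}(1-p_i)$. Hence on noiseless expectations the statistic
returns exactly $100\,p_i$ — the package's estimator-exactness test
verifies this to $10^{-9}$ against brute-force enumeration of all
$2^{n-1}$ cut patterns for parents up to 8 nt.

Efficiencies are categorized as **extremely low** ($<5$), **low**
($[5, 25)$), **moderate** ($[25, 50]$), **efficient** ($>50$). Exact
boundary values join the band whose printed range begins there (5 → low,
25 → moderate), and exactly 50 is moderate; the report JSON records
these conventions. A bond with $x_i + y_i = 0$ is reported as *no
coverage* (NA) — deliberately distinct from an observed 0 %, which
requires spanning products to exist.

Bonds flanked by modified residues aggregate under their exact-code
dinucleotide (`[m5C]pU` separately from `CpU`), since modifications can
silence cleavage entirely (e.g. `[m1A]pU`, `[m7G]pU` in the MC1 preset)
or leave it untouched (`[m5C]pU`, dihydrouridine behaving as U).

## Parameters that matter

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| `max_missed` | 2 | bonds | candidate lists for identification; two missed cleavages already cover the partial products seen in practice |
| `min_probability` | 1e-4 | — | bonds below this are not treated as cleavable sites, keeping candidate lists finite for low-probability models |
| `tol_ppm` | 10 | ppm | typical high-resolution negative-mode accuracy; a configuration default, not a claim about any instrument |
| `charges` | −1…−6 | — | usual ESI charge range for short oligonucleotides |
| `n_molecules` | 1e4 | molecules | simulation depth at which Poisson-scale relative error is well below the 5-point category resolution |
| `noise_sigma` | 0.2 | log-units | lognormal multiplicative abundance noise; reproduces the replicate scatter implied by reported min–max bands of tens of percent |
| `n_replicates` | 4 | — | the minimum replication the profiling design calls for |
| `min_detectable_length` | 2 | nt | mononucleotides are not retained/detected in typical LC-MS setups |

## The simulator, and what passing tests do and do not show

`simulate_digest()` multiplies exact expected abundances by lognormal
noise per product per replicate, censors products below the detection
floor, and emits unanchored identification tables plus a ground-truth
record. The seed fixes the entire output byte stream.

It emulates: partial digestion with bond-specific probabilities,
replicate-level multiplicative abundance noise, and the invisibility of
mononucleotides. It does **not** emulate: per-oligonucleotide ionization
efficiency (the uniform response is an idealization — the real method is
explicitly semi-quantitative), chromatographic effects, isotope
envelopes, spectral noise, or misidentification by the upstream search
engine. Recovery tests passing therefore demonstrate that the
*estimator and placement logic* are correct under the stated model, not
that any particular instrument result is reproduced. Category-level
recovery (efficient / moderate / low / extremely low) is the honest
resolution at which simulated and published profiles can be compared.

Two bias sources are worth knowing about, and both are visible in the
package's own tests:

* **Detection floor.** Removing mononucleotides biases only bonds
  adjacent to length-1 products; the ½-average definition of $x$ limits
  the bias to the missing end term. A bond *between two* censored
  mononucleotides (e.g. the middle of GGG under a complete G-specific
  digest) loses all its evidence and is reported as no coverage rather
  than silently wrong.
* **Placement ambiguity.** In `split` mode a product whose sequence
  occurs at several positions has its abundance divided equally among
  them, which can leak small amounts of spurious support onto bonds with
  true $p = 0$ (fractions of a percent to a few percent on the reference
  probe). `unique_only` mode trades this for loss of coverage instead;
  both placements are logged.

## Numerical and design choices

* **Masses are derived, never transcribed.** Residues are stored as
  elemental formulas (internal residue = nucleoside 3′-monophosphate −
  H₂O); all numeric masses come from one atomic-mass table at load time.
  Terminus chemistry is a signed formula delta. The test suite checks
  every tabulated mass against an independently coded elemental oracle
  and against literature NMP masses to 1e-4 Da.
* **Fragment series.** Defaults are the dominant RNA CID channels c, y,
  w, a−B, with the convention c = 5′ fragment bearing a *linear*
  3′-phosphate and y = 3′ fragment with 5′-OH, so
  $\mathrm{mass}(c_i) + \mathrm{mass}(y_{n-i}) = M + \mathrm{H_2O}$ for
  every $i$. Water-shifted variants (b = a − H₂O covers the cyclic-
  phosphate 5′ fragment; x, z analogously) are available behind the same
  flag. Published tools disagree on which water state the letters
  denote; the convention here is fixed, documented, and internally
  consistent, and matching tolerates the ±H₂O alternative.
* **Probe design.** A linearized de Bruijn cycle (17 nt) plus greedy run
  extension, re-checked for coverage and forbidden motifs, rather than
  an ILP: reproducible and obviously correct beats minimal. Extending an
  existing doubled base adds only an XpX pair that full coverage already
  contains, so coverage is preserved by construction. No minimality or
  structure/Tm claims are made.
* **Tie-breaks in matching:** smallest |ppm|, then higher charge
  magnitude; candidates isobaric within numerical precision are all
  reported and flagged ambiguous rather than resolved arbitrarily.
* **Determinism.** Every stochastic entry point takes an explicit seed;
  identical configurations produce byte-identical outputs.
* **5′ terminus of a synthesized probe** is taken as hydroxyl (as
  delivered by standard solid-phase synthesis); it is a flagged default,
  configurable at parse time.

## Problem sizes used in the checks

The shipped validation uses exhaustive cut-pattern enumeration for
parents ≤ 8 nt (≤ 128 patterns, exact to 1e-12), the 31-mer reference
probe for pipeline-level checks, and recovery simulations at 10⁴
molecules × 4 replicates × σ = 0.2 — depths at which the per-class
means are stable to well under one category width, as the acceptance
script's seed-to-seed spread shows.

## Known limitations

* Quantification is relative within a bond (x against y); no correction
  for differential ionization across oligonucleotides is attempted.
* The independent-cut model cannot represent processive or
  cooperative cleavage; systematic deviation between observed missed-
  cleavage patterns and the model would show up as efficiency estimates
  that drift with digestion extent.
* Sequence-specific endonucleases recognizing > 2 nt (MazF-like) are
  outside the model's vocabulary — the bond probability depends on the
  dinucleotide only.
* The fragment matcher is a basic substrate for identification, not a
  scored search engine: no FDR, isotope fitting, or MS² spectrum
  prediction.
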