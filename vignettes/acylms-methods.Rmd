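---
title: "AcylMS: models and methods for lipidated-peptide MS/MS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{AcylMS: models and methods for lipidated-peptide MS/MS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(AcylMS)
```

## The problem

Long-chain *S*-acylation links C14–C20 fatty acids to cysteine thiols via
a thioester; prenylation links farnesyl or geranylgeranyl isoprenoids via
a thioether. Both make peptides very hydrophobic, and the thioester is
labile under collisional activation, so a conventional search that knows
nothing about the lipid chemistry either misses these peptides or
mis-scores their spectra. AcylMS encodes the lipid-aware fragmentation
chemistry once, and builds annotation, localization, database search and
MS1 quantification on top of it.

## Mass model

Monoisotopic atomic masses are CODATA/NIST values (C = 12 exact,
H = 1.00782503207, N = 14.0030740048, O = 15.9949146196, S = 31.97207100,
P = 30.97376163); the proton is 1.007276466 Da. Electron mass is
neglected everywhere, including for radical species, which are tracked
only through a flag and their formula. A peptidoform's neutral mass is
the sum of residue masses + H2O + modification deltas; by construction
this equals the monoisotopic mass of the assembled elemental composition
(the suite checks the two routes agree to 1e-9 Da). Ambiguity codes
(B, J, O, U, X, Z) are rejected rather than approximated.

Modification deltas are derived from elemental formulas, not hard-coded
decimals: myristoyl C14H26O, palmitoyl C16H30O, stearoyl C18H34O,
farnesyl C15H24, geranylgeranyl C20H32, NEM C6H7NO2, carbamidomethyl
C2H3NO, acetyl C2H2O, oxidation O. Published reference values for these
deltas were computed with slightly different constant sets and differ
from ours by up to ~2.4e-6 Da, so every registry comparison uses a
5e-5 Da tolerance rather than asserting printed digits. User registries
are accepted as TSV in the same dialect; an entry may give only a delta
mass when its formula is unknown, at the cost of formula-based checks.

## Fragmentation model

Backbone ions follow the standard relations (singly protonated): y = sum
of C-terminal residues + H2O + proton; b is the complement; c = b +
17.026549 (NH3); z&#183; = y − 16.018724 (the radical z+1 species — the
only z type emitted). Fragment charges run from 1 to
`maxFragmentCharge`, default `min(2, precursor charge)`.

Neutral-loss channels are attached per *lability class*:

| class | activation | channel | series |
|---|---|---|---|
| thioester_acyl | CID | intact acyl (e.g. C16H30O) | y, p |
| thioester_acyl | HCD | intact acyl | b, y, p |
| thioester_acyl | ETD | acyl+S / acyl+S+H radicals | p, z&#183; |
| thioester_acyl | ETD | intact acyl | p |
| thioether_prenyl | CID/HCD | intact isoprenoid | b, y, p |
| thioether_prenyl | CID/HCD | C10H16 (geranylgeranyl only) | p |
| thioether_prenyl | ETD | intact isoprenoid | p |

A loss variant is generated only when the ion's residue span contains a
modification of the channel's class; for multiply lipidated spans the
loss multiplicity runs up to `lossCap` (default 2 — di-acylated peptides
can physically shed both chains, deeper multiplicities add nothing at
realistic intensities). Ion labels carry one asterisk per loss. Under
CID, b-series losses are not emitted (reported loss ions under CID are
y\*/p\*; b\* appears under HCD) — this is configurable through the rule
table. The EThcD rule set is the union of HCD and ETD channels.

Two modelling choices deserve emphasis:

* **Diagnostic ion (d\*).** Reference spectra of palmitoylated peptides
  show a 239.24 ion specific to the palmitoyl group, without a published
  formula. We model d\* as the acylium-type species *acyl delta +
  proton*, which reproduces 239.2369 for palmitoyl and generalizes to
  other chains (267.2682 for stearoyl). d\* is emitted under CID/HCD
  only; it is absent from ETD spectra.
* **ETD side-chain losses for non-palmitoyl chains.** The S–C cleavage
  products are demonstrated only for palmitoyl (C16H30OS&#183;,
  C16H31OS&#183;). We generalize the composition as *modification + S*
  and *+ S + H*; ions from the generalized formulas are flagged
  `extrapolated` in the fragment table.
* **Geranylgeranyl partial loss.** The C10H16 half-moiety loss is
  emitted at its formula-derived mass, 136.1252 Da. Reports quoting
  "136.14" for this loss are at odds with the composition; we follow the
  formula.

a-ions, immonium ions other than d\*, internal fragments and intensity
prediction are out of scope.

## Annotation, ion coverage, localization

Peak matching assigns each theoretical ion to the observed peak with the
smallest |ppm error| within the tolerance (default 20 ppm, matching
common high-resolution search settings). One observed peak may satisfy
several theoretical ions; such matches are kept and flagged ambiguous.
Match sets are monotone in the tolerance.

**Ion coverage** is defined over backbone cleavage sites, not ion
counts: site *i* of an *n*-residue peptide (i = 1..n−1) is covered if
any matched b/c ion of index i or y/z&#183; ion of index n−i exists;
coverage = covered/(n−1). Neutral-loss variants count by default because
they retain sequence information; a strict mode excludes them. Precursor
and diagnostic matches never count — they carry no backbone position.
This definition is the package's own (published ion-coverage figures for
this chemistry come from unpublished in-house scripts); it is stated
here precisely so results are interpretable.

**Localization** enumerates every distinct assignment of the given
modification multiset to the candidate sites (at most one modification
per site). An ion is *site-determining* when its theoretical m/z is not
shared by all assignments; each assignment's score is the number of its
matched site-determining ions plus 0.01 × matched-intensity fraction as
a tie-break. The delta score is the gap between the top two assignments;
zero means the spectrum contains no discriminating evidence and the call
is flagged ambiguous. The score is deliberately a transparent ion count;
probabilistic (Ascore-style) site scoring is out of scope.

## Digestion and the search engine

Strict trypsin means cleavage C-terminal to K/R except before proline
(the KR|P rule). Defaults: 2 missed cleavages, peptide length 7–50,
protein N-terminal Met clipping on. Clipping *adds* the peptides of the
Met-clipped protein rather than replacing the unclipped set, matching
how discovery engines treat the option; duplicates are removed by
(sequence, start). Variable-modification enumeration assigns each
eligible site one of {unmodified} ∪ {applicable mods} with at most
`maxMods` (default 3 — no published bound exists for this workflow;
three keeps di-acylated + capped-Cys peptidoforms reachable without
exploding the space) and deterministic ordering.

Decoys are per-protein reversals with the C-terminal residue fixed, the
simplest scheme that preserves tryptic C-termini. Candidates within the
precursor tolerance of the observed neutral mass are scored as the
number of matched backbone ions — neutral-loss variants and d\* included,
because they are precisely the lipid-specific evidence (a flag disables
them for ablation) — plus 0.01 × matched-intensity fraction. A candidate
is reported only when at least `minMatchedIons` (default 4) scoreable
ions matched: sparser matches carry no sequence evidence, and because
decoy counting is an estimate, chance 2–3-ion matches on noise spectra
can otherwise slip under any q-value threshold. The top PSM per spectrum
enters FDR estimation: PSMs are sorted by descending score, the running
FDR is decoys/targets, and q-values are the monotone minimum of
downstream FDRs. Unknown precursor charges are retried as 2–4 and
flagged. PeptideProphet-style modelling, open searches and protein
inference are out of scope.

## Stability quantification

XIC extraction sums, per MS1 scan, all peak intensities within ±tolPpm
(default 10 ppm) of the target m/z; scans without a matching peak
contribute zero. Peak integration takes the widest contiguous region
around the apex with intensity above 5% of the apex (the boundary rule
is ours — vendor boundary models are unstated — and is configurable),
extends it by the boundary-crossing point on each side, and applies the
trapezoid rule (intensity &times; seconds). The area is invariant to
time shifts and linear in intensity; all-zero traces integrate to 0 with
an `empty` flag.

Replicate areas are divided by the mean of the control condition, so the
control normalizes to mean 1 exactly. Two conditions are compared with
Student's unpaired two-sided t-test — read literally as equal-variance,
with Welch available via `varEqual = FALSE`; three or more with one-way
ANOVA plus Tukey's HSD adjusted pairwise p-values (all pairs reported,
comparisons against control among them). Significance labels: \*
p ≤ 0.05, \*\* p ≤ 0.01, \*\*\* p ≤ 0.001. Where a pooled-control design
is used (the same spike measured once per batch), the pooling is encoded
in the run list — normalization is to the pooled control mean — rather
than inferred.

## Synthetic data: what it does and does not emulate

`simulateSpectrum` draws the theoretical ions of a peptidoform, keeps
each with probability `ionSamplingFraction`, assigns log-normal
intensities with activation-specific series weights (HCD: y ≥ b, y\*
rivalling y at 3+; CID at 3+: p\* dominant; ETD: c/z&#183; ladders with
strong precursor losses), jitters m/z with Gaussian ppm noise and adds
uniform noise peaks. `simulateQuantDataset` draws replicate areas from a
mean-corrected log-normal at the requested CV and renders them as
Gaussian elution peaks (default grid 0–60 s at 1 s, sigma 3 s).
`writeFixtureFiles` combines a 20-protein synthetic Cys-rich FASTA, 100
planted + 100 noise spectra and a quantification dataset into a bundle
with a ground-truth manifest. Every simulator consumes a single RNG
stream seeded at entry, so subsamples can be recomputed by replaying the
stream, and fixed seeds give byte-identical files.

The simulators do *not* model isotope envelopes, chromatographic MS2
peak shapes, collision-energy dependence, co-isolation or real intensity
structure. Passing tests therefore certify the *computational* pipeline
— mass accuracy, channel logic, ranking, FDR control, calibration — not
performance on real instrument data, where intensity-dependent effects
and co-eluting interference dominate.

## Calibration checks and their problem sizes

The acceptance checks run at sizes chosen to make their statistics
meaningful while staying desk-scale: 50 random peptidoforms for the
fragment-algebra identities; 200 noiseless HCD spectra for localization
recovery; a 20-protein / 100+100-spectrum bundle for search recall and
false-positive control at q ≤ 0.01; 1000 null repetitions for ANOVA
type-I calibration; 200 seeds for spike-loss recovery.

One calibration deserves an honest caveat. With replicate areas at 10%
CV and three replicates per arm, the normalized treated mean is a ratio
of two 3-replicate means, with sampling SD ≈ 0.5·√2·0.10/√3 ≈ 0.041
around the true 0.5. The probability that a single 3-replicate
experiment lands within ±0.05 of the truth is therefore only ≈ 78% —
not ≥95%. The acceptance script reports the observed rate as computed;
a ≥95% within-±0.05 rate at this CV would require roughly three times
as many replicates, and quoting one would misrepresent what a
3-replicate design can resolve.

## Known limitations

* Centroid-only: profile spectra are rejected, never silently centroided.
* Proton adducts only; no average masses or fine isotope structure.
* Semi-tryptic/non-specific digestion and protease mixtures are not
  modelled; LysC+trypsin workflows collapse to the trypsin rule.
* The localization score counts ions; it does not produce site-level
  probabilities.
* Retention-time alignment and match-between-runs are out of scope for
  quantification.
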