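---
title: "Mapping photoaffinity-labeled fragments onto nucleotide-binding motifs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping photoaffinity-labeled fragments onto nucleotide-binding motifs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nbsmapr)
library(dplyr)
```

## The problem

Large ligand-gated channels such as the skeletal-muscle ryanodine receptor
(RyR1, ~5037 residues, ~565 kDa per subunit) are modulated by ATP binding
to sites whose location in the primary sequence is unknown. A classical
way to localise such sites is photoaffinity labeling: a photo-reactive,
biotin-tagged ATP analog is crosslinked into the binding pocket, the
protein is partially digested with trypsin, and the fragments that carry
the biotin tag (detected by streptavidin fluorescence) are identified by
N-terminal Edman sequencing and SDS-PAGE mobility. Intersecting the
labeled fragments' coordinates with glycine-rich nucleotide-binding
consensus motifs (Walker-A `GXGXXG`, partial Walker-B `[R/K]XXXGXXXL`,
GroES-type `Y[G/A/S/T][V/G][K/T/Q/S/N]`) yields candidate ATP-binding
regions and motifs.

`nbsmapr` implements the computational half of that experiment as a tested
pipeline: motif scanning, in-silico digestion, fragment-to-sequence
assignment, the elimination/refinement inference, and the
competition-binding IC50 fit, plus a synthetic-data generator so every
stage is testable without downloads.

## The inference model

Each streptavidin-positive ("labeled") fragment supports the hypothesis
that a binding site lies within its span. Four rules refine that support:

* **R1 (descend).** If a labeled fragment has labeled proteolytic
  products, the candidate region narrows to each deepest labeled
  descendant's span: the label travelled into the product, so residues
  unique to the precursor are not needed to explain it.
* **R2 (subtract).** Spans of unlabeled descendants are subtracted: a
  fragment observed without label cannot carry the site. Because gel-mass
  C-termini are assigned against clustered cleavage sites, an optional
  C-terminal ambiguity window `w` (default 0; ~20 residues is a realistic
  value for tryptic digests) shrinks each subtracted span at its
  C-terminus first.
* **R3 (demote).** A labeled fragment *all* of whose direct products are
  unlabeled is dropped: if the label survives in none of the products, its
  original placement is suspect — it may sit on residues trimmed during
  further digestion. This is an equivocal heuristic (the label may simply
  have been lost), so it is exposed as `demote_on_unlabeled_products` and
  on by default.
* **R4 (merge).** Overlapping surviving regions are merged.

Motif hits from the scanner then survive only if (i) fully contained in a
candidate region, (ii) not overlapping a span excluded by prior evidence
(e.g. alanine-scanning mutagenesis), and (iii) entirely cytoplasmic under
the membrane-topology annotation — a nucleotide site regulating the
channel from the cytosol cannot sit in a transmembrane segment or in the
lumen. Regions left with no surviving motif are reported as
*non-canonical* candidates: the labeling supports binding there but no
known consensus explains it. Every exclusion is logged with the rule that
fired, so `|in-region hits| == |survivors| + |logged exclusions|` holds by
construction.

Two formal caveats, verified by the test suite:

* R1 and R3 are *unsound* for fragments containing several sites (R1 can
  narrow away a precursor-only site; R3 can drop a genuinely labeled
  fragment). The soundness guarantee — every planted site ends up inside a
  candidate region — is therefore stated and tested for single-site
  lineages with demotion off.
* Monotonicity (adding an unlabeled fragment never adds candidate motifs)
  holds for the subtraction/narrowing rules, but not in combination with
  R3: a new unlabeled product can demote its parent, removing the R1
  anchor and widening the root's region. The monotonicity test runs with
  demotion off.

## The worked example

The package ships the published observation tables — the tryptic fragment
table (apparent kDa, Edman reads, label flags, parentage, pinned spans),
the transmembrane/luminal topology, and the mutagenesis exclusion list —
as plain TSVs:

```{r fixtures}
ryr1_fragments()
```

```{r pipeline}
calls <- call_binding_regions(ryr1_standin(), ryr1_fragments(),
                              topology = ryr1_topology(),
                              exclusions = ryr1_exclusions())
calls
```

The result reproduces the published inference: three candidate regions
(427–1302, 2402–2795, 4476–5037), four surviving Walker-A/GroES motifs in
the N-terminal region (699–704, 701–706, 1081–1084, 1195–1200), the
luminal motif 4602–4607 excluded by topology, and the central fragment
demoted through its unlabeled products.

## The synthetic stand-in sequence

The pipeline needs the protein sequence, which the package does not
redistribute. `ryr1_standin()` returns a **synthetic** 5037-residue
sequence, built deterministically by `build_reference_standin()`, that
satisfies every published constraint the pipeline consumes: the six Edman
reads at their published coordinates; lysine junctions (never followed by
proline) at every published fragment boundary; per-fragment average masses
tuned (by swapping background residues from a palette that can never
create a glycine, proline, lysine, arginine, leucine or tyrosine — i.e.
never a cleavage site or a motif anchor) until each published fragment
rounds to its printed integer kDa; the 16 published consensus-motif
instances planted at their spans; and no stray motif hits inside the
cytoplasmic parts of the candidate regions, enforced by a repair loop that
mutates one free anchor position per stray hit and locks it. Everything
else is random background drawn from SwissProt-like residue frequencies.

Results on this sequence validate coordinate arithmetic and inference
logic — they are *not* statements about the real protein. Substituting a
real P11716 FASTA via `read_fasta()` runs the identical analysis on the
true sequence; hit counts outside the pinned coordinates will then differ
from the stand-in's.

## Masses, digestion, assignment

Peptide masses use average (not monoisotopic) residue masses — the
fragments here are 45–176 kDa, where gel-calibrated masses follow the
average-mass scale — shipped as an auditable TSV, with one water added per
peptide and half-up rounding to integer kDa. Digestion uses the standard
Keil trypsin rule (cut after K/R, blocked by following P); the rule table
is pluggable. A complete digest is the generative primitive; limited
proteolysis is represented by admitting any span whose boundaries are
cleavage sites or termini.

Fragment assignment anchors the decoded Edman read (low-confidence
parenthesised calls, `X` and skipped cycles are wildcards — a shaky call
must not veto a position) at cleavage junctions, then ranks admissible
C-termini by relative mass error at a default tolerance of 0.15; observed
apparent-vs-calculated discrepancies reach ~9%, so a 10% tolerance would
be too tight. The assigner returns a ranked list rather than forcing an
answer, and accepts pinned spans (`known_start`/`known_end`) because at
5% gel noise the nearest cleavage site in mass is frequently not the true
one for large fragments — the rank-1 rate measured by simulation is ~86%,
which is exactly why the original analysis disambiguated against
previously characterised digests.

## The competition-binding fit

Specific binding of the probe is quantified as
$(F_{800}/F_{700})_{noATP} - (F_{800}/F_{700})_{ATP}$ and competition
series are normalised by $y = (F - F_0)/F_{max}$. The competition model is
one-site, $y = 1/(1 + (c/\mathrm{IC}_{50})^h)$, fit by unweighted
Levenberg–Marquardt with the Hill slope fixed at 1 by default (normalised
data on $[0,1]$, one site class); a free-slope variant is available. The
starting value is the geometric mean of the non-zero concentrations, so
fits are deterministic. $F_0$ defaults to the minimum-signal lane and the
weighting is unweighted, both overridable, since neither is pinned down by
the assay description.

```{r ic50}
cfg <- sim_config(seed = 42, ic50_mM = 0.6,
                  concentrations = 10^seq(-2, 1, length.out = 8),
                  curve_sigma = 0.05, replicates = 3)
fit <- fit_ic50(simulate_curve(cfg)$curve)
glance(fit)
```

## The generator and what passing tests show

`sim_config()` fixes the study conditions: multiplicative lognormal
gel-mass noise with $\sigma = 0.05$ (observed apparent/calculated
discrepancies are proportional, roughly 3–9%), 10-cycle Edman reads with a
5% per-cycle ambiguity rate, label flags driven by planted-site
containment (a fragment is labeled if it contains *any* site) with an
optional false-negative rate, and competition curves of 8 log-spaced
concentrations (0.01–10 mM for the membrane condition, 0.01–50 mM for the
purified condition) in 3 replicates with additive noise $\sigma = 0.05$.
These values were chosen once to match the experiment the pipeline
emulates and are not revisited per test.

The generator emulates coordinate structure and noise, not biology: no
gel-mobility anomalies (glycosylation, SDS binding), no sequence homology,
no real secondary structure. Passing tests therefore demonstrate that the
machinery is correct under the stated noise model, not that the analysis
of a real gel would be error-free.

Under these conditions, IC50 recovery over 200 seeded replicates stays
within ±0.2 mM of a 0.6 mM truth in >95% of fits, but within ±0.1 mM of a
0.95 mM truth in only ~80%: the fit's relative standard error at these
conditions is ~8%, so a ±10% band is a ~1.25-sigma interval. The second
band is an experiment-level (SEM of three experiments) uncertainty, not a
per-fit one, and the corresponding assertion in the acceptance suite
fails honestly rather than being loosened.

## Numerical choices and problem sizes

Coordinates are 1-based inclusive throughout. `X` residues are illegal in
mass spans unless an explicit fallback mass is supplied, and match nothing
in motif scans unless `permissive_x = TRUE`. Ties in mass error break
toward the larger fragment. Region merging joins overlapping (not merely
adjacent) intervals. The property suites run the scanner against a
brute-force window oracle on 1000 random sequences, digestion invariants
on 1000 sequences, planted-site soundness on 100 seeds, and 500-replicate
assignment simulations — sizes chosen so the whole suite completes in a
few minutes on one core.
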