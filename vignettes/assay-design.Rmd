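---
title: "Designing and validating allele-specific PCR assays for species authentication"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing and validating allele-specific PCR assays for species authentication}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aspcr)
```

## The problem

Market products derived from protected or high-value animals (antler,
hair, dried tissue) often cannot be identified morphologically, and full
DNA-barcode sequencing is slow and instrument-heavy. Allele-specific PCR
(AS-PCR, also called ARMS) replaces sequencing with a single reaction: a
primer whose 3'-terminal base sits on a species-diagnostic SNP extends
efficiently only on templates of the target species, because thermostable
polymerases without 3'→5' proofreading extend poorly from a terminal
mismatch. A positive band therefore *is* the identification.

`aspcr` implements the full computational side of building such an assay
from a species-labelled barcode alignment (typically mitochondrial COI):

1. **Diagnostic-site discovery** — find alignment columns fixed in the
   target species and absent from everything else.
2. **Primer construction** — anchor the diagnostic allele under the 3'
   terminus of the "downstream" (minus-strand) primer and deliberately
   weaken the primer with one more engineered mismatch near the 3' end.
3. **In silico PCR** — predict which templates amplify under a binding
   model that encodes 3'-mismatch extension blocking.
4. **Phylogenetic sanity check** — a neighbor-joining bootstrap tree to
   confirm the target forms a clean clade, i.e. that a fixed difference is
   even plausible.

## The diagnostic-site model

A column is diagnostic for species $t$ when every non-missing record of
$t$ carries one base $b$, no record of any other species carries $b$, and
the column's missing fraction (gaps, `N`, IUPAC ambiguity codes) is within
tolerance. This is the strict *fixed difference* notion; frequency
differentials (e.g. 95% vs 5%) are deliberately out of scope because an
assay anchored on a polymorphic or uncertain base misclassifies.

Three consequences of that reading, all fixed as package policy:

* ambiguity codes and gaps count as **missing, never as a match** — an
  uncertain base cannot anchor an assay; the default
  `max_missing_frac = 0` refuses columns with any missing data;
* gap columns are never diagnostic (the method is SNP-based, indels are a
  different assay class);
* sites are reported in position order with no quality ranking — whether a
  site supports a good primer is a question for the design stage, not the
  scan.

Coordinates are 1-based and inclusive everywhere a user sees them.

## Primer construction rules

For a diagnostic site at position $p$ with target allele $b$, the
downstream (minus-strand) primer is the reverse complement of the
template window $[p, p + L - 1]$, so its 3'-terminal base is the
Watson–Crick complement of $b$ and sits exactly on the SNP
(`template_start = p`). A single additional mismatch is then engineered at
the **antepenultimate** position (offset 3 from the 3' end; configurable
2–5, never 1 — editing the terminus would destroy the diagnostic anchor).

Why the extra mismatch: on the target template the primer then carries
exactly one 3'-proximal mismatch (the engineered one), which Taq
tolerates; on a non-target template it carries two — the engineered one
*plus* the terminal anchor mismatch — which reliably kills extension. The
edit converts a marginal single-mismatch discrimination into a robust
two-vs-one contrast.

When the caller does not dictate the replacement base, the package picks
the base forming the weakest duplex against the facing template base,
using a shipped ranking in which pyrimidine·pyrimidine transversion-type
mismatches (T·C, C·T) rank weakest, then C·C, A·A, T·T, then the
purine-containing pairs, with the stable G·T/T·G wobble last. Against a
template C whose perfect-match partner is G this yields the classic G→T
edit. The ranking is a deliberately simple ordinal stand-in for full
nearest-neighbor mismatch thermodynamics; it is shipped in code
(`MISMATCH_RANK`) so it can be audited and overridden per call.

The companion (forward) primer is conventional. Because real studies
rarely publish their companion-design criteria, the defaults here are
industry-standard and flagged in every report: length 18–25 nt, Tm window
55–65 °C, GC 0.35–0.65, product 100–1000 bp, plus a 3'-end 5-mer
self/cross-complementarity guard against primer dimers. Candidates are
ranked by Tm distance to the allele-specific primer (ties by position).
A full thermodynamic hairpin/dimer scan is out of scope.

Two melting-temperature estimators are provided: nearest-neighbor
thermodynamics (SantaLucia's unified 1998 parameter set, 50 mM Na+,
0.5 µM primer, the default) and the closed-form Wallace 2+4 rule, which
exists mainly because exact hand-checkable values make good tests.

## The in silico PCR model

Amplification is binary. A primer binding site is reported when its total
mismatch count is within `max_total_mismatches` (default 3); it is
*extendable* when the 3'-terminal base matches (unless
`block_on_3prime_mismatch = FALSE`) and at most `max_mismatches_last5`
(default 1) mismatches fall in the 3'-proximal five bases. A template
amplifies when an extendable plus-strand site and an extendable
minus-strand site face each other with a product of 50–2000 bp. Both
strand assignments are scanned, so predictions are invariant under
reverse-complementing a template.

The default `max_mismatches_last5 = 1` is not arbitrary: the engineered
offset-3 edit mismatches *every* template, so the budget of one admits
exactly the target (engineered edit only) and rejects every template that
also mismatches the anchor. Template ambiguity codes match a primer base
only when their set contains it; `N` matches nothing — conservative in
the direction of predicting amplification failure. No efficiency or
partial-extension modelling is attempted; a real gel can of course show
faint off-target bands the binary model cannot.

## Distances, NJ and bootstrap

The tree stage is a self-contained engine: p, Jukes–Cantor and Kimura
2-parameter distances with **pairwise deletion** of gap/ambiguity columns
(complete deletion discards too much signal in small barcode panels),
classic neighbor joining minimizing $Q(i,j) = (n-2)d_{ij} - r_i - r_j$,
and nonparametric bootstrap over columns. K2P is the default model, the
convention for COI barcoding. Numerical choices:

* NJ ties are broken by the lexicographically smallest index pair in the
  current matrix — determinism for testing, and effectively the common
  first-minimum convention;
* negative NJ branch lengths are clamped to zero with the deficit
  reported (raw values kept in an attribute);
* saturation ($1-2P-Q \le 0$ or $1-4p/3 \le 0$) raises an error naming
  the offending pair rather than returning `NaN`;
* a bootstrap replicate whose resampled matrix saturates contributes no
  bipartitions but still counts in the support denominator;
* supports are fractions in $[0,1]$ internally and integer percent in
  Newick output, 1000 replicates and seed 42 by default.

Trees are returned as standard `phylo` objects so the wider R phylo
ecosystem (plotting, re-rooting, comparison) applies directly; `ape` is
used in the test suite as an *independent oracle* (topology cross-checks,
Newick parse-back), never as the implementation.

## What the synthetic generator emulates — and what it does not

`synthetic_spec()` defaults describe the package's reference world,
shaped like a small Cervidae COI study: 8 species, 24 records
(3+3+3+3+3+2+2 across seven species and 5 in the eighth), 574 bp, two
diagnostic columns planted at positions 480 and 505 (target C vs
background T), interspecific divergence 0.08 substitutions/site and
intraspecific noise 0.002. The divergence value sits in the typical
congeneric-mammal COI range (≈8–15% pairwise after the star phylogeny
doubles it); the noise value reflects the <1% intraspecific variation
expected of conspecific barcodes. Generation draws a root sequence,
evolves one consensus per species, copies records with noise, and plants
the diagnostic alleles **after** noise so ground truth is exact by
construction.

The generator is a star phylogeny with uniform substitution: no rate
heterogeneity among sites, no transition/transversion bias, no indels, no
coalescent structure within species. A green test on this world
establishes algorithmic correctness — site discovery, anchoring,
blocking, monophyly — not performance on real data, where recombination
of those simplifications (codon structure, shared ancestral polymorphism,
alignment error) can break the fixed-difference assumption itself.

One subtlety worth knowing: at 8% divergence a 574-column alignment
*necessarily* contains additional genuine fixed differences beyond the two
planted ones. The ground truth against which recovery is scored is
therefore derived from the stored per-species consensus sequences, not
from the planted list alone; with zero noise the two derivations coincide
exactly and both precision and recall are 1 by test assertion, not by
definition.

## Worked example

```{r pipeline}
gen <- generate_alignment(synthetic_spec(seed = 7, intraspecific_noise = 0))
aln <- gen$alignment
sites <- find_diagnostic_sites(aln, "Cervus_nippon")
head(sites)

site <- sites[sites$position == 480, ]
template <- aln$seq[aln$species == "Cervus_nippon"][1]
rev <- design_allele_specific_primer(template, site)
fwd <- design_companion_primer(template, rev)[[1]]
design <- assay_design(fwd, rev, "Cervus_nippon", site)
design

screen <- specificity_screen(design, aln)
attr(screen, "specific")
cat(format_virtual_gel(screen), sep = "\n")

tree <- bootstrap_support(aln, replicates = 200, seed = 7)
is_monophyletic(tree, aln$id[aln$species == "Cervus_nippon"])
```

## Known limitations

* Real-data headline numbers (the published SNP positions and the printed
  primer strings of the motivating assay type) can only be recomputed from
  the corresponding GenBank records; the package never downloads, so its
  tests run entirely on the synthetic stand-in world.
* The binding model is binary and mismatch-counting; it knows nothing of
  annealing temperature, Mg2+, or polymerase identity.
* Companion-primer feasibility depends on the template actually offering a
  window within the Tm/GC constraints; on extreme-GC templates the
  designer correctly returns an empty candidate list (CLI exit code 3)
  rather than relaxing constraints silently.
* Input alignments must arrive aligned; trimming and alignment policy are
  upstream concerns.
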