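---
title: "Harmonizing gut microbial metabolite registries: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Harmonizing gut microbial metabolite registries: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Metabolites produced by the gut microbiota reach the systemic circulation
and form the *gut microbial exposome* — the totality of microbiota-derived
small molecules measurable in host biospecimens. Deciding which blood or
urine metabolites are microbial is hard: bacteria, host tissues and food
share pathways, and many compounds have mixed origins. Two complementary
strategies address this:

1. **Curated experimental evidence.** Literature records of three types
   support a microbial origin: (i) production by human faecal bacteria
   grown in vitro, (ii) reduced concentrations after oral antibiotic
   treatment, (iii) reduced concentrations in germ-free animals relative
   to conventional animals. A metabolite supported by the in vitro type
   *and* at least one in vivo type is expected to be largely or
   exclusively microbial.
2. **Genome-scale metabolic models (GSMMs).** The species lists of gut
   bacterial reconstructions enumerate metabolites the microbiota can
   produce; comparing them with a human reconstruction and with the
   curated set identifies *predicted unique microbial metabolites* —
   candidates no experiment has yet tied to the microbiota.

Both strategies reduce to one technical core: deciding when two metabolite
entries in different registries denote the same chemical entity, then
doing set algebra over the resolved entities. `microexposome` implements
that core, plus the evidence summaries and the Tanimoto similarity
networks used to visualize the chemical space.

## Entity resolution: the identifier cascade

Registries carry heterogeneous identifier coverage. Matching is
hierarchical, in decreasing order of confidence:

InChIKey → ChEBI → PubChem CID → HMDB → BiGG → MetaNetX → fuzzy name.

Each level only sees the *leftovers* of the levels above it: an entry
matched by InChIKey is never re-matched by ChEBI, so one entry appears in
at most one identifier-level match per counterpart registry. Identifier
matches are exact on canonicalized values (uppercase InChIKey,
`CHEBI:`-prefixed ChEBI, bare integer CID, uppercase HMDB) and are always
accepted. A matched pair that *disagrees* in a lower-priority namespace is
still matched — the cascade order encodes which namespace wins — but the
disagreement is logged. The full 27-character InChIKey is the default; a
skeleton mode using only the 14-character connectivity block is available
for reduced-confidence structural matching (it ignores stereochemistry
and protonation).

### Fuzzy name fallback

Entries with no shared identifiers fall through to name matching. Names
are first canonicalized (lower-case, collapsed whitespace, an ordered
rewrite-rule table: stereo-descriptor prefixes such as `cis-` → `z-` and
`trans-` → `e-` anchored at the start of the name; Greek letters spelled
out anywhere; quote and dash variants unified). The rule table is shipped
as data (`inst/extdata/normalization_rules.tsv`) and overridable, because
no published set of such rules is complete; anchoring the stereo rules at
the prefix avoids corrupting interior substrings, while Greek letters are
safe to replace anywhere. Normalization is idempotent by construction and
property-tested. A terminal carboxylate equivalence (`-ate` ↔ `-ic acid`)
is folded in at match time rather than rewriting display names.

The similarity metric is normalized indel similarity (insertions and
deletions cost 1, substitution 2) on token-sorted canonical names, with
default threshold **0.92**. The threshold is deliberately strict: at 0.92
only near-identical names (typographical variants, reordered tokens)
survive, which is what a subsequent manual review can realistically
confirm. Pairs equal after normalization score 1.0 and are auto-accepted;
every other candidate is written to a review file with status `REVIEW` and
is merged only when a review-decisions file accepts it — the package
mirrors a manual-checking step rather than trusting fuzzy scores.
Selection is greedy one-to-one by descending score with lexicographic tie
breaks, so results are reproducible regardless of input order.

### Clusters and set algebra

Accepted matches are closed transitively into entity clusters (connected
components); unmatched entries are singletons; every entry belongs to
exactly one cluster. The two gut reconstructions are pooled into one
`GUT_GSMM` set before the three-set Venn over
{curated, gut-GSMM, human-GSMM}; per-entry provenance is retained for
network colouring. Headline percentages are rounded half away from zero
to integers; exact fractions are kept in the JSON report.

Substrate metabolites — species a model consumes (e.g. from diet) rather
than produces — must not count as predicted microbial products. Clusters
whose gut members are flagged `is_substrate` (or listed explicitly) lose
their gut membership rather than disappearing entirely, so a substrate
that is *also* curated still counts as a curated metabolite. An optional
heuristic flags species occurring only in uptake/exchange reactions of a
supplied SBML model; because most GSMM reactions are bi-directional this
cannot discriminate consumed from produced metabolites systematically,
and the function says so in a warning.

## Evidence summaries

Evidence records are literature-derived and vocabulary-heterogeneous, so
evidence types, organisms and biospecimens pass through alias tables
(plasma/serum → `BLOOD`, caecal content → `GUT_CONTENT`, "germfree" →
`GERMFREE_REDUCTION`, ...). Per-metabolite profiles conserve record
counts exactly; the one/two/three-evidence-types partition is disjoint
and exhaustive over metabolites with at least one record; the
combined-evidence filter is the set expression
F ∩ (A ∪ G) over the three per-type supports. Class summaries count
metabolites, never records, and report unmapped classes in an explicit
`unmapped` bucket so totals always reconcile. Concentration values are
converted to nmol/L (volume-based units) or nmol/g (mass-based; faecal
samples) and summarized as group medians, with the conventional
even-group definition (mean of the two central values); mixing the two
unit bases in one group is an error rather than a silent conversion.

The package ships two transcribed summary tables as fixtures: the
combined-evidence listing (108 metabolites in 17 upper-level classes) and
the per-class metabolite counts (33 classes; 457 metabolites; 257/209/170
per evidence type). The listing does not resolve *which* in vivo evidence
type each metabolite carries, so `catalog_evidence_records()` represents
the in vivo support as a single antibiotic-reduction record — the choice
is immaterial to every quantity computed from the fixture, which only
requires "at least one in vivo type".

## Similarity networks

Chemical similarity uses hashed topological fingerprints computed from
SMILES (parsed with OpenBabel): `PATH_HASH` (all simple linear paths of
up to 7 atoms, Daylight-style; the default) or `CIRCULAR_R2` (iterated
neighbourhood invariants to radius 2, ECFP-style), both hashed into 1024
bits. The Tanimoto coefficient |A∩B|/|A∪B| over set bits thresholds the
network at **0.8** by default. Two fingerprints are comparable only
within one scheme and length, and the scheme is recorded in the exported
graph, so comparisons are always within-scheme. Two empty fingerprints
are defined to have similarity 0 — unparseable or featureless inputs
become isolated nodes, never spurious cliques. Node attributes (source
registry, record count, evidence-type combination, class) travel with the
GraphML export so the usual figure encodings — node size by record count,
colour by evidence or by source model — are reproducible downstream;
rendering itself is out of scope.

## The synthetic-data generator

No public accession carries the registries this pipeline consumes, so the
generator plants a known truth and emits the same file dialects the
pipeline reads:

* **Linked registries** with configurable sizes and pairwise/triple
  overlaps. The defaults mirror the summary cardinalities of the
  curated/predicted comparison: 457 curated, 2325 predicted gut
  metabolites of which 251 overlap the curated set (67 in all three
  sets), 598 shared with the human reconstruction, 1543 gut-only. The
  human-only region is not constrained by those cardinalities; the
  default human registry size (2400) is a round figure of the right order
  for a whole-organism reconstruction and does not affect any gut-centric
  quantity.
* **Identifier dropout** per namespace (defaults 0.3–0.5, deliberately
  uneven: structure keys and model-native ids survive more often than
  HMDB accessions, as in real GSMM extracts), and **name corruption** on
  20% of overlapping entries, produced by *inverting* the normalization
  rules (re-introducing `cis-`, Greek letters, case and whitespace
  noise). Tying corruption to the shipped rule table makes fuzzy-stage
  recall exactly measurable: a corrupted name must normalize back to its
  counterpart.
* **Evidence fixtures** whose per-type record counts equal the requested
  marginals exactly; when bucket sizes (318/99/40) and per-type
  metabolite counts (257/209/170) are also requested, a deterministic
  feasibility solver picks a two-type overlap split and the seeded stream
  decides which metabolite gets which evidence set. That both margins can
  be satisfied simultaneously is a non-trivial consistency property of
  the published tables (318 + 2·99 + 3·40 = 257 + 209 + 170 = 636).
* **SMILES panels** drawn from ~115 parametric scaffolds (alkanes,
  alcohols, acids, amines, diols, thiols, esters, substituted benzenes)
  with controlled duplicates. Scaffold chains stop at 7 atoms so distinct
  scaffolds yield distinct path fingerprints.

Every generator takes a mandatory seed and runs a single seeded stream;
identical configurations are byte-identical on disk. What the generator
does *not* emulate: realistic metabolite name distributions, realistic
chemistry (fingerprint similarity structure beyond the scaffold families),
correlated identifier missingness, or curation noise such as wrong
identifiers. Passing tests therefore demonstrate correctness of the
resolution and set algebra under controlled corruption, not performance
on real registry idiosyncrasies — on real data the fuzzy stage's review
file is the safety net.

## Numerical and degenerate-input choices

* Median of an even-sized group: arithmetic mean of the two central
  values.
* Percentages: rounded half away from zero for headlines; exact fractions
  retained in reports.
* Merge-group identifier conflicts: the value kept comes from the member
  with the highest-priority identifier evidence, then input order; all
  conflicts logged.
* Fuzzy ties: lexicographic on the two names, after descending score.
* Empty inputs: header-only registries, zero-species models and empty
  evidence files all produce empty results, not errors; a profile with
  zero evidence types, by contrast, is a validation error because the
  evidence partition would no longer be exhaustive.
* Unparseable SMILES: warning plus isolated node, never a crash.

## Problem sizes used in the shipped checks

The test suite exercises the matching and set-algebra oracles on designs
of 150–500 entries (brute-force all-pairs checks stay cheap there), runs
the cascade precision/recall property over 20 seeded designs with dropout
0/0.3/0.6 and 20% name corruption, checks the network against an O(n²)
oracle on 100-molecule panels, and runs one full end-to-end pipeline at
the default study-scale configuration (about 5,200 registry entries and
1,848 evidence records), which completes in well under two minutes on a
single CPU.

## Known limitations

* The exact published registry totals (2325 predicted, 1543 unique)
  depend on specific model releases and a private curation export;
  the package reproduces the *derived* quantities from printed
  cardinalities and the *procedures* on synthetic data, not those sets
  themselves.
* The complete normalization rule set used in the original curation is
  unpublished; the shipped table covers the documented rules plus
  conservative extensions and is overridable.
* Fuzzy matching below score 1.0 is never auto-accepted; recall on real
  data therefore depends on the reviewer completing the review file.
* The substrate heuristic is advisory only (reaction bi-directionality).
* Fingerprints are topological; stereochemistry and charge states do not
  influence network edges.
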