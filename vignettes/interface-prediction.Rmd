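---
title: "Knowledge-based interface-residue prediction: model, parameters, and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Knowledge-based interface-residue prediction: model, parameters, and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`ppisite` predicts protein–protein interaction (PPI) interface residues by
nearest-neighbor retrieval over a knowledge base of encoded structural
neighborhoods. This vignette is the package's own account of the model: what
is computed, which knobs matter, what the synthetic data generator does and
does not emulate, and where genuinely open design choices were resolved.

```{r setup}
library(ppisite)
```

## The model

A protein complex is reduced to a **labeled residue graph**: one node per
amino acid, an undirected edge whenever two Cα atoms are at most 6 Å apart.
The comparison is inclusive (`<=`, no epsilon) — a pair at exactly 6.000 Å is
an edge. Edges may cross chain boundaries within a complex, because contacts
across an interface are precisely what carries the signal
(`edges_across_chains = FALSE` disables this).

Each node carries up to two features:

* **Amino-acid type**, encoded as the 1-based alphabet position of the
  one-letter code ('A' → 1, 'C' → 3, …, 'Y' → 25). Common nonstandard
  residues are first mapped to a standard letter (MSE → M, SEC → C, …);
  unmappable residues are dropped from the graph with a warning.
* **RASA**, the residue's solvent-accessible surface area divided by its
  type's reference maximum (a unitless fraction, occasionally slightly
  above 1), binned into 10 equal-frequency bins whose 9 interior edges are
  the empirical deciles of the knowledge base's pooled RASA distribution.
  Bins are left-closed/right-open; a value equal to an edge falls in the
  higher bin; values above the last edge map to bin 9. The edges are stored
  in the knowledge-base header so queries are always binned exactly as the
  records were.

**Ground truth.** A residue is an interface residue iff the van der Waals
surface of at least one of its atoms is at most 0.5 Å from the vdW surface
of any atom of a *different* chain: `dist(a, b) − r(a) − r(b) <= 0.5`.
Labels are computed against the union of all other chains, not per chain
pair. A spatial grid with cell size equal to the largest possible contact
distance keeps labeling subquadratic; the test suite holds it equal to the
all-pairs reference on every fixture.

**Structural elements.** For each residue we extract a neighborhood
subgraph, either

* `d_i` — all nodes within `i` graph hops of the center (connected by
  construction), or
* `c_k` — the center plus its `k` nearest residues by Euclidean Cα distance
  over the whole structure, across chains (possibly disconnected).

`d_0` and `c_0` are the bare center. Ties for the k-th nearest slot are
broken by node index, deterministically: a tie-break rule is required
because the element — and hence its fingerprint — changes with the choice.

**Fingerprints.** An element is encoded in the style of atom-pair molecular
fingerprints: for every unordered pair of distinct members (the center is an
ordinary member), the feature codes of residue A, the pair's graph distance
`d`, and the codes of residue B are concatenated as fixed-width binary
fields (amino-acid type 5 bits, RASA bin 4 bits, distance 5 bits) into an
integer `i`, and bit `i mod l` of an `l`-bit array is set. Notes:

* Graph distance is measured **within the element's induced subgraph**, not
  the parent graph: the element is the stored pattern and must be
  self-contained for hashing. Pairs in different components of a
  disconnected `c_k` element — undefined in principle — are clamped to the
  sentinel `D_max = 2^5 − 1 = 31`, which keeps the encoding total and
  bounded.
* The raw concatenation g^A‖d‖g^B is asymmetric and nothing distinguishes
  which residue "is" A, so the pair is canonicalized first: the
  lexicographically smaller code tuple plays the role of A. Without this,
  identical neighborhoods could hash differently depending on iteration
  order.
* The hash is literally `i mod l`, with no secondary mixing. Lengths 63,
  255 and 1023 are the standard presets; `l` is otherwise free.
* Collisions are tolerated by design: two non-isomorphic elements may share
  a fingerprint, and no de-duplication or isomorphism post-filtering is
  attempted (retrieval quality does not warrant the cost, and the encoding
  is already lossy).

**Retrieval and scoring.** Fingerprints are compared by **bit difference**
(Hamming distance; smaller = more similar). A query against the knowledge
base proceeds: prefilter to records whose central-residue features equal the
query's (the K_A set); optionally remove the query structure's own records
(leave-query-protein-out); rank by bit difference and keep everything at or
below the n-th smallest distance — **ties with the n-th distance are all
kept**, so the result set S can exceed n. The interface probability is
|I|/|S|, the fraction of retrieved records whose central residue is
interface-labeled, and the call is `probability > threshold`, strictly.

## Parameters

| parameter | default | units | notes |
|---|---|---|---|
| `cutoff` | 6.0 | Å | Cα–Cα graph edge threshold, inclusive |
| `interface_tolerance` | 0.5 | Å | vdW surface gap for ground-truth labels |
| `min_chain_len` | 5 | residues | chains shorter than this are dropped for KB use; complexes with < 2 remaining chains are rejected (query-side prediction applies neither rule) |
| `probe_radius` | 1.4 | Å | water probe for SASA |
| `n_points` | 960 | — | Shrake–Rupley sphere quadrature per atom |
| `rasa_context` | chain | — | RASA computed on the isolated chain (see below) |
| neighborhood | `c_12` | — | element type and size |
| `l` | 1023 | bits | fingerprint length |
| features | `aa_type` | — | both pair encoding and central prefilter |
| `n` | 1 | elements | most-similar elements retrieved (tie-inclusive) |
| `threshold` | 0.5175 | — | decision threshold on \|I\|/\|S\| |

`ppi_params(preset = "published")` bundles the benchmark-comparison
configuration (c₁₂, 1023 bits, amino-acid type only, n = 1, τ = 0.5175);
with n = 1 and no ties the probability is 0 or 1 and the threshold only
matters for tie-split fractions, which is why the strict comparison is
innocuous and documented rather than consequential.

**RASA context.** Whether RASA should be computed on the isolated chain or
in the complex is genuinely open. The default is the isolated chain: in the
complex, interface residues are partially buried by their partner chain, so
complex-context RASA would leak the very label being predicted into a
feature. `rasa_context = "complex"` remains available for completeness.

**SASA normalization.** The exact SASA algorithm, probe radius, radii set
and normalization constants behind any particular published RASA table are
rarely stated; exact numeric reproduction of third-party RASA values is not
attempted. All four ingredients are explicit configuration here: a bundled
Bondi-style element → vdW radius table and a Tien-style theoretical
maximal-ASA table (both TSVs under `inst/extdata/`, both overridable per
call). Interface labels depend on the radii, which is why the table is
shipped and documented rather than hard-coded.

## Numerical choices

* **SASA quadrature.** Shrake–Rupley with a deterministic golden-spiral
  point set. Translation invariance is exact; rotation invariance holds only
  to the angular resolution of the quadrature (~1e-3 relative at 960
  points), which the tests assert at 1e-2. Residues with no reference ASA
  are skipped (`NA` RASA) or normalized by the table mean
  (`missing_ref = "fallback"`).
* **Degenerate RASA distributions.** Decile edges require at least 10
  distinct values with strictly increasing deciles; anything else is an
  explicit degenerate-distribution error rather than silent ties.
* **MCC conventions.** Any zero factor under the radical yields MCC = 0
  (the random-prediction value). Secondary metrics report 0 for 0/0 ratios
  and flag the affected names in an `"undefined"` attribute.
* **Nothing retrievable.** If the prefilter key group is empty (an unseen
  central feature value) the whole base is scanned with a warning — leaving
  residues unpredicted would be worse. If exclusion then empties the result,
  the probability is undefined: the residue is reported with `NA`
  probability, a non-interface call, and `defined = FALSE`.
* **Alternate locations** keep the highest-occupancy altloc (first on
  ties); residues are identified by (chain, author seqnum, insertion code);
  only the first model of multi-model files is read. Residues without a Cα
  cannot anchor an element and are excluded from the graph (they still count
  for chain-length filtering).
* **Aggregation.** Dataset-level metrics pool confusion counts over all
  residues; `per_protein = TRUE` additionally reports per-structure rows,
  since published evaluations are ambiguous about which convention they
  use.

## The knowledge-base file

`save_kb()`/`load_kb()` use a little-endian, versioned binary layout: magic
`FPKB`, version, fingerprint length, bit-widths, element spec, feature
configurations and bin edges in the header, then a structure-id table and
packed fixed-length records. The header makes the file self-describing:
loading refuses wrong magic or version, truncation is detected, and a query
with a mismatched fingerprint length is rejected instead of silently
comparing incompatible encodings. Two builds from the same input are
byte-identical, which the tests assert.

## Synthetic data: what it does and does not show

`make_complex()` builds schematic two-chain complexes: straight CA-only
traces with 3.8 Å consecutive spacing, chain B offset to chain A's residue
midpoints. Residues in a chosen contact window sit at a center distance
realising a vdW surface gap of ~0.3 Å (inside the 0.5 Å rule), all other
cross-chain pairs keep a gap ≥ 2 Å (a ≥ 1.5 Å margin on the other side), so
the ground-truth labels are known analytically — and are computed inside the
generator by a plain all-pairs distance loop, independently of the
grid-accelerated labeling they are tested against. `make_kb_corpus()`
additionally plants a shared sequence motif around the contact window, so
identical structural elements — and therefore distance-0 fingerprint
matches — exist across structures by construction.

This supports exactly the properties the validation needs: oracle
equivalence of neighborhoods and labeling, fingerprint determinism,
tie-inclusive retrieval, byte-stable serialization, and end-to-end
self-consistency (with self-exclusion disabled and n = 1, every residue
retrieves itself at distance 0 and inherits its own label, so pooled MCC is
exactly 1 when fingerprints are unique per key group). What it does **not**
emulate: real backbone conformations, side chains, sequence statistics,
realistic RASA distributions, or the size and redundancy structure of a
real knowledge base. Passing tests therefore demonstrate correctness of the
machinery, not benchmark-level predictive performance on real proteins —
reproducing published benchmark numbers would require a PDB-scale knowledge
base and the external evaluation datasets, which is out of scope here.

Validation problem sizes: 10-complex corpora of 16+16-residue chains
(320 residues) for end-to-end checks; 100 random geometric graphs of up to
50 nodes for neighborhood oracles; 20 fixture complexes for labeling
equivalence; 1000 random fingerprint triples for the metric axioms. These
sizes exercise every code path while keeping the whole suite fast enough to
run on every change.

## Known limitations

* Interface labels depend on the vdW radius table; a different radii set
  shifts marginal contacts. The table is explicit configuration for this
  reason.
* Whether the c_k neighborhood may cross chain boundaries is assumed yes
  (consistent with the physics of interfaces); a per-chain variant would
  need only a filter but is not offered.
* Exclusion during evaluation is by structure id; chains shared between a
  query dataset and knowledge-base entries under different ids are not
  detected automatically (`exclude_structure` accepts arbitrary id sets for
  manual control).
* Conditional-random-field smoothing of the per-residue calls and
  isomorphism-based post-filtering of retrieved matches are deliberately
  not implemented; both add complexity for marginal or unmeasurable gain.
* Biological-assembly reconstruction, symmetry mates and NMR multi-model
  handling beyond the first model are out of scope, as are sequence-derived
  features (conservation, PSSMs).
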