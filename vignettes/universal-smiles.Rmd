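---
title: "Canonical SMILES from InChI canonical labels: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Canonical SMILES from InChI canonical labels: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(unismiles)
```

## The procedure

A canonical SMILES needs a canonical atom numbering.  Rather than invent
one, this package reuses the numbering computed by the InChI algorithm,
which has a single reference implementation and is available in every
major toolkit.  Two pipelines are provided.

**Universal SMILES.**  A non-standard InChI is generated for the input
structure with the `FixedH` and `RecMet` options, and the correspondence
between input atoms and canonical labels is parsed from the auxiliary
information that accompanies it.  The original structure — bond orders,
charges, tautomeric state — is then written as SMILES under those labels.
`FixedH` matters whenever molecular symmetry is broken only by a
protonation state: without it, the two drawings
`C(=O)([O-])C(=O)O` and `C(=O)(O)C(=O)[O-]` of hydrogen oxalate receive
interchanged labels and produce different strings; with it, a
fixed-hydrogen label list (`/F:`) is added and both drawings yield
`C(=O)(C(=O)[O-])O`.  `RecMet` plays the analogous role when the Standard
InChI disconnects metal-ligand bonds.  Labels are extracted by the
preference `/R:/F:` > `/R:/N:` > `/F:` > `/N:`.  The composition of the
two orderings (reconnected over initial, fixed-H over base) follows from
their purposes; no worked example with simultaneous metal reconnection and
mobile hydrogens is available upstream, so the composed preference is a
design choice of this package.

**Inchified SMILES.**  The Standard InChI of the input is converted back
to a structure by the InChI library.  Several input structures map to one
InChI; the reconstruction is therefore normalised — ion-pair nitro groups
become `N(=O)=O`, sulfoxides `S=O`, supported tautomers collapse to one
form (amides, for instance, come back as imidic acids), metals are
disconnected — and its atoms arrive in canonical order, so the writer can
use the identity labelling.  When no normalisation applies, Universal and
Inchified SMILES are identical.

## The writer

Given labels, the writer traverses each connected component depth-first
and emits OpenSMILES standard form:

* components are visited in order of their lowest label, starting at the
  lowest-labelled atom;
* if the start atom would be a negatively charged oxygen whose neighbour
  also carries a doubly bonded oxygen, the lowest-labelled such carbonyl
  oxygen is used instead.  The InChI ignores bond orders and charge
  positions when numbering, so `-O^-^` and `=O` on one atom can swap labels
  between drawings; inside the traversal the multiple-bond preference
  absorbs this, but the start atom needs the explicit escape.  Among
  several equivalent carbonyl oxygens any choice would give the same
  string; the lowest label is fixed for determinism;
* at branch points, multiple bonds are taken first (triple before double —
  the tie is not fixed by the rule set and is resolved here toward earlier
  emission of higher bond orders), then explicit hydrogens that carry no
  InChI label (deuterium, then tritium, then others), then ascending
  label.  Unlabelled hydrogens are handled by giving them ordering keys
  below every real label, so the ordinary comparison implements the
  hydrogen rule; plain (non-isotopic, non-stereo) explicit hydrogens are
  folded into the parent's implicit count before writing;
* every explicit substituent of a double bond with defined cis/trans
  configuration is preceded by `/` or `\`.  Substituent bonds shared
  between conjugated double bonds couple the constraints, so direction
  values are solved as a 2-colouring over each conjugated system, with the
  one free bit per system fixed by the rule that the earliest-written
  symbol is `/`.  At a ring closure the symbol is written only with the
  digit on the double-bond atom; when both closure ends belong to
  configured double bonds each end gets its (mirrored) symbol — the rule
  set is silent here and the package extends the digit-placement rule by
  analogy;
* ring-closure digits take the lowest value not currently open and are
  freed once closed; on an atom with several digits, openings are listed
  first (ordered by the label of the distal atom), then closings (in
  opening order).  A digit freed at an atom is not reopened on that same
  atom, so a symbol never appears twice on one atom;
* tetrahedral centres are written `@`/`@@` per OpenSMILES winding relative
  to the written neighbour order (ring-closure neighbours count at their
  digit's position), with a stereocentre hydrogen inside the brackets
  (`[C@H]`), never as a branch.

## Aromaticity

OpenSMILES standard form writes aromatic systems in lowercase but does not
yet define which rings are aromatic, so any choice of model makes the
output depend on that model.  This package commits to one documented
model, applied identically when reading and writing, which keeps the
canonicality guarantee intact: a simple ring of size 3–7 is aromatic when
every ring atom is sp2-compatible and the ring satisfies the Hückel 4n+2
count (a double bond within the ring system contributes one electron; an
exocyclic double bond to a non-ring atom contributes zero at a carbon;
N/P/O/S without a double bond contribute a lone pair; charged carbons
contribute two or zero electrons).  Fused systems are evaluated
ring-by-ring.  Divergence from other toolkits' models is expected and
affects which of several equivalent strings is produced, never whether the
string is canonical.  Aromatic input is kekulised on reading (a
backtracking perfect matching over the flagged bonds; failure raises a
kekulisation error), and a valid Kekulé assignment is retained internally —
it is also what the InChI backend receives, making the backend independent
of the aromatic model.

## The backend

The InChI algorithm itself is never reimplemented: structures are handed
to Open Babel's `obabel` as Kekulé input-order SMILES and the InChI plus
auxiliary information are read back; InChI-to-structure conversion also
goes through `obabel`.  Atom-order bookkeeping is explicit on both sides
(the writer reports its token order; the reconstruction is permuted into
canonical order using the `/N:` labels of a regenerated Standard InChI).
Calls are batched — many records per invocation — and memoised within the
session, which keeps the fixture-scale test suites to a handful of
subprocess launches.  Backend warnings (proton rearrangement, undefined
stereo from degenerate geometry) are attached to each result rather than
swallowed.

One backend artefact is corrected after reconstruction: Open Babel's
SMILES writer suppresses double-bond stereo in rings of size 8 or less,
which silently discards a true trans-cyclooctene.  Because the
reconstructed atoms are in canonical order, the missing descriptors can be
recovered directly from the InChI `/b` layer; the parity convention
(references are the highest-canonically-numbered heavy neighbours; `+`
means opposite sides) was established against the reference implementation
over chain, ring, and trisubstituted alkenes, and the package restores any
`/b` entry absent from the reconstruction.

## Validation machinery and the synthetic fixtures

`shuffle_test()` regenerates each structure from `n_reps = 10` seeded
anti-canonical orderings (atoms permuted, then written under uniformly
random labels — the anti-canonical distribution is this package's choice,
as the original mechanism is unspecified) and passes a record only if all
repetitions yield one identical string.  `duplicate_test()` groups records
by byte-identical keys; no chemical fuzzy matching.  `exhaustive_shuffle()`
strengthens the sampled test for small molecules by enumerating *every*
atom ordering, deduplicating orderings that serialise identically and
labellings that coincide before writing.

`make_fixtures()` generates the ~260-structure set the tests and the
acceptance script run on.  It emulates, at desk scale, the variety of a
curated structure database: the worked examples above, cis/trans and
tetrahedral stereochemistry in chains and rings (including
trans-cyclooctene), conjugated polyenes, isotopes, hydrogen-only species,
multi-component salts, fused/spiro/bridged ring systems that exercise
ring-closure digit reuse, symmetric acids and anions that exercise the
start-atom escape, aromatic and heteroaromatic rings, a sample of
drug-like molecules, and seeded scrambled-order duplicates.  What it does
*not* emulate: database-scale frequency distributions, 2D depiction
artefacts of deposited structures (near-linear bond angles that make the
InChI drop a stereocentre), kekulisation defects of third-party files, and
element coverage beyond typical organic chemistry — so a 100% pass rate
here bounds method correctness at fixture scale, not toolkit robustness on
a million deposited records.

Two known non-canonical classes are tagged `expected_fail` and excluded
from pass-rate denominators, with tripwire tests asserting that they *do*
fail (a fix must consciously retire the tag): structures whose graph
symmetry is broken only by a delocalised charge (the InChI numbers atoms
ignoring bond orders and charges, so the charged and uncharged positions
receive interchangeable labels — the N-methylimidazolium fixture produces
exactly two strings), and structures whose symmetry is broken only by a
hydrogen isotope (the isotopic relabelling section of the auxiliary
information is parsed but not consumed, pending an upstream fix in its
emission).

## Numerical and procedural choices

* Randomness: every permutation and anti-canonical labelling derives from
  an explicit integer seed through R's default generator, restored after
  use; record `i` of a batch uses `seed + i`.
* Problem sizes: the shuffle suites run 10 repetitions per structure over
  the full fixture set in both modes; exhaustive enumeration covers
  fixtures with at most 7 heavy atoms (at most 8 atoms including explicit
  hydrogens, about 95,000 orderings in total) in the test suite, and the
  ≤6-atom subset (about 13,000 orderings) in the acceptance script.
* Degenerate inputs: the empty string round-trips to an empty graph;
  single atoms are trivially canonical and bypass label extraction (a bare
  proton's auxiliary information carries no `/N:` layer at all); explicit
  hydrogens bridging two heavy atoms without an InChI label are an error
  by construction.
* Mol-file stereo perception is deliberately local (wedges at the narrow
  end only, geometry-based cis/trans only outside rings of size ≤ 7 and
  only for ends distinguishable at depth one); whether a centre is
  canonically stereogenic is the InChI's decision downstream.
* Stereochemistry beyond tetrahedral centres and double bonds (axial
  allene, square-planar, octahedral) is dropped with a warning on input.

## Known limitations

* The two expected-fail classes above are inherent to the label source,
  not the writer; they remain non-canonical by design until the upstream
  isotopic section is usable and a charge-aware numbering option exists.
* Chromate-like drawings that put the charge on a doubly bonded oxygen of
  a symmetric oxo cluster fall outside the start-atom escape and stay
  non-canonical; they are drawing errors upstream.
* The aromatic model is intentionally simple (simple rings to size 7); it
  will disagree with other toolkits on exotic fused systems, changing the
  spelling, not the canonicality, of the output.
* Canonicality is conditional on the InChI: a structure the InChI cannot
  represent, or fails on, produces an error record rather than a SMILES.
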