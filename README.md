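# unismiles

Canonical SMILES strings built on the InChI canonicalisation.

## The problem

SMILES is the most widely used line notation for chemical structures, but
there is no community standard for generating a *canonical* SMILES: every
toolkit orders atoms with its own unpublished algorithm, so the "canonical"
string for one molecule differs between programs and cannot serve as a
portable database key.  The InChI, by contrast, has a single reference
implementation, and its auxiliary output exposes a canonical numbering of
the atoms.

`unismiles` turns that numbering into canonical SMILES in two flavours:

* **Universal SMILES** — keep the original structure (bond orders, charges,
  tautomeric state) and order the atoms by the canonical labels parsed from
  the auxiliary information of a *non-standard* InChI generated with the
  `FixedH` and `RecMet` options.  `FixedH` adds a fixed-hydrogen label
  section (`/F:`) so that atoms equivalent up to protonation keep distinct
  labels; `RecMet` adds a reconnected-metal section (`/R:`) so metal-ligand
  bonds do not scramble the numbering.  Labels are taken by the preference
  `/R:/F:` > `/R:/N:` > `/F:` > `/N:`.
* **Inchified SMILES** — round-trip the structure through the *Standard*
  InChI: the InChI string is converted back to a structure, which arrives
  normalised (nitro and sulfoxide ion pairs expanded, supported tautomers
  collapsed, metals disconnected) and in canonical atom order, and is then
  written out.  There is a one-to-one relationship between a Standard InChI
  and its Inchified SMILES.

Given the canonical labels, the writer performs a depth-first traversal
with fixed rules: start each component at its lowest-labelled atom (with a
carbonyl-oxygen escape for negatively charged oxygens, whose labels the
InChI cannot keep apart from the doubly bonded oxygen); prefer multiple
bonds, then unlabelled explicit hydrogens (deuterium before tritium), then
lower labels at branch points; OpenSMILES standard form for atoms; all
explicit substituents of configured double bonds carry `/` or `\` with the
earliest symbol of each conjugated system a `/`, and at ring closures the
symbol sits only on the digit attached to the double-bond atom; closure
digits take the lowest available value and are reused, openings before
closings on a shared atom.  The InChI itself is computed by Open Babel's
`obabel` program (the adapter never reimplements it).

The package also implements the two validation procedures used to
characterise such canonicalisers: the **shuffle test** (regenerate from ten
seeded "anti-canonical" atom orderings; a molecule passes when all ten
strings are identical) and the **duplicate test** (group records by
byte-identical keys), plus a deterministic ~260-structure fixture generator
that stands in for a structure database at desk scale.

## Worked example

```r
library(unismiles)

smi <- c("OCC", "C(=O)(O)C(=O)[O-]", "c1cc(/C=C/F)cc(c1)[N+](=O)[O-]")
universal_smiles(smi)
#> [1] "CCO"  "C(=O)(C(=O)[O-])O"  "c1cc(/C=C/F)cc(c1)[N+](=O)[O-]"
inchified_smiles(smi)
#> [1] "CCO"  "C(=O)(C(=O)O)[O-]"  "c1cc(/C=C/F)cc(c1)N(=O)=O"
```

Ethanol entered as `OCC` becomes `CCO`: its non-standard InChI auxiliary
information is `AuxInfo=1/0/N:3,2,1/...`, i.e. canonical labels 1,2,3
belong to input atoms 3,2,1, so the traversal starts at the terminal
carbon.  For hydrogen oxalate the `FixedH` labels make every drawing of the
anion produce one Universal string (the third-row nitro compound shows the
normalisation split: Universal keeps the charge-separated nitro group while
Inchified inherits the InChI's `N(=O)=O` form; the Inchified oxalate
differs from the Universal string because proton removal is also a
Standard-InChI normalisation).

```r
shuffle_test("CC(=O)Oc1ccccc1C(=O)O", n_reps = 10, base_seed = 1)
#> <shuffle_report> CC(=O)Oc1ccccc1C(=O)O [universal]: PASS (1 distinct over 10 reps)
```

A command-line front end is installed with the package:

```sh
$(Rscript -e 'cat(system.file("scripts", "unismiles", package = "unismiles"))') \
    gen --mode universal --in molecules.smi --out out.smi
```

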