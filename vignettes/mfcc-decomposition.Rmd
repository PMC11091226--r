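---
title: "Per-residue interaction energies by fragmentation with conjugated caps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Per-residue interaction energies by fragmentation with conjugated caps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mfccie)
```

## The model

A protein–ligand binding energy can be decomposed residue by residue when the
protein is fragmented at its peptide bonds. For residue $R^i$ with its
covalently bonded neighbours $C^{i-1}$ and $C^{i+1}$ retained as *caps* (so
the excised fragment sees nearly the same covalent environment as in the
chain), the interaction energy with the binder $BID$ is

$$IE(BID/R^i) = E(BID + C^{i-1}R^iC^{i+1}) - E(C^{i-1}R^iC^{i+1})
              - E(BID + C^{i-1}C^{i+1}) + E(C^{i-1}C^{i+1}).$$

The first difference contains the binder's interaction with the capped
tripeptide; the caps-only terms subtract the binder–cap interaction that the
first difference overcounts, and the final caps-only energy restores what was
subtracted twice. Negative $IE$ means attraction, positive repulsion. The
cumulative binding energy of a pocket of radius $r$ is the sum of $IE$ over
the residues within $r$ of the ligand; scanning $r$ on the half-Angstrom grid
($r = R/2$, $R = 1, 2, \dots$) and demanding that successive cumulative
energies differ by no more than 10% locates the radius beyond which more
distant residues no longer matter.

Three assumptions are built in. First, each residue's contribution is
defined by exactly this four-fragment combination — entropy, strain and
desolvation cycles are out of scope; the quantity is an interaction-energy
decomposition, not a free energy. Second, fragments are closed-shell
(multiplicity 1) with integer net charges given by the residues' formal
charges plus the ligand's. Third, the crystal (or otherwise prepared)
geometry is used as-is: the package performs no protonation prediction,
side-chain rebuilding or minimization, which belong to upstream preparation
tools.

## Fragmentation choices

**Cut site.** Chains are cut at the amide C(=O)–N peptide bond rather than
at C$\alpha$–C. This keeps each residue's backbone amide with its own
fragment and matches the reading of the caps as the groups bonded to the
amine and carboxyl ends of $R^i$.

**Link hydrogens.** Every cut bond is saturated by one hydrogen placed on
the fragment-side atom, *along the original bond vector*, at 1.09 Å from
carbon or 1.01 Å from nitrogen (standard bond lengths). An interior capped
tripeptide therefore carries 2 link hydrogens (its two outer cuts) and the
corresponding caps-only fragment 4 (outer cuts plus the two bonds to the
removed central residue). No original atom ever moves; cap and ligand
coordinates are bitwise-identical across the four fragments of a quartet.

**Termini and gaps.** A missing neighbour — chain terminus, or a crystal gap
detected as a C–N distance above 1.8 Å — simply omits that cap, and the
native terminal group is retained. Disulfide-bonded cysteines (S–S within
2.5 Å) are refused with a "cannot cap" error rather than silently cut;
supporting S–S link atoms is future work.

## The energy-evaluator contract

`decompose()` takes any function mapping a fragment to an energy in
kcal/mol. Two backends are provided.

**Classical backend.** A strictly pairwise-additive sum over unordered atom
pairs of screened Coulomb $332.0636\,q_iq_j/(\varepsilon r_{ij})$ plus
Lennard-Jones $4e_{ij}[(s_{ij}/r_{ij})^{12}-(s_{ij}/r_{ij})^6]$ with
Lorentz–Berthelot combining. Its purpose is *verification*, not physical
fidelity: because the energy is exactly additive, the MFCC combination can
be checked against the directly computed ligand↔residue cross energy. With
*ghost* link atoms (zero charge and well depth, the default) the cap terms
cancel algebraically and

$$IE(BID/R^i) \equiv E_{cross}(BID, R^i)$$

to floating-point accuracy — the package's central oracle test, run over 100
seeded random toy complexes. With *parameterized* link atoms the discrepancy
equals exactly the ligand↔inner-link-hydrogen cross energy, which the test
suite asserts in closed form. Note that individual fragment energies under
this backend are dominated by huge intramolecular bonded-pair terms
(Lennard-Jones at bonded distances); these are physically meaningless but
cancel identically in the four-term combination, which is the only quantity
interpreted.

**Quantum interface.** For production runs the package writes deterministic
Gaussian-style input decks — route line with method and basis (defaults
B97D, 6-311+G(d,p)), a conductor-like continuum (CPCM) parameterized only by
its dielectric constant, charge/multiplicity line, and Å coordinates at six
decimals — and parses plain-text outputs for the last
`SCF Done: E(...) = <hartree>` (or generic `FINAL ENERGY = <hartree>`) line,
converting by 627.509474 kcal/mol per hartree. A missing normal-termination
marker flags the result unconverged and the residue is reported as failed
without aborting the run, since production quantum jobs fail routinely.
Fragments are deduplicated by a content hash over role, charge,
multiplicity and geometry, and an energy cache guarantees identical content
is never evaluated twice.

The dielectric enters only through the Coulomb screening (classical) or the
continuum model (quantum). The two conventional settings are
$\varepsilon = 10$ and $\varepsilon = 40$ (the latter mimicking a
crystal-like environment); in the classical backend the Coulomb component
scales exactly as $1/\varepsilon$, so the ratio between the two settings is
exactly 4 and cumulative magnitudes at $\varepsilon = 10$ dominate those at
$\varepsilon = 40$ for Coulomb-dominated systems — a cheap sanity check that
both runs are consistent.

## Pocket selection and the radius scan

The pocket metric is the **minimum heavy-atom–to–heavy-atom distance**
between a residue and the ligand. A minimum-distance criterion is standard
pocket practice, and excluding hydrogens makes the selection robust to
hydrogen placement, which crystal structures rarely resolve; both choices
are exposed (`heavy_only`). Published residue counts at a given radius are
sensitive at the level of a couple of residues to this convention (centroid
vs minimum distance, hydrogens in or out), which is why the convention is
explicit and configurable.

The scan decomposes once at `r_max` (default 10 Å, chosen generously beyond
typical convergence so all relevant residues are evaluated) and then only
re-partitions membership by the stored distances — nothing is recomputed per
radius. Convergence is declared at the smallest radius $r_k$ ($k \ge 2$)
with

$$\frac{|E(r_k) - E(r_{k-1})|}{\max(|E(r_k)|, 10^{-6})} \le 0.10$$

*and* the criterion holding at every subsequent computed radius. Two details
here are genuine design choices, since "changed by no more than 10%" does
not pin them down: the denominator is the current cumulative energy (with a
$10^{-6}$ kcal/mol floor guarding empty or cancelling pockets), and the
hold-thereafter requirement prevents declaring convergence inside a plateau
that a later shell breaks. Both the threshold and the grid step are
configurable; an all-zero series yields no convergence radius, with a
warning.

Ranking sorts ascending by $IE$ (strongest attraction first) with ties
broken by chain, residue number and insertion code — deterministic output
for identical input. Residues with $|IE| < 10^{-6}$ kcal/mol are classed
neutral; the sign decides attractive vs repulsive otherwise.

## Contact annotation

Each reported residue is annotated with its nearest ligand atom, mapped
through the ligand's labelling scheme (atom labels, regions i/ii/iii, rings
A/B/C) when one is supplied, and a contact class from a deliberately reduced
geometric scheme: hydrogen bond (N/O donor–acceptor ≤ 3.5 Å,
donor–H–acceptor angle ≥ 120°), non-conventional hydrogen bond (same
geometry, C–H donor), aromatic (ring-centroid separation ≤ 5.5 Å),
hydrophobic (apolar-carbon pair ≤ 4.5 Å), else polar contact. The richer
typing of commercial visualization tools (π-alkyl, π-σ, π-sulfur,
dipole–dipole) is intentionally not reproduced: those assignments are
software-specific and not defined by published geometric criteria. The
thresholds here are community-standard values and configurable through
`contact_params()`. Annotation never feeds back into energies; tables join
by residue id only.

## The toy generator

`build_toy_complex()` emulates the smallest structures on which every
pipeline stage is still meaningful: short peptides (2–6 residues in the
tests) from a minimal library — GLY, ALA, SER, ASP(−1), LYS(+1), plus PHE so
that an aromatic residue ring exists for contact tests — built from internal
coordinates (N–C$\alpha$ 1.458 Å, C$\alpha$–C 1.525 Å, C–N 1.329 Å,
extended backbone by default), with explicit hydrogens only where a donor is
needed. Probes: a single Lennard-Jones sphere carrying +0.25 e, a neutral
diatomic dipole (±0.3 e, 1.2 Å apart), and an N-acetyl-amide "tripeptide
mimic" bearing a six-carbon ring proxy and a full label map, so every
annotation class is reachable. Charges come from an embedded table (each
residue summing exactly to its formal charge) or from seeded uniform draws
with per-residue neutrality enforced; either way generation is bit-for-bit
reproducible per seed. Geometries with any interatomic distance below 0.8 Å
are refused.

What passing the toy suites does and does not show: the fixtures validate
the *algebra and geometry* of the pipeline — fragmentation bookkeeping, link
placement, the exactness of the four-term combination, nesting and
convergence logic — under a backend whose ground truth is computable. They
do not mimic melatonin-analog chemistry, GPCR folds, polarization,
charge transfer or any other non-additive physics; nothing about DFT
accuracy follows from them. Conversely, because the quantum interface enters
only through the evaluator contract, correctness of the algebra transfers
unchanged to harvested quantum energies.

## Numerical choices and degenerate inputs

* Coulomb constant 332.0636 kcal·Å/(mol·e²); hartree → kcal/mol conversion
  627.509474. Oracle agreement is asserted at 1e-9 kcal/mol on fixtures
  below a thousand atoms.
* Coincident atoms (pair distance < 1e-9 Å) raise a singular-geometry error
  rather than returning infinities.
* Alternate locations resolve to the highest-occupancy conformer, ties to
  altloc "A". Author residue numbering (with insertion codes) is preserved
  end-to-end so reported residues match published numbering.
* PDB coordinates round-trip at the format's 3-decimal precision; deck
  coordinates carry 6 decimals; report CSVs print 2 decimals (typical
  kcal/mol reporting precision) while all internal arithmetic is double
  precision.
* Fragment content hashing uses an exact 32-bit FNV-1a implemented in
  doubles (intermediates below $2^{53}$); the in-memory cache keys on the
  full content string, so hash collisions cannot corrupt energies.
* Fusion-protein residues in engineered constructs are ordinary residues
  here; they are far from any pocket of interest and need no special-casing.
* `radius_scan()` operates on the decomposition table alone (which carries
  the stored minimum distances) rather than re-taking the complex — one
  source of truth for membership.

The test and acceptance workloads use 100 seeded toy complexes of 3–6
residues — sizes at which the brute-force oracle is exact and instantaneous —
and a reference 5-residue fixture for the scan, ranking and dielectric
checks.

## Command-line use

The exported functions are the primary interface; a thin script at
`inst/cli/mfccie.R` exposes them as subcommands (`toy`, `pocket`,
`decompose`, `decks`, `harvest`) so that deck generation and output
harvesting can run on different machines, with the run manifest and
`decks.csv` carrying the fragment-key mapping between them.

## Known limitations

* No mmCIF input; first MODEL only.
* No structure preparation: protonation states, missing side chains and
  minimization are assumed handled upstream.
* Disulfide bridges cannot be capped (refused explicitly).
* No BSSE/counterpoise handling in the quantum interface; the ligand is
  assumed neutral unless a formal charge is supplied.
* The classical backend is a verification stand-in; its absolute fragment
  energies are not physically interpretable, only the four-term combinations
  are.
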