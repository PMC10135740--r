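---
title: "Methods: time-resolved radial distribution functions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: time-resolved radial distribution functions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trrdf)
```

This vignette documents the statistical model behind `trrdf`, the meaning and
defaults of its parameters, the design of its synthetic trajectory
generators, and the numerical choices that determine its exactness
guarantees.

## 1. Model

### Radial distribution function

For a reference group of $N_a$ particles and a target group of $N_b$
particles in a periodic cell of volume $V$, the radial distribution function
over $N_f$ frames is estimated as

$$ g(r_k) \;=\; \frac{C_k}{V_k \,\rho_b\, N_a\, N_f}, $$

where $C_k$ is the number of (ordered) reference–target minimum-image
distances falling in radial bin $k$, $V_k = \tfrac{4\pi}{3}(r_{k,\mathrm{out}}^3 -
r_{k,\mathrm{in}}^3)$ is the exact spherical-shell volume of the bin, and
$\rho_b = N_b / \bar V$ is the bulk target density with $\bar V$ the mean
cell volume over the frames entering the estimate. Pairs where the reference
and target atom are the same atom (possible when the groups overlap) are
excluded; consequently, for identical groups the ideal-gas expectation of
$g$ is $(N-1)/N$, not 1 — visible, and tested, at small $N$.

Because the histogram is over *ordered* pairs, a symmetric ($a = b$)
analysis counts every unordered pair twice. The pair count in a bin is then
$2K$ with $K$ approximately Poisson, so its standard deviation is
$2\sqrt{\mathbb{E}K}$ — a factor $\sqrt 2$ larger than a naive Poisson band
on the raw count. The flatness tests and the acceptance script apply their
bands to $C_k/2$ for this reason.

### Time-resolved RDF and running coordination number

`compute_trrdf()` partitions the (optionally strided) frames into contiguous,
disjoint windows of a user-chosen length $N_W$ and computes the estimator
above independently per window, including a per-window bulk density from
that window's mean cell volume (relevant for NPT trajectories). Trailing
frames that do not fill a window are dropped by default
(`window_scheme(partial = "keep")` retains them, flagged).

The running coordination number is accumulated directly from counts,

$$ n(r_k, W) \;=\; \frac{1}{N_a N_W} \sum_{j \le k} C_j(W), $$

which requires no bulk density and is therefore exact for arbitrarily small
or inhomogeneous systems. It is algebraically identical to the integral of
$g(r)\,\rho_b\,4\pi r^2\,dr$ evaluated with the same shell volumes;
`running_coordination(result, "from-rdf")` computes that form and the test
suite verifies agreement to $10^{-9}$. Because the window mean runs over
frames, a single reference–target pair inside the shell for $k$ of the
$N_W$ frames yields exactly $n = k/N_W$: fractional values are occupancy
likelihoods, not noise.

### Distinct-part van Hove function

`compute_vhf()` generalizes the RDF to time lags: for lag $\tau$, distances
are taken between reference positions at an origin frame $t$ and target
positions at $t + \tau$, averaged over origins (thinned with
`origin_stride`), always excluding same-atom pairs and always using the
*origin* frame's cell for the minimum image. Normalization is per origin, so

- at $\tau = 0$ the result equals the RDF computed over the origin frames
  (tested to $10^{-10}$), and
- for a frozen system every lag slice is bit-identical to the $\tau = 0$
  slice (tested with `expect_identical`).

Cells that change by more than 1% across the used lags can be rejected with
`strict_cells = TRUE`; by default the origin-cell convention is applied
silently, which is the standard compromise for mildly fluctuating NPT cells.

### Per-residue ion profiling

`default_ion_sites()` maps each residue to a single representative
side-chain carbon (a packaged table covers charged and polar residues;
anything else falls back to the α-carbon, then to any carbon, with a
warning when a residue has no carbon at all). `per_residue_ion_counts()`
reads $n(r_c, W)$ at a cutoff $r_c$ for every residue and window and
averages over windows, optionally per conformational cluster via
`assign_windows_to_clusters()` (majority frame label per window; exact ties
stay unassigned). The default cutoff of 0.70 nm is the Bjerrum length of
water at 300 K:

```{r}
bjerrum_length(temperature = 300, relative_permittivity = 80)
```

i.e. $\lambda_B = e^2 / (4\pi\varepsilon_0\varepsilon_r k_B T)$ with CODATA
constants — the separation at which the Coulomb interaction of two unit
charges falls to $k_B T$, a physically motivated outer boundary for the
second hydration shell. `residue_distance_map()` provides the companion
residue–residue distance and 0.5 nm contact maps (α-carbon representative
by default, or closest-heavy-atom with `mode = "min"`).

## 2. Parameters and defaults

| Parameter | Default | Meaning |
|---|---|---|
| `r_max` | 2.0 nm | outer radius of the grid |
| `n_bins` | 400 | bins of width 0.005 nm |
| `frames_per_window` | none | $N_W$; always user-chosen, no privileged value |
| `stride` | 1 | frame thinning applied before windowing |
| `cutoff` | 0.70 nm | ion-shell cutoff (Bjerrum length at 300 K) |
| contact cutoff | 0.5 nm | residue–residue contact threshold |
| `origin_stride` | 1 | thinning of van Hove origin frames |

Units are nm and ps everywhere; readers convert (PDB/DCD are Å-native).
Atom indices are 1-based in the R API; NDX-like index *files* are 0-based
and converted on read. Residue ids may legitimately start at 0.

There is no default window length on purpose: $N_W$ trades time resolution
against per-window statistics and depends on the exchange kinetics under
study. A practical starting point is the longest window over which the
process of interest can be assumed stationary.

## 3. Synthetic generators and their realism

The package generates its own test fixtures; each has an analytically known
answer rather than mimicking full MD realism:

- `generate_ideal_gas()` — uniform i.i.d. positions per frame (or one frame
  repeated with `frozen = TRUE`). This is the exact null model of the RDF:
  $g \equiv (N-1)/N$ for identical groups, with Poisson-binomial bin counts.
  It deliberately lacks excluded volume and dynamics.
- `generate_lattice()` — simple-cubic and FCC crystals, whose coordination
  shells (6/18/26 and 12) are textbook integers.
- `generate_two_particle()` — one reference and one target at scripted
  separations; $g$ has a closed form $1/(V_k \rho_b)$ in the occupied bin
  and occupancies are exact fractions.
- `generate_random_walk_ions()` — ions performing Gaussian random walks,
  wrapped into the box, around fixed carbon "sites". This is the only
  generator with time correlation; it exercises windows, van Hove lags and
  occupancy without claiming physical ion kinetics (no interactions, no
  solvent, isotropic steps).

All generators are seeded and deterministic; coordinates stay inside the
primary cell so periodic analyses and the brute-force image oracles used in
the tests are exhaustive.

## 4. Numerical choices

- **Half-open bins.** Distances are histogrammed into $[r_{in}, r_{out})$;
  a distance exactly at `r_max` is dropped. Closed bins on both ends would
  double-count edges; the tests pin this down with distances placed exactly
  on edges.
- **Minimum image.** Orthorhombic cells use component-wise rounding.
  Triclinic cells (GROMACS reduced form, validated on input) use fractional
  rounding followed by a search over the 27 neighbor images, which is exact
  for reduced cells; the tests compare against a 125-image brute force to
  $10^{-12}$.
- **Half-cell guard.** The engines refuse `r_max` greater than half the
  minimum cell width (cell volume over the largest face area), the radius
  beyond which the nearest image is no longer unique. The error names the
  offending frame.
- **Per-window density.** Auto density uses each window's own mean cell
  volume, so constant-volume trajectories make the window average of the
  TRRDF reproduce the whole-trajectory RDF exactly (tested to $10^{-10}$),
  while NPT volume drift is handled per window rather than smeared.
- **Counts are kept.** Results store raw integer counts alongside $g$, so
  exports, the count-based coordination route and re-normalizations are
  lossless.

## 5. Limitations

- No XTC/TRR readers; convert binary GROMACS trajectories to GRO, PDB or
  DCD first. The GRO path is text (3 decimals, ±0.0005 nm); the package's
  CSV trajectory table is lossless when exact round-trips matter.
- Dense pair evaluation per frame, no cell/neighbor lists: cost is
  $O(N_a N_b)$ per frame. Intended for ion–site analyses (thousands of
  pairs), not all-atom solvent RDFs of large boxes.
- The van Hove implementation computes the distinct part only; the self
  part (same-atom displacements) is out of scope.
- The site table designates one carbon per residue; analyses needing full
  side-chain ion coordination should pass explicit atom groups instead.
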