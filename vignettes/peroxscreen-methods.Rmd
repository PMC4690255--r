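---
title: "Methods: screening predicted proteomes for peroxisome loss"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: screening predicted proteomes for peroxisome loss}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The scientific question

Peroxisomes are dispensable organelles in some animal lineages: several
endoparasitic flatworms and at least one free-living chordate appear to have
discarded the entire peroxisome biogenesis machinery. The genomic signature
of such a loss is categorical — *every* peroxin (Pex) family is absent from
the predicted proteome — while the peroxisomal metabolic enzymes either
disappear with the organelle or persist with their targeting signals eroded
or rerouted to other compartments.

`peroxscreen` implements this screen as a pipeline over predicted
proteomes:

1. **Homology search.** Each marker family (14 peroxins, 33 peroxisomal
   enzymes) is represented by a protein alignment. The built-in scorer turns
   the alignment into an ungapped position-specific scoring matrix (PSSM)
   and sweeps it along every protein; alternatively, per-domain tables from
   a real HMMER3 run can be ingested (`parse_domtbl()`).
2. **E-value calibration.** Raw sweep scores are converted to E-values with
   an empirically fitted extreme-value law (below).
3. **Orthogroup assignment.** Each protein is assigned to at most one family
   by a best-versus-next E-value separation score.
4. **Targeting signals.** PTS1 and PTS2 motifs are scanned verbatim and
   N-terminal mitochondrial/secretory signals classified (or ingested from
   TargetP-style predictions), giving each protein one of eight localization
   categories.
5. **Inference.** A species-by-family presence matrix, peroxisome loss
   verdicts resting on the essential peroxins Pex3 and Pex19, an enzyme
   localization matrix, and a unique-orthogroup complexity count.

A synthetic-cohort generator with machine-checkable ground truth makes the
whole pipeline testable end to end without genome downloads.

## Profile scores

For an alignment with columns $j = 1, \dots, K$ (columns with gap fraction
above $0.5$ are dropped), the profile holds log-odds in bits,

$$ m_{aj} = \log_2 \frac{(c_{aj} + \tau\, b_a) / (n_j + \tau)}{b_a}, $$

with $c_{aj}$ the count of residue $a$ in column $j$, $n_j$ the number of
non-gap residues, $b_a$ the background frequency (uniform $1/20$ by
default) and pseudocount weight $\tau = 1$. The ambiguity residue `X`
scores $0$ in every column.

The score of a protein is the maximum over all placements of the profile
along the sequence of the summed column log-odds. For a sequence of length
$n \ge K$ only complete placements are allowed; for $n < K$ the profile may
overhang either end provided at least $\lceil K/2 \rceil$ columns align to
residues, and if no placement qualifies the score is $-\infty$.

## E-value calibration

Scores of i.i.d. background sequences against a profile follow,
approximately, a Gumbel law — the classical extreme-value model behind
BLAST and HMMER statistics. `calibrate_evalue()` samples `n_null = 1000`
null sequences, fits location and scale by the method of moments
($\hat\beta = s\sqrt{6}/\pi$, $\hat\mu = \bar{x} - \gamma\hat\beta$ with
Euler's $\gamma$), and converts a score $s$ searched against a proteome of
$N$ proteins to

$$ E(s) = N \left(1 - e^{-e^{-(s - \hat\mu)/\hat\beta}}\right). $$

**Length correction.** The null distribution depends on the query length:
longer sequences offer more placements, and sequences shorter than the
profile aggregate fewer (mostly negative) columns, so their null scores sit
*higher*. Moreover the scoring rule changes regime exactly at $n = K$
(partial-overlap placements below, complete placements at and above), which
makes the null location discontinuous there. The calibration therefore
repeats the fit on a grid of null lengths covering both regimes
($\lceil K/2 \rceil$, $0.75K$, $K{-}1$ on the short side; $K$, $1.3K$,
$1.7K$ and the reference length 300 on the long side) and interpolates
$(\hat\mu, \hat\beta)$ at the query length **without ever interpolating
across the regime boundary**. This is the package's analogue of the
effective-length corrections used by BLAST and HMMER; without it, short
random decoys are systematically anticonservative.

The default reference null length of 300 residues is an upper bound on the
synthetic query lengths, so extrapolation never occurs upward; lengths
outside the grid clamp to its edge.

## Orthogroup assignment

Hits with E-value above `evalue_max` $= 10^{-3}$ are regarded as false
positives and discarded. For each protein the surviving hits are collapsed
to one per family (minimum E-value); with $E_{\mathrm{hit}}$ the best
family's E-value and $E_{\mathrm{next}}$ the runner-up family's (or
`evalue_max` when no second family survives — the least favorable accepted
value), the assignment score is

$$ S = \log_{10} E_{\mathrm{next}} - \log_{10} E_{\mathrm{hit}}. $$

Only strict winners ($S > 0$) are assigned; ties yield no assignment.
$S \ge 2$ (a hundred-fold separation) marks high confidence. E-values of
zero (possible in ingested HMMER tables) are floored at $10^{-300}$ with a
warning before taking logarithms.

## Targeting signals

* **PTS1**: the final three residues match `[SAC][KRHN][LIM]` or one of
  seven enumerated mammalian exceptions (`ASL`, `THL`, `LKL`, `SKV`,
  `KKL`, `SQL`, `PRL`) — 43 accepted tripeptides in total.
* **PTS2**: the 10-position pattern `[RK][LVIQ]..[LVIHQ][LSGAK]..[HQ][LAF]`
  with the whole match inside residues 1–100 (rule `"contain"`; the
  alternative `"start"` only requires the start at or before 100). `.`
  matches any canonical residue or `X`; character classes never match `X`.
* **N-terminal signals**: either ingested from a TargetP-style two-column
  table, or classified by deterministic rules (a run of 8 hydrophobic
  residues in the first 30 → secretory; else ≥3 R/K, ≥2 S/T and no D/E in
  the first 20 → mitochondrial). The built-in classifier is a transparent
  stand-in so synthetic cohorts are self-contained — for real proteomes,
  ingest real predictions.

Per (species, enzyme family) the signal flags are pooled across all
assigned paralogs and collapsed into one of eight categories (`none`,
`pts`, `mito`, `sec` and their unions), mirroring the color scheme of
comparative presence/localization matrices.

## Loss inference

Within each species, over the 14 peroxin families:

* `peroxisomes_lost` — every peroxin cell is absent;
* `peroxisomes_retained` — at least one peroxin is present at high
  confidence **and** both essential markers (Pex3, Pex19, whose
  experimental loss abolishes the organelle) are present at any
  confidence;
* `indeterminate` — anything in between, and any species whose proteome is
  empty (absence of data is not absence of genes).

External (e.g. phylogenetic) vetting verdicts can reject or confirm
individual cells before the verdict (`apply_vetting_overrides()`).

The complexity measure is the number of distinct families — panel plus
background orthogroups — with at least one assignment, a coarse proxy for
annotated gene-family complexity under which loss species rank strictly
below complete ones.

## The synthetic cohort

The generator is the package's own testbed, not a biological simulator. It
emulates exactly the structure the screen consumes:

* per-family consensus sequences with members sampled at per-site
  substitution probability `divergence = 0.15` (substitutions always change
  the residue, so expected identity is exactly $1 - d$);
* 24 species: 6 with zero peroxins (flukes, tapeworms, a whipworm-like and
  an appendicularian-like species), one lacking only Pex7, one lacking only
  Pex26, and 16 complete;
* planted targeting signals per enzyme family (most PTS1; thiolase-type
  and phytanoyl enzymes PTS2; carnitine transferases and the racemase
  dually targeted); loss species retain four enzymes without peroxisomal
  signals, catalase carrying a secretory signal instead;
* 25 random decoy proteins per species (lengths 80–240) whose C-termini
  are scrubbed of chance PTS1 motifs so ground truth stays unambiguous;
* 10 background orthogroups present everywhere, giving the complexity
  count a shared baseline.

It does **not** model insertions/deletions (alignments are gap-free by
construction; the gap-column logic is exercised by unit fixtures), domain
architecture, paralog families, or realistic residue composition. Default
sizes (alignments of 8 members × 150 columns; proteomes of ~60–85
proteins) are chosen so a full 24-species screen runs in well under a
minute — large enough for the extreme-value asymptotics to hold, small
enough for property tests over many seeds.

## Numerical choices and limitations

* All randomness derives from one run seed via labeled substreams
  (`substream_seed()`), so every stage is independently reproducible and
  written outputs are byte-identical across reruns.
* The method-of-moments Gumbel fit is an approximation: the finite-sample
  null maximum is not exactly Gumbel, and with 1000 fresh nulls a
  Kolmogorov–Smirnov uniformity test of the resulting p-values rejects at
  $\alpha = 0.01$ for an appreciable minority of seeds. The screen's
  decisions are robust to this because assignments rest on E-value
  *separations* many orders of magnitude wide, not on borderline
  significance.
* The built-in scorer is ungapped; diverged homologs with indels will score
  lower than a profile HMM would. For real data, run HMMER and ingest the
  domain table.
* Loss verdicts are as good as the proteome annotations: a fragmented
  assembly mimics loss. The `indeterminate` verdict and the vetting hooks
  exist precisely to keep such cases out of the `lost` set.
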