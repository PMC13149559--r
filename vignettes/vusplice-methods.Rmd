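---
title: "Methods: junction-level splicing outlier analysis and functional follow-up"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: junction-level splicing outlier analysis and functional follow-up}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vusplice)
```

This vignette documents the models, the tunable parameters, and the design
choices behind `vusplice` — the package's own account of why each stage is
computed the way it is, what the synthetic-data generator does and does not
emulate, and where the genuinely open decisions were made.

## Percent-spliced quantification

A splice junction is an intron interval, stored 0-based half-open; the STAR
`SJ.out.tab` dialect (1-based inclusive) is converted at the parser
boundary and only unique-mapping read counts are used by default
(`multimappers = TRUE` adds the multi-mapper column; upstream tools differ
on this and no single convention can be assumed, so both are exposed).

The exclusion set of junction $j$ contains every other junction whose
intron interval intersects $j$'s with nonzero length. Reads supporting such
a junction are incompatible splicing outcomes over the same interval, so

$$\mathrm{PS}(j, s) = \frac{n(j,s)}{n(j,s) + \sum_{j' \in E(j)} n(j',s)}.$$

Three conventions are fixed here and matter at the margins:

* **Half-open overlap.** Two introns sharing only a boundary coordinate do
  not overlap. An intron ending where another begins (adjacent exons spliced
  by consecutive junctions) must not compete, or every constitutive junction
  would dilute its neighbour.
* **Strand compatibility.** Junctions on explicitly opposite strands never
  exclude each other; unknown strand (`*`) matches both. Unstranded junction
  dialects exist, and penalising a junction for an antisense gene's introns
  would be wrong.
* **Missingness.** PS is `NA` when the denominator is zero — the sample
  simply has no information about that interval. Zero is a statement
  ("observed competitors, none of them this junction"); `NA` is the absence
  of one.

The overlap computation itself is delegated to
`GenomicRanges::findOverlaps`, whose `*`-strand semantics match the rule
above exactly; the test suite checks the whole PS computation against an
independent all-pairs interval scan.

## Outlier calling against a background cohort

Per junction, the background cohort's non-missing PS values give quartiles
$Q_1$, $Q_3$, $\mathrm{IQR} = Q_3 - Q_1$ and Tukey fences
$Q_1 - 1.5\,\mathrm{IQR}$ and $Q_3 + 1.5\,\mathrm{IQR}$. A query PS strictly
above the upper fence is an up-outlier; strictly below the lower fence, a
down-outlier. Equality is not an outlier — the definition is "larger
than"/"smaller than", and with a zero-IQR background (a junction used
identically by every reference sample) this makes the background value
itself `none` while any deviation, however small, is called. That is the
intended behaviour: a degenerate background genuinely has no tolerance.

Open choices, and how they were fixed:

* **Quantile rule.** No single quantile definition is canonical. The default
  is linear interpolation between order statistics (`stats::quantile`
  type 7, the common scientific-computing default); the `type` argument
  exposes the alternatives. With 670 background samples the choice moves
  fences by well under a percent of PS.
* **Missing background values** are dropped, not imputed as zero. Imputing
  zero would shrink $Q_1$ toward 0 for sparsely covered junctions and
  manufacture down-outliers in well-covered queries. A junction with fewer
  than `min_samples` (default 20) usable background values is flagged
  `not_evaluable` rather than silently fenced on noise.
* **The query must not sit in the background** (enforced by sample id in the
  pipeline): a 56%-usage patient inside a 670-sample cohort would shift
  $Q_3$ only trivially, but the principle is cheap to enforce and the
  contamination grows with effect size and shrinks with cohort size.

`cohort_usage_summary()` reports the fraction of background samples with
PS > 0 and the maximum PS — the two numbers that contextualise a novel
junction (rarely touched in the cohort, never dominant there, yet the
majority junction in the patient).

No multiple-testing correction is applied across junctions; calls are
descriptive flags against a reference distribution, not hypothesis tests.

## Isoform fractions, structure, and protein consequence

Fractions are TPM shares per gene; genes with zero total TPM get `NA`
(undefined, reported) rather than zeros.

Structural classification compares **intron chains**, not exon endpoints:
terminal-exon length differences (alternative TSS/polyA) leave the chain
intact and classify as `canonical_match`. Exon skipping is recognised when
every candidate intron either equals a canonical intron or spans a merged
run of canonical introns across whole skipped exons; the skipped ordinals
are reported in transcription order. A single intron boundary moved, with
the rest of the chain identical, is an `altered_splice_site` (cryptic site)
with the new genomic coordinate and donor/acceptor side.

Protein consequences are predicted by locating the canonical start codon's
genomic position in the candidate's exons, splicing the candidate's exonic
sequence (minus-strand transcripts are reverse-complemented at extraction;
all interval arithmetic stays genomic), and translating both frames to their
first stop (standard genetic code, no selenocysteine):

* identical peptides → `synonymous_structure`, `p.(=)`;
* a contiguous residue run deleted with frame and flanks preserved →
  `in_frame_deletion`, placed as far C-terminal as flanking repeats allow
  (the HGVS 3′ rule applied at residue level — a repeat-flanked deletion is
  reported at its 3′-most equivalent position, which is also why byte-level
  agreement with other tools' strings is not claimed);
* first divergent residue at position $p$ with a new downstream frame →
  `frameshift`, `p.<Ref><p><New>fs*n`, where $n$ counts the divergent
  residue as 1 and the new stop as $n$;
* start codon not contained in the candidate → `start_lost`.

One case falls outside this four-way scheme and was a real design decision:
a skip whose length is a multiple of 3 but whose splice joint is not on a
codon boundary preserves the frame yet fuses two partial codons into one
hybrid codon. The result is neither a clean deletion (one residue is new)
nor a frameshift (downstream sequence is intact). It is reported as kind
`other` with an explicit delins string (`p.<X><i>_<Y><j>delins<Z>`),
keeping `in_frame_deletion` strictly for clean deletions. The independent
brute-force translator in the test suite implements the same decision
procedure from scratch and agrees on 1000 random gene/skip constructions.

## Reporter PSI and Dunnett statistics

Peaks are assigned to the nearest expected amplicon size within
`tolerance_nt` (default ±5 nt — fragment analyzers drift by a few
nucleotides; the two expected sizes must be separated by more than twice the
tolerance so windows cannot overlap). Signals are summed per isoform and
$\mathrm{PSI} = 100\,\mathrm{inc}/(\mathrm{inc}+\mathrm{skip})$ per
replicate, on the 0–100 scale. No molar or size normalisation of signal is
applied by default — whether peak area should be length-corrected depends on
labelling chemistry, and the uncorrected ratio is the conservative default.

Condition effects use classical one-way fixed-effects ANOVA, then Dunnett's
many-to-one comparisons on the pooled within-group variance. The
family-wise adjustment is the distribution of $\max_i |t_i|$ under the
joint null; rather than tabulated critical values, it is estimated by
seeded Monte-Carlo simulation of the joint statistics (correlated through
the shared control mean and the pooled $\chi^2$ variance), which removes an
external dependency and generalises to unbalanced designs with no extra
machinery. Two numerical details:

* adjusted p-values use the add-one estimator $(r+1)/(B+1)$, so they are
  never exactly zero and the resolution at $B = 10^5$ replicates is
  $\approx 10^{-5}$;
* the adjusted p is floored at the unadjusted pooled-t p, which is the
  analytic $k = 2$ limit the Monte-Carlo estimate converges to.

`mc_reps` and the seed are recorded in the output; below $10^4$ replicates a
warning flags coarse p-values.

## Lipid ratio analysis

Technical replicates are averaged within each (sample, class, chain) before
any statistic — the unit of analysis is the biological sample, and treating
triplicate injections as independent observations would triple the apparent
n. The DHCer/Cer ratio per sample and chain is the desaturase-activity
readout; folds are expressed over the mean control ratio, so controls sit at
1 by construction, and both ratios and folds are invariant to any global
rescaling of concentrations (units cancel). Group comparisons default to
the pooled two-tailed Student's t (df $= n_a + n_b - 2$); Welch's variant is
available. Tests can be run on ratios (default) or raw concentrations, each
row labelled with the quantity tested, and no correction is applied across
lipid species — with two probands the analysis is descriptive confirmation,
not discovery.

## ASO walk design

A window of `k` nucleotides (default 18) slides along the target at stride
`step`; each design is the reverse complement of its window, emitted in the
DNA alphabet (ASOs are synthesised as modified DNA; RNA targets are
accepted, U pairing like T). Chemistry is annotated per design: 2′MOE sugar
at every position and a phosphorothioate backbone. The stride default is 1 —
a dense walk — because no spacing convention is canonical; callers thin the
tiling as needed. Windows containing N are emitted with a flag rather than
dropped, so tiling coordinates stay contiguous.

## The synthetic-data generator: what it emulates

The generator is a stated world, not a tuning knob; its defaults are the
conditions the analyses are specified against.

* **Junction cohort** (`cohort_sim_config`): 670 background samples — the
  scale of a GTEx-tissue background — and one patient in whom the skip
  junction carries 56% of junction usage. Per sample, total depth is
  negative-binomial (mean 2000, dispersion 0.1: typical bulk-RNA-seq
  junction-spanning depth, explicitly a placeholder since no cohort depth
  is specified anywhere); the skip fraction $\psi$ is Beta(mean 0.02,
  concentration 100) in the background and fixed at 0.56 in the patient;
  skip reads are Binomial($N$, $\psi$) and the rest split uniformly across
  the consecutive-exon junctions. Under this scheme the skip junction's
  expected PS equals $\psi$, which is what makes recovery testable against
  a closed form.
* **Reporter runs** (`reporter_sim_config`): nine biological replicates per
  condition; each peak's signal is its expected share of the total,
  perturbed by unit-mean log-normal noise (CV parameterisation — positive
  support, exact recovery at cv = 0). Zero-expected peaks are omitted, so a
  complete-skipping condition genuinely has no inclusion peak to find.
* **Lipid panel** (`lipid_sim_config`): 9 controls vs 2 probands, measured
  in triplicate, over the seven-chain panel C14:0–C26:0. The configured
  ratio fold (default 42, the low end of the effect range emulated) is
  realised symmetrically — DHCer multiplied and Cer divided by
  $\sqrt{\text{fold}}$ — so both class-level signatures (substrate up,
  product down) are present while the ratio fold is met exactly at cv = 0.

What the generator does **not** emulate: read-level artefacts (mapping
bias, overhang filters, duplicates), between-sample covariance in the
cohort, batch effects in the reporter assay, heteroscedastic or correlated
lipid species, and any real GTEx depth distribution. A green recovery test
therefore establishes that the analysis chain is correct under its own
model, not that the model captures every property of real data.

## Pipeline determinism

`validate_config()` range-checks every parameter, rejects unknown keys with
a nearest-key suggestion, and echoes all defaults. `run_pipeline()` executes
the enabled stages in dependency order, writes each stage's tabular output
plus one JSON report, and derives every stage's seed as a fixed offset of
the config seed — no stage reads the clock or OS entropy, so identical
config plus seed gives an identical report payload. A stage failure aborts
with the stage named; outputs already written are retained.

## Known limitations

* Exclusion sets are rebuilt from the junction table alone; no annotation
  guidance or minimum-overhang filtering is applied (out of scope — the
  package consumes aligner junction tables as given).
* HGVS strings are produced for the categories above only; complex
  rearrangements report `p.?`/kind `other`, and no NMD prediction is
  attempted.
* The Dunnett Monte-Carlo assumes normal within-group errors with a common
  variance, as the classical procedure does; PSI values near the 0/100
  boundary are heteroscedastic, which matters for marginal effects though
  not for the near-complete separations this assay targets.
* With two probands the lipid t-test has df barely above its minimum; it
  confirms large effects and should not be read as powered discovery.
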