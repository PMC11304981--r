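---
title: "Interpreting nucleocytovirus aminoacyl-tRNA synthetase gene trees"
author: "ncvaars"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Interpreting nucleocytovirus aminoacyl-tRNA synthetase gene trees}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ncvaars)
```

## The problem

Large and giant DNA viruses (phylum *Nucleocytoviricota*) are unusual
among viruses in encoding aminoacyl-tRNA synthetases (aaRSs), the enzymes
that charge tRNAs and are otherwise universal to cellular life. Whether
those viral aaRSs are recent thefts from host eukaryotes or relics of
much older exchanges — some possibly predating the last eukaryotic common
ancestor (LECA) — is a long-standing question, and the answer differs
gene by gene. The evidence is a set of large maximum-likelihood gene
trees, one per aaRS class, mixing viral sequences with bacterial,
archaeal and eukaryotic (nuclear and organellar) homologs.

`ncvaars` turns the interpretation of such trees into a reproducible
pipeline: reading annotated gene trees, rooting them, extracting
well-defined viral clades, assigning each clade one of six evolutionary
scenarios, generating the constrained topologies that downstream
approximately-unbiased (AU) tests consume, and analysing transfers,
losses and displacements inside the viral clades. Tree *inference*
(alignment, model selection, ML search, bootstrapping) is deliberately
out of scope: the package consumes trees, support labels, hit tables and
ANI tables produced by standard external tools.

## Input reduction rules

Four data-reduction steps precede interpretation, each with a fixed
default:

* **Dereplication** (`dereplicate`). Metagenome-assembled genomes (MAGs)
  are single-linkage clustered: two MAGs are linked when ANI > 98% and
  the alignment covers > 25% of the smaller genome (both strict). The
  representative is the largest Tara-Oceans MAG, else the largest member;
  ties break lexicographically. Reference genomes never enter clustering.
  Connected components are the minimal reading of pairs "clustered
  together" when no linkage is named.
* **Gap trimming** (`trim_alignment`). Columns gapped in more than 75% of
  sequences are removed (`max_gap_frac = 0.75`); the stringent rerun used
  to probe long-branch effects uses 0.50. The rule is strictly
  "more than": a column gapped in exactly 3 of 4 rows survives the
  default threshold.
* **aaRS assignment** (`assign_aars`). A gene is an aaRS iff its single
  best hit (highest bitscore, ties by lower e-value then subject id) has
  e-value ≤ 1e−5 and a description matching one of the 20 class keyword
  patterns. Only the best hit counts.
* **Contamination filtering** (`flag_contamination`). A viral tip is
  removed only when all three conditions hold: it is not inside any clade
  with ≥ 2 viral tips, it derives from a MAG, and its contig carries
  neither a nucleocytovirus core gene nor a gene with a nucleocytovirus
  best hit. Isolate sequences are never removed. The companion filter
  `flag_outlier_tips` operationalizes the removal of putatively
  nonfunctional genes with two declared (not literature-derived) knobs:
  minimum ungapped length 200 aa, and terminal branches longer than 5×
  the median tip depth.

## Rooting and support

Gene trees are rooted at the branch separating the major bacterial and
archaeal clades, the standard rooting for anciently duplicated
translation genes. `root_at_prok_split` scores every edge by
(fraction of bacterial tips on one side) × (fraction of archaeal tips on
the other), maximized over orientation; non-prokaryote tips are ignored.
Ties break first by prokaryote balance, then by lexicographically
smallest child leaf set, so rooting is deterministic. One caveat worth
stating: when other lineages attach *between* two monophyletic prokaryote
domains, every edge on the connecting path scores 1 and ties are real;
the tie-break chain then decides. When the separating edge is unique it
is always chosen, and the selected split always separates the domains
completely.

Node support is a dual label: a clade is statistically supported when
SH-aLRT ≥ 80% **and** ultrafast bootstrap (UFB) ≥ 95%. The thresholds
are inclusive by default (a `strict` flag switches to `>`); the
distinction never matters for the canonical near-miss of UFB = 94 with
SH-aLRT = 96.8, which fails either way. Labels absent from a node are
treated as *missing*, never as zero.

**Transfer bootstrap expectation** (`compute_tbe`) supplements the dual
basis for deep branches and large trees. For a reference branch $b$ with
lighter side of size $p \ge 2$,

$$\mathrm{TBE}(b) = 100\left(1 - \frac{1}{N}\sum_{i=1}^{N}
\frac{\min_{b' \in T_i}\delta(b, b')}{p - 1}\right),$$

where $\delta$ is the transfer distance (the smaller symmetric
difference over the two orientations) and the minimum runs over *all*
branches of bootstrap tree $T_i$, trivial ones included. The
implementation is an exhaustive $O(\text{branches}^2 \cdot
\text{leaves})$ scan — correct and fast at desk scale; the linearithmic
algorithm is intentionally not reimplemented. Closed-form limits anchor
the tests: a branch present in every replicate scores 100, and a cherry
($p = 2$) reduces exactly to the Felsenstein presence proportion. Clades
with TBE ≥ 70% count as supported on the TBE basis.

## The six-scenario classifier

`extract_viral_clades` returns every maximal clade whose tips are all
viral. A clade is *eligible* when it has ≥ 3 sequences or contains an
isolate; MAG singletons and pairs are treated as potential contamination
and skipped, while a lone isolate (a named virus embedded in a eukaryote
clade) is an eligible "branch".

`classify_scenario` applies ordered rules, first match wins. The order —
prokaryotic, nested, recent, proto, ancient, other — puts the most
topologically specific patterns first and is configurable in principle;
the published per-tree judgments were expert calls, and this ordering is
one consistent operationalization.

1. **`prok_v`** — the smallest clade properly containing the viral clade
   plus at least one cellular tip has ≥ 80% prokaryotic cellular tips
   (the 80% is a declared default).
2. **`v_to_euk`** — a nuclear eukaryote tip or clade is nested in viral
   context: its parent is majority-viral, and some further enclosing node
   containing the focal viral clade is majority-viral *with the far
   flank itself majority-viral*. The extra flank condition encodes
   "surrounded on both sides by viral sequences"; without it, a recent
   transfer whose small eukaryote sister happens to be outnumbered by
   the viral clade would satisfy the nesting arithmetic. Calls whose
   nested eukaryote group has ≥ 2 tips carry the note
   "encompassing a eukaryotic clade", which feeds the pre-LECA
   aggregation below.
3. **`recent_euk_to_v`** — the sister is nuclear-eukaryotic spanning a
   single supergroup, and an enclosing eukaryote clade spanning ≥ 2
   supergroups exists (supported if possible): the virus sits below the
   eukaryote radiation.
4. **`proto_euk_v`** — viral monophyly and sister monophyly are both
   supported, and the sister is a LECA-wide eukaryote clade: ≥ 3
   supergroups and ≥ 50% of the tree's nuclear eukaryote tips. An
   organellar variant accepts a supported all-organellar sister spanning
   ≥ 3 supergroups (the mitochondrial-like pattern).
5. **`ancient_euk_v`** — a eukaryote sister spanning ≥ 2 supergroups
   that misses the LECA-wide criteria (span, tip fraction, or support).
6. **`other_euk_v`** — eukaryotic sister context with unresolved timing;
   also the terminal fallback, so the six labels are exhaustive.

Support enters twice. Rules 4–5 *require* support where stated; a
support requirement is satisfiable on either the dual UFB/SH-aLRT basis
or the TBE basis. Separately, each call records a `support_basis`:
`topology_ufb_shalrt` when every rule-critical node passes the dual
thresholds, else `topology_tbe`, else `topology_only`. TBE-only support
does **not** demote a proto call to ancient — the published per-clade
table lists proto-eukaryotic calls resting on TBE — it only changes the
recorded basis. The ancient/other boundary for topology-only calls is
the one place where the published table reflects narrative judgment; the
rule-5/rule-6 split here is a declared, consistent operationalization.

`summarize_scenarios` aggregates calls: counts per scenario, distinct
aaRS classes per scenario, and the pre-LECA class count — classes with a
proto call, plus classes whose nested `v_to_euk` calls are annotated as
encompassing a eukaryotic clade (for those, the origin predates LECA
whichever direction the transfer ran).

## Constrained topologies for AU testing

For proto-pattern aaRSs, robustness is probed by AU tests over
constrained topologies. `split_top_bipartitions` cuts the major
eukaryote clade into three subclades at its top two bipartitions,
skipping any bipartition that would cut off a singleton or pair (those
tips are excluded); the larger side is split second (a declared choice —
the source procedure does not specify which child is split). With groups
E1, E2, E3 and the viral group V, `enumerate_constraints` emits all 15
rooted binary arrangements (15 = 5!! for four labeled leaves), each as a
Newick constraint with group members as multifurcations: 3 "original"
topologies (V sister to the intact eukaryote triple) and 12
"alternative" ones (V inside). The AU test itself runs in external ML
software on these files.

## Inside the viral clades

* `detect_vhgt` reports minority tips inside clades whose dominant group
  (virus order, refined by the aaRS-rich-clade flag) reaches 70%;
  ambiguous clades below the majority threshold yield nothing. The
  aaRS-rich clade is an input flag, not inferred — it is defined on the
  species tree, which this package consumes but does not build.
* `detect_displacement` compares each genome's gene-tree context
  (main viral clade / eukaryote-embedded / prokaryote-embedded) with the
  majority context of its 5 nearest species-tree neighbours; a call is
  made only when the neighbours kept the main viral copy. Both k = 5 and
  the loss-prevalence threshold below are declared defaults for analyses
  the source reasons about qualitatively from figures.
* `richness_profile` builds per-genome aaRS class sets, totals them over
  a chosen species-tree clade, and flags putative losses: classes
  present in ≥ 80% of a clade's sister genomes but absent from the
  focal subclade (the mimivirus-style loss pattern).

## The synthetic-data generator

Real inputs are thousands of genomes and trees from public archives; the
generator (`build_scaffold`, `simulate_gene_tree`) provides a desk-scale
stated world so every stage is testable offline. The default scaffold
emulates a broad three-domain sampling at roughly one-fifth scale: 7
bacterial phyla × 4 taxa, 5 archaeal phyla × 3, 4 eukaryote supergroups
× 6 nuclear taxa, 4 organellar lineages nested inside bacteria, and 3
virus orders (10/4/4 genomes) whose largest order holds a 6-genome
aaRS-rich subclade (two isolates, the rest Tara MAGs). These sizes keep
every structural feature the classifier reads — a LECA-wide radiation,
two-supergroup subclades, an organellar block, a rich subclade with
potential intruders — while a full simulation-classification round trip
runs in milliseconds.

Each simulated gene tree grafts an 8-tip viral clade according to the
planted scenario, exactly mirroring the patterns in the rules above; the
`other_euk_v` planting uses a mixed nuclear/organellar sister, which is
unresolvable by construction. Supports are *simulated labels*: high
nodes draw SH-aLRT from 85–100 and UFB from 96–100, perturbed nodes from
20–79 and 40–94 (both strictly below the thresholds). Topology noise
applies an independent NNI with probability `nni_prob` to each
rule-critical edge around the graft and marks the touched nodes
low-support. Branch lengths are exponential(1) — cosmetic; nothing
downstream reads them. All randomness flows from a single integer seed,
so every dataset is reproducible.

What a green test does and does not establish: recall ≥ 0.95 per
scenario on noise-free simulations shows the rules recover the planted
patterns they define; it does not show that real trees — with rogue
taxa, long-branch attraction, incomplete lineage sorting and
compartment mislabeling — are classified as an expert would. The noise
model perturbs topology only at rule-critical edges, which is why recall
degrades smoothly rather than collapsing; real estimation error is not
confined to those edges.

## Numerical and degenerate-input choices

* Missing support labels are missing, never 0; a node without the
  supports a basis needs is simply unsupported on that basis.
* Polytomies are accepted and preserved; monophyly tests run on them
  without resolving. A polytomous parent pools its children as an
  unsupported sister context. The top-two-bipartition splitter refuses
  to apply the skip rule across a polytomy rather than guess.
* TBE normalization always uses the *reference* branch's lighter-side
  size; bootstrap polytomies contribute only their resolved
  bipartitions; the two root edges of a rooted tree are reported once.
* Rooting places the root at the midpoint of the chosen edge when branch
  lengths exist — presentation only, nothing downstream uses the
  position.
* Cluster ids, clade ids and representatives are assigned from sorted
  leaf-name sets, so all outputs are invariant to input row and tip
  order.

## Worked example

```{r example}
scaffold <- build_scaffold(scaffold_config(seed = 1))
sim <- simulate_gene_tree(scaffold, sim_truth("proto_euk_v"),
                          noise_model(seed = 42))
classify_tree(sim$tree, sim$ann, aars_class = "GlyRS")

part <- split_top_bipartitions(ape::keep.tip(
  sim$tree, sim$ann$seq_id[sim$ann$domain == "eukaryote" &
                             sim$ann$compartment == "nuclear"]))
cons <- enumerate_constraints(part,
                              sim$ann$seq_id[sim$ann$domain == "virus"])
table(cons$klass)

summarize_scenarios(
  tibble::tibble(aars_class = table1_fixture()$aars_class,
                 clade_id = table1_fixture()$clade,
                 scenario = table1_fixture()$scenario,
                 support_basis = table1_fixture()$support_basis,
                 notes = table1_fixture()$notes))$n_pre_leca
```

## Known limitations

* The classifier reports evidence, not prose: narrative judgments (e.g.
  weighing an outlying deep-branching eukaryote lineage) are out of
  scope, and topology-only ancient/other boundaries are an
  operationalization.
* Subsection-tree reanalysis is supported by re-running classification
  on an extracted subtree; the package does not re-estimate the subtree.
* The generator plants one scenario per tree plus optional loss,
  displacement and vHGT events; it does not model sequence evolution,
  duplication/coalescent processes, or correlated estimation error.
* The AU test, ML inference, ANI computation and homology search are
  consumed as files, never executed.
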