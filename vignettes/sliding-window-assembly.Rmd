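---
title: "Sliding-window assembly of repeats and nonrepeats: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sliding-window assembly of repeats and nonrepeats: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(swassembly)
```

## The model

`swassembly` assembles repeats and nonrepeats *separately*, on the premise
that unique-read frequency encodes local copy number. After cleaning, every
read and its reverse complement are collapsed into a sorted unique-read table
with multiplicities. If reads start approximately uniformly at rate `S_d`
per base (reads per base, *not* coverage; coverage is `S_d * L_r`), then the
frequency of a unique read drawn from a single-copy locus is approximately
Poisson(`S_d`), while a read from a repeat occurring `c` times accumulates
the reads of all copies: approximately Poisson(`c * S_d`). Seeds with
frequency above `H_p = 2 S_d + 1` therefore start repeat contigs, seeds with
frequency at most `L_p = max(1, ceiling(S_d) - 1)` start nonrepeat contigs,
and middle frequencies -- characteristic of boundary-straddling reads -- are
never used as seeds.

Extension is greedy. At each step the assembler profiles, for the current
3' end, the summed frequencies `x_j` of unassembled table entries that
overlap the end by `t = max_ov - j + 1` bases, across the *dynamic
overlapping interval* of width `L_d = max_ov - min_ov` (this interval width
is what the method calls its "k-mer"; the code names it `interval_width` and
accepts `k_mer` as an alias). The profile is filtered with `N_f` passes of a
rectangular sliding window of length `L_w`, and the filtered interval mean
`m_y` is appended to the contig's trace `M_n`. Extension appends the optimal
extendable read (deepest overlap by default), consumes it, and repeats; the
5' end is extended by reverse-complementing the working contig so that a
single 3' code path serves both ends.

Two identities put all thresholds on one scale. The window is a windowed
*sum*, so a constant profile `c` maps to exactly `c * L_w^{N_f}`; hence the
filtered depth is `S_fd = S_d * L_w^{N_f}`, a nonrepeat interior fluctuates
around `S_fd`, and a `c`-copy repeat interior around `c * S_fd`. With
`delta = min(ceiling(S_fd / 3), S_fd / 2)`, nonrepeat extension continues
while `m_y < T_1 = S_fd + delta` and repeat extension while
`m_y > T_2 = 2 S_fd - delta`. Finally, the copy number of a finished contig
is `mean(M_n) / S_fd` rounded half-up (the definition says only "nearest
integer"; half-up is the fixed tie-break), floored at 1.

### Why the window sum, not the window mean

The rectangular-window formula is sometimes written with a `1/L_w` factor,
but the filtered-depth identity `S_fd = S_d * L_w^{N_f}` and every worked
threshold example are consistent only with summation. We adopt the sum so
that `T_1`/`T_2` live on the documented `S_fd` scale; the variance-reduction
property of the filter (variance divided by at least `L_w` for uncorrelated
input) is stated -- and tested -- on the mean-normalized signal, where it
belongs.

## Boundary detection: the confidence stop rule

The textbook rule -- stop the moment one `m_y` crosses its threshold -- is
statistically fragile. At `S_d = 6`, `L_w = 3`, `N_f = 1`, `L_d = 10`, a
2-copy repeat interior has `m_y` centred on `2 S_fd = 36` with standard
deviation about 3.3 under Poisson read starts, against `T_2 = 30`: roughly a
4% false-stop probability at *every* extension step, which would shatter any
kilobase-scale repeat. The thresholds are better read as a significance test
whose repeated, strongly dependent application needs an accumulation rule.

The default `stop_rule = "confidence"` therefore runs a one-sided CUSUM per
end: `S <- max(0, S + dev)` with `dev = T_2 - m_y` for repeats
(`m_y - T_1` for nonrepeats), stopping when `S` exceeds `h = 3 S_fd` and
trimming the contig back to the last step at which `S` was zero -- the
standard change-point estimate -- while releasing reads consumed past that
point. In a repeat interior the drift of `dev` is negative and `S` hugs
zero; at a true boundary the filtered mean settles a full `S_fd` below
`T_2`, so the CUSUM fires within a handful of steps and the trim removes
most of the overshoot. `h` scales with `S_fd` so the rule tightens and
loosens with the thresholds themselves; `h = 3 S_fd` was fixed from this
variance analysis, not fitted to outcomes. The literal per-step rule remains
available as `stop_rule = "threshold"`, where the recorded `M_n` values all
sit strictly on the accepting side of the threshold.

Boundary behaviour is asymmetric by construction. A nonrepeat contig
approaching a repeat keeps finding copy-specific junction reads and
penetrates up to `max_ov` bases into the repeat before candidates run out;
a repeat contig exits into exactly one copy's flank before its profile
collapses to single-copy scale. Both overhangs are bounded by the read
length, which is why evaluation tolerates them (below).

## Read consumption

During extension only the seed and each chosen read are marked assembled, so
overlap counts always reflect the still-unassembled pool and repeat copy
counts stay intact while a repeat is being traversed. When a contig is
*finished*, every table entry occurring as a read-length substring of it (in
either orientation) is retired. Identical repeat copies share their interior
entries, so assembling a family once retires all its copies -- the repeat
pass emits one contig per family -- and a finished nonrepeat segment cannot
re-seed, keeping genome coverage near 100% instead of several-fold. The
repeat pass runs before the nonrepeat pass so that nonrepeat extension
cannot wander into still-unassembled repeat interiors.

Leftover reads that straddle a finished contig's end can still seed; their
contigs are structurally shorter than `2 L_r` and fall under the 200 bp
output filter (`min_contig`), which is the filter's role. At read lengths
well above 100 bp such leftovers approach 200 bp and can begin to surface as
extra short contigs.

## Parameters

| parameter | meaning (units) | default | rationale |
|---|---|---|---|
| `L_r` | read length (bases) | -- | fixed-length algorithm |
| `max_ov`, `min_ov` | overlap interval bounds (bases) | `L_r - 1`, `max_ov - interval_width` | `min_ov >= L_r/2` enforced |
| `interval_width` (`L_d`) | dynamic-interval width (positions) | 10 | the simulation studies' setting |
| `L_w` | sliding-window length (positions, odd) | 3 | recommended `2 <= L_w <= L_d/2`; larger values only warn |
| `N_f` | filter passes | 1 | raise to 2 at low depth (compensation) |
| `S_d` | depth (reads/base) | -- | supplied by the user/simulator |
| `H_p`, `L_p` | seed count thresholds | `2 S_d + 1`, `max(1, ceil(S_d) - 1)` | "above double depth" / "below depth" |
| `T_1`, `T_2` | extension thresholds | `S_fd ± delta` as above | `T_1 <= T_2` required (equality occurs whenever the `delta` clip binds, i.e. `S_fd <= 6`) |
| `count_floor` | minimum nonrepeat-seed frequency | 2 | guards against error reads; effective floor `min(count_floor, L_p)` so low-depth pools are never empty |
| `min_contig` | output length filter (bases) | 200 | removes leftover fragments |
| `strategy` | optimal read | `longest_overlap` | `nearest_depth` is faster, less accurate |
| `stop_rule`, `h` | boundary decision | `confidence`, `3 S_fd` | see above |
| `L_k` | hash keyword length (bases) | `min(12, min_ov)` | `L_k <= min_ov` guarantees no legal overlap is missed |

Ties everywhere are deterministic: equal seed counts resolve by higher mean
quality then table (lexicographic) order; equal-overlap extension candidates
by higher frequency then table order.

## The simulator and what it does (not) emulate

`make_genome()` samples a uniform ACGT background and plants each family as
exact copies -- interspersed copies at loci separated by at least 200
nonrepeat bases and kept off the genome ends (so each intervening segment
survives the 200 bp output filter), tandem copies as one head-to-tail
cascade. Unit sequences are random and screened so no two families share a
31-mer, preventing accidental cross-family repeats; unit lengths default to
a uniform draw from 500-5000 bases when unspecified. `sample_reads()` draws
fragments with uniform (optionally lognormal-biased) starts and
Normal(300, 30) lengths truncated at `L_r`, reads both ends (second end
reverse-complemented), pools them single-read for assembly, applies i.i.d.
substitution errors, and emits exactly `round(S_d * L)` reads with constant
Q40 qualities (erroneous bases drop to Q10 with probability 0.5).

Real data differ in ways the simulator deliberately omits: indels and
platform error profiles, GC-dependent coverage curves, inexact repeat copies
(the hard case for frequency-based classification), and mate-pair libraries.
Passing tests therefore demonstrate the method's behaviour under its own
statistical assumptions, not performance on real libraries.

## Evaluation choices

Contigs are placed on the reference by exact substring search (identity-1
alignments found by Boyer-Moore) before falling back to Smith-Waterman
(match +2, mismatch -1, gap -2; both strands) anchored around exact 60-mer
hits. A contig is an *error contig* if no placement reaches identity 0.99
over at least 90% of its length; the 10% margin absorbs the legitimate
read-length boundary overhangs described above, which make a repeat contig
a concatenation of two genomic substrings rather than one. Repeat contigs
match a family when they align to its unit at identity at least 0.95 over at
least 90% of the shorter of contig and unit, so fragments of a broken family
each match it. Rep-accuracy caps each contig's aligned length at the unit
length, and N50/N90 are computed against the true genome size. Genome
coverage counts each repeat contig once, so genomes with many-copy families
evaluate below 100% even when perfectly assembled.

## Numerical and degenerate-input conventions

Window edges are replicate-padded so the constant-input identity
`c -> c L_w^{N_f}` holds exactly on the finite interval. Contigs shorter
than `max_ov` cap the longest profiled overlap at their own length. A seed
with no overlaps at either end returns itself as a (sub-`min_contig`)
contig; an empty read set yields an empty table and an empty assembly rather
than an error. Overlaps shorter than `L_k` are excluded from profiles by the
`min_ov >= L_k` constraint, keeping hash lookup exhaustive. All coordinates
in truth files are 0-based half-open.

## Problem sizes used by the test suite

Unit and property tests run on toy tables (tens to hundreds of entries) and
small simulations (12-21 kb genomes, depth 4). The end-to-end acceptance
tests regenerate the simulation studies at their native scale -- 500 kb
genomes, up to 3 million reads -- across five seeds for the depth-6
interspersed design and single seeds for the read-length-101 and tandem
designs; these sizes were chosen so the whole suite completes in minutes on
one CPU. The low-depth window/filter sweeps are asserted under the per-step
threshold rule (the rule whose noise sensitivity those sweeps measure); as
shipped, the package's boundary detection at low depth is substantially more
stable than the per-step rule in either direction of the sweep, so the
expected interior optimum need not appear.

## Known limitations

Near-identical (rather than exact) repeat copies violate the frequency
model and will be split or mis-counted; copy numbers close to 1.5x
boundaries can round either way under coverage bias; repeats whose copy
number times depth falls near `H_p` may fail to seed at very low coverage;
and scaffolding, gap filling and use of pairing information are out of
scope -- pairing survives only in read ids.
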