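# swassembly

Sliding-window greedy assembly of repeats and nonrepeats from short sequencing
reads, in R.

## The problem

De novo assemblers fragment or collapse repeats longer than the read length:
a read from inside a repeat looks identical wherever the repeat occurs, so
graph-based assemblers either break contigs at every repeat or merge copies
into one. `swassembly` implements a seed-and-extend algorithm that turns this
ambiguity into signal. Because identical copies collapse onto the same unique
read, the *frequency* of a unique read is proportional to how many times its
locus occurs: a read from a single-copy region is seen about `S_d` times
(`S_d` = reads per base), a read from a `c`-copy repeat about `c * S_d` times.
The assembler therefore:

1. cleans the reads and collapses them (plus reverse complements) into a
   sorted unique-read table with frequencies (table R);
2. indexes the table by quaternary keyword hashing of read prefixes/suffixes
   (A=0, C=1, G=2, T=3);
3. picks *repeat seeds* (frequency above `H_p = 2 S_d + 1`) and *nonrepeat
   seeds* (frequency at most `L_p`), avoiding boundary-straddling middle
   counts;
4. extends each seed greedily at both ends. At every step it profiles read
   counts `x_j` over the dynamic overlapping interval (overlap lengths
   `max_ov` down to `min_ov + 1`), filters the profile with `N_f` passes of a
   rectangular sliding-window sum of length `L_w`, and records the filtered
   interval mean `m_y` in the trace `M_n`. On the filtered scale
   `S_fd = S_d * L_w^{N_f}`, nonrepeat extension continues while
   `m_y < T_1 = S_fd + delta` and repeat extension while
   `m_y > T_2 = 2 S_fd - delta`; crossing the threshold marks a repeat
   boundary and stops the contig;
5. estimates each contig's copy number as `round(mean(M_n) / S_fd)`.

The sliding window is the method's defence against sequencing bias, and
raising `N_f` is its compensation mechanism for low coverage.

The package also ships the repeat-structured simulator used to validate the
method (interspersed, tandem and compound repeat designs with paired-end
fragments ~ Normal(300, 30)) and the repeat-aware evaluation suite: TRC
(repeat contigs emitted), CNRC (their copy numbers), NNC (nonrepeat contigs),
CN-accuracy `100 (1 - sum|c_est - c_true| / sum c_true)`, Rep-accuracy
`100 (1 - sum|L_a - L_true| / sum L_true)`, C-accuracy, N50/N90 against the
genome size, E-size `sum(l_c^2)/G`, and genome coverage, all based on
Smith-Waterman alignment back to the reference.

## Worked example

```r
library(swassembly)

# a 20 kb genome with one 1 kb repeat planted in 2 identical copies
genome <- make_genome(20000, list(repeat_family(copies = 2, unit_length = 1000)),
                      seed = 7)
reads  <- sample_reads(genome, L_r = 60, S_d = 4, seed = 8)   # 80,000 reads

params <- swa_params(S_d = 4, L_r = 60, L_w = 3, N_f = 1, interval_width = 10)
asm    <- swa_assemble(reads, params)
asm
#> Assembly: 4 contigs (1 repeat, 3 nonrepeat), 152 short contigs dropped
#>   repeat copy numbers: 2
#>   total length 19231, max 12921

evaluate(asm, genome)
#> Assembly evaluation
#>   TRC 1 | NNC 3 | Number C 4
#>   CNRC: 2
#>   N50 12921 | N90 1501 | mean 4807.8 | max 12921 | E-size 9605.0
#>   CN-accuracy 100.0% | Rep-accuracy 99.9% | C-accuracy 100.0%
#>   genome coverage 96.2%
```

The repeat was emitted as one contig with its copy number correctly estimated
as 2 (CN-accuracy 100%), the three flanking single-copy segments became the
three nonrepeat contigs, and every contig aligns back to the reference at
identity 1 (C-accuracy 100%).

A file-based pipeline with YAML/JSON configs is available through
`run_simulate()` / `run_assemble()` / `run_evaluate()` / `run_all()`, or from
a shell via the thin CLI at `inst/cli/swassembly`
(`swassembly all --config run.yaml`).

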