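# pkscan

H-type RNA pseudoknot prediction by syntactic pattern recognition, for
structural bioinformaticians who need the crossing-stem motif located in
short RNA sequences and a toolkit to evaluate such predictions.

An H-type pseudoknot is the simplest non-nested RNA fold: two helical stems
whose base pairs cross, `i1 < i2 < j1 < j2` with stem 1 pairing
`(i1, j1)` and stem 2 pairing `(i2, j2)`. pkscan:

1. **detects** all candidate core stems — either by parsing every sequence
   window with an ambiguous context-free grammar under an Earley chart
   parser, or by an equivalent brute-force scan (the two engines produce
   identical candidate sets);
2. **decorates** each core with contiguous stacked Watson-Crick pairs
   (optionally G-U) extending both stems outward;
3. **selects** the structure maximizing the pair count and, among those,
   minimizing the pseudoknot energy heuristic

   *G*<sub>pseudo</sub> = β₁ + β₂·B<sub>p</sub> + β₃·U<sub>p</sub>

   with defaults β₁ = 9.6, β₂ = β₃ = 0.1, B<sub>p</sub> the number of core
   stems and U<sub>p</sub> the unpaired bases inside the pseudoknot span;
4. **emits** extended dot-bracket notation (`[ ]` for stem 1, `( )` for
   stem 2) and provides per-base confusion metrics (PPV / recall / F1 /
   MCC), core-stem matching with one-position slippage, FASTA/CSV I/O, a
   CLI and a seeded planted-pseudoknot generator.

## Worked example

The 19-nt sequence `CCAUCGCCUGAUUUGAGGA` contains a pseudoknot whose core
stems are `(5,10)` (C-G) and `(9,16)` (U-A):

```r
library(pkscan)
p <- predict_structure(rna_sequence("CCAUCGCCUGAUUUGAGGA", "wx"))
print(p)
#> >wx (19 nt, bruteforce engine, 91 candidates)
#> CCAUCGCCUGAUUUGAGGA
#> ..[[[.(((]]]...))).
#> core stems (5,10)/(9,16), 6 pairs, G = 10.200
```

91 candidate cores are found; decoration extends the `(9,16)` stem with
pairs (8,17) and (7,18) and the `(5,10)` stem with (4,11) and (3,12), so
the winning structure has 6 pairs. Four bases inside the span (6, 13, 14,
15) stay unpaired, giving *G* = 9.6 + 0.1·2 + 0.1·4 = 10.2. The full
ranking is available as a stable CSV schema:

```r
head(candidates_table(rna_sequence("CCAUCGCCUGAUUUGAGGA", "wx")), 1)
#>  seq_id i1 i2 j1 j2 rule_id pair_count up g_pseudo         dot_bracket
#>      wx  1  3  6  9       2          3  4     10.2 [((..]..)).........
```

Evaluation reproduces published benchmark metrics from their confusion
counts:

```r
confusion_metrics(list(tp = 4212, tn = 4102, fp = 1162, fn = 1300))
#> PPV 0.784  recall 0.764  F1 0.774  MCC 0.543
```

## Command line

```sh
inst/cli/pkscan predict  --input seqs.fasta --engine bruteforce --max-gap 2 \
                         --workers 4 --csv-out candidates.csv
inst/cli/pkscan evaluate --pred pred.txt --ref ref.txt --bins "30,40,50"
inst/cli/pkscan generate --out fixtures.txt --n 100 --seed 7
```

(after installation: `$(Rscript -e 'cat(system.file("cli", "pkscan",
package = "pkscan"))')`). Option precedence is CLI flag > `--config`
JSON/YAML file > built-in default.

## Scope

Single H-type pseudoknot per sequence; no nested structure outside the
pseudoknot, no bulges/interior loops inside stems, no K/L/M-type folds.
See `vignettes/pseudoknot-methods.Rmd` for the model, parameter meanings,
design decisions and limitations.
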