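# Deposited DamID per-gene tables (not shipped)

The deposited-data benchmark in the test suite looks here for the
per-factor per-gene occupancy tables of the original study
(Mendeley Data, DOI 10.17632/czjj5m7btr.1), one TSV per chromatin
factor:

    polycomb.tsv   hp1a.tsv   polii.tsv

Each file must parse with `read_occupancy_tsv()`: per-gene replicate
log2(Dam-fusion/Dam) columns for control and mutant, a per-sample `fdr`
and a GATC-site count. The tables are too large to ship with the
package and are not redistributed; without them that one benchmark test
reports failure and every other test is unaffected.
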