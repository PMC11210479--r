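#!/usr/bin/env Rscript
# Build the synthetic stand-in cohort for the 31-protein study table and
# write its inputs (FASTA, per-domain hit table, reference annotations)
# plus the ground-truth table under results/cohort/.
suppressMessages(library(lpmominer))

co <- make_table1_cohort()
write_table1_fixtures("results/cohort", co)
cat(sprintf("built %d synthetic proteins (%d-%d aa), %d domain hits\n",
            nrow(co$records), min(nchar(co$records$residues)),
            max(nchar(co$records$residues)), nrow(co$hits)))
cat("files under results/cohort/: synthetic_table1_{lpmos.fasta,domtbl.txt,truth.tsv},",
    "synthetic_reference_annotations.tsv\n")
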