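#!/usr/bin/env Rscript
# Stage 3: key-residue conservation on the simulated family.
#
# Scores occupancy, percent identity (both denominators) and the
# substitution spectrum at each key site, overall and for the MAG subset,
# and exports sequence-logo matrices for the scored columns.

library(oxalotrace)

out <- "results/03_conservation"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

aln <- read_alignment("results/01_inputs/family.fasta",
                      meta = "results/01_inputs/family_meta.csv")
specs <- read_key_residues("results/01_inputs/key_residues.csv")
spec <- specs$demo

rep_all <- score_key_residues(aln, spec)
print(rep_all)
write_conservation_report(rep_all, file.path(out, "conservation_all.csv"))

rep_mag <- score_key_residues(aln, spec, record_class = "MAG")
write_conservation_report(rep_mag, file.path(out, "conservation_MAG.csv"))

cols <- map_reference_positions(aln, spec$reference_id)
lm <- logo_matrix(aln, columns = cols[as.character(spec$positions)])
write_logo_matrix(lm, file.path(out, "logo_key_columns.tsv"))

cat(sprintf(
  "site E-30 forced fully conserved: pid_occupied = %.3f (expected 1.0)\n",
  rep_all$pid_occupied[1]))
cat(sprintf(
  "MAG-only occupancy at R-150: %.2f (truncation lowers occupancy, not identity)\n",
  rep_mag$occupancy[3]))
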