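#!/usr/bin/env Rscript
# FG-motif valence accounting for the construct family: build the
# synthetic wild-type architecture (17 N-terminal + 21 C-terminal FG
# motifs, 3 + 6 of them GLFG), derive the mutants, and tabulate valence
# and N/Q/S/T composition per region.

suppressMessages(library(punctakit))
dir.create("results", showWarnings = FALSE)

wt <- generate_construct_sequence(17, 21, 3, 6, seed = 42)

variants <- list(
  wildtype = wt,
  mut_8FA = apply_mutations(wt, mutation_spec_for_motifs(wt, "cterm", "F>A", n = 8)),
  mut_21FGAA = apply_mutations(wt, mutation_spec_for_motifs(wt, "cterm", "FG>AA")),
  midi = protein_sequence("midi",
                          substr(wt$residues, wt$regions$cterm[1], wt$regions$cterm[2]))
)

nqst <- c("N", "Q", "S", "T")
rows <- lapply(names(variants), function(nm) {
  s <- variants[[nm]]
  data.frame(construct = nm,
             length = nchar(s$residues),
             fg = count_fg(s),
             glfg = count_glfg(s),
             nqst_fraction = round(composition_fraction(s, nqst), 4))
})
tab <- do.call(rbind, rows)
write_tables(tab, "results/fg_valence.csv")
print(tab, row.names = FALSE)

cat(sprintf("\nC-terminal region is the high-valence half: %d FG (%d GLFG) vs %d FG (%d GLFG) N-terminal\n",
            count_fg(wt, "cterm"), count_glfg(wt, "cterm"),
            count_fg(wt, "nterm"), count_glfg(wt, "nterm")))
write_fasta_sequences(variants, "results/constructs.fasta")
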