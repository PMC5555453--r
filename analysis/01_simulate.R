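#!/usr/bin/env Rscript
# Stage 1: generate the study's synthetic inputs.
#
# Two 500-kb regions emulate the comparison at the heart of the analysis:
# a repeat-dense, AT-biased "F-like" domain (per-class transposon densities
# LTR 42.1%, LINE 21.8%, RC/Helitron 7.3%, DNA 5.6%; codon GC3 target 0.30;
# bimodal intron mixture with ~70-bp and ~4.3-kb components) and a sparse,
# GC-biased "D-like" euchromatic reference (total transposon density 14.4%;
# GC3 0.65; mostly short introns). Codon-bias gene groups and ortholog
# pairs with known intron inflation complete the inputs.

suppressMessages(library(domainscape))
out <- "results/sim"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

f_cfg <- simulation_config(
  seed = 20170630, region_length = 500000L, seq_id = "f_like",
  gene_count = 25, gc_background = 0.38, gc3 = 0.30)
d_cfg <- simulation_config(
  seed = 20170631, region_length = 500000L, seq_id = "d_like",
  gene_count = 25, gc_background = 0.45, gc3 = 0.65,
  class_density = c(LTR = 0.040, LINE = 0.035, RC_Helitron = 0.026,
                    DNA = 0.043),
  intron_meanlog = c(log(65), log(500)))

message("simulating the repeat-dense (F-like) region ...")
f_sim <- simulate_region(f_cfg, file.path(out, "f_like"))
message("simulating the euchromatic reference (D-like) region ...")
d_sim <- simulate_region(d_cfg, file.path(out, "d_like"))

# merged inputs shared by the downstream stages
genome <- c(f_sim$genome, d_sim$genome)
Biostrings::writeXStringSet(genome, file.path(out, "genome.fa"))
keep <- function(p) grep("^#", readLines(p), invert = TRUE, value = TRUE)
writeLines(c("##gff-version 3", keep(f_sim$paths$gff3),
             keep(d_sim$paths$gff3)), file.path(out, "genes.gff3"))
write_repeatmasker_out(rbind(parse_repeatmasker_out(f_sim$paths$rm_out),
                             parse_repeatmasker_out(d_sim$paths$rm_out)),
                       file.path(out, "repeats.out"))
gr <- GenomicRanges::GRanges(c("f_like", "d_like"),
                             IRanges::IRanges(1, 500000L),
                             name = c("F_like", "D_like"))
rtracklayer::export(gr, file.path(out, "regions.bed"), format = "BED")

message("simulating codon-bias gene groups and the reference set ...")
cg <- simulate_codon_genes(f_cfg, file.path(out, "codon"))
message("simulating ortholog pairs with intron inflation x",
        f_cfg$ortholog_factor, " ...")
op <- simulate_ortholog_pairs(f_cfg, file.path(out, "orthologs"))

message("done: inputs under ", out)
message("  planted F-like total transposon density: ",
        round(sum(f_sim$truth$repeats$density), 3))
message("  planted D-like total transposon density: ",
        round(sum(d_sim$truth$repeats$density), 3))
message("  genes: ", nrow(f_sim$truth$genes), " + ",
        nrow(d_sim$truth$genes),
        "; codon genes: ", nrow(cg$truth),
        "; ortholog pairs: ", nrow(op$pairs))
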