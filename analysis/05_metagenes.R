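#!/usr/bin/env Rscript
# Stage 5: melting-temperature and enrichment metagenes.
#
# Builds the 9-bp sliding-window Tm metagene (3-kb standardized coding
# span, 2-kb flanks, position-wise median, OCV smoothing spline) for each
# region, then the log-likelihood enrichment metagene: the
# promoter-localized "active" signal against the body-localized
# "silencing" signal as control, mirroring a ChIP-vs-input comparison.

suppressMessages(library(domainscape))
sim <- "results/sim"
out <- "results/metagenes"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

genome <- Biostrings::readDNAStringSet(file.path(sim, "genome.fa"))
models <- read_gene_models(file.path(sim, "genes.gff3"))
by_region <- split(models, ifelse(vapply(models, function(m) m$seq_id,
                                         character(1)) == "f_like",
                                  "F_like", "D_like"))

for (reg in names(by_region)) {
  mg <- tm_metagene(by_region[[reg]], genome)
  write.table(mg, file.path(out, paste0("tm_", reg, ".tsv")), sep = "\t",
              quote = FALSE, row.names = FALSE)
  span <- mg$position >= 0 & mg$position <= 3000
  message(sprintf("%s: median span Tm %.2f C, median flank Tm %.2f C",
                  reg, median(mg$median[span], na.rm = TRUE),
                  median(mg$median[!span], na.rm = TRUE)))
}

for (reg_dir in c(F_like = "f_like", D_like = "d_like")) {
  reg <- names(which(c(F_like = "f_like", D_like = "d_like") == reg_dir))
  active <- read_bedgraph(file.path(sim, reg_dir, "signal_active.bedgraph"))
  body <- read_bedgraph(file.path(sim, reg_dir, "signal_body.bedgraph"))
  llr <- loglik_enrichment(active, body, pseudocount = 1e-5)
  write_bedgraph(llr, file.path(out, paste0("llr_active_vs_body_",
                                            reg, ".bedgraph")))
  mods <- by_region[[reg]]
  mg_a <- signal_metagene(active, mods)
  mg_s <- signal_metagene(body, mods)
  write.table(mg_a, file.path(out, paste0("active_", reg, ".tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(mg_s, file.path(out, paste0("silencing_", reg, ".tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  message(sprintf("%s: active-signal metagene peaks at position %+d",
                  reg, mg_a$position[which.max(mg_a$median)]))
}
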