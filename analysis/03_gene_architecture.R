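#!/usr/bin/env Rscript
# Stage 3: gene architecture.
#
# Selects the most comprehensive isoform per gene, computes coding-span
# metrics, partitions each region into coding/intronic/intergenic space,
# and builds ortholog difference records (species A minus species B) from
# the simulated pairs with known intron inflation.

suppressMessages(library(domainscape))
sim <- "results/sim"
out <- "results/genes"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

models <- read_gene_models(file.path(sim, "genes.gff3"))
metrics <- gene_metrics_table(models)
metrics$region <- ifelse(startsWith(metrics$gene_id, "f_like"), "F_like",
                         "D_like")
write.table(metrics, file.path(out, "gene_metrics.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
med <- aggregate(cbind(coding_span_size, total_intron_size, total_cds_size,
                       cds_count) ~ region, metrics, median)
message("median gene architecture per region:")
print(med, row.names = FALSE)

regions <- read_regions_bed(file.path(sim, "regions.bed"))
parts <- do.call(rbind, lapply(regions, function(r) {
  keep <- models[vapply(models, function(m)
    (m$seq_id == "f_like") == (r$name == "F_like"), logical(1))]
  p <- partition_regions(keep, r)
  data.frame(region = r$name, space = names(p$bp), bp = as.numeric(p$bp),
             fraction = round(as.numeric(p$bp) / r$total_bp, 4))
}))
write.table(parts, file.path(out, "partitions.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

# ortholog differences (A = inflated-intron species is B here, so the
# record is reported as B minus A to match "expanded minus compact")
ma <- read_gene_models(file.path(sim, "orthologs", "species_a.gff3"))
mb <- read_gene_models(file.path(sim, "orthologs", "species_b.gff3"))
met_a <- gene_metrics_table(ma)
met_b <- gene_metrics_table(mb)
pairs <- read.table(file.path(sim, "orthologs", "pairs.tsv"), header = TRUE,
                    sep = "\t", stringsAsFactors = FALSE)
diffs <- do.call(rbind, lapply(seq_len(nrow(pairs)), function(i)
  ortholog_difference(met_b[met_b$gene_id == pairs$gene_b[i], ],
                      met_a[met_a$gene_id == pairs$gene_a[i], ])))
write.table(diffs, file.path(out, "ortholog_differences.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
message(sprintf(paste0("ortholog differences (expanded - compact): median ",
                       "span %+d bp, median total intron %+d bp, ",
                       "median total CDS %+d bp"),
                round(median(diffs$d_coding_span_size)),
                round(median(diffs$d_total_intron_size)),
                round(median(diffs$d_total_cds_size))))
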