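#!/usr/bin/env Rscript
# Stage 6: cross-region statistics.
#
# Kruskal-Wallis tests with Dunn post hoc (Holm step-down) on the gene
# architecture and codon-bias metrics across the two regions, at
# alpha = 0.05; results collected into one comparisons table.

suppressMessages(library(domainscape))
out <- "results/stats"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

metrics <- read.table("results/genes/gene_metrics.tsv", header = TRUE,
                      sep = "\t", stringsAsFactors = FALSE)
bias <- read.table("results/codons/codon_bias.tsv", header = TRUE,
                   sep = "\t", stringsAsFactors = FALSE)

rows <- list()
compare <- function(values, groups, name) {
  keep <- !is.na(values)
  gl <- split(values[keep], groups[keep])
  res <- dunn_holm(gl, alpha = 0.05)
  message(sprintf("%-20s KW p = %.3g%s", name, res$kw$p_value,
                  if (res$performed) "" else "  (post hoc not run)"))
  if (res$performed && nrow(res$pairs)) {
    cbind(metric = name, res$pairs, kw_p = res$kw$p_value)
  } else {
    data.frame(metric = name, group_a = NA, group_b = NA, z = NA,
               p_value = NA, adj_p = NA, reject = NA,
               kw_p = res$kw$p_value)
  }
}
for (m in c("coding_span_size", "total_intron_size", "total_cds_size",
            "cds_count", "median_cds_size", "median_intron_size")) {
  rows[[m]] <- compare(metrics[[m]], metrics$region, m)
}
for (m in c("Nc", "CAI", "GC3")) {
  rows[[m]] <- compare(bias[[m]], bias$region, m)
}
tab <- do.call(rbind, c(rows, make.row.names = FALSE))
write.table(tab, file.path(out, "comparisons.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
message("wrote ", file.path(out, "comparisons.tsv"))
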