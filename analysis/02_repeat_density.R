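#!/usr/bin/env Rscript
# Stage 2: repeat-density accounting.
#
# Parses the RepeatMasker-style annotation, merges fragments with the
# class-conflict ("Overlapping") rule, reports per-class densities per
# region and the top-10 repeat tables, then demonstrates the
# foreign-match forensics: a set of "foreign assembly" matches is built by
# resampling planted transposon intervals (plus random background), and
# overlap attribution shows the matches are mostly transposon remnants.

suppressMessages(library(domainscape))
sim <- "results/sim"
out <- "results/repeats"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
set.seed(2)

feats <- parse_repeatmasker_out(file.path(sim, "repeats.out"))
regions <- read_regions_bed(file.path(sim, "regions.bed"))
segs <- merge_by_class(feats)

dens <- do.call(rbind, lapply(regions, function(r) {
  d <- class_density(segs, r)
  data.frame(region = r$name, class = c(names(d$densities), "total"),
             density = round(c(d$densities, d$total), 4))
}))
write.table(dens, file.path(out, "densities.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
message("per-class transposon densities:")
print(dens, row.names = FALSE)

tops <- do.call(rbind, lapply(regions, function(r)
  cbind(region = r$name, top_repeat_table(feats, r, n = 10))))
write.table(tops, file.path(out, "top_repeats.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

# foreign-match attribution demo on the repeat-dense region
f_feats <- feats[feats$seq_id == "f_like", ]
planted <- f_feats[sample.int(nrow(f_feats), 40), c("seq_id", "start", "end")]
bg_start <- sample.int(499000L, 15)
query <- rbind(
  data.frame(seq_id = planted$seq_id,
             start = planted$start + sample(0:50, nrow(planted), TRUE),
             end = pmax(planted$start + 60,
                        planted$end - sample(0:50, nrow(planted), TRUE))),
  data.frame(seq_id = "f_like", start = bg_start, end = bg_start + 400L))
query <- cbind(query, strand = "+", repeat_name = "foreign_match",
               raw_class = "Other", canonical_class = "Other",
               score = 300, overridden = FALSE)
attr_res <- overlap_attribution(query, f_feats)
message(sprintf("foreign matches overlapping annotated transposons: %.1f%%",
                100 * attr_res$fraction))
write.table(attr_res$per_name, file.path(out, "attribution.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

cov <- coverage_track(query[, c("seq_id", "start", "end")],
                      c(f_like = 500000L))
message("max alignment coverage on the F-like region: ",
        cov$f_like$max_coverage)
write_bedgraph(cov, file.path(out, "foreign_coverage.bedgraph"))
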