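#!/usr/bin/env Rscript
# Stage 2: pairwise K2P divergences, clade summaries, barcoding gap,
# 4x criterion, de novo threshold clusters and the bathymetric break.
# Reads the stage-1 outputs; writes per-marker tables under results/.

library(bathydelim)

indir <- "results/synthetic"
outdir <- "results/delimitation"
dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

md <- read_metadata(file.path(indir, "metadata.tsv"))
truth <- read_partition(file.path(indir, "partition.tsv"))

for (mk in c("COI", "16S", "28S")) {
  aln <- read_fasta(file.path(indir, paste0(mk, ".fasta")), marker = mk)
  dm <- distance_matrix(aln, model = "K2P", on_saturation = "mask")
  s <- intra_inter_summary(dm, truth)
  utils::write.table(s, file.path(outdir, paste0(mk, "_clade_divergences.tsv")),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  gap <- barcoding_gap(dm, truth)
  fx <- four_x(dm, truth)
  cat(sprintf("%s: max intra %.1f%%, min inter %.1f%%, gap %s, 4x %s\n",
              mk, 100 * gap$max_intra, 100 * gap$min_inter,
              ifelse(isTRUE(gap$gap_present), "present", "absent"),
              ifelse(fx$global_pass, "pass", "FAIL")))
  if (mk == "COI" && isTRUE(gap$gap_present)) {
    prop <- threshold_clusters(dm, mean(gap$gap_interval))
    write_partition(prop, file.path(outdir, "COI_proposed_clusters.tsv"))
    cat(sprintf("  COI threshold clustering at %.4f -> %d clades (%s truth)\n",
                mean(gap$gap_interval), length(unique(prop)),
                compare_partitions(prop, truth)$relation))
  }
}

db <- depth_break(truth, md)
cat(sprintf("Depth break: %s", paste(capture.output(print(db)), "\n")))
jsonlite::write_json(list(interval = db$interval,
                          clade_depths = db$clade_depths),
                     file.path(outdir, "depth_break.json"),
                     auto_unbox = TRUE, digits = NA)
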