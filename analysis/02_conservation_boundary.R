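#!/usr/bin/env Rscript
# Sliding-window conservation profile of a synthetic promoter alignment
# whose conservation is confined to the proximal ~250 bp, and the
# conserved-block/boundary calls that partition proximal from distal
# promoter (window 20 bp, threshold 70%, max gap 50 bp).

library(cisrobust)

dir.create("results", showWarnings = FALSE)
set.seed(1)

total_bp <- 1200; conserved_bp <- 250
ref <- sample(c("A", "C", "G", "T"), total_bp, replace = TRUE)
other <- sample(c("A", "C", "G", "T"), total_bp, replace = TRUE)
core <- (total_bp - conserved_bp + 1):total_bp       # 3' end abuts the ATG
other[core] <- ref[core]
mm <- core[seq(20, conserved_bp, by = 40)]           # sparse mismatches
other[mm] <- vapply(ref[mm],
                    function(b) setdiff(c("A", "C", "G", "T"), b)[1], "")

afa <- tempfile(fileext = ".afa")
writeLines(c(">cel", paste(ref, collapse = ""),
             ">cbr", paste(other, collapse = "")), afa)
aln <- read_alignment(afa)

prof <- sliding_identity(aln, "cel", window = 20, step = 1)
write.table(as.data.frame(prof), "results/conservation_profile.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

blocks <- call_blocks(prof, threshold = 0.70)
up <- upstream_coords(blocks, total_bp)
write_bed(genomic_intervals(rep("promoter", nrow(up)), up$start, up$end,
                            name = sprintf("block%d", seq_len(nrow(up))),
                            score = round(up$mean_identity, 3)),
          "results/conserved_blocks_upstream.bed")

bc <- call_boundary(up, max_gap = 50)
cat(sprintf("conserved blocks called: %d; proximal cluster: %d\n",
            nrow(up), nrow(bc$blocks_proximal)))
cat(sprintf("proximal/distal boundary: %d bp upstream of the ATG\n",
            bc$boundary_pos))
writeLines(sprintf("boundary_upstream_bp\t%d", bc$boundary_pos),
           "results/boundary_call.tsv")
stopifnot(bc$found, bc$boundary_pos >= 230, bc$boundary_pos <= 270)
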