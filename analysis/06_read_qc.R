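#!/usr/bin/env Rscript
# Long-read QC statistics: mean-quality filtering with end cropping, N50,
# and the insertion/deletion/mismatch decomposition of alignment error
# rates, demonstrated on simulated reads and alignments.

suppressPackageStartupMessages(library(triosv))

set.seed(20240907)
# read lengths: log-normal centred so the N50 lands in the tens of kb
lengths <- round(rlnorm(5000, log(15000), 0.8))
quals <- runif(5000, 4, 14)
reads <- data.frame(read_id = sprintf("r%04d", 1:5000),
                    length = lengths, mean_quality = quals)
kept <- filter_and_crop(reads)
cat(sprintf("filtering: %d of %d reads pass mean Q > 6 and 200 bp crop\n",
            nrow(kept), nrow(reads)))
cat(sprintf("N50 before filtering: %.1f kb; after: %.1f kb\n",
            n50(reads$length) / 1e3, n50(kept$length) / 1e3))

# alignment error profile at the study's per-base rates (2.2/3.5/2.2%)
d <- simulate_read_alignments(200, read_length = 8000, ins_rate = 0.022,
                              del_rate = 0.035, mism_rate = 0.022,
                              seed = 20240908)
ep <- alignment_error_profile(d)
cat(sprintf("median error rates: insertion %.2f%%, deletion %.2f%%, mismatch %.2f%% (total %.2f%%)\n",
            100 * ep$median[["insertion_rate"]],
            100 * ep$median[["deletion_rate"]],
            100 * ep$median[["mismatch_rate"]],
            100 * ep$median[["total_rate"]]))

out <- data.frame(metric = c("n_reads_in", "n_reads_kept", "n50_raw_bp",
                             "n50_kept_bp", "insertion_pct", "deletion_pct",
                             "mismatch_pct", "total_pct"),
                  value = c(nrow(reads), nrow(kept), n50(reads$length),
                            n50(kept$length),
                            round(100 * ep$median[["insertion_rate"]], 3),
                            round(100 * ep$median[["deletion_rate"]], 3),
                            round(100 * ep$median[["mismatch_rate"]], 3),
                            round(100 * ep$median[["total_rate"]], 3)))
write.table(out, "results/read_qc.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("wrote results/read_qc.tsv\n")
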