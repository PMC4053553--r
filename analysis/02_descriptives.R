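#!/usr/bin/env Rscript
# Stage 2: descriptive small-area statistics from the files stage 1
# wrote: per-condition admission totals, crude regional rates, EQ5-95 and
# EB variation statistics, pairwise SHR correlations, and Moran's I of
# the raw log-SHR surface of each condition.

suppressPackageStartupMessages(library(pphmap))

in_dir <- file.path("results", "synthetic")
out_dir <- file.path("results", "descriptives")
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

tab <- read_stratum_table(file.path(in_dir, "counts.csv"))
graph <- read_adjacency_gal(file.path(in_dir, "adjacency.gal"))
acd <- assemble(tab, graph)

vs <- variation_stats(tab, graph)
write.csv(vs, file.path(out_dir, "condition_summary.csv"),
          row.names = FALSE)
cat("condition summary (n, rate /1e5 py, EQ5-95, EB):\n")
print(vs, digits = 3)

shr_mat <- acd$observed / acd$expected
cors <- shr_correlations(shr_mat)
pairs <- which(upper.tri(cors$r), arr.ind = TRUE)
cor_tab <- data.frame(
  condition_a = acd$conditions[pairs[, 1]],
  condition_b = acd$conditions[pairs[, 2]],
  r = cors$r[pairs],
  p_value = cors$p_value[pairs])
write.csv(cor_tab, file.path(out_dir, "shr_correlations.csv"),
          row.names = FALSE)
cat(sprintf("\nmean pairwise SHR correlation: %.2f (range %.2f to %.2f)\n",
            mean(cor_tab$r), min(cor_tab$r), max(cor_tab$r)))

mor <- do.call(rbind, lapply(seq_along(acd$conditions), function(j) {
  m <- morans_i(log(pmax(shr_mat[, j], 0.5 / acd$expected[, j])),
                graph, n_permutations = 999, seed = 100 + j)
  data.frame(condition = acd$conditions[j], morans_i = m$i_statistic,
             p_value = m$p_value)
}))
write.csv(mor, file.path(out_dir, "morans_i_raw_shr.csv"),
          row.names = FALSE)
cat("\nMoran's I of raw log-SHR surfaces:\n")
print(mor, digits = 3)

write_manifest(file.path(out_dir, "manifest.json"),
               stage = "descriptives", inputs = in_dir)
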