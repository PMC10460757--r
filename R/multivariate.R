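# Cohort-level structure of the 10-parameter physiologic space:
# complete-case pooling, z-scaling, agglomerative hierarchical clustering
# of the parameter columns with cophenetic validation, and PCA.

cohort_params <- c("ABP", "ICP", "CPP", "rSO2", "PRx", "PAx", "RAC",
                   "AMP", "COx", "COx_a")

#' Pool minute-by-minute tables into a complete-case cohort matrix
#'
#' Concatenates the minute observations of all subjects over the 10
#' physiologic parameters (ABP, ICP, CPP, rSO2, PRx, PAx, RAC, AMP, COx,
#' COx_a) and removes every row with any missing parameter, yielding a
#' fully populated matrix.
#'
#' @param minutely_list List of `cvr_minutely` tables (one per subject).
#' @return A `cvr_cohort_matrix`: numeric matrix (rows = complete minute
#'   observations, columns = the 10 parameters) with a `dropped` attribute
#'   counting incomplete rows per subject.
#' @export
build_cohort_matrix <- function(minutely_list) {
  if (!length(minutely_list)) stop("need at least one subject", call. = FALSE)
  col_map <- c(ABP = "abp", ICP = "icp", CPP = "cpp", rSO2 = "rso2",
               PRx = "prx", PAx = "pax", RAC = "rac", AMP = "amp",
               COx = "cox", COx_a = "cox_a")
  pieces <- vector("list", length(minutely_list))
  dropped <- integer(length(minutely_list))
  ids <- character(length(minutely_list))
  for (i in seq_along(minutely_list)) {
    mt <- minutely_list[[i]]
    ids[i] <- attr(mt, "subject_id") %||% as.character(i)
    m <- as.matrix(mt[, col_map, drop = FALSE])
    colnames(m) <- names(col_map)
    keep <- stats::complete.cases(m)
    dropped[i] <- sum(!keep)
    pieces[[i]] <- m[keep, , drop = FALSE]
  }
  out <- do.call(rbind, pieces)
  if (!nrow(out))
    stop("no complete minute observations across the cohort", call. = FALSE)
  names(dropped) <- ids
  attr(out, "dropped") <- dropped
  attr(out, "subject") <- rep(ids, vapply(pieces, nrow, integer(1)))
  class(out) <- c("cvr_cohort_matrix", class(out))
  out
}

#' Z-scale each parameter over the entire cohort
#'
#' Centres each column to mean zero and scales to sample standard
#' deviation one, storing the centres and scales for inverse transforms.
#'
#' @param m Numeric matrix (e.g. a `cvr_cohort_matrix`).
#' @return A `cvr_scaled` list: `x` (scaled matrix), `center`, `scale`.
#' @export
scale_columns <- function(m) {
  m <- unclass(m)
  attr(m, "dropped") <- NULL
  attr(m, "subject") <- NULL
  sds <- apply(m, 2, stats::sd)
  if (any(sds == 0 | !is.finite(sds)))
    stop("constant column(s): ",
         paste(colnames(m)[sds == 0 | !is.finite(sds)], collapse = ", "),
         call. = FALSE)
  x <- scale(m)
  structure(list(x = x[, , drop = FALSE],
                 center = attr(x, "scaled:center"),
                 scale = attr(x, "scaled:scale")),
            class = "cvr_scaled")
}

#' Agglomerative hierarchical clustering of the physiologic parameters
#'
#' Computes Euclidean distances between the scaled parameter column
#' vectors and agglomerates them by complete linkage. The cophenetic
#' correlation coefficient (Pearson correlation between the original and
#' the dendrogram-implied pairwise distances) quantifies the goodness of
#' fit of the hierarchy.
#'
#' @param s A `cvr_scaled` object.
#' @return A `cvr_cluster` list: `hclust` (merge history and heights),
#'   `dist` (original distances), `cophenetic` (cophenetic distances),
#'   `coph_cor` (cophenetic correlation coefficient).
#' @export
cluster_parameters <- function(s) {
  stopifnot(inherits(s, "cvr_scaled"))
  if (ncol(s$x) < 3) stop("need at least 3 parameters", call. = FALSE)
  d <- stats::dist(t(s$x), method = "euclidean")
  hc <- stats::hclust(d, method = "complete")
  coph <- stats::cophenetic(hc)
  structure(list(hclust = hc, dist = d, cophenetic = coph,
                 coph_cor = stats::cor(as.vector(d), as.vector(coph))),
            class = "cvr_cluster")
}

#' @export
print.cvr_cluster <- function(x, ...) {
  cat("Complete-linkage clustering of", length(x$hclust$labels),
      "physiologic parameters\n")
  cat(sprintf("  cophenetic correlation: %.4f\n", x$coph_cor))
  invisible(x)
}

#' Principal component analysis of the scaled parameter matrix
#'
#' Singular-value decomposition of the z-scaled cohort matrix (equivalent
#' to an eigen-decomposition of the parameter correlation matrix).
#' Loadings are sign-fixed so the largest-magnitude loading of each
#' component is positive; biplot coordinates are loadings scaled by the
#' square root of the eigenvalue.
#'
#' @param s A `cvr_scaled` object.
#' @return A `cvr_pca` list: `eigenvalues` (descending), `var_frac`,
#'   `cum_var`, `loadings` (parameters x components), `scores`, `biplot`
#'   (parameters x 2).
#' @export
run_pca <- function(s) {
  stopifnot(inherits(s, "cvr_scaled"))
  if (nrow(s$x) <= ncol(s$x))
    stop("need more observations than parameters", call. = FALSE)
  pc <- stats::prcomp(s$x, center = FALSE, scale. = FALSE)
  eig <- pc$sdev^2
  load <- pc$rotation
  scores <- pc$x
  # sign convention: largest |loading| of each component is positive
  for (j in seq_len(ncol(load))) {
    k <- which.max(abs(load[, j]))
    if (load[k, j] < 0) {
      load[, j] <- -load[, j]
      scores[, j] <- -scores[, j]
    }
  }
  structure(list(
    eigenvalues = eig,
    var_frac = eig / sum(eig),
    cum_var = cumsum(eig) / sum(eig),
    loadings = load,
    scores = scores,
    biplot = sweep(load[, 1:2, drop = FALSE], 2, sqrt(eig[1:2]), `*`)
  ), class = "cvr_pca")
}

#' @export
print.cvr_pca <- function(x, ...) {
  cat("PCA of the scaled physiologic parameter matrix\n")
  cat(sprintf("  PC1 %.1f%%, PC2 %.1f%% (cumulative %.1f%%)\n",
              100 * x$var_frac[1], 100 * x$var_frac[2], 100 * x$cum_var[2]))
  invisible(x)
}

#' Pairwise proximity summary of clustering and PCA results
#'
#' Reports, for every parameter pair, the cophenetic distance and the
#' angle between their PC1/PC2 biplot vectors, and flags whether the five
#' reactivity indices (PRx, PAx, RAC, COx, COx_a) co-cluster — i.e. merge
#' among themselves at a lower height than any of them joins a raw
#' physiologic parameter (ABP, ICP, CPP, rSO2, AMP).
#'
#' @param cl A `cvr_cluster` result.
#' @param pca The matching `cvr_pca` result.
#' @param index_params Names of the reactivity-index leaves.
#' @return List: `pairs` (data frame parameter_1, parameter_2,
#'   cophenetic_distance, biplot_angle_deg), `indices_co_cluster`
#'   (logical), `max_within_index`, `min_index_to_other`.
#' @export
proximity_report <- function(cl, pca,
                             index_params = c("PRx", "PAx", "RAC",
                                              "COx", "COx_a")) {
  stopifnot(inherits(cl, "cvr_cluster"), inherits(pca, "cvr_pca"))
  labs <- cl$hclust$labels
  if (!setequal(labs, rownames(pca$loadings)))
    stop("clustering and PCA cover different parameter sets", call. = FALSE)
  cm <- as.matrix(cl$cophenetic)
  bp <- pca$biplot[labs, , drop = FALSE]
  ang <- function(u, v) {
    c_ <- sum(u * v) / sqrt(sum(u^2) * sum(v^2))
    acos(pmin(1, pmax(-1, c_))) * 180 / pi
  }
  pr <- t(utils::combn(labs, 2))
  pairs <- data.frame(
    parameter_1 = pr[, 1], parameter_2 = pr[, 2],
    cophenetic_distance = cm[pr],
    biplot_angle_deg = apply(pr, 1, function(p) ang(bp[p[1], ], bp[p[2], ]))
  )
  idx <- intersect(index_params, labs)
  oth <- setdiff(labs, idx)
  max_within <- max(cm[idx, idx])
  min_cross <- min(cm[idx, oth])
  list(pairs = pairs,
       indices_co_cluster = max_within < min_cross,
       max_within_index = max_within,
       min_index_to_other = min_cross)
}
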