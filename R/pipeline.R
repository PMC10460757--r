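# End-to-end pipeline: raw recordings -> filtered/decimated frames ->
# reactivity indices -> cohort clustering/PCA and VAR/IRF/Granger
# dynamics, with every artifact written as CSV plus a JSON run manifest.

#' Run the full analysis pipeline on a cohort
#'
#' Executes, in order: physiologic artifact filtering, ICP pulse-amplitude
#' derivation, 10-s decimation with CPP, minute-by-minute reactivity
#' indices, the pooled complete-case cohort matrix with z-scaling,
#' complete-linkage clustering with cophenetic validation and PCA, and —
#' on the 10-s tri-variate series — gap interpolation, stationarity
#' screening, first differencing, AIC order selection, the pooled cohort
#' VAR with orthogonal IRFs, and per-subject Granger tests. All outputs
#' are written under `out_dir` and listed in a JSON manifest.
#'
#' @param subjects List of `cvr_subject` or `cvr_recording` objects.
#' @param config A [pipeline_config()].
#' @param out_dir Output directory.
#' @param verbose Emit per-stage progress messages.
#' @return Invisibly, the manifest list (also written as
#'   `manifest.json`): per-stage row accounting and output file paths.
#' @export
run_pipeline <- function(subjects, config = pipeline_config(),
                         out_dir = tempfile("cvreact_run_"),
                         verbose = TRUE) {
  stopifnot(inherits(config, "cvr_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (verbose) message(sprintf(...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  files <- character(0)
  accounting <- list()

  recs <- lapply(subjects, function(s)
    if (inherits(s, "cvr_subject")) s$recording else s)
  n_sub <- length(recs)
  say("pipeline: %d subject(s) -> %s", n_sub, out_dir)

  minutely <- list(); tri <- list(); removed_all <- list()
  for (i in seq_len(n_sub)) {
    rec <- recs[[i]]
    id <- rec$subject_id
    flt <- stage("filter", apply_artifact_filters(
      rec, abp_min = config$abp_min, abp_max = config$abp_max,
      icp_max = config$icp_max, rso2_min = config$rso2_min))
    removed_all[[id]] <- flt$removed
    dec <- stage("decimate", decimate_10s(
      flt$recording, bin_s = config$decimate_s,
      min_frac = config$min_pair_frac))
    idx <- stage("indices", derive_indices(
      dec, window_s = config$window_s, update_s = config$update_s,
      min_pairs = as.integer(config$min_pair_frac * config$window_s /
                               config$decimate_s)))
    mt <- stage("minutely", export_minutely(dec, idx))
    minutely[[i]] <- mt
    tri[[i]] <- tri_series(dec)
    files <- c(files,
               write_table_csv(dec, file.path(out_dir,
                                              paste0(id, "_10s.csv"))),
               write_table_csv(mt, file.path(out_dir,
                                             paste0(id, "_minutely.csv"))))
    say("  %s: removed %s; %d bins, %d minutes", id,
        paste(names(flt$removed), flt$removed, collapse = " "),
        nrow(dec), nrow(mt))
  }

  # cohort parameter-space structure
  cm <- stage("cohort_matrix", build_cohort_matrix(minutely))
  say("cohort matrix: %d complete minutes (%d dropped)", nrow(cm),
      sum(attr(cm, "dropped")))
  accounting$cohort_rows <- nrow(cm)
  accounting$dropped_rows <- as.list(attr(cm, "dropped"))
  sc <- stage("scale", scale_columns(cm))
  cl <- stage("cluster", cluster_parameters(sc))
  pca <- stage("pca", run_pca(sc))
  prox <- stage("proximity", proximity_report(cl, pca))
  say("clustering: cophenetic correlation %.3f; PC1+PC2 %.1f%%",
      cl$coph_cor, 100 * pca$cum_var[2])

  files <- c(files, file.path(out_dir, "dendrogram.nwk"))
  writeLines(dendrogram_newick(cl$hclust),
             file.path(out_dir, "dendrogram.nwk"))
  mh <- cl$hclust
  files <- c(files, write_table_csv(
    data.frame(step = seq_len(nrow(mh$merge)), left = mh$merge[, 1],
               right = mh$merge[, 2], height = mh$height),
    file.path(out_dir, "cluster_merges.csv")))
  files <- c(files, write_table_csv(
    data.frame(component = seq_along(pca$eigenvalues),
               eigenvalue = pca$eigenvalues, var_frac = pca$var_frac,
               cum_var = pca$cum_var),
    file.path(out_dir, "pca_scree.csv")))
  ld <- as.data.frame(pca$loadings)
  ld <- cbind(parameter = rownames(pca$loadings), ld)
  files <- c(files, write_table_csv(ld,
                                    file.path(out_dir,
                                              "pca_loadings.csv")))

  # tri-variate dynamics on the 10-s grid
  stat_rows <- list(); granger_rows <- list(); diffed <- list()
  for (i in seq_len(n_sub)) {
    id <- attr(tri[[i]], "subject_id")
    ts <- stage("interpolate", interpolate_gaps(tri[[i]]))
    pre <- stage("stationarity", test_stationarity(ts, config$alpha))
    dts <- stage("difference", difference_series(ts))
    post <- stage("stationarity", test_stationarity(dts, config$alpha))
    pre$phase <- "raw"; post$phase <- "differenced"
    pre$subject_id <- post$subject_id <- id
    stat_rows[[i]] <- rbind(pre, post)
    diffed[[i]] <- dts
    g <- stage("granger", granger_pairs(dts))
    g$subject_id <- id
    granger_rows[[i]] <- g
  }
  files <- c(files, write_table_csv(do.call(rbind, stat_rows),
                                    file.path(out_dir,
                                              "stationarity.csv")))
  files <- c(files, write_table_csv(do.call(rbind, granger_rows),
                                    file.path(out_dir, "granger.csv")))

  ord <- stage("order_selection",
               select_var_order(pool_for_order(diffed),
                                orders = config$var_orders))
  say("AIC order selection: minimiser %d, elbow %d", ord$order_aic,
      ord$order_elbow)
  files <- c(files, write_table_csv(ord$aic_table,
                                    file.path(out_dir, "aic_order.csv")))

  vm <- stage("var", fit_cohort_var(diffed, p = config$chosen_order))
  irf <- stage("irf", orthogonal_irf(vm, impulse = "abp",
                                     horizon = config$irf_horizon,
                                     boot = config$boot,
                                     seed = config$boot_seed))
  irf_tab <- do.call(rbind, lapply(names(irf$responses), function(nm) {
    d <- irf$responses[[nm]]
    d$impulse <- "abp"; d$response <- nm
    d
  }))
  files <- c(files, write_table_csv(irf_tab,
                                    file.path(out_dir, "irf_cohort.csv")))

  manifest <- list(
    package = "cvreact",
    r_version = as.character(getRversion()),
    config = unclass(config),
    n_subjects = n_sub,
    subjects = vapply(recs, function(r) r$subject_id, character(1)),
    removed_samples = removed_all,
    accounting = accounting,
    order_selection = list(order_aic = ord$order_aic,
                           order_elbow = ord$order_elbow),
    cophenetic_correlation = cl$coph_cor,
    pc12_cum_var = pca$cum_var[2],
    indices_co_cluster = prox$indices_co_cluster,
    outputs = basename(files)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  manifest$out_dir <- out_dir
  say("pipeline complete: %d output files", length(files) + 1L)
  invisible(manifest)
}

# longest single-subject series for AIC order selection: AIC values must
# come from one contiguous estimation sample
pool_for_order <- function(diffed) {
  lens <- vapply(diffed, nrow, integer(1))
  diffed[[which.max(lens)]]
}

# hclust -> Newick with branch lengths derived from merge heights
dendrogram_newick <- function(hc) {
  n <- length(hc$labels)
  node <- function(i, parent_h) {
    if (i < 0) {                            # leaf
      sprintf("%s:%.6f", hc$labels[-i], parent_h)
    } else {
      h <- hc$height[i]
      sprintf("(%s,%s):%.6f", node(hc$merge[i, 1], h),
              node(hc$merge[i, 2], h), parent_h - h)
    }
  }
  top <- nrow(hc$merge)
  h <- hc$height[top]
  sprintf("(%s,%s);", node(hc$merge[top, 1], h), node(hc$merge[top, 2], h))
}
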