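#' Configure a pipeline run
#'
#' Exactly one input source must be given: file paths (`kinetics`,
#' `conditions`, optionally `strains`) or a synthetic study spec.
#'
#' @param kinetics,conditions,strains Paths to input tables (long kinetics,
#'   condition table, optional strain metadata).
#' @param synthetic A `pm_synth_spec` ([synthetic_spec()]); mutually
#'   exclusive with file inputs.
#' @param reference_id Reference strain for the log-ratio matrix.
#' @param w_max Smoothing window cap (odd, default 25 points).
#' @param eps Minimum usable control signal for %RSI (units, default 1).
#' @param clip Log-ratio clipping bound (default 3).
#' @param k_sensitive,k_tolerant Extremes labelled per ranking (5 / 10).
#' @param outdir Output directory (created if needed).
#' @param seed Seed recorded in the manifest (the synthetic spec carries its
#'   own seed; for file inputs the run is deterministic anyway).
#' @return A `pm_config` list.
#' @export
pm_config <- function(kinetics = NULL, conditions = NULL, strains = NULL,
                      synthetic = NULL, reference_id = "S288C",
                      w_max = 25L, eps = 1, clip = 3.0,
                      k_sensitive = 5L, k_tolerant = 10L,
                      outdir = tempfile("pmrun"), seed = 1L) {
  file_mode <- !is.null(kinetics) || !is.null(conditions)
  if (file_mode == !is.null(synthetic))
    stop("give either input file paths or a synthetic spec, not both")
  if (file_mode && (is.null(kinetics) || is.null(conditions)))
    stop("file input needs both kinetics and conditions paths")
  if (!is.null(synthetic)) stopifnot(inherits(synthetic, "pm_synth_spec"))
  stopifnot(w_max >= 1, w_max %% 2 == 1, eps >= 0, clip > 0,
            k_sensitive >= 0, k_tolerant >= 0)
  structure(list(kinetics = kinetics, conditions = conditions,
                 strains = strains, synthetic = synthetic,
                 reference_id = reference_id, w_max = as.integer(w_max),
                 eps = eps, clip = clip,
                 k_sensitive = as.integer(k_sensitive),
                 k_tolerant = as.integer(k_tolerant),
                 outdir = outdir, seed = as.integer(seed)),
            class = "pm_config")
}

#' Run the full stress-tolerance profiling pipeline
#'
#' read/simulate -> baseline transform -> monotone smoothing -> replicate
#' averaging -> %RSI scoring -> per-condition ranking and classification ->
#' log2-ratio matrix vs the reference strain -> centred-Pearson UPGMA
#' clustering -> TSV / CDT / GTR / Newick outputs plus a run manifest.
#' Re-running with an identical configuration reproduces every text output
#' byte for byte.
#'
#' @param config A `pm_config`.
#' @return A `pm_analysis` object: scores, rank tables, log-ratio matrix,
#'   distance matrix, dendrogram, ground truth (synthetic runs), file
#'   paths and the run log.
#' @examples
#' res <- run_pipeline(pm_config(
#'   synthetic = synthetic_spec(n_strains = 8, replicates = 2, seed = 7),
#'   outdir = tempfile()))
#' res
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pm_config"))
  t0 <- Sys.time()
  log <- character()
  say <- function(...) {
    msg <- paste0(...)
    log <<- c(log, msg)
    message(msg)
  }
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  truth <- NULL
  if (!is.null(config$synthetic)) {
    say("stage simulate: seed ", config$synthetic$seed, ", ",
        config$synthetic$n_strains, " strains, ",
        nrow(config$synthetic$conditions), " conditions, ",
        config$synthetic$replicates, " replicates")
    study <- simulate_study(config$synthetic)
    curves <- study$curves
    conditions <- config$synthetic$conditions
    truth <- study$truth
  } else {
    say("stage read: ", config$kinetics)
    curves <- read_kinetics(config$kinetics)
    conditions <- read_conditions(config$conditions)
    if (!is.null(config$strains)) {
      strains <- read_strains(config$strains)
      say("stage read: ", nrow(strains), " strain records")
    }
  }
  say("stage read: ", length(curves), " kinetic series")

  say("stage transform: baseline subtraction, floor at 0")
  curves <- lapply(curves, baseline_transform)

  say("stage smooth: adaptive centred moving average, cap ", config$w_max)
  curves <- lapply(curves, smooth_monotone, w_max = config$w_max)
  cap_hits <- sum(vapply(curves, function(s) s$residual_neg_slopes > 0,
                         logical(1L)))
  say("stage smooth: ", cap_hits,
      " curve(s) still non-monotone at the cap (running-maximum applied)")

  say("stage aggregate: replicate means")
  grp <- split(curves, vapply(curves, function(s)
    paste(s$strain_id, s$condition_id, sep = "\r"), character(1L)))
  means <- lapply(grp, aggregate_replicates)
  means <- means[order(names(means))]
  say("stage aggregate: ", length(means), " mean curves")

  say("stage score: %RSI at per-condition endpoints (eps = ", config$eps, ")")
  scores <- score_study(means, conditions, eps = config$eps)
  skipped <- attr(scores, "skipped")
  say("stage score: ", nrow(scores), " scores, ", sum(scores$low_control),
      " low-control flag(s), ", nrow(skipped), " skipped strain/condition(s)")
  for (i in seq_len(nrow(conditions))) {
    if (nzchar(conditions$control_id[i]))
      say("  endpoint ", conditions$condition_id[i], ": ",
          conditions$endpoint_hours[i], " h")
  }

  say("stage rank: per-condition ranking, extremes ", config$k_tolerant,
      " tolerant / ", config$k_sensitive, " sensitive")
  ranks <- lapply(split(scores, scores$condition_id), function(sc) {
    rk <- rank_strains(sc)
    ks <- min(config$k_sensitive, nrow(rk))
    kt <- min(config$k_tolerant, max(nrow(rk) - ks, 0L))
    classify_extremes(rk, k_sensitive = ks, k_tolerant = kt)
  })

  say("stage logratio: reference ", config$reference_id, ", clip ",
      config$clip)
  lr <- log_ratio_matrix(scores, reference_id = config$reference_id,
                         clip = config$clip)
  say("stage logratio: ", nrow(lr), " x ", ncol(lr), " matrix, ",
      attr(lr, "n_flagged"), " flagged cell(s)")

  say("stage cluster: centred Pearson distance + UPGMA")
  dmat <- centred_pearson_distance(lr)
  if (length(attr(dmat, "zero_variance")))
    say("stage cluster: zero-variance profile(s): ",
        paste(attr(dmat, "zero_variance"), collapse = ", "))
  dend <- upgma(dmat)

  files <- c(
    scores = file.path(config$outdir, "tolerance_scores.tsv"),
    logratio = file.path(config$outdir, "logratio_matrix.tsv"),
    newick = file.path(config$outdir, "strain_tree.nwk"),
    manifest = file.path(config$outdir, "run_manifest.txt"))
  write_tolerance_table(scores, files[["scores"]])
  write_matrix_tsv(lr, files[["logratio"]])
  cg <- write_cdt_gtr(dend, lr, file.path(config$outdir, "clustered"))
  files <- c(files, cg)
  write_newick(dend, files[["newick"]])
  for (cid in names(ranks)) {
    p <- file.path(config$outdir, paste0("rank_", cid, ".tsv"))
    rk <- ranks[[cid]]
    rk$percent_rsi <- format(signif(rk$percent_rsi, 6), digits = 15,
                             trim = TRUE)
    write_tsv(rk[, c("rank", "strain_id", "percent_rsi", "low_control",
                     "class")], p)
    files[[paste0("rank_", cid)]] <- p
  }
  say("stage export: ", length(files), " file(s) in ", config$outdir)

  manifest <- c(
    paste0("pmscreen ", as.character(utils::packageVersion("pmscreen"))),
    paste0("seed: ", if (!is.null(config$synthetic))
      config$synthetic$seed else config$seed),
    paste0("reference: ", config$reference_id),
    paste0("w_max: ", config$w_max, "  eps: ", config$eps, "  clip: ",
           config$clip),
    log)
  writeLines(manifest, con <- file(files[["manifest"]], "wb"), sep = "\n")
  close(con)
  say("done in ", format(round(as.numeric(difftime(Sys.time(), t0,
                                                   units = "secs")), 2)),
      " s")
  structure(list(config = config, conditions = conditions,
                 mean_curves = means, scores = scores, skipped = skipped,
                 ranks = ranks, logratio = lr, dist = dmat, dendrogram = dend,
                 truth = truth, files = files, log = log),
            class = "pm_analysis")
}

#' Run a small self-contained demonstration study
#'
#' Simulates a reduced synthetic study and runs the full pipeline on it.
#'
#' @param outdir Output directory.
#' @param seed Study seed.
#' @param n_strains Number of strains (default 20).
#' @return A `pm_analysis`.
#' @export
pm_demo <- function(outdir = tempfile("pmdemo"), seed = 42L,
                    n_strains = 20L) {
  spec <- synthetic_spec(n_strains = n_strains, replicates = 3L,
                         n_tolerant = max(2L, n_strains %/% 5L),
                         n_sensitive = max(2L, n_strains %/% 6L),
                         seed = seed)
  run_pipeline(pm_config(synthetic = spec, outdir = outdir, seed = seed))
}

#' @export
print.pm_analysis <- function(x, ...) {
  cat("<pm_analysis>\n")
  cat("  ", length(x$mean_curves), " mean curves, ", nrow(x$scores),
      " %RSI scores across ", length(x$ranks), " stress condition(s)\n",
      sep = "")
  cat("  reference: ", attr(x$logratio, "reference"), "; log-ratio matrix ",
      nrow(x$logratio), " x ", ncol(x$logratio), "\n", sep = "")
  cat("  dendrogram: ", x$dendrogram$n, " leaves, max height ",
      format(max(x$dendrogram$height), digits = 4), "\n", sep = "")
  cat("  outputs: ", dirname(x$files[["scores"]]), "\n", sep = "")
  invisible(x)
}

#' @export
summary.pm_analysis <- function(object, ...) {
  cat("Stress-tolerance profiling summary\n")
  cat("----------------------------------\n")
  for (cid in names(object$ranks)) {
    rk <- object$ranks[[cid]]
    top <- rk$strain_id[rk$class == "tolerant"]
    bot <- rk$strain_id[rk$class == "sensitive"]
    cat(cid, ": %RSI ", format(signif(min(rk$percent_rsi), 4)), "..",
        format(signif(max(rk$percent_rsi), 4)),
        "; tolerant: ", paste(utils::head(top, 3), collapse = ", "),
        if (length(top) > 3) ", ..." else "",
        "; sensitive: ", paste(utils::head(bot, 3), collapse = ", "),
        if (length(bot) > 3) ", ..." else "", "\n", sep = "")
  }
  invisible(object)
}

#' Heat-map and dendrogram display of a pipeline result
#'
#' Draws the clipped log-ratio matrix with rows in dendrogram leaf order
#' and the UPGMA strain tree alongside, the layout used for
#' TreeView-style figures.
#'
#' @param x A `pm_analysis`.
#' @param ... Passed to [stats::heatmap()].
#' @export
plot.pm_analysis <- function(x, ...) {
  m <- unclass(x$logratio)
  m[is.na(m)] <- 0
  stats::heatmap(m, Rowv = stats::as.dendrogram(as.hclust(x$dendrogram)),
                 Colv = NA, scale = "none",
                 col = grDevices::hcl.colors(64, "Green-Orange"), ...)
  invisible(x)
}
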