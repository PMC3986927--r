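#' Percentage redox signal intensity (%RSI)
#'
#' The study's tolerance statistic: the redox signal under stress divided by
#' the signal under the matched unstressed control, times 100, both read at
#' the condition's endpoint. Values above 100 indicate stimulation and are
#' kept as-is. Controls with near-zero signal (below `eps`) cannot support a
#' meaningful ratio; such scores are set to 0 and flagged `low_control`
#' rather than propagated as infinities.
#'
#' @param rsi_stress,rsi_control Endpoint signals (arbitrary units, >= 0);
#'   vectors are recycled to common length.
#' @param eps Minimum usable control signal (same units; default 1).
#' @return Data frame with columns `rsi_stress`, `rsi_control`,
#'   `percent_rsi`, `low_control`.
#' @examples
#' percent_rsi(30, 60)   # 50%
#' @export
percent_rsi <- function(rsi_stress, rsi_control, eps = 1) {
  if (any(rsi_stress < 0) || any(rsi_control < 0))
    stop("redox signal intensities must be non-negative")
  n <- max(length(rsi_stress), length(rsi_control))
  rsi_stress <- rep_len(as.numeric(rsi_stress), n)
  rsi_control <- rep_len(as.numeric(rsi_control), n)
  low <- rsi_control < eps
  pct <- ifelse(low, 0, 100 * rsi_stress / rsi_control)
  data.frame(rsi_stress = rsi_stress, rsi_control = rsi_control,
             percent_rsi = pct, low_control = low)
}

#' Score a study: %RSI for every strain under every stress condition
#'
#' For each stress condition the endpoint signal of the stress curve and of
#' the matched control curve are read at the condition's `endpoint_hours`
#' (the same endpoint for both, e.g. 24 h for the 40 degree assay) and
#' combined into %RSI. Curves are expected to be replicate-mean smoothed
#' curves. Strains missing either curve are skipped and recorded in the
#' `skipped` attribute.
#'
#' @param curves Named or unnamed list of [pm_series] (one per strain and
#'   condition, typically replicate `"mean"`).
#' @param conditions A `pm_conditions` table ([read_conditions()] /
#'   [as_pm_conditions()]).
#' @param eps Minimum usable control signal, see [percent_rsi()].
#' @return A `pm_scores` data frame (one row per strain x stress condition)
#'   with attribute `skipped` (data frame of strain/condition/reason).
#' @export
score_study <- function(curves, conditions, eps = 1) {
  stopifnot(inherits(conditions, "pm_conditions"))
  strain_of <- vapply(curves, function(s) s$strain_id, character(1L))
  cond_of <- vapply(curves, function(s) s$condition_id, character(1L))
  lookup <- setNames(seq_along(curves), paste(strain_of, cond_of, sep = "\r"))
  if (anyDuplicated(names(lookup)))
    stop("more than one curve per (strain, condition); aggregate replicates first")
  stress <- conditions[nzchar(conditions$control_id), , drop = FALSE]
  rows <- list()
  skipped <- list()
  for (i in seq_len(nrow(stress))) {
    cond <- stress$condition_id[i]
    ctrl <- stress$control_id[i]
    t_end <- stress$endpoint_hours[i]
    strains <- sort(unique(strain_of))
    with_stress <- strains[paste(strains, cond, sep = "\r") %in%
                             names(lookup)]
    if (!length(with_stress)) next
    has_ctrl <- with_stress[paste(with_stress, ctrl, sep = "\r") %in%
                              names(lookup)]
    if (!length(has_ctrl))
      stop("condition ", cond, ": no control curve ('", ctrl,
           "') for any strain (strains: ",
           paste(with_stress, collapse = ", "), ")")
    for (st in strains) {
      si <- lookup[paste(st, cond, sep = "\r")]
      ci <- lookup[paste(st, ctrl, sep = "\r")]
      if (is.na(si) || is.na(ci)) {
        skipped[[length(skipped) + 1L]] <-
          data.frame(strain_id = st, condition_id = cond,
                     reason = if (is.na(si)) "missing stress curve"
                              else "missing control curve",
                     stringsAsFactors = FALSE)
        next
      }
      frag <- percent_rsi(endpoint_signal(curves[[si]], t_end),
                          endpoint_signal(curves[[ci]], t_end), eps = eps)
      rows[[length(rows) + 1L]] <-
        cbind(data.frame(strain_id = st, condition_id = cond,
                         stringsAsFactors = FALSE), frag)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows)
         else data.frame(strain_id = character(), condition_id = character(),
                         rsi_stress = numeric(), rsi_control = numeric(),
                         percent_rsi = numeric(), low_control = logical())
  rownames(out) <- NULL
  attr(out, "skipped") <- if (length(skipped)) do.call(rbind, skipped)
                          else data.frame(strain_id = character(),
                                          condition_id = character(),
                                          reason = character())
  class(out) <- c("pm_scores", "data.frame")
  out
}

#' Rank strains within one condition by %RSI
#'
#' Descending by `percent_rsi` (most tolerant first); ties break by strain
#' id ascending; strains with a low-control flag cannot be ranked on their
#' ratio and go last, labelled.
#'
#' @param scores A `pm_scores` data frame restricted to one condition.
#' @return A `pm_rank` data frame with a `rank` column, ordered.
#' @export
rank_strains <- function(scores) {
  if (!NROW(scores)) stop("no scores to rank")
  if (length(unique(scores$condition_id)) != 1L)
    stop("rank_strains expects scores for a single condition; got: ",
         paste(unique(scores$condition_id), collapse = ", "))
  o <- order(scores$low_control, -scores$percent_rsi, scores$strain_id)
  out <- scores[o, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  class(out) <- c("pm_rank", "data.frame")
  out
}

#' Label ranking extremes as tolerant / intermediate / sensitive
#'
#' Mirrors the study's summary-table layout: the top `k_tolerant` strains
#' of a ranking are labelled tolerant, the bottom `k_sensitive` sensitive,
#' everything between intermediate.
#'
#' @param rank A `pm_rank` data frame from [rank_strains()].
#' @param k_sensitive,k_tolerant Numbers of strains to label at each
#'   extreme (defaults 5 and 10).
#' @return `rank` with an added `class` column.
#' @export
classify_extremes <- function(rank, k_sensitive = 5L, k_tolerant = 10L) {
  stopifnot(inherits(rank, "pm_rank"))
  n <- nrow(rank)
  if (k_sensitive < 0 || k_tolerant < 0 || k_sensitive + k_tolerant > n)
    stop("k_sensitive + k_tolerant must not exceed the number of strains (",
         n, ")")
  cls <- rep("intermediate", n)
  if (k_tolerant > 0) cls[seq_len(k_tolerant)] <- "tolerant"
  if (k_sensitive > 0) cls[(n - k_sensitive + 1L):n] <- "sensitive"
  rank$class <- cls
  rank
}

#' Log2-ratio matrix of strain profiles against a reference strain
#'
#' Each cell is log2(%RSI of the strain / %RSI of the reference) for one
#' condition, clipped to `[-clip, +clip]` — the displayed range of the
#' study's heat maps. The reference row is exactly zero. Cells whose score
#' carries a low-control flag (either strain or reference) are set missing.
#'
#' @param scores A `pm_scores` data frame covering the reference strain in
#'   every condition used.
#' @param reference_id Reference strain id (default `"S288C"`).
#' @param clip Clipping bound in log2 units (default 3).
#' @return Numeric matrix (strains x conditions, sorted ids) of class
#'   `pm_logratio` with attributes `reference` and `n_flagged`.
#' @export
log_ratio_matrix <- function(scores, reference_id = "S288C", clip = 3.0) {
  strains <- sort(unique(scores$strain_id))
  conds <- sort(unique(scores$condition_id))
  if (!(reference_id %in% strains))
    stop("reference strain '", reference_id, "' has no scores")
  pct <- matrix(NA_real_, length(strains), length(conds),
                dimnames = list(strains, conds))
  low <- matrix(FALSE, length(strains), length(conds),
                dimnames = list(strains, conds))
  idx <- cbind(match(scores$strain_id, strains),
               match(scores$condition_id, conds))
  pct[idx] <- scores$percent_rsi
  low[idx] <- scores$low_control
  ref <- pct[reference_id, ]
  if (any(is.na(ref)))
    stop("reference strain '", reference_id, "' missing scores for: ",
         paste(conds[is.na(ref)], collapse = ", "))
  bad <- low | is.na(pct) | matrix(low[reference_id, ] | ref <= 0,
                                   nrow(pct), ncol(pct), byrow = TRUE) |
         pct <= 0
  lr <- log2(sweep(pct, 2L, ref, "/"))
  lr <- pmin(pmax(lr, -clip), clip)
  lr[bad] <- NA_real_
  lr[reference_id, !bad[reference_id, ]] <- 0
  structure(lr, class = c("pm_logratio", class(lr)),
            reference = reference_id, clip = clip, n_flagged = sum(bad))
}

#' Pearson correlation between two conditions across strains
#'
#' Sample Pearson correlation of two columns of a strains x conditions
#' value matrix (endpoint signals or %RSI), using pairwise-complete
#' observations. Zero variance in either column makes the correlation
#' undefined; `NA` is returned with a warning.
#'
#' @param endpoint_matrix Numeric matrix, strains in rows, conditions in
#'   columns (named).
#' @param cond_a,cond_b Column names or indices.
#' @return Pearson r, or `NA` when undefined.
#' @export
condition_correlation <- function(endpoint_matrix, cond_a, cond_b) {
  x <- endpoint_matrix[, cond_a]
  y <- endpoint_matrix[, cond_b]
  ok <- is.finite(x) & is.finite(y)
  if (sum(ok) < 3L)
    stop("need at least 3 strains with values in both conditions")
  if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) {
    warning("correlation undefined: zero variance in a column")
    return(NA_real_)
  }
  stats::cor(x[ok], y[ok])
}
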