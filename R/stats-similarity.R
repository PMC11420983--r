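#' Kendall rank correlation (tau-b)
#'
#' Tau-b with tie correction, computed in O(n log n) so whole-brain edge
#' vectors (thousands of entries) are cheap. Agrees with
#' `cor(x, y, method = "kendall")`.
#'
#' @param x,y numeric vectors of equal length >= 2.
#' @return tau-b in [-1, 1], or `NA` if either input has zero variance.
#' @export
kendall_tau <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 2) stop("need at least 2 observations")
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 2) return(NA_real_)
  .kendall_tau_b(as.numeric(x[ok]), as.numeric(y[ok]))
}

#' Similarity of direct and indirect connectomes
#'
#' For each participant, the Kendall tau-b between the vectorized upper
#' triangles of the direct and indirect connectome, at both scales
#' (whole-brain and ROI). Scales are then compared with a two-sided paired
#' t-test across participants.
#'
#' @param conns list (one element per participant) of connectome quadruples
#'   as returned by [participant_connectomes()]; elements with a missing
#'   connectome are dropped with a log entry.
#' @param ids optional participant ids (default sequence).
#' @return list with `per_participant` (id, tau_whole, tau_roi), `summary`
#'   (scale, n_edges, median, min, max) and `paired` (t, df, p of the
#'   whole-vs-ROI comparison).
#' @export
connectome_similarity <- function(conns, ids = NULL) {
  if (is.null(ids)) ids <- sprintf("sub-%02d", seq_along(conns))
  ok <- vapply(conns, function(cn)
    all(c("direct_whole", "indirect_whole", "direct_roi", "indirect_roi")
        %in% names(cn)) && !any(vapply(cn, is.null, logical(1))), logical(1))
  if (any(!ok))
    clsm_log("connectome_similarity: dropped %d participants with missing connectomes",
             sum(!ok))
  conns <- conns[ok]; ids <- ids[ok]
  tau_of <- function(cn, which) {
    a <- upper_tri_vec(cn[[paste0("direct_", which)]]$weights)
    b <- upper_tri_vec(cn[[paste0("indirect_", which)]]$weights)
    kendall_tau(a, b)
  }
  tau_whole <- vapply(conns, tau_of, numeric(1), which = "whole")
  tau_roi <- vapply(conns, tau_of, numeric(1), which = "roi")
  n_whole <- length(upper_tri_vec(conns[[1]]$direct_whole$weights))
  n_roi <- length(upper_tri_vec(conns[[1]]$direct_roi$weights))
  summ <- data.frame(
    scale = c("whole", "roi"),
    n_edges = c(n_whole, n_roi),
    median = c(stats::median(tau_whole, na.rm = TRUE),
               stats::median(tau_roi, na.rm = TRUE)),
    min = c(min(tau_whole, na.rm = TRUE), min(tau_roi, na.rm = TRUE)),
    max = c(max(tau_whole, na.rm = TRUE), max(tau_roi, na.rm = TRUE)))
  diffs <- tau_roi - tau_whole
  paired <- if (all(is.na(diffs)) ||
                stats::sd(diffs, na.rm = TRUE) < 1e-12) {
    list(t = NA_real_, df = NA_real_, p = NA_real_)
  } else {
    tt <- stats::t.test(tau_roi, tau_whole, paired = TRUE)
    list(t = unname(tt$statistic), df = unname(tt$parameter),
         p = tt$p.value)
  }
  list(per_participant = data.frame(id = ids, tau_whole = tau_whole,
                                    tau_roi = tau_roi),
       summary = summ, paired = paired)
}

#' Correlation matrix of tract metrics, lesion size and behaviour
#'
#' Full symmetric correlation matrix over the eight metrics of one tract
#' plus overall lesion size and a behaviour score, with pairwise-complete
#' observations (direct metrics can be missing). Cells with fewer than 3
#' complete pairs are `NA`.
#'
#' @param metrics wide metric data.frame from [build_metric_matrix()].
#' @param tract tract name.
#' @param lesion_cc numeric vector of lesion volumes.
#' @param behavior numeric vector (e.g. naming scores).
#' @param method `"kendall"` (default) or `"pearson"`.
#' @return named 10 x 10 correlation matrix.
#' @export
metric_correlations <- function(metrics, tract, lesion_cc, behavior,
                                method = c("kendall", "pearson")) {
  method <- match.arg(method)
  cols <- paste0(tract, "_", TRACT_METRICS)
  missing_cols <- setdiff(cols, names(metrics))
  if (length(missing_cols))
    stop("metrics table lacks columns: ", paste(missing_cols, collapse = ", "))
  X <- cbind(as.matrix(metrics[cols]), LS = lesion_cc, behavior = behavior)
  colnames(X) <- c(TRACT_METRICS, "LS", "behavior")
  p <- ncol(X)
  R <- matrix(NA_real_, p, p, dimnames = list(colnames(X), colnames(X)))
  for (i in seq_len(p)) {
    R[i, i] <- 1
    for (j in seq_len(i - 1L)) {
      ok <- !is.na(X[, i]) & !is.na(X[, j])
      if (sum(ok) < 3) next
      if (stats::sd(X[ok, i]) == 0 || stats::sd(X[ok, j]) == 0) next
      r <- if (method == "kendall") kendall_tau(X[ok, i], X[ok, j])
           else stats::cor(X[ok, i], X[ok, j])
      R[i, j] <- R[j, i] <- r
    }
  }
  R
}
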