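#' Sparse canonical correlation of connectome edges with behaviour
#'
#' Relates a participants x edges matrix (vectorized connectome upper
#' triangles) to a residualized behaviour score with a sparse,
#' penalized-matrix-decomposition style canonical vector on the edge side.
#' With a univariate behavioural side the unpenalized canonical direction is
#' the least-squares solution `(X'X)^+ X'y`; the sparse direction is its
#' soft-thresholded, unit-L2-renormalized projection onto the L1 ball of
#' radius `1 + sparsity * (sqrt(p) - 1)` (so `sparsity = 1` is the
#' unpenalized direction and small values give few active edges).
#'
#' Fit quality is evaluated by k-fold cross-validation: the weight vector is
#' estimated on each training fold, test-fold scores are predicted as
#' `X w`, and the predictions of all folds are pooled into a single
#' observed-vs-predicted Pearson correlation whose one-sided p-value
#' measures significance.
#'
#' @param X numeric matrix, rows = participants, columns = named edges.
#' @param y numeric residualized behaviour vector.
#' @param sparsity in (0, 1]; fraction of the maximal L1 budget.
#' @param folds number of CV folds (default 4).
#' @param seed seed controlling the fold assignment.
#' @return list with `weights` (named, unit L2 norm, on standardized edges,
#'   estimated from the full data),
#'   `n_active` (nonzero weights), `predicted` (pooled CV predictions),
#'   `cv_r`, `p_value`, `folds` (fold assignment).
#' @export
sparse_cca <- function(X, y, sparsity = 0.3, folds = 4, seed = NULL) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (length(y) != n) stop("X and y sizes differ")
  if (sparsity <= 0 || sparsity > 1) stop("sparsity must be in (0, 1]")
  if (n < folds) stop("need at least as many participants as folds")
  if (is.null(colnames(X))) colnames(X) <- paste0("e", seq_len(ncol(X)))
  budget <- 1 + sparsity * (sqrt(ncol(X)) - 1)
  w_full <- scca_direction(X, y, budget)$w
  with_seed(seed, {
    fold <- sample(rep_len(seq_len(folds), n))
    pred <- rep(NA_real_, n)
    for (f in seq_len(folds)) {
      te <- fold == f
      d <- scca_direction(X[!te, , drop = FALSE], y[!te], budget)
      Xs_te <- sweep(sweep(X[te, , drop = FALSE], 2, d$mu), 2, d$sdv, "/")
      pred[te] <- Xs_te %*% d$w
    }
    ok <- is.finite(pred)
    if (stats::sd(pred[ok]) == 0 || stats::sd(y[ok]) == 0) {
      cv_r <- NA_real_; p <- NA_real_
    } else {
      # one-sided: only a positive observed-vs-predicted correlation is
      # evidence of predictive fit
      ct <- stats::cor.test(y[ok], pred[ok], alternative = "greater")
      cv_r <- unname(ct$estimate); p <- ct$p.value
    }
    list(weights = stats::setNames(w_full, colnames(X)),
         n_active = sum(w_full != 0),
         predicted = pred, cv_r = cv_r, p_value = p, folds = fold)
  })
}

# Sparse direction on standardized edges: minimum-norm least-squares
# solution soft-thresholded to the L1 budget and renormalized to unit L2
# norm. Returns the weights plus the standardization used to apply them.
scca_direction <- function(X, y, budget) {
  mu <- colMeans(X)
  sdv <- apply(X, 2, stats::sd)
  sdv[sdv == 0] <- Inf                       # constant edges get weight 0
  Xs <- sweep(sweep(X, 2, mu), 2, sdv, "/")
  yc <- y - mean(y)
  sv <- svd(Xs)
  pos <- sv$d > max(sv$d) * 1e-8
  w <- sv$v[, pos, drop = FALSE] %*%
    ((t(sv$u[, pos, drop = FALSE]) %*% yc) / sv$d[pos])
  list(w = soft_threshold_l1(drop(w), budget), mu = mu, sdv = sdv)
}

# Soft-threshold v so that the unit-L2 vector has L1 norm <= budget.
soft_threshold_l1 <- function(v, budget) {
  unit <- function(x) if (sum(x^2) == 0) x else x / sqrt(sum(x^2))
  u <- unit(v)
  if (sum(abs(u)) <= budget) return(u)
  lo <- 0; hi <- max(abs(v))
  for (it in 1:60) {
    th <- (lo + hi) / 2
    s <- sign(v) * pmax(abs(v) - th, 0)
    if (sum(abs(unit(s))) > budget) lo <- th else hi <- th
  }
  s <- sign(v) * pmax(abs(v) - hi, 0)
  unit(s)
}

#' Edge matrix of a cohort
#'
#' Stacks the vectorized upper triangles of one connectome per participant
#' into the participants x edges matrix used by [sparse_cca()].
#'
#' @param conns list of [participant_connectomes()] outputs.
#' @param which connectome to use (e.g. `"indirect_roi"`).
#' @return numeric matrix with named edge columns.
#' @export
edge_matrix <- function(conns, which = "indirect_roi") {
  rows <- lapply(conns, function(cn) upper_tri_vec(cn[[which]]$weights))
  do.call(rbind, rows)
}
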