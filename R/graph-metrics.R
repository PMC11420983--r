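#' Normalize connection weights to [0, 1]
#'
#' Divides all weights by the maximum weight. A zero matrix is returned
#' unchanged with a warning. This is the first stage of the metric chain
#' normalize -> length -> distance used by all graph metrics.
#'
#' @param W symmetric non-negative weight matrix, zero diagonal.
#' @return matrix with maximum entry 1 (or unchanged zero matrix).
#' @export
normalize_weights <- function(W) {
  W <- as.matrix(W)
  if (any(W < 0)) stop("weights must be non-negative")
  if (max(abs(W - t(W))) > 1e-8) stop("weight matrix must be symmetric")
  mx <- max(W)
  if (mx == 0) {
    warning("zero weight matrix: normalization is a no-op")
    return(W)
  }
  W / mx
}

#' Convert weights to lengths
#'
#' Edge length is the inverse of the (normalized) connection weight; absent
#' connections (weight 0) have infinite length.
#'
#' @param W normalized weight matrix.
#' @return length matrix with `Inf` where there is no edge; zero diagonal.
#' @export
to_length <- function(W) {
  L <- ifelse(W > 0, 1 / W, Inf)
  diag(L) <- 0
  L
}

#' All-pairs shortest-path distances
#'
#' Dijkstra from every source over the finite entries of the length matrix.
#' Unreachable pairs are `Inf`.
#'
#' @param L length matrix from [to_length()].
#' @return distance matrix (zero diagonal, `Inf` for unreachable pairs).
#' @export
graph_distances <- function(L) {
  L <- as.matrix(L)
  n <- nrow(L)
  g <- igraph::graph_from_adjacency_matrix(
    ifelse(is.finite(L), L, 0), mode = "undirected",
    weighted = TRUE, diag = FALSE)
  D <- igraph::distances(g, algorithm = "dijkstra")
  dimnames(D) <- dimnames(L)
  D
}

#' Characteristic path length
#'
#' Mean shortest-path length over reachable (finite) off-diagonal pairs.
#' Infinite pairs — disconnected fragments, common in heavily lesioned
#' indirect networks — are excluded and their count logged.
#'
#' @param D distance matrix from [graph_distances()].
#' @return mean finite off-diagonal distance, or `NA` if all pairs are
#'   unreachable.
#' @export
char_path_length <- function(D) {
  off <- D[row(D) != col(D)]
  n_inf <- sum(is.infinite(off))
  if (n_inf > 0)
    clsm_log("char_path_length: excluded %d unreachable pairs", n_inf)
  fin <- off[is.finite(off)]
  if (length(fin) == 0L) return(NA_real_)
  mean(fin)
}

#' Mean nodal strength
#'
#' Nodal strength (row sum of weights) averaged over nodes.
#'
#' @param W weight matrix.
#' @return non-negative scalar.
#' @export
strength_mean <- function(W) mean(rowSums(W))

#' Weighted transitivity
#'
#' Ratio of the geometric-mean triangle intensity to the number of connected
#' triples: `sum_ijk (w_ij w_jk w_ki)^(1/3) / sum_i k_i (k_i - 1)` with `k`
#' the binary degree. Weights are assumed normalized to [0, 1], so the value
#' lies in [0, 1]; it is 0 when no node has two neighbours.
#'
#' @param W normalized weight matrix.
#' @return scalar in [0, 1].
#' @export
transitivity_weighted <- function(W) {
  W3 <- W^(1 / 3)
  num <- sum(diag(W3 %*% W3 %*% W3))
  k <- rowSums(W > 0)
  den <- sum(k * (k - 1))
  if (den == 0) return(0)
  num / den
}

#' Modularity by Louvain-style greedy optimisation
#'
#' Iterated greedy node moving with aggregation (multi-level Louvain, via
#' igraph) on the weighted graph, scoring partitions with
#' `Q = sum_c (e_c - gamma * a_c^2)` where `e_c` is the fraction of weight
#' inside community `c` and `a_c` the fraction of weight incident to it.
#' The best partition over random restarts is kept.
#'
#' @param W weight matrix (>= 1 edge).
#' @param gamma resolution parameter (1 = classic modularity).
#' @param seed integer controlling restart order; `NULL` uses the current RNG.
#' @param restarts number of random restarts.
#' @return list with `Q` (modularity) and `membership` (integer vector).
#' @export
modularity_louvain <- function(W, gamma = 1, seed = NULL, restarts = 20) {
  W <- as.matrix(W)
  if (sum(W) == 0) stop("modularity is undefined on an empty graph")
  g <- igraph::graph_from_adjacency_matrix(W, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  with_seed(seed, {
    n <- nrow(W)
    best <- list(Q = -Inf, membership = seq_len(n))
    for (r in seq_len(restarts)) {
      # iterated local search: alternate the multi-level heuristic with a
      # random perturbation of the best partition so far, both polished by
      # single-node/merge refinement -- the perturbed restarts explore
      # basins the aggregation phase locks out
      memb0 <- if (r %% 2 == 1 || best$Q == -Inf) {
        as.integer(igraph::membership(
          igraph::cluster_louvain(g, resolution = gamma)))
      } else {
        pert <- best$membership
        shake <- stats::runif(n) < 0.3
        pert[shake] <- sample.int(max(pert) + 1L, sum(shake), replace = TRUE)
        pert
      }
      memb <- refine_partition(W, memb0, gamma)
      q <- modularity_q(W, memb, gamma)
      if (q > best$Q) best <- list(Q = q, membership = memb)
    }
    best
  })
}

# Greedy single-node refinement on the original graph: repeatedly move any
# node (to an existing community or a fresh singleton) while Q improves.
# Escapes the lock-in of the aggregation phase on small graphs.
refine_partition <- function(W, memb, gamma) {
  n <- nrow(W)
  two_m <- sum(W)
  k <- rowSums(W)
  memb <- match(memb, unique(memb))
  repeat {
    improved <- FALSE
    for (i in seq_len(n)) {
      nc <- max(memb)
      link <- vapply(seq_len(nc), function(c)
        sum(W[i, memb == c]) - if (memb[i] == c) 0 else 0, numeric(1))
      link[memb[i]] <- link[memb[i]] - 0  # W[i,i] is 0 by invariant
      tot <- vapply(seq_len(nc), function(c) sum(k[memb == c]), numeric(1))
      tot[memb[i]] <- tot[memb[i]] - k[i]
      # candidate communities: all existing plus a fresh singleton
      gain <- (link - gamma * k[i] * tot / two_m)
      gain <- c(gain, 0)                      # singleton: link 0, tot 0
      cur <- gain[memb[i]]
      jbest <- which.max(gain)
      if (gain[jbest] > cur + 1e-12) {
        memb[i] <- if (jbest > nc) nc + 1L else jbest
        memb <- match(memb, unique(memb))
        improved <- TRUE
      }
    }
    if (!improved) {
      # no single-node move helps: try merging a pair of communities
      nc <- max(memb)
      if (nc < 2) return(memb)
      tot <- vapply(seq_len(nc), function(c) sum(k[memb == c]), numeric(1))
      best_gain <- 0; best_pair <- NULL
      for (a in seq_len(nc - 1)) for (b in seq.int(a + 1, nc)) {
        s_ab <- sum(W[memb == a, memb == b])
        gain <- 2 * s_ab / two_m - 2 * gamma * tot[a] * tot[b] / two_m^2
        if (gain > best_gain + 1e-12) {
          best_gain <- gain; best_pair <- c(a, b)
        }
      }
      if (is.null(best_pair)) return(memb)
      memb[memb == best_pair[2]] <- best_pair[1]
      memb <- match(memb, unique(memb))
    }
  }
}

#' Modularity of a given partition
#' @keywords internal
modularity_q <- function(W, membership, gamma = 1) {
  two_m <- sum(W)
  if (two_m == 0) return(NA_real_)
  k <- rowSums(W)
  q <- 0
  for (c in unique(membership)) {
    in_c <- membership == c
    e_c <- sum(W[in_c, in_c]) / two_m
    a_c <- sum(k[in_c]) / two_m
    q <- q + e_c - gamma * a_c^2
  }
  q
}

#' Mean weighted rich-club coefficient
#'
#' For each degree level `k`, the rich-club coefficient is the total weight
#' among nodes of binary degree > `k`, divided by the sum of the same number
#' of largest weights anywhere in the graph. Levels where the surviving
#' subgraph has no edge are undefined; the mean is over defined levels.
#'
#' @param W weight matrix (>= 1 edge).
#' @return mean coefficient, or `NA` if no level is defined.
#' @export
rich_club_mean <- function(W) {
  W <- as.matrix(W)
  if (sum(W) == 0) stop("rich club is undefined on an empty graph")
  deg <- rowSums(W > 0)
  wts <- sort(W[upper.tri(W)][W[upper.tri(W)] > 0], decreasing = TRUE)
  phis <- c()
  for (k in seq_len(max(deg))) {
    keep <- deg > k
    if (sum(keep) < 2) next
    sub <- W[keep, keep, drop = FALSE]
    ne <- sum(sub[upper.tri(sub)] > 0)
    if (ne == 0) next
    phis <- c(phis, sum(sub[upper.tri(sub)]) / sum(wts[seq_len(ne)]))
  }
  if (length(phis) == 0L) return(NA_real_)
  mean(phis)
}

#' Small-worldness
#'
#' The sigma ratio `(C / <C_null>) / (CPL / <CPL_null>)`, with `C` the
#' weighted transitivity and `CPL` the characteristic path length, against an
#' ensemble of null networks that preserve the binary degree sequence
#' (degree-preserving edge rewiring) with the observed weights shuffled onto
#' the rewired edges.
#'
#' @param W normalized weight matrix.
#' @param n_null size of the null ensemble (default 100).
#' @param seed integer seed controlling the ensemble.
#' @return sigma, or `NA` if undefined (e.g. zero null clustering).
#' @export
small_worldness <- function(W, n_null = 100, seed = NULL) {
  W <- as.matrix(W)
  C <- transitivity_weighted(W)
  CPL <- char_path_length(graph_distances(to_length(W)))
  if (is.na(CPL) || CPL == 0) return(NA_real_)
  g <- igraph::graph_from_adjacency_matrix((W > 0) * 1, mode = "undirected",
                                           diag = FALSE)
  ne <- igraph::ecount(g)
  if (ne < 2) return(NA_real_)
  wts <- W[upper.tri(W)][W[upper.tri(W)] > 0]
  n <- nrow(W)
  with_seed(seed, {
    Cn <- numeric(n_null)
    Pn <- numeric(n_null)
    for (b in seq_len(n_null)) {
      gr <- igraph::rewire(g, igraph::keeping_degseq(niter = 10 * ne))
      el <- igraph::as_edgelist(gr, names = FALSE)
      Wn <- matrix(0, n, n)
      w <- sample(wts)
      Wn[el] <- w
      Wn <- Wn + t(Wn)
      Cn[b] <- transitivity_weighted(Wn)
      Pn[b] <- char_path_length(graph_distances(to_length(Wn)))
    }
    if (mean(Cn) == 0 || !any(is.finite(Pn)))
      stop("null ensemble has zero mean clustering")
    (C / mean(Cn)) / (CPL / mean(Pn, na.rm = TRUE))
  })
}

#' All six graph metrics of a connectome
#'
#' Runs the normalize -> length -> distance chain, then computes
#' characteristic path length, modularity, mean rich-club coefficient, mean
#' strength, small-worldness and transitivity. Metrics that are undefined on
#' the given network are reported as `NA`, never dropped.
#'
#' @param conn a [connectome()] or plain symmetric matrix.
#' @param seed seed for the stochastic metrics (modularity restarts and
#'   small-world null ensemble).
#' @param n_null null-ensemble size for small-worldness.
#' @param restarts modularity restarts.
#' @return named numeric vector with entries `cpl`, `modularity`, `rich_club`,
#'   `strength`, `small_world`, `transitivity`.
#' @export
all_graph_metrics <- function(conn, seed = NULL, n_null = 100, restarts = 20) {
  W <- if (inherits(conn, "connectome")) conn$weights else as.matrix(conn)
  out <- c(cpl = NA_real_, modularity = NA_real_, rich_club = NA_real_,
           strength = NA_real_, small_world = NA_real_,
           transitivity = NA_real_)
  if (max(W) == 0) {
    out["strength"] <- 0
    return(out)
  }
  Wn <- normalize_weights(W)
  D <- graph_distances(to_length(Wn))
  out["cpl"] <- char_path_length(D)
  out["strength"] <- strength_mean(Wn)
  out["transitivity"] <- transitivity_weighted(Wn)
  out["modularity"] <- modularity_louvain(Wn, seed = seed,
                                          restarts = restarts)$Q
  out["rich_club"] <- rich_club_mean(Wn)
  out["small_world"] <- tryCatch(
    small_worldness(Wn, n_null = n_null,
                    seed = if (is.null(seed)) NULL else seed + 1L),
    error = function(e) NA_real_)
  out
}
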