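#' Evaluate an expression with a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so seeded internals (modularity restarts,
#' null-network ensembles, fold assignment) are reproducible without
#' disturbing the caller's RNG stream.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(expr)
}

#' Pipeline logging
#'
#' Stage-level progress messages (participant id, stage, counts) emitted with
#' [message()]; silenced unless `options(clsmverse.verbose = TRUE)`.
#' @keywords internal
clsm_log <- function(...) {
  if (isTRUE(getOption("clsmverse.verbose", FALSE)))
    message("[clsmverse] ", sprintf(...))
  invisible(NULL)
}

#' Upper-triangle vectorisation of a symmetric matrix
#'
#' Column-major order over `i < j`; names edges `"<id_i>-<id_j>"`.
#' @param m symmetric matrix with dimnames.
#' @return named numeric vector of length `n(n-1)/2`.
#' @export
upper_tri_vec <- function(m) {
  ut <- upper.tri(m)
  v <- m[ut]
  ids <- if (!is.null(rownames(m))) rownames(m) else as.character(seq_len(nrow(m)))
  names(v) <- outer(ids, ids, function(a, b) paste0(a, "-", b))[ut]
  v
}
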