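#' Fit the covariate-only base model
#'
#' Ordinary least squares of an outcome on total lesion size and a
#' dummy-coded scanner factor (reference-level coding). With a single
#' scanner level the dummy block is empty and the model reduces to
#' lesion-size only.
#'
#' @param outcome numeric outcome vector.
#' @param lesion_cc numeric lesion volumes.
#' @param scanner factor (or coercible) of scanner codes.
#' @return list with `fit` (the `lm`), `r2`, `residuals` and `data` (the
#'   model frame used).
#' @export
fit_base <- function(outcome, lesion_cc, scanner) {
  scanner <- droplevels(as.factor(scanner))
  df <- data.frame(y = outcome, lesion = lesion_cc, scanner = scanner)
  if (nrow(df) < 2 + nlevels(scanner))
    stop("too few observations for the base model")
  fit <- if (nlevels(scanner) > 1) stats::lm(y ~ lesion + scanner, data = df)
         else stats::lm(y ~ lesion, data = df)
  if (any(is.na(stats::coef(fit))))
    stop("singular base-model design (collinear covariates)")
  list(fit = fit, r2 = summary(fit)$r.squared,
       residuals = stats::resid(fit), data = df)
}

#' Residualized behaviour
#'
#' Residuals of the outcome after regressing out lesion size and scanner —
#' the dependent variable of the sparse-CCA analyses. Exactly orthogonal to
#' the base-model columns.
#'
#' @inheritParams fit_base
#' @return numeric residual vector.
#' @export
residualize <- function(outcome, lesion_cc, scanner) {
  fit_base(outcome, lesion_cc, scanner)$residuals
}

#' Add one metric to the base model
#'
#' The add-one step of the multiverse: rows with a missing metric are
#' dropped from both models (per-metric complete-case N, so the nested
#' models are compared on identical data), the base model is refit, the
#' metric is added, and the improvement `delta_r2 = R2_full - R2_base` is
#' tested with the F-test of the single added term. No familywise
#' correction is applied. Significance classes: `significant` (p < 0.05),
#' `marginal` (0.05 <= p < 0.1), `ns` otherwise.
#'
#' @param outcome,lesion_cc,scanner base-model variables (full length).
#' @param metric numeric metric column (may contain `NA`).
#' @param metric_id,outcome_id labels carried into the result.
#' @return one-row data.frame: `outcome`, `metric`, `n`, `delta_r2`,
#'   `p_value`, `class`.
#' @export
add_one <- function(outcome, lesion_cc, scanner, metric,
                    metric_id = "metric", outcome_id = "outcome") {
  ok <- !is.na(metric) & !is.na(outcome) & !is.na(lesion_cc)
  base <- fit_base(outcome[ok], lesion_cc[ok], scanner[ok])
  df <- base$data
  df$m <- metric[ok]
  full <- stats::update(base$fit, . ~ . + m, data = df)
  delta_r2 <- summary(full)$r.squared - base$r2
  if (is.na(stats::coef(full)["m"]) ||
      stats::df.residual(full) == stats::df.residual(base$fit)) {
    warning("metric '", metric_id, "' is collinear with the base model")
    return(data.frame(outcome = outcome_id, metric = metric_id,
                      n = sum(ok), delta_r2 = 0, p_value = NA_real_,
                      class = "ns"))
  }
  p <- stats::anova(base$fit, full)[2, "Pr(>F)"]
  cls <- if (is.na(p)) "ns"
         else if (p < 0.05) "significant"
         else if (p < 0.1) "marginal" else "ns"
  data.frame(outcome = outcome_id, metric = metric_id, n = sum(ok),
             delta_r2 = max(delta_r2, 0), p_value = p, class = cls)
}

#' Run a multiverse grid of add-one analyses
#'
#' One [add_one()] cell per (outcome, metric column) combination. With the
#' six-tract, eight-measure metric matrix and two outcomes this yields 96
#' cells; with the 6-graph-metric x 4-network table it yields 48.
#'
#' @param metric_table data.frame of metric columns (a `participant` column,
#'   if present, is ignored).
#' @param participants data.frame with `naming`, `token`, `lesion_cc`,
#'   `scanner` (row-aligned with `metric_table`).
#' @param outcomes outcomes to analyse.
#' @return data.frame of cells (`outcome`, `metric`, `n`, `delta_r2`,
#'   `p_value`, `class`), deterministic given the inputs.
#' @export
multiverse_grid <- function(metric_table, participants,
                            outcomes = c("naming", "token")) {
  cols <- setdiff(names(metric_table), "participant")
  cells <- list()
  for (oc in outcomes) {
    for (cl in cols) {
      cells[[length(cells) + 1L]] <- add_one(
        participants[[oc]], participants$lesion_cc, participants$scanner,
        metric_table[[cl]], metric_id = cl, outcome_id = oc)
    }
  }
  do.call(rbind, cells)
}

#' Graph-metric table of a cohort
#'
#' Computes the six graph metrics for each participant's four connectomes
#' (direct/indirect x whole/ROI), the input of the graph-metric multiverse.
#'
#' @param cohort a `clsm_cohort`.
#' @param correction direct-connectome correction mode.
#' @param n_null,restarts passed to [all_graph_metrics()].
#' @param seed base seed (participant p uses `seed + p`).
#' @return data.frame: `participant` plus 24 columns named
#'   `<approach>_<scale>_<metric>`.
#' @export
cohort_graph_metrics <- function(cohort, correction = "full",
                                 n_null = 100, restarts = 20,
                                 seed = cohort$spec$seed + 9000L) {
  n <- nrow(cohort$participants)
  rows <- vector("list", n)
  for (p in seq_len(n)) {
    cn <- participant_connectomes(cohort, p, correction = correction)
    vals <- c()
    for (nm in names(cn)) {
      gm <- all_graph_metrics(cn[[nm]], seed = seed + p, n_null = n_null,
                              restarts = restarts)
      names(gm) <- paste0(nm, "_", names(gm))
      vals <- c(vals, gm)
    }
    rows[[p]] <- vals
    clsm_log("graph metrics: participant %s done",
             cohort$participants$id[p])
  }
  tab <- as.data.frame(do.call(rbind, rows))
  data.frame(participant = cohort$participants$id, tab, check.names = FALSE)
}
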