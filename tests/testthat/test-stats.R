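test_that("kendall tau handles perfect order, reversal and a counted example", {
  expect_equal(kendall_tau(1:10, 1:10), 1)
  expect_equal(kendall_tau(1:10, 10:1), -1)
  # x = 1..4, y = (1,3,2,4): one discordant pair of six
  expect_equal(kendall_tau(1:4, c(1, 3, 2, 4)), 4 / 6, tolerance = 1e-12)
  expect_true(is.na(kendall_tau(rep(1, 5), 1:5)))
})

test_that("kendall tau agrees with the reference implementation under ties", {
  set.seed(18)
  for (i in 1:100) {
    n <- sample(3:50, 1)
    x <- sample(1:6, n, replace = TRUE)
    y <- sample(1:6, n, replace = TRUE)
    ref <- suppressWarnings(cor(x, y, method = "kendall"))
    got <- kendall_tau(x, y)
    if (is.na(ref)) expect_true(is.na(got))
    else expect_equal(got, ref, tolerance = 1e-12)
  }
})

test_that("connectome similarity reports per-participant tau and a paired test", {
  set.seed(19)
  # identical connectomes -> tau 1, no scale difference
  mk <- function(W14, W30) list(
    direct_whole = connectome(W30, "direct", "whole"),
    indirect_whole = connectome(W30, "indirect", "whole"),
    direct_roi = connectome(W14, "direct", "roi"),
    indirect_roi = connectome(W14, "indirect", "roi"))
  conns <- replicate(6, mk(random_weights(14), random_weights(30)),
                     simplify = FALSE)
  sim <- connectome_similarity(conns)
  expect_equal(sim$per_participant$tau_whole, rep(1, 6))
  expect_equal(sim$per_participant$tau_roi, rep(1, 6))
  expect_equal(sim$summary$n_edges, c(choose(30, 2), 91))
  expect_true(is.na(sim$paired$t))

  # independent random connectomes: median tau near 0
  conns2 <- replicate(40, list(
    direct_whole = connectome(random_weights(30), "direct", "whole"),
    indirect_whole = connectome(random_weights(30), "indirect", "whole"),
    direct_roi = connectome(random_weights(14), "direct", "roi"),
    indirect_roi = connectome(random_weights(14), "indirect", "roi")),
    simplify = FALSE)
  sim2 <- connectome_similarity(conns2)
  expect_lt(abs(sim2$summary$median[1]), 0.12)
  expect_false(is.na(sim2$paired$p))
})

test_that("metric correlation matrices respect missingness and known identities", {
  co <- small_cohort()
  p <- co$participants
  R <- metric_correlations(co$metrics, "AF", p$lesion_cc, p$naming,
                           method = "kendall")
  expect_equal(dim(R), c(10, 10))
  expect_true(all(abs(R[!is.na(R)]) <= 1 + 1e-12))
  expect_equal(unname(diag(R)), rep(1, 10))
  # duplicated metric correlates 1, negated correlates -1
  m2 <- co$metrics
  m2$AF_FA <- m2$AF_MD
  R2 <- metric_correlations(m2, "AF", p$lesion_cc, p$naming)
  expect_equal(unname(R2["FA", "MD"]), 1)
  m3 <- co$metrics
  m3$AF_FA <- -m3$AF_MD
  R3 <- metric_correlations(m3, "AF", p$lesion_cc, p$naming)
  expect_equal(unname(R3["FA", "MD"]), -1)
  # pairwise-complete loop oracle (pearson)
  Rp <- metric_correlations(co$metrics, "UF", p$lesion_cc, p$naming,
                            method = "pearson")
  X <- cbind(as.matrix(co$metrics[paste0("UF_", clsmverse:::TRACT_METRICS)]),
             p$lesion_cc, p$naming)
  for (i in 1:10) for (j in 1:10) {
    ok <- !is.na(X[, i]) & !is.na(X[, j])
    ref <- if (sum(ok) < 3) NA_real_
           else if (i == j) 1
           else suppressWarnings(cor(X[ok, i], X[ok, j]))
    if (!is.na(ref) && i != j &&
        (sd(X[ok, i]) == 0 || sd(X[ok, j]) == 0)) ref <- NA_real_
    if (is.na(ref)) expect_true(is.na(Rp[i, j]))
    else expect_equal(unname(Rp[i, j]), ref, tolerance = 1e-12)
  }
})

test_that("the base model fits, reduces and errors as specified", {
  set.seed(20)
  n <- 40
  les <- rlnorm(n, 4, 0.5)
  sc <- factor(sample(c("a", "b", "c"), n, TRUE))
  # outcome exactly linear in lesion size: R^2 = 1
  b <- fit_base(5 - 0.2 * les, les, sc)
  expect_equal(b$r2, 1, tolerance = 1e-9)
  # independent noise: R^2 near 0 at large n
  b2 <- fit_base(rnorm(2000), rlnorm(2000, 4, 0.5),
                 factor(sample(c("a", "b"), 2000, TRUE)))
  expect_lt(b2$r2, 0.01)
  # single scanner level: model reduces to lesion only
  b3 <- fit_base(5 - 0.2 * les + rnorm(n), les, factor(rep("a", n)))
  expect_named(coef(b3$fit), c("(Intercept)", "lesion"))
  # singular design errors explicitly
  expect_error(fit_base(rnorm(n), rep(1, n), sc), "singular")
})

test_that("residualization is an orthogonal projection", {
  set.seed(21)
  n <- 30
  les <- rlnorm(n, 4, 0.5)
  sc <- factor(sample(c("a", "b"), n, TRUE))
  y <- 40 - 0.1 * les + rnorm(n, 0, 4)
  r <- residualize(y, les, sc)
  expect_lt(abs(sum(r * les)), 1e-8)
  expect_lt(abs(sum(r)), 1e-8)
  # exact base prediction -> all-zero residuals
  yhat <- fitted(fit_base(y, les, sc)$fit)
  expect_lt(max(abs(residualize(yhat, les, sc))), 1e-9)
  # permutation equivariance
  perm <- sample(n)
  expect_equal(residualize(y[perm], les[perm], sc[perm]), r[perm],
               ignore_attr = TRUE, tolerance = 1e-9)
})

test_that("add_one measures the nested-model improvement correctly", {
  set.seed(22)
  n <- 50
  les <- rlnorm(n, 4, 0.5)
  sc <- factor(sample(c("a", "b", "c"), n, TRUE))
  m <- rnorm(n)
  # noiseless outcome in (lesion, metric): delta R2 = 1 - R2_base, p ~ 0
  y <- 20 - 0.1 * les + 3 * m
  base_r2 <- fit_base(y, les, sc)$r2
  cell <- suppressWarnings(add_one(y, les, sc, m, "m", "naming"))
  expect_equal(cell$delta_r2, 1 - base_r2, tolerance = 1e-6)
  expect_equal(cell$class, "significant")
  # metric = copy of lesion size: no new information
  expect_warning(cell2 <- add_one(y, les, sc, les, "copy", "naming"),
                 "collinear")
  expect_equal(cell2$delta_r2, 0)
  expect_equal(cell2$class, "ns")
  # missing metric rows shrink n and both models are refit on common rows
  m_miss <- m; m_miss[1:10] <- NA
  y2 <- 20 - 0.1 * les + rnorm(n, 0, 3)
  cell3 <- add_one(y2, les, sc, m_miss, "m", "naming")
  expect_equal(cell3$n, 40)
  expect_gte(cell3$delta_r2, 0)
  expect_lte(cell3$delta_r2, 1)
  # F-test p equals the squared-t p of the added coefficient
  full <- lm(y2 ~ les + sc + m_miss)
  expect_equal(cell3$p_value,
               summary(full)$coefficients["m_miss", "Pr(>|t|)"],
               tolerance = 1e-9)
})

test_that("the multiverse grid enumerates outcome x metric cells", {
  co <- small_cohort()
  cells <- multiverse_grid(co$metrics, co$participants)
  expect_equal(nrow(cells), 6 * 8 * 2)
  expect_setequal(unique(cells$outcome), c("naming", "token"))
  expect_true(all(cells$delta_r2 >= 0 & cells$delta_r2 <= 1, na.rm = TRUE))
  expect_true(all(cells$class %in% c("significant", "marginal", "ns")))
  # classes follow the p thresholds exactly
  with_p <- cells[!is.na(cells$p_value), ]
  expect_equal(with_p$class,
               ifelse(with_p$p_value < 0.05, "significant",
                      ifelse(with_p$p_value < 0.1, "marginal", "ns")))
  cells2 <- multiverse_grid(co$metrics, co$participants)
  expect_identical(cells, cells2)
})
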