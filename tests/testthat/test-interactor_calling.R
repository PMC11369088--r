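mk_mat <- function(values, nr, nc, prefix = "ch") {
  matrix(values, nr, nc,
         dimnames = list(sprintf("P%03d", seq_len(nr)),
                         sprintf("%s%02d", prefix, seq_len(nc))))
}

test_that("log transform maps values, keeps missingness, rejects negatives", {
  q <- mk_mat(c(4, 0, NA, 1), 2, 2)
  expect_equal(log_transform(q)["P001", "ch01"], 2)
  expect_equal(log_transform(q, pseudocount = 1)["P002", "ch01"], 0)
  expect_true(is.na(log_transform(q)["P001", "ch02"]))
  q_neg <- q; q_neg[2, 2] <- -1
  expect_error(log_transform(q_neg), "negative")
})

test_that("median normalization equalizes channel medians and is idempotent", {
  set.seed(3)
  q <- mk_mat(rnorm(100 * 8), 100, 8)
  q[, 3] <- q[, 3] + 3
  qn <- median_normalize(q)
  med <- apply(qn, 2, median)
  expect_lt(max(abs(med - med[1])), 1e-9)
  expect_equal(median_normalize(qn), qn)
  # every channel median lands exactly on the grand median
  expect_equal(unname(apply(qn, 2, median)), rep(median(q), 8))
  q_empty <- q; q_empty[, 5] <- NA
  expect_error(median_normalize(q_empty), "ch05")
})

test_that("left-censored imputation is deterministic and hits the stated distribution", {
  set.seed(1)
  q <- mk_mat(rnorm(600, 20, 1), 100, 6)
  expect_identical(impute_minprob(q, seed = 5), q)  # nothing missing

  q[sample(length(q), 100)] <- NA
  a <- impute_minprob(q, seed = 5)
  b <- impute_minprob(q, seed = 5)
  expect_identical(a, b)
  expect_false(any(is.na(a)))
  obs <- !is.na(q)
  expect_identical(a[obs], q[obs])
  expect_error(impute_minprob(q, width = 0), "width")

  # Monte-Carlo check of the imputation law: channel with mu=20, sd=1,
  # shift=1.8 -> imputed mean ~ 18.2
  set.seed(2)
  big <- matrix(rnorm(60000, 20, 1), ncol = 1,
                dimnames = list(NULL, "c1"))
  rownames(big) <- sprintf("P%05d", seq_len(nrow(big)))
  big[1:10000, 1] <- NA
  imp <- impute_minprob(big, shift = 1.8, width = 0.3, seed = 9)
  expect_lt(abs(mean(imp[1:10000, 1]) - 18.2), 0.01)
  expect_lt(abs(sd(imp[1:10000, 1]) - 0.3), 0.01)
})

test_that("moderation fit recovers the variance prior and matches limma", {
  fit0 <- fit_moderation(rep(2, 50), residual_df = 8)
  expect_identical(fit0$d0, Inf)
  expect_equal(fit0$s2_prior, 2)

  set.seed(42)
  d0 <- 4; df <- 8; n <- 5000
  sigma2 <- 4 / rchisq(n, d0)  # s0^2 = 1
  s2 <- sigma2 * rchisq(n, df) / df
  fit <- fit_moderation(s2, df)
  expect_lt(abs(fit$d0 - d0) / d0, 0.2)
  expect_lt(abs(fit$s2_prior - 1), 0.1)

  skip_if_not_installed("limma")
  lf <- limma::fitFDist(s2, df1 = df)
  expect_equal(fit$d0, lf$df2, tolerance = 1e-8)
  expect_equal(fit$s2_prior, lf$scale, tolerance = 1e-8)

  # one extreme outlier among equal variances -> finite positive d0
  fit_out <- fit_moderation(c(rep(1, 99), 400), residual_df = 8)
  expect_true(is.finite(fit_out$d0) && fit_out$d0 > 0)
})

test_that("moderated t has the correct limit cases", {
  set.seed(7)
  d <- tiny_design(n_rep = 5L)
  n_prot <- 50L
  q <- matrix(rnorm(n_prot * nrow(d), 20, 1), n_prot, nrow(d),
              dimnames = list(sprintf("P%03d", 1:n_prot), d$channel_id))

  # d0 = 0: equals the ordinary pooled two-sample t
  mod0 <- structure(list(s2_prior = 1, d0 = 0, residual_df = 8),
                    class = "trip_moderation")
  e0 <- moderated_test(q, d, mod = mod0)
  boost <- d$channel_id[d$role == "booster"]
  bg <- d$channel_id[d$role == "minus_hpg"]
  for (i in c(1L, 17L, 50L)) {
    tt <- t.test(q[i, boost], q[i, bg], var.equal = TRUE)
    expect_equal(e0$t_mod[i], unname(tt$statistic), tolerance = 1e-12)
    expect_equal(e0$p[i], tt$p.value, tolerance = 1e-9)
  }

  # d0 = Inf: every protein shares the prior variance
  modI <- structure(list(s2_prior = 2.5, d0 = Inf, residual_df = 8),
                    class = "trip_moderation")
  eI <- moderated_test(q, d, mod = modI)
  fc <- rowMeans(q[, boost]) - rowMeans(q[, bg])
  expect_equal(eI$t_mod, unname(fc / sqrt(2.5 * (1 / 5 + 1 / 5))),
               tolerance = 1e-12)

  # monotone in d0 between the limits: posterior variance between s2 and prior
  mod4 <- structure(list(s2_prior = 2.5, d0 = 4, residual_df = 8),
                    class = "trip_moderation")
  e4 <- moderated_test(q, d, mod = mod4)
  s2 <- sapply(seq_len(n_prot), function(i) {
    (4 * var(q[i, boost]) + 4 * var(q[i, bg])) / 8
  })
  post <- (fc / e4$t_mod)^2 / (1 / 5 + 1 / 5)
  expect_true(all(post >= pmin(s2, 2.5) - 1e-12 & post <= pmax(s2, 2.5) + 1e-12))
})

test_that("moderated p-values are uniform under the null", {
  set.seed(123)
  d <- tiny_design(n_rep = 5L)
  q <- matrix(rnorm(2000 * nrow(d), 20, 1), 2000, nrow(d),
              dimnames = list(sprintf("P%04d", 1:2000), d$channel_id))
  e <- moderated_test(q, d)
  ks <- suppressWarnings(ks.test(e$p, "punif"))
  expect_lt(unname(ks$statistic), 0.05)
})

test_that("BH adjustment matches the brute-force step-up oracle", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.37), 0.37)
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")

  set.seed(99)
  for (i in 1:25) {
    p <- runif(sample(1:1000, 1))
    q <- bh_adjust(p)
    expect_identical(q, bh_brute_force(p))
    expect_true(all(q >= p))
    expect_true(all(diff(q[order(p)]) >= -1e-15))
  }
})

test_that("interactor calling applies the joint sigma fold-change + FDR rule", {
  e_null <- data.frame(protein_id = sprintf("P%02d", 1:20),
                       log2fc = 0, p = 1, tested = TRUE)
  called <- call_interactors(e_null)
  expect_equal(sum(called$enriched), 0L)
  expect_error(call_interactors(e_null[1:5, ]), "fewer than 10")

  # planted positives pass, strong *depletion* is never flagged (one-sided)
  set.seed(5)
  e <- data.frame(protein_id = sprintf("P%03d", 1:120),
                  log2fc = c(rnorm(100, 0, 0.3), rep(4, 10), rep(-4, 10)),
                  p = c(runif(100, 0.2, 1), rep(1e-8, 20)),
                  tested = TRUE)
  called <- call_interactors(e)
  expect_true(all(called$enriched[101:110]))
  expect_false(any(called$enriched[111:120]))
  expect_equal(attr(called, "fc_threshold"),
               2 * robust_sigma(e$log2fc))
})

test_that("spike-in recovery at 4-sigma planted effect meets sensitivity and FDR bounds", {
  # enrichment tables built under the normal model: null log2FCs with the
  # 5v5 group-mean sd, planted log2FCs at exactly 4x that sigma
  sens <- fdp <- numeric(20)
  s_fc <- sqrt(2 / 5)
  for (s in 1:20) {
    set.seed(s)
    n_null <- 500L; n_true <- 50L
    fc <- c(rnorm(n_null, 0, s_fc), rep(4 * s_fc, n_true))
    e <- data.frame(protein_id = sprintf("P%03d", seq_along(fc)),
                    log2fc = fc, p = 2 * pnorm(-abs(fc) / s_fc),
                    tested = TRUE)
    e$fdr <- bh_adjust(e$p)
    called <- with(call_interactors(e), protein_id[enriched])
    truth <- e$protein_id[(n_null + 1):(n_null + n_true)]
    sens[s] <- mean(truth %in% called)
    fdp[s] <- if (length(called)) mean(!called %in% truth) else 0
  }
  expect_gte(mean(sens), 0.95)
  expect_lte(mean(fdp), 0.08)
})

test_that("the calling stage is deterministic given data and seed", {
  cfg <- null_sim_config(seed = 21, n_background = 150L)
  ds <- emit_trip_dataset(cfg)
  run_cfg <- default_config()
  e1 <- run_interactor_calling(ds$quant, ds$design, run_cfg)
  e2 <- run_interactor_calling(ds$quant, ds$design, run_cfg)
  expect_identical(e1, e2)
})
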