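grid <- default_timepoint_grid()

test_that("bait normalization cancels per-channel gains and unitizes the bait", {
  d <- tiny_design(n_rep = 2L)
  set.seed(4)
  q <- matrix(rlnorm(5 * nrow(d), 10, 1), 5, nrow(d),
              dimnames = list(c("BAIT", sprintf("P%d", 1:4)), d$channel_id))
  qb <- bait_normalize(q, d, "BAIT")
  norm_ch <- d$channel_id[d$role != "booster"]
  expect_equal(unname(qb["BAIT", norm_ch]), rep(1, length(norm_ch)))

  # doubling every value of one channel (bait included) changes nothing
  q2 <- q; q2[, 3] <- q2[, 3] * 2
  expect_equal(bait_normalize(q2, d, "BAIT"), qb)

  q_miss <- q; q_miss["BAIT", 2] <- NA
  expect_error(bait_normalize(q_miss, d, "BAIT"), d$channel_id[2])
})

test_that("replicate QC excludes bait-inconsistent replicates only", {
  d <- tiny_design(n_rep = 3L)
  q <- matrix(50, 2, nrow(d),
              dimnames = list(c("BAIT", "P1"), d$channel_id))
  qc0 <- qc_replicates(q, d, "BAIT")
  expect_false(any(qc0$excluded))

  # bait missing in one chase channel of replicate 2
  q_miss <- q
  q_miss["BAIT", d$channel_id[d$replicate == 2 & d$role == "chase"][1]] <- NA
  qc1 <- qc_replicates(q_miss, d, "BAIT")
  expect_true(qc1$excluded[qc1$replicate == 2])
  expect_match(qc1$reason[qc1$replicate == 2], "bait missing")
  expect_false(any(qc1$excluded[qc1$replicate != 2]))

  # bait CV at twice the threshold in replicate 3 only
  q_cv <- q
  ch3 <- d$channel_id[d$replicate == 3 & d$role == "chase"]
  q_cv["BAIT", ch3] <- 50 * exp(seq(-1.5, 1.5, length.out = length(ch3)))
  cv3 <- sd(q_cv["BAIT", ch3]) / mean(q_cv["BAIT", ch3])
  qc2 <- qc_replicates(q_cv, d, "BAIT", cv_threshold = cv3 / 2)
  expect_identical(which(qc2$excluded), which(qc2$replicate == 3))
})

test_that("enrichment is the log2 chase/background ratio with missing propagation", {
  d <- tiny_design(n_rep = 2L)
  q <- quant_from_profile(d, list(`1` = c(1, 4, 2, 1, 1, 1),
                                  `2` = c(1, 4, 2, 1, 1, 1)), ref = 1)
  qb <- bait_normalize(q, d, "BAIT")
  enr <- compute_enrichment(qb, d, proteins = "P1")
  e1 <- enr$log2_enrichment[enr$replicate == 1]
  expect_equal(e1, c(0, 2, 1, 0, 0, 0))

  # missing reference kills that replicate's enrichments only
  q_noref <- q
  q_noref["P1", d$channel_id[d$replicate == 2 & d$role == "minus_hpg"]] <- NA
  qb2 <- bait_normalize(q_noref, d, "BAIT")
  enr2 <- compute_enrichment(qb2, d, proteins = "P1")
  expect_true(all(is.na(enr2$log2_enrichment[enr2$replicate == 2])))
  expect_false(any(is.na(enr2$log2_enrichment[enr2$replicate == 1])))
})

test_that("scaling maps replicate-mean profiles onto [0,1] with the stated rules", {
  d <- tiny_design(n_rep = 2L)
  prof_vals <- c(0.5, 1.0, 2.0, 1.0, 0.5, 0.25)
  q <- quant_from_profile(d, list(`1` = 2^prof_vals, `2` = 2^prof_vals), ref = 1)
  qb <- bait_normalize(q, d, "BAIT")
  prof <- scale_profiles(compute_enrichment(qb, d, proteins = "P1"))
  expect_equal(prof$profiles$scaled, c(0.25, 0.5, 1.0, 0.5, 0.25, 0.125))
  expect_equal(prof$scale$scale_max, 2.0)

  # all-negative mean profile is clamped to all zeros with absent scale
  q_neg <- quant_from_profile(d, list(`1` = rep(0.25, 6), `2` = rep(0.5, 6)),
                              ref = 1)
  qb_neg <- bait_normalize(q_neg, d, "BAIT")
  prof_neg <- scale_profiles(compute_enrichment(qb_neg, d, proteins = "P1"))
  expect_equal(prof_neg$profiles$scaled, rep(0, 6))
  expect_true(is.na(prof_neg$scale$scale_max))
})

test_that("joint scaling scope shares one scale factor across conditions", {
  dA <- tiny_design(n_rep = 2L, condition = "WT")
  dB <- tiny_design(n_rep = 2L, condition = "MUT")
  d <- rbind(dA, dB)
  profA <- c(0.5, 1, 2, 1, 0.5, 0.25)   # max 2
  profB <- profA / 2                     # max 1
  qA <- quant_from_profile(dA, list(`1` = 2^profA, `2` = 2^profA))
  qB <- quant_from_profile(dB, list(`1` = 2^profB, `2` = 2^profB))
  q <- cbind(qA, qB[, dB$channel_id])
  qb <- bait_normalize(q, d, "BAIT")
  enr <- compute_enrichment(qb, d, proteins = "P1")

  joint <- scale_profiles(enr, "joint_across_conditions")
  pj <- joint$profiles
  expect_equal(max(pj$scaled[pj$condition == "WT"]), 1.0)
  expect_equal(max(pj$scaled[pj$condition == "MUT"]), 0.5)

  per <- scale_profiles(enr, "per_condition")
  pp <- per$profiles
  expect_equal(max(pp$scaled[pp$condition == "MUT"]), 1.0)
})

test_that("scaling is invariant to a constant gain on one replicate's channels", {
  d <- tiny_design(n_rep = 2L)
  set.seed(8)
  q <- matrix(rlnorm(6 * nrow(d), 6, 0.5), 6, nrow(d),
              dimnames = list(c("BAIT", sprintf("P%d", 1:5)), d$channel_id))
  gained <- q
  ch_r2 <- d$channel_id[d$replicate == 2]
  gained[, ch_r2] <- gained[, ch_r2] * 7.3
  p1 <- scale_profiles(compute_enrichment(bait_normalize(q, d, "BAIT"), d,
                                          proteins = sprintf("P%d", 1:5)))
  p2 <- scale_profiles(compute_enrichment(bait_normalize(gained, d, "BAIT"), d,
                                          proteins = sprintf("P%d", 1:5)))
  expect_equal(p1$profiles$scaled, p2$profiles$scaled)
})

test_that("excluding one replicate leaves the others' enrichments untouched", {
  d <- tiny_design(n_rep = 3L)
  set.seed(9)
  q <- matrix(rlnorm(4 * nrow(d), 6, 0.5), 4, nrow(d),
              dimnames = list(c("BAIT", sprintf("P%d", 1:3)), d$channel_id))
  qb <- bait_normalize(q, d, "BAIT")
  all_reps <- compute_enrichment(qb, d, proteins = sprintf("P%d", 1:3))
  kept <- compute_enrichment(qb, d, proteins = sprintf("P%d", 1:3),
                             keep_replicates = data.frame(condition = "WT",
                                                          replicate = c(1, 3)))
  sub <- all_reps[all_reps$replicate != 2, ]
  rownames(sub) <- NULL
  expect_equal(kept[order(kept$replicate, kept$protein_id, kept$timepoint_h), ],
               sub[order(sub$replicate, sub$protein_id, sub$timepoint_h), ],
               ignore_attr = TRUE)
})

test_that("pathway aggregates are order statistics of member profiles", {
  d <- tiny_design(n_rep = 2L)
  set.seed(10)
  ids <- sprintf("P%02d", 1:20)
  q <- matrix(rlnorm(21 * nrow(d), 6, 0.7), 21, nrow(d),
              dimnames = list(c("BAIT", ids), d$channel_id))
  prof <- scale_profiles(compute_enrichment(bait_normalize(q, d, "BAIT"), d,
                                            proteins = ids))
  map <- data.frame(protein_id = ids, pathway = "Hsp70/90-assisted folding")
  agg <- aggregate_pathways(prof, map)
  expect_true(all(agg$q1 <= agg$median + 1e-12 & agg$median <= agg$q3 + 1e-12))
  expect_true(all(agg$median >= 0 & agg$median <= 1))
  expect_equal(unique(agg$n_proteins), 20L)

  # a pathway made of one profile repeated collapses its band
  q3 <- q[c("BAIT", "P01", "P01", "P01"), ]
  rownames(q3) <- c("BAIT", "A", "B", "C")
  prof3 <- scale_profiles(compute_enrichment(bait_normalize(q3, d, "BAIT"), d,
                                             proteins = c("A", "B", "C")))
  agg3 <- aggregate_pathways(prof3, data.frame(protein_id = c("A", "B", "C"),
                                               pathway = "px"))
  expect_equal(agg3$q1, agg3$median)
  expect_equal(agg3$q3, agg3$median)

  expect_warning(
    aggregate_pathways(prof, data.frame(protein_id = "P01", pathway = "lonely")),
    "lonely")
})

test_that("profile features read peak, onset, area and tie rules off the grid", {
  mk_prof <- function(scaled) {
    structure(list(profiles = data.frame(
      protein_id = "P1", condition = "WT", timepoint_h = grid,
      mean_log2 = scaled, sem = 0, scaled = scaled, n_replicates = 2L),
      scale = data.frame(protein_id = "P1", scale_max = 1),
      grid = grid, scope = "joint_across_conditions"),
      class = "trip_profiles")
  }
  f <- profile_summary(mk_prof(c(0.25, 0.5, 1.0, 0.5, 0.25, 0.125)))
  expect_equal(f$peak_time, 1.0)
  expect_equal(f$onset_time, 0.5)
  expect_equal(f$peak_scaled, 1.0)
  expect_equal(f$area_under_profile,
               trip:::trapezoid_area(grid, c(0.25, 0.5, 1.0, 0.5, 0.25, 0.125)))

  f0 <- profile_summary(mk_prof(rep(0, 6)))
  expect_true(is.na(f0$peak_time))
  expect_true(is.na(f0$onset_time))
  expect_equal(f0$area_under_profile, 0)

  # plateau at the maximum: earliest timepoint wins
  fp <- profile_summary(mk_prof(c(0.2, 0.6, 1.0, 1.0, 0.4, 0.1)))
  expect_equal(fp$peak_time, 1.0)
})
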