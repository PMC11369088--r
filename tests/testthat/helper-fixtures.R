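# Shared fixtures and independent oracles, built in code at test time.

# independent brute-force BH step-up: sort, take running min of p * n / rank
# from the largest p down, cap at 1, return in input order
bh_brute_force <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- p[o] * (n / seq_len(n))
  for (i in (n - 1):1) if (n > 1) q[i] <- min(q[i], q[i + 1])
  q <- pmin(q, 1)
  out <- numeric(n)
  out[o] <- q
  out
}

# minimal valid design: one condition, `n_rep` replicates, full chase grid
# plus one background and one booster channel per replicate
tiny_design <- function(n_rep = 2L, condition = "WT",
                        grid = default_timepoint_grid()) {
  do.call(rbind, lapply(seq_len(n_rep), function(r) {
    data.frame(
      channel_id = c(sprintf("%s_r%d_t%g", condition, r, grid),
                     sprintf("%s_r%d_bg", condition, r),
                     sprintf("%s_r%d_boost", condition, r)),
      plex_id = sprintf("plex%02d", ceiling(r / 2)),
      condition = condition,
      timepoint_h = c(grid, NA, NA),
      replicate = r,
      role = c(rep("chase", length(grid)), "minus_hpg", "booster"),
      stringsAsFactors = FALSE)
  }))
}

# quant matrix with given values for one protein across a tiny_design,
# bait constant; used for hand-computed enrichment examples
quant_from_profile <- function(design, chase_by_rep, ref = 1,
                               protein = "P1", bait = "BAIT") {
  m <- matrix(NA_real_, 2, nrow(design),
              dimnames = list(c(bait, protein), design$channel_id))
  m[bait, ] <- 100
  for (r in names(chase_by_rep)) {
    rep_i <- as.integer(r)
    sel <- design$replicate == rep_i & design$role == "chase"
    m[protein, design$channel_id[sel]] <- chase_by_rep[[r]]
    m[protein, design$channel_id[design$replicate == rep_i &
                                   design$role == "minus_hpg"]] <- ref
    m[protein, design$channel_id[design$replicate == rep_i &
                                   design$role == "booster"]] <- ref
  }
  m * 1  # drop any integer storage
}

# small null simulation config used across calling tests
null_sim_config <- function(seed, n_background = 300L) {
  simulation_config(seed = seed, interactors = NULL,
                    n_background = n_background)
}
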