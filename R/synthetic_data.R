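#' Engagement-class kinetic presets
#'
#' Two-exponential engagement waves `E(t) = A * (exp(-k_off t) -
#' exp(-k_on t)) / max`, normalized to peak at `A`, produce the early,
#' intermediate and late peak classes seen in chase-resolved interactomes;
#' the flat class engages constitutively.
#'
#' @keywords internal
engagement_classes <- function() {
  list(early = c(k_on = 8,   k_off = 1.2),
       mid   = c(k_on = 1.5, k_off = 0.5),
       late  = c(k_on = 0.7, k_off = 0.18),
       flat  = c(k_on = NA,  k_off = NA))
}

#' Build a default interactor roster
#'
#' Deterministic roster with engagement amplitudes spread over
#' `[amplitude_min, 1]` within each class.
#'
#' @param n_early,n_mid,n_late,n_flat interactors per temporal class.
#' @param amplitude_min smallest engagement amplitude (default 0.4).
#' @return `data.frame`: `protein_id`, `class`, `A`, `k_on`, `k_off`.
#' @export
default_interactor_roster <- function(n_early = 6L, n_mid = 6L, n_late = 6L,
                                      n_flat = 6L, amplitude_min = 0.4) {
  cls <- engagement_classes()
  mk <- function(class, n) {
    if (n == 0L) return(NULL)
    data.frame(protein_id = sprintf("INT_%s_%02d", class, seq_len(n)),
               class = class,
               A = seq(1, amplitude_min, length.out = n),
               k_on = cls[[class]][["k_on"]], k_off = cls[[class]][["k_off"]],
               stringsAsFactors = FALSE)
  }
  do.call(rbind, c(lapply(names(cls), function(cl)
    mk(cl, c(early = n_early, mid = n_mid, late = n_late, flat = n_flat)[[cl]])),
    list(make.row.names = FALSE)))
}

#' Pulse-chase simulation configuration
#'
#' Defaults mirror the study design being emulated: a 6-timepoint chase grid
#' (0-3 h after a 1 h pulse), one minus-Hpg background and one booster
#' channel per (condition, replicate) packed two-per-16-plex, five
#' replicates for the wild-type-like condition and six for the mutant-like
#' condition, lognormal channel noise (SD 0.25 on the natural-log scale) and
#' left-censoring of the lowest 20% of intensities. Wild-type-like bait
#' kinetics are set so ~70% of the bait is secreted by 4 h; the mutant-like
#' condition is nearly secretion-dead with slow degradation.
#'
#' @param timepoint_grid chase grid in hours.
#' @param conditions named list of `list(k_s, k_d)` bait rates (1/h).
#' @param n_replicates named integer vector of replicates per condition.
#' @param interactors roster `data.frame` (see [default_interactor_roster()]).
#' @param n_background number of non-interactor proteins.
#' @param noise_sd lognormal channel noise SD (natural log).
#' @param channel_gain_sd per-channel loading gain SD (natural log).
#' @param censor_quantile detection-limit quantile for MNAR censoring.
#' @param floor background intensity floor.
#' @param enrichment_scale signal-to-floor ratio multiplying `B(t) * E(t)`.
#' @param booster_snr amplitude-weighted booster signal-to-floor ratio.
#' @param booster_log2fc optional planted booster log2 fold change (scalar
#'   or per-interactor), overriding the amplitude-weighted default.
#' @param booster_channel_gain bulk abundance gain of the booster channel.
#' @param bait_abundance bait intensity (constant across channels; channel
#'   gains multiply it so bait normalization has work to do).
#' @param seed integer RNG seed.
#' @return configuration list of class `trip_sim_config`.
#' @export
simulation_config <- function(timepoint_grid = default_timepoint_grid(),
                              conditions = list(
                                WT = list(k_s = -log(0.3) / 4, k_d = 0.01),
                                C1264R = list(k_s = 0.004, k_d = 0.042)),
                              n_replicates = c(WT = 5L, C1264R = 6L),
                              interactors = default_interactor_roster(),
                              n_background = 500L,
                              noise_sd = 0.25,
                              channel_gain_sd = 0.1,
                              censor_quantile = 0.20,
                              floor = 1e5,
                              enrichment_scale = 30,
                              booster_snr = 30,
                              booster_log2fc = NULL,
                              booster_channel_gain = 10,
                              bait_abundance = 1e8,
                              seed = 1L) {
  cfg <- list(timepoint_grid = timepoint_grid, conditions = conditions,
              n_replicates = n_replicates, interactors = interactors,
              n_background = as.integer(n_background), noise_sd = noise_sd,
              channel_gain_sd = channel_gain_sd,
              censor_quantile = censor_quantile, floor = floor,
              enrichment_scale = enrichment_scale, booster_snr = booster_snr,
              booster_log2fc = booster_log2fc,
              booster_channel_gain = booster_channel_gain,
              bait_abundance = bait_abundance, seed = as.integer(seed))
  if (any(diff(timepoint_grid) <= 0)) stop("timepoint grid must be strictly increasing")
  for (cn in names(conditions)) {
    r <- conditions[[cn]]
    if (r$k_s < 0 || r$k_d < 0) stop("rates must be non-negative")
  }
  if (!all(names(conditions) %in% names(n_replicates)))
    stop("n_replicates must name every condition")
  structure(cfg, class = "trip_sim_config")
}

#' Bait cohort kinetics
#'
#' The pulse-labeled bait cohort decays by first-order secretion (rate
#' `k_s`) and degradation (rate `k_d`):
#' `B(t) = exp(-(k_s + k_d) t)` (cohort fraction remaining), with secreted
#' and degraded fractions partitioned proportionally to the two rates.
#'
#' @param cfg `trip_sim_config`.
#' @param condition condition name.
#' @param t timepoints in hours (default the config grid).
#' @return `data.frame`: `timepoint_h`, `B`, `secreted_fraction`,
#'   `degraded_fraction`.
#' @export
simulate_bait <- function(cfg, condition, t = cfg$timepoint_grid) {
  r <- cfg$conditions[[condition]]
  if (is.null(r)) stop("unknown condition '", condition, "'")
  ktot <- r$k_s + r$k_d
  B <- exp(-ktot * t)
  lost <- 1 - B
  sec <- if (ktot > 0) r$k_s / ktot * lost else rep(0, length(t))
  deg <- if (ktot > 0) r$k_d / ktot * lost else rep(0, length(t))
  data.frame(timepoint_h = t, B = B, secreted_fraction = sec,
             degraded_fraction = deg)
}

#' Analytic engagement peak time
#' @param k_on,k_off onset and release rates (1/h), `k_on != k_off`.
#' @return peak time in hours.
#' @export
engagement_peak_time <- function(k_on, k_off) {
  if (k_on == k_off) stop("k_on must differ from k_off")
  log(k_on / k_off) / (k_on - k_off)
}

#' Interactor engagement fraction over time
#'
#' @param interactor one row of the roster (list or single-row
#'   `data.frame` with `class`, `A`, `k_on`, `k_off`).
#' @param t timepoints in hours.
#' @return engagement values `E(t)` in `[0, A]`.
#' @export
simulate_engagement <- function(interactor, t) {
  A <- interactor$A
  if (interactor$class == "flat") return(rep(A, length(t)))
  k_on <- interactor$k_on; k_off <- interactor$k_off
  if (k_on == k_off)
    stop("k_on = k_off is degenerate for a two-exponential class")
  tp <- engagement_peak_time(k_on, k_off)
  raw <- function(x) exp(-k_off * x) - exp(-k_on * x)
  A * raw(t) / raw(tp)
}

.sim_channels <- function(cfg) {
  rows <- list(); unit <- 0L
  for (cond in names(cfg$conditions)) {
    for (rep in seq_len(cfg$n_replicates[[cond]])) {
      unit <- unit + 1L
      plex <- sprintf("plex%02d", ceiling(unit / 2))
      ids <- c(sprintf("%s_r%d_t%g", cond, rep, cfg$timepoint_grid),
               sprintf("%s_r%d_bg", cond, rep),
               sprintf("%s_r%d_boost", cond, rep))
      rows[[unit]] <- data.frame(
        channel_id = ids, plex_id = plex, condition = cond,
        timepoint_h = c(cfg$timepoint_grid, NA, NA), replicate = rep,
        role = c(rep("chase", length(cfg$timepoint_grid)), "minus_hpg", "booster"),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Generate a complete synthetic TRIP dataset
#'
#' Emits a protein-by-channel quant matrix, its channel design and the
#' ground truth. Chase-channel intensity for interactor i in condition c is
#' `floor * (1 + enrichment_scale * B_c(t) * E_i(t))`, the minus-Hpg channel
#' sits at the background floor, and the booster channel carries every true
#' interactor at an amplitude-weighted (or explicitly planted) offset over
#' the floor, with the whole channel scaled up by `booster_channel_gain`.
#' Background proteins fluctuate around the floor everywhere and the bait
#' row is present in every channel. All cells are multiplied by a
#' per-channel loading gain and per-cell lognormal noise; intensities below
#' the `censor_quantile` detection limit are set missing (MNAR).
#'
#' The RNG substream order is fixed: channel gains first, then the noise
#' matrix protein-by-protein, so enlarging the roster appends draws without
#' reshuffling earlier proteins.
#'
#' @param cfg `trip_sim_config`.
#' @return list: `quant` (matrix), `design` (`data.frame`), `truth` (list
#'   with `interactors`, per-condition `grid_peak` table, `bait` curves,
#'   planted `booster_log2fc`, `censor_threshold`).
#' @export
emit_trip_dataset <- function(cfg) {
  design <- .sim_channels(cfg)
  grid <- cfg$timepoint_grid
  ints <- cfg$interactors
  n_int <- if (is.null(ints)) 0L else nrow(ints)
  prots <- c("BAIT_TG",
             if (n_int) ints$protein_id,
             if (cfg$n_background) sprintf("BG%04d", seq_len(cfg$n_background)))
  M <- matrix(cfg$floor, nrow = length(prots), ncol = nrow(design),
              dimnames = list(prots, design$channel_id))
  M["BAIT_TG", ] <- cfg$bait_abundance

  booster_fc <- if (n_int) {
    if (!is.null(cfg$booster_log2fc)) rep_len(cfg$booster_log2fc, n_int)
    else log2(1 + cfg$booster_snr * ints$A)
  } else numeric(0)

  B_by_cond <- lapply(names(cfg$conditions), function(cn)
    simulate_bait(cfg, cn, grid)$B)
  names(B_by_cond) <- names(cfg$conditions)

  if (n_int) {
    E <- t(vapply(seq_len(n_int),
                  function(i) simulate_engagement(ints[i, ], grid),
                  numeric(length(grid))))
    for (j in seq_len(nrow(design))) {
      ch <- design[j, ]
      if (ch$role == "chase") {
        ti <- match(ch$timepoint_h, grid)
        M[ints$protein_id, j] <- cfg$floor *
          (1 + cfg$enrichment_scale * B_by_cond[[ch$condition]][ti] * E[, ti])
      } else if (ch$role == "booster") {
        M[ints$protein_id, j] <- cfg$floor * 2^booster_fc
      }
    }
  }
  boost_cols <- design$role == "booster"
  M[, boost_cols] <- M[, boost_cols, drop = FALSE] * cfg$booster_channel_gain

  set.seed(cfg$seed)
  gains <- exp(stats::rnorm(nrow(design), 0, cfg$channel_gain_sd))
  z <- matrix(stats::rnorm(length(prots) * nrow(design)),
              nrow = length(prots), byrow = TRUE)
  Q <- M * rep(gains, each = length(prots)) * exp(cfg$noise_sd * z)

  censor_threshold <- NA_real_
  if (cfg$censor_quantile > 0) {
    nonbait <- Q[rownames(Q) != "BAIT_TG", , drop = FALSE]
    censor_threshold <- stats::quantile(nonbait, cfg$censor_quantile,
                                        names = FALSE)
    Q[Q < censor_threshold & rownames(Q) != "BAIT_TG"] <- NA_real_
  }

  grid_peak <- NULL
  if (n_int) {
    grid_peak <- do.call(rbind, lapply(names(cfg$conditions), function(cn) {
      sig <- sweep(E, 2L, B_by_cond[[cn]], "*")
      data.frame(protein_id = ints$protein_id, condition = cn,
                 peak_h = grid[apply(sig, 1L, which.max)],
                 stringsAsFactors = FALSE)
    }))
  }
  truth <- list(
    interactors = if (n_int) cbind(ints, analytic_peak_h = vapply(
      seq_len(n_int), function(i)
        if (ints$class[i] == "flat") NA_real_ else
          engagement_peak_time(ints$k_on[i], ints$k_off[i]), numeric(1)),
      booster_log2fc = booster_fc) else NULL,
    grid_peak = grid_peak,
    bait = lapply(names(cfg$conditions), function(cn) simulate_bait(cfg, cn)),
    censor_threshold = censor_threshold,
    bait_id = "BAIT_TG")
  names(truth$bait) <- names(cfg$conditions)
  list(quant = Q, design = design, truth = truth)
}

#' Simulate labeled scaled profiles for clustering benchmarks
#'
#' Draws unit-peak class template profiles on the grid (early/mid/late
#' two-exponential waves, constant for flat), adds Gaussian noise, and
#' clamps to `[0, 1]` — a direct test surface for the clustering stage with
#' known class labels.
#'
#' @param n_per_class profiles per class.
#' @param classes subset of `c("early", "mid", "late", "flat")`.
#' @param noise_sd Gaussian noise SD on the scaled profiles.
#' @param seed integer RNG seed.
#' @param grid timepoint grid.
#' @return list: `x` (profile matrix with `sim@t` columns), `class` (true
#'   labels).
#' @export
simulate_profiles <- function(n_per_class = 20L,
                              classes = c("early", "late", "flat"),
                              noise_sd = 0.1, seed = 1L,
                              grid = default_timepoint_grid()) {
  cls <- engagement_classes()
  bad <- setdiff(classes, names(cls))
  if (length(bad)) stop("unknown class(es): ", paste(bad, collapse = ", "))
  templates <- lapply(classes, function(cl) {
    if (cl == "flat") return(rep(1, length(grid)))
    row <- list(class = cl, A = 1, k_on = cls[[cl]][["k_on"]],
                k_off = cls[[cl]][["k_off"]])
    e <- simulate_engagement(row, grid)
    e / max(e)
  })
  set.seed(as.integer(seed))
  x <- do.call(rbind, lapply(seq_along(classes), function(i) {
    t(replicate(n_per_class,
                pmin(pmax(templates[[i]] + stats::rnorm(length(grid), 0, noise_sd), 0), 1)))
  }))
  rownames(x) <- sprintf("P_%s_%02d", rep(classes, each = n_per_class),
                         sequence(rep(n_per_class, length(classes))))
  colnames(x) <- paste("sim", grid, sep = "@")
  list(x = x, class = rep(classes, each = n_per_class))
}

#' siRNA screen simulation configuration
#'
#' Defaults emulate the screen design being modeled: 167 target genes in
#' 96-well plates with four control types (non-targeting, siGLO, vehicle,
#' TOX), lysate and media readouts, two replicate experiments for the
#' wild-type-like and fully retained constructs and three for the partially
#' secreted mutant.
#'
#' @param genes gene identifiers.
#' @param replicates named integer vector of replicates per construct.
#' @param readouts readout names.
#' @param test_capacity test wells per plate (<= 86 with 10 control wells).
#' @param controls named counts of control wells per plate.
#' @param noise_sd lognormal well noise SD (natural log).
#' @param plate_gain_sd lognormal per-plate gain SD (natural log).
#' @param tox_level TOX control level relative to test wells.
#' @param planted_hits optional `data.frame(gene, construct, readout,
#'   effect)` of multiplicative planted effects.
#' @param seed integer RNG seed.
#' @return configuration list.
#' @export
screen_config <- function(genes = sprintf("GENE%03d", 1:167),
                          replicates = c(WT = 2L, A2234D = 2L, C1264R = 3L),
                          readouts = c("lysate", "media"),
                          test_capacity = 86L,
                          controls = c(non_targeting = 4L, siGLO = 2L,
                                       vehicle = 2L, TOX = 2L),
                          noise_sd = 0.1, plate_gain_sd = 0.3,
                          tox_level = 0.01, planted_hits = NULL,
                          seed = 1L) {
  if (test_capacity + sum(controls) > 96L) stop("plate capacity exceeded")
  list(genes = genes, replicates = replicates, readouts = readouts,
       test_capacity = as.integer(test_capacity), controls = controls,
       noise_sd = noise_sd, plate_gain_sd = plate_gain_sd,
       tox_level = tox_level, planted_hits = planted_hits,
       seed = as.integer(seed))
}

#' Generate synthetic siRNA screen plates
#'
#' Well luminescence is `plate gain x gene effect x lognormal noise`; null
#' genes and the non-targeting, siGLO and vehicle controls sit at effect 1,
#' TOX (lethal) wells near zero, and planted hits multiply by their stated
#' effect size. Deterministic given the config seed (plates are generated
#' in construct, readout, replicate, plate order; the plate gain is drawn
#' before its well noise).
#'
#' @param cfg configuration from [screen_config()].
#' @return list: `plates` (long-format well `data.frame`), `truth` (planted
#'   hits table, possibly `NULL`).
#' @export
emit_screen_dataset <- function(cfg) {
  set.seed(cfg$seed)
  n_plates <- ceiling(length(cfg$genes) / cfg$test_capacity)
  gene_plate <- rep(seq_len(n_plates), each = cfg$test_capacity)[seq_along(cfg$genes)]
  well_names <- as.vector(outer(sprintf("%02d", 1:12), LETTERS[1:8],
                                function(c, r) paste0(r, c)))
  out <- list()
  for (construct in names(cfg$replicates)) {
    for (readout in cfg$readouts) {
      for (repl in seq_len(cfg$replicates[[construct]])) {
        for (pl in seq_len(n_plates)) {
          gain <- exp(stats::rnorm(1, 0, cfg$plate_gain_sd))
          g <- cfg$genes[gene_plate == pl]
          roles <- c(rep("test", length(g)),
                     rep(names(cfg$controls), times = cfg$controls))
          genes <- c(g, rep(NA_character_, sum(cfg$controls)))
          eff <- rep(1, length(roles))
          eff[roles == "TOX"] <- cfg$tox_level
          if (!is.null(cfg$planted_hits)) {
            hit <- cfg$planted_hits[cfg$planted_hits$construct == construct &
                                      cfg$planted_hits$readout == readout, ,
                                    drop = FALSE]
            idx <- match(genes, hit$gene)
            eff[!is.na(idx)] <- hit$effect[idx[!is.na(idx)]]
          }
          lum <- gain * eff * exp(stats::rnorm(length(roles), 0, cfg$noise_sd))
          out[[length(out) + 1L]] <- data.frame(
            plate_id = sprintf("%s_%s_rep%d_p%d", construct, readout, repl, pl),
            construct = construct, readout = readout, replicate = repl,
            well = well_names[seq_along(roles)], role = roles, gene = genes,
            luminescence = lum, stringsAsFactors = FALSE)
        }
      }
    }
  }
  list(plates = do.call(rbind, out), truth = cfg$planted_hits)
}
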