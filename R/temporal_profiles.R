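#' Normalize channels to the bait protein's abundance
#'
#' Divides every protein's intensity in a channel by the bait's intensity in
#' that channel (chase and minus-Hpg channels only; the booster channel is
#' left untouched). This cancels per-channel loading and labeling gains and
#' accounts for the gradual loss of bait to secretion and degradation over
#' the chase, so that downstream ratios reflect interaction stoichiometry
#' relative to the bait. The bait row becomes identically 1 in the
#' normalized channels.
#'
#' @param q linear-scale quant matrix.
#' @param design channel design.
#' @param bait_id protein accession of the bait.
#' @return bait-normalized matrix.
#' @export
bait_normalize <- function(q, design, bait_id) {
  validate_quant_matrix(q)
  if (!bait_id %in% rownames(q)) stop("bait '", bait_id, "' not in matrix")
  ch <- as.character(design$channel_id[design$role %in% c("chase", "minus_hpg")])
  ch <- intersect(ch, colnames(q))
  bait <- q[bait_id, ch]
  bad <- ch[!is.finite(bait) | bait <= 0]
  if (length(bad))
    stop("bait missing or non-positive in channel(s): ",
         paste(bad, collapse = ", "),
         " (candidate replicate exclusion; see qc_replicates())")
  q[, ch] <- sweep(q[, ch, drop = FALSE], 2L, bait, "/")
  q
}

#' Replicate quality control on bait quantification
#'
#' A replicate is excluded when the bait is unquantified in any of its chase
#' or background channels, or when the bait's coefficient of variation
#' across that replicate's chase channels exceeds `cv_threshold` —
#' operationalizing the exclusion of replicates with inconsistent bait
#' recovery (e.g. sample loss during enrichment). Excluded replicates are
#' dropped from all downstream averaging.
#'
#' @param q linear-scale (pre-bait-normalization) quant matrix.
#' @param design channel design.
#' @param bait_id bait accession.
#' @param cv_threshold CV cutoff on raw bait intensity (default 0.5).
#' @return `data.frame` with one row per (condition, replicate):
#'   `bait_complete`, `bait_cv`, `excluded`, `reason`.
#' @export
qc_replicates <- function(q, design, bait_id, cv_threshold = 0.5) {
  validate_quant_matrix(q)
  if (!bait_id %in% rownames(q)) stop("bait '", bait_id, "' not in matrix")
  cr <- unique(design[design$role == "chase", c("condition", "replicate")])
  cr <- cr[order(cr$condition, cr$replicate), , drop = FALSE]
  out <- lapply(seq_len(nrow(cr)), function(i) {
    sel <- design$condition == cr$condition[i] & design$replicate == cr$replicate[i]
    ch_chase <- as.character(design$channel_id[sel & design$role == "chase"])
    ch_all <- as.character(design$channel_id[sel & design$role %in% c("chase", "minus_hpg")])
    bait_all <- q[bait_id, intersect(ch_all, colnames(q))]
    complete <- length(bait_all) == length(ch_all) && all(is.finite(bait_all) & bait_all > 0)
    bait_chase <- q[bait_id, intersect(ch_chase, colnames(q))]
    bv <- bait_chase[is.finite(bait_chase)]
    cv <- if (length(bv) >= 2L) stats::sd(bv) / mean(bv) else NA_real_
    excluded <- FALSE; reason <- ""
    if (!complete) { excluded <- TRUE; reason <- "bait missing" }
    else if (is.finite(cv) && cv > cv_threshold) {
      excluded <- TRUE; reason <- sprintf("bait CV %.3f > %.3f", cv, cv_threshold)
    }
    data.frame(condition = cr$condition[i], replicate = cr$replicate[i],
               bait_complete = complete, bait_cv = cv,
               excluded = excluded, reason = reason,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Per-replicate log2 enrichment over the minus-Hpg background
#'
#' For each protein, condition, replicate and chase timepoint computes
#' `log2(chase / reference)` on bait-normalized intensities, where the
#' reference is that replicate's own minus-Hpg channel (default) or the
#' condition-average background. Missing or non-positive chase or reference
#' values yield missing enrichment, never infinities.
#'
#' @param q bait-normalized quant matrix.
#' @param design channel design.
#' @param reference `"replicate_matched"` (default) or `"condition_average"`.
#' @param proteins optional subset of protein ids to profile.
#' @param keep_replicates optional `data.frame(condition, replicate)` of
#'   replicates to retain (e.g. the non-excluded rows of [qc_replicates()]).
#' @return long `data.frame`: `protein_id`, `condition`, `replicate`,
#'   `timepoint_h`, `log2_enrichment`.
#' @export
compute_enrichment <- function(q, design,
                               reference = c("replicate_matched", "condition_average"),
                               proteins = NULL, keep_replicates = NULL) {
  reference <- match.arg(reference)
  validate_quant_matrix(q, allow_negative = TRUE)
  if (is.null(proteins)) proteins <- rownames(q)
  proteins <- intersect(proteins, rownames(q))
  chase <- design[design$role == "chase", , drop = FALSE]
  if (!is.null(keep_replicates)) {
    key <- paste(chase$condition, chase$replicate)
    chase <- chase[key %in% paste(keep_replicates$condition, keep_replicates$replicate), ,
                   drop = FALSE]
  }
  cr <- unique(chase[, c("condition", "replicate")])
  pieces <- vector("list", nrow(cr))
  for (i in seq_len(nrow(cr))) {
    cond <- cr$condition[i]; repl <- cr$replicate[i]
    sub <- chase[chase$condition == cond & chase$replicate == repl, , drop = FALSE]
    sub <- sub[order(sub$timepoint_h), , drop = FALSE]
    ref_ch <- as.character(design$channel_id[design$role == "minus_hpg" &
                                               design$condition == cond &
                                               if (reference == "replicate_matched")
                                                 design$replicate == repl else TRUE])
    if (!length(ref_ch) || !all(ref_ch %in% colnames(q)))
      stop(sprintf("reference channel absent for (condition %s, replicate %d)", cond, repl))
    ref <- if (length(ref_ch) == 1L) q[proteins, ref_ch] else
      rowMeans(q[proteins, ref_ch, drop = FALSE], na.rm = TRUE)
    ref[!is.finite(ref) | ref <= 0] <- NA_real_
    vals <- q[proteins, as.character(sub$channel_id), drop = FALSE]
    vals[!is.finite(vals) | vals <= 0] <- NA_real_
    enr <- log2(sweep(vals, 1L, ref, "/"))
    pieces[[i]] <- data.frame(
      protein_id = rep(proteins, times = nrow(sub)),
      condition = cond, replicate = repl,
      timepoint_h = rep(sub$timepoint_h, each = length(proteins)),
      log2_enrichment = as.vector(enr),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, pieces)
}

#' Scale mean enrichment profiles to the unit interval
#'
#' Replicate log2 enrichments are averaged per (protein, condition,
#' timepoint); negative means are clamped to 0 (enrichment below background);
#' the clamped means are divided by the maximum positive value within the
#' protein's scaling group so the maximum maps to exactly 1. With the
#' default joint scope one scale factor is shared across conditions per
#' protein, so cross-condition amplitude differences remain visible; with
#' per-condition scope each condition peaks at 1 independently. The SEM of
#' the replicate means is divided by the same factor. A group with no
#' positive mean yields an all-zero profile and an absent `scale_max`.
#' Timepoints missing in every replicate stay missing.
#'
#' @param enr long enrichment table from [compute_enrichment()].
#' @param scaling_scope `"joint_across_conditions"` (default) or
#'   `"per_condition"`.
#' @return object of class `trip_profiles`: list with `profiles` (long
#'   `data.frame`: `protein_id`, `condition`, `timepoint_h`, `mean_log2`,
#'   `sem`, `scaled`, `n_replicates`), `scale` (per scaling group
#'   `scale_max`), `grid`, `scope`.
#' @export
scale_profiles <- function(enr,
                           scaling_scope = c("joint_across_conditions", "per_condition")) {
  scaling_scope <- match.arg(scaling_scope)
  grids <- tapply(enr$timepoint_h, enr$condition,
                  function(t) paste(sort(unique(t)), collapse = ","))
  if (scaling_scope == "joint_across_conditions" && length(unique(grids)) > 1L)
    stop("joint scaling requires all conditions on the same timepoint grid")
  n_rep <- tapply(enr$replicate, enr$condition, function(r) length(unique(r)))
  if (any(n_rep < 2L))
    stop("need >= 2 replicates per condition after QC: ",
         paste(names(n_rep)[n_rep < 2L], collapse = ", "))

  ag <- stats::aggregate(enr$log2_enrichment,
                         by = list(protein_id = enr$protein_id,
                                   condition = enr$condition,
                                   timepoint_h = enr$timepoint_h),
                         FUN = function(x) {
                           x <- x[is.finite(x)]
                           c(mean = if (length(x)) mean(x) else NA_real_,
                             sem = if (length(x) >= 2L) stats::sd(x) / sqrt(length(x)) else NA_real_,
                             n = length(x))
                         })
  prof <- data.frame(protein_id = ag$protein_id, condition = ag$condition,
                     timepoint_h = ag$timepoint_h,
                     mean_log2 = ag$x[, "mean"], sem = ag$x[, "sem"],
                     n_replicates = as.integer(ag$x[, "n"]),
                     stringsAsFactors = FALSE)
  prof <- prof[order(prof$protein_id, prof$condition, prof$timepoint_h), ]
  rownames(prof) <- NULL

  clamped <- pmax(prof$mean_log2, 0)
  group <- if (scaling_scope == "joint_across_conditions") prof$protein_id else
    paste(prof$protein_id, prof$condition, sep = "\r")
  smax <- tapply(clamped, group, function(x) {
    x <- x[is.finite(x) & x > 0]
    if (length(x)) max(x) else NA_real_
  })
  sm <- as.vector(smax[group])
  scaled <- ifelse(is.na(prof$mean_log2), NA_real_,
                   ifelse(is.na(sm), 0, clamped / sm))
  prof$scaled <- scaled
  prof$sem <- ifelse(is.na(sm), prof$sem, prof$sem / sm)

  scale_tab <- if (scaling_scope == "joint_across_conditions")
    data.frame(protein_id = names(smax), scale_max = as.vector(smax),
               stringsAsFactors = FALSE)
  else {
    p <- do.call(rbind, strsplit(names(smax), "\r", fixed = TRUE))
    data.frame(protein_id = p[, 1L], condition = p[, 2L],
               scale_max = as.vector(smax), stringsAsFactors = FALSE)
  }
  structure(list(profiles = prof, scale = scale_tab,
                 grid = sort(unique(enr$timepoint_h)), scope = scaling_scope),
            class = "trip_profiles")
}

#' @export
print.trip_profiles <- function(x, ...) {
  cat(sprintf("TRIP temporal profiles: %d proteins x %d condition(s), grid {%s} h, %s scaling\n",
              length(unique(x$profiles$protein_id)),
              length(unique(x$profiles$condition)),
              paste(x$grid, collapse = ", "), x$scope))
  invisible(x)
}

#' Pathway-level profile aggregates
#'
#' Median and first/third quartile (linear-interpolation, type 7 convention)
#' of member scaled enrichments per (pathway, condition, timepoint), for
#' ribbon plots of pathway engagement. Pathways with fewer than two mapped
#' profiled proteins are skipped with a warning.
#'
#' @param profiles `trip_profiles` object.
#' @param map pathway map `data.frame` (`protein_id`, `pathway`).
#' @return `data.frame`: `pathway`, `condition`, `timepoint_h`, `median`,
#'   `q1`, `q3`, `n_proteins`.
#' @export
aggregate_pathways <- function(profiles, map) {
  prof <- profiles$profiles
  prof <- merge(prof, map, by = "protein_id")
  out <- list()
  for (pw in sort(unique(map$pathway))) {
    sub <- prof[prof$pathway == pw, , drop = FALSE]
    if (length(unique(sub$protein_id)) < 2L) {
      warning("pathway '", pw, "' has < 2 profiled proteins; skipped")
      next
    }
    key <- interaction(sub$condition, sub$timepoint_h, drop = TRUE)
    agg <- do.call(rbind, lapply(split(sub, key), function(s) {
      x <- s$scaled[is.finite(s$scaled)]
      qs <- if (length(x)) stats::quantile(x, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
        else rep(NA_real_, 3L)
      data.frame(pathway = pw, condition = s$condition[1L],
                 timepoint_h = s$timepoint_h[1L],
                 median = qs[2L], q1 = qs[1L], q3 = qs[3L],
                 n_proteins = length(x), stringsAsFactors = FALSE)
    }))
    out[[pw]] <- agg
  }
  res <- do.call(rbind, out)
  if (is.null(res)) return(res)
  res <- res[order(res$pathway, res$condition, res$timepoint_h), ]
  rownames(res) <- NULL
  res
}

#' Per-profile summary features
#'
#' Peak time (earliest timepoint attaining the maximum scaled value), peak
#' scaled value, trapezoidal area under the scaled profile, and onset time
#' (first timepoint with scaled enrichment >= 0.5). All-zero profiles have
#' absent peak/onset and zero area.
#'
#' @param profiles `trip_profiles` object.
#' @return `data.frame`: `protein_id`, `condition`, `peak_time`,
#'   `peak_scaled`, `area_under_profile`, `onset_time`.
#' @export
profile_summary <- function(profiles) {
  prof <- profiles$profiles
  key <- interaction(prof$protein_id, prof$condition, drop = TRUE)
  res <- do.call(rbind, lapply(split(prof, key), function(s) {
    s <- s[order(s$timepoint_h), , drop = FALSE]
    obs <- is.finite(s$scaled)
    t <- s$timepoint_h[obs]; y <- s$scaled[obs]
    any_pos <- length(y) > 0L && any(y > 0)
    peak_time <- if (any_pos) t[which.max(y)] else NA_real_
    onset <- if (any_pos && any(y >= 0.5)) t[which(y >= 0.5)[1L]] else NA_real_
    auc <- if (length(y) >= 2L) trapezoid_area(t, y) else 0
    data.frame(protein_id = s$protein_id[1L], condition = s$condition[1L],
               peak_time = peak_time,
               peak_scaled = if (length(y)) max(y) else NA_real_,
               area_under_profile = auc, onset_time = onset,
               stringsAsFactors = FALSE)
  }))
  res <- res[order(res$protein_id, res$condition), ]
  rownames(res) <- NULL
  res
}

#' Wide scaled-profile matrix for heatmaps
#'
#' Rows are proteins, columns `condition@timepoint`, values scaled
#' enrichment; rows ordered by peak time then protein id for stable display.
#'
#' @param profiles `trip_profiles` object.
#' @return numeric matrix.
#' @export
profiles_heatmap_matrix <- function(profiles) {
  prof <- profiles$profiles
  col <- paste(prof$condition, prof$timepoint_h, sep = "@")
  cols <- unique(col[order(prof$condition, prof$timepoint_h)])
  prots <- unique(prof$protein_id)
  m <- matrix(NA_real_, length(prots), length(cols), dimnames = list(prots, cols))
  m[cbind(match(prof$protein_id, prots), match(col, cols))] <- prof$scaled
  feats <- profile_summary(profiles)
  pk <- tapply(feats$peak_time, feats$protein_id, function(x) suppressWarnings(min(x, na.rm = TRUE)))
  pk[!is.finite(pk)] <- Inf
  m[order(pk[prots], prots), , drop = FALSE]
}
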