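#' Valid screen well roles
#' @keywords internal
screen_roles <- function() c("test", "non_targeting", "siGLO", "vehicle", "TOX")

#' Read long-format screen plate tables
#'
#' One row per well: `plate_id`, `construct`, `readout` (lysate or media),
#' `replicate`, `well`, `role` (test well or one of the four control types),
#' `gene` (empty for controls), `luminescence`.
#'
#' @param path TSV/CSV file.
#' @param sep optional separator override.
#' @return validated `data.frame` of wells.
#' @export
read_screen_plates <- function(path, sep = NULL) {
  p <- utils::read.table(path, header = TRUE, sep = .sniff_sep(path, sep),
                         stringsAsFactors = FALSE, quote = "",
                         na.strings = c("", "NA"))
  validate_screen_plates(p)
}

#' Validate screen plate wells
#' @param p long-format well `data.frame`.
#' @return `p` after validation.
#' @export
validate_screen_plates <- function(p) {
  needed <- c("plate_id", "construct", "readout", "replicate", "well", "role",
              "gene", "luminescence")
  miss <- setdiff(needed, names(p))
  if (length(miss)) stop("plate table missing columns: ", paste(miss, collapse = ", "))
  bad <- setdiff(unique(p$role), screen_roles())
  if (length(bad)) stop("unknown well role(s): ", paste(bad, collapse = ", "))
  if (!all(p$readout %in% c("lysate", "media")))
    stop("readout must be 'lysate' or 'media'")
  if (any(p$luminescence < 0, na.rm = TRUE)) stop("negative luminescence")
  n_wells <- table(paste(p$plate_id, p$readout, p$replicate))
  if (any(n_wells > 96L)) stop("a plate holds at most 96 wells")
  p
}

#' Median-normalize screen plates
#'
#' Each well on a plate is divided by the median luminescence of that
#' plate's test wells (controls are excluded from the median so the lethal
#' TOX wells cannot drag it down). After the call the test-well median of
#' every plate is exactly 1, and any per-plate multiplicative gain is
#' removed.
#'
#' @param p long-format well `data.frame`; a plate is a
#'   (plate_id, construct, readout, replicate) group.
#' @param min_test_wells minimum test wells required per plate (default 8).
#' @return `p` with `luminescence` replaced by plate-median units.
#' @export
normalize_plate <- function(p, min_test_wells = 8L) {
  validate_screen_plates(p)
  key <- paste(p$plate_id, p$construct, p$readout, p$replicate, sep = "\r")
  for (k in unique(key)) {
    sel <- key == k
    test <- sel & p$role == "test"
    if (sum(test) < min_test_wells)
      stop("plate '", p$plate_id[sel][1L], "' has fewer than ", min_test_wells,
           " test wells")
    med <- stats::median(p$luminescence[test], na.rm = TRUE)
    if (!is.finite(med) || med == 0) stop("zero test-well median on plate '",
                                          p$plate_id[sel][1L], "'")
    p$luminescence[sel] <- p$luminescence[sel] / med
  }
  p
}

#' Call screen hits at a sigma-multiple cutoff
#'
#' Per (gene, construct, readout), normalized values are averaged across
#' replicate plates; within each (construct, readout) stratum the center is
#' the median of per-gene means and sigma is their normal-consistent MAD
#' (plain SD available). A gene is a hit when its standardized score
#' `(mean - center) / sigma` exceeds `sigma_multiplier` in absolute value,
#' with direction given by the sign — i.e. genes whose silencing increases
#' or decreases reporter abundance by more than 3 sigma under the defaults.
#'
#' @param p normalized plate wells (see [normalize_plate()]).
#' @param sigma_multiplier hit cutoff in sigma units (default 3).
#' @param min_replicates drop genes observed on fewer replicate plates
#'   (default 2).
#' @param sigma_estimator `"mad"` (default) or `"sd"`.
#' @return `data.frame`: `gene`, `construct`, `readout`, `normalized_mean`,
#'   `score`, `hit`, `direction`, `n_replicates`; per-stratum `center` and
#'   `sigma` attached as attribute `"calibration"`.
#' @export
call_screen_hits <- function(p, sigma_multiplier = 3, min_replicates = 2L,
                             sigma_estimator = c("mad", "sd")) {
  sigma_estimator <- match.arg(sigma_estimator)
  tw <- p[p$role == "test" & !is.na(p$gene), , drop = FALSE]
  ag <- stats::aggregate(tw$luminescence,
                         by = list(gene = tw$gene, construct = tw$construct,
                                   readout = tw$readout),
                         FUN = function(x) c(mean = mean(x, na.rm = TRUE),
                                             n = sum(is.finite(x))))
  res <- data.frame(gene = ag$gene, construct = ag$construct,
                    readout = ag$readout,
                    normalized_mean = ag$x[, "mean"],
                    n_replicates = as.integer(ag$x[, "n"]),
                    stringsAsFactors = FALSE)
  res <- res[res$n_replicates >= min_replicates, , drop = FALSE]
  res$score <- NA_real_
  calib <- list()
  for (k in unique(paste(res$construct, res$readout, sep = "\r"))) {
    sel <- paste(res$construct, res$readout, sep = "\r") == k
    x <- res$normalized_mean[sel]
    center <- stats::median(x)
    sigma <- robust_sigma(x, sigma_estimator)
    if (sigma == 0) stop("zero sigma in stratum ", gsub("\r", "/", k))
    res$score[sel] <- (x - center) / sigma
    calib[[gsub("\r", "/", k)]] <- c(center = center, sigma = sigma)
  }
  res$hit <- abs(res$score) >= sigma_multiplier
  res$direction <- ifelse(res$score >= 0, "up", "down")
  res <- res[order(res$construct, res$readout, -abs(res$score)), ]
  rownames(res) <- NULL
  attr(res, "calibration") <- calib
  attr(res, "sigma_multiplier") <- sigma_multiplier
  res
}

#' Control QC across screen plates
#'
#' Per plate: mean and CV of the non-targeting siRNA control, the TOX
#' (lethal) control signal as a fraction of the test-well median — the
#' kill-control viability check — and the vehicle-vs-non-targeting delta.
#' Plates failing the configurable bounds, or lacking any of the four
#' control types, are flagged.
#'
#' @param p plate wells (raw or normalized).
#' @param nt_cv_max maximum acceptable non-targeting CV (default 0.3).
#' @param tox_ratio_max maximum TOX/test-median ratio for a working kill
#'   control (default 0.2).
#' @return `data.frame` with one row per plate and a `flag` column
#'   (empty when the plate passes).
#' @export
summarize_controls <- function(p, nt_cv_max = 0.3, tox_ratio_max = 0.2) {
  validate_screen_plates(p)
  key <- unique(p[, c("plate_id", "construct", "readout", "replicate")])
  out <- lapply(seq_len(nrow(key)), function(i) {
    sel <- p$plate_id == key$plate_id[i] & p$construct == key$construct[i] &
      p$readout == key$readout[i] & p$replicate == key$replicate[i]
    w <- p[sel, , drop = FALSE]
    flags <- character(0)
    if (!all(setdiff(screen_roles(), "test") %in% w$role))
      flags <- c(flags, "controls incomplete")
    test_med <- stats::median(w$luminescence[w$role == "test"], na.rm = TRUE)
    nt <- w$luminescence[w$role == "non_targeting"]
    nt_mean <- mean(nt, na.rm = TRUE)
    nt_cv <- if (sum(is.finite(nt)) >= 2L) stats::sd(nt, na.rm = TRUE) / nt_mean else NA_real_
    if (is.finite(nt_cv) && nt_cv > nt_cv_max)
      flags <- c(flags, sprintf("non-targeting CV %.2f", nt_cv))
    tox_ratio <- mean(w$luminescence[w$role == "TOX"], na.rm = TRUE) / test_med
    if (is.finite(tox_ratio) && tox_ratio > tox_ratio_max)
      flags <- c(flags, sprintf("TOX ratio %.2f", tox_ratio))
    veh_delta <- mean(w$luminescence[w$role == "vehicle"], na.rm = TRUE) - nt_mean
    data.frame(key[i, , drop = FALSE],
               nt_mean = nt_mean, nt_cv = nt_cv, tox_ratio = tox_ratio,
               vehicle_vs_nt = veh_delta,
               flag = paste(flags, collapse = "; "),
               stringsAsFactors = FALSE, row.names = NULL)
  })
  do.call(rbind, out)
}
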