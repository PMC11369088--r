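#' Log2-transform a quantification matrix
#'
#' @param q linear-scale quant matrix (values >= 0).
#' @param pseudocount non-negative value added before taking log2.
#' @return log2-scale matrix; missing entries stay missing.
#' @export
log_transform <- function(q, pseudocount = 0) {
  validate_quant_matrix(q)
  stopifnot_scalar_number(pseudocount, "pseudocount")
  if (pseudocount < 0) stop("pseudocount must be non-negative")
  log2(q + pseudocount)
}

#' Median-align channels of a log2 matrix
#'
#' Subtracts each channel's median over observed values and adds back the
#' grand median, so all channel medians coincide afterwards. This removes
#' per-channel loading/labeling offsets (including the deliberate abundance
#' offset of the booster channel) before differential testing.
#'
#' @param q log2-scale quant matrix.
#' @return matrix with equalized channel medians.
#' @export
median_normalize <- function(q) {
  validate_quant_matrix(q, allow_negative = TRUE)
  n_obs <- colSums(!is.na(q))
  if (any(n_obs == 0L))
    stop("channel(s) with zero observed values: ",
         paste(colnames(q)[n_obs == 0L], collapse = ", "))
  med <- apply(q, 2L, stats::median, na.rm = TRUE)
  grand <- stats::median(q, na.rm = TRUE)
  sweep(q, 2L, med - grand, "-")
}

#' Left-censored missing-value imputation
#'
#' Missing TMT intensities are predominantly below the detection limit
#' (missing not at random), so each missing cell in channel `c` is drawn from
#' a down-shifted narrow normal,
#' `Normal(mu_c - shift * sd_c, (width * sd_c)^2)`, with `mu_c`, `sd_c` the
#' observed mean and SD of that channel. Observed values are untouched and
#' the result is deterministic given `seed`.
#'
#' @param q log2-scale, normalized quant matrix.
#' @param shift down-shift in channel SD units (default 1.8).
#' @param width width of the imputation distribution in channel SD units,
#'   in (0, 1] (default 0.3).
#' @param seed integer RNG seed.
#' @return matrix with no missing values.
#' @export
impute_minprob <- function(q, shift = 1.8, width = 0.3, seed = 1L) {
  validate_quant_matrix(q, allow_negative = TRUE)
  stopifnot_scalar_number(shift, "shift")
  stopifnot_scalar_number(width, "width")
  if (width <= 0) stop("width must be > 0")
  if (!any(is.na(q))) return(q)
  n_obs <- colSums(!is.na(q))
  if (any(n_obs < 10L))
    stop("channel(s) with fewer than 10 observed values: ",
         paste(colnames(q)[n_obs < 10L], collapse = ", "))
  set.seed(as.integer(seed))
  for (j in seq_len(ncol(q))) {
    miss <- which(is.na(q[, j]))
    if (!length(miss)) next
    mu <- mean(q[, j], na.rm = TRUE)
    sd_c <- stats::sd(q[, j], na.rm = TRUE)
    q[miss, j] <- stats::rnorm(length(miss), mu - shift * sd_c, width * sd_c)
  }
  q
}

# Newton inversion of the trigamma function (solve trigamma(y) = x, y > 0)
trigamma_inverse <- function(x) {
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, deriv = 2L)
    y <- y + dif
    if (abs(dif / y) < 1e-10) break
  }
  y
}

#' Fit the empirical-Bayes variance prior
#'
#' Per-protein sample variances are modeled as scaled chi-square draws around
#' protein-level true variances that themselves follow a scaled inverse
#' chi-square prior with `d0` degrees of freedom and scale `s2_prior`. The
#' prior is fit by moment matching on the log variances: the excess
#' dispersion of `log(s^2)` beyond the trigamma term implied by the residual
#' degrees of freedom determines `d0`; when no excess dispersion remains the
#' prior is degenerate (`d0 = Inf`) and `s2_prior` is the mean variance.
#'
#' @param sample_variances positive per-protein sample variances.
#' @param residual_df residual degrees of freedom per variance (scalar).
#' @return list of class `trip_moderation` with `s2_prior`, `d0`,
#'   `residual_df`.
#' @export
fit_moderation <- function(sample_variances, residual_df) {
  s2 <- sample_variances[is.finite(sample_variances) & sample_variances > 0]
  if (length(s2) < 3L) stop("need >= 3 finite positive sample variances")
  if (residual_df < 1) stop("residual_df must be >= 1")
  df <- residual_df
  e <- log(s2) - digamma(df / 2) + log(df / 2)
  emean <- mean(e)
  evar <- stats::var(e) - trigamma(df / 2)
  if (is.finite(evar) && evar > 0) {
    d0 <- 2 * trigamma_inverse(evar)
    s2_prior <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  } else {
    d0 <- Inf
    s2_prior <- mean(s2)
  }
  structure(list(s2_prior = s2_prior, d0 = d0, residual_df = residual_df),
            class = "trip_moderation")
}

#' Moderated two-group enrichment test (booster vs background)
#'
#' For each protein the log2 fold change is the mean over booster channels
#' minus the mean over minus-Hpg background channels. The per-protein pooled
#' variance is shrunk toward the empirical-Bayes prior,
#' `s2_post = (d0 * s2_prior + df * s2) / (d0 + df)`, and the moderated t
#' statistic `log2FC / (s_post * sqrt(1/n1 + 1/n2))` is referred to a t
#' distribution on `d0 + df` degrees of freedom (standard normal when
#' `d0 = Inf`). With `d0 = 0` the statistic reduces to the ordinary pooled
#' two-sample t.
#'
#' Proteins observed in fewer than two channels per group are flagged
#' (`tested = FALSE`) and carry `NA` statistics rather than being dropped.
#'
#' @param q log2-scale (normalized, typically imputed) quant matrix.
#' @param design channel design; all booster channels are compared against
#'   all minus_hpg channels (replicates pooled across conditions).
#' @param mod optional [fit_moderation()] result; fitted from the data when
#'   `NULL`.
#' @return `data.frame` with columns `protein_id`, `log2fc`, `t_mod`, `p`,
#'   `n_obs_booster`, `n_obs_background`, `tested`; the moderation fit is
#'   attached as attribute `"moderation"`.
#' @export
moderated_test <- function(q, design, mod = NULL) {
  validate_quant_matrix(q, allow_negative = TRUE)
  ch_boost <- as.character(design$channel_id[design$role == "booster"])
  ch_bg <- as.character(design$channel_id[design$role == "minus_hpg"])
  if (length(ch_boost) < 2L || length(ch_bg) < 2L)
    stop("need >= 2 booster and >= 2 minus_hpg channels")
  miss <- setdiff(c(ch_boost, ch_bg), colnames(q))
  if (length(miss)) stop("channels absent from matrix: ", paste(miss, collapse = ", "))

  x1 <- q[, ch_boost, drop = FALSE]
  x2 <- q[, ch_bg, drop = FALSE]
  n1 <- rowSums(is.finite(x1))
  n2 <- rowSums(is.finite(x2))
  m1 <- rowMeans(x1, na.rm = TRUE)
  m2 <- rowMeans(x2, na.rm = TRUE)
  v1 <- apply(x1, 1L, stats::var, na.rm = TRUE)
  v2 <- apply(x2, 1L, stats::var, na.rm = TRUE)
  tested <- n1 >= 2L & n2 >= 2L
  df <- n1 + n2 - 2L
  s2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / df

  if (is.null(mod)) {
    df_full <- max(df[tested])
    s2_fit <- s2[tested & df == df_full]
    mod <- if (sum(is.finite(s2_fit) & s2_fit > 0) >= 3L)
      fit_moderation(s2_fit, df_full)
    else  # degenerate data (e.g. noise-free simulation): flat shared variance
      structure(list(s2_prior = mean(s2_fit), d0 = Inf, residual_df = df_full),
                class = "trip_moderation")
  }
  d0 <- mod$d0
  s2_post <- if (is.infinite(d0)) rep(mod$s2_prior, length(s2)) else
    (d0 * mod$s2_prior + df * s2) / (d0 + df)

  log2fc <- m1 - m2
  se <- sqrt(s2_post * (1 / n1 + 1 / n2))
  t_mod <- log2fc / se
  p <- if (is.infinite(d0)) 2 * stats::pnorm(-abs(t_mod)) else
    2 * stats::pt(-abs(t_mod), df = d0 + df)

  out <- data.frame(protein_id = rownames(q), log2fc = log2fc,
                    t_mod = t_mod, p = p,
                    n_obs_booster = n1, n_obs_background = n2,
                    tested = tested, row.names = NULL,
                    stringsAsFactors = FALSE)
  out$log2fc[!tested] <- ifelse(n1[!tested] >= 1L & n2[!tested] >= 1L,
                                log2fc[!tested], NA_real_)
  out$t_mod[!tested] <- NA_real_
  out$p[!tested] <- NA_real_
  attr(out, "moderation") <- mod
  out
}

#' Benjamini-Hochberg step-up FDR adjustment
#'
#' @param p_values p-values in `[0, 1]`.
#' @return adjusted values in the original order.
#' @export
bh_adjust <- function(p_values) {
  ok <- !is.na(p_values)
  if (any(p_values[ok] < 0 | p_values[ok] > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Flag enriched interactors by sigma-scaled fold change and FDR
#'
#' The fold-change cutoff is expressed in sigma units where sigma is, by
#' default, the normal-consistent MAD of the full tested log2FC distribution
#' (robust to the true-interactor tail); a protein is enriched when its
#' log2FC is at least `sigma_multiplier * sigma` (positive direction only)
#' and its BH-adjusted p-value is at most `fdr_threshold`. The estimated
#' sigma and both thresholds are attached as attributes for run metadata.
#'
#' @param e result of [moderated_test()] with an `fdr` column (see
#'   [bh_adjust()]); if `fdr` is absent it is computed from `p`.
#' @param fdr_threshold BH FDR cutoff (default 0.05).
#' @param sigma_multiplier fold-change cutoff in sigma units (default 2).
#' @param sigma_estimator `"mad"` (default) or `"sd"`.
#' @return `e` with columns `fdr` and logical `enriched` populated.
#' @export
call_interactors <- function(e, fdr_threshold = 0.05, sigma_multiplier = 2,
                             sigma_estimator = c("mad", "sd")) {
  sigma_estimator <- match.arg(sigma_estimator)
  if (is.null(e$fdr)) e$fdr <- bh_adjust(e$p)
  fc <- e$log2fc[is.finite(e$log2fc)]
  if (length(fc) < 10L) stop("fewer than 10 proteins: sigma unestimable")
  sigma <- robust_sigma(fc, sigma_estimator)
  fc_threshold <- sigma_multiplier * sigma
  e$enriched <- !is.na(e$log2fc) & !is.na(e$fdr) &
    e$log2fc >= fc_threshold & e$fdr <= fdr_threshold
  if (!is.null(e$tested)) e$enriched <- e$enriched & e$tested
  attr(e, "sigma") <- sigma
  attr(e, "fc_threshold") <- fc_threshold
  attr(e, "fdr_threshold") <- fdr_threshold
  e
}

#' Run the full interactor-calling stage
#'
#' log2 transform, median normalization, left-censored imputation, moderated
#' booster-vs-background test, BH adjustment and sigma/FDR calling, in that
#' order, deterministically given the config seed.
#'
#' @param q linear-scale quant matrix.
#' @param design channel design.
#' @param config configuration list (see [default_config()]).
#' @return enrichment `data.frame` (see [call_interactors()]).
#' @export
run_interactor_calling <- function(q, design, config = default_config()) {
  rep <- validate_inputs(q, design)
  if (!rep$ok)
    stop("quant matrix and design disagree; see validate_inputs()")
  ql <- log_transform(q, config$pseudocount)
  ql <- median_normalize(ql)
  ql <- impute_minprob(ql, shift = config$impute_shift,
                       width = config$impute_width, seed = config$seed)
  e <- moderated_test(ql, design)
  e$fdr <- bh_adjust(e$p)
  call_interactors(e, fdr_threshold = config$fdr_threshold,
                   sigma_multiplier = config$sigma_multiplier,
                   sigma_estimator = config$sigma_estimator)
}
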