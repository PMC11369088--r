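#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Robust scale estimate used for sigma-multiple thresholds
#'
#' The "2-sigma" fold-change rule and the "3-sigma" screen cutoff both need a
#' scale estimate for a distribution dominated by nulls but carrying a true-
#' effect tail. The default is the MAD rescaled for normal consistency
#' (1.4826 * MAD); the plain standard deviation is available for comparison.
#'
#' @param x numeric vector; non-finite values are dropped.
#' @param estimator `"mad"` (default) or `"sd"`.
#' @return a single non-negative number.
#' @export
robust_sigma <- function(x, estimator = c("mad", "sd")) {
  estimator <- match.arg(estimator)
  x <- x[is.finite(x)]
  if (length(x) < 2L) stop("need at least 2 finite values to estimate sigma")
  if (estimator == "mad") stats::mad(x) else stats::sd(x)
}

# trapezoidal area under y(t); t strictly increasing
trapezoid_area <- function(t, y) {
  sum(diff(t) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

# write a numeric-bearing data frame as TSV with round-trip-exact numerics
write_tsv_precise <- function(df, path) {
  out <- df
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) {
      v <- out[[j]]
      s <- sprintf("%.17g", v)
      s[is.na(v)] <- NA_character_
      out[[j]] <- s
    }
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

stopifnot_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a single finite number", name))
  invisible(x)
}
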