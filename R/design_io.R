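#' Default chase timepoint grid (hours)
#'
#' Chase samples are collected at 0, 0.5, 1, 1.5, 2 and 3 h after a 1 h
#' labeling pulse; all validation and simulation defaults use this grid.
#'
#' @return numeric vector of timepoints in hours.
#' @export
default_timepoint_grid <- function() c(0, 0.5, 1, 1.5, 2, 3)

#' Canonical channel roles
#' @keywords internal
channel_roles <- function() c("chase", "minus_hpg", "booster")

.missing_tokens <- c("", "na", "nan", "n/a")

.sniff_sep <- function(path, sep = NULL) {
  if (!is.null(sep)) return(sep)
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

#' Read a protein-by-channel quantification table
#'
#' Expects delimited text with one header row of channel ids and a first
#' column of protein accessions; abundances are on the raw (linear) scale.
#' Empty cells and the tokens `NA`, `NaN`, `N/A` (case-insensitive) are
#' recorded as missing; any other non-numeric cell is an error reported with
#' its row/column coordinates. Missing values are an explicit state and are
#' never zero-coded.
#'
#' @param path file path to a TSV/CSV table (format sniffed from extension).
#' @param orientation `"proteins_in_rows"` (default) or `"channels_in_rows"`;
#'   the returned matrix always has proteins in rows.
#' @param sep optional field separator overriding the extension sniff.
#' @return numeric matrix, rows named by protein id, columns by channel id,
#'   `NA` marking missing entries.
#' @export
read_quant_table <- function(path,
                             orientation = c("proteins_in_rows", "channels_in_rows"),
                             sep = NULL) {
  orientation <- match.arg(orientation)
  sep <- .sniff_sep(path, sep)
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", check.names = FALSE,
                           quote = "", comment.char = "", na.strings = NULL,
                           stringsAsFactors = FALSE)
  if (ncol(raw) < 2L) stop("quant table needs an id column plus at least one channel")
  ids <- raw[[1L]]
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop("duplicate protein ids: ", paste(dup, collapse = ", "))
  vals <- as.matrix(raw[, -1L, drop = FALSE])
  m <- matrix(NA_real_, nrow = nrow(vals), ncol = ncol(vals),
              dimnames = list(ids, colnames(vals)))
  for (j in seq_len(ncol(vals))) {
    cell <- vals[, j]
    is_missing <- tolower(trimws(cell)) %in% .missing_tokens
    parsed <- suppressWarnings(as.numeric(cell))
    bad <- which(!is_missing & is.na(parsed))
    if (length(bad))
      stop(sprintf("non-numeric cell at row %d, column '%s': '%s'",
                   bad[1L], colnames(vals)[j], cell[bad[1L]]))
    parsed[is_missing] <- NA_real_
    m[, j] <- parsed
  }
  if (orientation == "channels_in_rows") m <- t(m)
  validate_quant_matrix(m)
  m
}

#' Write a quantification matrix losslessly
#'
#' Values are serialized with 17 significant digits so that a write/read
#' round trip reproduces doubles exactly; missing entries are written as `NA`.
#'
#' @param q numeric protein-by-channel matrix.
#' @param path output path (TSV or CSV by extension).
#' @param id_column header for the protein id column.
#' @export
write_quant_table <- function(q, path, id_column = "protein_id") {
  validate_quant_matrix(q)
  sep <- .sniff_sep(path)
  txt <- matrix(sprintf("%.17g", q), nrow = nrow(q))
  txt[is.na(q)] <- "NA"
  df <- data.frame(rownames(q), txt, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df) <- c(id_column, colnames(q))
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Validate a quantification matrix
#'
#' @param q numeric matrix with protein row names and channel column names.
#' @param allow_negative set `TRUE` for log-scale matrices.
#' @return `q`, invisibly, after validation.
#' @export
validate_quant_matrix <- function(q, allow_negative = FALSE) {
  if (!is.matrix(q) || !is.numeric(q)) stop("quant matrix must be a numeric matrix")
  if (is.null(rownames(q)) || is.null(colnames(q)))
    stop("quant matrix needs protein row names and channel column names")
  if (!allow_negative && any(q < 0, na.rm = TRUE))
    stop("negative abundances are not allowed on the linear scale")
  invisible(q)
}

#' Read and validate a channel design table
#'
#' The design assigns each TMT channel a plex, condition, chase timepoint,
#' replicate and role. Roles are normalized to `chase`, `minus_hpg`
#' (background control lacking the pulse label) and `booster` (the
#' high-abundance carrier channel). Chase channels must carry a timepoint on
#' the declared grid; control channels must not carry one.
#'
#' @param path delimited text with columns `channel_id`, `plex_id`,
#'   `condition`, `timepoint_h`, `replicate`, `role`.
#' @param grid declared chase timepoint grid in hours.
#' @param sep optional separator override.
#' @return validated design `data.frame`.
#' @export
read_design <- function(path, grid = default_timepoint_grid(), sep = NULL) {
  sep <- .sniff_sep(path, sep)
  d <- utils::read.table(path, header = TRUE, sep = sep,
                         stringsAsFactors = FALSE, quote = "",
                         na.strings = c("", "NA"))
  validate_design(d, grid = grid)
}

#' Validate an in-memory channel design
#'
#' @param d design `data.frame` (see [read_design()] for columns).
#' @param grid declared chase timepoint grid in hours.
#' @return the design with canonical role tokens, invisibly usable downstream.
#' @export
validate_design <- function(d, grid = default_timepoint_grid()) {
  needed <- c("channel_id", "plex_id", "condition", "timepoint_h", "replicate", "role")
  miss <- setdiff(needed, names(d))
  if (length(miss)) stop("design is missing columns: ", paste(miss, collapse = ", "))
  d$role <- gsub("[ -]", "_", tolower(trimws(as.character(d$role))))
  d$role[d$role %in% c("minus_hpg", "minushpg", "(_)hpg", "background")] <- "minus_hpg"
  d$role[d$role %in% c("booster", "carrier")] <- "booster"
  bad_role <- setdiff(unique(d$role), channel_roles())
  if (length(bad_role))
    stop("unknown role token(s): ", paste(bad_role, collapse = ", "))
  d$timepoint_h <- as.numeric(d$timepoint_h)
  d$replicate <- as.integer(d$replicate)
  if (any(!is.finite(d$replicate)) || any(d$replicate < 1L))
    stop("replicate must be a positive integer")

  chase <- d$role == "chase"
  if (any(chase & is.na(d$timepoint_h)))
    stop("chase channel(s) missing a timepoint: ",
         paste(d$channel_id[chase & is.na(d$timepoint_h)], collapse = ", "))
  off <- chase & !is.na(d$timepoint_h) & !(d$timepoint_h %in% grid)
  if (any(off))
    stop(sprintf("timepoint(s) off the declared grid {%s}: %s",
                 paste(grid, collapse = ", "),
                 paste(unique(d$timepoint_h[off]), collapse = ", ")))
  if (any(!chase & !is.na(d$timepoint_h)))
    stop("minus_hpg/booster channel(s) must not carry a timepoint: ",
         paste(d$channel_id[!chase & !is.na(d$timepoint_h)], collapse = ", "))

  dup <- stats::aggregate(seq_len(nrow(d)),
                          by = list(plex = d$plex_id, ch = d$channel_id),
                          FUN = length)
  if (any(dup$x > 1L))
    stop("duplicated channel_id within a plex: ",
         paste(unique(dup$ch[dup$x > 1L]), collapse = ", "))

  cr <- unique(d[chase, c("condition", "replicate")])
  for (i in seq_len(nrow(cr))) {
    n_bg <- sum(d$role == "minus_hpg" &
                  d$condition == cr$condition[i] &
                  d$replicate == cr$replicate[i])
    if (n_bg != 1L)
      stop(sprintf("(condition %s, replicate %d) has %d minus_hpg channels; exactly 1 required",
                   cr$condition[i], cr$replicate[i], n_bg))
  }
  d
}

#' Write a channel design table
#' @param d validated design `data.frame`.
#' @param path output path.
#' @export
write_design <- function(d, path) {
  utils::write.table(d, path, sep = .sniff_sep(path), quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Cross-check a quant matrix against a channel design
#'
#' Returns a report naming channels present in the design but absent from the
#' matrix and vice versa; the report is symmetric in the two column sets.
#' Downstream stages refuse mismatched inputs unless explicitly overridden.
#'
#' @param q quant matrix.
#' @param d channel design.
#' @return list with `missing_in_matrix`, `missing_in_design`, and logical `ok`.
#' @export
validate_inputs <- function(q, d) {
  in_design <- unique(as.character(d$channel_id))
  in_matrix <- colnames(q)
  rep <- list(
    missing_in_matrix = setdiff(in_design, in_matrix),
    missing_in_design = setdiff(in_matrix, in_design)
  )
  rep$ok <- length(rep$missing_in_matrix) == 0L && length(rep$missing_in_design) == 0L
  rep
}

#' Read a protein-to-pathway map
#'
#' Two-column delimited text (`protein_id`, `pathway`). A protein maps to at
#' most one pathway group per map; unmapped proteins are permitted downstream.
#'
#' @param path file path.
#' @param sep optional separator override.
#' @return `data.frame` with columns `protein_id`, `pathway`.
#' @export
read_pathway_map <- function(path, sep = NULL) {
  m <- utils::read.table(path, header = TRUE, sep = .sniff_sep(path, sep),
                         stringsAsFactors = FALSE, quote = "")
  if (!all(c("protein_id", "pathway") %in% names(m)))
    stop("pathway map needs columns protein_id, pathway")
  dup <- unique(m$protein_id[duplicated(m$protein_id)])
  if (length(dup))
    stop("protein mapped to more than one pathway: ", paste(dup, collapse = ", "))
  m[, c("protein_id", "pathway")]
}

#' Default run configuration
#'
#' Central defaults for thresholds, imputation parameters, scaling scope and
#' the chase grid; [read_run_config()] merges a YAML file over these.
#'
#' @return named list of configuration values.
#' @export
default_config <- function() {
  list(
    timepoint_grid = default_timepoint_grid(),
    pseudocount = 0,
    impute_shift = 1.8,
    impute_width = 0.3,
    fdr_threshold = 0.05,
    sigma_multiplier = 2,
    sigma_estimator = "mad",
    cv_threshold = 0.5,
    scaling_scope = "joint_across_conditions",
    reference = "replicate_matched",
    screen_sigma_multiplier = 3,
    screen_min_replicates = 2,
    seed = 1L
  )
}

#' Read a YAML run configuration
#'
#' @param path YAML file; keys override [default_config()].
#' @return merged configuration list.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  utils::modifyList(default_config(), cfg)
}
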