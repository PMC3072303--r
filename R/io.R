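#' @keywords internal
"_PACKAGE"

# Shared tabular conventions: tab-delimited expression matrices with gene ids
# in column 1 and a header row of sample ids; CSV sample sheets; UTF-8 and "."
# decimal throughout. Floats are serialized at 9 significant digits so that a
# write/read round trip is stable without inflating noise digits.

.FLOAT_DIGITS <- 9L

.SEX_LEVELS <- c("M", "F")
.STATUS_LEVELS <- c("case", "control")
.CHEST_PAIN_LEVELS <- c("asymptomatic", "atypical", "non-anginal", "typical")

#' Construct an expression matrix object
#'
#' A thin wrapper around a numeric genes x samples matrix carrying a scale tag
#' (`linear` or `log2`) and a platform tag (`microarray` or `rtpcr`).
#' RT-PCR values are interpreted as -dCt-like quantities: higher value means
#' higher transcript abundance, on the same log2-type scale as microarray
#' intensities.
#'
#' @param values numeric matrix, genes in rows, samples in columns, with
#'   non-empty, unique dimnames.
#' @param scale `"linear"` or `"log2"`.
#' @param platform `"microarray"` or `"rtpcr"`.
#' @return An `expression_matrix` (a classed numeric matrix with attributes).
#' @export
expression_matrix <- function(values, scale = c("log2", "linear"),
                              platform = c("microarray", "rtpcr")) {
  scale <- match.arg(scale)
  platform <- match.arg(platform)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("expression matrix requires gene (row) and sample (column) names")
  }
  if (anyDuplicated(rownames(values))) {
    stop("duplicate gene ids: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]),
               collapse = ", "))
  }
  if (anyDuplicated(colnames(values))) {
    stop("duplicate sample ids: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]),
               collapse = ", "))
  }
  structure(values, scale = scale, platform = platform,
            class = c("expression_matrix", class(values)))
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d genes x %d samples [%s, %s]\n",
              nrow(x), ncol(x), attr(x, "scale"), attr(x, "platform")))
  invisible(x)
}

# Subsetting keeps tags; dimnames checks re-run through the constructor.
#' @export
`[.expression_matrix` <- function(x, i, j, ..., drop = FALSE) {
  out <- NextMethod(drop = drop)
  if (is.matrix(out)) {
    attr(out, "scale") <- attr(x, "scale")
    attr(out, "platform") <- attr(x, "platform")
    class(out) <- class(x)
  }
  out
}

.fmt_num <- function(x) {
  out <- formatC(signif(x, .FLOAT_DIGITS), format = "g",
                 digits = .FLOAT_DIGITS)
  gsub(" ", "", out)
}

#' Read an expression matrix
#'
#' Two on-disk formats are supported: plain tab-delimited (gene ids in column
#' 1, header row of sample ids) and the GEO series-matrix flavor, in which
#' metadata lines are prefixed with `!` and the value block sits between
#' `!series_matrix_table_begin` and `!series_matrix_table_end`.
#'
#' @param path file path.
#' @param format `"tsv"` or `"geo_series_matrix"`.
#' @param scale,platform tags attached to the returned matrix.
#' @return An [expression_matrix()].
#' @export
read_expression <- function(path, format = c("tsv", "geo_series_matrix"),
                            scale = "log2", platform = "microarray") {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (format == "geo_series_matrix") {
    begin <- grep("^!series_matrix_table_begin", lines)
    end <- grep("^!series_matrix_table_end", lines)
    if (length(begin) == 1 && length(end) == 1 && end > begin + 1) {
      lines <- lines[(begin + 1):(end - 1)]
    } else {
      lines <- lines[!startsWith(lines, "!")]
    }
    lines <- lines[nzchar(lines)]
  }
  if (length(lines) < 2) stop("format error: no data rows in ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1]]
  n_col <- length(header)
  body <- fields[-1]
  widths <- lengths(body)
  if (any(widths != n_col)) {
    bad <- which(widths != n_col)[1]
    stop(sprintf("ragged row at line %d: %d fields, expected %d",
                 bad + 1L, widths[bad], n_col))
  }
  gene_ids <- gsub('^"|"$', "", vapply(body, `[`, "", 1L))
  sample_ids <- gsub('^"|"$', "", header[-1])
  vals <- matrix(NA_real_, nrow = length(body), ncol = n_col - 1L,
                 dimnames = list(gene_ids, sample_ids))
  for (i in seq_along(body)) {
    vals[i, ] <- as.numeric(body[[i]][-1])
  }
  expression_matrix(vals, scale = scale, platform = platform)
}

#' Write an expression matrix as TSV
#'
#' Byte-identical output for identical input: fixed column order and fixed
#' 9-significant-digit float formatting.
#'
#' @param mat an [expression_matrix()] or plain named matrix.
#' @param path output path.
#' @export
write_expression <- function(mat, path) {
  header <- paste(c("gene", colnames(mat)), collapse = "\t")
  rows <- vapply(seq_len(nrow(mat)), function(i) {
    paste(c(rownames(mat)[i], .fmt_num(mat[i, ])), collapse = "\t")
  }, character(1))
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Read a sample annotation sheet
#'
#' CSV with required columns `id`, `status`, `sex`, `age`; optional columns
#' `diabetic`, `neutrophil_count`, `lymphocyte_count`, `pair_id`,
#' `chest_pain` and free covariates. Status and sex tokens are normalized
#' case-insensitively and validated; a record missing `age` is kept but
#' flagged (`complete = FALSE`) so that age-requiring stages can drop it with
#' a warning.
#'
#' @param path CSV file path.
#' @return A data.frame of sample records.
#' @export
read_samples <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("id", "status", "sex", "age")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols)) {
    stop("sample sheet missing required columns: ",
         paste(missing_cols, collapse = ", "))
  }
  status <- tolower(trimws(df$status))
  bad <- which(!status %in% .STATUS_LEVELS)
  if (length(bad)) {
    stop(sprintf("unknown status token '%s' in row %d", df$status[bad[1]],
                 bad[1]))
  }
  sex <- toupper(trimws(df$sex))
  sex[sex %in% c("MALE")] <- "M"
  sex[sex %in% c("FEMALE")] <- "F"
  bad <- which(!sex %in% .SEX_LEVELS)
  if (length(bad)) {
    stop(sprintf("unknown sex token '%s' in row %d", df$sex[bad[1]], bad[1]))
  }
  df$status <- status
  df$sex <- sex
  df$age <- as.numeric(df$age)
  if ("chest_pain" %in% names(df)) {
    cp <- tolower(trimws(df$chest_pain))
    ok <- is.na(cp) | cp == "" | cp %in% .CHEST_PAIN_LEVELS
    if (!all(ok)) {
      stop(sprintf("unknown chest_pain token '%s' in row %d",
                   df$chest_pain[which(!ok)[1]], which(!ok)[1]))
    }
    cp[cp == ""] <- NA
    df$chest_pain <- cp
  }
  df$complete <- !is.na(df$age)
  if (any(!df$complete)) {
    warning(sum(!df$complete),
            " record(s) missing age; flagged and excluded from ",
            "age-requiring stages")
  }
  df
}

#' Write a sample sheet as CSV
#' @param records sample record data.frame.
#' @param path output path.
#' @export
write_samples <- function(records, path) {
  records$complete <- NULL
  num <- vapply(records, is.numeric, logical(1))
  for (nm in names(records)[num]) {
    records[[nm]] <- .fmt_num(records[[nm]])
  }
  utils::write.csv(records, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write per-gene association results as TSV
#'
#' Stable column order: gene, beta, se, p_unadj, p_adj, q, flag.
#' @param assoc association result data.frame.
#' @param path output path.
#' @export
write_association <- function(assoc, path) {
  cols <- c("gene", "beta", "se", "p_unadj", "p_adj", "q", "flag")
  cols <- cols[cols %in% names(assoc)]
  out <- assoc[, cols, drop = FALSE]
  for (nm in names(out)) {
    if (is.numeric(out[[nm]])) out[[nm]] <- .fmt_num(out[[nm]])
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Build and validate a run configuration
#'
#' Stage parameters with defaults, a global seed, and paths. Unknown keys are
#' rejected so that typos fail loudly instead of silently running defaults.
#'
#' @param ... overrides of the defaults.
#' @return A named list with class `run_config`.
#' @export
run_config <- function(...) {
  defaults <- list(
    seed = 1L,
    trim_fraction = 0.02,
    log2_offset = 1,
    norm_target = 100,
    qc_percent_present_min = 60,
    qc_corr_min = 0.6,
    qc_intensity_mad = 3,
    alpha = 0.05,
    corr_cutoff = 0.7,
    cell_type_corr_threshold = 0.3,
    panel_size = 113L,
    age_knot = 60,
    n_folds = 10L,
    verbosity = 1L
  )
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(defaults))
  if (length(unknown)) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  }
  defaults[names(overrides)] <- overrides
  structure(defaults, class = "run_config")
}

#' Echo a resolved configuration to a JSON file
#' @param config a [run_config()].
#' @param path output path.
#' @export
write_config_echo <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
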