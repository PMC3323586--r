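## CSV readers/writers. Dialect: comma-separated, UTF-8, "." decimal, header
## required. Numeric columns are written at full precision (17 significant
## digits) so that read(write(x)) reproduces x bitwise.

#' Read dentin growth-layer records from CSV
#'
#' Expects a header naming the five fields `individual_id`, `layer_index`,
#' `context`, `d13c`, `cn_ratio`. Row order is preserved; malformed numeric
#' cells are reported with their row numbers.
#'
#' @param path Path to a CSV file.
#' @return A validated [dentin_records()] data frame.
#' @export
read_dentin_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  missing_cols <- setdiff(DENTIN_COLUMNS, names(df))
  if (length(missing_cols) > 0) {
    stop("missing column(s) in ", path, ": ", paste(missing_cols, collapse = ", "))
  }
  for (col in c("layer_index", "d13c", "cn_ratio")) {
    parsed <- suppressWarnings(as.numeric(df[[col]]))
    bad_rows <- which(is.na(parsed))
    if (length(bad_rows) > 0) {
      stop("malformed numeric value(s) in column '", col, "' at row(s): ",
           paste(bad_rows, collapse = ", "))
    }
    df[[col]] <- parsed
  }
  dentin_records(df)
}

#' @rdname read_dentin_csv
#' @param records A [dentin_records()] data frame.
#' @export
write_dentin_csv <- function(records, path) {
  records <- dentin_records(as.data.frame(records))
  out <- data.frame(individual_id = records$individual_id,
                    layer_index = records$layer_index,
                    context = records$context,
                    d13c = fmt_full(records$d13c),
                    cn_ratio = fmt_full(records$cn_ratio))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read/write per-individual longevities
#'
#' Two-column CSV: `individual_id`, `longevity` (years).
#'
#' @param path Path to a CSV file.
#' @return Named numeric vector of longevities (names = individual ids).
#' @export
read_longevity_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("individual_id", "longevity")
  if (!all(need %in% names(df))) {
    stop("longevity CSV must have columns: ", paste(need, collapse = ", "))
  }
  lv <- suppressWarnings(as.numeric(df$longevity))
  bad <- which(is.na(lv) | lv <= 0)
  if (length(bad) > 0) stop("invalid longevity at row(s): ", paste(bad, collapse = ", "))
  stats::setNames(lv, as.character(df$individual_id))
}

#' @rdname read_longevity_csv
#' @param longevities Named numeric vector (names = individual ids).
#' @export
write_longevity_csv <- function(longevities, path) {
  utils::write.csv(data.frame(individual_id = names(longevities),
                              longevity = fmt_full(unname(longevities))),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write retained posterior draws to CSV
#'
#' One column per scalar parameter, one row per retained draw, plus `chain`
#' and `iteration` columns. Values are written at full precision so that
#' [read_posterior_csv()] reproduces them bitwise.
#'
#' @param draws An `mcmc.list` (from coda) or a data frame with `chain` and
#'   `iteration` columns.
#' @param path Output path.
#' @export
write_posterior_csv <- function(draws, path) {
  df <- draws_to_df(draws)
  if (nrow(df) == 0) stop("draws must be non-empty")
  num_cols <- setdiff(names(df), c("chain", "iteration"))
  if (any(vapply(df[num_cols], function(x) any(is.nan(x)), logical(1)))) {
    stop("draws contain NaN: sampler failure, refusing to write")
  }
  out <- df
  for (col in num_cols) out[[col]] <- fmt_full(df[[col]])
  ## bracketed parameter names would break an unquoted CSV header
  names(out) <- gsub("\\]", "", gsub("\\[|,", "_", names(out)))
  con <- file(path, "w")
  on.exit(close(con))
  utils::write.csv(out, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_posterior_csv
#' @return A data frame of draws with `chain` and `iteration` columns.
#' @export
read_posterior_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

draws_to_df <- function(draws) {
  if (inherits(draws, "mcmc.list")) {
    do.call(rbind, lapply(seq_along(draws), function(ch) {
      m <- as.matrix(draws[[ch]])
      cbind(data.frame(chain = ch, iteration = seq_len(nrow(m))),
            as.data.frame(m))
    }))
  } else if (is.data.frame(draws)) {
    if (!all(c("chain", "iteration") %in% names(draws))) {
      stop("draws data frame must have 'chain' and 'iteration' columns")
    }
    draws
  } else {
    stop("draws must be an mcmc.list or a data frame")
  }
}

## full-precision decimal formatting (round-trips through read.csv bitwise)
fmt_full <- function(x) {
  vapply(x, function(v) {
    if (is.na(v)) return("NA")
    sprintf("%.17g", v)
  }, character(1))
}
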