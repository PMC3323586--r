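## Data model: dentin records and per-individual isotope series.

DENTIN_COLUMNS <- c("individual_id", "layer_index", "context", "d13c", "cn_ratio")
CONTEXT_LEVELS <- c("ashore", "at_sea")

#' Construct and validate a table of dentin growth-layer records
#'
#' One row per sampled growth layer: individual id, 1-based layer index
#' (innermost = oldest layer, deposited first), ashore/at-sea context, the
#' layer's delta-13C (permil VPDB) and its C/N mass ratio (used downstream to
#' screen diagenetic alteration).
#'
#' @param df A data frame with columns `individual_id`, `layer_index`,
#'   `context`, `d13c`, `cn_ratio`.
#' @return The validated data frame, classed `dentin_records`.
#' @export
dentin_records <- function(df) {
  missing_cols <- setdiff(DENTIN_COLUMNS, names(df))
  if (length(missing_cols) > 0) {
    stop("missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  df <- df[, DENTIN_COLUMNS]
  df$individual_id <- as.character(df$individual_id)
  bad <- function(cond, what) {
    rows <- which(cond)
    if (length(rows) > 0) {
      stop("invalid ", what, " in row(s): ", paste(rows, collapse = ", "))
    }
  }
  bad(!is.finite(df$layer_index) | df$layer_index < 1 |
        df$layer_index != round(df$layer_index), "layer_index (need integer >= 1)")
  bad(!df$context %in% CONTEXT_LEVELS, "context (need 'ashore' or 'at_sea')")
  bad(!is.finite(df$d13c), "d13c")
  bad(!is.finite(df$cn_ratio) | df$cn_ratio <= 0, "cn_ratio (need positive number)")
  class(df) <- c("dentin_records", "data.frame")
  df
}

#' Construct a per-individual isotope series
#'
#' An individual's age-indexed delta-13C series plus its observed longevity.
#' Ages must be strictly increasing and cannot exceed the longevity (a tooth
#' layer cannot post-date death).
#'
#' @param individual_id Identifier string.
#' @param ages Ages in years (strictly increasing).
#' @param values delta-13C (permil VPDB), one per age.
#' @param longevity Observed lifespan in years (> 0).
#' @param qc_flags Logical, one per point: passed the C/N filter. Defaults to
#'   all `TRUE`.
#' @return An object of class `isotope_series`.
#' @export
isotope_series <- function(individual_id, ages, values, longevity,
                           qc_flags = rep(TRUE, length(ages))) {
  if (length(ages) != length(values)) {
    stop("ages and values must have the same length (", individual_id, ")")
  }
  if (length(qc_flags) != length(ages)) {
    stop("qc_flags must match ages in length (", individual_id, ")")
  }
  if (length(ages) > 0) {
    if (any(diff(ages) <= 0)) stop("ages must be strictly increasing (", individual_id, ")")
    if (max(ages) > longevity + 1e-9) {
      stop("age ", max(ages), " exceeds stated longevity ", longevity,
           " for individual ", individual_id)
    }
  }
  if (!is.finite(longevity) || longevity <= 0) {
    stop("longevity must be a positive number (", individual_id, ")")
  }
  structure(list(individual_id = as.character(individual_id),
                 ages = as.numeric(ages), values = as.numeric(values),
                 longevity = as.numeric(longevity),
                 qc_flags = as.logical(qc_flags)),
            class = "isotope_series")
}

#' @export
print.isotope_series <- function(x, ...) {
  cat("<isotope_series> id:", x$individual_id,
      " n =", length(x$ages),
      " ages", if (length(x$ages)) paste0("[", min(x$ages), ", ", max(x$ages), "]") else "[]",
      " longevity =", x$longevity, "yr\n")
  invisible(x)
}

#' Flatten a list of isotope series to a long data frame
#'
#' @param series_list List of [isotope_series()] objects.
#' @return Data frame with columns `individual_id`, `age`, `d13c`, `qc_pass`,
#'   `longevity`.
#' @export
series_to_df <- function(series_list) {
  if (length(series_list) == 0) {
    return(data.frame(individual_id = character(), age = numeric(),
                      d13c = numeric(), qc_pass = logical(),
                      longevity = numeric()))
  }
  do.call(rbind, lapply(series_list, function(s) {
    data.frame(individual_id = s$individual_id, age = s$ages, d13c = s$values,
               qc_pass = s$qc_flags, longevity = s$longevity)
  }))
}

#' Rebuild isotope series from a long data frame
#'
#' Inverse of [series_to_df()].
#'
#' @param df Long data frame with columns `individual_id`, `age`, `d13c`,
#'   `qc_pass` (optional), `longevity`.
#' @return Named list of [isotope_series()].
#' @export
df_to_series <- function(df) {
  out <- lapply(split(df, df$individual_id), function(d) {
    d <- d[order(d$age), ]
    isotope_series(d$individual_id[1], d$age, d$d13c, d$longevity[1],
                   if ("qc_pass" %in% names(d)) d$qc_pass else rep(TRUE, nrow(d)))
  })
  out[unique(df$individual_id)]
}
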