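#' Read a long-format observation table
#'
#' Observations are stored one row per measurement with columns `subject`,
#' `time_h`, `value`, `dose_mg_kg`, `interval_h`, `n_doses`, `route`.
#' `value` is a plasma concentration in ng/mL (`kind = "conc"`) or a tumor
#' Met-EF1alpha level in ug per mg total protein (`kind = "pd"`). Times are
#' hours since the first dose. Rows out of time order within a subject are
#' re-sorted with a warning.
#'
#' @param path Path to a CSV file (comma-separated, dot decimal, UTF-8).
#' @param kind `"conc"` or `"pd"`; recorded as an attribute and used by the
#'   fitting functions to pick the model arm.
#' @return A data.frame of validated observations with attribute `kind`.
#' @export
read_observations <- function(path, kind = c("conc", "pd")) {
  kind <- match.arg(kind)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_observations(df, kind)
}

#' Write a long-format observation table
#'
#' Inverse of [read_observations()]: values survive a write/read round trip at
#' full double precision.
#'
#' @param obs Observation data.frame (see [read_observations()]).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_observations <- function(obs, path) {
  utils::write.csv(format(obs, digits = 17, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

obs_columns <- c("subject", "time_h", "value", "dose_mg_kg",
                 "interval_h", "n_doses", "route")

#' Validate an observation data.frame
#'
#' Enforces the long-format contract: all required columns present, numeric
#' fields numeric, no negative times or values, positive doses. Rows are
#' re-sorted by time within subject if needed (with a warning).
#'
#' @param df A data.frame.
#' @param kind `"conc"` or `"pd"`.
#' @return The validated (possibly re-sorted) data.frame, with attribute
#'   `kind`.
#' @export
validate_observations <- function(df, kind = c("conc", "pd")) {
  kind <- match.arg(kind)
  missing_cols <- setdiff(obs_columns, names(df))
  if (length(missing_cols))
    stop(sprintf("observation table is missing column(s): %s",
                 paste(missing_cols, collapse = ", ")))
  for (col in c("time_h", "value", "dose_mg_kg", "interval_h", "n_doses")) {
    df[[col]] <- suppressWarnings(as.numeric(df[[col]]))
    if (anyNA(df[[col]]))
      stop(sprintf("column '%s' contains non-numeric or missing entries", col))
  }
  bad <- which(df$time_h < 0 | df$value < 0)
  if (length(bad))
    stop(sprintf("negative time or value at row(s): %s",
                 paste(bad, collapse = ", ")))
  bad <- which(df$dose_mg_kg <= 0 | df$n_doses < 1)
  if (length(bad))
    stop(sprintf("non-positive dose or n_doses at row(s): %s",
                 paste(bad, collapse = ", ")))
  unsorted <- tapply(df$time_h, df$subject, is.unsorted)
  if (any(unsorted)) {
    warning(sprintf("times out of order for subject(s) %s; re-sorting",
                    paste(names(unsorted)[unsorted], collapse = ", ")))
    df <- df[order(match(df$subject, unique(df$subject)), df$time_h), ,
             drop = FALSE]
    rownames(df) <- NULL
  }
  attr(df, "kind") <- kind
  df
}

# the unique regimens present in an observation table, as dose_regimen objects
obs_regimens <- function(obs) {
  key <- unique(obs[, c("dose_mg_kg", "interval_h", "n_doses", "route")])
  lapply(seq_len(nrow(key)), function(i)
    dose_regimen(key$dose_mg_kg[i], key$interval_h[i], key$n_doses[i],
                 key$route[i]))
}

# integer index mapping each observation row to obs_regimens(obs)
obs_regimen_index <- function(obs) {
  key <- unique(obs[, c("dose_mg_kg", "interval_h", "n_doses", "route")])
  match(
    interaction(obs$dose_mg_kg, obs$interval_h, obs$n_doses, obs$route,
                drop = FALSE),
    interaction(key$dose_mg_kg, key$interval_h, key$n_doses, key$route,
                drop = FALSE)
  )
}
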