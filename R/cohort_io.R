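#' Canonical cohort schema
#'
#' The column schema every cohort table is validated against. Mandatory
#' columns carry the paired mammogram dimensions, the inter-mammogram
#' interval and the survival outcome; clinicopathological columns are
#' optional and stored as explicit \code{NA} when absent.
#'
#' @return A data frame with columns \code{column}, \code{type}
#'   (\code{"character"}, \code{"numeric"} or \code{"integer"}) and
#'   \code{required}.
#' @export
cohort_schema <- function() {
  data.frame(
    column = c("patient_id",
               "screen_dim_major", "screen_dim_minor",
               "diag_dim_major", "diag_dim_minor",
               "interval_days",
               "age_years", "grade", "histological_size_mm", "npi",
               "nodal_stage", "mitotic_score", "ki67_percent",
               "er_status", "pr_status", "her2_status", "lvi", "subtype",
               "bcss_months", "event"),
    type = c("character",
             "numeric", "numeric", "numeric", "numeric",
             "numeric",
             "numeric", "integer", "numeric", "numeric",
             "integer", "integer", "numeric",
             "character", "character", "character", "character", "character",
             "numeric", "integer"),
    required = c(TRUE,
                 TRUE, TRUE, TRUE, TRUE,
                 TRUE,
                 FALSE, FALSE, FALSE, FALSE,
                 FALSE, FALSE, FALSE,
                 FALSE, FALSE, FALSE, FALSE, FALSE,
                 TRUE, TRUE),
    stringsAsFactors = FALSE
  )
}

.tri_state  <- c("positive", "negative")
.lvi_levels <- c("negative", "probable", "definite")
.subtypes   <- c("luminal A", "luminal B", "HER2", "TNBC", "BLBC")

#' Construct a validated cohort table
#'
#' Coerces a data frame to the canonical schema, enforces the record
#' invariants and attaches provenance metadata. The reader-level invariants
#' are: dimensions positive with major >= minor (pairs are reordered with a
#' warning when supplied the other way round), \code{grade} and
#' \code{mitotic_score} in 1..3, \code{ki67_percent} in [0, 100],
#' \code{bcss_months >= 0} and \code{event} in {0, 1}. Rows violating a hard
#' invariant are rejected with row-indexed diagnostics.
#'
#' If an \code{interval_months} column is present instead of
#' \code{interval_days} it is converted at 30.44 days/month. If \code{npi}
#' is absent but \code{histological_size_mm}, \code{grade} and
#' \code{nodal_stage} are present, NPI is computed as
#' 0.2 * size(cm) + grade + nodal stage.
#'
#' @param df A data frame using the canonical column names (case-insensitive).
#' @param provenance Free-text label recorded on the table.
#' @return A \code{cohort_table}: a data frame in canonical column order with
#'   attributes \code{provenance} and \code{schema_version}.
#' @export
as_cohort <- function(df, provenance = "unspecified") {
  stopifnot(is.data.frame(df))
  names(df) <- tolower(names(df))
  schema <- cohort_schema()

  if (!"interval_days" %in% names(df) && "interval_months" %in% names(df)) {
    df$interval_days <- as.numeric(df$interval_months) * 30.44
    df$interval_months <- NULL
  }

  missing_cols <- setdiff(schema$column[schema$required], names(df))
  if (length(missing_cols)) {
    stop("cohort is missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }

  n <- nrow(df)
  out <- vector("list", nrow(schema))
  names(out) <- schema$column
  for (i in seq_len(nrow(schema))) {
    col <- schema$column[i]
    if (col %in% names(df)) {
      v <- df[[col]]
      if (schema$type[i] != "character") {
        v_chr <- trimws(as.character(v))
        v_chr[v_chr %in% c("", "NA")] <- NA
        vn <- suppressWarnings(as.numeric(v_chr))
        bad <- which(!is.na(v_chr) & is.na(vn))
        if (length(bad)) {
          stop(sprintf("non-numeric value in numeric field '%s' at row(s) %s",
                       col, paste(bad, collapse = ", ")), call. = FALSE)
        }
        v <- if (schema$type[i] == "integer") as.integer(round(vn)) else vn
      } else {
        v <- as.character(v)
        v[!is.na(v) & trimws(v) %in% c("", "NA")] <- NA
      }
    } else {
      v <- if (schema$type[i] == "character") rep(NA_character_, n)
           else if (schema$type[i] == "integer") rep(NA_integer_, n)
           else rep(NA_real_, n)
    }
    out[[col]] <- v
  }
  out <- as.data.frame(out, stringsAsFactors = FALSE)

  if (anyDuplicated(out$patient_id)) {
    stop("patient_id values must be unique", call. = FALSE)
  }

  # NPI from components when not supplied (0.2 * size_cm + grade + nodal stage)
  fill <- is.na(out$npi) & !is.na(out$histological_size_mm) &
    !is.na(out$grade) & !is.na(out$nodal_stage)
  out$npi[fill] <- 0.2 * out$histological_size_mm[fill] / 10 +
    out$grade[fill] + out$nodal_stage[fill]

  # major >= minor enforced by reordering
  for (pref in c("screen", "diag")) {
    maj <- paste0(pref, "_dim_major"); mnr <- paste0(pref, "_dim_minor")
    swap <- which(!is.na(out[[maj]]) & !is.na(out[[mnr]]) &
                    out[[maj]] < out[[mnr]])
    if (length(swap)) {
      tmp <- out[[maj]][swap]
      out[[maj]][swap] <- out[[mnr]][swap]
      out[[mnr]][swap] <- tmp
      warning(sprintf("%s dimensions reordered (major < minor) at row(s) %s",
                      pref, paste(swap, collapse = ", ")), call. = FALSE)
    }
  }

  bad_row <- function(cond, what) {
    idx <- which(cond)
    if (length(idx)) {
      stop(sprintf("invalid %s at row(s) %s", what,
                   paste(idx, collapse = ", ")), call. = FALSE)
    }
  }
  dims <- c("screen_dim_major", "screen_dim_minor",
            "diag_dim_major", "diag_dim_minor")
  for (d in dims) bad_row(!is.na(out[[d]]) & out[[d]] <= 0,
                          paste0("non-positive dimension ", d))
  bad_row(!is.na(out$interval_days) & out$interval_days < 0, "interval_days")
  bad_row(!is.na(out$grade) & !out$grade %in% 1:3, "grade (must be 1-3)")
  bad_row(!is.na(out$mitotic_score) & !out$mitotic_score %in% 1:3,
          "mitotic_score (must be 1-3)")
  bad_row(!is.na(out$ki67_percent) &
            (out$ki67_percent < 0 | out$ki67_percent > 100),
          "ki67_percent (must be 0-100)")
  bad_row(!is.na(out$bcss_months) & out$bcss_months < 0, "bcss_months")
  bad_row(!is.na(out$event) & !out$event %in% c(0L, 1L),
          "event (must be 0/1)")
  for (col in c("er_status", "pr_status", "her2_status")) {
    bad_row(!is.na(out[[col]]) & !out[[col]] %in% .tri_state,
            paste0(col, " (positive/negative)"))
  }
  bad_row(!is.na(out$lvi) & !out$lvi %in% .lvi_levels, "lvi")
  bad_row(!is.na(out$subtype) & !out$subtype %in% .subtypes, "subtype")

  structure(out,
            provenance = provenance,
            schema_version = "1.0",
            class = c("cohort_table", "data.frame"))
}

#' Read a cohort table from delimited text
#'
#' @param path Path to a delimited text file with one header row using the
#'   canonical column names (case-insensitive). Missing values are empty
#'   strings or \code{"NA"}.
#' @param sep Field delimiter; \code{NULL} (default) sniffs comma vs tab from
#'   the header line.
#' @param provenance Provenance label; defaults to the file name.
#' @return A \code{cohort_table}.
#' @export
read_cohort <- function(path, sep = NULL, provenance = basename(path)) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(sep)) {
    hdr <- readLines(path, n = 1L)
    sep <- if (grepl("\t", hdr)) "\t" else ","
  }
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", na.strings = c("", "NA"),
                           check.names = FALSE, stringsAsFactors = FALSE)
  as_cohort(raw, provenance = provenance)
}

#' Write a cohort table to delimited text
#'
#' Numeric fields are written at full double precision so that
#' \code{read_cohort(write_cohort(x))} reproduces \code{x} field for field.
#'
#' @param cohort A \code{cohort_table}.
#' @param path Output path.
#' @param sep Field delimiter (default comma).
#' @return \code{path}, invisibly.
#' @export
write_cohort <- function(cohort, path, sep = ",") {
  stopifnot(inherits(cohort, "cohort_table"))
  out <- as.data.frame(cohort)
  for (col in names(out)) {
    if (is.numeric(out[[col]]) && !is.integer(out[[col]])) {
      v <- sprintf("%.17g", out[[col]])
      v[is.na(out[[col]])] <- NA
      out[[col]] <- v
    }
  }
  utils::write.table(out, path, sep = sep, row.names = FALSE,
                     quote = TRUE, na = "NA")
  invisible(path)
}

#' Restrict a cohort to complete cases on selected fields
#'
#' @param cohort A \code{cohort_table}.
#' @param required_fields Character vector of canonical column names; records
#'   missing any of them are dropped (the count is reported via message).
#' @return The filtered \code{cohort_table}.
#' @export
complete_case_subset <- function(cohort, required_fields = character()) {
  stopifnot(inherits(cohort, "cohort_table"))
  unknown <- setdiff(required_fields, names(cohort))
  if (length(unknown)) {
    stop("unknown field name(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (!length(required_fields)) return(cohort)
  keep <- rep(TRUE, nrow(cohort))
  for (f in required_fields) keep <- keep & !is.na(cohort[[f]])
  dropped <- sum(!keep)
  if (dropped > 0) {
    message(dropped, " record(s) dropped as incomplete on: ",
            paste(required_fields, collapse = ", "))
  }
  res <- cohort[keep, , drop = FALSE]
  rownames(res) <- NULL
  if (nrow(res) == 0L) {
    warning("all records missing a required field; cohort is empty",
            call. = FALSE)
  }
  structure(res,
            provenance = attr(cohort, "provenance"),
            schema_version = attr(cohort, "schema_version"),
            class = c("cohort_table", "data.frame"))
}

#' @export
print.cohort_table <- function(x, ...) {
  cat(sprintf("<cohort_table> %d record(s), provenance: %s\n",
              nrow(x), attr(x, "provenance")))
  NextMethod()
}
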