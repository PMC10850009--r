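# Versioned session container: all imported tables, every user decision that
# affects the statistics (exclusions in order, transferred uncertainty
# terms, k, rounding precision, planned lifetime) and file provenance are
# kept in one state object that persists losslessly to a checksummed JSON
# file.  Measurement values are never modified by any session operation.

SESSION_SCHEMA_VERSION <- 1L

#' Create an empty analysis session
#'
#' @param k default expansion factor (default 2).
#' @return an object of class `certification_session`.
#' @export
new_session <- function(k = 2) {
  structure(list(
    schema_version = SESSION_SCHEMA_VERSION,
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
    modified = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
    homogeneity = NULL,
    stability = NULL,
    certification = NULL,
    lts = NULL,
    options = list(
      excluded_labs = tibble(lab_id = character(), analyte = character(),
                             reason = character(), test = character()),
      transferred_terms = numeric(0),
      k = k,
      rounding_digits = NULL,
      t_cert = NULL
    ),
    source_files = character(0)
  ), class = "certification_session")
}

touch <- function(state) {
  state$modified <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S")
  state
}

#' Attach an imported table to a session
#'
#' @param state a `certification_session`.
#' @param slot one of `"homogeneity"`, `"stability"`, `"certification"`,
#'   `"lts"`.
#' @param table the object returned by the corresponding reader.
#' @return the updated session.
#' @export
session_set <- function(state, slot, table) {
  stopifnot(inherits(state, "certification_session"))
  slot <- match.arg(slot, c("homogeneity", "stability", "certification", "lts"))
  state[[slot]] <- table
  src <- attr(table, "source_file", exact = TRUE) %||%
    attr(table, "source_files", exact = TRUE) %||%
    (if (inherits(table, "lts_dataset")) table$source_file else NULL)
  state$source_files <- union(state$source_files, src)
  touch(state)
}

#' Record the exclusion of a laboratory
#'
#' Exclusions are an ordered, append-only record of user decisions; the
#' measurement data of excluded laboratories remain in the session.
#'
#' @param state a `certification_session`.
#' @param lab_id laboratory identifier.
#' @param analyte analyte the exclusion applies to.
#' @param reason free-text reason.
#' @param test name of the test that motivated the exclusion.
#' @return the updated session.
#' @export
session_exclude <- function(state, lab_id, analyte, reason = NA_character_,
                            test = NA_character_) {
  stopifnot(inherits(state, "certification_session"))
  state$options$excluded_labs <- bind_rows(
    state$options$excluded_labs,
    tibble(lab_id = lab_id, analyte = analyte, reason = reason, test = test))
  touch(state)
}

#' Transfer a relative uncertainty term into the budget
#'
#' @param state a `certification_session`.
#' @param term term name (e.g. `"u_bb"`, `"u_stab"`, `"u_rep"`).
#' @param value relative value in percent (>= 0).
#' @return the updated session.
#' @export
session_transfer <- function(state, term, value) {
  stopifnot(inherits(state, "certification_session"))
  if (!is.numeric(value) || value < 0) stop_validation("term value must be >= 0")
  state$options$transferred_terms[[term]] <- as.numeric(value)
  touch(state)
}

#' @export
print.certification_session <- function(x, ...) {
  loaded <- c("homogeneity", "stability", "certification", "lts")
  loaded <- loaded[!vapply(x[loaded], is.null, TRUE)]
  cat(sprintf("<certification_session> v%d, modules: %s\n", x$schema_version,
              if (length(loaded)) paste(loaded, collapse = ", ") else "(none)"))
  if (nrow(x$options$excluded_labs) > 0) {
    cat(sprintf("  exclusions: %s\n",
                paste(x$options$excluded_labs$lab_id, collapse = " -> ")))
  }
  if (length(x$options$transferred_terms) > 0) {
    cat(sprintf("  transferred: %s\n",
                paste(sprintf("%s=%.3g%%", names(x$options$transferred_terms),
                              x$options$transferred_terms), collapse = ", ")))
  }
  invisible(x)
}

# ---- serialization -------------------------------------------------------

encode_table <- function(tbl) {
  if (is.null(tbl)) return(NULL)
  df <- as.data.frame(tbl)
  for (nm in names(df)) if (inherits(df[[nm]], "Date")) {
    df[[nm]] <- format(df[[nm]], "%Y-%m-%d")
  }
  list(data = df,
       attrs = list(source_file = attr(tbl, "source_file", exact = TRUE),
                    source_files = attr(tbl, "source_files", exact = TRUE),
                    arrhenius = attr(tbl, "arrhenius", exact = TRUE),
                    analyte_warnings = attr(tbl, "analyte_warnings", exact = TRUE)))
}

decode_table <- function(enc, date_cols = character(0), int_cols = character(0),
                         num_cols = character(0)) {
  if (is.null(enc)) return(NULL)
  df <- as_tibble(as.data.frame(enc$data, stringsAsFactors = FALSE))
  for (nm in intersect(date_cols, names(df))) df[[nm]] <- as.Date(df[[nm]])
  for (nm in intersect(int_cols, names(df))) df[[nm]] <- as.integer(df[[nm]])
  for (nm in intersect(num_cols, names(df))) df[[nm]] <- as.numeric(df[[nm]])
  attrs <- enc$attrs
  # exact indexing: $ would partial-match source_file -> source_files
  if (!is.null(attrs[["source_file"]])) attr(df, "source_file") <- attrs[["source_file"]]
  if (!is.null(attrs[["source_files"]])) attr(df, "source_files") <- unlist(attrs[["source_files"]])
  if (!is.null(attrs[["analyte_warnings"]])) {
    attr(df, "analyte_warnings") <- as.character(unlist(attrs[["analyte_warnings"]]))
  }
  if (!is.null(attrs[["arrhenius"]])) attr(df, "arrhenius") <- attrs[["arrhenius"]]
  df
}

encode_lts <- function(lts) {
  if (is.null(lts)) return(NULL)
  meta <- lts$meta
  meta$certification_date <- format(meta$certification_date, "%Y-%m-%d")
  list(meta = meta,
       points = encode_table(lts$points)$data,
       source_file = lts$source_file)
}

decode_lts <- function(enc) {
  if (is.null(enc)) return(NULL)
  meta <- enc$meta
  meta$certification_date <- as.Date(meta$certification_date)
  pts <- as_tibble(as.data.frame(enc$points, stringsAsFactors = FALSE))
  pts$date <- as.Date(pts$date)
  if (!"comment" %in% names(pts)) pts$comment <- NA_character_
  pts$comment <- as.character(pts$comment)
  new_lts_dataset(meta = meta, points = pts,
                  source_file = enc$source_file %||% NA_character_)
}

session_payload <- function(state) {
  list(
    created = state$created,
    modified = state$modified,
    homogeneity = encode_table(state$homogeneity),
    stability = encode_table(state$stability),
    certification = encode_table(state$certification),
    lts = encode_lts(state$lts),
    options = list(
      excluded_labs = as.data.frame(state$options$excluded_labs),
      transferred_terms = as.list(state$options$transferred_terms),
      k = state$options$k,
      rounding_digits = state$options$rounding_digits,
      t_cert = state$options$t_cert
    ),
    source_files = state$source_files
  )
}

#' Save a session to a checksummed JSON file
#'
#' The payload is serialized once to JSON at full numeric precision; its
#' SHA-256 checksum is stored next to it so that accidental manipulation or
#' truncation of the file is detected on reload.
#'
#' @param state a `certification_session`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
save_session <- function(state, path) {
  stopifnot(inherits(state, "certification_session"))
  payload_json <- as.character(jsonlite::toJSON(
    session_payload(state), dataframe = "columns", digits = NA,
    auto_unbox = TRUE, na = "null", null = "null"))
  obj <- list(format = "certifyr-session",
              schema_version = state$schema_version,
              checksum = digest::digest(payload_json, algo = "sha256",
                                        serialize = FALSE),
              payload = payload_json)
  writeLines(as.character(jsonlite::toJSON(obj, auto_unbox = TRUE)), path)
  invisible(path)
}

#' Load a session from a JSON file
#'
#' Verifies the schema version and the payload checksum before
#' reconstructing the state; `load_session(save_session(x))` reproduces `x`
#' including user options and exclusion order.
#'
#' @param path path to a session file written by [save_session()].
#' @return a `certification_session`.
#' @export
load_session <- function(path) {
  if (!file.exists(path)) stop_format("session file not found: %s", path)
  obj <- tryCatch(jsonlite::fromJSON(readr::read_file(path), simplifyVector = TRUE),
                  error = function(e) {
                    stop_integrity("session file is corrupt or truncated: %s",
                                   conditionMessage(e))
                  })
  if (!identical(obj$format, "certifyr-session")) {
    stop_integrity("not a session file (missing format marker)")
  }
  if (obj$schema_version > SESSION_SCHEMA_VERSION) {
    abort(sprintf("session schema_version %d is newer than supported version %d",
                  obj$schema_version, SESSION_SCHEMA_VERSION),
          class = "certifyr_unsupported_version")
  }
  checksum <- digest::digest(obj$payload, algo = "sha256", serialize = FALSE)
  if (!identical(checksum, obj$checksum)) {
    stop_integrity("session checksum mismatch: file content has been altered")
  }
  payload <- jsonlite::fromJSON(obj$payload, simplifyVector = TRUE,
                                simplifyDataFrame = TRUE)
  excl <- payload$options$excluded_labs
  excl <- if (is.null(excl) || length(excl) == 0 ||
              (is.data.frame(excl) && nrow(excl) == 0)) {
    tibble(lab_id = character(), analyte = character(),
           reason = character(), test = character())
  } else {
    excl <- as_tibble(excl)
    for (nm in c("lab_id", "analyte", "reason", "test")) {
      excl[[nm]] <- as.character(excl[[nm]])
    }
    excl
  }
  tt <- payload$options$transferred_terms
  # NB: build the whole list in one expression -- assigning NULL to a list
  # element would delete the slot and break positional equality
  structure(list(
    schema_version = as.integer(obj$schema_version),
    created = payload$created,
    modified = payload$modified,
    homogeneity = decode_table(payload$homogeneity, int_cols = "replicate"),
    stability = decode_table(payload$stability, date_cols = "date",
                             num_cols = "temperature"),
    certification = decode_table(payload$certification, int_cols = "replicate"),
    lts = decode_lts(payload$lts),
    options = list(
      excluded_labs = excl,
      transferred_terms = if (is.null(tt) || length(tt) == 0) numeric(0) else unlist(tt),
      k = payload$options$k,
      rounding_digits = payload$options$rounding_digits,
      t_cert = payload$options$t_cert
    ),
    source_files = unlist(payload$source_files) %||% character(0)
  ), class = "certification_session")
}
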