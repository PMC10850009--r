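# Session evaluation and HTML reporting.  The report renders exactly the
# numbers the modules computed (full precision, no re-rounding in the
# template); presentation rounding appears only where the budget itself
# rounded (DIN 1333 columns).

#' Evaluate every module present in a session
#'
#' Runs the homogeneity, stability, certification/budget and monitoring
#' computations on the tables stored in a session, honouring the recorded
#' user options (exclusion order, transferred terms, k, t_cert, rounding
#' override).
#'
#' @param state a `certification_session`.
#' @return a list with elements `homogeneity`, `stability`, `arrhenius`,
#'   `certification`, `budget`, `lts` (each `NULL` when the corresponding
#'   table is absent).
#' @export
evaluate_session <- function(state) {
  stopifnot(inherits(state, "certification_session"))
  out <- list()
  if (!is.null(state$homogeneity)) {
    out$homogeneity <- lapply(unique(state$homogeneity$analyte), function(a) {
      evaluate_homogeneity(state$homogeneity, a)
    })
    names(out$homogeneity) <- unique(state$homogeneity$analyte)
  }
  if (!is.null(state$stability)) {
    if (isTRUE(attr(state$stability, "arrhenius")) ||
        !all(is.na(state$stability$temperature))) {
      rates <- keff_per_temperature(state$stability)
      out$arrhenius <- list(rates = rates, model = fit_arrhenius(rates))
    } else {
      t_cert <- state$options$t_cert %||% 24
      out$stability <- purrr::map_dfr(unique(state$stability$analyte), function(a) {
        fit_stability(state$stability, t_cert = t_cert, analyte = a)
      })
    }
  }
  if (!is.null(state$certification)) {
    analytes <- unique(state$certification$analyte)
    out$certification <- lapply(analytes, function(a) {
      evaluate_battery(state$certification, a,
                       exclusions = state$options$excluded_labs)
    })
    names(out$certification) <- analytes
    out$budget <- lapply(analytes, function(a) {
      sm <- lab_summaries(state$certification, a,
                          exclusions = state$options$excluded_labs)
      uncertainty_budget(sm, transferred = state$options$transferred_terms,
                         k = state$options$k %||% 2,
                         digits = state$options$rounding_digits)
    })
    names(out$budget) <- analytes
  }
  if (!is.null(state$lts)) {
    fit <- lts_fit(state$lts)
    out$lts <- list(fit = fit,
                    shelf_life = lts_shelf_life(fit),
                    shelf_life_ci = lts_shelf_life(fit, use_ci = TRUE))
  }
  out
}

html_escape_text <- function(x) xml_escape(as.character(x))

html_table <- function(df, caption = NULL) {
  fmt <- function(v) {
    if (is.numeric(v)) format_num(v) else html_escape_text(v)
  }
  cells <- vapply(names(df), function(nm) nm, "")
  head_row <- paste0("<tr>", paste0("<th>", html_escape_text(cells), "</th>",
                                    collapse = ""), "</tr>")
  body <- vapply(seq_len(nrow(df)), function(i) {
    row <- vapply(seq_along(df), function(j) {
      v <- df[[j]][i]
      if (inherits(v, "Date")) v <- format(v, "%Y-%m-%d")
      paste0("<td>", if (is.na(v)) "" else fmt(v), "</td>")
    }, "")
    paste0("<tr>", paste(row, collapse = ""), "</tr>")
  }, "")
  paste0("<table>",
         if (!is.null(caption)) paste0("<caption>", html_escape_text(caption),
                                       "</caption>"),
         "<thead>", head_row, "</thead><tbody>",
         paste(body, collapse = ""), "</tbody></table>")
}

#' Render a self-contained HTML report of a session
#'
#' @param state a `certification_session` with at least one module present.
#' @param path optional output file; when given the document is written
#'   there.
#' @return the HTML document as a single string (invisibly when `path` is
#'   given).
#' @export
render_report <- function(state, path = NULL) {
  results <- evaluate_session(state)
  if (length(results) == 0) stop_validation("session contains no evaluable module")
  parts <- c(
    "<!DOCTYPE html><html><head><meta charset='utf-8'>",
    "<title>Certification report</title>",
    "<style>body{font-family:sans-serif;margin:2em}table{border-collapse:collapse;margin:1em 0}",
    "td,th{border:1px solid #999;padding:0.3em 0.6em}caption{font-weight:bold;text-align:left}</style>",
    "</head><body>",
    "<h1>Reference material certification report</h1>",
    sprintf("<p>Session created %s, last modified %s.</p>",
            html_escape_text(state$created), html_escape_text(state$modified)),
    if (length(state$source_files) > 0) {
      sprintf("<p>Source files: %s</p>",
              paste(html_escape_text(state$source_files), collapse = ", "))
    })
  if (!is.null(results$homogeneity)) {
    parts <- c(parts, "<h2>Homogeneity study</h2>",
               html_table(purrr::map_dfr(results$homogeneity, tidy),
                          caption = "Homogeneity ANOVA and between-bottle dispersion (relative %)"))
  }
  if (!is.null(results$stability)) {
    parts <- c(parts, "<h2>Stability study</h2>",
               html_table(results$stability,
                          caption = "Linear drift model and u_stab"))
  }
  if (!is.null(results$arrhenius)) {
    parts <- c(parts, "<h2>Accelerated stability (Arrhenius)</h2>",
               html_table(results$arrhenius$rates,
                          caption = "Per-temperature effective rates k_eff (1/month)"),
               html_table(glance(results$arrhenius$model),
                          caption = "Arrhenius model"))
  }
  if (!is.null(results$certification)) {
    for (a in names(results$certification)) {
      b <- results$certification[[a]]
      parts <- c(parts, sprintf("<h2>Certification study: %s</h2>",
                                html_escape_text(a)),
                 html_table(b$summaries, caption = "Laboratory summaries"),
                 html_table(b$tests, caption = "Statistical test battery"),
                 html_table(glance(results$budget[[a]]),
                            caption = "Uncertainty budget"),
                 html_table(tidy(results$budget[[a]]),
                            caption = "Relative uncertainty contributions (%)"))
    }
  }
  if (!is.null(results$lts)) {
    parts <- c(parts, "<h2>Post-certification monitoring</h2>",
               html_table(tidy(results$lts$fit), caption = "LTS regression"),
               html_table(bind_rows(results$lts$shelf_life,
                                    results$lts$shelf_life_ci),
                          caption = "Prospective shelf life (months)"))
  }
  parts <- c(parts, "</body></html>")
  doc <- paste(parts, collapse = "\n")
  if (!is.null(path)) {
    readr::write_file(doc, path)
    return(invisible(doc))
  }
  doc
}
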