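#' Screen a drug table and assemble a report
#'
#' The main entry point: load a drug table (the packaged knowledge base or a
#' user CSV/TSV), classify every record on both delivery routes, attach the
#' packaged efflux-transporter annotations where available, and optionally
#' write the report to disk as JSON, CSV or markdown.
#'
#' @param input `"packaged"` (default) for the built-in reference table, or a
#'   path readable by [read_drug_table()].
#' @param cfg a [rule_config()].
#' @param format output format used when `out` is given: `"json"`, `"csv"` or
#'   `"markdown"`.
#' @param out optional output file path.
#' @param ascii render label symbols in plain ASCII (see [label_symbol()]).
#' @param provenance include input path, timestamp and package version in the
#'   report (disable for byte-identical reruns).
#' @return an object of class `bbbced_screen_report`: a list with `table`
#'   (the [screen_drugs()] tibble, plus efflux columns when packaged),
#'   `counts` (per-route label counts), `config` and `provenance`.
#' @export
#' @examples
#' rep <- run_screen()
#' rep$counts
run_screen <- function(input = "packaged", cfg = rule_config(),
                       format = c("json", "csv", "markdown"), out = NULL,
                       ascii = FALSE, provenance = TRUE) {
  format <- match.arg(format)
  if (identical(input, "packaged")) {
    kb <- load_knowledge_base()
    records <- kb$drugs
    efflux <- kb$efflux
  } else {
    records <- read_drug_table(input)
    efflux <- NULL
  }
  scr <- screen_drugs(records, cfg)
  if (!is.null(efflux) && nrow(scr)) {
    eff <- efflux
    eff$name_key <- tolower(eff$name)
    scr$name_key <- tolower(scr$name)
    scr <- dplyr::left_join(
      scr, eff[, c("name_key", "pgp", "bcrp", "mrp1")], by = "name_key"
    )
    scr$name_key <- NULL
  }
  counts <- list(
    systemic = count_labels(scr$systemic_label, SYSTEMIC_LEVELS),
    ced = count_labels(scr$ced_label, CED_LEVELS)
  )
  report <- structure(
    list(
      table = scr,
      counts = counts,
      config = cfg,
      provenance = if (provenance) list(
        input = if (identical(input, "packaged")) "packaged" else input,
        timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
        tool_version = as.character(utils::packageVersion("bbbced"))
      ) else NULL,
      ascii = ascii
    ),
    class = "bbbced_screen_report"
  )
  if (!is.null(out)) write_screen_report(report, out, format)
  report
}

count_labels <- function(labels, levels) {
  out <- vapply(levels, function(l) sum(labels == l), integer(1))
  names(out) <- levels
  out
}

#' @export
print.bbbced_screen_report <- function(x, ...) {
  n <- nrow(x$table)
  cat(sprintf("<delivery screen: %d drugs>\n", n))
  cs <- x$counts$systemic
  cc <- x$counts$ced
  cat(sprintf("  systemic likely: %d / %d (%d%%), intermediate: %d, unlikely: %d\n",
              cs[["likely"]], n, percent_truncated(cs[["likely"]], n),
              cs[["intermediate"]], cs[["unlikely"]]))
  cat(sprintf("  CED suitable: %d / %d (%d%%), speculative: %d, unsuitable: %d\n",
              cc[["suitable"]], n, percent_truncated(cc[["suitable"]], n),
              cc[["speculative"]], cc[["unsuitable"]]))
  invisible(x)
}

# serialize a screen report table for output
report_rows <- function(report) {
  scr <- report$table
  ascii <- isTRUE(report$ascii)
  scr$systemic_symbol <- label_symbol(scr$systemic_label, ascii = ascii)
  scr$systemic_color <- label_color(scr$systemic_label)
  scr$ced_symbol <- label_symbol(scr$ced_label, ascii = ascii)
  scr$ced_color <- label_color(scr$ced_label)
  scr
}

#' Write a screen report to disk
#'
#' @param report a `bbbced_screen_report`.
#' @param path output path.
#' @param format `"json"`, `"csv"` or `"markdown"`.
#' @return `path`, invisibly.
#' @export
write_screen_report <- function(report, path, format = c("json", "csv", "markdown")) {
  format <- match.arg(format)
  rows <- report_rows(report)
  if (format == "csv") {
    readr::write_csv(rows, path, progress = FALSE)
  } else if (format == "markdown") {
    writeLines(screen_markdown(rows), path)
  } else {
    payload <- list(
      drugs = lapply(seq_len(nrow(rows)), function(i) {
        r <- as.list(rows[i, ])
        r$systemic_reasons <- as.list(split_set(r$systemic_reasons))
        r$systemic_overrides <- as.list(split_set(r$systemic_overrides))
        r$ced_reasons <- as.list(split_set(r$ced_reasons))
        r
      }),
      counts = lapply(report$counts, as.list),
      config = config_payload(report$config),
      provenance = report$provenance
    )
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                         null = "null", na = "null", pretty = TRUE)
  }
  invisible(path)
}

config_payload <- function(cfg) {
  out <- unclass(cfg)
  wl <- out$discrepancy_whitelist
  out$discrepancy_whitelist <- lapply(seq_len(nrow(wl)), function(i) {
    list(name = wl$name[i], route = wl$route[i])
  })
  out
}

screen_markdown <- function(rows) {
  header <- c(
    "| Drug | Class | Log P | MW (g/mol) | Charge (%) | Systemic | CED |",
    "|---|---|---|---|---|---|---|"
  )
  fmt <- function(x) ifelse(is.na(x), "unknown", as.character(x))
  body <- sprintf(
    "| %s | %s | %s | %s | %s | %s | %s |",
    rows$name, rows$drug_class, fmt(rows$log_p),
    fmt(rows$molecular_weight_g_per_mol),
    ifelse(is.na(rows$charge_percent), "unknown",
           paste0(rows$charge_percent,
                  ifelse(rows$charge_sign %in% c("neutral", "unknown"), "",
                         paste0(" (", rows$charge_sign, ")")))),
    rows$systemic_symbol, rows$ced_symbol
  )
  c(header, body)
}

#' Render the packaged reference table with computed labels
#'
#' Emits the packaged drug table with the computed systemic and CED labels
#' side-by-side with the published ones, in the requested format.
#'
#' @param format `"markdown"`, `"csv"` or `"json"`.
#' @param cfg a [rule_config()].
#' @param ascii render symbols in plain ASCII.
#' @return a character vector of lines (markdown/csv) or a JSON string.
#' @export
render_reference_table <- function(format = c("markdown", "csv", "json"),
                                   cfg = rule_config(), ascii = FALSE) {
  format <- match.arg(format)
  kb <- load_knowledge_base()
  scr <- screen_drugs(kb$drugs, cfg)
  scr$computed_systemic <- label_symbol(scr$systemic_label, ascii = ascii)
  scr$computed_ced <- label_symbol(scr$ced_label, ascii = ascii)
  cols <- c("name", "drug_class", "log_p", "molecular_weight_g_per_mol",
            "charge_percent", "charge_sign", "computed_systemic",
            "published_systemic", "computed_ced", "published_ced")
  tab <- scr[cols]
  if (format == "csv") {
    return(readr::format_csv(tab))
  }
  if (format == "json") {
    return(as.character(jsonlite::toJSON(tab, pretty = TRUE, auto_unbox = TRUE,
                                         na = "null", digits = NA)))
  }
  fmt <- function(x) ifelse(is.na(x), "unknown", as.character(x))
  c(
    paste("|", paste(names(tab), collapse = " | "), "|"),
    paste0("|", paste(rep("---", length(names(tab))), collapse = "|"), "|"),
    apply(tab, 1L, function(r) paste("|", paste(fmt(r), collapse = " | "), "|"))
  )
}
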