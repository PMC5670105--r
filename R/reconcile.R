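#' Reconcile computed labels against published labels
#'
#' Re-classifies every record on both routes and compares the computed labels
#' with the published reference labels carried by the records. Mismatches are
#' checked against the configuration's discrepancy whitelist — the named rows
#' whose published labels are known not to be reproducible by any uniform
#' threshold set — so that a rule change that silently alters agreement with
#' the reference table is caught.
#'
#' Records without a published label for a route are skipped for that route
#' with a warning.
#'
#' @param records tibble of drug records carrying published labels.
#' @param cfg a [rule_config()].
#' @return an object of class `bbbced_reconciliation`: a list with `rows`
#'   (tibble: `name`, `route`, `computed`, `published`, `match`, `notes`),
#'   `mismatches` (the non-matching subset), `new_mismatches` (mismatches not
#'   on the whitelist) and `ok` (`TRUE` iff every mismatch is whitelisted).
#' @export
#' @examples
#' kb <- load_knowledge_base()
#' rec <- reconcile(kb$drugs)
#' rec$ok
reconcile <- function(records, cfg = rule_config()) {
  scr <- screen_drugs(records, cfg)
  long <- dplyr::bind_rows(
    tibble::tibble(
      name = scr$name, route = "systemic",
      computed = label_to_symbol_ascii(scr$systemic_label),
      published = scr$published_systemic,
      notes = scr$systemic_overrides
    ),
    tibble::tibble(
      name = scr$name, route = "ced",
      computed = label_to_symbol_ascii(scr$ced_label),
      published = scr$published_ced,
      notes = scr$ced_reasons
    )
  )
  skipped <- long[is.na(long$published), ]
  if (nrow(skipped)) {
    warning(sprintf("%d record/route pair(s) lack a published label and were skipped (e.g. %s)",
                    nrow(skipped), skipped$name[[1]]))
    long <- long[!is.na(long$published), ]
  }
  long$match <- long$computed == long$published
  mism <- long[!long$match, c("name", "route", "computed", "published", "notes")]
  wl <- cfg$discrepancy_whitelist
  wl_key <- paste(tolower(wl$name), wl$route)
  new_mism <- mism[!paste(tolower(mism$name), mism$route) %in% wl_key, ]
  structure(
    list(
      rows = long[, c("name", "route", "computed", "published", "match", "notes")],
      mismatches = mism,
      new_mismatches = new_mism,
      ok = nrow(new_mism) == 0L
    ),
    class = "bbbced_reconciliation"
  )
}

#' @export
print.bbbced_reconciliation <- function(x, ...) {
  n <- nrow(x$rows)
  cat(sprintf("<reconciliation: %d comparisons, %d match, %d mismatch (%d whitelisted)>\n",
              n, sum(x$rows$match), nrow(x$mismatches),
              nrow(x$mismatches) - nrow(x$new_mismatches)))
  if (nrow(x$mismatches)) {
    m <- x$mismatches
    for (i in seq_len(nrow(m))) {
      cat(sprintf("  %-16s %-8s computed %-4s published %-4s\n",
                  m$name[i], m$route[i], m$computed[i], m$published[i]))
    }
  }
  cat(if (x$ok) "  status: all mismatches whitelisted\n"
      else "  status: NEW mismatches present\n")
  invisible(x)
}
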