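#' @importFrom rlang %||% .data
NULL

# canonical drug-table columns, in order
DRUG_COLUMNS <- c(
  "name", "drug_class", "log_p", "molecular_weight_g_per_mol",
  "charge_percent", "charge_sign", "is_prodrug", "oral_only",
  "compound_flags", "published_systemic", "published_ced", "footnotes"
)

# accepted aliases for user-supplied tables (header subset is allowed)
COLUMN_ALIASES <- list(
  log_p = c("log_p", "logp"),
  molecular_weight_g_per_mol = c("molecular_weight_g_per_mol", "molecular_weight", "mw"),
  charge_percent = c("charge_percent", "charge")
)

#' Construct a single drug record
#'
#' A drug record is one row of the drug table: identity, physicochemical
#' properties, administration flags, and (optionally) the published delivery
#' labels it is reconciled against. Missing numeric properties are `NA`, never
#' sentinel values. If `charge_sign` is omitted it is inferred: a charge of 0
#' is neutral, a missing charge is unknown; any other charge requires an
#' explicit sign.
#'
#' @param name drug name (unique, case-insensitive key; stored as given).
#' @param drug_class one of the mechanism-of-action classes (see
#'   `validate_record()` for the enumeration); default `"other_drug"`.
#' @param log_p octanol/water partition coefficient, or `NA`.
#' @param molecular_weight_g_per_mol molecular weight in g/mol, or `NA`.
#' @param charge_percent percent of molecules carrying a net charge at
#'   physiological pH, in `[0, 100]`, or `NA`.
#' @param charge_sign `"positive"`, `"negative"`, `"zwitterionic"`,
#'   `"neutral"` or `"unknown"`; inferred when `NULL`.
#' @param is_prodrug requires metabolic activation?
#' @param oral_only only available as an oral formulation?
#' @param compound_flags character vector, subset of
#'   `c("platinum_complex", "biologic")`.
#' @param published_systemic,published_ced published labels as `"+"`, `"+/-"`
#'   or `"-"` (Unicode minus accepted), or `NA` for user records.
#' @param footnotes character vector of footnote markers.
#' @return a one-row tibble with the canonical drug-table columns.
#' @export
#' @examples
#' drug_record("Carmustine", "alkylating", log_p = 1.53,
#'             molecular_weight_g_per_mol = 214.10, charge_percent = 0)
drug_record <- function(name,
                        drug_class = "other_drug",
                        log_p = NA_real_,
                        molecular_weight_g_per_mol = NA_real_,
                        charge_percent = NA_real_,
                        charge_sign = NULL,
                        is_prodrug = FALSE,
                        oral_only = FALSE,
                        compound_flags = character(),
                        published_systemic = NA_character_,
                        published_ced = NA_character_,
                        footnotes = character()) {
  if (is.null(charge_sign)) {
    charge_sign <- if (is.na(charge_percent)) "unknown"
      else if (charge_percent == 0) "neutral"
      else stop("charge_sign must be given when charge_percent is nonzero")
  }
  tibble::tibble(
    name = as.character(name),
    drug_class = as.character(drug_class),
    log_p = as.double(log_p),
    molecular_weight_g_per_mol = as.double(molecular_weight_g_per_mol),
    charge_percent = as.double(charge_percent),
    charge_sign = as.character(charge_sign),
    is_prodrug = isTRUE(is_prodrug),
    oral_only = isTRUE(oral_only),
    compound_flags = paste(compound_flags, collapse = ";"),
    published_systemic = canon_symbol(published_systemic),
    published_ced = canon_symbol(published_ced),
    footnotes = paste(footnotes, collapse = ";")
  )
}

#' Load the packaged drug knowledge base
#'
#' Returns the reference table of chemotherapeutics historically administered
#' to DIPG patients (physicochemical properties, administration flags,
#' published systemic and CED labels) together with the efflux-transporter
#' substrate annotations (P-gp, BCRP, MRP1). The efflux annotations are
#' descriptive only: transporter affinity is concentration-dependent and is
#' never used by the classification rules.
#'
#' @return a list with elements `drugs` (tibble of drug records, in table
#'   order) and `efflux` (tibble with columns `name`, `pgp`, `bcrp`, `mrp1`,
#'   `references`), keyed 1:1 by case-insensitive name.
#' @export
#' @examples
#' kb <- load_knowledge_base()
#' nrow(kb$drugs)
load_knowledge_base <- function() {
  drugs_path <- system.file("extdata", "dipg_drugs.csv", package = "bbbced")
  efflux_path <- system.file("extdata", "dipg_efflux.csv", package = "bbbced")
  if (!nzchar(drugs_path) || !file.exists(drugs_path)) {
    stop("packaged knowledge base missing: extdata/dipg_drugs.csv")
  }
  if (!nzchar(efflux_path) || !file.exists(efflux_path)) {
    stop("packaged knowledge base missing: extdata/dipg_efflux.csv")
  }
  drugs <- read_drug_table(drugs_path)
  efflux <- readr::read_csv(
    efflux_path, comment = "#", show_col_types = FALSE,
    col_types = readr::cols(.default = readr::col_character())
  )
  efflux[is.na(efflux)] <- ""
  efflux$references <- efflux$references
  for (col in c("pgp", "bcrp", "mrp1")) {
    bad <- !efflux[[col]] %in% c("substrate", "non_substrate", "ambiguous", "unknown")
    if (any(bad)) {
      stop("corrupted efflux table (", efflux_path, "): bad value in column ", col)
    }
  }
  key_d <- tolower(drugs$name)
  key_e <- tolower(efflux$name)
  if (anyDuplicated(key_d) || anyDuplicated(key_e) ||
      !setequal(key_d, key_e)) {
    stop("knowledge base tables are not keyed 1:1 by drug name")
  }
  list(drugs = drugs, efflux = efflux)
}

#' Read a drug table from CSV or TSV
#'
#' Parses a user-supplied drug table into canonical records. Only the `name`
#' column is mandatory; missing optional columns become explicit missing
#' values (`NA` numerics, `"unknown"` charge sign), never silent zeros.
#' Column aliases `mw`/`molecular_weight` and `charge` are accepted.
#' Unrecognized columns are preserved as pass-through metadata after the
#' canonical columns.
#'
#' @param path path to the file.
#' @param dialect `"csv"` (default) or `"tsv"`; guessed from the file
#'   extension when not given.
#' @return a tibble of drug records.
#' @export
read_drug_table <- function(path, dialect = NULL) {
  if (!file.exists(path)) stop("drug table not found: ", path)
  dialect <- dialect %||%
    (if (grepl("\\.tsv$", path, ignore.case = TRUE)) "tsv" else "csv")
  dialect <- match.arg(dialect, c("csv", "tsv"))
  reader <- if (dialect == "tsv") readr::read_tsv else readr::read_csv
  raw <- reader(
    path, comment = "#", show_col_types = FALSE, progress = FALSE,
    col_types = readr::cols(.default = readr::col_character())
  )
  if (!"name" %in% names(raw)) {
    stop("drug table ", path, " lacks mandatory column 'name'; found: ",
         paste(names(raw), collapse = ", "))
  }
  parse_drug_frame(raw, context = path)
}

# shared parser for character data frames (file input and round trips)
parse_drug_frame <- function(raw, context = "drug table") {
  n <- nrow(raw)
  # resolve aliases onto canonical names
  for (canon in names(COLUMN_ALIASES)) {
    hits <- intersect(COLUMN_ALIASES[[canon]], names(raw))
    if (length(hits) && !canon %in% names(raw)) {
      names(raw)[names(raw) == hits[[1]]] <- canon
    }
  }
  get_chr <- function(col, default = NA_character_) {
    if (col %in% names(raw)) as.character(raw[[col]]) else rep(default, n)
  }
  parse_num <- function(col) {
    x <- get_chr(col)
    x[!is.na(x) & !nzchar(trimws(x))] <- NA_character_
    x[!is.na(x) & tolower(trimws(x)) %in% c("na", "unknown")] <- NA_character_
    out <- suppressWarnings(as.double(gsub(",", "", x)))
    bad <- which(!is.na(x) & is.na(out))
    if (length(bad)) {
      stop(sprintf("%s: non-numeric value '%s' in row %d, column %s",
                   context, x[bad[1]], bad[1], col))
    }
    out
  }
  parse_lgl <- function(col) {
    x <- toupper(trimws(get_chr(col, default = "FALSE")))
    x[is.na(x) | !nzchar(x)] <- "FALSE"
    out <- x %in% c("TRUE", "T", "1", "YES")
    bad <- which(!x %in% c("TRUE", "T", "1", "YES", "FALSE", "F", "0", "NO"))
    if (length(bad)) {
      stop(sprintf("%s: non-boolean value in row %d, column %s",
                   context, bad[1], col))
    }
    out
  }
  log_p <- parse_num("log_p")
  mw <- parse_num("molecular_weight_g_per_mol")
  charge <- parse_num("charge_percent")
  sign <- tolower(trimws(get_chr("charge_sign")))
  sign[is.na(sign) | !nzchar(sign)] <- NA_character_
  # infer sign where absent: 0 -> neutral, missing charge -> unknown
  sign[is.na(sign) & !is.na(charge) & charge == 0] <- "neutral"
  sign[is.na(sign)] <- "unknown"
  flags <- get_chr("compound_flags", default = "")
  flags[is.na(flags)] <- ""
  fns <- get_chr("footnotes", default = "")
  fns[is.na(fns)] <- ""
  out <- tibble::tibble(
    name = get_chr("name"),
    drug_class = {
      dc <- get_chr("drug_class", default = "other_drug")
      dc[is.na(dc) | !nzchar(dc)] <- "other_drug"
      dc
    },
    log_p = log_p,
    molecular_weight_g_per_mol = mw,
    charge_percent = charge,
    charge_sign = sign,
    is_prodrug = parse_lgl("is_prodrug"),
    oral_only = parse_lgl("oral_only"),
    compound_flags = flags,
    published_systemic = canon_symbol(get_chr("published_systemic")),
    published_ced = canon_symbol(get_chr("published_ced")),
    footnotes = fns
  )
  extra <- setdiff(names(raw), c(DRUG_COLUMNS, unlist(COLUMN_ALIASES)))
  if (length(extra)) out <- dplyr::bind_cols(out, raw[extra])
  out
}

#' Write a drug table to CSV or TSV
#'
#' Inverse of [read_drug_table()]: canonical columns first, pass-through
#' columns after, numerics written at full precision so a read/write round
#' trip reproduces every value exactly.
#'
#' @param records tibble of drug records.
#' @param path output file path.
#' @param dialect `"csv"` (default) or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_drug_table <- function(records, path, dialect = c("csv", "tsv")) {
  dialect <- match.arg(dialect)
  cols <- c(intersect(DRUG_COLUMNS, names(records)),
            setdiff(names(records), DRUG_COLUMNS))
  writer <- if (dialect == "tsv") readr::write_tsv else readr::write_csv
  writer(records[cols], path, progress = FALSE)
  invisible(path)
}

#' Validate a drug record against the table invariants
#'
#' Checks one record (or every row of a table via `validate_drug_table()`)
#' against the structural invariants: known drug class and charge sign,
#' charge percent within `[0, 100]`, positive molecular weight, a present
#' charge implying a known sign (and zero charge implying neutral), known
#' compound flags, and recognizable published labels. The validator reports;
#' it never throws.
#'
#' @param record a one-row tibble (or coercible list) of a drug record.
#' @return character vector of violation messages; empty when valid.
#' @export
#' @examples
#' validate_record(drug_record("DrugX", log_p = 2, charge_percent = 0))
validate_record <- function(record) {
  r <- as.list(record)
  v <- character()
  if (is.na(r$name) || !nzchar(r$name)) {
    v <- c(v, "name: must be non-empty")
  }
  if (!r$drug_class %in% DRUG_CLASSES) {
    v <- c(v, sprintf("drug_class: '%s' is not a known class", r$drug_class))
  }
  if (!r$charge_sign %in% CHARGE_SIGNS) {
    v <- c(v, sprintf("charge_sign: '%s' is not a known sign", r$charge_sign))
  }
  if (!is.na(r$molecular_weight_g_per_mol) && r$molecular_weight_g_per_mol <= 0) {
    v <- c(v, "molecular_weight_g_per_mol: must be > 0 when present")
  }
  ch <- r$charge_percent
  if (!is.na(ch)) {
    if (ch < 0 || ch > 100) {
      v <- c(v, "charge_percent: must lie in [0, 100]")
    }
    if (r$charge_sign == "unknown") {
      v <- c(v, "charge_sign: must not be 'unknown' when charge_percent is present")
    }
    if (ch == 0 && !r$charge_sign %in% c("neutral", "unknown")) {
      v <- c(v, "charge_sign: must be 'neutral' when charge_percent is 0")
    }
    if (ch > 0 && r$charge_sign == "neutral") {
      v <- c(v, "charge_sign: 'neutral' contradicts a nonzero charge_percent")
    }
  }
  flags <- split_set(r$compound_flags %||% "")
  bad_flags <- setdiff(flags, COMPOUND_FLAGS)
  if (length(bad_flags)) {
    v <- c(v, sprintf("compound_flags: unknown flag(s) %s",
                      paste(bad_flags, collapse = ", ")))
  }
  v
}

#' @rdname validate_record
#' @param records tibble of drug records.
#' @return `validate_drug_table()` returns a tibble with columns `name` and
#'   `violation`, one row per violation (zero rows when all records pass).
#' @export
validate_drug_table <- function(records) {
  rows <- lapply(seq_len(nrow(records)), function(i) {
    v <- validate_record(records[i, ])
    if (length(v)) tibble::tibble(name = records$name[i], violation = v)
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0L) tibble::tibble(name = character(), violation = character())
  else out
}

#' Export drug records as JSON
#'
#' @param records tibble of drug records.
#' @param pretty pretty-print the JSON?
#' @return a JSON string (one object per record; missing values as `null`,
#'   set-valued columns as arrays).
#' @export
drug_table_json <- function(records, pretty = TRUE) {
  recs <- lapply(seq_len(nrow(records)), function(i) {
    r <- as.list(records[i, ])
    r$compound_flags <- as.list(split_set(r$compound_flags))
    r$footnotes <- as.list(split_set(r$footnotes))
    r
  })
  jsonlite::toJSON(recs, pretty = pretty, auto_unbox = TRUE, na = "null",
                   digits = NA)
}

# case-insensitive lookup of records by name
lookup_drug <- function(records, name) {
  hit <- which(tolower(records$name) == tolower(name))
  if (length(hit) == 0L) stop("drug not found in table: ", name)
  records[hit[[1]], ]
}
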