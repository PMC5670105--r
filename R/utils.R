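# internal helpers shared across modules

SYSTEMIC_LEVELS <- c("likely", "intermediate", "unlikely")
CED_LEVELS <- c("suitable", "speculative", "unsuitable")

DRUG_CLASSES <- c(
  "alkylating", "topoisomerase_inhibitor", "monoclonal_antibody",
  "tyrosine_kinase_inhibitor", "mtor_inhibitor", "other_signal_transduction",
  "cytotoxic_antibiotic", "antimitotic", "antimetabolite", "platinum",
  "antihormone", "other_chemo", "other_drug"
)

CHARGE_SIGNS <- c("positive", "negative", "zwitterionic", "neutral", "unknown")

COMPOUND_FLAGS <- c("platinum_complex", "biologic")

#' Render a classification label as its report symbol
#'
#' Delivery labels are carried internally as words (`likely`, `intermediate`,
#' `unlikely` for the systemic route; `suitable`, `speculative`, `unsuitable`
#' for CED) and rendered as `+`, `+/-`, `-` in reports. By default the minus is
#' the Unicode minus sign; `ascii = TRUE` gives a plain hyphen for diff-stable
#' CSV output.
#'
#' @param label character vector of label words (either route).
#' @param ascii use ASCII `-` instead of Unicode minus.
#' @return character vector of symbols; `NA` maps to `NA`.
#' @export
#' @examples
#' label_symbol(c("likely", "speculative", "unlikely"))
label_symbol <- function(label, ascii = FALSE) {
  minus <- if (ascii) "-" else "−"
  out <- rep(NA_character_, length(label))
  out[label %in% c("likely", "suitable")] <- "+"
  out[label %in% c("intermediate", "speculative")] <- paste0("+/", minus)
  out[label %in% c("unlikely", "unsuitable")] <- minus
  bad <- !is.na(label) & is.na(out)
  if (any(bad)) {
    stop("unknown label(s): ", paste(unique(label[bad]), collapse = ", "))
  }
  out
}

# canonical ASCII form of a published +/- symbol (accepts Unicode minus and
# en dash as printed in the source table)
canon_symbol <- function(x) {
  x <- gsub("[−–]", "-", trimws(x))
  x[x == ""] <- NA_character_
  bad <- !is.na(x) & !x %in% c("+", "+/-", "-")
  if (any(bad)) {
    stop("unrecognized label symbol(s): ", paste(unique(x[bad]), collapse = ", "))
  }
  x
}

# word label -> canonical ASCII symbol
label_to_symbol_ascii <- function(label) {
  ifelse(is.na(label), NA_character_,
    c(
      likely = "+", intermediate = "+/-", unlikely = "-",
      suitable = "+", speculative = "+/-", unsuitable = "-"
    )[label]
  )
}

# colors used in the reference table: green = top label, yellow = intermediate,
# red = bottom label
label_color <- function(label) {
  ifelse(is.na(label), NA_character_,
    c(
      likely = "green", intermediate = "yellow", unlikely = "red",
      suitable = "green", speculative = "yellow", unsuitable = "red"
    )[label]
  )
}

# truncated integer percent, the arithmetic used for the headline summary
# (8 likely out of 53 -> "15%")
percent_truncated <- function(k, n) {
  if (n == 0) return(0L)
  as.integer(floor(100 * k / n))
}

# split a semicolon-packed set column into a character vector
split_set <- function(x) {
  if (is.na(x) || !nzchar(x)) return(character())
  trimws(strsplit(x, ";", fixed = TRUE)[[1]])
}

# derive an independent RNG seed for stream k from a master seed, kept within
# 32-bit integer range so adding a stream never shifts the others
derive_seed <- function(seed, k) {
  as.integer((as.double(seed) * 48271 + k * 1000003) %% 2147483647)
}
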