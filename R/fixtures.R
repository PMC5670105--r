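#' Specification for deterministic synthetic drug records
#'
#' Fixture generation is a pure function of `(spec, config)`: a single master
#' seed governs all random streams, with per-stream derived seeds so that
#' adding a stratum never shifts the values drawn by another.
#'
#' @param n number of records (or profiles) to generate.
#' @param seed master RNG seed (integer).
#' @param boundary_emphasis fraction in `[0, 1]` of records placed exactly on
#'   the configured decision thresholds (log P bounds, MW bounds, charge band
#'   edges), to exercise boundary inclusivity.
#' @param include_flags named logical vector switching the `prodrug`,
#'   `oral_only`, `platinum` and `biologic` strata on or off.
#' @param flag_rate per-record probability of each enabled flag stratum.
#' @return an object of class `bbbced_fixture_spec`.
#' @export
fixture_spec <- function(n, seed = 1L, boundary_emphasis = 0,
                         include_flags = c(prodrug = TRUE, oral_only = TRUE,
                                           platinum = TRUE, biologic = TRUE),
                         flag_rate = 0.1) {
  stopifnot(n >= 0, boundary_emphasis >= 0, boundary_emphasis <= 1)
  defaults <- c(prodrug = TRUE, oral_only = TRUE, platinum = TRUE, biologic = TRUE)
  defaults[names(include_flags)] <- include_flags
  structure(
    list(n = as.integer(n), seed = as.integer(seed),
         boundary_emphasis = boundary_emphasis,
         include_flags = defaults, flag_rate = flag_rate),
    class = "bbbced_fixture_spec"
  )
}

# draw under a derived stream seed without disturbing the caller's RNG state
with_stream <- function(seed, k, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(derive_seed(seed, k))
  force(expr)
}

#' Generate synthetic drug records
#'
#' Samples log P uniformly over `[-4, 8]`, molecular weight over
#' `[100, 1300]` Da and charge over the integers `0..100`, with sign strata
#' for charged records. A `boundary_emphasis` fraction of the records is
#' placed exactly on the configured thresholds (`logp_lower`, `logp_upper`,
#' `mw_max_da`, `mw_hard_cap_da`, and the charge band edges), cycling through
#' the boundary grid. Flag strata (prodrug, oral-only, platinum complex,
#' biologic) are drawn independently; biologic records get missing log P and
#' charge, as for real biologics, and are only drawn outside the boundary
#' block so the boundary count is exact. Every generated record passes
#' [validate_record()]. Published labels are absent.
#'
#' @param spec a [fixture_spec()].
#' @param cfg a [rule_config()] supplying the boundary values.
#' @return a tibble of drug records.
#' @export
#' @examples
#' generate_drug_records(fixture_spec(5, seed = 7))
generate_drug_records <- function(spec, cfg = rule_config()) {
  stopifnot(inherits(spec, "bbbced_fixture_spec"))
  n <- spec$n
  if (n == 0L) return(screen_empty_records())
  seed <- spec$seed
  log_p <- with_stream(seed, 1L, stats::runif(n, -4, 8))
  mw <- with_stream(seed, 2L, stats::runif(n, 100, 1300))
  charge <- with_stream(seed, 3L, sample(0:100, n, replace = TRUE))
  sign_pool <- with_stream(seed, 4L, sample(c("positive", "negative", "zwitterionic"),
                                            n, replace = TRUE,
                                            prob = c(0.45, 0.45, 0.10)))
  classes <- with_stream(seed, 5L, sample(DRUG_CLASSES, n, replace = TRUE))
  flag_draw <- function(k, enabled) {
    if (!enabled) return(rep(FALSE, n))
    with_stream(seed, k, stats::runif(n) < spec$flag_rate)
  }
  prodrug <- flag_draw(6L, spec$include_flags[["prodrug"]])
  oral <- flag_draw(7L, spec$include_flags[["oral_only"]])
  platinum <- flag_draw(8L, spec$include_flags[["platinum"]])
  biologic <- flag_draw(9L, spec$include_flags[["biologic"]])

  # boundary block: first m records pinned to threshold values
  m <- floor(n * spec$boundary_emphasis)
  if (m > 0L) {
    idx <- seq_len(m)
    logp_bounds <- c(cfg$logp_lower, cfg$logp_upper)
    mw_bounds <- c(cfg$mw_max_da, cfg$mw_hard_cap_da)
    charge_bounds <- c(0, cfg$charge_neutral_max_percent,
                       cfg$charge_full_min_percent, 100)
    log_p[idx] <- logp_bounds[(idx - 1L) %% length(logp_bounds) + 1L]
    mw[idx] <- mw_bounds[(idx - 1L) %% length(mw_bounds) + 1L]
    charge[idx] <- charge_bounds[(idx - 1L) %% length(charge_bounds) + 1L]
    biologic[idx] <- FALSE
  }

  sign <- ifelse(charge == 0, "neutral", sign_pool)
  log_p[biologic] <- NA_real_
  charge[biologic] <- NA_real_
  sign[biologic] <- "unknown"
  flags <- character(n)
  flags[platinum] <- "platinum_complex"
  flags[biologic] <- ifelse(platinum[biologic], "platinum_complex;biologic", "biologic")

  tibble::tibble(
    name = sprintf("SYN-%04d", seq_len(n)),
    drug_class = classes,
    log_p = log_p,
    molecular_weight_g_per_mol = mw,
    charge_percent = as.double(charge),
    charge_sign = sign,
    is_prodrug = prodrug,
    oral_only = oral,
    compound_flags = flags,
    published_systemic = NA_character_,
    published_ced = NA_character_,
    footnotes = ""
  )
}

screen_empty_records <- function() {
  tibble::tibble(
    name = character(), drug_class = character(), log_p = double(),
    molecular_weight_g_per_mol = double(), charge_percent = double(),
    charge_sign = character(), is_prodrug = logical(), oral_only = logical(),
    compound_flags = character(), published_systemic = character(),
    published_ced = character(), footnotes = character()
  )
}

#' Generate synthetic ionization profiles
#'
#' Each profile gets 0-4 ionizable groups with pKa uniform on `[1, 13]` and a
#' random acid/base kind; generation is deterministic per seed and every
#' profile respects the enumeration bound.
#'
#' @param spec a [fixture_spec()] (`n` profiles, `seed`).
#' @return a list of [ionization_profile()] objects.
#' @export
generate_ionization_profiles <- function(spec) {
  stopifnot(inherits(spec, "bbbced_fixture_spec"))
  n <- spec$n
  if (n == 0L) return(list())
  sizes <- with_stream(spec$seed, 21L, sample(0:4, n, replace = TRUE))
  kinds <- with_stream(spec$seed, 22L,
                       sample(c("acid", "base"), sum(sizes), replace = TRUE))
  pkas <- with_stream(spec$seed, 23L, stats::runif(sum(sizes), 1, 13))
  offsets <- cumsum(c(0L, sizes))
  lapply(seq_len(n), function(i) {
    take <- if (sizes[i] == 0L) integer() else (offsets[i] + 1L):offsets[i + 1L]
    ionization_profile(kind = kinds[take], pka = pkas[take])
  })
}
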