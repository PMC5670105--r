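# largest profile for which all 2^n protonation states are enumerated
MAX_ENUMERATED_GROUPS <- 20L

#' Ionizable groups and ionization profiles
#'
#' An ionizable group is an acid or base site with a pKa; an ionization
#' profile is the ordered collection of a molecule's ionizable groups. The
#' model treats sites as independent (no microstate coupling or tautomer
#' corrections): each group ionizes according to its own Henderson-Hasselbalch
#' fraction, and microspecies probabilities are products over groups.
#'
#' @param kind `"acid"` or `"base"` (vectorized in `ionization_profile()`).
#' @param pka pKa of the group, same scale as pH. Values far outside the
#'   aqueous window (0-14) trigger a warning but are accepted.
#' @return `ionizable_group()` a one-row tibble; `ionization_profile()` a
#'   tibble of class `bbbced_ionization_profile` with columns `kind`, `pka`.
#' @export
#' @examples
#' ionization_profile(kind = c("acid", "base"), pka = c(4.0, 9.0))
ionizable_group <- function(kind, pka) {
  kind <- match.arg(kind, c("acid", "base"))
  stopifnot(is.numeric(pka), length(pka) == 1L, is.finite(pka))
  if (pka < 0 || pka > 14) {
    warning(sprintf("pKa %g is outside the usual aqueous window (0, 14)", pka))
  }
  tibble::tibble(kind = kind, pka = as.double(pka))
}

#' @rdname ionizable_group
#' @export
ionization_profile <- function(kind = character(), pka = numeric()) {
  stopifnot(length(kind) == length(pka))
  if (length(kind)) {
    groups <- dplyr::bind_rows(purrr::map2(kind, pka, ionizable_group))
  } else {
    groups <- tibble::tibble(kind = character(), pka = double())
  }
  structure(groups, class = c("bbbced_ionization_profile", class(groups)))
}

#' Fraction ionized of a single group at a given pH
#'
#' Henderson-Hasselbalch closed form: an acid's ionized (deprotonated)
#' fraction is `1 / (1 + 10^(pKa - pH))`; a base's ionized (protonated)
#' fraction is `1 / (1 + 10^(pH - pKa))`. At `pH = pKa` either form gives
#' exactly 0.5.
#'
#' @param group a one-row group (from [ionizable_group()]) or a profile, in
#'   which case a vector of per-group fractions is returned.
#' @param ph pH of the medium.
#' @return numeric vector of fractions in `[0, 1]`.
#' @export
#' @examples
#' fraction_ionized(ionizable_group("acid", 7.4), ph = 7.4)  # 0.5
fraction_ionized <- function(group, ph) {
  stopifnot(is.numeric(ph), length(ph) == 1L)
  ifelse(group$kind == "acid",
         1 / (1 + 10^(group$pka - ph)),
         1 / (1 + 10^(ph - group$pka)))
}

#' Enumerate the microspecies distribution of a profile
#'
#' Enumerates all `2^n` protonation states of an `n`-group profile under the
#' independent-sites model: each state's probability is the product of its
#' groups' ionized or un-ionized fractions. A state's net charge counts
#' protonated bases as +1 each and deprotonated acids as -1 each; a state is
#' zwitterionic when it carries at least one of each.
#'
#' @param profile an [ionization_profile()].
#' @param ph pH of the medium.
#' @return a tibble with one row per microspecies: `state` (a string of 0/1
#'   ionization indicators, one per group, in profile order), `n_positive`,
#'   `n_negative`, `net_charge`, `zwitterionic`, `probability`. Probabilities
#'   sum to 1. The empty profile yields one all-neutral state of probability 1.
#' @export
microspecies_distribution <- function(profile, ph) {
  n <- nrow(profile)
  if (n > MAX_ENUMERATED_GROUPS) {
    stop(sprintf(paste0(
      "profile has %d ionizable groups; enumeration is limited to %d. ",
      "Use charge_summary() on a reduced profile or the closed-form ",
      "net_average_charge."), n, MAX_ENUMERATED_GROUPS))
  }
  if (n == 0L) {
    return(tibble::tibble(
      state = "", n_positive = 0L, n_negative = 0L, net_charge = 0L,
      zwitterionic = FALSE, probability = 1
    ))
  }
  f <- fraction_ionized(profile, ph)
  states <- as.matrix(expand.grid(rep(list(c(0L, 1L)), n)))
  prob <- apply(states, 1L, function(s) prod(ifelse(s == 1L, f, 1 - f)))
  n_pos <- as.integer(states %*% (profile$kind == "base"))
  n_neg <- as.integer(states %*% (profile$kind == "acid"))
  tibble::tibble(
    state = apply(states, 1L, paste, collapse = ""),
    n_positive = n_pos,
    n_negative = n_neg,
    net_charge = n_pos - n_neg,
    zwitterionic = n_pos > 0L & n_neg > 0L,
    probability = prob
  )
}

#' Summarize molecular charge at a given pH
#'
#' Bins the microspecies of a profile by the sign of their net charge and
#' reports the percent of molecules that are positively charged, negatively
#' charged, or net-neutral (these three sum to 100), plus the percent that are
#' zwitterionic (at least one protonated base and one deprotonated acid; this
#' overlaps the net-charge bins since a balanced zwitterion is net-neutral).
#' The net average charge, in elementary charges, is the closed-form sum of
#' protonated-base fractions minus deprotonated-acid fractions and is
#' available for profiles of any size. The dominant sign is the largest of
#' the positive, negative and zwitterionic percentages (neutral when all are
#' zero); an exact positive/negative tie is reported as zwitterionic.
#'
#' Percentages are exact; rounding is left to presentation.
#'
#' @param profile an [ionization_profile()].
#' @param ph pH of the medium.
#' @return an object of class `bbbced_charge_summary`: a list with fields
#'   `ph`, `percent_positive`, `percent_negative`, `percent_neutral`,
#'   `percent_zwitterionic`, `net_average_charge`, `dominant_sign`,
#'   `dominant_percent`.
#' @export
#' @examples
#' pro <- ionization_profile("base", 9.4)
#' charge_summary(pro, ph = 7.4)
charge_summary <- function(profile, ph) {
  f <- fraction_ionized(profile, ph)
  net_avg <- sum(f[profile$kind == "base"]) - sum(f[profile$kind == "acid"])
  dist <- microspecies_distribution(profile, ph)
  p_pos <- 100 * sum(dist$probability[dist$net_charge > 0L])
  p_neg <- 100 * sum(dist$probability[dist$net_charge < 0L])
  p_neu <- 100 * sum(dist$probability[dist$net_charge == 0L])
  p_zwit <- 100 * sum(dist$probability[dist$zwitterionic])
  cand <- c(positive = p_pos, negative = p_neg, zwitterionic = p_zwit)
  if (all(cand == 0)) {
    dominant <- "neutral"
    dom_pct <- p_neu
  } else if (p_pos == p_neg && p_pos >= p_zwit && p_pos > 0) {
    dominant <- "zwitterionic"
    dom_pct <- max(p_zwit, p_pos)
  } else {
    dominant <- names(cand)[which.max(cand)]
    dom_pct <- max(cand)
  }
  structure(
    list(
      ph = ph,
      percent_positive = p_pos,
      percent_negative = p_neg,
      percent_neutral = p_neu,
      percent_zwitterionic = p_zwit,
      net_average_charge = net_avg,
      dominant_sign = dominant,
      dominant_percent = dom_pct
    ),
    class = "bbbced_charge_summary"
  )
}

#' @export
print.bbbced_charge_summary <- function(x, ...) {
  cat(sprintf("<charge summary at pH %.2f>\n", x$ph))
  cat(sprintf("  positive: %.4f%%  negative: %.4f%%  neutral: %.4f%%\n",
              x$percent_positive, x$percent_negative, x$percent_neutral))
  cat(sprintf("  zwitterionic: %.4f%%\n", x$percent_zwitterionic))
  cat(sprintf("  net average charge: %+.4f e\n", x$net_average_charge))
  cat(sprintf("  dominant: %s (%.4f%%)\n", x$dominant_sign, x$dominant_percent))
  invisible(x)
}

#' Charge summaries over a pH grid
#'
#' @param profile an [ionization_profile()].
#' @param ph numeric vector of pH values.
#' @return a tibble with one row per pH and the [charge_summary()] fields as
#'   columns.
#' @export
titration_table <- function(profile, ph) {
  dplyr::bind_rows(lapply(ph, function(h) {
    s <- charge_summary(profile, h)
    tibble::as_tibble(unclass(s))
  }))
}

#' Read or write ionization profiles as a JSON sidecar
#'
#' The sidecar maps drug names to arrays of `{kind, pka}` objects, so charge
#' can be recomputed for user drugs whose percent charge is not supplied.
#'
#' @param path file path.
#' @return `read_ionization_profiles()` returns a named list of
#'   [ionization_profile()] objects.
#' @export
read_ionization_profiles <- function(path) {
  if (!file.exists(path)) stop("profile sidecar not found: ", path)
  raw <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  out <- lapply(raw, function(groups) {
    if (length(groups) == 0L) return(ionization_profile())
    groups <- tibble::as_tibble(groups)
    ionization_profile(kind = groups$kind, pka = groups$pka)
  })
  out
}

#' @rdname read_ionization_profiles
#' @param profiles named list of profiles.
#' @export
write_ionization_profiles <- function(profiles, path) {
  payload <- lapply(profiles, function(p) {
    lapply(seq_len(nrow(p)), function(i) list(kind = p$kind[i], pka = p$pka[i]))
  })
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
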