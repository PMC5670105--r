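#' Rule configuration for the delivery classifiers
#'
#' Every threshold the model uses, gathered in one configurable object. The
#' defaults encode the reference rule set: the permeability heuristics
#' (molecular weight at most 500 Da, log P at most 5), the charge bands
#' (at most 10% charged = effectively neutral, at least 90% = fully charged),
#' a lower lipophilicity bound below which a compound is too hydrophilic to
#' partition into the membrane, a hard molecular-weight cap above which no
#' systemic suitability is granted regardless of the other criteria, the
#' treatment of platinum coordination complexes (log P not assessable, since
#' aquation yields charged species in vivo), and the handling of prodrugs
#' (classified by their active metabolite, whose properties are not tabulated,
#' hence capped at the intermediate label).
#'
#' @param ph physiological pH at which charge is evaluated (default 7.4).
#' @param logp_lower exclusive lower bound on log P for the lipophilicity
#'   criterion; at or below it a drug is scored too hydrophilic.
#' @param logp_upper inclusive upper bound on log P (rule-of-five bound).
#' @param mw_max_da inclusive molecular-weight bound (Da) for the weight
#'   criterion.
#' @param mw_hard_cap_da molecular weight (Da) at or above which a drug is
#'   demoted to unlikely for systemic delivery regardless of score.
#' @param charge_neutral_max_percent inclusive upper bound of the
#'   effectively-neutral charge band (percent of molecules charged at `ph`).
#' @param charge_full_min_percent inclusive lower bound of the fully-charged
#'   band.
#' @param platinum_logp_not_assessable treat log P of platinum complexes as
#'   not assessable (criterion scored 0)?
#' @param prodrug_systemic_cap `"intermediate"` (default) forces every prodrug
#'   to the intermediate systemic label (its active metabolite, not the parent,
#'   determines permeation); `"none"` disables the override.
#' @param discrepancy_whitelist data frame with columns `name` and `route`
#'   listing known, accepted mismatches between computed and published labels.
#' @return an object of class `bbbced_rule_config` (a validated list).
#' @seealso [classify_systemic()], [classify_ced()], [reconcile()]
#' @export
#' @examples
#' cfg <- rule_config()
#' cfg$mw_max_da
rule_config <- function(ph = 7.4,
                        logp_lower = -0.5,
                        logp_upper = 5.0,
                        mw_max_da = 500,
                        mw_hard_cap_da = 900,
                        charge_neutral_max_percent = 10,
                        charge_full_min_percent = 90,
                        platinum_logp_not_assessable = TRUE,
                        prodrug_systemic_cap = c("intermediate", "none"),
                        discrepancy_whitelist = default_whitelist()) {
  prodrug_systemic_cap <- match.arg(prodrug_systemic_cap)
  cfg <- structure(
    list(
      ph = ph,
      logp_lower = logp_lower,
      logp_upper = logp_upper,
      mw_max_da = mw_max_da,
      mw_hard_cap_da = mw_hard_cap_da,
      charge_neutral_max_percent = charge_neutral_max_percent,
      charge_full_min_percent = charge_full_min_percent,
      platinum_logp_not_assessable = isTRUE(platinum_logp_not_assessable),
      prodrug_systemic_cap = prodrug_systemic_cap,
      discrepancy_whitelist = tibble::as_tibble(discrepancy_whitelist)
    ),
    class = "bbbced_rule_config"
  )
  validate_rule_config(cfg)
  cfg
}

#' @rdname rule_config
#' @export
default_whitelist <- function() {
  tibble::tibble(
    name = c("Mitoxantrone", "Cobimetinib"),
    route = c("systemic", "systemic")
  )
}

validate_rule_config <- function(cfg) {
  stopifnot(
    is.numeric(cfg$ph), length(cfg$ph) == 1L,
    is.numeric(cfg$logp_lower), is.numeric(cfg$logp_upper),
    is.numeric(cfg$mw_max_da), is.numeric(cfg$mw_hard_cap_da),
    is.numeric(cfg$charge_neutral_max_percent),
    is.numeric(cfg$charge_full_min_percent)
  )
  if (!(cfg$logp_lower < cfg$logp_upper)) {
    stop("rule_config: logp_lower must be < logp_upper")
  }
  if (!(cfg$charge_neutral_max_percent > 0 &&
        cfg$charge_neutral_max_percent < cfg$charge_full_min_percent &&
        cfg$charge_full_min_percent <= 100)) {
    stop("rule_config: require 0 < charge_neutral_max_percent < charge_full_min_percent <= 100")
  }
  if (!(cfg$mw_max_da < cfg$mw_hard_cap_da)) {
    stop("rule_config: mw_max_da must be < mw_hard_cap_da")
  }
  wl <- cfg$discrepancy_whitelist
  if (!all(c("name", "route") %in% names(wl))) {
    stop("rule_config: discrepancy_whitelist needs columns 'name' and 'route'")
  }
  if (nrow(wl) && !all(wl$route %in% c("systemic", "ced"))) {
    stop("rule_config: whitelist route must be 'systemic' or 'ced'")
  }
  invisible(cfg)
}

#' @export
print.bbbced_rule_config <- function(x, ...) {
  cat("<delivery rule configuration>\n")
  cat(sprintf("  pH: %.2f\n", x$ph))
  cat(sprintf("  log P window: (%g, %g]\n", x$logp_lower, x$logp_upper))
  cat(sprintf("  MW limit: <= %g Da (hard cap at %g Da)\n",
              x$mw_max_da, x$mw_hard_cap_da))
  cat(sprintf("  charge bands: neutral <= %g%%, fully charged >= %g%%\n",
              x$charge_neutral_max_percent, x$charge_full_min_percent))
  cat(sprintf("  platinum log P not assessable: %s\n",
              x$platinum_logp_not_assessable))
  cat(sprintf("  prodrug systemic cap: %s\n", x$prodrug_systemic_cap))
  cat(sprintf("  whitelisted discrepancies: %d\n",
              nrow(x$discrepancy_whitelist)))
  invisible(x)
}

#' Read or write a rule configuration as YAML
#'
#' The file holds the configuration fields under their R names; the
#' discrepancy whitelist is a list of `{name, route}` entries. Fields absent
#' from the file keep their defaults, so a config file may override a single
#' threshold.
#'
#' @param path file path.
#' @return `read_rule_config()` returns a `bbbced_rule_config`;
#'   `write_rule_config()` returns `path` invisibly.
#' @export
read_rule_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  wl <- raw$discrepancy_whitelist
  args <- raw[setdiff(names(raw), "discrepancy_whitelist")]
  known <- setdiff(names(formals(rule_config)), "discrepancy_whitelist")
  unknown <- setdiff(names(args), known)
  if (length(unknown)) {
    stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  }
  if (!is.null(wl)) {
    args$discrepancy_whitelist <- dplyr::bind_rows(lapply(wl, tibble::as_tibble))
    if (nrow(args$discrepancy_whitelist) == 0L) {
      args$discrepancy_whitelist <- tibble::tibble(
        name = character(), route = character()
      )
    }
  }
  do.call(rule_config, args)
}

#' @rdname read_rule_config
#' @param cfg a `bbbced_rule_config`.
#' @export
write_rule_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "bbbced_rule_config"))
  out <- unclass(cfg)
  wl <- out$discrepancy_whitelist
  out$discrepancy_whitelist <- if (nrow(wl) == 0L) list() else
    lapply(seq_len(nrow(wl)), function(i) list(name = wl$name[i], route = wl$route[i]))
  yaml::write_yaml(out, path)
  invisible(path)
}
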