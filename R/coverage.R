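#' Days-of-supply rules for the four index depot antipsychotics
#'
#' Returns the bundled table of coverage periods: the number of treatment days
#' supplied by one dispensed unit of a given drug/strength in a given country.
#' Coverage follows the summary of product characteristics (SmPC) for each
#' product, with one data-driven exception: in the Netherlands most patients on
#' olanzapine pamoate 405 mg refill every 14 days rather than 28, so that
#' strength carries a 14-day coverage period under `country = "NL"` and 28 days
#' under `"BE"`.
#'
#' Olanzapine pamoate 300 mg can be prescribed on either a 2-week or a 4-week
#' scheme and the dispensing record does not say which; its coverage is
#' therefore shipped as `NA` and must be resolved explicitly through
#' `olanzapine_300_days` before any episode involving that strength can be
#' built. No default is applied silently.
#'
#' @param olanzapine_300_days Either `14` or `28`: the pack scheme to assume
#'   for olanzapine pamoate 300 mg. Leave `NULL` to keep it unresolved.
#' @param file Optional path to an alternative rules CSV with columns
#'   `drug,strength_mg,country,coverage_days`.
#' @return A data.frame with columns `drug`, `strength_mg`, `country`,
#'   `coverage_days`.
#' @seealso [grace_scenarios()], [permissible_gap()]
#' @export
#' @examples
#' rules <- coverage_rules(olanzapine_300_days = 28)
#' subset(rules, drug == "olanzapine_pamoate")
coverage_rules <- function(olanzapine_300_days = NULL, file = NULL) {
  path <- if (is.null(file)) {
    system.file("extdata", "coverage_rules.csv", package = "laipersist",
                mustWork = TRUE)
  } else {
    file
  }
  rules <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(olanzapine_300_days)) {
    if (!olanzapine_300_days %in% c(14, 28)) {
      stop("`olanzapine_300_days` must be 14 or 28", call. = FALSE)
    }
    sel <- rules$drug == "olanzapine_pamoate" & rules$strength_mg == 300
    rules$coverage_days[sel] <- olanzapine_300_days
  }
  rules
}

#' Grace-period scenarios
#'
#' The grace period is the slack allowed beyond the days covered by the last
#' purchase before a patient is deemed to have discontinued. Four scenarios are
#' bundled:
#' \describe{
#'   \item{base}{28 days for every drug (pharmacokinetic rationale: plasma
#'     levels of the depot products remain near-therapeutic for roughly four
#'     weeks past the coverage period).}
#'   \item{sensitivity}{60 days for every drug.}
#'   \item{lower}{7 days for the 28-day products (PP1M, haloperidol
#'     decanoate), 3 days for risperidone microspheres; olanzapine pamoate
#'     gets 3 days when dispensed as a 14-day pack and 7 days as a 28-day
#'     pack.}
#'   \item{upper}{390 days for every drug — effectively no interruption can be
#'     declared inside a 13-month follow-up, so only complete stops count.}
#' }
#'
#' @param file Optional path to an alternative CSV with columns
#'   `scenario,drug,pack_days,grace_days` (`pack_days = NA` means the row
#'   applies to any pack length).
#' @return A data.frame with columns `scenario`, `drug`, `pack_days`,
#'   `grace_days`.
#' @export
grace_scenarios <- function(file = NULL) {
  path <- if (is.null(file)) {
    system.file("extdata", "grace_scenarios.csv", package = "laipersist",
                mustWork = TRUE)
  } else {
    file
  }
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' @rdname grace_scenarios
#' @export
grace_scenario_names <- function() c("base", "sensitivity", "lower", "upper")

# Vectorised coverage lookup; errors on missing or unresolved rules.
lookup_coverage <- function(drug, strength_mg, country, rules) {
  key <- paste(drug, strength_mg, country, sep = "|")
  rkey <- paste(rules$drug, rules$strength_mg, rules$country, sep = "|")
  i <- match(key, rkey)
  if (anyNA(i)) {
    stop("no coverage rule for: ",
         paste(unique(key[is.na(i)]), collapse = ", "), call. = FALSE)
  }
  cov <- rules$coverage_days[i]
  if (anyNA(cov)) {
    stop("coverage for olanzapine pamoate 300 mg is ambiguous (14 or 28 ",
         "days); resolve it with coverage_rules(olanzapine_300_days = ...)",
         call. = FALSE)
  }
  cov
}

# Vectorised grace lookup keyed on scenario + drug, with pack-length-specific
# rows taking precedence over pack-agnostic (pack_days = NA) rows.
lookup_grace <- function(drug, pack_days, scenario, grace) {
  g <- grace[grace$scenario == scenario, , drop = FALSE]
  if (!nrow(g)) stop("unknown grace scenario: ", scenario, call. = FALSE)
  i <- match(paste(drug, pack_days), paste(g$drug, g$pack_days))
  if (anyNA(i)) {
    any_rows <- is.na(g$pack_days)
    j <- match(drug[is.na(i)], g$drug[any_rows])
    i[is.na(i)] <- which(any_rows)[j]
  }
  if (anyNA(i)) {
    stop("no grace rule under scenario '", scenario, "' for: ",
         paste(unique(drug[is.na(i)]), collapse = ", "), call. = FALSE)
  }
  g$grace_days[i]
}

#' Permissible gap after a purchase
#'
#' The permissible gap is the longest interval after a purchase within which
#' the next purchase of the index drug must occur for the patient to count as
#' continuously treated:
#'
#' \deqn{gap = coverage\_days \times units + grace\_days}
#'
#' where the coverage period is per dispensed unit of the purchased strength
#' (see [coverage_rules()]) and the grace period comes from the chosen
#' scenario (see [grace_scenarios()]). All arguments are vectorised over
#' purchases.
#'
#' @param drug Drug code(s), e.g. `"pp1m"`.
#' @param strength_mg Strength in mg per unit.
#' @param units Number of units in the purchase.
#' @param country `"NL"` or `"BE"`.
#' @param scenario One of [grace_scenario_names()].
#' @param rules Coverage table from [coverage_rules()].
#' @param grace Grace table from [grace_scenarios()].
#' @return Numeric vector of permissible gaps in days.
#' @export
#' @examples
#' permissible_gap("pp1m", 100, 1, "NL")                  # 28 + 28 = 56
#' permissible_gap("olanzapine_pamoate", 405, 1, "NL")    # 14 + 28 = 42
#' permissible_gap("olanzapine_pamoate", 405, 1, "BE")    # 28 + 28 = 56
permissible_gap <- function(drug, strength_mg, units, country,
                            scenario = "base",
                            rules = coverage_rules(),
                            grace = grace_scenarios()) {
  stopifnot(all(units >= 1), all(strength_mg > 0))
  cov <- lookup_coverage(drug, strength_mg, country, rules)
  g <- lookup_grace(drug, cov, scenario, grace)
  cov * units + g
}
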