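# Model parameterization: loading, validation, provenance, path access.

BRANCH_IDS <- c("initial_consultation", "low", "intermediate",
                "intermediate_after_hosp", "suspected_pe_birth",
                "pe_after_ambulatory")
STRATUM_LABELS <- c("ratio_le_38", "ratio_38_85", "ratio_ge_85")
STRATEGIES <- c("no_test", "test")

#' Derive the size of the suspected-preeclampsia cohort
#'
#' The modelled cohort is the fraction of all births in which preeclampsia is
#' suspected; the product is truncated toward zero so the cohort is a whole
#' number of women.
#'
#' @param births Number of births per year (positive scalar).
#' @param rate Suspicion rate, strictly between 0 and 1.
#' @return Integer cohort size, `trunc(births * rate)`.
#' @examples
#' derive_cohort_size(86919, 0.07)  # 6084
#' @export
derive_cohort_size <- function(births, rate) {
  if (!is.numeric(births) || length(births) != 1L || is.na(births) || births <= 0) {
    stop_invalid("births must be a single positive number, got %s", format(births))
  }
  if (!is.numeric(rate) || length(rate) != 1L || is.na(rate) || rate <= 0 || rate >= 1) {
    stop_invalid("suspicion rate must lie strictly between 0 and 1, got %s", format(rate))
  }
  as.integer(trunc(births * rate))
}

# Fetch a required key from a nested list; `path` is dotted.
req_key <- function(x, path) {
  parts <- strsplit(path, ".", fixed = TRUE)[[1]]
  for (p in parts) {
    if (!is.list(x) || is.null(x[[p]])) {
      stop_config("configuration is missing required key '%s'", path)
    }
    x <- x[[p]]
  }
  x
}

req_num <- function(x, path) {
  v <- req_key(x, path)
  if (!is.numeric(v) || length(v) != 1L || is.na(v)) {
    stop_config("configuration key '%s' must be a single number", path)
  }
  as.numeric(v)
}

branches_to_df <- function(lst, strategy) {
  if (!is.list(lst) || length(lst) == 0L) {
    stop_config("strategies.%s.branches must be a non-empty list", strategy)
  }
  rows <- lapply(lst, function(b) {
    for (k in c("branch_id", "n_patients", "total_cost")) {
      if (is.null(b[[k]])) {
        stop_config("strategies.%s.branches: entry missing '%s'", strategy, k)
      }
    }
    data.frame(branch_id = as.character(b$branch_id),
               label = as.character(if (is.null(b$label)) b$branch_id else b$label),
               n = as.numeric(b$n_patients),
               total_cost = as.numeric(b$total_cost),
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  bad <- setdiff(df$branch_id, BRANCH_IDS)
  if (length(bad)) {
    stop_config("strategies.%s.branches: unknown branch_id '%s'", strategy, bad[1])
  }
  df$per_patient <- ifelse(df$n > 0, df$total_cost / df$n, 0)
  df
}

# Decompose each branch's per-patient cost into outpatient-care,
# hospitalization and birth components. The decomposition is the model's own
# (the source tables print branch totals only); it is constrained so the
# components sum exactly to the per-patient cost. Conventions:
#   * every pathway that ends in a birth carries the blended no-preeclampsia
#     delivery cost as its birth component;
#   * the discharged-after-admission branch carries the mean cost of a
#     suspected-preeclampsia stay without birth as its hospitalization
#     component;
#   * preeclampsia branches book their DRG excess over the blended delivery
#     cost as hospitalization.
decompose_components <- function(branches, blended_birth, hosp_stay_mean) {
  out <- branches
  out$comp_outpatient <- 0
  out$comp_hospitalization <- 0
  out$comp_birth <- 0
  for (i in seq_len(nrow(out))) {
    pp <- out$per_patient[i]
    switch(out$branch_id[i],
      initial_consultation = {
        out$comp_outpatient[i] <- pp
      },
      low = ,
      intermediate = {
        out$comp_birth[i] <- blended_birth
        out$comp_outpatient[i] <- pp - blended_birth
      },
      intermediate_after_hosp = {
        out$comp_birth[i] <- blended_birth
        out$comp_hospitalization[i] <- hosp_stay_mean
        out$comp_outpatient[i] <- pp - blended_birth - hosp_stay_mean
      },
      suspected_pe_birth = ,
      pe_after_ambulatory = {
        out$comp_birth[i] <- blended_birth
        out$comp_hospitalization[i] <- pp - blended_birth
      }
    )
  }
  out
}

#' Path to the shipped base-case configuration
#' @return File path of the base-case YAML document installed with the package.
#' @export
base_case_path <- function() {
  system.file("extdata", "base_case.yaml", package = "preecon", mustWork = TRUE)
}

#' Load a model configuration
#'
#' Reads a YAML configuration document, resolves the service-catalog and
#' inpatient-group CSV files relative to it, derives the cohort size and the
#' per-patient branch costs (total cost divided by branch N, carried at full
#' precision), and decomposes branch costs into outpatient/hospitalization/
#' birth components.
#'
#' @param path Path to a YAML configuration; defaults to the shipped base case.
#' @return An object of class `pe_config`.
#' @export
load_config <- function(path = base_case_path()) {
  if (!file.exists(path)) stop_config("configuration file not found: %s", path)
  raw <- yaml::read_yaml(path)
  dir <- dirname(normalizePath(path))

  births <- req_num(raw, "cohort.births_per_year")
  rate <- req_num(raw, "cohort.suspicion_rate")
  cohort_size <- derive_cohort_size(births, rate)

  strata_raw <- req_key(raw, "strata")
  strata <- do.call(rbind, lapply(strata_raw, function(s) {
    for (k in c("label", "prevalence", "p_hospitalized")) {
      if (is.null(s[[k]])) stop_config("strata: entry missing '%s'", k)
    }
    data.frame(label = as.character(s$label), prevalence = as.numeric(s$prevalence),
               p_hospitalized = as.numeric(s$p_hospitalized), stringsAsFactors = FALSE)
  }))

  resolve_file <- function(key) {
    f <- as.character(req_key(raw, key))
    full <- if (file.exists(f)) f else file.path(dir, f)
    if (!file.exists(full)) stop_config("file referenced by '%s' not found: %s", key, f)
    full
  }
  catalog <- load_service_catalog(resolve_file("costs.outpatient.catalog_file"))
  groups <- load_inpatient_groups(resolve_file("costs.inpatient.groups_file"))

  birth <- list(
    csection_share = req_num(raw, "costs.birth.csection_share"),
    vaginal_cost_no_pe = req_num(raw, "costs.birth.vaginal_cost_no_pe"),
    csection_cost_no_pe = req_num(raw, "costs.birth.csection_cost_no_pe")
  )
  birth$blended_cost_no_pe <- blended_birth_cost(
    birth$csection_share, birth$vaginal_cost_no_pe, birth$csection_cost_no_pe
  )
  hosp_stay_mean <- groups$cost_mean[groups$label == "suspected_no_birth"]
  if (length(hosp_stay_mean) != 1L) {
    stop_config("inpatient groups must contain exactly one 'suspected_no_birth' row")
  }

  strategies <- lapply(setNames(STRATEGIES, STRATEGIES), function(s) {
    df <- branches_to_df(req_key(raw, sprintf("strategies.%s.branches", s)), s)
    decompose_components(df, birth$blended_cost_no_pe, hosp_stay_mean)
  })

  uptake_raw <- req_key(raw, "budget_impact.uptake")
  uptake <- do.call(rbind, lapply(uptake_raw, function(u) {
    data.frame(year = as.integer(req_key(u, "year")),
               n_test = as.numeric(req_key(u, "n_test")))
  }))

  schedules <- lapply(req_key(raw, "costs.outpatient.schedules"), function(s) {
    list(visits = as.numeric(req_key(s, "visits")), weeks = as.numeric(req_key(s, "weeks")))
  })

  provenance <- unlist(req_key(raw, "provenance"))

  cfg <- structure(list(
    source_path = normalizePath(path),
    births_per_year = births,
    suspicion_rate = rate,
    cohort_size = cohort_size,
    exchange_rate = req_num(raw, "currency.eur_per_chf"),
    test_unit_cost = req_num(raw, "costs.test_unit_cost"),
    extra_tests = req_num(raw, "costs.extra_tests"),
    discount_rate = req_num(raw, "budget_impact.discount_rate"),
    strata = strata,
    probability = list(no_test = list(
      p_admit = req_num(raw, "probability.no_test.p_admit"),
      p_pe_given_admit = req_num(raw, "probability.no_test.p_pe_given_admit")
    )),
    strategies = strategies,
    uptake = uptake,
    outpatient = list(
      catalog = catalog,
      catalog_file = basename(resolve_file("costs.outpatient.catalog_file")),
      intermediate_total_override = req_num(raw, "costs.outpatient.intermediate_total_override"),
      schedules = schedules
    ),
    inpatient = list(
      groups = groups,
      groups_file = basename(resolve_file("costs.inpatient.groups_file"))
    ),
    birth = birth,
    sensitivity = list(
      one_way = req_key(raw, "sensitivity.one_way"),
      scenarios = req_key(raw, "sensitivity.scenarios")
    ),
    provenance = provenance
  ), class = "pe_config")
  cfg
}

#' Write a model configuration back to YAML
#'
#' Serializes a `pe_config` so that loading the written document reproduces the
#' configuration field by field. The service-catalog and inpatient-group CSV
#' files are copied next to the written YAML.
#'
#' @param config A `pe_config`.
#' @param path Output YAML path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "pe_config"))
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  strata_list <- lapply(seq_len(nrow(config$strata)), function(i) {
    as.list(config$strata[i, c("label", "prevalence", "p_hospitalized")])
  })
  branch_list <- function(df) {
    lapply(seq_len(nrow(df)), function(i) {
      list(branch_id = df$branch_id[i], label = df$label[i],
           n_patients = df$n[i], total_cost = df$total_cost[i])
    })
  }
  doc <- list(
    cohort = list(births_per_year = config$births_per_year,
                  suspicion_rate = config$suspicion_rate),
    currency = list(eur_per_chf = config$exchange_rate),
    costs = list(
      test_unit_cost = config$test_unit_cost,
      extra_tests = config$extra_tests,
      outpatient = list(
        catalog_file = config$outpatient$catalog_file,
        intermediate_total_override = config$outpatient$intermediate_total_override,
        schedules = config$outpatient$schedules
      ),
      inpatient = list(groups_file = config$inpatient$groups_file),
      birth = config$birth[c("csection_share", "vaginal_cost_no_pe", "csection_cost_no_pe")]
    ),
    strata = strata_list,
    probability = config$probability,
    strategies = lapply(config$strategies, function(df) list(branches = branch_list(df))),
    budget_impact = list(
      discount_rate = config$discount_rate,
      uptake = lapply(seq_len(nrow(config$uptake)), function(i) {
        list(year = config$uptake$year[i], n_test = config$uptake$n_test[i])
      })
    ),
    sensitivity = config$sensitivity,
    provenance = as.list(config$provenance)
  )
  yaml::write_yaml(doc, path, precision = 12L)
  src_dir <- dirname(config$source_path)
  for (f in c(config$outpatient$catalog_file, config$inpatient$groups_file)) {
    src <- file.path(src_dir, f)
    if (file.exists(src)) file.copy(src, file.path(dirname(path), f), overwrite = TRUE)
  }
  invisible(path)
}

#' @export
print.pe_config <- function(x, ...) {
  cat("<pe_config>\n")
  cat(sprintf("  cohort: %d suspected-preeclampsia pregnancies (%.0f births x %.1f%%)\n",
              x$cohort_size, x$births_per_year, 100 * x$suspicion_rate))
  cat(sprintf("  test unit cost: EUR %.2f; discount rate: %.1f%%/year\n",
              x$test_unit_cost, 100 * x$discount_rate))
  cat(sprintf("  strata: %s\n",
              paste(sprintf("%s %.0f%%", x$strata$label, 100 * x$strata$prevalence),
                    collapse = ", ")))
  cat(sprintf("  strategies: %s\n", paste(names(x$strategies), collapse = ", ")))
  invisible(x)
}

# Validation -------------------------------------------------------------------

#' Validate a model configuration
#'
#' Checks every structural invariant of the parameterization and reports all
#' violations instead of raising: suspicion rate in (0,1), stratum prevalences
#' summing to one, probabilities in \[0,1\], non-negative branch costs,
#' component sums matching per-patient costs to the cent, cohort conservation
#' of branch sizes within one woman, and a consistent uptake schedule.
#'
#' @param config A `pe_config`.
#' @return A `pe_validation` object with fields `ok` and `messages`.
#' @export
validate_config <- function(config) {
  msgs <- list()
  add <- function(severity, path, text) {
    msgs[[length(msgs) + 1L]] <<- data.frame(
      severity = severity, path = path, text = text, stringsAsFactors = FALSE)
  }

  if (config$suspicion_rate <= 0 || config$suspicion_rate >= 1) {
    add("error", "cohort.suspicion_rate", "must lie strictly between 0 and 1")
  }
  if (config$cohort_size != derive_cohort_size(config$births_per_year, config$suspicion_rate)) {
    add("error", "cohort.cohort_size", "not equal to trunc(births x suspicion rate)")
  }
  if (nrow(config$strata) != 3L || !setequal(config$strata$label, STRATUM_LABELS)) {
    add("error", "strata", "exactly the three ratio strata are required")
  }
  if (abs(sum(config$strata$prevalence) - 1) > 1e-9) {
    add("error", "strata", sprintf("prevalences sum to %.10f, not 1", sum(config$strata$prevalence)))
  }
  bad_p <- config$strata$p_hospitalized < 0 | config$strata$p_hospitalized > 1
  if (any(bad_p)) {
    add("error", sprintf("strata.%s.p_hospitalized", config$strata$label[bad_p][1]),
        "hospitalization probability outside [0, 1]")
  }
  for (pn in c("p_admit", "p_pe_given_admit")) {
    v <- config$probability$no_test[[pn]]
    if (v < 0 || v > 1) add("error", paste0("probability.no_test.", pn), "outside [0, 1]")
  }
  for (s in names(config$strategies)) {
    df <- config$strategies[[s]]
    if (any(df$per_patient < 0)) {
      add("error", sprintf("strategies.%s.%s", s, df$branch_id[df$per_patient < 0][1]),
          "negative per-patient cost")
    }
    if (any(df$n < 0)) {
      add("error", sprintf("strategies.%s", s), "negative branch size")
    }
    comp_sum <- df$comp_outpatient + df$comp_hospitalization + df$comp_birth
    off <- abs(comp_sum - df$per_patient) > 0.01
    if (any(off)) {
      add("error", sprintf("strategies.%s.%s", s, df$branch_id[off][1]),
          "cost components do not sum to the per-patient cost (0.01 EUR tolerance)")
    }
    alloc <- sum(df$n[df$branch_id != "initial_consultation"])
    if (abs(alloc - config$cohort_size) > 1) {
      add("error", sprintf("strategies.%s", s),
          sprintf("branch sizes sum to %.1f; cohort is %d (tolerance 1)", alloc, config$cohort_size))
    }
  }
  if (config$test_unit_cost < 0) add("error", "costs.test_unit_cost", "negative test cost")
  if (config$discount_rate < 0) add("error", "budget_impact.discount_rate", "negative discount rate")
  up <- config$uptake
  if (!identical(up$year, seq_len(nrow(up)))) {
    add("error", "budget_impact.uptake", "year indices must run 1, 2, ... consecutively")
  }
  if (any(up$n_test < 0 | up$n_test > config$cohort_size)) {
    add("error", "budget_impact.uptake", "n_test outside [0, cohort size]")
  }
  bs <- config$birth
  if (bs$csection_share < 0 || bs$csection_share > 1) {
    add("error", "costs.birth.csection_share", "C-section share outside [0, 1]")
  }
  blend <- (1 - bs$csection_share) * bs$vaginal_cost_no_pe +
    bs$csection_share * bs$csection_cost_no_pe
  if (abs(blend - bs$blended_cost_no_pe) > 0.01) {
    add("error", "costs.birth", "blended birth cost inconsistent with its parts")
  }

  messages <- if (length(msgs)) do.call(rbind, msgs) else
    data.frame(severity = character(), path = character(), text = character(),
               stringsAsFactors = FALSE)
  structure(list(ok = !any(messages$severity == "error"), messages = messages),
            class = "pe_validation")
}

#' @export
print.pe_validation <- function(x, ...) {
  cat(sprintf("<pe_validation> ok: %s\n", x$ok))
  if (nrow(x$messages)) {
    for (i in seq_len(nrow(x$messages))) {
      cat(sprintf("  [%s] %s: %s\n", x$messages$severity[i],
                  x$messages$path[i], x$messages$text[i]))
    }
  } else cat("  no findings\n")
  invisible(x)
}

#' Check provenance coverage of the configuration
#'
#' Every numeric leaf of the configuration document must be covered by an
#' entry of its `provenance` map; a provenance key covers a path if it equals
#' the path or is a prefix of it (at a dot boundary).
#'
#' @param config A `pe_config`.
#' @return List with `covered` (logical), `paths`, and `uncovered`.
#' @export
provenance_coverage <- function(config) {
  leaf_paths <- function(x, prefix = character()) {
    if (is.list(x)) {
      unlist(lapply(names(x), function(nm) {
        leaf_paths(x[[nm]], c(prefix, nm))
      }), use.names = FALSE)
    } else if (is.numeric(x)) {
      paste(prefix, collapse = ".")
    } else character()
  }
  doc <- list(
    cohort = list(births_per_year = config$births_per_year,
                  suspicion_rate = config$suspicion_rate),
    currency = list(eur_per_chf = config$exchange_rate),
    costs = list(test_unit_cost = config$test_unit_cost,
                 extra_tests = config$extra_tests,
                 outpatient = list(
                   intermediate_total_override = config$outpatient$intermediate_total_override,
                   schedules = config$outpatient$schedules),
                 birth = config$birth[c("csection_share", "vaginal_cost_no_pe",
                                        "csection_cost_no_pe")]),
    strata = setNames(
      lapply(seq_len(nrow(config$strata)), function(i)
        as.list(config$strata[i, c("prevalence", "p_hospitalized")])),
      config$strata$label),
    probability = config$probability,
    strategies = lapply(config$strategies, function(df)
      list(branches = setNames(
        lapply(seq_len(nrow(df)), function(i) as.list(df[i, c("n", "total_cost")])),
        df$branch_id))),
    budget_impact = list(discount_rate = config$discount_rate,
                         uptake = setNames(
                           lapply(seq_len(nrow(config$uptake)), function(i)
                             as.list(config$uptake[i, , drop = FALSE])),
                           paste0("year", config$uptake$year)),
                         NULL),
    sensitivity = config$sensitivity
  )
  paths <- unique(leaf_paths(doc))
  keys <- names(config$provenance)
  covered_by_key <- function(p) {
    any(vapply(keys, function(k) {
      p == k || startsWith(p, paste0(k, "."))
    }, logical(1)))
  }
  covered <- vapply(paths, covered_by_key, logical(1))
  list(covered = all(covered), paths = paths, uncovered = paths[!covered])
}

# Dotted-path access -----------------------------------------------------------

# Resolve a scalar parameter path to a getter/setter pair. Component-level
# paths ("costs.hospitalization" etc.) are handled in apply_modifier().
path_accessor <- function(path) {
  parts <- strsplit(path, ".", fixed = TRUE)[[1]]
  if (identical(parts[1], "strata") && length(parts) == 3L &&
      parts[3] %in% c("prevalence", "p_hospitalized")) {
    lab <- parts[2]
    field <- parts[3]
    return(list(
      get = function(cfg) {
        i <- match(lab, cfg$strata$label)
        if (is.na(i)) stop_config("unknown stratum '%s' in path '%s'", lab, path)
        cfg$strata[[field]][i]
      },
      set = function(cfg, v) {
        i <- match(lab, cfg$strata$label)
        if (is.na(i)) stop_config("unknown stratum '%s' in path '%s'", lab, path)
        cfg$strata[[field]][i] <- v
        cfg
      }
    ))
  }
  scalar_map <- list(
    "cohort.births_per_year" = c("births_per_year"),
    "cohort.suspicion_rate" = c("suspicion_rate"),
    "costs.test_unit_cost" = c("test_unit_cost"),
    "costs.extra_tests" = c("extra_tests"),
    "currency.eur_per_chf" = c("exchange_rate"),
    "budget_impact.discount_rate" = c("discount_rate"),
    "probability.no_test.p_admit" = c("probability", "no_test", "p_admit"),
    "probability.no_test.p_pe_given_admit" = c("probability", "no_test", "p_pe_given_admit")
  )
  slot <- scalar_map[[path]]
  if (is.null(slot)) stop_config("cannot resolve parameter path '%s'", path)
  list(
    get = function(cfg) cfg[[slot]],
    set = function(cfg, v) {
      cfg[[slot]] <- v
      cfg
    }
  )
}

#' Read a scalar parameter by dotted path
#' @param config A `pe_config`.
#' @param path Dotted parameter path, e.g. `"costs.test_unit_cost"` or
#'   `"strata.ratio_le_38.p_hospitalized"`.
#' @return The parameter value.
#' @export
config_get <- function(config, path) path_accessor(path)$get(config)

#' Replace a scalar parameter by dotted path
#'
#' Derived quantities (cohort size) are recomputed after the assignment.
#'
#' @inheritParams config_get
#' @param value New value.
#' @return A new `pe_config`; the input is unchanged.
#' @export
config_set <- function(config, path, value) {
  cfg <- path_accessor(path)$set(config, value)
  cfg$cohort_size <- derive_cohort_size(cfg$births_per_year, cfg$suspicion_rate)
  cfg
}
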