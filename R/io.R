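config_keys <- c(
  "parameters", "battery", "scenarios", "sensitivity", "output_dir", "units"
)

#' Load and validate a run configuration
#'
#' Reads a YAML or JSON configuration file and fills every unspecified
#' field with its default. Recognised top-level keys:
#' \describe{
#'   \item{`parameters`}{named overrides of [ltci_params()] fields}
#'   \item{`battery`}{one of `"individual_rate"`, `"reimbursement"`,
#'     `"government_enterprise"`, `"disability_rate"`, `"all"`}
#'   \item{`scenarios`}{custom scenarios, each a map with `name` and
#'     `levers` (lever-value pairs)}
#'   \item{`sensitivity`}{`n`, `seed`, and optional `ranges` (list of
#'     `lever`/`low`/`high` maps)}
#'   \item{`output_dir`}{directory for outputs}
#'   \item{`units`}{`"yuan"` or `"millions"` for CSV output}
#' }
#' Unknown keys are rejected with an error naming the key. Lever values
#' outside the documented policy ranges are accepted with a warning
#' flagging them as extrapolation.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file. An empty file
#'   yields the all-defaults configuration.
#' @return an `ltci_config` list with elements `params` (`ltci_params`),
#'   `battery`, `scenarios` (list of [ltci_scenario()]), `sensitivity`
#'   (`n`, `seed`, `ranges` tibble), `output_dir`, `units`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(raw)) raw <- list()
  if (!is.list(raw)) stop("config must be a mapping at top level", call. = FALSE)
  unknown <- setdiff(names(raw), config_keys)
  if (length(unknown) > 0) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
      call. = FALSE
    )
  }

  par_over <- raw$parameters
  if (!is.null(par_over)) {
    bad <- setdiff(names(par_over), names(formals(ltci_params)))
    if (length(bad) > 0) {
      stop("unknown parameter key(s) in config: ", paste(bad, collapse = ", "),
        call. = FALSE
      )
    }
  }
  params <- do.call(ltci_params, as.list(par_over))
  flag_extrapolation(params)

  battery <- raw$battery %||% "all"
  choices <- c(names(default_batteries()), "all")
  if (!battery %in% choices) {
    stop("config key 'battery' must be one of: ",
      paste(choices, collapse = ", "),
      call. = FALSE
    )
  }

  scenarios <- lapply(raw$scenarios, function(s) {
    if (is.null(s$name)) stop("each custom scenario needs a name", call. = FALSE)
    do.call(ltci_scenario, c(list(name = s$name), as.list(s$levers)))
  })

  sens <- raw$sensitivity %||% list()
  # YAML 1.1 parses a bare `n:` key as the boolean FALSE; map it back
  names(sens)[names(sens) == "FALSE"] <- "n"
  sens_ranges <- if (is.null(sens$ranges)) {
    sensitivity_ranges()
  } else {
    tibble::tibble(
      lever = vapply(sens$ranges, `[[`, character(1), "lever"),
      low = vapply(sens$ranges, `[[`, numeric(1), "low"),
      high = vapply(sens$ranges, `[[`, numeric(1), "high")
    )
  }

  units <- raw$units %||% "yuan"
  if (!units %in% c("yuan", "millions")) {
    stop("config key 'units' must be 'yuan' or 'millions'", call. = FALSE)
  }

  structure(
    list(
      params = params,
      battery = battery,
      scenarios = scenarios,
      sensitivity = list(
        n = as.integer(sens$n %||% 200L),
        seed = as.integer(sens$seed %||% 2019L),
        ranges = sens_ranges
      ),
      output_dir = raw$output_dir %||% ".",
      units = units
    ),
    class = "ltci_config"
  )
}

# warn (once per lever) when a configured lever leaves its documented
# policy range
flag_extrapolation <- function(params) {
  rg <- lever_ranges()
  val <- list(
    r_ind = params$r_ind, reimb = params$reimb,
    r_gov_r_ent = params$r_gov, d_sev = params$d_sev
  )
  for (lever in names(rg)) {
    v <- val[[lever]]
    if (v < rg[[lever]][1] || v > rg[[lever]][2]) {
      warning("lever '", lever, "' = ", format(v),
        " lies outside the documented policy range [",
        rg[[lever]][1], ", ", rg[[lever]][2], "]; treating as extrapolation",
        call. = FALSE
      )
    }
  }
  invisible(params)
}

#' Write a configuration back to YAML
#'
#' Serialises an `ltci_config` so that [load_config()] on the written
#' file reproduces it exactly.
#'
#' @param config an `ltci_config` from [load_config()].
#' @param path output path (`.yaml`).
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "ltci_config"))
  raw <- list(
    parameters = unclass(config$params),
    battery = config$battery,
    scenarios = lapply(config$scenarios, function(s) {
      list(name = s$name, levers = s$overrides)
    }),
    sensitivity = list(
      n = config$sensitivity$n,
      seed = config$sensitivity$seed,
      ranges = lapply(seq_len(nrow(config$sensitivity$ranges)), function(i) {
        as.list(config$sensitivity$ranges[i, ])
      })
    ),
    output_dir = config$output_dir,
    units = config$units
  )
  yaml::write_yaml(raw, path, precision = 15)
  invisible(path)
}

#' Export scenario trajectories as tidy CSV
#'
#' One row per scenario and year, columns `scenario`, `year`,
#' `rev_individual`, `rev_enterprise`, `rev_government`, `rev_total`,
#' `expenditure`, `balance_annual`, `balance_cumulative`. Values are
#' written at full double precision in the requested units.
#'
#' @param results a single trajectory ([ltci_simulate()]), a single
#'   result, or a list of `ltci_result` objects from [run_battery()].
#' @param path output CSV path.
#' @param units `"yuan"` or `"millions"`.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(results, path, units = c("yuan", "millions")) {
  units <- match.arg(units)
  tidy <- tidy_results(results)
  if (nrow(tidy) == 0) stop("no results to write", call. = FALSE)
  tidy <- as.data.frame(trajectory_in_units(tidy, units))
  num <- vapply(tidy, is.double, logical(1))
  tidy[num] <- lapply(tidy[num], function(v) {
    format(v, digits = 17, trim = TRUE, scientific = FALSE)
  })
  utils::write.csv(tidy, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read back a trajectory CSV written by [write_trajectory_csv()]
#'
#' @param path CSV path.
#' @return a tibble in the same tidy layout.
#' @export
read_trajectory_csv <- function(path) {
  tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}

# normalise trajectory / result / list-of-results to one tidy tibble
tidy_results <- function(results) {
  one <- function(r, fallback) {
    if (inherits(r, "ltci_result")) {
      tr <- r$trajectory
      nm <- r$name
    } else {
      tr <- r
      nm <- fallback
    }
    out <- tibble::as_tibble(tr)
    tibble::add_column(out, scenario = nm, .before = 1)
  }
  if (inherits(results, "ltci_trajectory") || inherits(results, "ltci_result")) {
    return(one(results, "baseline"))
  }
  if (!is.list(results) || length(results) == 0) {
    stop("results must be a trajectory or a non-empty list of results",
      call. = FALSE
    )
  }
  nms <- names(results) %||% sprintf("scenario_%d", seq_along(results))
  parts <- Map(one, results, nms)
  do.call(rbind, parts)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
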