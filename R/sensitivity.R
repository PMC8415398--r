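#' Default sensitivity ranges for the policy levers
#'
#' One row per lever with its uniform sampling range; defaults equal the
#' ranges explored by the policy batteries: `r_ind` 0.06-0.1% of
#' disposable income, `reimb` 50-90%, joint `r_gov_r_ent` 0.04-0.07% of
#' GDP, `d_sev` 0.3-0.5%.
#'
#' @return a tibble with columns `lever`, `low`, `high`.
#' @export
sensitivity_ranges <- function() {
  rg <- lever_ranges()
  tibble::tibble(
    lever = names(rg),
    low = unname(vapply(rg, `[`, numeric(1), 1)),
    high = unname(vapply(rg, `[`, numeric(1), 2))
  )
}

#' Draw uniform parameter samples over the lever ranges
#'
#' Each lever is drawn independently from a uniform distribution on its
#' `[low, high]` range; all other parameters are taken from `base`.
#' Reproducible for a fixed seed.
#'
#' @param ranges a data frame as from [sensitivity_ranges()].
#' @param n number of draws (>= 0).
#' @param seed RNG seed (the sampler leaves the session RNG untouched).
#' @param base an [ltci_params()] object supplying the non-lever fields.
#' @return a list of `n` `ltci_params` objects; attribute `seed` records
#'   the seed used.
#' @examples
#' length(sample_parameters(n = 5, seed = 2019))
#' @export
sample_parameters <- function(ranges = sensitivity_ranges(), n = 200,
                              seed = 2019, base = ltci_params()) {
  stopifnot(
    is.numeric(n), n >= 0, n == round(n),
    all(c("lever", "low", "high") %in% names(ranges))
  )
  if (any(ranges$low > ranges$high)) {
    stop("each range must satisfy low <= high", call. = FALSE)
  }
  known <- c("r_ind", "reimb", "r_gov_r_ent", "d_sev")
  bad <- setdiff(ranges$lever, known)
  if (length(bad) > 0) {
    stop("unknown lever(s) in ranges: ", paste(bad, collapse = ", "),
      call. = FALSE
    )
  }
  draws <- withr::with_seed(seed, {
    m <- matrix(NA_real_, nrow = n, ncol = nrow(ranges))
    for (j in seq_len(nrow(ranges))) {
      m[, j] <- stats::runif(n, ranges$low[j], ranges$high[j])
    }
    m
  })
  samples <- lapply(seq_len(n), function(i) {
    args <- list(name = sprintf("draw_%04d", i))
    for (j in seq_len(nrow(ranges))) args[[ranges$lever[j]]] <- draws[i, j]
    apply_scenario(base, do.call(ltci_scenario, args))
  })
  attr(samples, "seed") <- seed
  samples
}

#' Run a sampled parameter ensemble and summarise the balance envelope
#'
#' Simulates every sampled parameter set and aggregates per-year
#' statistics of the annual fund balance: minimum, 5th percentile,
#' median, 95th percentile, maximum (type-7 quantiles).
#'
#' @param samples a non-empty list of `ltci_params` objects, e.g. from
#'   [sample_parameters()].
#' @return an `ltci_envelope`: a tibble with columns `year`, `min`, `p05`,
#'   `median`, `p95`, `max` (yuan/year), with attributes `n_draws` and
#'   `seed` (the latter `NA` if the samples carry none).
#' @examples
#' env <- run_ensemble(sample_parameters(n = 25, seed = 2019))
#' env[env$year == 2030, ]
#' @export
run_ensemble <- function(samples) {
  if (length(samples) == 0) stop("samples must be non-empty", call. = FALSE)
  trajs <- lapply(samples, ltci_simulate)
  years <- trajs[[1]]$year
  bal <- vapply(trajs, `[[`, numeric(length(years)), "balance_annual")
  bal <- matrix(bal, nrow = length(years))
  qs <- apply(bal, 1, stats::quantile, probs = c(0, 0.05, 0.5, 0.95, 1))
  env <- tibble::tibble(
    year = years,
    min = qs[1, ], p05 = qs[2, ], median = qs[3, ],
    p95 = qs[4, ], max = qs[5, ]
  )
  class(env) <- c("ltci_envelope", class(env))
  attr(env, "n_draws") <- length(samples)
  seed <- attr(samples, "seed")
  attr(env, "seed") <- if (is.null(seed)) NA_integer_ else seed
  env
}

#' Fan plot of a sensitivity envelope
#'
#' Draws the per-year min/max band, the 5-95% band, and the median of the
#' annual balance (millions of yuan). Requires ggplot2.
#'
#' @param env an envelope from [run_ensemble()].
#' @return a ggplot object.
#' @export
plot_envelope <- function(env) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_envelope() requires the ggplot2 package", call. = FALSE)
  }
  d <- as.data.frame(env)
  for (col in c("min", "p05", "median", "p95", "max")) d[[col]] <- d[[col]] / 1e6
  ggplot2::ggplot(d, ggplot2::aes(x = year)) +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = min, ymax = max),
      fill = "grey85"
    ) +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = p05, ymax = p95),
      fill = "grey65"
    ) +
    ggplot2::geom_line(ggplot2::aes(y = median), linewidth = 0.8) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed") +
    ggplot2::labs(
      x = "Year", y = "Annual fund balance (million yuan)",
      title = sprintf(
        "Balance envelope, %d uniform draws", attr(env, "n_draws")
      )
    ) +
    ggplot2::theme_minimal()
}
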