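#' Growth-simulation configuration
#'
#' Defines the statistical population of per-plant growth trajectories the
#' synthetic experiment draws from. Projected area (PA) follows a logistic
#' law `K / (1 + exp(-r (t - t0)))` in decimal DAS `t`, evaluated on the
#' daylight measurement grid only, with multiplicative measurement noise.
#' Plant-to-plant variation enters through per-plant draws of the plateau
#' `K`, growth rate `r` and midpoint `t0`. A degenerate `"linear"` law
#' (constant absolute growth rate) is available for exact-recovery tests.
#'
#' Area is expressed in arbitrary "area units" throughout; the default
#' plateau of 10 units stands for a mature rosette.
#'
#' @param n_plants Number of plants.
#' @param grid A [time_grid()].
#' @param K,r,t0 Lists `list(mean=, sd=)`: plateau (area units), logistic
#'   rate (per day) and midpoint (DAS). `sd = 0` gives identical plants.
#' @param noise_sd Multiplicative measurement-noise fraction (0 disables).
#' @param compactness_range Range of the per-plant true compactness
#'   (PA / convex hull area) used to derive hull area.
#' @param law `"logistic"` or `"linear"`.
#' @param experiment Integer experiment label stored in the records.
#' @param seed Integer seed; identical seeds give bit-identical output.
#' @return An object of class `growth_sim_config`.
#' @export
growth_sim_config <- function(n_plants = 110L, grid = time_grid(),
                              K = list(mean = 10, sd = 1.5),
                              r = list(mean = 1.1, sd = 0.12),
                              t0 = list(mean = 17, sd = 0.8),
                              noise_sd = 0.04,
                              compactness_range = c(0.6, 1.0),
                              law = c("logistic", "linear"),
                              experiment = 1L, seed = 1L) {
  law <- match.arg(law)
  stopifnot(n_plants >= 1, noise_sd >= 0,
            length(compactness_range) == 2,
            compactness_range[1] > 0, compactness_range[2] <= 1,
            is.list(K), is.list(r), is.list(t0))
  structure(list(n_plants = as.integer(n_plants), grid = grid, K = K, r = r,
                 t0 = t0, noise_sd = noise_sd,
                 compactness_range = compactness_range, law = law,
                 experiment = as.integer(experiment),
                 seed = as.integer(seed)),
            class = "growth_sim_config")
}

draw_param <- function(n, spec) {
  sd <- spec$sd %||% 0
  if (sd == 0) rep(spec$mean, n) else rnorm(n, spec$mean, sd)
}

#' Simulate per-plant growth trajectories
#'
#' Emits one feature record per plant per grid step: projected area under the
#' configured growth law times `(1 + eps)` with `eps ~ N(0, noise_sd)`, hull
#' area derived from the per-plant true compactness, and a perimeter scaled
#' as the boundary of an equivalent disc inflated by the non-compactness of
#' the rosette. Negative noisy areas are clipped to zero (with a message).
#' Noiseless trajectories are monotone nondecreasing and bounded by `K`.
#'
#' @param config A [growth_sim_config()].
#' @return A data frame with columns `plant_id, experiment, time_step, das,
#'   pa, hull_area, perimeter, compactness`, and attributes `params` (the
#'   per-plant truth: K, r, t0, compactness) and `true_pa` (noiseless PA
#'   matrix, steps x plants).
#' @export
simulate_growth_curves <- function(config) {
  stopifnot(inherits(config, "growth_sim_config"))
  grid <- config$grid
  steps <- seq_len(grid$total_steps)
  das <- step_to_das(steps, grid)
  with_rng(config$seed, {
    n <- config$n_plants
    K <- pmax(draw_param(n, config$K), 1e-6)
    r <- pmax(draw_param(n, config$r), 1e-3)
    t0 <- draw_param(n, config$t0)
    comp <- runif(n, config$compactness_range[1], config$compactness_range[2])
    true_pa <- matrix(0, length(steps), n)
    for (p in seq_len(n)) {
      true_pa[, p] <- switch(config$law,
        logistic = K[p] / (1 + exp(-r[p] * (das - t0[p]))),
        # constant per-step increment, reaching K at the last step
        linear = K[p] * steps / grid$total_steps
      )
    }
    eps <- if (config$noise_sd > 0) {
      matrix(rnorm(length(true_pa), 0, config$noise_sd), nrow(true_pa))
    } else {
      matrix(0, nrow(true_pa), ncol(true_pa))
    }
    pa <- true_pa * (1 + eps)
    n_clip <- sum(pa < 0)
    if (n_clip > 0) {
      message("clipped ", n_clip, " negative noisy PA values to 0")
      pa[pa < 0] <- 0
    }
    records <- data.frame(
      plant_id = rep(seq_len(n), each = length(steps)),
      experiment = config$experiment,
      time_step = rep(steps, n),
      das = rep(das, n),
      pa = as.vector(pa),
      hull_area = as.vector(pa) / rep(comp, each = length(steps)),
      perimeter = 2 * sqrt(pi * as.vector(pa)) /
        sqrt(rep(comp, each = length(steps))),
      compactness = rep(comp, each = length(steps))
    )
    attr(records, "params") <- data.frame(plant_id = seq_len(n), K = K, r = r,
                                          t0 = t0, compactness = comp)
    attr(records, "true_pa") <- true_pa
    attr(records, "grid") <- grid
    records
  })
}

#' Allometry parameters for fresh-weight simulation
#'
#' Linear allometry `FW = slope * PA + intercept + N(0, noise_sd)` by
#' default; setting `exponent` switches to the power-law form
#' `FW = slope * PA^exponent + intercept + noise`.
#'
#' @param slope FW units per area unit.
#' @param intercept FW units.
#' @param noise_sd FW units.
#' @param exponent Optional power-law exponent (NULL = linear).
#' @return An object of class `allometry_params`.
#' @export
allometry_params <- function(slope = 0.8, intercept = 0.5, noise_sd = 0.25,
                             exponent = NULL) {
  stopifnot(slope > 0, noise_sd >= 0)
  structure(list(slope = slope, intercept = intercept, noise_sd = noise_sd,
                 exponent = exponent),
            class = "allometry_params")
}

#' Simulate destructive fresh-weight harvests
#'
#' Randomly selects `n_per_harvest` not-yet-harvested plants at each harvest
#' day, computes fresh weight from the plant's *true* (noiseless) projected
#' area at the last daylight step of that day via the allometry, and removes
#' all later records of harvested plants (destructive sampling).
#'
#' @param records Output of [simulate_growth_curves()] (or a previous call's
#'   `$records`, to chain successive harvests).
#' @param harvest_das Integer days at which harvests occur (default 14, 17,
#'   20 DAS, the early pre-flowering schedule).
#' @param n_per_harvest Plants taken per harvest day.
#' @param params An [allometry_params()].
#' @param seed Integer seed.
#' @return List with `fw` (data frame `plant_id, das, time_step, fw, pa`
#'   where `pa` is the true area at harvest) and `records` (input records
#'   truncated at each harvested plant's harvest step).
#' @export
simulate_fresh_weight <- function(records, harvest_das = c(14L, 17L, 20L),
                                  n_per_harvest = 30L,
                                  params = allometry_params(), seed = 1L) {
  stopifnot(inherits(params, "allometry_params"))
  params_tab <- attr(records, "params")
  true_pa <- attr(records, "true_pa")
  grid <- attr(records, "grid") %||% time_grid()
  if (is.null(params_tab) || is.null(true_pa)) {
    stop("records must carry generator truth attributes")
  }
  harvested_before <- attr(records, "harvested") %||% integer(0)
  with_rng(seed, {
    fw_rows <- list()
    harvested <- harvested_before
    for (h in harvest_das) {
      day_steps <- which(floor(step_to_das(seq_len(grid$total_steps), grid)) == h)
      if (!length(day_steps)) stop("harvest day ", h, " not on the grid")
      step <- max(day_steps)
      if (!any(records$time_step == step)) {
        stop("harvest step ", step, " absent from records")
      }
      avail <- setdiff(unique(records$plant_id), harvested)
      if (length(avail) < n_per_harvest) {
        stop("not enough unharvested plants at ", h, " DAS")
      }
      take <- sort(sample(avail, n_per_harvest))
      pa_true <- true_pa[step, take]
      mu <- if (is.null(params$exponent)) {
        params$slope * pa_true + params$intercept
      } else {
        params$slope * pa_true^params$exponent + params$intercept
      }
      fw <- mu + if (params$noise_sd > 0) {
        rnorm(length(mu), 0, params$noise_sd)
      } else 0
      fw_rows[[length(fw_rows) + 1L]] <- data.frame(
        plant_id = take, das = step_to_das(step, grid), time_step = step,
        fw = pmax(fw, 0), pa = pa_true
      )
      harvested <- c(harvested, take)
      keep <- !(records$plant_id %in% take & records$time_step > step)
      records <- records[keep, , drop = FALSE]
    }
    out_records <- records
    attr(out_records, "params") <- params_tab
    attr(out_records, "true_pa") <- true_pa
    attr(out_records, "grid") <- grid
    attr(out_records, "harvested") <- harvested
    list(fw = do.call(rbind, fw_rows), records = out_records)
  })
}
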