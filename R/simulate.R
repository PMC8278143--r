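#' Simulation configuration
#'
#' Parameters of the agent-based lifecycle simulator. Defaults emulate a
#' CHO-K1-like population imaged every 5 minutes for 48 hours: about 50
#' founder cells in a 1388 x 1040 px field, cell-cycle durations drawn
#' uniformly from 12-16 h, an initial handling-stress arrest of about 5.7 h
#' during which no transitions occur, a small exponential death hazard and a
#' small permanently non-dividing fraction. \code{irradiatedConfig()}
#' returns a preset expressing radiation effects purely through the
#' configuration: slightly longer arrest, slower cycling, a larger
#' non-dividing fraction, a per-division failure probability and a higher
#' death hazard. No dose-response law is assumed.
#'
#' @param n_initial number of founder cells.
#' @param field_size image (width, height) in pixels.
#' @param frame_interval_min minutes between frames.
#' @param duration_h length of the simulated video in hours.
#' @param cycle_h length-2 range (hours) of the uniform cell-cycle draw;
#'   the cycle includes the round and div dwells.
#' @param arrest_h growth-arrest offset: before this time all agents hold
#'   their state (constant cell numbers).
#' @param death_hazard_per_h per-cell exponential death rate (1/h); death
#'   can occur from any vital state and is absorbing.
#' @param frac_nondividing probability, assigned at birth, that a cell
#'   permanently stops cycling.
#' @param division_prob probability that a cell reaching the end of its
#'   div dwell actually divides; otherwise it re-attaches and stops cycling.
#' @param round_duration_min,div_duration_min dwell times (minutes) in the
#'   transient round and div states preceding division.
#' @param box_size_stats per-class box-size distributions: a named list of
#'   \code{c(mean_w, mean_h, sd)} in pixels.
#' @param motility_px_per_frame standard deviation of the per-frame
#'   random-walk step of each box centre (dead boxes stop moving).
#' @param seed integer RNG seed.
#' @param sample_id,dose_gy,irradiated sample metadata recorded on the
#'   output video.
#' @return A validated list of class \code{"SimConfig"}.
#' @seealso [simulatePopulation()]
#' @export
simConfig <- function(n_initial = 50,
                      field_size = c(1388, 1040),
                      frame_interval_min = 5,
                      duration_h = 48,
                      cycle_h = c(12, 16),
                      arrest_h = 5.7,
                      death_hazard_per_h = 0.002,
                      frac_nondividing = 0.08,
                      division_prob = 1,
                      round_duration_min = 30,
                      div_duration_min = 15,
                      box_size_stats = list(liv = c(46, 38, 7),
                                            round = c(30, 30, 4),
                                            div = c(52, 32, 6),
                                            dead = c(28, 28, 4)),
                      motility_px_per_frame = 2,
                      seed = 1L,
                      sample_id = "sim",
                      dose_gy = 0,
                      irradiated = FALSE) {
  cfg <- list(n_initial = n_initial, field_size = field_size,
              frame_interval_min = frame_interval_min,
              duration_h = duration_h, cycle_h = cycle_h,
              arrest_h = arrest_h,
              death_hazard_per_h = death_hazard_per_h,
              frac_nondividing = frac_nondividing,
              division_prob = division_prob,
              round_duration_min = round_duration_min,
              div_duration_min = div_duration_min,
              box_size_stats = box_size_stats,
              motility_px_per_frame = motility_px_per_frame,
              seed = as.integer(seed), sample_id = sample_id,
              dose_gy = dose_gy, irradiated = irradiated)
  .validate_sim_config(cfg)
  class(cfg) <- c("SimConfig", "list")
  cfg
}

#' @rdname simConfig
#' @param ... overrides passed on to [simConfig()].
#' @export
irradiatedConfig <- function(dose_gy = 4, ...) {
  args <- list(arrest_h = 5.8, cycle_h = c(13, 17.5),
               death_hazard_per_h = 0.0025, frac_nondividing = 0.15,
               division_prob = 0.9, dose_gy = dose_gy, irradiated = TRUE,
               sample_id = "sim_irr")
  override <- list(...)
  args[names(override)] <- override
  do.call(simConfig, args)
}

.validate_sim_config <- function(cfg) {
  stopifnot(cfg$n_initial >= 1, length(cfg$field_size) == 2,
            all(cfg$field_size > 0), cfg$frame_interval_min > 0,
            cfg$duration_h > 0, length(cfg$cycle_h) == 2)
  if (any(cfg$cycle_h <= 0) || cfg$cycle_h[2] < cfg$cycle_h[1])
    stop("cycle_h must be a positive, non-decreasing range")
  if (cfg$arrest_h < 0 || cfg$death_hazard_per_h < 0)
    stop("rates and offsets must be non-negative")
  if (cfg$frac_nondividing < 0 || cfg$frac_nondividing > 1 ||
      cfg$division_prob < 0 || cfg$division_prob > 1)
    stop("probabilities must lie in [0, 1]")
  dwell_h <- (cfg$round_duration_min + cfg$div_duration_min) / 60
  if (dwell_h >= cfg$cycle_h[1])
    stop("round + div dwell must be shorter than the minimum cycle time")
  if (prod(cfg$field_size) < cfg$n_initial)
    stop("field too small to place ", cfg$n_initial, " distinct cells")
  invisible(cfg)
}

.draw_size <- function(stats, n) {
  w <- pmax(6, stats[1] + stats[3] * stats::rnorm(n))
  h <- pmax(6, stats[2] + stats[3] * stats::rnorm(n))
  cbind(w, h)
}

#' Simulate a cell population's lifecycle
#'
#' Agent-based forward simulation of the four-class lifecycle. Each vital
#' agent follows the transition cycle liv -> round -> div -> two liv
#' daughters; death to the absorbing dead state can occur from any vital
#' state, and dead boxes persist (motionless) for the rest of the video.
#' Before \code{arrest_h} all agents hold their state, producing the initial
#' phase of constant cell numbers. Founders start asynchronously (uniform
#' position within their first cycle), so divisions spread out after the
#' arrest ends.
#'
#' Per frame, every agent emits one labelled box whose class is its state;
#' boxes may overlap (cells crowd) and are kept inside the field. Each
#' division replaces one agent by two daughters, incrementing the total
#' count by exactly one. The returned lineage is complete: one record per
#' agent with parent link, generation, birth, death and division times, all
#' in minutes.
#'
#' @param config a [simConfig()] list.
#' @return A list with elements \code{video} (a ground-truth
#'   [CellVideo-class], confidence 1, \code{object_id} = agent id) and
#'   \code{lineage} (data.frame with columns \code{cell_id, parent_id,
#'   generation, birth_min, death_min, division_min}).
#' @examples
#' sim <- simulatePopulation(simConfig(n_initial = 10, duration_h = 12,
#'                                     seed = 7))
#' sim$video
#' head(sim$lineage)
#' @export
simulatePopulation <- function(config) {
  .validate_sim_config(config)
  set.seed(config$seed)
  dt <- config$frame_interval_min
  n_frames <- floor(config$duration_h * 60 / dt)
  arrest_min <- config$arrest_h * 60
  fw <- config$field_size[1]; fh <- config$field_size[2]
  hazard_p <- 1 - exp(-config$death_hazard_per_h * dt / 60)

  n0 <- config$n_initial
  # agent state (parallel vectors, grown as daughters appear)
  id <- seq_len(n0)
  parent <- rep(NA_integer_, n0)
  generation <- rep(0L, n0)
  state <- rep("liv", n0)
  present <- rep(TRUE, n0)        # FALSE once replaced by daughters
  cycle_min <- stats::runif(n0, config$cycle_h[1], config$cycle_h[2]) * 60
  liv_dur <- function(cyc) cyc - config$round_duration_min -
    config$div_duration_min
  clock <- stats::runif(n0) * liv_dur(cycle_min)
  timer <- rep(0, n0)
  nondiv <- stats::runif(n0) < config$frac_nondividing
  sz <- .draw_size(config$box_size_stats$liv, n0)
  w <- sz[, 1]; h <- sz[, 2]
  # distinct positions with the whole box inside the field
  x <- stats::runif(n0, w / 2, fw - w / 2)
  y <- stats::runif(n0, h / 2, fh - h / 2)
  while (anyDuplicated(cbind(x, y))) {
    dup <- duplicated(cbind(x, y))
    x[dup] <- stats::runif(sum(dup), w[dup] / 2, fw - w[dup] / 2)
  }
  birth_min <- rep(0, n0)
  death_min <- rep(NA_real_, n0)
  division_min <- rep(NA_real_, n0)
  next_id <- n0 + 1L

  frames <- vector("list", n_frames)
  for (k in seq_len(n_frames)) {
    t_new <- k * dt
    if (t_new > arrest_min) {
      vital <- present & state != "dead"
      # deaths from any vital state
      if (hazard_p > 0 && any(vital)) {
        dies <- vital & stats::runif(length(state)) < hazard_p
        if (any(dies)) {
          state[dies] <- "dead"
          death_min[dies] <- t_new
          ds <- .draw_size(config$box_size_stats$dead, sum(dies))
          w[dies] <- ds[, 1]; h[dies] <- ds[, 2]
        }
      }
      # div -> division (processed first so each state lasts >= 1 frame)
      in_div <- present & state == "div"
      timer[in_div] <- timer[in_div] - dt
      done <- which(in_div & timer <= 0)
      for (i in done) {
        present[i] <- FALSE
        division_min[i] <- t_new
        for (d in 1:2) {
          ds <- .draw_size(config$box_size_stats$liv, 1)
          off <- (if (d == 1) -1 else 1) * w[i] / 2
          nx <- min(max(x[i] + off, ds[1] / 2), fw - ds[1] / 2)
          ny <- min(max(y[i], ds[2] / 2), fh - ds[2] / 2)
          id <- c(id, next_id); parent <- c(parent, id[i])
          generation <- c(generation, generation[i] + 1L)
          state <- c(state, "liv"); present <- c(present, TRUE)
          cyc <- stats::runif(1, config$cycle_h[1], config$cycle_h[2]) * 60
          cycle_min <- c(cycle_min, cyc)
          clock <- c(clock, 0); timer <- c(timer, 0)
          nondiv <- c(nondiv,
                      stats::runif(1) < config$frac_nondividing)
          w <- c(w, ds[1]); h <- c(h, ds[2])
          x <- c(x, nx); y <- c(y, ny)
          birth_min <- c(birth_min, t_new)
          death_min <- c(death_min, NA_real_)
          division_min <- c(division_min, NA_real_)
          next_id <- next_id + 1L
        }
      }
      # round -> div
      in_round <- present & state == "round"
      timer[in_round] <- timer[in_round] - dt
      to_div <- in_round & timer <= 0
      if (any(to_div)) {
        state[to_div] <- "div"
        timer[to_div] <- config$div_duration_min
        ds <- .draw_size(config$box_size_stats$div, sum(to_div))
        w[to_div] <- ds[, 1]; h[to_div] <- ds[, 2]
      }
      # liv clock -> round; a cell reaching the end of its cycle commits to
      # division with division_prob, otherwise it permanently stops cycling
      in_liv <- present & state == "liv" & !nondiv
      clock[in_liv] <- clock[in_liv] + dt
      ripe <- which(in_liv & clock >= liv_dur(cycle_min))
      if (length(ripe)) {
        commit <- stats::runif(length(ripe)) < config$division_prob
        nondiv[ripe[!commit]] <- TRUE
        to_round <- ripe[commit]
        if (length(to_round)) {
          state[to_round] <- "round"
          timer[to_round] <- config$round_duration_min
          rs <- .draw_size(config$box_size_stats$round, length(to_round))
          w[to_round] <- rs[, 1]; h[to_round] <- rs[, 2]
        }
      }
    }
    # motility (dead boxes stop moving)
    moving <- present & state != "dead"
    if (config$motility_px_per_frame > 0 && any(moving)) {
      nm <- sum(moving)
      x[moving] <- x[moving] +
        stats::rnorm(nm, 0, config$motility_px_per_frame)
      y[moving] <- y[moving] +
        stats::rnorm(nm, 0, config$motility_px_per_frame)
      x[moving] <- pmin(pmax(x[moving], w[moving] / 2), fw - w[moving] / 2)
      y[moving] <- pmin(pmax(y[moving], h[moving] / 2), fh - h[moving] / 2)
    }
    emit <- which(present)
    frames[[k]] <- data.frame(
      frame = k,
      x_min = x[emit] - w[emit] / 2, y_min = y[emit] - h[emit] / 2,
      x_max = x[emit] + w[emit] / 2, y_max = y[emit] + h[emit] / 2,
      class = state[emit], confidence = 1,
      object_id = as.character(id[emit]), stringsAsFactors = FALSE)
  }
  objects <- do.call(rbind, frames)
  video <- cellVideo(objects, frameIndices = seq_len(n_frames),
                     frameInterval = dt, imageSize = config$field_size,
                     sampleMeta = list(sample_id = config$sample_id,
                                       dose_gy = config$dose_gy,
                                       irradiated = config$irradiated))
  lineage <- data.frame(cell_id = as.character(id),
                        parent_id = as.character(parent),
                        generation = generation,
                        birth_min = birth_min, death_min = death_min,
                        division_min = division_min,
                        stringsAsFactors = FALSE)
  list(video = video, lineage = lineage)
}
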