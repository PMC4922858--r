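#' Simulate ground-truth molecule histories
#'
#' Runs one Gillespie (continuous-time Markov) trajectory per molecule over
#' \eqn{[0, t_{max}]} and converts the state path into per-channel binding
#' intervals via the scheme's emission map.  Each molecule uses its own RNG
#' stream derived from the master seed, so results are reproducible and
#' stable under changes of \code{n_molecules}.
#'
#' @param scheme a [kinetic_scheme()].
#' @param n_molecules number of molecules (>= 1).
#' @param config an [acquisition_config()] (provides \code{t_max}).
#' @param seed master integer seed.
#' @return data frame of class \code{"molecule_truth"} with columns
#'   \code{molecule_id}, \code{channel}, \code{t_bind_s}, \code{t_release_s},
#'   \code{censored} (1 if the spot persists at \code{t_max}).  Molecules
#'   with no visible intervals do not appear; the attribute
#'   \code{n_molecules} records the full count.
#' @examples
#' tr <- simulate_molecules(scheme_preset("2mM"), 20, acquisition_config(),
#'                          seed = 1)
#' head(tr)
#' @export
simulate_molecules <- function(scheme, n_molecules, config = acquisition_config(),
                               seed = 1) {
  stopifnot(inherits(scheme, "kinetic_scheme"), n_molecules >= 1)
  t_max <- config$t_max
  # per-state outgoing transitions
  out <- split(scheme$transitions[c("to", "rate")], scheme$transitions$from)
  res <- vector("list", n_molecules)
  for (i in seq_len(n_molecules)) {
    set.seed(.derive_seed(seed, i))
    path_state <- character(64); path_t <- numeric(64); np <- 0L
    st <- scheme$initial; t <- 0
    repeat {
      np <- np + 1L
      if (np > length(path_state)) {
        length(path_state) <- 2L * np; length(path_t) <- 2L * np
      }
      path_state[np] <- st; path_t[np] <- t
      tr <- out[[st]]
      R <- if (is.null(tr)) 0 else sum(tr$rate)
      if (R <= 0) { t <- t_max; break }
      t <- t + stats::rexp(1, R)
      if (t >= t_max) { t <- t_max; break }
      st <- if (nrow(tr) == 1L) tr$to else
        tr$to[sample.int(nrow(tr), 1L, prob = tr$rate)]
    }
    res[[i]] <- .intervals_from_path(path_state[seq_len(np)],
                                     path_t[seq_len(np)], t_max,
                                     scheme$emission_map, i)
  }
  events <- do.call(rbind, res[!vapply(res, is.null, logical(1))])
  if (is.null(events))
    events <- data.frame(molecule_id = integer(), channel = character(),
                         t_bind_s = numeric(), t_release_s = numeric(),
                         censored = integer())
  rownames(events) <- NULL
  structure(events, n_molecules = n_molecules, t_max = t_max, seed = seed,
            class = c("molecule_truth", "data.frame"))
}

.derive_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 48271 + i * 69621) %% 2147483647)
}

# collapse a state path into per-channel (bind, release, censored) intervals
.intervals_from_path <- function(states, t_enter, t_max, emission_map, mol_id) {
  t_exit <- c(t_enter[-1], t_max)
  rows <- list()
  channels <- sort(unique(unlist(emission_map[states])))
  for (ch in channels) {
    on <- vapply(states, function(s) ch %in% emission_map[[s]], logical(1))
    r <- rle(on)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    for (j in which(r$values)) {
      t0 <- t_enter[starts[j]]; t1 <- t_exit[ends[j]]
      if (t1 <= t0) next
      rows[[length(rows) + 1L]] <- data.frame(
        molecule_id = mol_id, channel = ch, t_bind_s = t0, t_release_s = t1,
        censored = as.integer(ends[j] == length(states) && t1 >= t_max))
    }
  }
  if (length(rows)) do.call(rbind, rows) else NULL
}

#' Render noisy intensity traces from molecule histories
#'
#' Converts binding intervals into per-frame integrated intensities: each
#' frame's intensity is baseline + amplitude x (number of bound, unbleached
#' fluorophores, fractionally weighted by overlap with the illuminated frame
#' duration) + Gaussian noise.  With \code{photobleach_coeff > 0} each
#' fluorophore independently goes dark with first-order rate
#' \code{photobleach_coeff * laser_power_uW}, measured from its binding time.
#'
#' @param truth a \code{"molecule_truth"} data frame from
#'   [simulate_molecules()] (or the same columns).
#' @param config an [acquisition_config()].
#' @param seed integer seed for noise and bleaching.
#' @param channels channels to render; default: every channel in
#'   \code{truth}.  All requested channels are rendered for every molecule,
#'   including molecules without events (flat noise traces).
#' @param molecule_ids molecules to render; default: \code{1:n_molecules}
#'   from the truth attribute.
#' @return tidy data frame of class \code{"intensity_traces"}: columns
#'   \code{molecule_id}, \code{channel}, \code{frame_index}, \code{t_mid_s},
#'   \code{intensity}.
#' @export
render_traces <- function(truth, config = acquisition_config(), seed = 1,
                          channels = NULL, molecule_ids = NULL) {
  if (is.null(channels)) channels <- sort(unique(truth$channel))
  if (is.null(molecule_ids)) {
    nm <- attr(truth, "n_molecules")
    molecule_ids <- if (is.null(nm)) sort(unique(truth$molecule_id)) else seq_len(nm)
  }
  fr <- .frame_times(config)
  set.seed(seed)
  key <- interaction(truth$molecule_id, truth$channel, drop = TRUE)
  idx <- split(seq_len(nrow(truth)), key)
  blocks <- vector("list", length(molecule_ids) * length(channels))
  b <- 0L
  for (m in molecule_ids) for (ch in channels) {
    rows <- idx[[paste(m, ch, sep = ".")]]
    occ <- numeric(fr$n)
    if (length(rows)) {
      nl <- .labels_for(config, ch)
      kbl <- config$photobleach_coeff * config$laser_power_uW
      for (r in rows) {
        t0 <- truth$t_bind_s[r]
        ends <- rep(truth$t_release_s[r], nl)
        if (kbl > 0) ends <- pmin(ends, t0 + stats::rexp(nl, kbl))
        for (t1 in ends) {
          ov <- pmax(0, pmin(t1, fr$start + config$frame_duration) -
                        pmax(t0, fr$start)) / config$frame_duration
          occ <- occ + ov / 1  # one amplitude unit per fluorophore
        }
      }
    }
    b <- b + 1L
    blocks[[b]] <- data.frame(
      molecule_id = m, channel = ch, frame_index = seq_len(fr$n),
      t_mid_s = fr$mid,
      intensity = config$baseline + config$amplitude * occ +
        if (config$noise_sd > 0) stats::rnorm(fr$n, 0, config$noise_sd) else 0)
  }
  out <- do.call(rbind, blocks)
  rownames(out) <- NULL
  structure(out, config = config,
            class = c("intensity_traces", "data.frame"))
}

#' Render background binding at empty areas of interest
#'
#' Emulates nonspecific fluorophore binding at control AOIs with no tethered
#' pre-mRNA: a Poisson process of arrivals at \code{rate_per_min} events per
#' AOI per minute, each with a short exponential dwell, rendered as intensity
#' traces with the acquisition settings.
#'
#' @param n_empty_aois number of control AOIs.
#' @param rate_per_min binding events per AOI per minute (>= 0).
#' @param config an [acquisition_config()].
#' @param seed integer seed.
#' @param dwell_mean_s mean dwell of a background binding event (s).
#' @param channel channel label for the rendered traces.
#' @return list with \code{$events} (a \code{"molecule_truth"} data frame)
#'   and \code{$traces} (an \code{"intensity_traces"} data frame).
#' @export
render_background <- function(n_empty_aois, rate_per_min,
                              config = acquisition_config(), seed = 1,
                              dwell_mean_s = 10, channel = "U4") {
  stopifnot(n_empty_aois >= 1, rate_per_min >= 0)
  set.seed(.derive_seed(seed, 0L))
  dur_min <- config$t_max / 60
  rows <- list()
  for (i in seq_len(n_empty_aois)) {
    n_ev <- stats::rpois(1, rate_per_min * dur_min)
    if (n_ev == 0) next
    t0 <- sort(stats::runif(n_ev, 0, config$t_max))
    dw <- stats::rexp(n_ev, 1 / dwell_mean_s)
    t1 <- pmin(t0 + dw, config$t_max)
    rows[[length(rows) + 1L]] <- data.frame(
      molecule_id = i, channel = channel, t_bind_s = t0, t_release_s = t1,
      censored = as.integer(t0 + dw >= config$t_max))
  }
  events <- if (length(rows)) do.call(rbind, rows) else
    data.frame(molecule_id = integer(), channel = character(),
               t_bind_s = numeric(), t_release_s = numeric(),
               censored = integer())
  rownames(events) <- NULL
  events <- structure(events, n_molecules = n_empty_aois,
                      t_max = config$t_max,
                      class = c("molecule_truth", "data.frame"))
  traces <- render_traces(events, config, seed = seed, channels = channel,
                          molecule_ids = seq_len(n_empty_aois))
  list(events = events, traces = traces)
}

#' Write / read event tables
#'
#' Event tables (\code{molecule_id}, \code{channel}, \code{t_bind_s},
#' \code{t_release_s}, \code{censored}) and tidy trace tables are exchanged
#' as plain CSV.
#'
#' @param events,traces data frames in the package schemas.
#' @param path file path.
#' @return \code{read_events_csv} returns a \code{"molecule_truth"} data
#'   frame.
#' @export
write_events_csv <- function(events, path) {
  utils::write.csv(as.data.frame(events)[c("molecule_id", "channel",
                                           "t_bind_s", "t_release_s",
                                           "censored")],
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_events_csv
#' @export
read_events_csv <- function(path) {
  ev <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("molecule_id", "channel", "t_bind_s", "t_release_s", "censored")
  if (!all(need %in% names(ev))) stop("missing event columns")
  structure(ev[need], class = c("molecule_truth", "data.frame"))
}

#' @rdname write_events_csv
#' @export
write_traces_csv <- function(traces, path) {
  utils::write.csv(as.data.frame(traces), path, row.names = FALSE)
  invisible(path)
}

#' Acquisition-config sidecar files
#'
#' Trace CSVs carry no acquisition metadata; the settings travel in a
#' key-value YAML sidecar (fields exactly those of [acquisition_config()]).
#'
#' @param config an [acquisition_config()].
#' @param path sidecar file path.
#' @return \code{read_acquisition_config} returns an
#'   \code{"acquisition_config"}.
#' @export
write_acquisition_config <- function(config, path) {
  stopifnot(inherits(config, "acquisition_config"))
  vals <- unclass(config)
  vals$n_labels <- as.list(vals$n_labels)  # keep channel names in the map
  yaml::write_yaml(vals, path)
  invisible(path)
}

#' @rdname write_acquisition_config
#' @export
read_acquisition_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(acquisition_config, vals)
}
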