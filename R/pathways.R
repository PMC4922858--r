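# normalize truth-schema or detector-schema event tables to start/end columns
.norm_events <- function(events) {
  ev <- as.data.frame(events)
  if (!"t_start_s" %in% names(ev) && "t_bind_s" %in% names(ev)) {
    ev$t_start_s <- ev$t_bind_s
    ev$t_end_s <- ev$t_release_s
  }
  if (!all(c("molecule_id", "t_start_s", "t_end_s") %in% names(ev)))
    stop("events need molecule_id and start/end times")
  if (!"censored" %in% names(ev)) ev$censored <- 0L
  ev
}

#' Match coincident arrivals across two channels
#'
#' Pairs events from two channels of the same molecules when their start
#' times agree within a tolerance (default one frame spacing), emulating the
#' "simultaneous appearance" criterion used to identify tri-snRNP (U4+U5)
#' binding.  Pairing is greedy by nearest start time within each molecule;
#' each event is used at most once; ties are broken in within-molecule time
#' order.
#'
#' @param events_a,events_b event tables (truth or detector schema) for the
#'   two channels.
#' @param tolerance_s start-time tolerance (s); the analysis default is one
#'   frame spacing (3 s).
#' @return list with \code{$pairs} (data frame: \code{molecule_id},
#'   \code{t_arrival_s}, and \code{a_*}/\code{b_*} start/end/censored
#'   columns), \code{$unmatched_a}, \code{$unmatched_b}.
#' @export
match_coincident <- function(events_a, events_b, tolerance_s = 3) {
  a <- .norm_events(events_a); b <- .norm_events(events_b)
  mols <- union(unique(a$molecule_id), unique(b$molecule_id))
  pair_rows <- list(); una <- list(); unb <- list()
  for (m in mols) {
    am <- a[a$molecule_id == m, , drop = FALSE]
    bm <- b[b$molecule_id == m, , drop = FALSE]
    am <- am[order(am$t_start_s), , drop = FALSE]
    bm <- bm[order(bm$t_start_s), , drop = FALSE]
    used_b <- rep(FALSE, nrow(bm))
    matched_a <- rep(FALSE, nrow(am))
    for (i in seq_len(nrow(am))) {
      if (!nrow(bm)) break
      d <- abs(bm$t_start_s - am$t_start_s[i])
      d[used_b] <- Inf
      j <- which.min(d)
      if (length(j) && is.finite(d[j]) && d[j] <= tolerance_s) {
        used_b[j] <- TRUE; matched_a[i] <- TRUE
        pair_rows[[length(pair_rows) + 1L]] <- data.frame(
          molecule_id = m,
          t_arrival_s = min(am$t_start_s[i], bm$t_start_s[j]),
          a_start = am$t_start_s[i], a_end = am$t_end_s[i],
          a_censored = am$censored[i],
          b_start = bm$t_start_s[j], b_end = bm$t_end_s[j],
          b_censored = bm$censored[j])
      }
    }
    if (any(!matched_a)) una[[length(una) + 1L]] <- am[!matched_a, , drop = FALSE]
    if (any(!used_b)) unb[[length(unb) + 1L]] <- bm[!used_b, , drop = FALSE]
  }
  empty_pairs <- data.frame(molecule_id = integer(), t_arrival_s = numeric(),
                            a_start = numeric(), a_end = numeric(),
                            a_censored = integer(), b_start = numeric(),
                            b_end = numeric(), b_censored = integer())
  pairs <- if (length(pair_rows)) do.call(rbind, pair_rows) else empty_pairs
  rownames(pairs) <- NULL
  list(pairs = pairs,
       unmatched_a = if (length(una)) do.call(rbind, una) else a[0, ],
       unmatched_b = if (length(unb)) do.call(rbind, unb) else b[0, ])
}

#' Classify outcome routes of coincident binding events
#'
#' Assigns each matched pair one of four mutually exclusive outcomes:
#' \code{A_FIRST} (channel-A spot lost first, e.g. U4 loss on activation),
#' \code{B_FIRST}, \code{SIMULTANEOUS_LOSS} (end times within tolerance;
#' tri-snRNP discard), or \code{PERSIST} (both spots censored at the end of
#' the recording).
#'
#' @param pairs the \code{$pairs} data frame from [match_coincident()].
#' @param tolerance_s end-time simultaneity tolerance (s).
#' @param labels optional channel labels used to rename \code{A_FIRST}/
#'   \code{B_FIRST} in printing (e.g. \code{c("U4", "U5")}).
#' @return object of class \code{"pathway_tally"}: \code{$pairs} with an
#'   \code{outcome} column, \code{$counts}, \code{$total},
#'   \code{$percentage}.
#' @export
classify_outcomes <- function(pairs, tolerance_s = 3, labels = c("U4", "U5")) {
  outcome <- character(nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    ac <- pairs$a_censored[i] > 0; bc <- pairs$b_censored[i] > 0
    if (ac && bc) outcome[i] <- "PERSIST"
    else if (!ac && !bc &&
             abs(pairs$a_end[i] - pairs$b_end[i]) <= tolerance_s)
      outcome[i] <- "SIMULTANEOUS_LOSS"
    else if (bc || (!ac && pairs$a_end[i] < pairs$b_end[i]))
      outcome[i] <- "A_FIRST"
    else outcome[i] <- "B_FIRST"
  }
  lev <- c("A_FIRST", "B_FIRST", "SIMULTANEOUS_LOSS", "PERSIST")
  pairs$outcome <- factor(outcome, levels = lev)
  counts <- table(pairs$outcome)
  total <- nrow(pairs)
  structure(list(pairs = pairs, counts = counts, total = total,
                 percentage = if (total) 100 * as.numeric(counts) / total
                              else rep(0, 4),
                 labels = labels, tolerance_s = tolerance_s),
            class = "pathway_tally")
}

#' @export
print.pathway_tally <- function(x, ...) {
  nm <- c(paste0(x$labels[1], "_FIRST"), paste0(x$labels[2], "_FIRST"),
          "SIMULTANEOUS_LOSS", "PERSIST")
  cat(sprintf("Outcome routes for %d coincident binding events:\n", x$total))
  for (i in seq_along(nm))
    cat(sprintf("  %-18s %5d  (%.1f%%)\n", nm[i], x$counts[i],
                x$percentage[i]))
  invisible(x)
}

#' Multiple-binding summary per molecule
#'
#' Tabulates how many coincident binding events each molecule exhibited, how
#' many molecules underwent at least two activation rounds (two or more
#' \code{A_FIRST} outcomes), and how often two paired complexes were
#' co-bound in time on the same molecule.
#'
#' @param tally a \code{"pathway_tally"} from [classify_outcomes()].
#' @param n_molecules total number of molecules observed (including
#'   molecules without events).
#' @return list: \code{$events_per_molecule} (table), \code{$n_multi}
#'   molecules with >= 2 events, \code{$n_repeat_activation} molecules with
#'   >= 2 \code{A_FIRST} outcomes, \code{$frac_repeat_activation},
#'   \code{$n_cobound} molecules with overlapping paired intervals.
#' @export
multi_binding_summary <- function(tally, n_molecules) {
  p <- tally$pairs
  per <- table(factor(p$molecule_id, levels = sort(unique(p$molecule_id))))
  act <- p[p$outcome == "A_FIRST", , drop = FALSE]
  act_per <- table(act$molecule_id)
  n_repeat <- sum(act_per >= 2)
  cobound <- 0L
  for (m in unique(p$molecule_id)) {
    pm <- p[p$molecule_id == m, , drop = FALSE]
    if (nrow(pm) < 2) next
    pm <- pm[order(pm$t_arrival_s), ]
    span_end <- pmax(pm$a_end, pm$b_end)
    if (any(pm$t_arrival_s[-1] < span_end[-nrow(pm)] - 1e-9))
      cobound <- cobound + 1L
  }
  list(events_per_molecule = per,
       n_multi = sum(per >= 2),
       n_repeat_activation = n_repeat,
       frac_repeat_activation = n_repeat / n_molecules,
       n_cobound = cobound,
       n_molecules = n_molecules)
}

#' Channel-A reappearance (rebinding) after A-first loss
#'
#' For every coincident event whose outcome was \code{A_FIRST} (e.g. U4 loss
#' during activation), asks whether a new channel-A event appeared while the
#' channel-B spot was still present, and expresses the instances as a
#' fraction of eligible cases and as a per-minute rate over the eligible
#' B-visible time, for comparison with the background binding rate.
#'
#' @param tally a \code{"pathway_tally"} from [classify_outcomes()].
#' @param events_a full channel-A event table (to find reappearances).
#' @param background_rate_per_min optional background binding rate
#'   (events/min) for comparison; when missing the comparison is omitted
#'   with a warning.
#' @return list: \code{$n_rebind}, \code{$n_eligible}, \code{$fraction},
#'   \code{$percent}, \code{$rate_per_min}, \code{$eligible_time_min},
#'   \code{$background_rate_per_min}, \code{$rate_ratio}.
#' @export
rebinding_analysis <- function(tally, events_a,
                               background_rate_per_min = NULL) {
  a <- .norm_events(events_a)
  el <- tally$pairs[tally$pairs$outcome == "A_FIRST", , drop = FALSE]
  n_rebind <- 0L
  t_eligible <- 0
  for (i in seq_len(nrow(el))) {
    m <- el$molecule_id[i]
    win0 <- el$a_end[i]; win1 <- el$b_end[i]
    t_eligible <- t_eligible + max(0, win1 - win0)
    am <- a[a$molecule_id == m, , drop = FALSE]
    hit <- am$t_start_s > win0 + 1e-9 & am$t_start_s < win1 - 1e-9
    if (any(hit)) n_rebind <- n_rebind + 1L
  }
  rate <- if (t_eligible > 0) n_rebind / (t_eligible / 60) else NA_real_
  ratio <- NULL
  if (is.null(background_rate_per_min)) {
    warning("no background rate supplied; comparison omitted")
  } else if (is.finite(rate) && background_rate_per_min > 0) {
    ratio <- rate / background_rate_per_min
  }
  list(n_rebind = n_rebind, n_eligible = nrow(el),
       fraction = if (nrow(el)) n_rebind / nrow(el) else NA_real_,
       percent = if (nrow(el)) 100 * n_rebind / nrow(el) else NA_real_,
       rate_per_min = rate, eligible_time_min = t_eligible / 60,
       background_rate_per_min = background_rate_per_min,
       rate_ratio = ratio)
}

#' Ordering of channel-A release vs channel-B arrival
#'
#' For each molecule with at least one channel-A release (e.g. U4 loss) and
#' one channel-B arrival (e.g. NTC appearance), computes the offset
#' \eqn{\Delta = t_{A,release} - t_{B,arrival}}.  The sign convention:
#' \eqn{\Delta > 0} means B arrived before A was released; \eqn{\Delta < 0}
#' means B arrived after A release.  Molecules with several candidates use
#' the pair minimizing \eqn{|\Delta|}; molecules lacking either event are
#' excluded and counted.
#'
#' @param release_events channel-A event table; non-censored end times are
#'   release times.
#' @param arrival_events channel-B event table; start times are arrivals.
#' @return object of class \code{"ordering_record"}: data frame
#'   \code{$offsets} (\code{molecule_id}, \code{delta_s}),
#'   \code{$fraction_negative}, \code{$n}, \code{$n_excluded}.
#' @export
ordering_offsets <- function(release_events, arrival_events) {
  a <- .norm_events(release_events); b <- .norm_events(arrival_events)
  a <- a[a$censored == 0, , drop = FALSE]
  mols <- union(unique(a$molecule_id), unique(b$molecule_id))
  rows <- list(); excluded <- 0L
  for (m in mols) {
    rel <- a$t_end_s[a$molecule_id == m]
    arr <- b$t_start_s[b$molecule_id == m]
    if (!length(rel) || !length(arr)) { excluded <- excluded + 1L; next }
    d <- outer(rel, arr, "-")
    ix <- which(abs(d) == min(abs(d)), arr.ind = TRUE)[1, ]
    rows[[length(rows) + 1L]] <- data.frame(molecule_id = m,
                                            delta_s = d[ix[1], ix[2]])
  }
  offsets <- if (length(rows)) do.call(rbind, rows) else
    data.frame(molecule_id = integer(), delta_s = numeric())
  rownames(offsets) <- NULL
  structure(list(offsets = offsets,
                 fraction_negative = if (nrow(offsets))
                   mean(offsets$delta_s < 0) else NA_real_,
                 n = nrow(offsets), n_excluded = excluded),
            class = "ordering_record")
}

#' @export
print.ordering_record <- function(x, ...) {
  cat(sprintf("Ordering offsets for %d molecules (%d excluded)\n",
              x$n, x$n_excluded))
  cat(sprintf("  fraction with delta < 0 (B after A release): %.1f%%\n",
              100 * x$fraction_negative))
  invisible(x)
}

#' Randomized control for the ordering analysis
#'
#' Builds the chance expectation for the release-vs-arrival offset
#' distribution by permuting arrival times across molecules (release times
#' held fixed), recomputing the offsets, and averaging histograms over
#' shuffles.
#'
#' @inheritParams ordering_offsets
#' @param n_shuffles number of across-molecule permutations.
#' @param seed integer seed (results identical for identical seeds).
#' @param breaks histogram bin edges for the offsets (s); the default
#'   resolves the +/- 200 s region finely and pools the long tails.
#' @return list: \code{$breaks}, \code{$observed} (counts),
#'   \code{$control} (mean counts over shuffles), \code{$observed_record}.
#' @export
randomized_control <- function(release_events, arrival_events,
                               n_shuffles = 100, seed = 1,
                               breaks = c(-3600, seq(-200, 200, by = 25),
                                          3600)) {
  a <- .norm_events(release_events); b <- .norm_events(arrival_events)
  obs <- ordering_offsets(a, b)
  mols <- intersect(unique(a$molecule_id[a$censored == 0]),
                    unique(b$molecule_id))
  if (length(mols) < 2L) stop("need >= 2 molecules with both event types")
  set.seed(seed)
  arr_by_mol <- split(b$t_start_s, factor(b$molecule_id, levels = mols))
  rel_by_mol <- split(a$t_end_s[a$censored == 0],
                      factor(a$molecule_id[a$censored == 0], levels = mols))
  clip <- function(x) pmin(pmax(x, breaks[1]), breaks[length(breaks)])
  ctrl <- matrix(0, n_shuffles, length(breaks) - 1L)
  for (s in seq_len(n_shuffles)) {
    perm <- sample(length(mols))
    deltas <- numeric(0)
    for (i in seq_along(mols)) {
      rel <- rel_by_mol[[i]]; arr <- arr_by_mol[[perm[i]]]
      if (!length(rel) || !length(arr)) next
      d <- outer(rel, arr, "-")
      deltas <- c(deltas, d[which.min(abs(d))])
    }
    if (length(deltas))
      ctrl[s, ] <- graphics::hist(clip(deltas), breaks = breaks,
                                  plot = FALSE)$counts
  }
  obs_counts <- graphics::hist(clip(obs$offsets$delta_s), breaks = breaks,
                               plot = FALSE)$counts
  list(breaks = breaks, observed = obs_counts, control = colMeans(ctrl),
       observed_record = obs, n_shuffles = n_shuffles, seed = seed)
}

#' Rank correlation between paired dwell times
#'
#' Spearman correlation with a two-sided permutation p-value, used to ask
#' whether the time to channel-A loss predicts the subsequent channel-B
#' dwell (no correlation is expected for memoryless sequential kinetics).
#'
#' @param x,y paired dwell times (n >= 5).
#' @param n_perm number of permutations (>= 1000 recommended).
#' @param seed integer seed.
#' @return list: \code{$rho}, \code{$p_value}, \code{$n}, \code{$n_perm};
#'   \code{$degenerate} is TRUE (with \code{rho} NA) for ties-only input.
#' @export
dwell_correlation <- function(x, y, n_perm = 1000, seed = 1) {
  stopifnot(length(x) == length(y))
  if (length(x) < 5) stop("need at least 5 pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(rho = NA_real_, p_value = NA_real_, n = length(x),
                n_perm = 0L, degenerate = TRUE))
  rho <- stats::cor(x, y, method = "spearman")
  set.seed(seed)
  exceed <- 0L
  for (i in seq_len(n_perm)) {
    r <- stats::cor(x, sample(y), method = "spearman")
    if (abs(r) >= abs(rho) - 1e-12) exceed <- exceed + 1L
  }
  list(rho = rho, p_value = (exceed + 1) / (n_perm + 1), n = length(x),
       n_perm = n_perm, degenerate = FALSE)
}

#' Background binding rate at empty AOIs
#'
#' Events per AOI per minute, with an exact Poisson confidence interval.
#'
#' @param events event table on control AOIs, or a bare event count.
#' @param n_aois number of control AOIs monitored.
#' @param duration_min observation time (minutes).
#' @param conf_level confidence level for the Poisson interval.
#' @return list: \code{$rate} (events / AOI / min), \code{$ci},
#'   \code{$n_events}, \code{$aoi_minutes}.
#' @export
background_rate <- function(events, n_aois, duration_min,
                            conf_level = 0.95) {
  stopifnot(duration_min > 0, n_aois > 0)
  n_events <- if (is.numeric(events) && length(events) == 1L) events
              else nrow(as.data.frame(events))
  expo <- n_aois * duration_min
  ci <- stats::poisson.test(n_events, conf.level = conf_level)$conf.int / expo
  list(rate = n_events / expo, ci = as.numeric(ci), n_events = n_events,
       aoi_minutes = expo)
}
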