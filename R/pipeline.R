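#' Deterministic event-table fixtures from printed tallies
#'
#' Reconstructs minimal two-channel event tables whose analysis reproduces a
#' requested tally exactly.  Useful as worked examples and for checking the
#' pathway arithmetic against published per-route counts.  All fixtures are
#' synthetic reconstructions; they carry the requested counts, not raw data.
#'
#' Types:
#' \describe{
#'   \item{\code{"outcomes"}}{\code{counts} has entries \code{A_FIRST},
#'     \code{B_FIRST}, \code{SIMULTANEOUS_LOSS}, \code{PERSIST} (and
#'     optionally \code{total}, which must equal their sum).  One coincident
#'     U4/U5 event per molecule.}
#'   \item{\code{"coincidence"}}{entries \code{paired}, \code{only_a},
#'     \code{only_b}: paired arrivals start simultaneously; unpaired events
#'     appear on one channel only.}
#'   \item{\code{"rebinding"}}{entries \code{rebind}, \code{eligible}:
#'     \code{eligible} A-first molecules of which \code{rebind} show a new
#'     channel-A event while channel B persists.}
#'   \item{\code{"repeat_activation"}}{entries \code{repeat_molecules},
#'     \code{total_molecules}: molecules with two activation rounds among a
#'     total population.}
#' }
#'
#' @param type fixture type.
#' @param counts named list/vector of non-negative counts (see above).
#' @param t_max recording length (s) used for censored events.
#' @return a \code{"molecule_truth"} event table (channels \code{U4},
#'   \code{U5}).
#' @examples
#' ev <- make_fixture("outcomes",
#'                    c(A_FIRST = 79, B_FIRST = 3, SIMULTANEOUS_LOSS = 46,
#'                      PERSIST = 0))
#' @export
make_fixture <- function(type = c("outcomes", "coincidence", "rebinding",
                                  "repeat_activation"),
                         counts, t_max = 3600) {
  type <- match.arg(type)
  counts <- as.list(counts)
  if (any(unlist(counts) < 0)) stop("counts must be non-negative")
  rows <- list()
  add <- function(m, ch, t0, t1, cens = 0L)
    rows[[length(rows) + 1L]] <<- data.frame(
      molecule_id = m, channel = ch, t_bind_s = t0, t_release_s = t1,
      censored = as.integer(cens))
  m <- 0L
  n_molecules <- 0L
  if (type == "outcomes") {
    need <- c("A_FIRST", "B_FIRST", "SIMULTANEOUS_LOSS", "PERSIST")
    cnt <- vapply(need, function(k) if (is.null(counts[[k]])) 0 else
      counts[[k]], numeric(1))
    if (!is.null(counts$total) && counts$total != sum(cnt))
      stop("route counts do not sum to total")
    for (i in seq_len(cnt["A_FIRST"])) {
      m <- m + 1L; add(m, "U4", 100, 400); add(m, "U5", 100, 700)
    }
    for (i in seq_len(cnt["B_FIRST"])) {
      m <- m + 1L; add(m, "U4", 100, 700); add(m, "U5", 100, 400)
    }
    for (i in seq_len(cnt["SIMULTANEOUS_LOSS"])) {
      m <- m + 1L; add(m, "U4", 100, 400); add(m, "U5", 100, 400)
    }
    for (i in seq_len(cnt["PERSIST"])) {
      m <- m + 1L
      add(m, "U4", 100, t_max, 1L); add(m, "U5", 100, t_max, 1L)
    }
    n_molecules <- m
  } else if (type == "coincidence") {
    for (i in seq_len(counts$paired %||% 0)) {
      m <- m + 1L; add(m, "U4", 100, 300); add(m, "U5", 100, 300)
    }
    for (i in seq_len(counts$only_a %||% 0)) {
      m <- m + 1L; add(m, "U4", 100, 300)
    }
    for (i in seq_len(counts$only_b %||% 0)) {
      m <- m + 1L; add(m, "U5", 100, 300)
    }
    n_molecules <- m
  } else if (type == "rebinding") {
    if (counts$rebind > counts$eligible)
      stop("rebind count exceeds eligible count")
    for (i in seq_len(counts$eligible)) {
      m <- m + 1L
      add(m, "U4", 100, 400); add(m, "U5", 100, 1500)
      if (i <= counts$rebind) add(m, "U4", 800, 830)
    }
    n_molecules <- m
  } else {
    if (counts$repeat_molecules > counts$total_molecules)
      stop("repeat count exceeds total molecule count")
    for (i in seq_len(counts$repeat_molecules)) {
      m <- m + 1L
      add(m, "U4", 100, 300); add(m, "U5", 100, 500)
      add(m, "U4", 900, 1100); add(m, "U5", 900, 1300)
    }
    for (i in seq_len(counts$total_molecules - counts$repeat_molecules)) {
      m <- m + 1L
      add(m, "U4", 100, 300); add(m, "U5", 100, 500)
    }
    n_molecules <- counts$total_molecules
  }
  events <- if (length(rows)) do.call(rbind, rows) else
    data.frame(molecule_id = integer(), channel = character(),
               t_bind_s = numeric(), t_release_s = numeric(),
               censored = integer())
  rownames(events) <- NULL
  structure(events, n_molecules = n_molecules, t_max = t_max,
            class = c("molecule_truth", "data.frame"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Seeded end-to-end analysis pipeline
#'
#' Runs simulate -> render -> detect -> match -> classify -> fit with one
#' configuration and seed, returning a machine-readable report bundle.  The
#' bundle is identical for identical configuration and seed.
#'
#' @param preset kinetic preset passed to [scheme_preset()], or a
#'   [kinetic_scheme()] object.
#' @param n_molecules molecules to simulate (0 gives an empty, schema-valid
#'   report).
#' @param seed master seed for all stages.
#' @param acquisition an [acquisition_config()].
#' @param detector a [detector_config()].
#' @param use_detection if TRUE (default) events come from rendered traces
#'   through the threshold detector; if FALSE the ground-truth intervals are
#'   used directly (no rendering).
#' @param fit_release model name for fitting the simultaneous-loss
#'   (tri-snRNP release) dwell distribution, or \code{"none"} to skip;
#'   \code{"auto"} picks \code{"exp3"} for the 2 mM preset and \code{"exp2"}
#'   otherwise.
#' @param n_boot bootstrap resamples for the release fit (0 skips the
#'   bootstrap).
#' @param ordering run the U4-release vs NTC-arrival ordering analysis?
#' @param out_dir optional directory; when given, writes \code{events.csv},
#'   \code{tally.json}, \code{fit_release.json}, \code{histogram.csv} and
#'   \code{manifest.json}.
#' @return list of class \code{"cosmos_report"} with elements \code{truth},
#'   \code{events}, \code{match}, \code{tally}, \code{dwells},
#'   \code{fit_release}, \code{ordering}, \code{manifest}.
#' @export
run_pipeline <- function(preset = "2mM", n_molecules = 100, seed = 1,
                         acquisition = acquisition_config(),
                         detector = detector_config(),
                         use_detection = TRUE, fit_release = "auto",
                         n_boot = 0, ordering = TRUE, out_dir = NULL) {
  scheme <- if (inherits(preset, "kinetic_scheme")) preset
            else scheme_preset(preset)
  if (identical(fit_release, "auto"))
    fit_release <- if (identical(scheme$label, "2mM")) "exp3" else "exp2"
  t_m <- acquisition$frame_spacing
  empty_ev <- data.frame(molecule_id = integer(), channel = character(),
                         t_bind_s = numeric(), t_release_s = numeric(),
                         censored = integer())
  if (n_molecules >= 1) {
    truth <- simulate_molecules(scheme, n_molecules, acquisition, seed)
  } else {
    truth <- structure(empty_ev, n_molecules = 0L, t_max = acquisition$t_max,
                       class = c("molecule_truth", "data.frame"))
  }
  if (use_detection && n_molecules >= 1) {
    traces <- render_traces(truth, acquisition, seed = .derive_seed(seed, -1L),
                            channels = intersect(c("U4", "U5", "NTC"),
                                                 scheme$channels))
    events <- detect_all_events(traces, detector,
                                frame_spacing = acquisition$frame_spacing)
  } else {
    events <- .norm_events(truth)
    attr(events, "frame_spacing") <- acquisition$frame_spacing
  }
  ev_u4 <- events[events$channel == "U4", , drop = FALSE]
  ev_u5 <- events[events$channel == "U5", , drop = FALSE]
  mm <- match_coincident(ev_u4, ev_u5,
                         tolerance_s = acquisition$frame_spacing)
  tally <- classify_outcomes(mm$pairs,
                             tolerance_s = acquisition$frame_spacing)
  rel <- tally$pairs[tally$pairs$outcome == "SIMULTANEOUS_LOSS", ,
                     drop = FALSE]
  dwells <- pmax(rel$a_end, rel$b_end) - rel$t_arrival_s
  dwells <- pmin(pmax(dwells, t_m), acquisition$t_max)
  fit <- NULL
  k_free <- if (identical(fit_release, "none")) Inf else
    switch(fit_release, exp1 = 1L, exp2 = 3L, exp3 = 5L, conv = 2L)
  if (length(dwells) >= 3L * k_free) {
    fit <- fit_dwells(dwells, fit_release, t_m = t_m,
                      t_max = acquisition$t_max)
    if (n_boot > 0) fit <- bootstrap_errors(fit, n_boot = n_boot,
                                            seed = .derive_seed(seed, -2L))
  }
  ord <- NULL
  if (ordering && "NTC" %in% scheme$channels && nrow(events)) {
    ev_ntc <- events[events$channel == "NTC", , drop = FALSE]
    if (nrow(ev_u4) && nrow(ev_ntc))
      ord <- ordering_offsets(ev_u4, ev_ntc)
  }
  manifest <- list(package = "cosmosdwell",
                   version = as.character(utils::packageVersion("cosmosdwell")),
                   preset = scheme$label, n_molecules = n_molecules,
                   seed = seed, use_detection = use_detection,
                   frame_duration_s = acquisition$frame_duration,
                   frame_spacing_s = acquisition$frame_spacing,
                   t_max_s = acquisition$t_max)
  report <- structure(list(truth = truth, events = events, match = mm,
                           tally = tally, dwells = dwells,
                           fit_release = fit, ordering = ord,
                           manifest = manifest),
                      class = "cosmos_report")
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' @export
print.cosmos_report <- function(x, ...) {
  cat(sprintf("CoSMoS pipeline report [%s preset, %d molecules, seed %d]\n",
              x$manifest$preset, x$manifest$n_molecules, x$manifest$seed))
  print(x$tally)
  if (!is.null(x$fit_release)) print(x$fit_release)
  if (!is.null(x$ordering)) print(x$ordering)
  invisible(x)
}

#' Serialize a pipeline report bundle
#'
#' Writes the report as plain CSV/JSON files (percentages to one decimal).
#'
#' @param report a \code{"cosmos_report"} from [run_pipeline()].
#' @param out_dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_events_csv(report$events[c("molecule_id", "channel",
                                   if ("t_start_s" %in% names(report$events))
                                     c("t_start_s", "t_end_s") else
                                     c("t_bind_s", "t_release_s"),
                                   "censored")] |> .as_truth_cols(),
                   file.path(out_dir, "events.csv"))
  tally_json <- list(
    total = report$tally$total,
    counts = as.list(stats::setNames(as.integer(report$tally$counts),
                                     names(report$tally$counts))),
    percent = as.list(stats::setNames(round(report$tally$percentage, 1),
                                      names(report$tally$counts))))
  jsonlite::write_json(tally_json, file.path(out_dir, "tally.json"),
                       auto_unbox = TRUE, digits = NA)
  if (!is.null(report$fit_release)) {
    f <- report$fit_release
    jsonlite::write_json(list(model = f$spec, par = as.list(f$par),
                              boot_sd = if (!is.null(f$boot))
                                as.list(f$boot$sd) else NULL,
                              loglik = f$loglik, n = f$n, t_m = f$t_m,
                              t_max = f$t_max),
                         file.path(out_dir, "fit_release.json"),
                         auto_unbox = TRUE, digits = NA)
    if (f$n >= 2) {
      h <- histogram_pd(report$dwells, t_m = f$t_m, t_max = f$t_max)
      utils::write.csv(data.frame(bin_lo = h$breaks[-length(h$breaks)],
                                  bin_hi = h$breaks[-1], count = h$counts,
                                  density = h$density, error = h$error),
                       file.path(out_dir, "histogram.csv"),
                       row.names = FALSE)
    }
  }
  jsonlite::write_json(report$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

.as_truth_cols <- function(ev) {
  nm <- names(ev)
  nm[nm == "t_start_s"] <- "t_bind_s"
  nm[nm == "t_end_s"] <- "t_release_s"
  names(ev) <- nm
  ev
}

#' Check a report bundle against the published schema
#'
#' Verifies that a serialized report directory contains the expected files
#' and that the JSON reports carry the required fields (schema description
#' in \code{inst/extdata/report-schema.json}).
#'
#' @param out_dir directory written by [write_report()].
#' @return TRUE invisibly; stops with a message otherwise.
#' @export
validate_report <- function(out_dir) {
  for (f in c("events.csv", "tally.json", "manifest.json"))
    if (!file.exists(file.path(out_dir, f))) stop("missing ", f)
  tly <- jsonlite::read_json(file.path(out_dir, "tally.json"))
  if (!all(c("total", "counts", "percent") %in% names(tly)))
    stop("tally.json missing fields")
  man <- jsonlite::read_json(file.path(out_dir, "manifest.json"))
  need <- c("package", "version", "preset", "n_molecules", "seed")
  if (!all(need %in% names(man))) stop("manifest.json missing fields")
  ev <- utils::read.csv(file.path(out_dir, "events.csv"))
  if (!all(c("molecule_id", "channel", "t_bind_s", "t_release_s",
             "censored") %in% names(ev))) stop("events.csv missing columns")
  invisible(TRUE)
}
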