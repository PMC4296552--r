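# Four-class topology of nucleosome architecture around TF binding sites.
#
# Classes (operationalized from the qualitative patterns):
#   LINKER          - sites depleted of nucleosomes, flanked by the two
#                     adjacent nucleosomes (core pluripotency factors).
#   NUCLEOSOMAL     - sites enriched on nucleosomal DNA (self-renewal
#                     regulators, p300, Stat3).
#   PERIODIC_LINKER - linker sites inside a long phased array with
#                     nucleosome-repeat periodicity (CTCF-like).
#   BORDER          - sites on nucleosomal DNA enriched at the particle
#                     borders (E2F1, c-Myc-like).
# Every threshold below is a config knob; defaults follow canonical
# nucleosome geometry (147-bp core, ~190-bp repeat).

#' Default thresholds for topology classification
#'
#' @param center_z_low standardized central depletion bound (default -1).
#' @param center_z_high standardized central enrichment bound (default +1).
#' @param linker_peak_range bp window for the nearest flanking nucleosome
#'   of a linker site (default `c(70, 130)`).
#' @param border_peak_range bp window for the twin border peaks
#'   (default `c(40, 90)`).
#' @param nucleosomal_tol bp: maximal distance from offset 0 to the
#'   nearest peak for a nucleosomal call (default 30).
#' @param period_range acceptable nucleosome repeat lengths in bp
#'   (default `c(160, 220)`).
#' @param min_periodic_peaks phased peaks required per side (default 3).
#' @param baseline_range bp band used as the flank-tail baseline
#'   (default `c(800, 1000)`).
#' @return list of thresholds.
#' @export
topology_rules <- function(center_z_low = -1, center_z_high = 1,
                           linker_peak_range = c(70, 130),
                           border_peak_range = c(40, 90),
                           nucleosomal_tol = 30,
                           period_range = c(160, 220),
                           min_periodic_peaks = 3,
                           baseline_range = c(800, 1000)) {
  list(center_z_low = center_z_low, center_z_high = center_z_high,
       linker_peak_range = linker_peak_range, border_peak_range = border_peak_range,
       nucleosomal_tol = nucleosomal_tol, period_range = period_range,
       min_periodic_peaks = min_periodic_peaks, baseline_range = baseline_range)
}

#' Nucleosome profile centered on binding sites
#'
#' Delegates to [anchored_profile()] with unstranded anchors at the site
#' centers. Duplicate sites count as many times as they occur.
#'
#' @param track a `midpoint_track`.
#' @param sites table with `chrom` and `center` (see [read_bed_sites()]).
#' @param flank bp on each side (default 1000).
#' @param bin_width bin width in bp (default 10).
#' @param ... passed to [profile_params()].
#' @return a `nuc_profile`.
#' @export
site_profile <- function(track, sites, flank = 1000, bin_width = 10, ...) {
  sites <- as.data.table(sites)
  if (nrow(sites) == 0L) stop_nucorg("site set is empty")
  anchors <- data.table(chrom = sites$chrom, pos = sites$center, strand = "*")
  anchored_profile(track, anchors, profile_params(flank = flank, bin_width = bin_width, ...),
                   anchor_set_id = "sites")
}

#' Diagnostic features of a site-centered nucleosome profile
#'
#' `center_z` standardizes the smoothed occupancy at offset 0 against the
#' flank-tail baseline (mean/sd of bins with `|offset|` in
#' `baseline_range`); the sd is floored at 10% of the baseline mean so
#' that flat, shot-noise-limited baselines do not blow the statistic up.
#' Periodicity comes from the autocorrelation of the mean-subtracted
#' smoothed profile: the spacing is the lag of the first non-zero-lag
#' local maximum and the strength that autocorrelation value clipped to
#' `[0, 1]`. `n_periodic_peaks` counts, per side, the run of successive
#' local maxima whose spacing stays within 140-240 bp, and reports the
#' weaker side.
#'
#' @param profile a `nuc_profile` covering +-1000 bp with no missing
#'   central bins.
#' @param rules see [topology_rules()].
#' @return list of features: `center_z`, `peak_offsets` (sorted by
#'   `|offset|`), `period_bp`, `period_strength`, `n_periodic_peaks`,
#'   `central_minor_peak`.
#' @export
topology_features <- function(profile, rules = topology_rules()) {
  stopifnot(inherits(profile, "nuc_profile"))
  p <- attr(profile, "params")
  if (p$flank < 1000) stop_nucorg("topology features need a profile covering +-1000 bp")
  x <- profile$smoothed
  mid <- profile$bin_mid
  scope <- abs(mid) <= 1000
  if (any(is.na(x[abs(mid) <= rules$baseline_range[2]]))) {
    stop_nucorg("profile has missing bins inside the feature window")
  }
  base_idx <- which(abs(mid) >= rules$baseline_range[1] & abs(mid) <= rules$baseline_range[2])
  base_mean <- mean(x[base_idx])
  base_sd <- max(sd(x[base_idx]), 0.1 * base_mean)
  center_val <- x[which.min(abs(mid))]
  center_z <- (center_val - base_mean) / base_sd

  # nucleosome peaks: local maxima that clear the baseline by one
  # standardized unit AND by a quarter of the profile's dynamic range;
  # smoothed shot noise produces local maxima every 100-200 bp that would
  # otherwise masquerade as phased nucleosomes at low site counts
  raw_peaks <- local_maxima(ifelse(scope, x, NA_real_), halfwidth = 2L)
  prom <- base_mean + max(base_sd, 0.25 * (max(x[scope], na.rm = TRUE) - base_mean))
  peaks <- raw_peaks[x[raw_peaks] > prom]
  peak_offsets <- mid[peaks][order(abs(mid[peaks]))]

  xs <- x[scope]
  ac <- stats::acf(xs - mean(xs), lag.max = length(xs) - 2L, plot = FALSE,
                   demean = FALSE)$acf[, 1, 1]
  # local maxima over the full acf including lag 0 (then discarded), so a
  # monotone decay cannot fake a lag-1 "peak" at the series edge
  lagmax <- setdiff(local_maxima(ac, halfwidth = 2L), 1L) - 1L
  if (length(lagmax) > 0L) {
    period_bp <- lagmax[1] * p$bin_width
    period_strength <- min(max(ac[lagmax[1] + 1L], 0), 1)
  } else {
    period_bp <- NA_real_
    period_strength <- 0
  }

  count_side <- function(offs) {
    offs <- sort(offs)
    if (length(offs) == 0L) return(0L)
    n <- 1L
    for (i in seq_len(length(offs) - 1L)) {
      gap <- offs[i + 1L] - offs[i]
      if (gap >= 140 && gap <= 240) n <- n + 1L else break
    }
    n
  }
  n_periodic_peaks <- min(count_side(abs(peak_offsets[peak_offsets > 0])),
                          count_side(abs(peak_offsets[peak_offsets < 0])))
  # the small central bump of periodic-linker sites need not clear the
  # baseline, so it is read off the unfiltered maxima
  central_minor_peak <- any(abs(mid[raw_peaks]) <= 30)

  list(center_z = center_z, peak_offsets = peak_offsets,
       period_bp = period_bp, period_strength = period_strength,
       n_periodic_peaks = n_periodic_peaks, central_minor_peak = central_minor_peak)
}

#' Classify the nucleosome topology of a binding-site profile
#'
#' Rule order: (i) deep central depletion with >= `min_periodic_peaks`
#' near-periodic flanking peaks per side at a repeat inside `period_range`
#' is PERIODIC_LINKER (a small central peak is tolerated); (ii) deep
#' central depletion with the nearest flanking peaks inside
#' `linker_peak_range` is LINKER; (iii) central enrichment with offset 0
#' within `nucleosomal_tol` of the nearest peak is NUCLEOSOMAL; (iv) twin
#' peaks inside `border_peak_range` flanking a shallow central dip is
#' BORDER. Anything else is an error ("unclassifiable"), never forced
#' into a class.
#'
#' @param profile a `nuc_profile` covering +-1000 bp.
#' @param rules see [topology_rules()].
#' @return list with `class` (one of "LINKER", "NUCLEOSOMAL",
#'   "PERIODIC_LINKER", "BORDER") and `features`.
#' @export
classify_topology <- function(profile, rules = topology_rules()) {
  f <- topology_features(profile, rules)
  po <- f$peak_offsets
  nearest_pos <- po[po > 0][which.min(abs(po[po > 0]))[1]]
  nearest_neg <- po[po < 0][which.min(abs(po[po < 0]))[1]]
  nearest_any <- if (length(po)) min(abs(po)) else Inf
  in_range <- function(v, r) length(v) == 1L && !is.na(v) && abs(v) >= r[1] && abs(v) <= r[2]

  cls <- NULL
  if (f$center_z <= rules$center_z_low &&
      f$n_periodic_peaks >= rules$min_periodic_peaks &&
      !is.na(f$period_bp) &&
      f$period_bp >= rules$period_range[1] && f$period_bp <= rules$period_range[2]) {
    cls <- "PERIODIC_LINKER"
  } else if (f$center_z <= rules$center_z_low &&
             in_range(nearest_pos, rules$linker_peak_range) &&
             in_range(nearest_neg, rules$linker_peak_range)) {
    cls <- "LINKER"
  } else if (f$center_z >= rules$center_z_high && nearest_any <= rules$nucleosomal_tol) {
    cls <- "NUCLEOSOMAL"
  } else if (f$center_z > rules$center_z_low &&
             in_range(nearest_pos, rules$border_peak_range) &&
             in_range(nearest_neg, rules$border_peak_range)) {
    cls <- "BORDER"
  }
  if (is.null(cls)) stop_nucorg("unclassifiable nucleosome topology (center_z = %.2f)", f$center_z)
  list(class = cls, features = f)
}

#' Classify several binding-site sets against one midpoint track
#'
#' Per-set errors are collected into the result, never fatal to the
#' batch. Rows keep the order of `site_sets`.
#'
#' @param track a `midpoint_track`.
#' @param site_sets named list of site tables.
#' @param flank,bin_width profile geometry (defaults 1000 / 10).
#' @param rules see [topology_rules()].
#' @return `data.table` with one row per set: `set`, `class` (NA on
#'   error), `center_z`, `period_bp`, `period_strength`,
#'   `n_periodic_peaks`, `central_minor_peak`, `peak_offsets`
#'   (comma-joined), `n_sites`, `error`.
#' @export
batch_classify <- function(track, site_sets, flank = 1000, bin_width = 10,
                           rules = topology_rules()) {
  stopifnot(is.list(site_sets), !is.null(names(site_sets)))
  rows <- lapply(names(site_sets), function(nm) {
    sites <- site_sets[[nm]]
    out <- tryCatch({
      prof <- site_profile(track, sites, flank = flank, bin_width = bin_width)
      call <- classify_topology(prof, rules)
      f <- call$features
      data.table(set = nm, class = call$class, center_z = f$center_z,
                 period_bp = f$period_bp, period_strength = f$period_strength,
                 n_periodic_peaks = f$n_periodic_peaks,
                 central_minor_peak = f$central_minor_peak,
                 peak_offsets = paste(round(f$peak_offsets), collapse = ","),
                 n_sites = nrow(as.data.table(sites)), error = NA_character_)
    }, error = function(e) {
      data.table(set = nm, class = NA_character_, center_z = NA_real_,
                 period_bp = NA_real_, period_strength = NA_real_,
                 n_periodic_peaks = NA_integer_, central_minor_peak = NA,
                 peak_offsets = NA_character_,
                 n_sites = nrow(as.data.table(site_sets[[nm]])),
                 error = conditionMessage(e))
    })
    out
  })
  rbindlist(rows)
}
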