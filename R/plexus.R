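#' Find density peaks and troughs in a depth profile
#'
#' Plateau-aware local maxima with a topographic prominence filter:
#' equal-valued runs are compressed, a run higher than both neighbours is
#' a candidate peak (reported at the run's central plane), and its
#' prominence is its height minus the higher of the two saddle minima
#' toward the nearest higher ground on either side. Peaks with prominence
#' below `min_prominence` are dropped; troughs are the minima between
#' consecutive retained peaks. Deterministic; a flat profile yields zero
#' peaks.
#'
#' @param profile a [depth_density_profile()] (absent planes count as 0)
#'   or a plain numeric vector.
#' @param min_prominence minimum prominence in density units
#'   (default 0.02).
#' @return object of class `plexus_findings`: data.frames `peaks`
#'   (`z`, `height`, `prominence`, `plexus` = NA until assigned) and
#'   `troughs` (`z`, `height`).
#' @export
find_peaks_troughs <- function(profile, min_prominence = 0.02) {
  if (inherits(profile, "depth_density_profile")) {
    d <- profile$density
    region <- attr(profile, "region")
    center <- attr(profile, "center")
  } else {
    d <- as.numeric(profile); region <- NA; center <- NULL
  }
  if (length(d) < 5) stop("profile needs at least 5 planes")
  d[is.na(d)] <- 0
  r <- rle(d)
  v <- r$values
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  nruns <- length(v)
  peaks <- data.frame(z = integer(0), height = numeric(0),
                      prominence = numeric(0))
  if (nruns >= 2) {
    for (i in seq_len(nruns)) {
      lo <- if (i > 1) v[i - 1] else -Inf
      hi <- if (i < nruns) v[i + 1] else -Inf
      if (!(v[i] > lo && v[i] > hi)) next
      if (i == 1 || i == nruns) next      # boundary runs are not peaks
      # prominence: saddle to nearest higher ground left and right
      left_min <- Inf
      j <- i - 1
      while (j >= 1 && v[j] < v[i]) { left_min <- min(left_min, v[j]); j <- j - 1 }
      if (j < 1) left_min <- min(left_min, min(v[seq_len(i - 1)]))
      right_min <- Inf
      j <- i + 1
      while (j <= nruns && v[j] < v[i]) { right_min <- min(right_min, v[j]); j <- j + 1 }
      if (j > nruns) right_min <- min(right_min, min(v[(i + 1):nruns]))
      prom <- v[i] - max(left_min, right_min)
      if (prom >= min_prominence) {
        zc <- floor((starts[i] + ends[i]) / 2)
        peaks <- rbind(peaks, data.frame(z = zc, height = v[i],
                                         prominence = prom))
      }
    }
  }
  troughs <- data.frame(z = integer(0), height = numeric(0))
  if (nrow(peaks) >= 2) {
    for (k in seq_len(nrow(peaks) - 1)) {
      seg <- peaks$z[k]:peaks$z[k + 1]
      zt <- seg[which.min(d[seg])]
      troughs <- rbind(troughs, data.frame(z = zt, height = min(d[seg])))
    }
  }
  peaks$plexus <- rep(NA_character_, nrow(peaks))
  structure(list(peaks = peaks, troughs = troughs, region = region,
                 center = center, min_prominence = min_prominence),
            class = "plexus_findings")
}

#' @export
print.plexus_findings <- function(x, ...) {
  cat(sprintf("<plexus_findings> region '%s': %d peak(s), %d trough(s)\n",
              x$region, nrow(x$peaks), nrow(x$troughs)))
  if (nrow(x$peaks)) print(x$peaks, row.names = FALSE)
  invisible(x)
}

#' Assign anatomic plexus labels to detected peaks
#'
#' Labels each peak by the anatomic band containing its depth: NFL band
#' (ILM to NFL/GCL) is RPCP; GCL band (NFL/GCL to the inner-80%-of-GCC
#' limit) is SVP; the deep vascular complex splits at mid-INL into ICP
#' and DCP — unless it contains exactly one peak sitting at mid-INL
#' (within 1.5 planes), which is labeled the merged ICP/DCP. Peaks
#' outside all bands stay "unassigned". Labels are invariant to uniform
#' rescaling of profile heights.
#'
#' @param findings output of [find_peaks_troughs()].
#' @param layers [layer_model()] in the same (normalized) depth frame.
#' @param region region label (the peripapillary region legitimately
#'   shows RPCP and SVP without an intervening trough; labeling is by
#'   band either way).
#' @param center optional `c(x_mm, y_mm)`; boundaries are averaged over
#'   the profile's sampling window when the findings carry one.
#' @param volume optional volume for window-to-pixel conversion.
#' @return the findings with `peaks$plexus` filled and a `plexus_count`.
#' @export
assign_plexus_labels <- function(findings, layers, region = findings$region,
                                 center = findings$center, volume = NULL) {
  sel <- NULL
  if (!is.null(center) && !is.null(volume)) {
    w <- window_columns(volume, center, c(0.1, 0.8))
    d2 <- dim(layers$surfaces$ILM)
    sel <- as.vector(outer(w$ix, (w$iy - 1) * d2[1], "+"))
  }
  b <- mean_boundaries(layers, sel)
  gcc80 <- b[["ILM"]] + 0.8 * (b[["IPL_INL"]] - b[["ILM"]])
  mid_inl <- (b[["IPL_INL"]] + b[["INL_OPL"]]) / 2
  pk <- findings$peaks
  lab <- rep("unassigned", nrow(pk))
  z <- pk$z
  lab[z >= b[["ILM"]] & z < b[["NFL_GCL"]]] <- "RPCP"
  lab[z >= b[["NFL_GCL"]] & z < gcc80] <- "SVP"
  in_dvc <- z >= gcc80 & z < b[["OPL_ONL"]]
  if (sum(in_dvc) == 1 && abs(z[in_dvc] - mid_inl) <= 1.5) {
    lab[in_dvc] <- "merged ICP/DCP"
  } else {
    lab[in_dvc & z < mid_inl] <- "ICP"
    lab[in_dvc & z >= mid_inl] <- "DCP"
  }
  pk$plexus <- lab
  findings$peaks <- pk
  findings$region <- region
  findings$plexus_count <- length(unique(lab[lab != "unassigned"]))
  findings
}

#' Estimate the ICP/DCP merge eccentricity
#'
#' Given depth profiles ordered by eccentricity along the
#' macula-to-periphery axis, counts the peaks inside the deep vascular
#' complex band for each and returns the smallest eccentricity from
#' which every profile at or beyond it has exactly one DVC peak. Returns
#' NA when the plexuses never merge. A non-monotone peak count (noise)
#' takes the last transition and flags instability. Windows intersecting
#' the foveal avascular zone ring should be excluded by the caller (the
#' estimate concerns the temporal periphery).
#'
#' @param profiles list of [depth_density_profile()]s.
#' @param layers [layer_model()] in the same depth frame.
#' @param eccentricities numeric vector (mm), same length; defaults to
#'   the profiles' stored x centers.
#' @param min_prominence passed to [find_peaks_troughs()].
#' @param volume optional volume for window-local boundaries.
#' @return eccentricity in mm (NA_real_ if never merged), with
#'   attributes `peak_counts` and `stable`.
#' @export
estimate_merge_eccentricity <- function(profiles, layers,
                                        eccentricities = NULL,
                                        min_prominence = 0.02,
                                        volume = NULL) {
  if (length(profiles) < 5)
    stop("need >= 5 profiles spanning the macula-to-periphery axis")
  if (is.null(eccentricities))
    eccentricities <- vapply(profiles, function(p) attr(p, "center")[1],
                             numeric(1))
  ord <- order(eccentricities)
  profiles <- profiles[ord]; eccentricities <- eccentricities[ord]
  counts <- vapply(seq_along(profiles), function(i) {
    f <- find_peaks_troughs(profiles[[i]], min_prominence)
    f <- assign_plexus_labels(f, layers, center = attr(profiles[[i]], "center"),
                              volume = volume)
    sum(f$peaks$plexus %in% c("ICP", "DCP", "merged ICP/DCP"))
  }, numeric(1))
  merged <- counts == 1
  est <- NA_real_; stable <- TRUE
  if (any(merged)) {
    # last transition into the merged state that persists to the edge
    idx <- max(which(!merged), 0)
    if (idx == length(merged)) {
      est <- NA_real_                      # outermost profile not merged
    } else {
      est <- eccentricities[idx + 1]
      stable <- all(merged[seq(idx + 1, length(merged))]) &&
        !any(merged[seq_len(idx)])
    }
  }
  structure(est, peak_counts = counts, eccentricities = eccentricities,
            stable = stable)
}
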