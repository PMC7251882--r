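#' Weighted Ks histogram of duplication events
#'
#' Accumulates node weights (so the y-axis counts duplication events,
#' not duplicate pairs) into bins over `(0, max_ks]`.
#'
#' @param events data.frame with columns `ks` and `weight` (e.g. from
#'   [weight_ks_by_node()] or [simulate_paranome_ks()]), pre-filtered to
#'   the `(0, max_ks]` range.
#' @param bin_width positive bin width.
#' @param max_ks upper end of the binned range.
#' @param provenance `"whole_paranome"` or `"anchors_only"` label.
#' @return object of class `ks_histogram`: list with `edges` (length
#'   `nbin + 1`), `counts` (weighted, right-closed bins), `total_weight`,
#'   `bin_width`, `provenance`.
#' @export
build_ks_histogram <- function(events, bin_width = 0.1, max_ks = 5,
                               provenance = "whole_paranome") {
  if (bin_width <= 0) stop("bin width must be positive")
  ks <- events$ks
  w <- events$weight %||% rep(1, length(ks))
  if (any(ks <= 0 | ks > max_ks)) stop("events must be pre-filtered to (0, max_ks]")
  nb <- ceiling(max_ks / bin_width)
  idx <- pmin(ceiling(ks / bin_width), nb)
  counts <- vapply(seq_len(nb), function(i) sum(w[idx == i]), numeric(1))
  structure(list(edges = seq(0, by = bin_width, length.out = nb + 1L),
                 counts = counts, total_weight = sum(w), bin_width = bin_width,
                 provenance = provenance),
            class = "ks_histogram")
}

#' @export
print.ks_histogram <- function(x, ...) {
  cat("Ks histogram (", x$provenance, "): ", length(x$counts), " bins of ",
      x$bin_width, ", total event weight ", round(x$total_weight, 3), "\n", sep = "")
  invisible(x)
}

#' @export
plot.ks_histogram <- function(x, main = x$provenance, ...) {
  graphics::barplot(x$counts, width = x$bin_width, space = 0,
                    names.arg = NULL, xlab = "Ks", ylab = "duplication events",
                    main = main, col = "orangered", border = NA, ...)
  graphics::axis(1, at = pretty(x$edges), labels = pretty(x$edges))
  invisible(x)
}

#' Detect WGD-candidate peaks in a weighted Ks distribution
#'
#' Estimates a Gaussian-kernel density of the weighted duplication
#' events (bandwidth by Silverman's rule on the weighted sample, floored
#' at 0.05 Ks) and reports interior local maxima: modes located beyond
#' the boundary-exclusion window (the L-shaped small-scale-duplication
#' mode near Ks = 0 must not be called a WGD peak) whose topographic
#' prominence exceeds a fraction of the maximum interior density.
#'
#' @param events data.frame with `ks` and `weight` columns.
#' @param bw kernel bandwidth; `NULL` for the weighted Silverman rule.
#' @param bw_floor lower bound on the bandwidth (Ks units).
#' @param prominence_frac minimal prominence, as a fraction of the
#'   maximum interior density.
#' @param boundary peaks at Ks below this are treated as the SSD boundary
#'   mode and excluded.
#' @param min_total_weight minimum total event weight required.
#' @param max_ks upper end of the evaluated range.
#' @return data.frame of class `ks_peaks`: `location`, `height`,
#'   `prominence`, `mass_share` (event-weight fraction inside the
#'   supporting interval), `lo`, `hi` (supporting interval between the
#'   flanking density minima).
#' @export
detect_ks_peaks <- function(events, bw = NULL, bw_floor = 0.05,
                            prominence_frac = 0.10, boundary = 0.1,
                            min_total_weight = 200, max_ks = 5) {
  ks <- events$ks
  w <- events$weight %||% rep(1, length(ks))
  if (sum(w) < min_total_weight)
    stop("insufficient events: total weight ", round(sum(w), 1), " < ",
         min_total_weight)
  if (is.null(bw)) {
    wm <- sum(w * ks) / sum(w)
    wsd <- sqrt(sum(w * (ks - wm)^2) / sum(w))
    neff <- sum(w)^2 / sum(w^2)
    bw <- 0.9 * wsd * neff^(-1/5)
  }
  bw <- max(bw, bw_floor)
  # reflection at Ks = 0 keeps the L-shaped SSD mode at the boundary
  # instead of letting smoothing push it into the interior
  d <- stats::density(c(ks, -ks), weights = rep(w / (2 * sum(w)), 2), bw = bw,
                      from = 0, to = max_ks, n = 512)
  d$y <- 2 * d$y
  y <- d$y; x <- d$x
  interior <- x > boundary
  ymax <- max(y[interior])
  locmax <- which(diff(sign(diff(y))) < 0) + 1L
  locmax <- locmax[x[locmax] > boundary]
  locmin <- c(1L, which(diff(sign(diff(y))) > 0) + 1L, length(y))
  peaks <- lapply(locmax, function(i) {
    left <- max(locmin[locmin < i])
    right <- min(locmin[locmin > i])
    prom <- y[i] - max(y[left], y[right])
    data.frame(location = x[i], height = y[i], prominence = prom,
               lo = x[left], hi = x[right])
  })
  peaks <- if (length(peaks)) do.call(rbind, peaks) else
    data.frame(location = numeric(), height = numeric(), prominence = numeric(),
               lo = numeric(), hi = numeric())
  peaks <- peaks[peaks$prominence >= prominence_frac * ymax, , drop = FALSE]
  peaks$mass_share <- vapply(seq_len(nrow(peaks)), function(i)
    sum(w[ks > peaks$lo[i] & ks <= peaks$hi[i]]) / sum(w), numeric(1))
  peaks <- peaks[order(-peaks$height),
                 c("location", "height", "prominence", "mass_share", "lo", "hi")]
  rownames(peaks) <- NULL
  class(peaks) <- c("ks_peaks", class(peaks))
  attr(peaks, "bw") <- bw
  peaks
}

#' Decision framework: WGD versus segmental burst versus background SSD
#'
#' Applies the decision table distinguishing a whole-genome duplication
#' signature from a burst of segmental duplication or plain continuous
#' small-scale duplication:
#' \itemize{
#'   \item `WGD_consistent` — an interior paranome Ks peak exists, the
#'     anchor-pair Ks mass concentrates inside that peak's supporting
#'     interval (at least `anchor_mass_frac`), and at least `inter_frac`
#'     of the co-linear blocks lie on different scaffolds (under
#'     fragmented assemblies, genuine WGD blocks reside on different
#'     scaffolds).
#'   \item `segmental_burst` — co-linear blocks exist but the anchor-Ks
#'     clustering or the inter-scaffold condition fails (e.g. recent
#'     blocks with no corresponding paranome peak, or blocks organized
#'     as palindromes/tandem arrays within scaffolds).
#'   \item `SSD_like` — neither blocks nor an interior peak.
#'   \item `inconclusive` — anything else (e.g. a peak without blocks).
#' }
#'
#' @param paranome_peaks result of [detect_ks_peaks()] on the whole
#'   paranome (may have zero rows).
#' @param anchor_events data.frame with `ks` and `weight` of anchor-pair
#'   duplication events (may be empty).
#' @param block_topology character vector (or table) of block topology
#'   labels (`inter_scaffold`, `tandem_array`, `palindrome`); may be
#'   empty.
#' @param anchor_mass_frac,inter_frac decision-table thresholds.
#' @return object of class `signature_verdict`: list with `label` and the
#'   `evidence` record the label is a pure function of.
#' @export
assess_duplication_signature <- function(paranome_peaks, anchor_events,
                                         block_topology,
                                         anchor_mass_frac = 0.5,
                                         inter_frac = 0.5) {
  topo <- as.character(block_topology)
  n_blocks <- length(topo)
  has_peak <- !is.null(paranome_peaks) && nrow(paranome_peaks) > 0
  anchor_clustered <- FALSE
  anchor_mass <- NA_real_
  if (has_peak && !is.null(anchor_events) && nrow(anchor_events) > 0) {
    top <- paranome_peaks[1, ]
    w <- anchor_events$weight %||% rep(1, nrow(anchor_events))
    anchor_mass <- sum(w[anchor_events$ks > top$lo & anchor_events$ks <= top$hi]) / sum(w)
    anchor_clustered <- anchor_mass >= anchor_mass_frac
  }
  inter_fraction <- if (n_blocks) mean(topo == "inter_scaffold") else NA_real_
  inter_ok <- isTRUE(inter_fraction >= inter_frac)
  label <- if (n_blocks > 0 && has_peak && anchor_clustered && inter_ok) {
    "WGD_consistent"
  } else if (n_blocks > 0) {
    "segmental_burst"
  } else if (!has_peak) {
    "SSD_like"
  } else "inconclusive"
  structure(list(label = label,
                 evidence = list(has_peak = has_peak,
                                 peak_location = if (has_peak) paranome_peaks$location[1] else NA_real_,
                                 anchor_mass = anchor_mass,
                                 anchor_clustered = anchor_clustered,
                                 n_blocks = n_blocks,
                                 inter_scaffold_fraction = inter_fraction,
                                 inter_ok = inter_ok,
                                 thresholds = c(anchor_mass_frac = anchor_mass_frac,
                                                inter_frac = inter_frac))),
            class = "signature_verdict")
}

#' @export
print.signature_verdict <- function(x, ...) {
  e <- x$evidence
  cat("Duplication-signature verdict:", x$label, "\n")
  cat(sprintf("  paranome peak: %s%s\n",
              if (e$has_peak) "yes" else "no",
              if (e$has_peak) sprintf(" (Ks ~ %.2f)", e$peak_location) else ""))
  cat(sprintf("  anchor Ks mass in peak: %s (clustered: %s)\n",
              ifelse(is.na(e$anchor_mass), "-", sprintf("%.2f", e$anchor_mass)),
              e$anchor_clustered))
  cat(sprintf("  blocks: %d, inter-scaffold fraction: %s\n", e$n_blocks,
              ifelse(is.na(e$inter_scaffold_fraction), "-",
                     sprintf("%.2f", e$inter_scaffold_fraction))))
  invisible(x)
}
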