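#' Simulate a per-base read-coverage track with haplotig segments
#'
#' Background depths are drawn around `base_depth`; with
#' `overdispersion = 0` the track is exactly `base_depth` everywhere,
#' otherwise depths follow a negative binomial with mean `m` and variance
#' `m + overdispersion * m^2` (always exceeding the Poisson variance).
#' Haplotig segments — regions representing an uncollapsed alternate
#' haplotype — are drawn around `base_depth * depth_fraction`.
#'
#' @param scaffold_lengths named integer vector of scaffold lengths (bp).
#' @param base_depth expected background depth (integer for the
#'   deterministic `overdispersion = 0` case).
#' @param overdispersion non-negative dispersion parameter (see above).
#' @param haplotig_segments `NULL` or data.frame with columns `scaffold`,
#'   `start`, `end` (1-based, closed), `depth_fraction` in `(0, 1]`.
#' @param seed integer seed.
#' @return object of class `coverage_track`: list with `depths` (named
#'   list of integer vectors) and `haplotigs` (the segment registry).
#' @examples
#' trk <- simulate_coverage_track(c(s1 = 1000), 100, 0.05,
#'   data.frame(scaffold = "s1", start = 401, end = 600, depth_fraction = 0.5),
#'   seed = 1)
#' mean(trk$depths$s1[401:600]) / mean(trk$depths$s1[1:400])
#' @export
simulate_coverage_track <- function(scaffold_lengths, base_depth = 100,
                                    overdispersion = 0, haplotig_segments = NULL,
                                    seed = NULL) {
  if (any(scaffold_lengths <= 0)) stop("scaffold lengths must be positive")
  if (overdispersion < 0) stop("overdispersion must be non-negative")
  if (!is.null(seed)) set.seed(seed)
  draw <- function(n, m) {
    if (overdispersion == 0) rep(as.integer(round(m)), n)
    else as.integer(stats::rnbinom(n, size = 1 / overdispersion, mu = m))
  }
  depths <- lapply(scaffold_lengths, function(L) draw(L, base_depth))
  names(depths) <- names(scaffold_lengths)
  if (!is.null(haplotig_segments)) {
    for (i in seq_len(nrow(haplotig_segments))) {
      h <- haplotig_segments[i, ]
      if (h$depth_fraction <= 0 || h$depth_fraction > 1)
        stop("depth_fraction must lie in (0, 1]")
      L <- scaffold_lengths[[h$scaffold]]
      if (is.null(L) || h$start < 1 || h$end > L || h$start > h$end)
        stop("haplotig segment outside scaffold bounds")
      idx <- h$start:h$end
      depths[[h$scaffold]][idx] <- draw(length(idx), base_depth * h$depth_fraction)
    }
  }
  structure(list(depths = depths,
                 haplotigs = haplotig_segments %||%
                   data.frame(scaffold = character(), start = integer(),
                              end = integer(), depth_fraction = numeric())),
            class = "coverage_track")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.coverage_track <- function(x, ...) {
  cat("Coverage track:", length(x$depths), "scaffolds,",
      sum(lengths(x$depths)), "bp; ",
      nrow(x$haplotigs), "haplotig segment(s)\n")
  invisible(x)
}
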