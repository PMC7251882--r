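#' Simulate a paranome Ks age distribution
#'
#' Draws duplication-event ages (in Ks units) from a mixture of a
#' quasi-exponential small-scale-duplication (SSD) background — duplicate
#' survival decaying exponentially with age, giving the L-shaped
#' distribution characteristic of continuous duplication and loss — and
#' optional Gaussian WGD pulses truncated to `(0, 5]`.
#'
#' The SSD decay law is a modeling convention: continuous duplication at
#' constant intensity with exponential survival per unit Ks; no specific
#' generative law is implied by the L-shape itself.
#'
#' @param background_size relative mass of the SSD background component.
#' @param loss_hazard exponential decay rate of the background in 1/Ks.
#' @param wgd_pulses `NULL` or data.frame with columns `mean`, `sd`,
#'   `size` (relative masses); pulse means must lie in `(0, 5]`.
#' @param n_events total number of events to draw.
#' @param seed integer seed.
#' @return data.frame with columns `ks`, `weight` (all 1) and `component`
#'   (`"background"` or `"pulse<i>"`).
#' @examples
#' ks <- simulate_paranome_ks(1, 1.5, data.frame(mean = .8, sd = .1, size = .25),
#'                            n_events = 1000, seed = 1)
#' table(ks$component)
#' @export
simulate_paranome_ks <- function(background_size = 1, loss_hazard = 1,
                                 wgd_pulses = NULL, n_events = 1000, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sizes <- c(background = background_size,
             if (!is.null(wgd_pulses)) stats::setNames(wgd_pulses$size,
                                                       paste0("pulse", seq_len(nrow(wgd_pulses)))))
  if (any(sizes < 0)) stop("component sizes must be non-negative")
  if (sum(sizes) <= 0) stop("all component sizes are zero")
  if (!is.null(wgd_pulses) && any(wgd_pulses$mean <= 0 | wgd_pulses$mean > 5))
    stop("pulse means must lie in (0, 5]")
  n_comp <- stats::rmultinom(1L, n_events, sizes / sum(sizes))[, 1]
  out <- list()
  if (n_comp[1] > 0) {
    x <- rtrunc(n_comp[1], function(n) stats::rexp(n, loss_hazard))
    out[[1]] <- data.frame(ks = x, weight = 1, component = "background")
  }
  if (!is.null(wgd_pulses)) {
    for (i in seq_len(nrow(wgd_pulses))) {
      ni <- n_comp[i + 1L]
      if (ni == 0) next
      x <- rtrunc(ni, function(n) stats::rnorm(n, wgd_pulses$mean[i], wgd_pulses$sd[i]))
      out[[length(out) + 1L]] <- data.frame(ks = x, weight = 1,
                                            component = paste0("pulse", i))
    }
  }
  do.call(rbind, out)
}

# rejection sampling into (0, 5]
rtrunc <- function(n, rfun) {
  x <- rfun(n)
  bad <- x <= 0 | x > 5
  while (any(bad)) {
    x[bad] <- rfun(sum(bad))
    bad <- x <= 0 | x > 5
  }
  x
}
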