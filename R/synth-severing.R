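# Poisson severing-event simulator: per-cell event counts are
# Poisson(rate x area x duration), positions uniform within each (circular
# stand-in) cell, times uniform over the observation window.

#' Specification of a simulated severing-event series
#'
#' @param rate severing rate (events per um^2 per minute, >= 0).
#' @param cell_areas observed cell areas (um^2).
#' @param duration observation duration (minutes, > 0); recycled per cell.
#' @param seed RNG seed.
#' @return a `severing_sim_spec`.
#' @export
severing_sim_spec <- function(rate, cell_areas, duration, seed = 1L) {
  stopifnot(rate >= 0, all(cell_areas > 0), all(duration > 0))
  structure(list(rate = rate, cell_areas = as.numeric(cell_areas),
                 duration = rep_len(as.numeric(duration), length(cell_areas)),
                 seed = as.integer(seed)),
            class = "severing_sim_spec")
}

#' Simulate severing events
#'
#' @param spec a [severing_sim_spec()].
#' @return a `severing_record`: `events` data.frame (`cell`, `x`, `y`, `t`),
#'   `cell_areas`, `duration`.
#' @export
make_severing_series <- function(spec) {
  stopifnot(inherits(spec, "severing_sim_spec"))
  with_seed(spec$seed, {
    n_cells <- length(spec$cell_areas)
    rows <- vector("list", n_cells)
    for (ci in seq_len(n_cells)) {
      lam <- spec$rate * spec$cell_areas[ci] * spec$duration[ci]
      k <- if (lam > 0) rpois(1L, lam) else 0L
      if (k == 0L) next
      r <- sqrt(spec$cell_areas[ci] / pi) * sqrt(runif(k))
      a <- runif(k, 0, 2 * pi)
      rows[[ci]] <- data.frame(cell = ci, x = r * cos(a), y = r * sin(a),
                               t = runif(k, 0, spec$duration[ci]))
    }
    ev <- if (any(!vapply(rows, is.null, TRUE)))
      do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
    else data.frame(cell = integer(0), x = numeric(0), y = numeric(0),
                    t = numeric(0))
    rownames(ev) <- NULL
    structure(list(events = ev, cell_areas = spec$cell_areas,
                   duration = spec$duration),
              class = "severing_record")
  })
}
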