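#' Best frequency, octave bandwidth and latency of an STRF
#'
#' Operationalizes the standard tuning summaries on a coefficient grid:
#' the best frequency (BF) is the center frequency of the cell with the
#' largest positive coefficient, and the peak latency is that cell's lag.
#' The bandwidth (BW) is measured at the peak's lag as the contiguous
#' run of channels through the peak whose coefficients exceed
#' `threshold_frac` of the peak (half-height by default), reported in
#' octaves `log2(f_hi / f_lo)` over the run's extreme center frequencies.
#' A run confined to a single channel is reported at one-channel
#' resolution: the octave span between the geometric midpoints to its
#' neighbouring channels. Excitatory/suppressive masks mark the connected
#' component (4-neighbour) of positive cells containing the peak and all
#' negative cells respectively.
#'
#' With `all_components = TRUE` one row is returned per disjoint
#' excitatory component (multiple best frequencies), ranked by peak
#' value.
#'
#' @param beta an `F x T` STRF grid (frequency ascending by row), or an
#'   `strf_fit`.
#' @param map the [make_cochleotopic_map()] the grid rows refer to.
#' @param lags the [lag_grid()] the grid columns refer to.
#' @param threshold_frac half-height fraction for the bandwidth run
#'   (default 0.5).
#' @param all_components report every excitatory component rather than
#'   only the global peak's.
#' @return A tibble of class `strf_features` with columns `component`,
#'   `best_frequency_hz`, `bandwidth_octaves`, `peak_latency_s`,
#'   `peak_value`, `single_channel` (bandwidth reported at one-channel
#'   resolution), and attributes `excitatory_mask`, `suppressive_mask`
#'   (disjoint `F x T` logical grids).
#' @export
extract_features <- function(beta, map, lags, threshold_frac = 0.5,
                             all_components = FALSE) {
  if (inherits(beta, "strf_fit")) beta <- beta$coefficients$beta
  if (all(beta == 0)) rlang::abort("all-zero grid: no receptive field")
  if (max(beta) <= 0) rlang::abort("no positive coefficients: no excitatory field")
  freqs <- channel_freqs(map)
  stopifnot(nrow(beta) == length(freqs), ncol(beta) == lags$n_lags)
  comp <- .connected_components(beta > 0)
  peak_of <- function(cid) {
    cells <- which(comp == cid, arr.ind = TRUE)
    vals <- beta[cells]
    k <- which.max(vals)
    list(f = unname(cells[k, 1]), t = unname(cells[k, 2]), v = vals[k])
  }
  ids <- sort(unique(comp[comp > 0]))
  peaks <- lapply(ids, peak_of)
  ord <- order(-vapply(peaks, `[[`, numeric(1), "v"))
  ids <- ids[ord]; peaks <- peaks[ord]
  if (!all_components) { ids <- ids[1]; peaks <- peaks[1] }
  rows <- purrr::map2(ids, peaks, function(cid, pk) {
    col <- beta[, pk$t]
    above <- col > threshold_frac * pk$v
    lo <- pk$f; while (lo > 1 && above[lo - 1]) lo <- lo - 1
    hi <- pk$f; while (hi < length(col) && above[hi + 1]) hi <- hi + 1
    single <- lo == hi
    if (single) {
      f_lo <- if (lo > 1) sqrt(freqs[lo - 1] * freqs[lo]) else freqs[lo]
      f_hi <- if (hi < length(freqs)) sqrt(freqs[hi] * freqs[hi + 1])
              else freqs[hi]
    } else {
      f_lo <- freqs[lo]; f_hi <- freqs[hi]
    }
    tibble::tibble(component = cid,
                   best_frequency_hz = freqs[pk$f],
                   bandwidth_octaves = log2(f_hi / f_lo),
                   peak_latency_s = (pk$t - 1) * lags$lag_step_s,
                   peak_value = pk$v,
                   single_channel = single)
  })
  out <- dplyr::bind_rows(rows)
  gp <- peaks[[1]]
  attr(out, "excitatory_mask") <- comp == comp[gp$f, gp$t]
  attr(out, "suppressive_mask") <- beta < 0
  class(out) <- c("strf_features", class(out))
  out
}

# 4-neighbour connected component labelling of a logical matrix
.connected_components <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  cur <- 0L
  for (j in seq_len(ncol(mask))) for (i in seq_len(nrow(mask))) {
    if (mask[i, j] && lab[i, j] == 0L) {
      cur <- cur + 1L
      stack <- list(c(i, j))
      while (length(stack)) {
        cell <- stack[[length(stack)]]
        stack[[length(stack)]] <- NULL
        a <- cell[1]; b <- cell[2]
        if (a < 1 || b < 1 || a > nrow(mask) || b > ncol(mask)) next
        if (!mask[a, b] || lab[a, b] != 0L) next
        lab[a, b] <- cur
        stack <- c(stack, list(c(a - 1, b), c(a + 1, b),
                               c(a, b - 1), c(a, b + 1)))
      }
    }
  }
  lab
}
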