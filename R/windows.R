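#' Tile chromosomes with sliding windows
#'
#' Windows of `window_size` bp start every `step` bp from position 0
#' (0-based, half-open intervals). After the last full window, one truncated
#' window is appended when the remaining stretch is at least `step` long, so
#' that every base pair is covered under the default `window_size = 2 * step`
#' geometry. A chromosome shorter than one window yields a single truncated
#' window `[0, length)`.
#'
#' @param chrom_lengths Named numeric vector of chromosome lengths (bp).
#' @param window_size Window width in bp (default 10000).
#' @param step Step between window starts in bp (default 5000; must be
#'   `<= window_size`).
#' @return Tibble with `chrom`, `start`, `end` (0-based half-open), carrying
#'   `window_size` and `step` as attributes.
#' @export
#' @examples
#' make_windows(c(chr1 = 25000))
make_windows <- function(chrom_lengths, window_size = 10000, step = 5000) {
  stopifnot(all(chrom_lengths > 0), step <= window_size, step > 0)
  out <- purrr::map(names(chrom_lengths), function(ch) {
    len <- chrom_lengths[[ch]]
    if (len <= window_size) {
      starts <- 0
      ends <- len
    } else {
      k_max <- floor((len - window_size) / step)
      starts <- seq(0, k_max) * step
      ends <- starts + window_size
      if (ends[length(ends)] < len) {
        cand <- (k_max + 1) * step
        if (len - cand >= step) {
          starts <- c(starts, cand)
          ends <- c(ends, len)
        }
      }
    }
    tibble::tibble(chrom = ch, start = as.numeric(starts),
                   end = as.numeric(ends))
  })
  w <- dplyr::bind_rows(out)
  attr(w, "window_size") <- window_size
  attr(w, "step") <- step
  w
}

# Map site positions (1-based) onto sliding-window row indices.
# Returns a tibble (site = row index into `sites`, window = row index into
# `windows`); a site lands in every window whose half-open interval covers
# it (two windows under the default half-overlapping geometry).
site_window_map <- function(sites, windows) {
  ws <- attr(windows, "window_size")
  step <- attr(windows, "step")
  if (is.null(ws) || is.null(step)) {
    abort("windows must come from make_windows()")
  }
  win_idx <- split(seq_len(nrow(windows)), windows$chrom)
  pieces <- purrr::map(names(win_idx), function(ch) {
    rows <- win_idx[[ch]]
    n_w <- length(rows)
    s_idx <- which(sites$chrom == ch)
    if (length(s_idx) == 0) return(NULL)
    pos0 <- sites$pos[s_idx] - 1  # 0-based
    k_hi <- pmin(n_w - 1, floor(pos0 / step))
    k_lo <- pmax(0, floor((pos0 - ws) / step) + 1)
    reps <- pmax(0L, as.integer(k_hi - k_lo + 1))
    site <- rep(s_idx, reps)
    k <- unlist(purrr::map2(k_lo, k_hi, function(a, b) {
      if (b < a) integer() else seq(a, b)
    }))
    tibble::tibble(site = site, window = rows[k + 1L])
  })
  out <- dplyr::bind_rows(pieces)
  if (nrow(out) == 0) {
    return(tibble::tibble(site = integer(), window = integer()))
  }
  # guard: drop site/window pairs outside the actual interval (truncated tail)
  keep <- sites$pos[out$site] - 1 >= windows$start[out$window] &
    sites$pos[out$site] - 1 < windows$end[out$window]
  out[keep, , drop = FALSE]
}
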