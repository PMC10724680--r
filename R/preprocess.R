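# In-scope preprocessing: median intensity normalization, pad/crop to a
# cubic grid without losing brain voxels, and brain-intensity histograms.
# Skull-stripping, bias-field correction and registration are upstream,
# external steps; this module consumes already masked, registered volumes.

#' Median intensity normalization
#'
#' Rescales a volume so the median of its brain voxels equals `target`
#' (default 500). A pure rescaling: `output = input * target / median`;
#' background voxels (zero) are unchanged. Median normalization is less
#' sensitive to outliers than maximum normalization.
#'
#' @param vol a [volume()] with a nonempty mask.
#' @param target target brain median intensity.
#' @return a [volume()].
#' @export
normalize_median <- function(vol, target = 500) {
  bv <- brain_values(vol)
  med <- stats::median(bv)
  if (!is.finite(med) || med <= 0)
    stop("degenerate input: brain median is not positive")
  out <- vol$data * (target / med)
  volume(out, mask = vol$mask, spacing = vol$spacing, affine = vol$affine)
}

#' Pad and crop to a cubic grid
#'
#' Pads and/or crops a volume to `target` voxels per axis without removing
#' any brain voxel. The brain bounding-box center is mapped to the grid
#' center, ties broken toward the lower index; padding value is 0. Refuses
#' (rather than silently cropping brain) when the brain extent exceeds
#' `target` on any axis.
#'
#' @param vol a [volume()] with a nonempty mask.
#' @param target output edge length in voxels (default 192).
#' @return a [volume()] with dimensions `target^3`.
#' @export
pad_crop <- function(vol, target = 192L) {
  if (is.null(vol$mask) || !any(vol$mask > 0))
    stop("pad_crop requires a nonempty brain mask")
  target <- as.integer(target)
  d <- dim(vol$data)
  idx <- which(vol$mask > 0, arr.ind = TRUE)
  lo <- apply(idx, 2L, min)
  hi <- apply(idx, 2L, max)
  if (any(hi - lo + 1L > target))
    stop("brain extent (", paste(hi - lo + 1L, collapse = "x"),
         ") exceeds target ", target, " on at least one axis")
  bctr <- (lo + hi) %/% 2L                  # tie toward lower index
  tctr <- (1L + target) %/% 2L
  off <- tctr - bctr                        # input i -> output i + off

  out <- array(0, dim = rep(target, 3L))
  outm <- array(0, dim = rep(target, 3L))
  src <- lapply(1:3, function(a) {
    i <- seq_len(d[a])
    i[i + off[a] >= 1L & i + off[a] <= target]
  })
  dst <- lapply(1:3, function(a) src[[a]] + off[a])
  out[dst[[1]], dst[[2]], dst[[3]]] <- vol$data[src[[1]], src[[2]], src[[3]]]
  outm[dst[[1]], dst[[2]], dst[[3]]] <- vol$mask[src[[1]], src[[2]], src[[3]]]
  if (sum(outm) != sum(vol$mask))
    stop("internal error: pad_crop lost brain voxels")   # nocov
  volume(out, mask = outm, spacing = vol$spacing, affine = vol$affine)
}

#' Brain intensity histogram
#'
#' Histogram of brain-voxel intensities over `n_bins` consecutive bins from
#' `lo` to `hi` (default: 100 bins from 0 to 900). Bins are half-open
#' `[edge_i, edge_{i+1})`, the last bin closed at `hi`. Voxels outside
#' `[lo, hi]` are ignored (not clipped); their count is recorded.
#'
#' @param vol a [volume()] with a nonempty mask.
#' @param n_bins number of bins.
#' @param lo,hi intensity range.
#' @return an object of class `histogram_summary` with fields `counts`,
#'   `edges` and `n_ignored`.
#' @export
brain_histogram <- function(vol, n_bins = 100L, lo = 0, hi = 900) {
  bv <- brain_values(vol)
  edges <- seq(lo, hi, length.out = n_bins + 1L)
  inside <- bv >= lo & bv <= hi
  bin <- findInterval(bv[inside], edges, rightmost.closed = TRUE)
  counts <- tabulate(bin, nbins = n_bins)
  histogram_summary(counts, edges, n_ignored = sum(!inside))
}

#' Construct a histogram summary
#' @param counts bin counts (or mean counts), length `length(edges) - 1`.
#' @param edges bin boundaries, increasing.
#' @param n_ignored number of voxels outside the range.
#' @return an object of class `histogram_summary`.
#' @export
histogram_summary <- function(counts, edges, n_ignored = 0L) {
  stopifnot(length(counts) == length(edges) - 1L, all(counts >= 0),
            !is.unsorted(edges))
  structure(list(counts = as.numeric(counts), edges = as.numeric(edges),
                 n_ignored = n_ignored), class = "histogram_summary")
}

#' Average a collection of histograms
#'
#' Elementwise arithmetic mean of the counts; all inputs must share edges.
#'
#' @param hists list of `histogram_summary` objects.
#' @return a `histogram_summary` of mean counts.
#' @export
average_histograms <- function(hists) {
  stopifnot(length(hists) >= 1L)
  e1 <- hists[[1]]$edges
  for (h in hists) {
    if (!isTRUE(all.equal(h$edges, e1)))
      stop("histograms have mismatched edges")
  }
  cm <- rowMeans(vapply(hists, function(h) h$counts,
                        numeric(length(hists[[1]]$counts))))
  histogram_summary(cm, e1,
                    n_ignored = mean(vapply(hists, function(h)
                      as.numeric(h$n_ignored), numeric(1))))
}

#' Write / read histograms as CSV (edges, counts)
#' @param h a `histogram_summary`.
#' @param path CSV path.
#' @return `read_histogram_csv` returns a `histogram_summary`.
#' @export
write_histogram_csv <- function(h, path) {
  utils::write.csv(data.frame(edge_lo = h$edges[-length(h$edges)],
                              edge_hi = h$edges[-1], count = h$counts),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_histogram_csv
#' @export
read_histogram_csv <- function(path) {
  tab <- utils::read.csv(path)
  histogram_summary(tab$count, c(tab$edge_lo, tab$edge_hi[nrow(tab)]))
}
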