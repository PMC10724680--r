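# Shared helpers: scoped seeding, separable Gaussian smoothing, flat
# key-value config files.

# Evaluate expr under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Draw independent sub-seeds from a master seed (kept below 2^31).
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

gauss_kernel <- function(sigma) {
  if (sigma <= 0) return(1)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k / sum(k)
}

# Smooth along the first axis of a 3D array with reflect padding.
smooth_axis1 <- function(a, kern) {
  L <- length(kern)
  if (L == 1L) return(a)
  r <- (L - 1L) %/% 2L
  d <- dim(a)
  n <- d[1L]
  m <- matrix(a, nrow = n)
  idx <- c(rev(seq_len(r) + 1L), seq_len(n), n - seq_len(r))
  mp <- m[idx, , drop = FALSE]
  out <- matrix(0, nrow = n, ncol = ncol(m))
  for (l in seq_len(L))
    out <- out + kern[l] * mp[seq_len(n) + (l - 1L), , drop = FALSE]
  array(out, dim = d)
}

# Separable 3D Gaussian smoothing (sigma in voxels, reflect boundaries).
gaussian_smooth3 <- function(a, sigma) {
  k <- gauss_kernel(sigma)
  a <- smooth_axis1(a, k)
  a <- aperm(smooth_axis1(aperm(a, c(2, 1, 3)), k), c(2, 1, 3))
  aperm(smooth_axis1(aperm(a, c(3, 2, 1)), k), c(3, 2, 1))
}

# Flat key = value config files: numerics parsed, comma lists become
# vectors, everything else stays character.
write_flat_config <- function(x, path) {
  lines <- vapply(names(x), function(nm) {
    v <- x[[nm]]
    paste0(nm, " = ", paste(format(v, scientific = FALSE, trim = TRUE),
                            collapse = ","))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

read_flat_config <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^\\s*#", lines)]
  out <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) < 2L) stop("malformed config line: ", ln)
    key <- trimws(kv[1])
    val <- trimws(paste(kv[-1], collapse = "="))
    parts <- trimws(strsplit(val, ",", fixed = TRUE)[[1]])
    num <- suppressWarnings(as.numeric(parts))
    out[[key]] <- if (!anyNA(num)) num else parts
  }
  out
}

# Single 6-connected component check via vectorized flood fill.
single_connected_component <- function(mask) {
  m <- mask > 0
  if (!any(m)) return(FALSE)
  d <- dim(m)
  seedpos <- which(m)[1]
  reach <- array(FALSE, dim = d)
  reach[seedpos] <- TRUE
  shift1 <- function(a, ax, by) {
    idx <- lapply(d, seq_len)
    src <- idx
    src[[ax]] <- pmin(pmax(idx[[ax]] - by, 1L), d[ax])
    out <- do.call(`[`, c(list(a), src))
    sel <- idx[[ax]] - by
    bad <- sel < 1L | sel > d[ax]
    if (any(bad)) {
      zer <- lapply(d, seq_len)
      zer[[ax]] <- which(bad)
      out <- array(out, dim = d)
      out <- do.call(`[<-`, c(list(out), zer, list(FALSE)))
    }
    array(out, dim = d)
  }
  repeat {
    grown <- reach
    for (ax in 1:3) for (by in c(-1L, 1L))
      grown <- grown | shift1(reach, ax, by)
    grown <- grown & m
    if (identical(grown, reach)) break
    reach <- grown
  }
  all(reach == m)
}

mask_touches_boundary <- function(mask) {
  d <- dim(mask)
  any(mask[c(1, d[1]), , ] > 0) || any(mask[, c(1, d[2]), ] > 0) ||
    any(mask[, , c(1, d[3])] > 0)
}
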