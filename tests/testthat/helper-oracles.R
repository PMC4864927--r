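# Independent brute-force oracles used to verify the package's
# implementations on small instances. These deliberately avoid the code
# paths they check.

# connected-component labeling by raster-scan flood fill
oracle_label <- function(mask, connectivity = 8L) {
  H <- nrow(mask); W <- ncol(mask)
  lab <- matrix(0L, H, W)
  steps <- if (connectivity == 8L) {
    list(c(-1, -1), c(-1, 0), c(-1, 1), c(0, -1), c(0, 1), c(1, -1), c(1, 0), c(1, 1))
  } else {
    list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  }
  k <- 0L
  for (r in seq_len(H)) for (co in seq_len(W)) {
    if (!mask[r, co] || lab[r, co] != 0L) next
    k <- k + 1L
    queue <- list(c(r, co)); lab[r, co] <- k
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      for (s in steps) {
        q <- p + s
        if (q[1] < 1 || q[1] > H || q[2] < 1 || q[2] > W) next
        if (mask[q[1], q[2]] && lab[q[1], q[2]] == 0L) {
          lab[q[1], q[2]] <- k
          queue[[length(queue) + 1]] <- q
        }
      }
    }
  }
  lab
}

# exact nearest-reference-pixel scan (distances in pixels): squared
# distance from every pixel to every reference pixel, minimized per pixel
oracle_edt <- function(ref) {
  H <- nrow(ref); W <- ncol(ref)
  idx <- which(ref, arr.ind = TRUE)
  r_all <- rep(seq_len(H), times = W)
  c_all <- rep(seq_len(W), each = H)
  best <- rep(Inf, H * W)
  for (j in seq_len(nrow(idx))) {
    d2 <- (r_all - idx[j, 1])^2 + (c_all - idx[j, 2])^2
    best <- pmin(best, d2)
  }
  matrix(sqrt(best), H, W)
}

# normalized cross-correlation over all integer shifts in +/- S
oracle_ncc <- function(fixed, moving, S) {
  H <- nrow(fixed); W <- ncol(fixed)
  shifts <- -S:S
  ncc <- matrix(NA_real_, length(shifts), length(shifts),
                dimnames = list(shifts, shifts))
  for (i in seq_along(shifts)) for (j in seq_along(shifts)) {
    dy <- shifts[i]; dx <- shifts[j]
    rs <- max(1, 1 + dy):min(H, H + dy)
    cs <- max(1, 1 + dx):min(W, W + dx)
    f <- as.vector(fixed[rs, cs])
    m <- as.vector(moving[rs - dy, cs - dx])
    if (length(f) >= 2 && stats::sd(f) > 0 && stats::sd(m) > 0) {
      ncc[i, j] <- stats::cor(f, m)
    }
  }
  ncc
}

# one-way ANOVA from explicit sums of squares
oracle_anova <- function(groups) {
  x <- unlist(groups, use.names = FALSE)
  ns <- lengths(groups)
  k <- length(groups); N <- length(x)
  gm <- mean(x)
  ssb <- sum(ns * (vapply(groups, mean, numeric(1)) - gm)^2)
  ssw <- sum(unlist(lapply(groups, function(v) (v - mean(v))^2)))
  f <- (ssb / (k - 1)) / (ssw / (N - k))
  list(F = f, p = stats::pf(f, k - 1, N - k, lower.tail = FALSE),
       df_between = as.integer(k - 1), df_within = as.integer(N - k))
}

# expected distance-binned means implied by the ground truth: sigmoid of
# the true distance field, quantized like the generator, averaged over
# the same left-closed bins
oracle_profile_expectation <- function(d_um, params, viable, bin_width_um,
                                       max_distance_um, quantize = TRUE) {
  n_bins <- ceiling(max_distance_um / bin_width_um)
  sel <- viable & (d_um < max_distance_um)
  d <- d_um[sel]
  val <- params$I0 + (params$Imax - params$I0) / (1 + exp(-(d - params$d0) / params$s))
  if (quantize) val <- round(pmin(pmax(val, 0), 65535))
  bin <- pmin(floor(d / bin_width_um), n_bins - 1L) + 1L
  cnt <- tabulate(bin, nbins = n_bins)
  sums <- numeric(n_bins)
  s <- rowsum(val, bin)
  sums[as.integer(rownames(s))] <- s[, 1]
  list(mean = ifelse(cnt > 0, sums / cnt, NA_real_), count = cnt)
}

# small fast generator settings shared by tests (override freely)
tiny_model <- function(...) {
  args <- utils::modifyList(
    list(height_px = 192, width_px = 192, n_vessels = 40,
         vessel_radius_um = c(3, 6), necrosis_fraction = 0.1,
         n_specks = 10, noise_sd = 50, seed = 7),
    list(...))
  do.call(section_model, args)
}
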