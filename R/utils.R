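# Shared numeric helpers: separable Gaussian smoothing, connected
# components, overlap scores.

gaussian_kernel <- function(sigma) {
  if (sigma <= 0) return(1)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k / sum(k)
}

# convolve a 3D array along one axis with a 1D kernel (zero padding)
conv_axis <- function(arr, k, axis) {
  if (length(k) == 1L) return(arr)
  d <- dim(arr)
  perm <- c(axis, setdiff(1:3, axis))
  a <- aperm(arr, perm)
  n <- dim(a)[1]
  m <- matrix(a, nrow = n)
  r <- (length(k) - 1L) / 2L
  K <- matrix(0, n, n)
  for (off in seq(-r, r)) {
    idx <- seq_len(n)
    src <- idx + off
    ok <- src >= 1 & src <= n
    K[cbind(idx[ok], src[ok])] <- K[cbind(idx[ok], src[ok])] + k[off + r + 1]
  }
  out <- K %*% m
  aperm(array(out, dim(a)), order(perm))
}

# separable Gaussian smoothing, sigma per axis in voxels
gaussian_smooth <- function(arr, sigma_vox) {
  sigma_vox <- rep(sigma_vox, length.out = 3)
  for (ax in 1:3) arr <- conv_axis(arr, gaussian_kernel(sigma_vox[ax]), ax)
  arr
}

# renormalized masked smoothing: values outside the mask do not bleed in,
# and a constant field stays constant inside the mask
smooth_masked <- function(arr, mask, sigma_vox) {
  m <- array(as.double(mask), dim(arr))
  num <- gaussian_smooth(arr * m, sigma_vox)
  den <- gaussian_smooth(m, sigma_vox)
  out <- array(0, dim(arr))
  ok <- den > 1e-12
  out[ok] <- num[ok] / den[ok]
  out
}

# largest 6-connected component of a logical 3D array
largest_component6 <- function(mask) {
  d <- dim(mask)
  n <- prod(d)
  lab <- integer(n)
  mvec <- as.vector(mask)
  strides <- c(1L, d[1], d[1] * d[2])
  comp <- 0L
  best <- integer(0)
  todo <- which(mvec)
  seen <- logical(n)
  for (s in todo) {
    if (seen[s]) next
    comp <- comp + 1L
    frontier <- s
    seen[s] <- TRUE
    members <- s
    while (length(frontier)) {
      nxt <- integer(0)
      for (ax in 1:3) {
        i <- ((frontier - 1L) %/% strides[ax]) %% d[ax]
        up <- frontier[i < d[ax] - 1L] + strides[ax]
        dn <- frontier[i > 0L] - strides[ax]
        nxt <- c(nxt, up, dn)
      }
      nxt <- unique(nxt[mvec[nxt] & !seen[nxt]])
      seen[nxt] <- TRUE
      members <- c(members, nxt)
      frontier <- nxt
    }
    if (length(members) > length(best)) best <- members
  }
  out <- array(FALSE, d)
  out[best] <- TRUE
  out
}

#' Dice overlap of two masks
#' @param a,b logical arrays of equal dimension.
#' @export
dice <- function(a, b) {
  2 * sum(a & b) / (sum(a) + sum(b))
}

fwhm_to_sigma <- function(fwhm) fwhm / (2 * sqrt(2 * log(2)))

# one step of 6-connected binary dilation
dilate6 <- function(mask) {
  d <- dim(mask)
  out <- mask
  out[-1, , ] <- out[-1, , ] | mask[-d[1], , ]
  out[-d[1], , ] <- out[-d[1], , ] | mask[-1, , ]
  out[, -1, ] <- out[, -1, ] | mask[, -d[2], ]
  out[, -d[2], ] <- out[, -d[2], ] | mask[, -1, ]
  out[, , -1] <- out[, , -1] | mask[, , -d[3]]
  out[, , -d[3]] <- out[, , -d[3]] | mask[, , -1]
  out
}
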