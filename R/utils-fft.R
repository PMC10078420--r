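# Small internal helpers: seeded RNG scoping and centered 2-D FFTs.
# k-space matrices are kept in the "centered" convention (DC component at
# floor(n/2)+1 along each axis) so that apodization windows, zero-filling
# and the Gaussian line mask can be expressed around the matrix center.

with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(code)
}

fftshift_idx <- function(n) {
  h <- floor(n / 2)
  c((h + 1):n, seq_len(h))            # move DC (index 1) to h+1
}

ifftshift_idx <- function(n) {
  h <- ceiling(n / 2)
  c((h + 1):n, seq_len(h))
}

fftshift2 <- function(x) x[fftshift_idx(nrow(x)), fftshift_idx(ncol(x)), drop = FALSE]
ifftshift2 <- function(x) x[ifftshift_idx(nrow(x)), ifftshift_idx(ncol(x)), drop = FALSE]

# image -> centered k-space
fft2c <- function(img) fftshift2(stats::fft(img))

# centered k-space -> image (unitary pair: ifft2c(fft2c(x)) == x)
ifft2c <- function(ks) stats::fft(ifftshift2(ks), inverse = TRUE) / length(ks)

center_index <- function(n) floor(n / 2) + 1L
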