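# Periodized discrete wavelet transform with orthonormal Daubechies
# filters. Periodization keeps the transform square and orthonormal, so
# coefficient energy equals sample energy exactly (Parseval) and the
# inverse is the transpose.

# Scaling (low-pass) filters, sum = sqrt(2). "dbN" has N vanishing moments
# and 2N taps.
.db_filters <- list(
  db2 = c(0.48296291314453414, 0.8365163037378079,
          0.2241438680420134, -0.12940952255126037),
  db4 = c(0.23037781330885523, 0.7148465705525415, 0.6308807679295904,
          -0.02798376941698385, -0.18703481171888114, 0.030841381835986965,
          0.032883011666982945, -0.010597401784997278)
)

wavelet_filters <- function(wavelet) {
  h <- .db_filters[[wavelet]]
  if (is.null(h)) {
    stop_validation("unsupported wavelet family '", wavelet,
                    "'; supported: ", paste(names(.db_filters), collapse = ", "))
  }
  g <- rev(h) * (-1)^(seq_along(h) - 1)
  list(h = h, g = g)
}

# One periodized analysis level on a samples-x-windows matrix.
dwt_level <- function(x, h, g) {
  n <- nrow(x)
  half <- n %/% 2
  a <- matrix(0, half, ncol(x))
  d <- matrix(0, half, ncol(x))
  base <- 2 * (seq_len(half) - 1)
  for (m in seq_along(h)) {
    idx <- (base + (m - 1)) %% n + 1
    a <- a + h[m] * x[idx, , drop = FALSE]
    d <- d + g[m] * x[idx, , drop = FALSE]
  }
  list(a = a, d = d)
}

#' Multilevel discrete wavelet transform
#'
#' Periodized orthonormal DWT of each window (column). With `levels = L`
#' the detail band `d{j}` spans roughly `[fs/2^(j+1), fs/2^j]` Hz and the
#' final approximation `a{L}` spans `[0, fs/2^(L+1)]` Hz.
#'
#' @param segment Numeric vector (one window) or samples-x-windows matrix;
#'   length/rows must be at least `2^levels` and divisible by `2^levels`.
#' @param wavelet Wavelet family name (`"db4"` default, `"db2"` supported).
#' @param levels Number of decomposition levels.
#' @return A list of class `dwt_pyramid` with matrices `d1 ... dL`, `aL`,
#'   plus attributes `wavelet`, `levels`, `n`.
#' @export
dwt_enhance <- function(segment, wavelet = "db4", levels = 4) {
  x <- if (is.matrix(segment)) segment else matrix(segment, ncol = 1)
  n <- nrow(x)
  assert_that(n >= 2^levels, "segment length ", n,
              " shorter than 2^levels = ", 2^levels)
  assert_that(n %% 2^levels == 0,
              "periodized DWT needs length divisible by 2^levels")
  flt <- wavelet_filters(wavelet)
  out <- list()
  cur <- x
  for (j in seq_len(levels)) {
    lv <- dwt_level(cur, flt$h, flt$g)
    out[[paste0("d", j)]] <- lv$d
    cur <- lv$a
  }
  out[[paste0("a", levels)]] <- cur
  structure(out, wavelet = wavelet, levels = levels, n = n,
            class = "dwt_pyramid")
}

#' Inverse multilevel DWT
#'
#' Reconstructs the signal from a [dwt_enhance()] pyramid; exact for the
#' periodized orthonormal filters used here.
#'
#' @param pyr A `dwt_pyramid`.
#' @return Matrix of reconstructed samples (samples x windows).
#' @export
dwt_reconstruct <- function(pyr) {
  flt <- wavelet_filters(attr(pyr, "wavelet"))
  levels <- attr(pyr, "levels")
  cur <- pyr[[paste0("a", levels)]]
  for (j in rev(seq_len(levels))) {
    d <- pyr[[paste0("d", j)]]
    half <- nrow(cur)
    n <- 2 * half
    x <- matrix(0, n, ncol(cur))
    base <- 2 * (seq_len(half) - 1)
    for (m in seq_along(flt$h)) {
      idx <- (base + (m - 1)) %% n + 1
      x[idx, ] <- x[idx, ] + flt$h[m] * cur + flt$g[m] * d
    }
    cur <- x
  }
  cur
}
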