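# Periodized orthogonal wavelet-packet transform.
#
# The transform matrix rows are circular shifts (by 2) of the scaling filter h
# and the quadrature-mirror wavelet filter g[j] = (-1)^j h[L-1-j]; the matrix
# is orthonormal, so perfect reconstruction is exact to rounding. Packet
# leaves are produced in "natural" (filter-path) order and mapped to frequency
# order by the inverse binary-reflected Gray code.

wavelet_filters <- function(name = c("db20", "db10", "db4", "db2", "haar")) {
  name <- match.arg(name)
  h <- switch(name,
    haar = c(1, 1) / sqrt(2),
    db2 = c(0.48296291314469025, 0.836516303737469,
            0.22414386804185735, -0.12940952255092145),
    db4 = c(0.2303778133088965, 0.7148465705529157, 0.6308807679298589,
            -0.027983769416859854, -0.18703481171909309,
            0.030841381835560764, 0.0328830116668852,
            -0.010597401785069032),
    db10 = c(0.026670057900555554, 0.1881768000776915, 0.5272011889317256,
             0.6884590394536035, 0.2811723436605775, -0.24984642432731538,
             -0.19594627437737705, 0.12736934033579325, 0.09305736460357235,
             -0.07139414716639708, -0.029457536821875813, 0.033212674059341,
             0.0036065535669561697, -0.010733175483330575,
             0.001395351747052901, 0.001992405295185056,
             -0.0006858566949597116, -0.00011646685512928545,
             9.358867032006959e-05, -1.3264202894521244e-05),
    db20 = c(0.0007799536136668463, 0.010549394624950399,
             0.06342378045908152, 0.21994211355139703, 0.4726961853109017,
             0.6104932389385939, 0.36150229873933104, -0.13921208801148388,
             -0.32678680043403496, -0.016727088309077008,
             0.22829105081991632, 0.0398502464577712, -0.15545875070726795,
             -0.024716827338613585, 0.10229171917444256,
             0.005632246857307436, -0.06172289962468046,
             0.005874681811811827, 0.03229429953076958,
             -0.00878932492390156, -0.01381052613715192,
             0.006721627302259457, 0.004420542387045791,
             -0.0035814942596096226, -0.0008315621728225569,
             0.0013925596193231364, -5.349759843997695e-05,
             -0.00038510474869921763, 0.00010153288973670291,
             6.77428082837773e-05, -3.710586183394713e-05,
             -4.376143862183997e-06, 7.2412482876736205e-06,
             -1.0119940100188862e-06, -6.847079597000557e-07,
             2.6339242262700013e-07, 2.0143220235505126e-10,
             -1.814843248299696e-08, 4.056127055551833e-09,
             -2.9988364896193194e-10)
  )
  L <- length(h)
  g <- (-1)^(seq_len(L) - 1) * rev(h)
  list(h = h, g = g, length = L, name = name)
}

# one analysis step: x (even length N) -> list(approx, detail), length N/2
wp_analysis_step <- function(x, flt) {
  n <- length(x)
  if (n %% 2L != 0L) stop("signal length must be even at every level")
  half <- n %/% 2L
  base <- 2L * (seq_len(half) - 1L)
  a <- numeric(half)
  d <- numeric(half)
  for (j in seq_len(flt$length)) {
    xi <- x[((base + (j - 1L)) %% n) + 1L]
    a <- a + flt$h[j] * xi
    d <- d + flt$g[j] * xi
  }
  list(a = a, d = d)
}

# inverse of wp_analysis_step
wp_synthesis_step <- function(a, d, flt) {
  half <- length(a)
  n <- 2L * half
  x <- numeric(n)
  base <- 2L * (seq_len(half) - 1L)
  for (j in seq_len(flt$length)) {
    k <- ((base + (j - 1L)) %% n) + 1L
    x[k] <- x[k] + flt$h[j] * a + flt$g[j] * d
  }
  x
}

# full packet tree; returns leaves in natural order (list of 2^depth vectors)
wp_decompose <- function(x, flt, depth) {
  if (depth < 1) stop("`depth` must be >= 1")
  if (length(x) %% 2^depth != 0) {
    stop("signal length (", length(x),
         ") must be divisible by 2^depth = ", 2^depth)
  }
  nodes <- list(x)
  for (lev in seq_len(depth)) {
    nxt <- vector("list", 2L * length(nodes))
    for (i in seq_along(nodes)) {
      s <- wp_analysis_step(nodes[[i]], flt)
      nxt[[2L * i - 1L]] <- s$a
      nxt[[2L * i]] <- s$d
    }
    nodes <- nxt
  }
  nodes
}

wp_reconstruct <- function(leaves, flt) {
  nodes <- leaves
  while (length(nodes) > 1L) {
    nxt <- vector("list", length(nodes) %/% 2L)
    for (i in seq_along(nxt)) {
      nxt[[i]] <- wp_synthesis_step(nodes[[2L * i - 1L]], nodes[[2L * i]], flt)
    }
    nodes <- nxt
  }
  nodes[[1]]
}

# natural-order leaf index (0-based) for frequency rank r: gray(r) = r XOR r>>1
wp_freq_to_natural <- function(r) {
  bitwXor(r, bitwShiftR(r, 1L))
}

# nominal frequency interval [lo, hi) in Hz of frequency-ranked leaf r
wp_leaf_band <- function(r, rate, depth) {
  width <- rate / 2^(depth + 1)
  c(r * width, (r + 1) * width)
}
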