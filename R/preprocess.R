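#' Flag artifact samples by the amplitude rule
#'
#' Scalp EEG rarely exceeds a few tens of microvolts; following common
#' clinical practice, any sample with absolute amplitude strictly greater
#' than the cutoff (default 50 uV) is flagged as artifact. A sample exactly
#' at the cutoff is not flagged. If an epoch length is supplied, per-epoch
#' contamination flags are also returned: an epoch is contaminated iff any of
#' its samples is flagged.
#'
#' @param x an [eeg_record()], or a numeric matrix/vector of amplitudes (uV).
#' @param cutoff amplitude cutoff in uV (> 0); default 50.
#' @param epoch_length optional epoch length in seconds (requires an
#'   `eeg_record` input) to compute per-epoch flags.
#' @return an `artifact_mask`: list with `samples` (logical matrix, same
#'   shape as the input), `epochs` (logical vector or `NULL`), and `cutoff`.
#' @examples
#' m <- flag_artifacts(c(10, -60, 50), cutoff = 50)
#' which(m$samples)
#' @export
flag_artifacts <- function(x, cutoff = 50, epoch_length = NULL) {
  if (!is.numeric(cutoff) || length(cutoff) != 1 || cutoff <= 0) {
    stop("`cutoff` must be a single positive amplitude in uV")
  }
  rate <- NULL
  if (inherits(x, "eeg_record")) {
    rate <- x$sampling_rate
    amp <- x$samples
  } else if (is.numeric(x)) {
    amp <- if (is.matrix(x)) x else matrix(x, nrow = 1)
  } else {
    stop("`x` must be an eeg_record or a numeric matrix/vector")
  }
  if (any(!is.finite(amp))) stop("amplitudes must be finite")
  flags <- abs(amp) > cutoff          # strictly greater than the cutoff
  epochs <- NULL
  if (!is.null(epoch_length)) {
    if (is.null(rate)) stop("epoch flags require an eeg_record input")
    w <- as.integer(round(epoch_length * rate))
    n_ep <- ncol(flags) %/% w
    epochs <- vapply(seq_len(n_ep), function(i) {
      any(flags[, ((i - 1) * w + 1):(i * w)])
    }, logical(1))
  }
  structure(list(samples = flags, epochs = epochs, cutoff = cutoff),
            class = "artifact_mask")
}

#' Remove artifacts by blind source separation
#'
#' Separates the recording into uncorrelated source components by
#' second-order blind identification (SOBI: whitening followed by approximate
#' joint diagonalization of time-lagged covariance matrices), rejects
#' components that look like artifacts, and reconstructs the signal from the
#' remaining components. A component is rejected when its back-projection
#' into channel space violates the amplitude rule (any sample above `cutoff`)
#' or when its raw kurtosis exceeds `kurtosis_bound` (sparse transients such
#' as blinks are strongly leptokurtic; Gaussian background activity has
#' kurtosis 3).
#'
#' Multichannel input is separated across channels. Single-channel input is
#' first delay-embedded into `embed_dim` lagged copies (a trajectory matrix,
#' as in singular-spectrum analysis), separated there, and mapped back to one
#' channel by diagonal averaging. When no component is rejected the
#' reconstruction equals the input up to rounding.
#'
#' Rejected components whose back-projection violates the amplitude rule are
#' subtracted only on the intervals where that violation occurs (dilated by
#' `support_margin` seconds), so brain activity sharing a component with a
#' transient artifact is preserved away from the artifact itself. Components
#' rejected on kurtosis alone (e.g. sub-threshold spike trains) are
#' subtracted over the whole record.
#'
#' @param record an [eeg_record()].
#' @param embed_dim number of lagged copies for single-channel input
#'   (default 16; must be >= 2).
#' @param n_components number of components kept in the whitened space;
#'   default all with non-negligible variance.
#' @param cutoff amplitude rule in uV applied to component back-projections.
#' @param kurtosis_bound raw-kurtosis rejection bound (default 5).
#' @param lags covariance lags (in samples) jointly diagonalized.
#' @param support_margin dilation (s) of the artifact support on each side
#'   when subtracting amplitude-rule violations (default 0.25 s).
#' @param seed unused (the algorithm is deterministic); accepted for API
#'   stability.
#' @return the cleaned [eeg_record()], with attribute `bss_report`: a
#'   data.frame with one row per component (`component`, `variance`,
#'   `kurtosis`, `max_abs_uv`, `rejected`).
#' @export
remove_artifacts_bss <- function(record, embed_dim = 16, n_components = NULL,
                                 cutoff = 50, kurtosis_bound = 5,
                                 lags = 1:8, support_margin = 0.25,
                                 seed = NULL) {
  stopifnot(inherits(record, "eeg_record"))
  x <- record$samples
  single <- nrow(x) == 1
  if (single && embed_dim < 2) {
    stop("single-channel input requires `embed_dim` >= 2")
  }
  if (ncol(x) <= embed_dim) {
    stop("record must be longer than `embed_dim` samples")
  }
  if (sum(x^2) == 0) {                       # silent record: nothing to do
    attr(record, "bss_report") <- data.frame(
      component = integer(0), variance = numeric(0), kurtosis = numeric(0),
      max_abs_uv = numeric(0), rejected = logical(0))
    return(record)
  }
  X <- if (single) delay_embed(as.numeric(x), embed_dim) else x
  dec <- sobi(X, n_components = n_components, lags = lags)
  p <- nrow(dec$S)
  report <- vector("list", p)
  n <- ncol(x)
  art_global <- matrix(0, nrow(x), n)        # kurtosis-only rejections
  art_local <- matrix(0, nrow(x), n)         # amplitude-rule rejections
  support <- matrix(FALSE, nrow(x), n)
  for (k in seq_len(p)) {
    bp <- dec$A[, k, drop = FALSE] %*% dec$S[k, , drop = FALSE]
    ck <- if (single) matrix(diag_average(bp), nrow = 1) else bp
    s <- dec$S[k, ]
    m2 <- mean((s - mean(s))^2)
    kurt <- if (m2 > 0) mean((s - mean(s))^4) / m2^2 else 3
    mx <- max(abs(ck))
    amp_viol <- mx > cutoff
    rejected <- amp_viol || kurt > kurtosis_bound
    if (amp_viol) {
      art_local <- art_local + ck
      support <- support | abs(ck) > cutoff
    } else if (rejected) {
      art_global <- art_global + ck
    }
    report[[k]] <- data.frame(component = k, variance = stats::var(s),
                              kurtosis = kurt, max_abs_uv = mx,
                              rejected = rejected)
  }
  margin <- as.integer(round(support_margin * record$sampling_rate))
  support <- t(apply(support, 1, dilate_mask, margin = margin))
  clean <- x - art_global
  clean[support] <- clean[support] - art_local[support]
  out <- eeg_record(clean, record$sampling_rate, record$channel_labels,
                    record$start_time)
  attr(out, "bss_report") <- do.call(rbind, report)
  out
}

# extend TRUE runs of a logical vector by `margin` samples on each side
dilate_mask <- function(mask, margin) {
  if (margin <= 0 || !any(mask)) return(mask)
  idx <- which(mask)
  lo <- pmax(1L, idx - margin)
  hi <- pmin(length(mask), idx + margin)
  out <- logical(length(mask))
  for (i in seq_along(idx)) out[lo[i]:hi[i]] <- TRUE
  out
}

# trajectory matrix: row i holds x shifted by i-1 samples (length N-m+1)
delay_embed <- function(x, m) {
  n <- length(x)
  k <- n - m + 1
  out <- matrix(0, nrow = m, ncol = k)
  for (i in seq_len(m)) out[i, ] <- x[i:(i + k - 1)]
  out
}

# inverse of delay_embed: average each anti-diagonal back onto the signal
diag_average <- function(M) {
  m <- nrow(M); k <- ncol(M)
  n <- m + k - 1
  acc <- numeric(n)
  cnt <- numeric(n)
  for (i in seq_len(m)) {
    idx <- i:(i + k - 1)
    acc[idx] <- acc[idx] + M[i, ]
    cnt[idx] <- cnt[idx] + 1
  }
  acc / cnt
}

# Second-order blind identification. X: p x N (rows are channels/lags).
# Returns unmixed sources S (rows), mixing matrix A with X_centered ~ A %*% S.
sobi <- function(X, n_components = NULL, lags = 1:8, tol = 1e-8,
                 max_sweeps = 100) {
  p <- nrow(X); n <- ncol(X)
  Xc <- X - rowMeans(X)
  C0 <- tcrossprod(Xc) / n
  eg <- eigen(C0, symmetric = TRUE)
  pos <- eg$values > max(eg$values) * 1e-10
  r <- if (is.null(n_components)) sum(pos) else min(n_components, sum(pos))
  E <- eg$vectors[, seq_len(r), drop = FALSE]
  # fix eigenvector signs for determinism
  for (j in seq_len(r)) {
    i <- which.max(abs(E[, j]))
    if (E[i, j] < 0) E[, j] <- -E[, j]
  }
  d <- eg$values[seq_len(r)]
  W <- diag(1 / sqrt(d), r) %*% t(E)          # whitener
  Z <- W %*% Xc
  Rs <- lapply(lags, function(tau) {
    if (tau >= n) stop("lag exceeds record length")
    R <- tcrossprod(Z[, 1:(n - tau), drop = FALSE],
                    Z[, (1 + tau):n, drop = FALSE]) / (n - tau)
    (R + t(R)) / 2
  })
  V <- joint_diagonalize(Rs, tol = tol, max_sweeps = max_sweeps)
  S <- t(V) %*% Z
  A <- E %*% diag(sqrt(d), r) %*% V           # X ~ A S
  list(S = S, A = A, W = W, V = V)
}

# Jacobi-like approximate joint diagonalization of symmetric matrices
# (Cardoso-Souloumiac rotations); returns orthogonal V with t(V) M V ~ diag.
joint_diagonalize <- function(Ms, tol = 1e-8, max_sweeps = 100) {
  p <- nrow(Ms[[1]])
  V <- diag(p)
  if (p < 2) return(V)
  for (sweep in seq_len(max_sweeps)) {
    changed <- FALSE
    for (i in 1:(p - 1)) {
      for (j in (i + 1):p) {
        g11 <- 0; g12 <- 0; g22 <- 0
        for (M in Ms) {
          h1 <- M[i, i] - M[j, j]
          h2 <- 2 * M[i, j]
          g11 <- g11 + h1 * h1
          g12 <- g12 + h1 * h2
          g22 <- g22 + h2 * h2
        }
        # principal eigenvector of the 2x2 Gram matrix [[g11,g12],[g12,g22]]
        theta <- 0.5 * atan2(2 * g12, g11 - g22)
        x <- cos(theta); y <- sin(theta)
        if (x < 0) { x <- -x; y <- -y }
        c_ <- sqrt((1 + x) / 2)
        s_ <- y / (2 * c_)
        if (abs(s_) > tol) {
          changed <- TRUE
          for (k in seq_along(Ms)) {
            M <- Ms[[k]]
            rot <- function(A) {
              ai <- A[, i]; aj <- A[, j]
              A[, i] <- c_ * ai + s_ * aj
              A[, j] <- -s_ * ai + c_ * aj
              A
            }
            M <- rot(M)
            ri <- M[i, ]; rj <- M[j, ]
            M[i, ] <- c_ * ri + s_ * rj
            M[j, ] <- -s_ * ri + c_ * rj
            Ms[[k]] <- M
          }
          vi <- V[, i]; vj <- V[, j]
          V[, i] <- c_ * vi + s_ * vj
          V[, j] <- -s_ * vi + c_ * vj
        }
      }
    }
    if (!changed) break
  }
  V
}
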