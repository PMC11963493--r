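# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: brute-force double sums, direct window
# recomputation, closed forms.

# mutual information by the textbook double sum over the joint distribution
brute_mi <- function(joint) {
  joint <- as.matrix(joint)
  n <- sum(joint)
  p <- joint / n
  px <- rowSums(p)
  py <- colSums(p)
  s <- 0
  for (i in seq_len(nrow(p))) {
    for (j in seq_len(ncol(p))) {
      if (p[i, j] > 0) s <- s + p[i, j] * log2(p[i, j] / (px[i] * py[j]))
    }
  }
  s
}

brute_entropy <- function(counts) {
  p <- counts[counts > 0] / sum(counts)
  -sum(p * log2(p))
}

# direct per-window Hampel recomputation (sort-based, no shared helpers)
brute_hampel <- function(x, k, n_mad) {
  n <- length(x)
  out <- x
  rep_mask <- logical(n)
  for (i in seq_len(n)) {
    if (is.na(x[i])) next
    w <- x[max(1, i - k):min(n, i + k)]
    w <- w[!is.na(w)]
    sw <- sort(w)
    m <- length(sw)
    med <- if (m %% 2 == 1) sw[(m + 1) / 2] else (sw[m / 2] + sw[m / 2 + 1]) / 2
    dev <- sort(abs(w - med))
    mad_w <- if (m %% 2 == 1) dev[(m + 1) / 2] else (dev[m / 2] + dev[m / 2 + 1]) / 2
    if (abs(x[i] - med) > n_mad * 1.4826 * mad_w) {
      out[i] <- med
      rep_mask[i] <- TRUE
    }
  }
  list(values = out, replaced = rep_mask)
}

# closed-form unimodal van Genuchten (Mualem constraint), for the w1 -> 1 limit
unimodal_theta <- function(psi, theta_r, theta_s, alpha, n) {
  m <- 1 - 1 / n
  theta_r + (theta_s - theta_r) * (1 + (alpha * abs(psi))^n)^(-m)
}

unimodal_psi <- function(theta, theta_r, theta_s, alpha, n) {
  m <- 1 - 1 / n
  se <- (theta - theta_r) / (theta_s - theta_r)
  -(se^(-1 / m) - 1)^(1 / n) / alpha
}

# all joint count tables with `cells` cells and total count <= n_max,
# as a matrix with one composition per row (exhaustive enumeration)
enumerate_counts <- function(n_max, cells) {
  total <- choose(n_max + cells, cells) # compositions of 0..n_max into `cells`
  out <- matrix(0L, total, cells)
  row_i <- 0L
  rec <- function(prefix, remaining, slot) {
    if (slot == cells) {
      for (v in 0:remaining) {
        row_i <<- row_i + 1L
        out[row_i, ] <<- c(prefix, v)
      }
      return(invisible())
    }
    for (v in 0:remaining) {
      rec(c(prefix, v), remaining - v, slot + 1L)
    }
  }
  rec(integer(0), n_max, 1L)
  stopifnot(row_i == total)
  out
}

# small, fast experiment configuration for unit tests
tiny_config <- function(seed = 1L, ...) {
  experiment_config(n_trees = 2, n_days = 8, sampling_days = c(1, 3, 6),
                    rewater_day = 5, seed = seed, ...)
}
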