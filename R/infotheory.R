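# Plug-in (maximum-likelihood) entropy and mutual information on
# daily-summarised variables. All entropies are in bits (log base 2); with the
# default 2-bin quantile discretisation MI is bounded by 1 bit, which suits
# sample sizes as small as five sampling days.

#' Discretize a numeric series into bins
#'
#' Converts a numeric vector into integer bin labels for plug-in entropy
#' estimation. Two schemes are offered: `equal_width` partitions the observed
#' range into bins of equal width (final bin right-closed), while `quantile`
#' assigns labels by rank so that bin counts are as equal as possible, with
#' ties between equal values resolved by original index order.
#'
#' @param values numeric vector; `NA`s are carried through as `NA` labels and
#'   excluded from binning.
#' @param n_bins number of bins (>= 2).
#' @param scheme `"quantile"` (default) or `"equal_width"`.
#' @return An object of class `discretized_variable`: a list with `labels`
#'   (0-based integer bin per input element, `NA` where the input was missing),
#'   `n_bins` (effective bin count) and `scheme`.
#'
#' A constant series cannot be split by quantiles; it is returned as a single
#' bin (entropy 0) with a warning.
#' @examples
#' discretize(c(1, 2, 3, 4), 2, "equal_width")$labels  # 0 0 1 1
#' @export
discretize <- function(values, n_bins = 2, scheme = c("quantile", "equal_width")) {
  scheme <- match.arg(scheme)
  if (!is.numeric(values)) stop("`values` must be numeric")
  if (n_bins < 2) stop("`n_bins` must be at least 2")
  keep <- !is.na(values)
  x <- values[keep]
  if (length(x) < 2) stop("need at least 2 non-missing values to discretize")
  labels <- rep(NA_integer_, length(values))
  if (diff(range(x)) == 0) {
    warning("constant series: single-bin discretization (entropy 0)")
    labels[keep] <- 0L
    n_eff <- 1L
  } else if (scheme == "equal_width") {
    w <- diff(range(x)) / n_bins
    labels[keep] <- as.integer(pmin(floor((x - min(x)) / w), n_bins - 1))
    n_eff <- as.integer(n_bins)
  } else {
    ord <- order(x) # stable: ties keep input index order
    lab <- integer(length(x))
    lab[ord] <- as.integer(floor((seq_along(x) - 1) * n_bins / length(x)))
    labels[keep] <- lab
    n_eff <- as.integer(n_bins)
  }
  structure(list(labels = labels, n_bins = n_eff, scheme = scheme),
            class = "discretized_variable")
}

label_vector <- function(labels) {
  if (inherits(labels, "discretized_variable")) labels <- labels$labels
  labels
}

entropy_from_counts <- function(counts) {
  n <- sum(counts)
  p <- counts[counts > 0] / n
  -sum(p * log2(p))
}

#' Shannon entropy of discrete labels
#'
#' Plug-in entropy in bits, with the convention 0 * log(0) = 0. Missing labels
#' are dropped.
#'
#' @param labels integer/factor label vector or a [discretize()] result.
#' @return entropy in bits.
#' @examples
#' entropy(rep(0:3, 5)) # 2 bits
#' @export
entropy <- function(labels) {
  labels <- label_vector(labels)
  labels <- labels[!is.na(labels)]
  if (length(labels) == 0) stop("entropy of an empty label vector is undefined")
  entropy_from_counts(as.numeric(table(labels)))
}

#' Conditional entropy H(X | Y)
#'
#' Plug-in conditional entropy in bits computed from the joint histogram of two
#' equal-length label vectors as the label-frequency-weighted mean of the
#' within-stratum entropies of X.
#'
#' @param labels_x,labels_y label vectors (or [discretize()] results) of equal
#'   length; pairs with a missing value in either are dropped.
#' @return H(X | Y) in bits.
#' @export
conditional_entropy <- function(labels_x, labels_y) {
  x <- label_vector(labels_x)
  y <- label_vector(labels_y)
  if (length(x) != length(y)) stop("label vectors must have equal length")
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) == 0) stop("no pairwise-complete label pairs")
  joint <- table(x, y)
  cond_entropy_from_counts(joint)
}

# H(X|Y) as sum_y p(y) H(X | Y = y): deliberately a different computational
# route from H(X,Y) - H(Y) so the two MI identities cross-check each other.
cond_entropy_from_counts <- function(joint) {
  joint <- as.matrix(joint)
  n <- sum(joint)
  h <- 0
  for (j in seq_len(ncol(joint))) {
    nj <- sum(joint[, j])
    if (nj > 0) h <- h + (nj / n) * entropy_from_counts(joint[, j])
  }
  h
}

#' Mutual information from a joint count table
#'
#' Computes plug-in mutual information in bits from a joint histogram, by both
#' identities: `H(X) - H(X|Y)` (with the conditional entropy accumulated per
#' stratum of Y) and `H(X) + H(Y) - H(X,Y)`. The two routes must agree to
#' 1e-12; tiny negative values (< 1e-12 in magnitude) are clipped to zero.
#'
#' @param joint numeric matrix (or table) of joint counts, X in rows.
#' @return list with `mi` (bits), `mi_joint_form` (the second identity, for
#'   cross-checking), `h_x`, `h_y`, `h_xy`, `h_x_given_y`, and `n`.
#' @export
mi_from_counts <- function(joint) {
  joint <- as.matrix(joint)
  if (any(joint < 0) || sum(joint) <= 0) {
    stop("`joint` must be a non-negative count table with positive total")
  }
  n <- sum(joint)
  h_x <- entropy_from_counts(rowSums(joint))
  h_y <- entropy_from_counts(colSums(joint))
  h_xy <- entropy_from_counts(as.vector(joint))
  h_x_given_y <- cond_entropy_from_counts(joint)
  mi <- h_x - h_x_given_y
  mi_joint <- h_x + h_y - h_xy
  if (abs(mi - mi_joint) > 1e-12) {
    stop("internal inconsistency: the two mutual-information identities disagree")
  }
  if (mi < 0 && mi > -1e-12) mi <- 0
  list(mi = mi, mi_joint_form = mi_joint, h_x = h_x, h_y = h_y, h_xy = h_xy,
       h_x_given_y = h_x_given_y, n = n)
}

#' Mutual information between two daily series
#'
#' Pairs the two series element-wise (pairwise-complete), discretizes each with
#' the requested scheme, and returns the plug-in mutual information in bits.
#' Fewer than three complete pairs yields a result flagged unreliable rather
#' than an error, since sampling-day variables can leave very short strata.
#'
#' @param x,y numeric vectors of equal length (same-day pairing by position).
#' @param n_bins bins per variable (default 2).
#' @param scheme discretization scheme, see [discretize()].
#' @return An object of class `mi_result`: list with `mi` (bits), `h_x`, `h_y`,
#'   `h_xy`, `n` (complete pairs), `n_bins`, `scheme`, `reliable`.
#' @export
mutual_information <- function(x, y, n_bins = 2,
                               scheme = c("quantile", "equal_width")) {
  scheme <- match.arg(scheme)
  if (length(x) != length(y)) stop("`x` and `y` must have equal length")
  ok <- !is.na(x) & !is.na(y)
  n <- sum(ok)
  if (n < 2) {
    return(structure(list(mi = NA_real_, h_x = NA_real_, h_y = NA_real_,
                          h_xy = NA_real_, n = n, n_bins = n_bins,
                          scheme = scheme, reliable = FALSE),
                     class = "mi_result"))
  }
  lx <- suppressWarnings(discretize(x[ok], n_bins, scheme))$labels
  ly <- suppressWarnings(discretize(y[ok], n_bins, scheme))$labels
  res <- mi_from_counts(table(factor(lx), factor(ly)))
  structure(list(mi = res$mi, h_x = res$h_x, h_y = res$h_y, h_xy = res$h_xy,
                 n = n, n_bins = n_bins, scheme = scheme, reliable = n >= 3),
            class = "mi_result")
}

#' @export
print.mi_result <- function(x, ...) {
  cat(sprintf("mutual information: %.4f bits (H_x %.4f, H_y %.4f, n %d%s)\n",
              x$mi, x$h_x, x$h_y, x$n,
              if (isTRUE(x$reliable)) "" else ", UNRELIABLE"))
  invisible(x)
}
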