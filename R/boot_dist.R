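#' Bootstrap distribution of an estimate
#'
#' A `boot_dist` is an ordered vector of bootstrap replicate values together
#' with its summary (mean and 2.5/97.5 percentile interval). Replicate order is
#' meaningful: replicate `i` of one quantity is paired with replicate `i` of
#' every other quantity derived in the same bootstrap run, so arithmetic on
#' `boot_dist` objects is performed replicate-wise and preserves the pairing.
#'
#' @param replicates numeric vector of bootstrap replicate estimates.
#' @param seed optional integer recording the seed the replicates were drawn
#'   under (bookkeeping only; not consumed).
#' @return An object of class `boot_dist`.
#' @examples
#' b <- boot_dist(rnorm(1000, 10))
#' mean(b)
#' ci(b)
#' @export
boot_dist <- function(replicates, seed = NULL) {
  replicates <- as.numeric(replicates)
  if (length(replicates) < 1L || anyNA(replicates)) {
    stop("'replicates' must be a non-empty numeric vector without NAs")
  }
  structure(list(replicates = replicates, seed = seed), class = "boot_dist")
}

#' @export
is.boot_dist <- function(x) inherits(x, "boot_dist")

#' @rdname boot_dist
#' @param x,object a `boot_dist`.
#' @param ... unused.
#' @export
mean.boot_dist <- function(x, ...) mean(x$replicates)

#' Percentile confidence interval of a bootstrap distribution
#'
#' @param x a [boot_dist()].
#' @param level coverage of the percentile interval (default 0.95, i.e. the
#'   2.5 and 97.5 percentiles).
#' @return Named numeric vector `c(ci_low, ci_high)`.
#' @export
ci <- function(x, level = 0.95) {
  stopifnot(is.boot_dist(x), level > 0, level < 1)
  a <- (1 - level) / 2
  q <- stats::quantile(x$replicates, c(a, 1 - a), names = FALSE, type = 7)
  c(ci_low = q[1], ci_high = q[2])
}

#' @export
length.boot_dist <- function(x) length(x$replicates)

#' @export
quantile.boot_dist <- function(x, ...) stats::quantile(x$replicates, ...)

#' @export
print.boot_dist <- function(x, digits = 4, ...) {
  q <- ci(x)
  cat(sprintf("<boot_dist: n_boot = %d>\n", length(x$replicates)))
  cat(sprintf("  mean %s  [95%% CI %s, %s]\n",
              format(mean(x), digits = digits),
              format(q[1], digits = digits), format(q[2], digits = digits)))
  invisible(x)
}

#' @export
Ops.boot_dist <- function(e1, e2) {
  if (!.Generic %in% c("+", "-", "*", "/", "^")) {
    stop(sprintf("operation '%s' not defined for boot_dist", .Generic))
  }
  v1 <- if (is.boot_dist(e1)) e1$replicates else e1
  if (missing(e2)) return(boot_dist(get(.Generic)(v1)))
  v2 <- if (is.boot_dist(e2)) e2$replicates else e2
  if (is.boot_dist(e1) && is.boot_dist(e2) && length(v1) != length(v2)) {
    stop("boot_dist arithmetic requires equal n_boot (replicates are paired)")
  }
  boot_dist(get(.Generic)(v1, v2))
}

#' Replicate-wise sum of paired bootstrap distributions
#'
#' Sums a list of `boot_dist` objects replicate by replicate, preserving the
#' pairing contract (replicate `i` of the sum is the sum of replicates `i`).
#'
#' @param xs list of [boot_dist()] objects sharing the same `n_boot`.
#' @return A [boot_dist()].
#' @export
bd_sum <- function(xs) {
  stopifnot(length(xs) >= 1L, all(vapply(xs, is.boot_dist, logical(1))))
  n <- vapply(xs, length, integer(1))
  if (length(unique(n)) != 1L) {
    stop("cannot sum boot_dist objects with mismatched n_boot: ",
         paste(unique(n), collapse = ", "))
  }
  boot_dist(Reduce(`+`, lapply(xs, `[[`, "replicates")))
}

#' @export
log.boot_dist <- function(x, ...) boot_dist(log(x$replicates, ...))

#' Summarise a bootstrap distribution as a one-row data frame
#'
#' @param x a [boot_dist()].
#' @return data frame with columns mean, ci_low, ci_high, n_boot.
#' @export
bd_summary <- function(x) {
  q <- ci(x)
  data.frame(mean = mean(x), ci_low = q[1], ci_high = q[2],
             n_boot = length(x), row.names = NULL)
}
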