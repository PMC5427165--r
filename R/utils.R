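#' Evaluate an expression under a fixed random seed
#'
#' Thin wrapper around [withr::with_seed()] that tolerates a `NULL` seed
#' (in which case the expression runs under the ambient RNG state).
#'
#' @param seed Integer seed or `NULL`.
#' @param expr Expression to evaluate.
#' @noRd
with_seed_maybe <- function(seed, expr) {
  if (is.null(seed)) {
    force(expr)
  } else {
    withr::with_seed(as.integer(seed), expr)
  }
}

#' Draw analyzable cell counts per well
#'
#' Samples integer per-well analyzable cell counts from a zero-truncated
#' normal distribution calibrated so that the *truncated* distribution has the
#' requested mean. The defaults (mean 795, SD 345 cells) reproduce the
#' detected-count distribution typical of a 384-well high-content screen with
#' automated segmentation.
#'
#' @param n Number of wells to sample.
#' @param mean Target mean of the truncated distribution, in cells.
#' @param sd Latent normal standard deviation, in cells.
#' @param seed Optional integer seed for reproducibility.
#'
#' @return Integer vector of length `n`, all values `>= 0`.
#'
#' @details The latent normal location is solved numerically so that
#'   `E[X | X >= 0] == mean`; without this adjustment truncation at zero
#'   inflates the mean by roughly `sd * dnorm(a) / (1 - pnorm(a))` where
#'   `a = -mean/sd`.
#'
#' @examples
#' x <- sample_cell_counts(100, seed = 1)
#' mean(x)
#' @export
sample_cell_counts <- function(n, mean = 795, sd = 345, seed = NULL) {
  stopifnot(n >= 0, sd > 0, mean > 0)
  mu <- truncnorm_latent_mean(mean, sd)
  with_seed_maybe(seed, {
    out <- numeric(n)
    todo <- seq_len(n)
    while (length(todo) > 0) {
      draw <- rnorm(length(todo), mu, sd)
      ok <- draw >= 0
      out[todo[ok]] <- draw[ok]
      todo <- todo[!ok]
    }
    as.integer(round(out))
  })
}

# Latent location of a zero-truncated normal whose truncated mean is `target`.
truncnorm_latent_mean <- function(target, sd) {
  trunc_mean <- function(mu) {
    a <- (0 - mu) / sd
    mu + sd * dnorm(a) / (1 - pnorm(a))
  }
  uniroot(function(mu) trunc_mean(mu) - target,
          lower = target - 4 * sd, upper = target, tol = 1e-8)$root
}

# Draw from a log-normal with mean 1 and coefficient of variation `cv`.
rlnorm_cv1 <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

# Well names in 384-well row-major convention: A1..A24, B1..B24, ..., P24.
well_names_384 <- function(plate_size = 384) {
  n_col <- 24L
  n_row <- as.integer(ceiling(plate_size / n_col))
  paste0(rep(LETTERS[seq_len(n_row)], each = n_col),
         rep(seq_len(n_col), times = n_row))[seq_len(plate_size)]
}

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x < lower || x > upper) {
    abort(sprintf("`%s` must be a single finite number in [%s, %s]",
                  name, format(lower), format(upper)),
          class = "appscreen_param_error")
  }
  invisible(x)
}
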