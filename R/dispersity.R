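# Dispersity statistics of filament length samples (number- and
# weight-averaged length, sigma, PDI) and (zero-truncated) Poisson fitting
# of label-count histograms.

#' Construct a length sample
#'
#' @param values positive lengths `L_i` (nm, or tile counts).
#' @param multiplicities object counts `N_i` per value (default 1 each).
#' @return an object of class `length_sample` with elements `values`,
#'   `multiplicities`, `N` (total object count).
#' @export
length_sample <- function(values, multiplicities = NULL) {
  if (length(values) == 0L)
    stop("empty length sample", call. = FALSE)
  if (!is.numeric(values) || any(!is.finite(values)))
    stop("`values` must be finite numbers", call. = FALSE)
  if (any(values <= 0))
    stop("lengths must be > 0 (drop undetectable objects first)",
         call. = FALSE)
  if (is.null(multiplicities)) multiplicities <- rep(1, length(values))
  if (length(multiplicities) != length(values))
    stop("`multiplicities` must match `values` in length", call. = FALSE)
  if (any(multiplicities < 0) || any(!is.finite(multiplicities)))
    stop("`multiplicities` must be finite and >= 0", call. = FALSE)
  if (sum(multiplicities) <= 0)
    stop("total multiplicity must be positive", call. = FALSE)
  structure(list(values = as.numeric(values),
                 multiplicities = as.numeric(multiplicities),
                 N = sum(multiplicities)),
            class = "length_sample")
}

#' Dispersity summary of a length sample
#'
#' Computes the number-averaged length, weight-averaged length, population
#' standard deviation and polydispersity index of a sample of object
#' lengths `L_i` with multiplicities `N_i`:
#' \deqn{L_n = \sum N_i L_i / \sum N_i}
#' \deqn{L_w = \sum N_i L_i^2 / \sum N_i L_i}
#' \deqn{\sigma = \sqrt{\frac{1}{N}\sum N_i (L_i - L_n)^2}}
#' \deqn{PDI = L_w / L_n}
#' The standard deviation uses the population form (divisor `N`, not
#' `N - 1`). `L_w >= L_n` always (Cauchy-Schwarz), with equality iff the
#' sample is monodisperse, so `PDI >= 1`.
#'
#' @param sample a [length_sample()] (a bare numeric vector is accepted and
#'   wrapped with unit multiplicities).
#' @return object of class `dispersity_summary` with elements `Ln`, `Lw`,
#'   `sigma`, `PDI`, `N`.
#' @examples
#' dispersity_summary(length_sample(c(100, 100, 200)))
#' @export
dispersity_summary <- function(sample) {
  if (is.numeric(sample)) sample <- length_sample(sample)
  stopifnot(inherits(sample, "length_sample"))
  L <- sample$values
  Ni <- sample$multiplicities
  Ln <- sum(Ni * L) / sum(Ni)
  Lw <- sum(Ni * L^2) / sum(Ni * L)
  sigma <- sqrt(sum(Ni * (L - Ln)^2) / sample$N)
  structure(list(Ln = Ln, Lw = Lw, sigma = sigma, PDI = Lw / Ln,
                 N = sample$N),
            class = "dispersity_summary")
}

#' @export
print.dispersity_summary <- function(x, ...) {
  cat(sprintf("Dispersity (N = %g): Ln = %.4g, Lw = %.4g, sigma = %.4g, PDI = %.4f\n",
              x$N, x$Ln, x$Lw, x$sigma, x$PDI))
  invisible(x)
}

#' Construct a label-count histogram
#'
#' @param counts named numeric vector mapping label number `k` to observed
#'   frequency, or a data.frame with columns `k` and `freq`.
#' @param truncated logical: `TRUE` when the zero class is unobservable
#'   (e.g. an unlabeled filament is invisible on the surface); a truncated
#'   histogram must not contain a `k = 0` entry.
#' @return object of class `label_histogram`.
#' @export
label_histogram <- function(counts, truncated = FALSE) {
  if (is.data.frame(counts)) {
    k <- counts$k
    freq <- counts$freq
  } else {
    k <- as.integer(names(counts))
    freq <- as.numeric(counts)
  }
  if (length(k) > 0L) {
    if (any(is.na(k)) || any(k < 0))
      stop("label numbers k must be named, integer and >= 0", call. = FALSE)
    if (any(freq < 0)) stop("frequencies must be >= 0", call. = FALSE)
    if (truncated && any(k == 0L & freq > 0))
      stop("truncated histogram cannot contain a k = 0 class", call. = FALSE)
    keep <- freq > 0
    k <- k[keep]
    freq <- freq[keep]
    o <- order(k)
    k <- k[o]
    freq <- freq[o]
  }
  structure(list(k = as.integer(k), freq = as.numeric(freq),
                 truncated = isTRUE(truncated)),
            class = "label_histogram")
}

#' Tabulate integer label counts into a histogram
#'
#' @param x integer vector of per-object label counts.
#' @param truncated drop the zero class and flag the histogram truncated.
#' @return a [label_histogram()].
#' @export
tabulate_labels <- function(x, truncated = FALSE) {
  stopifnot(is.numeric(x))
  if (truncated) x <- x[x > 0]
  tab <- table(factor(x, levels = sort(unique(x))))
  label_histogram(stats::setNames(as.numeric(tab), names(tab)),
                  truncated = truncated)
}

#' Fit a (zero-truncated) Poisson distribution to a label histogram
#'
#' Untruncated: the maximum-likelihood estimate is the weighted sample mean.
#' Zero-truncated (zero-label objects undetectable): the MLE solves
#' `lambda / (1 - exp(-lambda)) = mean` by a bracketed scalar root search
#' (tolerance 1e-8). A truncated sample whose mean is at the minimal
#' support (all mass at k = 1) drives `lambda` to the zero boundary; this
#' is reported via `boundary = TRUE` rather than silently.
#'
#' @param hist a [label_histogram()].
#' @param truncated override the histogram's truncation flag (default: use
#'   the flag).
#' @return object of class `poisson_fit` with `lambda_hat`,
#'   `log_likelihood`, `truncated`, `boundary`, `n`.
#' @export
fit_poisson <- function(hist, truncated = NULL) {
  stopifnot(inherits(hist, "label_histogram"))
  if (is.null(truncated)) truncated <- hist$truncated
  k <- hist$k
  f <- hist$freq
  if (length(k) == 0L || sum(f) <= 0)
    stop("histogram has no observations", call. = FALSE)
  n <- sum(f)
  m <- sum(k * f) / n
  if (m == 0)
    stop("all mass at k = 0: Poisson mean not identifiable", call. = FALSE)
  boundary <- FALSE
  if (!truncated) {
    lambda <- m
    ll <- sum(f * stats::dpois(k, lambda, log = TRUE))
  } else {
    if (any(k == 0L))
      stop("zero-truncated fit given a histogram containing k = 0",
           call. = FALSE)
    if (m <= 1 + 1e-12) {
      # mean at minimal support: ZTP mean -> 1 as lambda -> 0
      lambda <- 0
      boundary <- TRUE
      ll <- NA_real_
    } else {
      g <- function(l) l / (1 - exp(-l)) - m
      upper <- m
      while (g(upper) < 0) upper <- upper * 2  # ZTP mean > lambda, converges
      lambda <- stats::uniroot(g, c(1e-12, upper), tol = 1e-8)$root
      ll <- sum(f * (stats::dpois(k, lambda, log = TRUE) -
                       log1p(-exp(-lambda))))
    }
  }
  structure(list(lambda_hat = lambda, log_likelihood = ll,
                 truncated = truncated, boundary = boundary, n = n),
            class = "poisson_fit")
}

#' @export
print.poisson_fit <- function(x, ...) {
  cat(sprintf("%s Poisson fit (n = %g): lambda_hat = %.4f%s, logLik = %.2f\n",
              if (x$truncated) "Zero-truncated" else "Untruncated",
              x$n, x$lambda_hat,
              if (x$boundary) " [boundary]" else "",
              x$log_likelihood))
  invisible(x)
}

#' Simulate streptavidin label counts for a population
#'
#' Each A monomer carries one biotin anchor; a streptavidin label attaches
#' independently with probability `labeling_efficiency`, so the label count
#' of a chain is Binomial(n_A, efficiency). With truncation, chains carrying
#' zero labels are invisible on the surface and are dropped from the
#' histogram.
#'
#' @param pop a [dht_population].
#' @param labeling_efficiency per-site labeling probability in `[0, 1]`.
#' @param seed RNG seed.
#' @param truncated drop zero-label chains and flag the histogram
#'   (default `TRUE`, the detection-realistic convention).
#' @return a [label_histogram()].
#' @export
label_counts <- function(pop, labeling_efficiency = 1, seed = NULL,
                         truncated = TRUE) {
  stopifnot(inherits(pop, "dht_population"))
  stop_if_not_scalar_number(labeling_efficiency, "labeling_efficiency",
                            nonneg = TRUE)
  if (labeling_efficiency > 1)
    stop("labeling_efficiency must be <= 1", call. = FALSE)
  nA <- chain_composition(pop)$n_A
  labels <- with_seed(seed, {
    if (labeling_efficiency == 1) nA
    else stats::rbinom(length(nA), nA, labeling_efficiency)
  })
  tabulate_labels(labels, truncated = truncated)
}
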