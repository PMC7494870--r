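# Synthetic particle populations: true interior configuration labels, a
# classification-confusion model emulating marginalization data-hiding, and
# maximum-likelihood recovery of the true saturation fraction.

#' Classification confusion model
#'
#' Label-level model of how marginalized single-particle classification
#' distorts class populations.  A truly saturated (tetrahedral) particle is
#' lost to the non-tetrahedral class N with probability `lambda_loss`
#' (sub-populations hidden by broad backprojection); a truly non-tetrahedral
#' particle is spuriously assigned to a tetrahedral class with probability
#' `eta_gain`, split equally between X and Y.
#'
#' @param lambda_loss probability in `[0, 1]` that a tetrahedral particle is
#'   observed as N.
#' @param eta_gain probability in `[0, 1]` that a non-tetrahedral particle
#'   is observed as X or Y.
#' @return an `ObservationModel` (list with `lambda_loss`, `eta_gain`).
#' @export
observation_model <- function(lambda_loss = 0, eta_gain = 0) {
  check_prob(lambda_loss, "lambda_loss")
  check_prob(eta_gain, "eta_gain")
  structure(list(lambda_loss = lambda_loss, eta_gain = eta_gain),
            class = "ObservationModel")
}

check_prob <- function(x, what) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    stop(what, " must be a probability in [0, 1]")
  }
  invisible(x)
}

#' Expected observed class fractions
#'
#' Forward model linking the true saturation fraction (probability that a
#' particle's interior is complete, hence in one of the two tetrahedral
#' arrangements, split equally between X and Y by the assembly symmetry) to
#' the expected observed class fractions under the confusion model:
#' \deqn{f_X = f_Y = \frac{s}{2}(1-\lambda) + \frac{1-s}{2}\,\eta, \qquad
#'       f_N = 1 - f_X - f_Y.}
#' With no confusion, a true saturation of 0.60 gives the observed split
#' (0.30, 0.30, 0.40).
#'
#' @param saturation true saturation fraction `s` in `[0, 1]`.
#' @param obs an [`observation_model()`].
#' @return named numeric vector `c(X = fX, Y = fY, N = fN)` summing to 1.
#' @examples
#' expected_fractions(0.6, observation_model())  # 0.30 0.30 0.40
#' @export
expected_fractions <- function(saturation, obs = observation_model()) {
  check_prob(saturation, "saturation")
  stopifnot(inherits(obs, "ObservationModel"))
  fx <- saturation / 2 * (1 - obs$lambda_loss) +
    (1 - saturation) / 2 * obs$eta_gain
  c(X = fx, Y = fx, N = 1 - 2 * fx)
}

#' Generate a synthetic particle population
#'
#' Draws per-particle true interior states from
#' `(tetrahedral-X, tetrahedral-Y, non-tetrahedral)` with probabilities
#' `(s/2, s/2, 1 - s)` and passes each through the confusion model to give
#' an observed label in `{X, Y, N}`.  Unsaturated and suboptimal true
#' interiors are collapsed into the single `non-tetrahedral` state, because
#' the classification being emulated cannot reconstruct them separately.
#'
#' @param n number of particles (>= 0).
#' @param saturation true saturation fraction in `[0, 1]`.
#' @param obs an [`observation_model()`].
#' @param seed integer seed.
#' @return a `PopulationTable`: data frame with columns `particle`,
#'   `true_class` (`"tetrahedral-X"`, `"tetrahedral-Y"`,
#'   `"non-tetrahedral"`), `observed_class` (`"X"`, `"Y"`, `"N"`), with the
#'   generating parameters in `attr(, "metadata")`.
#' @export
generate_population <- function(n, saturation, obs = observation_model(),
                                seed = 1L) {
  n <- as.integer(n)
  if (is.na(n) || n < 0L) stop("n must be a non-negative integer")
  check_prob(saturation, "saturation")
  stopifnot(inherits(obs, "ObservationModel"))
  set.seed(as.integer(seed))
  true_levels <- c("tetrahedral-X", "tetrahedral-Y", "non-tetrahedral")
  if (n > 0L) {
    true_class <- sample(true_levels, n, replace = TRUE,
                         prob = c(saturation / 2, saturation / 2,
                                  1 - saturation))
    u <- stats::runif(n)
    observed_class <- character(n)
    tet <- true_class != "non-tetrahedral"
    observed_class[tet] <- ifelse(u[tet] < obs$lambda_loss, "N",
                                  substr(true_class[tet], 13L, 13L))
    gain_xy <- ifelse(u < obs$eta_gain / 2, "X",
                      ifelse(u < obs$eta_gain, "Y", "N"))
    observed_class[!tet] <- gain_xy[!tet]
  } else {
    true_class <- character(0)
    observed_class <- character(0)
  }
  out <- data.frame(particle = seq_len(n), true_class = true_class,
                    observed_class = observed_class,
                    stringsAsFactors = FALSE)
  attr(out, "metadata") <- list(n = n, saturation = saturation,
                                lambda_loss = obs$lambda_loss,
                                eta_gain = obs$eta_gain,
                                seed = as.integer(seed))
  class(out) <- c("PopulationTable", "data.frame")
  out
}

#' Observed class counts of a population table
#'
#' @param pop a [`generate_population()`] table.
#' @return named integer vector `c(X = , Y = , N = )`.
#' @export
class_counts <- function(pop) {
  stopifnot(inherits(pop, "PopulationTable"))
  vapply(c("X", "Y", "N"),
         function(k) sum(pop$observed_class == k), integer(1))
}

#' Maximum-likelihood estimate of the true saturation fraction
#'
#' Inverts the [`expected_fractions()`] forward model: given observed X/Y/N
#' counts and *known* confusion parameters, estimates the true saturation
#' fraction by maximum likelihood under the trinomial model, with a
#' profile-likelihood confidence interval.  Because the model never
#' distinguishes X from Y, the likelihood depends on the data only through
#' the tetrahedral total `nX + nY`, and the observed three counts carry two
#' degrees of freedom: `(saturation, lambda_loss, eta_gain)` is not jointly
#' identifiable, which is why the confusion parameters must be supplied, not
#' estimated.
#'
#' The closed-form unconstrained maximiser is
#' \eqn{\hat s = (p̂ - \eta) / (1 - \lambda - \eta)} with
#' \eqn{p̂ = (n_X + n_Y)/n}; it is clipped to `[0, 1]` (flagged as a
#' boundary estimate when the raw value falls outside, i.e. the counts are
#' incompatible with the model for every interior saturation).  When
#' `1 - lambda_loss - eta_gain = 0` the likelihood is flat in the saturation
#' and the estimate is flagged non-identifiable.
#'
#' @param counts numeric vector of observed counts, in X, Y, N order (names
#'   `X`/`Y`/`N` honoured if present); non-negative, not all zero.
#' @param obs the (known) [`observation_model()`].
#' @param conf_level confidence level for the profile-likelihood interval.
#' @return a `ClassFractionEstimate`: list with `estimate`, `conf_int`
#'   (length 2), `conf_level`, `log_likelihood`, `boundary`,
#'   `identifiable`, `counts`.
#' @examples
#' est <- estimate_saturation(c(X = 300, Y = 300, N = 400))
#' est$estimate  # 0.6
#' @export
estimate_saturation <- function(counts, obs = observation_model(),
                                conf_level = 0.95) {
  stopifnot(inherits(obs, "ObservationModel"))
  if (!is.null(names(counts)) && all(c("X", "Y", "N") %in% names(counts))) {
    counts <- counts[c("X", "Y", "N")]
  }
  counts <- as.numeric(counts)
  if (length(counts) != 3L || anyNA(counts) || any(counts < 0)) {
    stop("counts must be three non-negative values (X, Y, N)")
  }
  n <- sum(counts)
  if (n == 0) stop("counts must not all be zero")
  k <- counts[1] + counts[2]
  slope <- 1 - obs$lambda_loss - obs$eta_gain  # d(2 fX)/d(saturation)

  ll_of <- function(s) {
    p <- s * slope + obs$eta_gain  # P(observed tetrahedral)
    xlogy(k, p) + xlogy(n - k, 1 - p)
  }

  if (abs(slope) < .Machine$double.eps^0.5) {
    return(structure(
      list(estimate = NA_real_, conf_int = c(0, 1),
           conf_level = conf_level, log_likelihood = ll_of(0),
           boundary = FALSE, identifiable = FALSE,
           counts = stats::setNames(counts, c("X", "Y", "N"))),
      class = "ClassFractionEstimate"))
  }

  s_raw <- (k / n - obs$eta_gain) / slope
  s_hat <- min(max(s_raw, 0), 1)
  boundary <- s_raw < 0 || s_raw > 1
  ll_hat <- ll_of(s_hat)
  drop <- stats::qchisq(conf_level, df = 1) / 2
  f <- function(s) ll_of(s) - (ll_hat - drop)
  lo <- if (s_hat == 0 || f(0) >= 0) 0 else
    stats::uniroot(f, c(0, s_hat), tol = 1e-10)$root
  hi <- if (s_hat == 1 || f(1) >= 0) 1 else
    stats::uniroot(f, c(s_hat, 1), tol = 1e-10)$root

  structure(
    list(estimate = s_hat, conf_int = c(lo, hi), conf_level = conf_level,
         log_likelihood = ll_hat, boundary = boundary, identifiable = TRUE,
         counts = stats::setNames(counts, c("X", "Y", "N"))),
    class = "ClassFractionEstimate")
}

xlogy <- function(x, y) if (x == 0) 0 else x * log(y)

#' @export
print.ClassFractionEstimate <- function(x, ...) {
  if (!x$identifiable) {
    cat("ClassFractionEstimate: saturation not identifiable",
        "(1 - lambda_loss - eta_gain = 0)\n")
  } else {
    cat(sprintf("ClassFractionEstimate: saturation = %.4f, %d%% CI [%.4f, %.4f]%s\n",
                x$estimate, round(100 * x$conf_level),
                x$conf_int[1], x$conf_int[2],
                if (x$boundary) " (boundary estimate)" else ""))
  }
  invisible(x)
}

#' Write a population table as CSV with a JSON metadata sidecar
#'
#' @param pop a [`generate_population()`] table.
#' @param path CSV output path; the metadata goes to `<path>.meta.json`.
#' @return invisibly, the two paths written.
#' @export
write_population <- function(pop, path) {
  stopifnot(inherits(pop, "PopulationTable"))
  utils::write.csv(as.data.frame(pop), path, row.names = FALSE, quote = FALSE)
  meta_path <- paste0(path, ".meta.json")
  jsonlite::write_json(attr(pop, "metadata"), meta_path, auto_unbox = TRUE,
                       digits = NA)
  invisible(c(csv = path, metadata = meta_path))
}
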