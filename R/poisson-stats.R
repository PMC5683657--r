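#' Fano factor of trial spike counts
#'
#' Variance of the spike count across repeated trials divided by its mean,
#' using the unbiased (n-1) variance estimator. Equals 1 for a Poisson
#' process at any rate and window length.
#'
#' @param counts Integer vector of spike counts, one per trial (`>= 2`).
#' @return Variance/mean ratio, or `NA` when the mean count is zero (the
#'   ratio is undefined; such cells are excluded from summaries).
#' @export
fano_factor <- function(counts) {
  if (length(counts) < 2) stop("need at least 2 trials")
  m <- mean(counts)
  if (m == 0) return(NA_real_)
  var(counts) / m
}

#' Observed and Poisson-predicted coefficient of variation
#'
#' `cv_observed()` is the ratio of the standard deviation to the mean of the
#' single-trial rate estimates. For a Poisson neuron with true rate `r_m`
#' observed for `T` seconds the CV equals `1 / sqrt(r_m * T)` -- the inverse
#' square root of the expected spike count -- which `cv_poisson()` returns.
#'
#' @param rates Numeric vector of single-trial rate estimates (spikes/s).
#' @return `cv_observed()`: sd/mean, `NA` when the mean is zero.
#' @export
cv_observed <- function(rates) {
  if (length(rates) < 2) stop("need at least 2 trials")
  m <- mean(rates)
  if (m == 0) return(NA_real_)
  sd(rates) / m
}

#' @rdname cv_observed
#' @param r_m True (or estimated mean) spiking rate in spikes/s, `> 0`.
#' @param T Observation window length in seconds, `> 0`.
#' @return `cv_poisson()`: `1 / sqrt(r_m * T)`.
#' @export
cv_poisson <- function(r_m, T) {
  if (any(r_m <= 0) || any(T <= 0)) stop("'r_m' and 'T' must be positive")
  1 / sqrt(r_m * T)
}

#' Variance in observed CVs explained by the Poisson prediction
#'
#' Coefficient of determination
#' `r^2 = 1 - sum((CV_obs - CV_Poisson)^2) / sum((CV_obs - mean(CV_obs))^2)`
#' comparing observed CVs against the zero-parameter Poisson prediction; can
#' be negative when the prediction fits worse than the mean.
#'
#' @param cv_obs,cv_pred Paired vectors of observed and predicted CVs;
#'   pairs with missing values are dropped.
#' @return `r^2`.
#' @export
cv_r_squared <- function(cv_obs, cv_pred) {
  ok <- is.finite(cv_obs) & is.finite(cv_pred)
  cv_obs <- cv_obs[ok]
  cv_pred <- cv_pred[ok]
  if (length(cv_obs) < 2) stop("need at least 2 usable CV pairs")
  ss_tot <- sum((cv_obs - mean(cv_obs))^2)
  if (ss_tot == 0) stop("observed CVs have zero variance")
  1 - sum((cv_obs - cv_pred)^2) / ss_tot
}

#' Likelihood-ratio goodness-of-fit test for Poisson counts
#'
#' Tests the Poisson null against a negative-binomial (overdispersed)
#' alternative. Because the Poisson sits on the boundary of the
#' negative-binomial family, the LRT statistic is referred to the boundary
#' mixture `0.5 chi2_0 + 0.5 chi2_1`. Underdispersion is not the tested
#' alternative, so constant counts give `p = 1`.
#'
#' @param counts Integer vector of spike counts across trials (`>= 2`).
#' @return p-value for the Poisson null.
#' @export
poisson_gof_test <- function(counts) {
  if (length(counts) < 2) stop("need at least 2 trials")
  m <- mean(counts)
  if (m == 0) return(1)
  ll_pois <- sum(dpois(counts, m, log = TRUE))
  nll_nb <- function(log_theta)
    -sum(dnbinom(counts, size = exp(log_theta), mu = m, log = TRUE))
  opt <- optimize(nll_nb, c(-7, 25))
  stat <- 2 * ((-opt$objective) - ll_pois)        # 2*(llNB - llPois)
  if (!is.finite(stat) || stat <= 0) return(1)
  0.5 * pchisq(stat, df = 1, lower.tail = FALSE)
}

#' Poisson count discriminability between two rates
#'
#' Standardised separation of the spike-count distributions evoked by two
#' stimuli in a window of `T` seconds,
#' `d' = |r1 - r2| T / sqrt((r1 + r2) T / 2)` (count-domain d-prime with the
#' two Poisson variances averaged). Exactly invariant under uniform
#' adaptation with a compensating window:
#' `d'(k r1, k r2, T/k) = d'(r1, r2, T)` for any `k > 0`, which is why
#' scaling all rates down while growing the read-out window leaves decoding
#' unchanged for Poisson populations.
#'
#' @param r1,r2 Rates in spikes/s, `>= 0`.
#' @param T Window length in seconds, `> 0`.
#' @return d-prime (0 when both rates are zero).
#' @export
poisson_discriminability <- function(r1, r2, T) {
  if (any(r1 < 0) || any(r2 < 0) || any(T <= 0))
    stop("need r1, r2 >= 0 and T > 0")
  s <- (r1 + r2) * T / 2
  ifelse(s == 0, 0, abs(r1 - r2) * T / sqrt(s))
}

#' Poisson diagnostics across a spike-train set
#'
#' Computes, for every (neuron, stimulus, window) cell over nonoverlapping
#' windows, the trial mean and variance of the spike count, the Fano
#' factor, the mean rate, the observed CV and the Poisson-predicted CV, and
#' labels each window's response epoch (`pre` before onset, `onset`
#' `[0, 200)` ms, `sustained` `[200, 500]` ms, `post` afterwards).
#'
#' @param data A [spike_train_set()].
#' @param window_length Nonoverlapping window length in ms.
#' @param span Interval to cover; default the record span.
#' @return Data frame with columns `neuron`, `stimulus`, `window_start`,
#'   `mean_count`, `var_count`, `fano`, `mean_rate`, `cv_obs`,
#'   `cv_poisson`, `epoch`. Cells with zero mean count carry `NA`
#'   diagnostics.
#' @export
poisson_diagnostics <- function(data, window_length = 15, span = NULL) {
  stopifnot(inherits(data, "spike_train_set"))
  if (is.null(span)) span <- data$record_span
  win <- sliding_windows(span, window_length, window_length)
  Tsec <- window_length / 1000
  nn <- n_neurons(data)
  ns <- n_stimuli(data)
  out <- vector("list", nrow(win))
  for (w in seq_len(nrow(win))) {
    cnt <- count_tensor(data, time_window(win$start[w], window_length))
    mc <- apply(cnt, c(1, 2), mean)
    vc <- apply(cnt, c(1, 2), var)
    mr <- mc / Tsec
    cvp <- ifelse(mr > 0, 1 / sqrt(mr * Tsec), NA_real_)
    cvo <- ifelse(mc > 0, sqrt(vc) / mc, NA_real_)
    out[[w]] <- data.frame(
      neuron = rep(data$neurons, times = ns),
      stimulus = rep(seq_len(ns), each = nn),
      window_start = win$start[w],
      mean_count = as.vector(mc), var_count = as.vector(vc),
      fano = as.vector(ifelse(mc > 0, vc / mc, NA_real_)),
      mean_rate = as.vector(mr), cv_obs = as.vector(cvo),
      cv_poisson = as.vector(cvp))
  }
  res <- do.call(rbind, out)
  res$epoch <- cut(res$window_start, c(-Inf, 0, 200, 500 + 1e-9, Inf),
                   labels = c("pre", "onset", "sustained", "post"),
                   right = FALSE)
  res
}
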