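#' Squeeze [0,1] responses into the open unit interval
#'
#' The beta likelihood is undefined at exactly 0 or 1, and zero-activity
#' hours are common, so the response is compressed once, globally, with the
#' standard shrink-toward-1/2 transform y' = (y (n - 1) + 1/2) / n before
#' any fit. 1/2 is its fixed point and the transform is invertible.
#'
#' @param y values in `[0, 1]`
#' @param n sample size driving the shrink (default `length(y)`)
#' @return values strictly inside (0, 1)
#' @export
boundary_transform <- function(y, n = length(y)) {
  if (any(y < 0 | y > 1)) stop("values must lie in [0, 1]")
  (y * (n - 1) + 0.5) / n
}

#' @rdname boundary_transform
#' @param y_prime transformed values
#' @export
inverse_boundary_transform <- function(y_prime, n) {
  (y_prime * n - 0.5) / (n - 1)
}

# Build the model formula: smooth-designated predictors get penalized
# thin-plate splines, everything else enters parametrically (factors as
# dummies, ordinal numerics linearly).
.gam_formula <- function(response, predictors, smooth_terms, k) {
  if (length(predictors) == 0) {
    rhs <- "1"
  } else {
    terms <- ifelse(predictors %in% smooth_terms,
                    sprintf("s(%s, k = %d)", predictors, k), predictors)
    rhs <- paste(terms, collapse = " + ")
  }
  stats::as.formula(paste(response, "~", rhs))
}

#' Fit a beta-regression GAM for normalized hourly activity
#'
#' Penalized-spline generalized additive model with a beta-distributed
#' response on (0,1) and logit mean link, the model family used for the
#' normalized mean acoustic activity (MAA). Continuous predictors named in
#' `smooth_terms` (by default the hour of day, hours since explosion and
#' cumulative hours) receive thin-plate regression splines; categorical
#' predictors enter as factors and ordinal ones linearly. Smoothness is
#' selected by REML.
#'
#' @param data data.frame of response and predictors
#' @param response name of the response column (values strictly in (0,1);
#'   apply [boundary_transform()] first)
#' @param predictors character vector of predictor column names (possibly
#'   empty for the intercept-only model)
#' @param smooth_terms predictors to model as penalized smooths
#' @param k basis dimension per smooth (default 10)
#' @param link link function for the beta mean (default logit)
#' @return object of class `beta_gam_fit`: list with the mgcv `fit`,
#'   `aicc`, `dev_expl`, `r_sq`, `edf` (total effective df incl. the
#'   precision parameter), `phi`, `predictors`, `converged`
#' @export
fit_beta_gam <- function(data, response = "maa", predictors = character(0),
                         smooth_terms = c("hour_of_day",
                                          "hours_since_explosion",
                                          "cumulative_hours"),
                         k = 10, link = "logit") {
  y <- data[[response]]
  if (any(y <= 0 | y >= 1))
    stop("response must be strictly inside (0,1); apply boundary_transform()")
  form <- .gam_formula(response, predictors, smooth_terms, k)
  fam <- do.call(mgcv::betar, list(link = link))  # betar() substitutes `link`
  fit <- mgcv::gam(form, family = fam, data = data, method = "REML")
  n <- stats::nobs(fit)
  edf <- sum(fit$edf) + 1  # + 1 for the beta precision parameter
  ll <- as.numeric(stats::logLik(fit))
  aicc <- -2 * ll + 2 * edf + 2 * edf * (edf + 1) / (n - edf - 1)
  s <- summary(fit)
  structure(list(fit = fit, aicc = aicc, dev_expl = s$dev.expl,
                 r_sq = s$r.sq, edf = edf,
                 phi = fit$family$getTheta(TRUE), logLik = ll, n = n,
                 predictors = predictors,
                 converged = isTRUE(fit$converged)),
            class = "beta_gam_fit")
}

#' @export
print.beta_gam_fit <- function(x, ...) {
  cat(sprintf(
    "beta GAM (logit link): %s\n  n = %d, edf = %.2f, phi = %.2f, AICc = %.2f, deviance explained = %.1f%%\n",
    if (length(x$predictors)) paste(x$predictors, collapse = " + ")
    else "intercept only",
    x$n, x$edf, x$phi, x$aicc, 100 * x$dev_expl))
  invisible(x)
}

#' All-subsets model selection by AICc
#'
#' Fits every subset of the candidate predictors (the intercept is always
#' included), ranks them by the corrected Akaike information criterion
#' AICc = -2 logLik + 2k + 2k(k+1)/(n-k-1), with k the total effective
#' parameter count (sum of effective df plus one for the beta precision).
#' The minimum-AICc model is selected; if AICc values tie to 2 decimal
#' places the model with fewest predictors wins.
#'
#' @inheritParams fit_beta_gam
#' @param candidates candidate predictor names (at most 12)
#' @return list with `table` (predictors, r_sq, dev_expl, df, aicc,
#'   delta_aicc, sorted ascending), `best` (selected predictor subset) and
#'   `best_fit` (its `beta_gam_fit`)
#' @export
all_subsets_selection <- function(data, response = "maa", candidates,
                                  smooth_terms = c("hour_of_day",
                                                   "hours_since_explosion",
                                                   "cumulative_hours"),
                                  k = 10, link = "logit") {
  if (length(candidates) > 12)
    stop("at most 12 candidate predictors (2^12 fits)")
  p <- length(candidates)
  subsets <- lapply(0:(2^p - 1), function(m)
    candidates[bitwAnd(m, 2^(seq_len(p) - 1)) > 0])
  rows <- list()
  fits <- list()
  for (i in seq_along(subsets)) {
    sub <- subsets[[i]]
    f <- tryCatch(
      fit_beta_gam(data, response, sub, smooth_terms, k, link),
      error = function(e) {
        message("subset skipped (", paste(sub, collapse = "+"), "): ",
                conditionMessage(e))
        NULL
      })
    if (is.null(f)) next
    if (f$n <= f$edf + 1) next
    key <- if (length(sub)) paste(sort(sub), collapse = " + ") else "(intercept)"
    fits[[key]] <- f
    rows[[key]] <- data.frame(predictors = key, n_predictors = length(sub),
                              r_sq = f$r_sq, dev_expl = f$dev_expl,
                              df = f$edf, aicc = f$aicc)
  }
  tab <- do.call(rbind, rows)
  tab <- tab[order(tab$aicc), ]
  tab$delta_aicc <- tab$aicc - tab$aicc[1]
  rownames(tab) <- NULL
  tied <- which(round(tab$aicc, 2) == round(tab$aicc[1], 2))
  best_key <- tab$predictors[tied[which.min(tab$n_predictors[tied])]]
  best_fit <- fits[[best_key]]
  list(table = tab, best = best_fit$predictors, best_fit = best_fit)
}

#' Per-predictor explained-deviance contributions
#'
#' For each predictor retained in the selected model, refits the model
#' without that predictor and reports the drop in explained deviance,
#' contribution = DE(full) - DE(full minus predictor). Contributions are
#' reported individually and need not sum to the full model's explained
#' deviance.
#'
#' @inheritParams fit_beta_gam
#' @param predictors predictors of the selected model
#' @return data.frame with `predictor`, `dev_expl_without`, `contribution`
#' @export
deviance_by_predictor <- function(data, response = "maa", predictors,
                                  smooth_terms = c("hour_of_day",
                                                   "hours_since_explosion",
                                                   "cumulative_hours"),
                                  k = 10, link = "logit") {
  full <- fit_beta_gam(data, response, predictors, smooth_terms, k, link)
  rows <- lapply(predictors, function(p) {
    f <- tryCatch(fit_beta_gam(data, response, setdiff(predictors, p),
                               smooth_terms, k, link),
                  error = function(e) NULL)
    data.frame(predictor = p,
               dev_expl_without = if (is.null(f)) NA_real_ else f$dev_expl,
               contribution = if (is.null(f)) NA_real_
               else full$dev_expl - f$dev_expl)
  })
  out <- do.call(rbind, rows)
  attr(out, "dev_expl_full") <- full$dev_expl
  out[order(-out$contribution), ]
}

#' Residual autocorrelation diagnostics
#'
#' Sample autocorrelations to lag 48 and the Durbin-Watson statistic
#' DW = sum((e_t - e_{t-1})^2) / sum(e_t^2) on residuals ordered in time,
#' with a permutation p-value (the classical DW bounds assume ordinary
#' linear regression, which this model is not). Independent residuals give
#' DW near 2; AR(1) residuals with coefficient rho give DW near 2(1-rho).
#'
#' @param residuals residuals ordered by time
#' @param lag_max maximum acf lag (default 48)
#' @param n_perm number of order permutations (default 2000)
#' @param seed RNG seed for the permutations
#' @return list with `acf` (lags 1..lag_max), `dw`, `p_value`
#' @export
residual_autocorrelation <- function(residuals, lag_max = 48, n_perm = 2000,
                                     seed = 1L) {
  n <- length(residuals)
  if (n < 50) {
    warning("fewer than 50 residuals; acf truncated")
    lag_max <- min(lag_max, n - 1)
  }
  lag_max <- min(lag_max, n - 1)
  ac <- as.numeric(stats::acf(residuals, lag.max = lag_max,
                              plot = FALSE)$acf)[-1]
  dw_of <- function(e) sum(diff(e)^2) / sum(e^2)
  dw <- dw_of(residuals)
  set.seed(seed)
  perm <- replicate(n_perm, dw_of(sample(residuals)))
  p_lo <- (sum(perm <= dw) + 1) / (n_perm + 1)
  p_hi <- (sum(perm >= dw) + 1) / (n_perm + 1)
  list(acf = ac, dw = dw, p_value = min(1, 2 * min(p_lo, p_hi)))
}

#' Simulate hourly-activity data with known GAM structure
#'
#' Generates (response, predictors) rows from a beta distribution through
#' the logit link: a smooth diel effect on the hour of day (elevated at
#' night, depressed in working hours), categorical day-relative-to-event
#' effects (reduced day of / day after, elevated second day after) and
#' optional seasonal effects. Used for parameter- and selection-recovery
#' checks; the generating components are returned as attributes.
#'
#' @param n rows
#' @param phi beta precision (default 20)
#' @param intercept linear-predictor intercept
#' @param diel_amplitude amplitude of the smooth hour effect
#' @param day_effects named vector of effects for day_of, day_after,
#'   second_day_after (day_before is the reference)
#' @param season_effects length-4 vector (autumn, winter, spring, summer);
#'   zeros exclude season from the truth
#' @param seed RNG seed
#' @return data.frame with `hour_of_day`, `day`, `season`, `maa`;
#'   attributes `true_mu`, `true_smooth` (per-row diel component)
#' @export
simulate_gam_data <- function(n = 1000, phi = 20, intercept = -0.3,
                              diel_amplitude = 0.8,
                              day_effects = c(day_of = -0.7,
                                              day_after = -0.4,
                                              second_day_after = 0.3),
                              season_effects = c(autumn = 0, winter = 0,
                                                 spring = 0, summer = 0),
                              seed = 1L) {
  set.seed(seed)
  hour <- sample(0:23, n, replace = TRUE)
  day <- factor(sample(c("day_before", "day_of", "day_after",
                         "second_day_after"), n, replace = TRUE),
                levels = c("day_before", "day_of", "day_after",
                           "second_day_after"))
  season <- factor(sample(names(season_effects), n, replace = TRUE),
                   levels = names(season_effects))
  smooth <- diel_amplitude * cos(2 * pi * (hour - 2) / 24)
  eta <- intercept + smooth +
    c(day_before = 0, day_effects)[as.character(day)] +
    season_effects[as.character(season)]
  mu <- stats::plogis(eta)
  y <- stats::rbeta(n, mu * phi, (1 - mu) * phi)
  y <- pmin(pmax(y, 1e-6), 1 - 1e-6)
  out <- data.frame(hour_of_day = hour, day = day, season = season, maa = y)
  attr(out, "true_mu") <- mu
  attr(out, "true_smooth") <- smooth
  attr(out, "phi") <- phi
  out
}

#' Assemble the GAM predictor table from simulator output
#'
#' Builds the hourly predictor/response rows used by the activity model:
#' hour of day, day label relative to the nearest eligible training event,
#' day/night block, season (autumn = Sep-Nov, winter = Dec-Feb,
#' spring = Mar-May, summer = Jun-Aug), hours since the most recent
#' detonation, size of the most recent detonation (0 when none yet),
#' number of previous detonations within the event, deployment label and
#' cumulative hours since the start of the dataset. Only hours that fall
#' inside an event's labelled window are retained (hours with no recorded
#' segments are dropped, not imputed).
#'
#' @param hourly [hourly_mean_activity()] output
#' @param events event schedule with `undet_time` (and optionally
#'   `size_class` as ordinal 1-3)
#' @param deployment single label or per-event labels
#' @return data.frame of predictors plus `maa` in [0,1]
#' @export
build_gam_table <- function(hourly, events, deployment = "1") {
  lt <- as.POSIXlt(hourly$hour_start, tz = "UTC")
  date <- as.Date(hourly$hour_start, tz = "UTC")
  month <- lt$mon + 1L
  season <- c("winter", "winter", "spring", "spring", "spring", "summer",
              "summer", "summer", "autumn", "autumn", "autumn",
              "winter")[month]
  rows <- list()
  t0 <- min(hourly$hour_start)
  undet_times <- sort(events$undet_time)
  sizes <- if ("size_ordinal" %in% names(events))
    events$size_ordinal[order(events$undet_time)] else rep(2L, nrow(events))
  for (i in seq_len(nrow(events))) {
    days <- label_event_days(events[i, ])
    ix <- which(date %in% days$date & !is.na(hourly$maa_raw))
    if (!length(ix)) next
    lab <- days$label[match(date[ix], days$date)]
    # hours since the most recent detonation at or before each hour
    tnum <- as.numeric(hourly$hour_start[ix])
    unum <- as.numeric(undet_times)
    hse <- vapply(tnum, function(tt) {
      d <- (tt - unum) / 3600
      d <- d[d >= 0]
      if (length(d)) min(d) else NA_real_
    }, 0)
    last_sz <- vapply(tnum, function(tt) {
      ok <- which(unum <= tt)
      if (length(ok)) as.integer(sizes[ok[length(ok)]]) else 0L
    }, 0L)
    rows[[i]] <- data.frame(
      hour_start = hourly$hour_start[ix],
      maa = hourly$maa[ix],
      hour_of_day = lt$hour[ix],
      day = factor(as.character(lab),
                   levels = c("day_before", "day_of", "day_after",
                              "second_day_after")),
      day_night = factor(ifelse(lt$hour[ix] %in% 6:17, "day", "night")),
      season = factor(season[ix],
                      levels = c("autumn", "winter", "spring", "summer")),
      hours_since_explosion = hse,
      size_of_explosion = last_sz,
      # cumulative detonations within this event up to each hour
      previous_explosions = as.integer(tnum >= as.numeric(events$undet_time[i])),
      deployment = factor(rep_len(deployment, length(ix))),
      cumulative_hours = as.numeric(difftime(hourly$hour_start[ix], t0,
                                             units = "hours")) + 1)
  }
  out <- do.call(rbind, rows)
  out$hours_since_explosion[is.na(out$hours_since_explosion)] <- 0
  rownames(out) <- NULL
  out
}
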