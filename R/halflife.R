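#' First-order aminoacylation decay model
#'
#' N(t) = N0 * (1/2)^(t / t_half) + N_inf: charge decays exponentially
#' from N0 + N_inf at t = 0 toward the floor N_inf, which accommodates the
#' small fraction of tRNAs still presenting a CCA end after full
#' deacylation.
#'
#' @param t Time in minutes (>= 0).
#' @param N0 Decaying amplitude, percent, in \[0, 100\].
#' @param t_half Half-life in minutes, in \[1, 1e5\].
#' @param N_inf Charge floor, percent, in \[0, 3.5\].
#' @return Charge (percent) at time `t`.
#' @export
decay_model <- function(t, N0, t_half, N_inf) {
  if (any(t < 0)) stop("negative time")
  N0 * 0.5^(t / t_half) + N_inf
}

#' The default sampling grid: 0, 4, 8, 16, 32 min, 1, 2, 4, 8, 16 and 40 h,
#' in minutes.
#' @rdname decay_model
#' @export
decay_timepoints <- function() c(0, 4, 8, 16, 32, 60, 120, 240, 480, 960,
                                 2400)

decay_bounds <- function() {
  list(lower = c(N0 = 0, t_half = 1, N_inf = 0),
       upper = c(N0 = 100, t_half = 1e5, N_inf = 3.5))
}

decay_sse <- function(par, t, y) {
  sum((decay_model(t, par[1L], par[2L], par[3L]) - y)^2)
}

#' Fit first-order aminoacylation decay
#'
#' Minimizes the pooled sum of squared errors over all timepoints and
#' replicates by bounded quasi-Newton (L-BFGS-B) with box constraints
#' N0 in \[0, 100\], t_half in \[1, 1e5\] min, N_inf in \[0, 3.5\].
#' The SSE surface has local minima in t_half, so the optimizer is
#' multi-started from a coarse log-spaced t_half lattice (10^0..10^5) and
#' the best converged minimum is kept; the result is deterministic.
#'
#' @param data Data frame: `t_minutes`, `charge_pct`, optional `replicate`.
#' @param group_id Label carried into the output.
#' @param starts_t_half Multi-start lattice for t_half (minutes).
#' @return List of class `decay_fit`: `group_id`, `N0`, `t_half`, `N_inf`,
#'   `sse`, `at_bound` (named logical per parameter), `identifiable`
#'   (FALSE when t_half is pinned at a bound or N0 is ~0: no decay
#'   signal).
#' @export
fit_decay <- function(data, group_id = "group",
                      starts_t_half = 10^(0:5)) {
  stopifnot(all(c("t_minutes", "charge_pct") %in% names(data)))
  t <- data$t_minutes; y <- data$charge_pct
  if (length(unique(t)) < 4L)
    stop("need at least 4 distinct timepoints to fit 3 parameters")
  b <- decay_bounds()
  n0_start <- min(100, max(0, max(y) - min(y)))
  ninf_start <- min(3.5, max(0, min(y)))
  fits <- lapply(starts_t_half, function(th0) {
    p0 <- c(n0_start, min(max(th0, 1), 1e5), ninf_start)
    optim(p0, decay_sse, t = t, y = y, method = "L-BFGS-B",
          lower = b$lower, upper = b$upper, control = list(factr = 1e2))
  })
  best <- fits[[which.min(vapply(fits, `[[`, numeric(1), "value"))]]
  par <- setNames(best$par, c("N0", "t_half", "N_inf"))
  eps <- 1e-6
  at_bound <- (par <= b$lower * (1 + eps) + eps) |
    (par >= b$upper * (1 - eps))
  structure(list(group_id = group_id, N0 = par[["N0"]],
                 t_half = par[["t_half"]], N_inf = par[["N_inf"]],
                 sse = best$value, at_bound = at_bound,
                 identifiable = !(at_bound[["t_half"]] ||
                                    par[["N0"]] < 1)),
            class = "decay_fit")
}

#' Bootstrap confidence intervals for the decay parameters
#'
#' Resamples N = `n_boot` synthetic time series: at every timepoint one
#' replicate measurement is drawn uniformly at random (independently per
#' timepoint by default; `paired = TRUE` draws one replicate index shared
#' across all timepoints), the model is refitted, and the 2.5/97.5
#' percentiles of the refitted parameters give the 95% interval.
#' Deterministic given `seed`. Refits start from the point estimate, which
#' the bootstrap perturbs only slightly.
#'
#' @param data Data frame: `t_minutes`, `replicate`, `charge_pct`.
#' @param fit The point-estimate [fit_decay()] (computed if missing).
#' @param n_boot Bootstrap replicates (default 1000).
#' @param seed Integer seed.
#' @param paired Share the replicate draw across timepoints.
#' @param conf Confidence level (default 0.95).
#' @return Data frame: `parameter`, `estimate`, `ci_lower`, `ci_upper`.
#' @export
bootstrap_decay <- function(data, fit = NULL, n_boot = 1000L, seed = 1L,
                            paired = FALSE, conf = 0.95) {
  stopifnot(all(c("t_minutes", "replicate", "charge_pct") %in% names(data)))
  if (is.null(fit)) fit <- fit_decay(data)
  tps <- sort(unique(data$t_minutes))
  by_tp <- lapply(tps, function(tp)
    data$charge_pct[data$t_minutes == tp])
  n_rep <- lengths(by_tp)
  b <- decay_bounds()
  p0 <- c(fit$N0, fit$t_half, fit$N_inf)
  draws <- withr::with_seed(as.integer(seed), {
    vapply(seq_len(n_boot), function(i) {
      idx <- if (paired) rep(sample.int(min(n_rep), 1L), length(tps))
        else vapply(n_rep, sample.int, integer(1), size = 1L)
      y <- mapply(function(v, j) v[[j]], by_tp, idx)
      o <- optim(p0, decay_sse, t = tps, y = y, method = "L-BFGS-B",
                 lower = b$lower, upper = b$upper,
                 control = list(factr = 1e2))
      o$par
    }, numeric(3))
  })
  alpha <- (1 - conf) / 2
  est <- c(N0 = fit$N0, t_half = fit$t_half, N_inf = fit$N_inf)
  data.frame(parameter = names(est), estimate = unname(est),
             ci_lower = apply(draws, 1L, quantile, alpha),
             ci_upper = apply(draws, 1L, quantile, 1 - alpha),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Fit decay per group from a long table
#'
#' @param data Data frame: `group_id`, `t_minutes`, `replicate`,
#'   `charge_pct`.
#' @param n_boot,seed Bootstrap settings ([bootstrap_decay()]); `n_boot =
#'   0` skips the bootstrap.
#' @return Data frame: one row per group with point estimates, SSE and CI
#'   bounds per parameter.
#' @export
fit_decay_table <- function(data, n_boot = 1000L, seed = 1L) {
  out <- lapply(sort(unique(data$group_id)), function(g) {
    sub <- data[data$group_id == g, , drop = FALSE]
    fit <- fit_decay(sub, group_id = g)
    row <- data.frame(group_id = g, N0 = fit$N0, t_half = fit$t_half,
                      N_inf = fit$N_inf, sse = fit$sse,
                      identifiable = fit$identifiable,
                      stringsAsFactors = FALSE)
    if (n_boot > 0L) {
      ci <- bootstrap_decay(sub, fit, n_boot = n_boot, seed = seed)
      row$N0_lo <- ci$ci_lower[1L]; row$N0_hi <- ci$ci_upper[1L]
      row$t_half_lo <- ci$ci_lower[2L]; row$t_half_hi <- ci$ci_upper[2L]
      row$N_inf_lo <- ci$ci_lower[3L]; row$N_inf_hi <- ci$ci_upper[3L]
    }
    row
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
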