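#' Enzyme velocity under a kinetic model
#'
#' Michaelis-Menten: v = Vmax S / (Km + S).  Substrate inhibition:
#' v = Vmax S / (Km + S (1 + S / Ki)); the curve rises to a maximum at
#' S = sqrt(Km Ki) and declines beyond it.
#'
#' @param model `"michaelis_menten"` or `"substrate_inhibition"`
#' @param S substrate concentration(s), >= 0
#' @param params list with positive `Vmax`, `Km`, and `Ki` for substrate
#'   inhibition
#' @return velocities, same length as `S`
#' @export
velocity <- function(model = c("michaelis_menten", "substrate_inhibition"),
                     S, params) {
  model <- match.arg(model)
  if (any(S < 0)) stop("substrate concentrations must be >= 0", call. = FALSE)
  if (is.null(params$Vmax) || params$Vmax <= 0 ||
      is.null(params$Km) || params$Km <= 0)
    stop("Vmax and Km must be positive", call. = FALSE)
  if (model == "michaelis_menten")
    return(params$Vmax * S / (params$Km + S))
  if (is.null(params$Ki) || params$Ki <= 0)
    stop("substrate inhibition needs positive Ki", call. = FALSE)
  params$Vmax * S / (params$Km + S * (1 + S / params$Ki))
}

#' Convert raw fluorescence to concentration via a standard curve
#'
#' Ordinary-least-squares line signal = intercept + slope * concentration
#' through the standard points, inverted at the observed signals.
#'
#' @param rfu observed fluorescence values
#' @param standards data.frame with columns `conc` and `signal`
#'   (>= 2 points with distinct concentrations)
#' @return concentrations, with `slope` and `intercept` attributes
#' @export
rfu_to_concentration <- function(rfu, standards) {
  stopifnot(all(c("conc", "signal") %in% names(standards)))
  x <- standards$conc; y <- standards$signal
  if (length(x) < 2L || var(x) == 0)
    stop("standards are degenerate (need >= 2 distinct concentrations)",
         call. = FALSE)
  slope <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  intercept <- mean(y) - slope * mean(x)
  structure((rfu - intercept) / slope, slope = slope, intercept = intercept)
}

#' Global nonlinear fit of dose-response datasets
#'
#' Joint unweighted least squares over one or more datasets with a
#' per-dataset Vmax and Km handled by `km_mode`: `"shared"` estimates a
#' single Km across datasets (the stabilising assumption used when
#' comparing Vmax between enzyme variants), `"fixed"` holds Km at
#' `km_value`, `"free"` estimates Km per dataset.  For the substrate
#' inhibition model Ki is shared across datasets (per-dataset under
#' `"free"`), or held at `ki_value` when given.  Parameters are optimised
#' on the log scale (positivity); asymptotic 95% confidence intervals come
#' from the residual Jacobian at the optimum,
#' cov = s^2 (J' J)^-1 with s^2 = RSS / (N - p).
#'
#' @param datasets a data.frame with columns `condition`, `S`, `v`
#'   (replicate rows allowed), or a list of per-condition data.frames
#' @param model `"michaelis_menten"` or `"substrate_inhibition"`
#' @param km_mode `"shared"`, `"fixed"` or `"free"`
#' @param km_value Km value for `km_mode = "fixed"`
#' @param ki_value optional fixed Ki (substrate inhibition)
#' @return an object of class `kinetic_fit`: `fits` (data.frame with
#'   per-condition Vmax, se and 95% CI), `Km`, `Ki`, `rss`, `df`,
#'   `model`, `km_mode`, `converged`
#' @export
global_fit <- function(datasets,
                       model = c("michaelis_menten", "substrate_inhibition"),
                       km_mode = c("shared", "fixed", "free"),
                       km_value = NULL, ki_value = NULL) {
  model <- match.arg(model)
  km_mode <- match.arg(km_mode)
  si <- model == "substrate_inhibition"
  if (km_mode == "fixed" && (is.null(km_value) || km_value <= 0))
    stop("km_mode = 'fixed' needs a positive km_value", call. = FALSE)

  if (is.data.frame(datasets)) {
    if (!"condition" %in% names(datasets)) datasets$condition <- "cond1"
    datasets <- split(datasets, datasets$condition)
  }
  nd <- length(datasets)
  if (!nd) stop("no datasets", call. = FALSE)
  conds <- vapply(seq_len(nd), function(i) {
    d <- datasets[[i]]
    as.character(d$condition[1L] %||% names(datasets)[i] %||% paste0("cond", i))
  }, "")
  for (d in datasets)
    if (length(unique(d$S)) < 3L)
      stop("each dataset needs >= 3 distinct concentrations", call. = FALSE)

  Sx <- lapply(datasets, function(d) d$S)
  vx <- lapply(datasets, function(d) d$v)
  N <- sum(lengths(vx))

  # parameter layout on log scale: Vmax_1..nd, then Km term(s), then Ki term(s)
  n_km <- switch(km_mode, shared = 1L, fixed = 0L, free = nd)
  n_ki <- if (!si || !is.null(ki_value)) 0L else if (km_mode == "free") nd else 1L
  p <- nd + n_km + n_ki
  if (N <= p) stop("fewer residual degrees of freedom than parameters",
                   call. = FALSE)

  unpack <- function(th) {
    e <- exp(th)
    vmax <- e[seq_len(nd)]
    km <- switch(km_mode,
                 fixed = rep(km_value, nd),
                 shared = rep(e[nd + 1L], nd),
                 free = e[nd + seq_len(nd)])
    ki <- if (!si) rep(NA_real_, nd)
          else if (!is.null(ki_value)) rep(ki_value, nd)
          else if (km_mode == "free") e[nd + n_km + seq_len(nd)]
          else rep(e[nd + n_km + 1L], nd)
    list(vmax = vmax, km = km, ki = ki)
  }
  residuals_at <- function(th) {
    pr <- unpack(th)
    unlist(lapply(seq_len(nd), function(i) {
      par <- list(Vmax = pr$vmax[i], Km = pr$km[i], Ki = pr$ki[i])
      vx[[i]] - velocity(model, Sx[[i]], par)
    }))
  }
  rss_at <- function(th) sum(residuals_at(th)^2)

  # standard starts: Vmax0 = max v, Km0 = S at half max, Ki0 = max S
  th0 <- log(vapply(seq_len(nd), function(i) max(max(vx[[i]]), 1e-8), 0))
  km0 <- vapply(seq_len(nd), function(i) {
    half <- max(vx[[i]]) / 2
    s <- Sx[[i]][Sx[[i]] > 0]
    v <- vx[[i]][Sx[[i]] > 0]
    if (!length(s)) return(1)
    max(s[which.min(abs(v - half))], 1e-8)
  }, 0)
  if (km_mode == "shared") th0 <- c(th0, log(mean(km0)))
  if (km_mode == "free") th0 <- c(th0, log(km0))
  if (n_ki > 0) th0 <- c(th0, rep(log(max(unlist(Sx))), n_ki))

  if (p > 1L)  # Nelder-Mead to get near the basin, then a BFGS polish
    fit <- optim(th0, rss_at, method = "Nelder-Mead",
                 control = list(maxit = 5000, reltol = 1e-12))
  else fit <- list(par = th0)
  fit <- optim(fit$par, rss_at, method = "BFGS",
               control = list(maxit = 1000, reltol = 1e-14))
  if (!is.finite(fit$value))
    stop("global fit failed to converge (non-finite RSS); check data scale",
         call. = FALSE)

  # asymptotic covariance from the numeric Jacobian in raw-parameter space
  th <- fit$par
  raw <- exp(th)
  J <- matrix(0, nrow = N, ncol = p)
  r0 <- residuals_at(th)
  for (k in seq_len(p)) {
    h <- max(1e-6 * abs(raw[k]), 1e-10)
    thk <- th; thk[k] <- log(raw[k] + h)
    J[, k] <- -(residuals_at(thk) - r0) / h   # d(model)/d(raw param)
  }
  dof <- N - p
  s2 <- fit$value / dof
  cov <- tryCatch(s2 * solve(crossprod(J)), error = function(e) {
    matrix(NA_real_, p, p)
  })
  se <- sqrt(pmax(diag(cov), 0))
  tq <- qt(0.975, dof)

  pr <- unpack(th)
  fits <- data.frame(condition = conds, Vmax = pr$vmax,
                     se = se[seq_len(nd)],
                     ci_lo = pr$vmax - tq * se[seq_len(nd)],
                     ci_hi = pr$vmax + tq * se[seq_len(nd)])
  km_out <- if (km_mode == "free") pr$km else pr$km[1L]
  ki_out <- if (!si) NULL else if (km_mode == "free") pr$ki else pr$ki[1L]
  structure(list(model = model, km_mode = km_mode, fits = fits,
                 Km = km_out, Ki = ki_out, rss = fit$value, df = dof,
                 n_obs = N, converged = fit$convergence == 0,
                 cov = cov),
            class = "kinetic_fit")
}

#' @export
print.kinetic_fit <- function(x, ...) {
  cat(sprintf("<kinetic_fit> %s, Km %s = %s%s, RSS = %.4g (df %d)\n",
              x$model, x$km_mode,
              paste(formatC(x$Km, format = "g"), collapse = ","),
              if (!is.null(x$Ki))
                paste0(", Ki = ", paste(formatC(x$Ki, format = "g"),
                                        collapse = ",")) else "",
              x$rss, x$df))
  print(x$fits, row.names = FALSE)
  invisible(x)
}

#' Extra-sum-of-squares model comparison
#'
#' F-test of substrate inhibition (full) against Michaelis-Menten
#' (reduced, Ki -> Inf) on the same datasets; the operational reading of
#' choosing the model "by best fit" at alpha = 0.05.
#'
#' @inheritParams global_fit
#' @param alpha significance level
#' @return list: `model` (the selected tag), `F`, `p_value`, and both fits
#' @export
select_model <- function(datasets, km_mode = "shared", km_value = NULL,
                         alpha = 0.05) {
  mm <- global_fit(datasets, "michaelis_menten", km_mode, km_value)
  si <- global_fit(datasets, "substrate_inhibition", km_mode, km_value)
  df1 <- mm$df - si$df
  Fst <- ((mm$rss - si$rss) / df1) / (si$rss / si$df)
  pv <- stats::pf(Fst, df1, si$df, lower.tail = FALSE)
  list(model = if (is.finite(pv) && pv < alpha) "substrate_inhibition"
               else "michaelis_menten",
       F = Fst, p_value = pv, fit_mm = mm, fit_si = si)
}

#' Percent change of Vmax relative to a reference
#'
#' 100 (reference - variant) / reference: positive = reduction.
#'
#' @param vmax_variant,vmax_reference Vmax estimates; reference must be > 0
#' @return percent change
#' @export
percent_change <- function(vmax_variant, vmax_reference) {
  100 * (vmax_reference - vmax_variant) / vmax_reference
}
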