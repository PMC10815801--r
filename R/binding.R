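#' Saturation-binding model parameters
#'
#' Parameters of the one-site total-binding model
#' `response = Bmax * X / (X + Kd) + NS * X + Background`, where `X` is the
#' aptamer concentration in nM, `Bmax` the maximal specific binding
#' (response units, e.g. MFI), `Kd` the dissociation constant (nM), `NS` a
#' nonspecific linear slope (response units per nM) and `Background` the
#' signal floor.
#'
#' @param Bmax maximal specific binding, `>= 0`.
#' @param Kd dissociation constant in nM, `> 0`.
#' @param NS nonspecific slope, `>= 0`.
#' @param Background signal floor, `>= 0`.
#' @return A named numeric vector of class `binding_params`.
#' @export
binding_params <- function(Bmax, Kd, NS = 0, Background = 0) {
  p <- c(Bmax = as.numeric(Bmax), Kd = as.numeric(Kd),
         NS = as.numeric(NS), Background = as.numeric(Background))
  if (any(!is.finite(p))) stop("binding parameters must be finite")
  if (p["Bmax"] < 0) stop("Bmax must be >= 0")
  if (p["Kd"] <= 0) stop("Kd must be > 0")
  if (p["NS"] < 0) stop("NS must be >= 0")
  if (p["Background"] < 0) stop("Background must be >= 0")
  structure(p, class = "binding_params")
}

#' Evaluate the saturation-binding model
#'
#' @param X aptamer concentration(s) in nM, `>= 0`; vectorized.
#' @param params a [binding_params] object (or named vector with elements
#'   Bmax, Kd, NS, Background).
#' @return Predicted response, same length as `X`. Monotone nondecreasing in
#'   `X` for valid parameters.
#' @examples
#' model_response(100, binding_params(Bmax = 100, Kd = 100))  # 50
#' @export
model_response <- function(X, params) {
  p <- unclass(params)
  if (is.null(names(p)) || !all(c("Bmax", "Kd", "NS", "Background") %in%
                                names(p)))
    stop("params must carry Bmax, Kd, NS, Background")
  if (p[["Kd"]] <= 0) stop("Kd must be > 0")
  if (any(X < 0)) stop("X must be >= 0")
  p[["Bmax"]] * X / (X + p[["Kd"]]) + p[["NS"]] * X + p[["Background"]]
}

#' Background and nonspecific-slope priors from control samples
#'
#' `Background` is estimated as the mean response of zero-aptamer controls;
#' a nonspecific-slope prior is derived from an initial-library control at a
#' known dose as `(library response - Background) / dose`, and is 0 when no
#' library control exists.
#'
#' @param controls data frame with columns `response`, `control_type`
#'   (one of `"no_aptamer"`, `"library"`) and `dose_nM` (used for library
#'   controls).
#' @return A list with `Background` and `NS` priors. With no control rows a
#'   warning is raised and both priors are 0.
#' @export
estimate_background <- function(controls) {
  if (is.null(controls) || !NROW(controls)) {
    warning("no control records; using Background = 0, NS = 0 priors")
    return(list(Background = 0, NS = 0))
  }
  stopifnot(all(c("response", "control_type") %in% names(controls)))
  bg_rows <- controls$control_type == "no_aptamer"
  bg <- if (any(bg_rows)) mean(controls$response[bg_rows]) else 0
  lib_rows <- which(controls$control_type == "library")
  ns <- 0
  if (length(lib_rows)) {
    dose <- controls$dose_nM[lib_rows]
    ok <- is.finite(dose) & dose > 0
    if (any(ok))
      ns <- max(0, mean((controls$response[lib_rows][ok] - bg) /
                          dose[ok]))
  }
  list(Background = max(0, bg), NS = ns)
}

#' Fit the saturation-binding model to dose-response data
#'
#' Nonlinear least squares (bounded Levenberg-Marquardt via
#' \pkg{minpack.lm}) of `Bmax * X/(X + Kd) + NS * X + Background` with all
#' four parameters free on `[0, Inf)` (`Kd` on `(0, Inf)`). Initialization:
#' `Bmax0 = max(response) - min(response)`, `Kd0 =` median positive dose,
#' `NS0`/`Background0` from [estimate_background()] on any control rows.
#' Standard errors come from the Jacobian at the optimum. Fitting is
#' unweighted by default; supply per-observation `weights` to downweight
#' noisy replicates.
#'
#' @param data data frame with columns `dose_nM`, `response`, and optionally
#'   `replicate` and `control_type` (`NA`/`""` for ordinary records;
#'   `"no_aptamer"`/`"library"` rows are used for initialization and, when
#'   their dose is recorded, enter the fit like any other observation).
#' @param weights optional nonnegative per-row weights.
#' @param start optional named list/vector overriding initial values.
#' @return An object of class `kd_fit` with elements `params`
#'   ([binding_params]), `se`, `rss`, `sigma`, `converged`, `niter`,
#'   `kd_identifiable`, `data`, `fitted` and `call`. Methods: `print`,
#'   `summary`, `coef`, `predict`, `fitted`, `residuals`, `plot`,
#'   `simulate`.
#' @export
fit_kd <- function(data, weights = NULL, start = NULL) {
  stopifnot(is.data.frame(data), all(c("dose_nM", "response") %in%
                                       names(data)))
  d <- data
  d$dose_nM <- as.numeric(d$dose_nM)
  d$response <- as.numeric(d$response)
  if (any(!is.finite(d$dose_nM)) || any(!is.finite(d$response)))
    stop("doses and responses must be finite")
  if (any(d$dose_nM < 0)) stop("doses must be >= 0")
  # control rows (zero-aptamer, initial-library) inform initialization but
  # are excluded from the saturation-model least squares: the library
  # control follows the nonspecific line, not the binding model
  is_ctl <- if ("control_type" %in% names(d)) {
    !is.na(d$control_type) & nzchar(as.character(d$control_type))
  } else d$dose_nM == 0
  ctl <- d[is_ctl, , drop = FALSE]
  if (NROW(ctl) && !"control_type" %in% names(ctl))
    ctl$control_type <- "no_aptamer"
  d <- d[!is_ctl, , drop = FALSE]
  if (!NROW(d)) stop("no non-control dose-response records")
  pos <- unique(d$dose_nM[d$dose_nM > 0])
  if (length(pos) < 3L)
    stop("need at least 3 distinct positive doses to fit")
  priors <- if (NROW(ctl)) estimate_background(ctl) else
    list(Background = min(d$response), NS = 0)
  s <- list(Bmax = max(d$response) - min(d$response),
            Kd = stats::median(pos),
            NS = priors$NS,
            Background = max(0, priors$Background))
  if (!is.null(start)) s[names(start)] <- as.list(unlist(start))
  s$Bmax <- max(s$Bmax, 1e-8)

  # degenerate: flat responses
  if (stats::sd(d$response) < .Machine$double.eps^0.5 * max(1, abs(mean(d$response)))) {
    p <- binding_params(Bmax = 0, Kd = stats::median(pos),
                        NS = 0, Background = max(0, mean(d$response)))
    out <- structure(list(params = p,
                          se = c(Bmax = NA, Kd = NA, NS = NA,
                                 Background = 0),
                          rss = 0, sigma = 0, converged = TRUE, niter = 0L,
                          kd_identifiable = FALSE, data = d,
                          fitted = rep(mean(d$response), nrow(d)),
                          call = match.call()),
                     class = "kd_fit")
    return(out)
  }

  w <- if (is.null(weights)) rep(1, nrow(d)) else as.numeric(weights)
  if (length(w) != nrow(d) || any(w < 0))
    stop("weights must be nonnegative, one per row")
  X <- d$dose_nM
  y <- d$response
  one_fit <- function(st) tryCatch(
    minpack.lm::nlsLM(
      y ~ Bmax * X / (X + Kd) + NS * X + Background,
      start = st, weights = w,
      lower = c(Bmax = 0, Kd = 1e-9, NS = 0, Background = 0),
      control = minpack.lm::nls.lm.control(maxiter = 1000,
                                           ftol = 1e-12, ptol = 1e-12)),
    error = function(e) NULL)
  # the 4-parameter objective is non-convex (Bmax/Kd/NS trade-off), so
  # restart from a small set of principled starts and keep the lowest RSS;
  # one start comes from a variable-projection scan: for fixed (Kd, NS) the
  # model is linear in (Bmax, Background), so a coarse Kd x NS grid with
  # closed-form linear least squares locates the global basin
  vp_best <- NULL; vp_rss <- Inf
  kd_grid <- exp(seq(log(min(pos) / 10), log(max(pos) * 10),
                     length.out = 40))
  ns_max <- (max(y) - min(y)) / max(X)
  ns_grid <- c(0, ns_max * c(0.05, 0.1, 0.2, 0.4, 0.7, 1))
  for (kd0 in kd_grid) for (ns0 in ns_grid) {
    sat <- X / (X + kd0)
    z <- y - ns0 * X
    A <- cbind(sat, 1)
    cf2 <- tryCatch(stats::lm.wfit(A, z, w)$coefficients,
                    error = function(e) c(NA, NA))
    if (any(!is.finite(cf2))) next
    cf2 <- pmax(cf2, 0)                       # respect the [0, Inf) bounds
    rss0 <- sum(w * (z - A %*% cf2)^2)
    if (rss0 < vp_rss) {
      vp_rss <- rss0
      vp_best <- list(Bmax = max(cf2[1], 1e-8), Kd = kd0, NS = ns0,
                      Background = cf2[2])
    }
  }
  kd_starts <- unique(c(s$Kd, unname(stats::quantile(pos, c(.25, .75))),
                        max(pos), max(pos) / 10))
  ns_starts <- unique(c(s$NS, 0, (max(y) - min(y)) / max(X) / 4))
  starts <- list()
  for (kd0 in kd_starts) for (ns0 in ns_starts) {
    st <- s; st$Kd <- max(kd0, 1e-9); st$NS <- ns0
    starts[[length(starts) + 1L]] <- st
  }
  if (!is.null(vp_best)) starts[[length(starts) + 1L]] <- vp_best
  fit <- NULL; best_rss <- Inf
  for (st in starts) {
    f0 <- one_fit(st)
    if (!is.null(f0)) {
      rss0 <- sum(w * stats::residuals(f0)^2)
      if (rss0 < best_rss - 1e-12) { best_rss <- rss0; fit <- f0 }
    }
  }
  if (is.null(fit)) stop("nonlinear least squares failed from all starts")
  cf <- stats::coef(fit)
  # LM can stall when parameters sit on the [0, Inf) bounds; a bounded
  # quasi-Newton polish from the LM optimum finishes the job
  obj <- function(th) sum(w * (y - (th[1] * X / (X + th[2]) + th[3] * X +
                                      th[4]))^2)
  pol <- tryCatch(stats::optim(pmax(unname(cf[c("Bmax", "Kd", "NS",
                                                "Background")]),
                                    c(0, 1e-9, 0, 0)),
                               obj, method = "L-BFGS-B",
                               lower = c(0, 1e-9, 0, 0),
                               control = list(factr = 10, maxit = 500)),
                  error = function(e) NULL)
  if (!is.null(pol) && pol$value < best_rss - 1e-12) {
    best_rss <- pol$value
    cf <- stats::setNames(pol$par, c("Bmax", "Kd", "NS", "Background"))
  }
  conv <- fit$convInfo$isConv %||% TRUE
  niter <- fit$convInfo$finIter %||% NA_integer_
  kd_ok <- is.finite(cf[["Bmax"]]) && cf[["Bmax"]] > 1e-6 * max(abs(y), 1)
  p <- binding_params(Bmax = max(cf[["Bmax"]], 0),
                      Kd = max(cf[["Kd"]], 1e-9),
                      NS = max(cf[["NS"]], 0),
                      Background = max(cf[["Background"]], 0))
  res <- y - model_response(X, p)
  # SEs from the analytic Jacobian at the final parameters
  J <- cbind(Bmax = X / (X + p[["Kd"]]),
             Kd = -p[["Bmax"]] * X / (X + p[["Kd"]])^2,
             NS = X, Background = rep(1, length(X)))
  se <- tryCatch({
    sigma2 <- sum(w * res^2) / max(1, length(y) - 4L)
    sqrt(pmax(diag(solve(crossprod(J * sqrt(w)))) * sigma2, 0))
  }, error = function(e) stats::setNames(rep(NA_real_, 4), colnames(J)))
  structure(list(params = p, se = se[names(cf)],
                 rss = sum(w * res^2),
                 sigma = sqrt(sum(w * res^2) / max(1, nrow(d) - 4)),
                 converged = isTRUE(conv), niter = niter,
                 kd_identifiable = kd_ok, data = d, fitted = y - res,
                 call = match.call()),
            class = "kd_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
coef.kd_fit <- function(object, ...) unclass(object$params)

#' @export
print.kd_fit <- function(x, digits = 4, ...) {
  cat("Saturation-binding fit: Bmax*X/(X+Kd) + NS*X + Background\n")
  cat(sprintf("  Kd = %s nM%s\n", signif(x$params[["Kd"]], digits),
              if (is.finite(x$se[["Kd"]]))
                sprintf(" (SE %s)", signif(x$se[["Kd"]], 3)) else ""))
  cat("  Bmax =", signif(x$params[["Bmax"]], digits),
      " NS =", signif(x$params[["NS"]], digits),
      " Background =", signif(x$params[["Background"]], digits), "\n")
  cat("  RSS =", signif(x$rss, digits),
      " converged:", x$converged, "\n")
  if (!x$kd_identifiable)
    cat("  warning: Kd not identifiable (flat or near-zero specific binding)\n")
  invisible(x)
}

#' @export
summary.kd_fit <- function(object, ...) {
  tab <- cbind(estimate = unclass(object$params),
               std_error = object$se[names(object$params)])
  structure(list(coefficients = tab, rss = object$rss,
                 sigma = object$sigma, converged = object$converged,
                 kd_identifiable = object$kd_identifiable,
                 n = nrow(object$data)),
            class = "summary.kd_fit")
}

#' @export
print.summary.kd_fit <- function(x, ...) {
  cat("Saturation-binding fit (", x$n, " observations)\n", sep = "")
  print(signif(x$coefficients, 5))
  cat("RSS:", signif(x$rss, 5), "  residual sigma:", signif(x$sigma, 5),
      "  converged:", x$converged, "\n")
  if (!x$kd_identifiable) cat("Kd flagged not identifiable\n")
  invisible(x)
}

#' @export
predict.kd_fit <- function(object, newdata = NULL, ...) {
  X <- if (is.null(newdata)) object$data$dose_nM else {
    if (is.data.frame(newdata)) newdata$dose_nM else as.numeric(newdata)
  }
  model_response(X, object$params)
}

#' @export
fitted.kd_fit <- function(object, ...) object$fitted

#' @export
residuals.kd_fit <- function(object, ...)
  object$data$response - object$fitted

#' @export
simulate.kd_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  X <- object$data$dose_nM
  mu <- model_response(X, object$params)
  out <- as.data.frame(replicate(nsim, mu + stats::rnorm(length(mu),
                                                         0, object$sigma)))
  names(out) <- paste0("sim_", seq_len(nsim))
  cbind(object$data["dose_nM"], out)
}

#' @export
plot.kd_fit <- function(x, ...) {
  d <- x$data
  xs <- seq(0, max(d$dose_nM) * 1.05, length.out = 200)
  graphics::plot(d$dose_nM, d$response, xlab = "aptamer concentration (nM)",
                 ylab = "response", pch = 19,
                 main = sprintf("Kd = %.3g nM", x$params[["Kd"]]), ...)
  graphics::lines(xs, model_response(xs, x$params), col = "firebrick",
                  lwd = 2)
  invisible(x)
}

#' Per-replicate Kd fits with a pooled summary
#'
#' Fits the saturation model independently within each replicate and reports
#' the mean and SD of the per-replicate Kd estimates (the usual
#' "Kd = mean +/- SD over independent replicates" presentation), alongside a
#' pooled all-data fit whose SE is the fit standard error. Both spreads are
#' labeled so they are never conflated.
#'
#' @param data as for [fit_kd()], requiring a `replicate` column.
#' @return An object of class `kd_replicate_summary`: list with `fits`
#'   (per-replicate `kd_fit`s), `pooled` (all-data `kd_fit`), `kd_mean`,
#'   `kd_sd` (across replicates) and `kd_se_pooled` (fit SE).
#' @export
kd_replicate_fits <- function(data) {
  stopifnot("replicate" %in% names(data))
  reps <- split(data, data$replicate)
  fits <- lapply(reps, fit_kd)
  kds <- vapply(fits, function(f) f$params[["Kd"]], 0)
  pooled <- fit_kd(data)
  structure(list(fits = fits, pooled = pooled,
                 kd_mean = mean(kds), kd_sd = stats::sd(kds),
                 kd_se_pooled = pooled$se[["Kd"]]),
            class = "kd_replicate_summary")
}

#' @export
print.kd_replicate_summary <- function(x, ...) {
  cat(sprintf("Kd = %.4g +/- %.2g nM (mean +/- SD over %d replicate fits)\n",
              x$kd_mean, x$kd_sd, length(x$fits)))
  cat(sprintf("pooled fit: Kd = %.4g nM (fit SE %.2g)\n",
              x$pooled$params[["Kd"]], x$kd_se_pooled))
  invisible(x)
}
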