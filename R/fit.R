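#' Fit two-state transcription kinetics to one gene
#'
#' Alternating least-squares ("simplified EM") fit of the ON-then-OFF
#' kinetic curve ([fit_curve()]) to a gene's smoothed unspliced/spliced
#' profile across cells. The splicing rate is fixed to `beta = 1` as the
#' time-scale gauge, so the fitted `gamma` estimates the
#' degradation-to-splicing ratio gamma/beta. Each iteration (i) assigns
#' every cell the latent time minimizing the variance-scaled squared
#' distance of `(Mu, Ms)` to the curve, over a `grid_n`-point grid refined
#' by local quadratic interpolation, and (ii) updates
#' `(alpha, gamma, t_switch)` by derivative-free least squares with the
#' assignments fixed. Both steps can only lower the objective, so it is
#' non-increasing across iterations.
#'
#' The fit likelihood rescales the mean Gaussian log-density of the
#' residuals (under the data's own spread as the unit) to `[0, 1]`:
#' `exp(-mean(ru^2)/(2*sd(Mu)^2) - mean(rs^2)/(2*sd(Ms)^2))`. A perfect
#' fit scores 1; a fit no better than a constant scores about `exp(-1)`;
#' any valid fit scores strictly above 0. Degenerate genes (all-zero, or
#' fewer than 20 cells with signal) are marked invalid with likelihood 0.
#'
#' @param mu,ms numeric vectors: smoothed unspliced and spliced values of
#'   one gene across cells.
#' @param gene_id optional identifier carried into the result.
#' @param max_iter maximum number of alternating iterations.
#' @param tol relative objective decrease declaring convergence.
#' @param grid_n latent-time grid resolution.
#' @param min_signal_cells minimum number of cells with nonzero signal.
#' @return object of class `gene_fit`: list with fitted `alpha`, `beta`
#'   (fixed 1), `gamma`, `t_switch`, `t_total`, per-cell `latent_time`,
#'   `residual_scale`, `fit_likelihood`, `direction` (sign of the fitted
#'   unspliced trend), `objective` trace, `iterations`, `converged`,
#'   `valid`.
#' @export
fit_gene_kinetics <- function(mu, ms, gene_id = NA_character_,
                              max_iter = 12L, tol = 1e-5, grid_n = 200L,
                              min_signal_cells = 20L) {
  n <- length(mu)
  stopifnot(length(ms) == n)
  invalid <- function() {
    structure(list(gene_id = gene_id, alpha = NA_real_, beta = 1,
                   gamma = NA_real_, t_switch = NA_real_,
                   t_total = NA_real_, latent_time = rep(NA_real_, n),
                   residual_scale = NA_real_, fit_likelihood = 0,
                   direction = NA_character_, objective = numeric(),
                   iterations = 0L, converged = FALSE, valid = FALSE),
              class = "gene_fit")
  }
  if (sum(mu > 0 | ms > 0) < min_signal_cells) return(invalid())
  su <- max(stats::sd(mu), 1e-8)
  ss <- max(stats::sd(ms), 1e-8)
  if (stats::sd(mu) < 1e-12 && stats::sd(ms) < 1e-12) return(invalid())

  safe_gamma <- function(g) if (abs(g - 1) < 1e-6) 1 + 1e-6 else g

  unit_curve <- function(par, times) {
    fit_curve(1, safe_gamma(exp(par[1])), exp(par[2]), t_total = Inf,
              times = times)
  }
  # the curve is linear in alpha (zero initial condition), so given
  # (gamma, t_switch) and the per-cell times alpha has a closed-form
  # least-squares solution
  profile_alpha <- function(par, times) {
    unit <- unit_curve(par, times)
    num <- sum(mu * unit$u) / su^2 + sum(ms * unit$s) / ss^2
    den <- sum(unit$u^2) / su^2 + sum(unit$s^2) / ss^2
    max(num / max(den, 1e-300), 1e-8)
  }
  curve_at <- function(par, alpha, times) {
    unit <- unit_curve(par, times)
    list(u = alpha * unit$u, s = alpha * unit$s)
  }
  obj_at <- function(par, times) {
    unit <- unit_curve(par, times)
    num <- sum(mu * unit$u) / su^2 + sum(ms * unit$s) / ss^2
    den <- sum(unit$u^2) / su^2 + sum(unit$s^2) / ss^2
    alpha <- max(num / max(den, 1e-300), 1e-8)
    mean(((mu - alpha * unit$u) / su)^2 + ((ms - alpha * unit$s) / ss)^2)
  }

  # initialization from the phase-portrait extremes (u_max ~ alpha,
  # s_max ~ alpha/gamma in beta = 1 units); t_switch is started both
  # small (switch-off visible in the data) and large (purely rising
  # gene), and the better end point wins
  a0 <- max(stats::quantile(mu, 0.98), 1e-6)
  g0 <- safe_gamma(a0 / max(stats::quantile(ms, 0.98), 1e-6))
  tsw_inits <- c(3, 4 + 4 / min(1, g0))
  alpha_cur <- a0

  # grid span: for a purely rising gene t_switch is unidentified above
  # the data's range and can inflate freely; the assignment grid caps
  # the ON segment at 12 splicing timescales (saturation is complete by
  # ~5) so resolution over the data never degrades
  t_total_of <- function(par)
    min(exp(par[2]), 12) + 4 / min(1, exp(par[1]))

  assign_times <- function(par, alpha, prev = NULL) {
    tt <- t_total_of(par)
    grid <- seq(0, tt, length.out = grid_n)
    cv <- curve_at(par, alpha, grid)
    D <- outer(mu / su, cv$u / su, "-")^2 + outer(ms / ss, cv$s / ss, "-")^2
    j <- max.col(-D, ties.method = "first")
    t_hat <- grid[j]
    d_hat <- D[cbind(seq_len(n), j)]
    # quadratic refinement on interior grid points
    interior <- j > 1L & j < grid_n
    if (any(interior)) {
      ji <- j[interior]
      dm <- D[cbind(which(interior), ji - 1L)]
      d0 <- D[cbind(which(interior), ji)]
      dp <- D[cbind(which(interior), ji + 1L)]
      denom <- dm - 2 * d0 + dp
      step <- ifelse(denom > 1e-300, 0.5 * (dm - dp) / denom, 0)
      step <- pmax(pmin(step, 1), -1)
      dt <- grid[2] - grid[1]
      t_ref <- grid[ji] + step * dt
      cvr <- curve_at(par, alpha, t_ref)
      idx <- which(interior)
      d_ref <- ((mu[idx] - cvr$u) / su)^2 + ((ms[idx] - cvr$s) / ss)^2
      better <- d_ref < d_hat[idx]
      t_hat[idx[better]] <- t_ref[better]
      d_hat[idx[better]] <- d_ref[better]
    }
    if (!is.null(prev)) {
      # keep an earlier continuous assignment wherever the grid is worse,
      # so the objective is non-increasing across iterations
      cvp <- curve_at(par, alpha, prev)
      d_prev <- ((mu - cvp$u) / su)^2 + ((ms - cvp$s) / ss)^2
      keep_prev <- d_prev < d_hat
      t_hat[keep_prev] <- prev[keep_prev]
      d_hat[keep_prev] <- d_prev[keep_prev]
    }
    list(times = t_hat, obj = mean(d_hat))
  }

  run_em <- function(state, iters) {
    par <- state$par; alpha_cur <- state$alpha
    times <- state$times
    if (is.null(times)) times <- assign_times(par, alpha_cur)
    trace <- c(state$trace, if (is.null(state$trace)) times$obj)
    converged <- FALSE
    done <- state$iter %||% 0L
    for (i in seq_len(iters)) {
      opt <- stats::optim(par, obj_at, times = times$times,
                          method = "Nelder-Mead",
                          control = list(maxit = 60))
      par <- opt$par
      alpha_cur <- profile_alpha(par, times$times)
      times <- assign_times(par, alpha_cur, prev = times$times)
      trace <- c(trace, times$obj)
      prev <- trace[length(trace) - 1L]
      done <- done + 1L
      if (prev - times$obj <= tol * max(prev, 1e-12)) {
        converged <- TRUE
        break
      }
    }
    list(par = par, alpha = alpha_cur, times = times, trace = trace,
         iter = done, converged = converged)
  }
  # probe each t_switch start briefly, then run the better one out
  probe <- min(2L, max_iter)
  starts <- lapply(tsw_inits, function(tsw0)
    run_em(list(par = c(log(g0), log(tsw0)), alpha = alpha_cur), probe))
  best <- starts[[which.min(vapply(starts, function(s) s$times$obj, 1))]]
  if (!best$converged && best$iter < max_iter)
    best <- run_em(best, max_iter - best$iter)

  # if the alternating scheme stalled near a perfect fit without
  # converging, polish on the variable-projection objective (assignment
  # and alpha folded in): on noiseless rising-arc genes the EM crawls
  # along the shallow (alpha, gamma) ridge, a direct 2-D search does
  # not. Noisy fits (objective far from zero) gain nothing from this
  # and skip it.
  obj_full <- function(p) {
    t1 <- assign_times(p, best$alpha)
    a1 <- profile_alpha(p, t1$times)
    assign_times(p, a1, prev = t1$times)$obj
  }
  pol <- if (best$converged || best$times$obj > 0.01) list(value = Inf)
    else stats::optim(best$par, obj_full, method = "Nelder-Mead",
                      control = list(maxit = 100))
  if (pol$value < best$times$obj) {
    best$par <- pol$par
    t1 <- assign_times(pol$par, best$alpha)
    best$alpha <- profile_alpha(pol$par, t1$times)
    best$times <- assign_times(pol$par, best$alpha, prev = t1$times)
    best$trace <- c(best$trace, best$times$obj)
  }
  par <- best$par; times <- best$times
  converged <- best$converged; iter <- best$iter; trace <- best$trace

  alpha <- best$alpha; gamma <- safe_gamma(exp(par[1]))
  t_switch <- exp(par[2]); t_total <- t_total_of(par)
  cv <- curve_at(par, alpha, times$times)
  ru <- mu - cv$u; rs <- ms - cv$s
  q_u <- mean(ru^2) / su^2; q_s <- mean(rs^2) / ss^2
  lik <- exp(-(q_u + q_s) / 2)
  slope <- stats::cov(times$times, mu) / max(stats::var(times$times), 1e-12)
  structure(list(gene_id = gene_id, alpha = alpha, beta = 1, gamma = gamma,
                 t_switch = t_switch, t_total = t_total,
                 latent_time = times$times,
                 residual_scale = sqrt((mean(ru^2) + mean(rs^2)) / 2),
                 fit_likelihood = lik,
                 direction = if (slope < 0) "repression" else "induction",
                 objective = trace, iterations = iter,
                 converged = converged, valid = TRUE),
            class = "gene_fit")
}

#' @export
print.gene_fit <- function(x, ...) {
  if (!x$valid) {
    cat(sprintf("<gene_fit> %s: invalid (degenerate gene)\n", x$gene_id))
  } else {
    cat(sprintf(
      "<gene_fit> %s: alpha=%.3g gamma=%.3g t_switch=%.3g lik=%.3f (%s, %d it%s)\n",
      x$gene_id, x$alpha, x$gamma, x$t_switch, x$fit_likelihood,
      x$direction, x$iterations, if (x$converged) ", converged" else ""))
  }
  invisible(x)
}

#' Fit kinetics for every gene of a moments object
#'
#' @param moments a [compute_moments()] result.
#' @param genes optional character vector restricting the genes fitted.
#' @param ... passed to [fit_gene_kinetics()].
#' @return named list of `gene_fit` objects.
#' @export
fit_all_genes <- function(moments, genes = NULL, ...) {
  stopifnot(inherits(moments, "moments"))
  ids <- colnames(moments$Mu)
  if (is.null(ids)) ids <- sprintf("gene%04d", seq_len(ncol(moments$Mu)))
  if (!is.null(genes)) ids <- intersect(ids, genes)
  fits <- lapply(ids, function(g) {
    fit_gene_kinetics(moments$Mu[, g], moments$Ms[, g], gene_id = g, ...)
  })
  names(fits) <- ids
  fits
}

#' Select driver genes by fit likelihood
#'
#' Driver genes are those with a valid kinetic fit and
#' `fit_likelihood > threshold` (default 0, which admits every valid
#' fit since the likelihood of a valid fit is strictly positive). Each
#' driver carries a direction label from the sign of its fitted unspliced
#' trend: decreasing = repression, increasing = induction.
#'
#' @param fits list of `gene_fit` (e.g. from [fit_all_genes()]).
#' @param threshold likelihood cutoff in `[0, 1]`.
#' @return data.frame with `gene_id`, `fit_likelihood`, `direction`.
#' @export
select_driver_genes <- function(fits, threshold = 0) {
  keep <- vapply(fits, function(f) f$valid && f$fit_likelihood > threshold,
                 TRUE)
  data.frame(
    gene_id = vapply(fits[keep], `[[`, "", "gene_id"),
    fit_likelihood = vapply(fits[keep], `[[`, 1, "fit_likelihood"),
    direction = vapply(fits[keep], `[[`, "", "direction"),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Project new cells onto a fitted kinetic curve
#'
#' Assigns each cell of a (possibly different) sample the latent time
#' minimizing the variance-scaled squared distance of its `(mu, ms)`
#' values to the curve of an existing fit — the assignment step of the
#' fitting scheme with the parameters held fixed. This is how a
#' perturbed sample is placed on the reference manifold fitted to the
#' unperturbed one.
#'
#' @param fit a valid `gene_fit`.
#' @param mu,ms the new sample's unspliced/spliced values for this gene.
#' @param grid_n grid resolution over `[0, t_total]`.
#' @return numeric vector of latent times.
#' @export
project_latent_time <- function(fit, mu, ms, grid_n = 200L) {
  stopifnot(inherits(fit, "gene_fit"), fit$valid, length(mu) == length(ms))
  su <- max(stats::sd(mu), 1e-8)
  ss <- max(stats::sd(ms), 1e-8)
  grid <- seq(0, fit$t_total, length.out = grid_n)
  cv <- fit_curve(fit$alpha, fit$gamma, fit$t_switch, Inf, grid)
  D <- outer(mu / su, cv$u / su, "-")^2 + outer(ms / ss, cv$s / ss, "-")^2
  grid[max.col(-D, ties.method = "first")]
}

#' Per-cell inferred cell time from gene-level latent times
#'
#' Aggregates per-gene latent times into one per-cell time: each
#' contributing gene's latent times are min-max scaled to `[0, 1]`
#' (latent times are identified only up to each gene's own time gauge)
#' and aggregated per cell across genes — by default with the mean,
#' which pools the weak per-gene signal of sparse counts far more
#' efficiently than the median (genes whose projection is degenerate
#' contribute a neutral 0.5). Contributing genes are valid fits with
#' `fit_likelihood` at or above the `likelihood_quantile` of all valid
#' fits. Downstream orderings break ties by cell index.
#'
#' When `mu` and `ms` matrices are supplied, the cells they describe are
#' first projected onto each contributing gene's fitted curve with
#' [project_latent_time()] (reference-manifold projection of another
#' sample); otherwise the latent times stored in the fits are used.
#'
#' @param fits list of `gene_fit`.
#' @param likelihood_quantile quantile cutoff in `[0, 1)` on the valid
#'   fits' likelihoods.
#' @param min_genes minimum number of contributing genes.
#' @param mu,ms optional cells x genes matrices (columns named by gene)
#'   of a sample to project onto the fitted curves.
#' @param aggregate `"mean"` (default) or `"median"` across genes.
#' @return numeric vector of per-cell times in `[0, 1]`.
#' @export
inferred_cell_time <- function(fits, likelihood_quantile = 0.5,
                               min_genes = 10L, mu = NULL, ms = NULL,
                               aggregate = c("mean", "median")) {
  aggregate <- match.arg(aggregate)
  valid <- Filter(function(f) f$valid, fits)
  if (!length(valid)) stop("no valid fits")
  liks <- vapply(valid, `[[`, 1, "fit_likelihood")
  cutoff <- stats::quantile(liks, likelihood_quantile)
  contrib <- valid[liks >= cutoff]
  if (length(contrib) < min_genes)
    stop("only ", length(contrib), " genes at or above the likelihood ",
         "quantile cutoff ", likelihood_quantile, " (= ",
         signif(cutoff, 3), "); need at least ", min_genes)
  times_of <- function(f) {
    if (is.null(mu)) f$latent_time
    else project_latent_time(f, mu[, f$gene_id], ms[, f$gene_id])
  }
  n_cells <- if (is.null(mu)) length(contrib[[1]]$latent_time) else nrow(mu)
  scaled <- vapply(contrib, function(f) {
    t <- times_of(f)
    r <- range(t)
    if (diff(r) < 1e-9) rep(0.5, length(t)) else (t - r[1]) / diff(r)
  }, numeric(n_cells))
  if (aggregate == "median") apply(scaled, 1L, stats::median)
  else rowMeans(scaled)
}
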