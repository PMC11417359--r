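#' Construct a per-gene kinetic parameter record
#'
#' A gene under the two-state transcription model is described by a
#' transcription rate in the ON state (`alpha_on`), a splicing rate `beta`,
#' a degradation rate `gamma`, and the time `t_switch` at which the
#' transcription state changes. The `gene_class` determines which state the
#' gene starts in: `"repression"` genes are ON before `t_switch` and OFF
#' after, `"induction"` genes are OFF before `t_switch` and ON after, and
#' `"steady"` genes transcribe at constant `alpha_on` throughout.
#'
#' @param gene_id character scalar.
#' @param alpha_on transcription rate in the ON state (molecules per unit
#'   time, > 0).
#' @param beta splicing rate (1 / unit time, > 0).
#' @param gamma degradation rate (1 / unit time, > 0, must differ from
#'   `beta`: the closed-form solution assumes distinct rates).
#' @param t_switch time of the transcription state change (>= 0).
#' @param gene_class one of `"induction"`, `"repression"`, `"steady"`.
#' @param ko_frozen logical; whether this gene is perturbed in the KO
#'   sample (repression genes stay ON, induction genes never switch ON).
#' @return An object of class `kinetic_gene` (a named list).
#' @export
kinetic_gene <- function(gene_id, alpha_on, beta, gamma, t_switch,
                         gene_class = c("induction", "repression", "steady"),
                         ko_frozen = FALSE) {
  gene_class <- match.arg(gene_class)
  stopifnot(is.character(gene_id), length(gene_id) == 1L)
  if (!is.numeric(alpha_on) || alpha_on <= 0)
    stop("alpha_on must be strictly positive for gene ", gene_id)
  if (!is.numeric(beta) || beta <= 0)
    stop("beta must be strictly positive for gene ", gene_id)
  if (!is.numeric(gamma) || gamma <= 0)
    stop("gamma must be strictly positive for gene ", gene_id)
  if (isTRUE(all.equal(beta, gamma)))
    stop("beta == gamma: the closed-form solution ",
         "u0*exp(-beta*tau) + ... + (alpha - beta*u0)/(gamma - beta)*(...) ",
         "is degenerate for equal splicing and degradation rates (gene ",
         gene_id, ")")
  if (!is.numeric(t_switch) || t_switch < 0)
    stop("t_switch must be >= 0 for gene ", gene_id)
  structure(
    list(gene_id = gene_id, alpha_on = alpha_on, beta = beta, gamma = gamma,
         t_switch = t_switch, gene_class = gene_class,
         ko_frozen = isTRUE(ko_frozen)),
    class = "kinetic_gene"
  )
}

#' @export
print.kinetic_gene <- function(x, ...) {
  cat(sprintf(
    "<kinetic_gene> %s [%s%s] alpha=%.3g beta=%.3g gamma=%.3g t_switch=%.3g\n",
    x$gene_id, x$gene_class, if (x$ko_frozen) ", ko_frozen" else "",
    x$alpha_on, x$beta, x$gamma, x$t_switch))
  invisible(x)
}

#' Closed-form solution of one constant-rate phase
#'
#' Within a phase of constant transcription rate `alpha`, with `tau` the
#' time elapsed since the phase started at `(u0, s0)`:
#' \deqn{u(\tau) = u_0 e^{-\beta\tau} + \frac{\alpha}{\beta}(1 - e^{-\beta\tau})}
#' \deqn{s(\tau) = s_0 e^{-\gamma\tau} + \frac{\alpha}{\gamma}(1 - e^{-\gamma\tau})
#'   + \frac{\alpha - \beta u_0}{\gamma - \beta}(e^{-\gamma\tau} - e^{-\beta\tau})}
#'
#' @param alpha transcription rate in this phase (0 in the OFF state).
#' @param beta,gamma splicing and degradation rates (`beta != gamma`).
#' @param tau vector of elapsed times since phase start (>= 0).
#' @param u0,s0 unspliced / spliced abundance at phase start.
#' @return A list with numeric vectors `u` and `s` matching `tau`.
#' @export
kinetics_phase <- function(alpha, beta, gamma, tau, u0 = 0, s0 = 0) {
  if (isTRUE(all.equal(beta, gamma)))
    stop("beta == gamma: closed form degenerate, rates must be distinct")
  if (any(tau < -1e-12)) stop("tau must be >= 0 (time since phase start)")
  tau <- pmax(tau, 0)
  eb <- exp(-beta * tau)
  eg <- exp(-gamma * tau)
  u <- u0 * eb + alpha / beta * (1 - eb)
  s <- s0 * eg + alpha / gamma * (1 - eg) +
    (alpha - beta * u0) / (gamma - beta) * (eg - eb)
  list(u = pmax(u, 0), s = pmax(s, 0))
}

#' Expected spliced/unspliced abundance of a gene at absolute time t
#'
#' Evaluates the piecewise two-state trajectory of a [kinetic_gene()] at
#' absolute times `t >= 0`, chaining the closed-form phase solution across
#' the transcription switch so that the trajectory is continuous (the
#' second phase starts from the first phase's value at `t_switch`).
#'
#' Initial conditions at t = 0 follow the gene class: repression genes
#' start at the ON steady state (alpha/beta, alpha/gamma) and switch OFF at
#' `t_switch`; induction genes start at (0, 0), stay OFF, and switch ON at
#' `t_switch`; steady genes sit at the ON steady state throughout.
#'
#' @param gene a [kinetic_gene()].
#' @param t numeric vector of absolute times (>= 0).
#' @param perturbed logical; evaluate the KO-frozen branch instead of the
#'   normal one (only differs when `gene$ko_frozen` is TRUE): frozen
#'   repression genes never switch OFF, frozen induction genes never
#'   switch ON.
#' @param phase_initial optional numeric `c(u0, s0)` overriding the
#'   class-determined state at t = 0.
#' @return list with vectors `u` and `s` (both >= 0).
#' @export
kinetics_expected <- function(gene, t, perturbed = FALSE,
                              phase_initial = NULL) {
  stopifnot(inherits(gene, "kinetic_gene"))
  if (any(t < 0)) stop("t must be >= 0")
  a <- gene$alpha_on; b <- gene$beta; g <- gene$gamma; tsw <- gene$t_switch
  frozen <- perturbed && gene$ko_frozen

  init <- phase_initial
  u <- numeric(length(t)); s <- numeric(length(t))

  if (gene$gene_class == "steady" ||
      (frozen && gene$gene_class == "repression")) {
    # constant ON transcription; repression genes frozen ON never decline
    if (is.null(init)) init <- c(a / b, a / g)
    ph <- kinetics_phase(a, b, g, t, init[1], init[2])
    return(ph)
  }
  if (frozen && gene$gene_class == "induction") {
    # never switches ON: decays from the initial state (default 0,0)
    if (is.null(init)) init <- c(0, 0)
    return(kinetics_phase(0, b, g, t, init[1], init[2]))
  }

  if (gene$gene_class == "repression") {
    if (is.null(init)) init <- c(a / b, a / g)
    a1 <- a; a2 <- 0
  } else { # induction
    if (is.null(init)) init <- c(0, 0)
    a1 <- 0; a2 <- a
  }
  pre <- t < tsw
  if (any(pre)) {
    ph <- kinetics_phase(a1, b, g, t[pre], init[1], init[2])
    u[pre] <- ph$u; s[pre] <- ph$s
  }
  if (any(!pre)) {
    at_sw <- kinetics_phase(a1, b, g, tsw, init[1], init[2])
    ph <- kinetics_phase(a2, b, g, t[!pre] - tsw, at_sw$u, at_sw$s)
    u[!pre] <- ph$u; s[!pre] <- ph$s
  }
  list(u = u, s = s)
}

#' Parametric fitting curve: ON from the origin, then OFF
#'
#' The curve used by the kinetics fitter: transcription switches ON at time
#' 0 from (0, 0), runs until `t_switch`, then switches OFF until `t_total`.
#' The splicing rate is fixed to `beta = 1` as the time-scale gauge (the
#' spliced/unspliced phase portrait identifies rates only up to a common
#' rescaling of time).
#'
#' @param alpha,gamma ON transcription rate and degradation rate
#'   (in units of the splicing rate).
#' @param t_switch switch-off time (> 0).
#' @param t_total end of the fitted time window (> `t_switch`).
#' @param times numeric vector of latent times in `[0, t_total]`.
#' @return list with vectors `u`, `s`.
#' @keywords internal
fit_curve <- function(alpha, gamma, t_switch, t_total, times) {
  beta <- 1
  on <- times <= t_switch
  u <- numeric(length(times)); s <- numeric(length(times))
  if (any(on)) {
    ph <- kinetics_phase(alpha, beta, gamma, times[on], 0, 0)
    u[on] <- ph$u; s[on] <- ph$s
  }
  if (any(!on)) {
    at_sw <- kinetics_phase(alpha, beta, gamma, t_switch, 0, 0)
    ph <- kinetics_phase(0, beta, gamma, times[!on] - t_switch,
                         at_sw$u, at_sw$s)
    u[!on] <- ph$u; s[!on] <- ph$s
  }
  list(u = u, s = s)
}
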