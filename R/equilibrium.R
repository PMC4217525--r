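#' Convert a concentration to a molecule count
#'
#' Uses the fixed unit system uM / fl: one uM in one fl corresponds to
#' 602.214076 molecules (Avogadro's number times 1e-21). The returned count
#' is real-valued; callers that need integer copy numbers (e.g. SSA initial
#' states) round half-to-even via [round()].
#'
#' @param conc Concentration (uM), >= 0. Vectorized.
#' @param volume Volume (fl), > 0.
#' @return Real-valued molecule count `conc * volume * 602.214076`.
#' @examples
#' concentration_to_count(0.1, 1)  # ~60 ions at 100 nM in 1 fl
#' @export
concentration_to_count <- function(conc, volume) {
  if (any(!is.finite(conc)) || any(conc < 0))
    stop("'conc' must be non-negative")
  if (any(!is.finite(volume)) || any(volume <= 0))
    stop("'volume' must be positive")
  conc * volume * COUNTS_PER_UM_FL
}

#' Convert a molecule count to a concentration (uM)
#'
#' Inverse of [concentration_to_count()].
#'
#' @param count Molecule count (real-valued), >= 0.
#' @param volume Volume (fl), > 0.
#' @return Concentration in uM.
#' @export
count_to_concentration <- function(count, volume) {
  if (any(!is.finite(count)) || any(count < 0))
    stop("'count' must be non-negative")
  if (any(!is.finite(volume)) || any(volume <= 0))
    stop("'volume' must be positive")
  count / (volume * COUNTS_PER_UM_FL)
}

#' Equilibrium state of a buffered microdomain
#'
#' At chemical equilibrium the bound-complex concentration of each buffer
#' follows from mass action: `z_j = B_T,j / (1 + K_D,j / x)`, where `x` is
#' the free-calcium concentration. Free buffer is `y_j = B_T,j - z_j` and
#' the total calcium concentration is `x_T = x + sum_j z_j`.
#'
#' @param system A [ca_system()].
#' @return An object of class `ca_equilibrium`: a list with concentrations
#'   `x_eq`, `y_eq` (per buffer), `z_eq` (per buffer), `x_T` (all uM) and
#'   `counts`, the same quantities as real-valued copy numbers in the
#'   system's volume.
#' @examples
#' eq <- equilibrium_state(ca_system("CaM", volume = 0.125, ca_eq = 0.1))
#' eq$z_eq  # 5 uM bound calmodulin
#' @export
equilibrium_state <- function(system) {
  stopifnot(inherits(system, "ca_system"))
  x <- system$ca_eq
  M <- n_buffers(system)
  if (M > 0L) {
    B_T <- buffer_field(system, "B_T")
    K_D <- buffer_field(system, "K_D")
    z <- B_T / (1 + K_D / x)
    y <- B_T - z
    names(z) <- names(y) <- vapply(system$buffers, `[[`, "", "name")
  } else {
    z <- y <- numeric(0)
  }
  x_T <- x + sum(z)
  V <- system$volume
  structure(
    list(x_eq = x, y_eq = y, z_eq = z, x_T = x_T,
         counts = list(
           x_eq = concentration_to_count(x, V),
           y_eq = concentration_to_count(y, V),
           z_eq = concentration_to_count(z, V),
           B_T = concentration_to_count(if (M > 0L) B_T else numeric(0), V),
           x_T = concentration_to_count(x_T, V)),
         volume = V),
    class = "ca_equilibrium")
}

#' @export
print.ca_equilibrium <- function(x, ...) {
  cat(sprintf("<ca_equilibrium> x = %g uM (%.4g counts), x_T = %g uM\n",
              x$x_eq, x$counts$x_eq, x$x_T))
  if (length(x$z_eq))
    for (j in seq_along(x$z_eq))
      cat(sprintf("  %-8s y = %g uM, z = %g uM\n",
                  names(x$z_eq)[j], x$y_eq[j], x$z_eq[j]))
  invisible(x)
}

#' Equilibrium from total calcium
#'
#' Solves the inverse equilibrium problem: given the total calcium
#' concentration `x_T` (free plus bound across all buffers), find the free
#' concentration `x` satisfying `x + sum_j B_T,j/(1 + K_D,j/x) = x_T`. The
#' map is strictly increasing in `x`, so the root is found by bracketed
#' bisection ([uniroot()]) on `[0, x_T]` to relative tolerance 1e-12.
#'
#' @param x_T Total calcium concentration (uM), >= 0.
#' @param buffers Buffers as accepted by [ca_system()].
#' @param volume Volume (fl) used to fill the count fields of the returned
#'   state (default 1).
#' @return A `ca_equilibrium` (see [equilibrium_state()]).
#' @export
totals_to_equilibrium <- function(x_T, buffers = list(), volume = 1) {
  if (!is.numeric(x_T) || length(x_T) != 1L || !is.finite(x_T) || x_T < 0)
    stop("'x_T' must be a single non-negative number (uM)")
  if (inherits(buffers, "buffer_spec") || is.character(buffers))
    buffers <- as.list(buffers)
  buffers <- lapply(buffers, as_buffer_spec)
  if (x_T == 0 || length(buffers) == 0L) {
    x_eq <- x_T
  } else {
    B_T <- vapply(buffers, `[[`, numeric(1), "B_T")
    K_D <- vapply(buffers, `[[`, numeric(1), "K_D")
    total <- function(x) x + sum(B_T / (1 + K_D / x)) - x_T
    # total(0+) = -x_T < 0 and total(x_T) >= 0: the bracket always works.
    x_eq <- uniroot(total, lower = 0, upper = x_T,
                    f.lower = -x_T, tol = 1e-14 * max(x_T, 1))$root
  }
  if (x_eq == 0) {
    # degenerate all-zero system; build the state directly
    M <- length(buffers)
    z <- y <- numeric(M)
    if (M > 0L) {
      y <- vapply(buffers, `[[`, numeric(1), "B_T")
      names(z) <- names(y) <- vapply(buffers, `[[`, "", "name")
    }
    return(structure(
      list(x_eq = 0, y_eq = y, z_eq = z, x_T = 0,
           counts = list(x_eq = 0,
                         y_eq = concentration_to_count(y, volume),
                         z_eq = z, B_T = concentration_to_count(y, volume),
                         x_T = 0),
           volume = volume),
      class = "ca_equilibrium"))
  }
  equilibrium_state(ca_system(buffers, volume = volume, ca_eq = x_eq))
}

#' @importFrom stats uniroot
NULL

#' Stochastic rate constants for a microdomain
#'
#' Converts deterministic mass-action rate constants into the per-molecule
#' stochastic rates used by the SSA and the chemical Langevin equation.
#' Bimolecular association rates scale with the reaction volume,
#' `c_plus = k_plus / (602.214076 * V)`, so that the propensity
#' `c_plus * X * Y` in copy numbers reproduces the deterministic flux
#' `k_plus * x * y`; monomolecular rates are unchanged (`c_minus = k_minus`).
#' With diffusion enabled, the hop rate is `c_d = D_Ca / L^2`.
#'
#' @param system A [ca_system()].
#' @return A list of class `stochastic_rates` with per-buffer vectors
#'   `c_plus` (ms^-1 per molecule pair) and `c_minus` (ms^-1), and scalar
#'   `c_d` (ms^-1; 0 when diffusion is off).
#' @examples
#' stochastic_rates(ca_system("CaM", volume = 1, ca_eq = 0.1))$c_plus
#' @export
stochastic_rates <- function(system) {
  stopifnot(inherits(system, "ca_system"))
  M <- n_buffers(system)
  if (M > 0L) {
    c_plus <- buffer_field(system, "k_plus") /
      (COUNTS_PER_UM_FL * system$volume)
    c_minus <- buffer_field(system, "k_minus")
    names(c_plus) <- names(c_minus) <-
      vapply(system$buffers, `[[`, "", "name")
  } else {
    c_plus <- c_minus <- numeric(0)
  }
  c_d <- if (is.null(system$D_Ca)) 0 else system$D_Ca / system$edge_length^2
  structure(list(c_plus = c_plus, c_minus = c_minus, c_d = c_d),
            class = "stochastic_rates")
}
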