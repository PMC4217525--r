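#' Define a buffered calcium microdomain
#'
#' A microdomain is a small, well-mixed reaction volume holding free calcium
#' at a nominal equilibrium concentration together with `M >= 0` calcium
#' buffers. Optionally, calcium (but not buffer) exchanges with an
#' equilibrated surrounding pool by diffusion across the voxel boundary.
#'
#' The voxel is taken to be cubic, so the edge length is `volume^(1/3)`
#' (1 fl = 1 um^3). The diffusive hop rate used by the stochastic engines is
#' `c_d = D_Ca / L^2`.
#'
#' @param buffers Buffers in the domain: a list of [buffer_spec()] objects,
#'   character names resolved via [buffer_from_table()], or parameter lists;
#'   may be empty.
#' @param volume Reaction volume in femtoliters, > 0.
#' @param ca_eq Equilibrium free-calcium concentration (uM), > 0.
#' @param D_Ca Calcium diffusion constant (um^2/ms), or `NULL` for a closed
#'   voxel with no diffusion.
#' @return An object of class `ca_system` with fields `buffers` (list of
#'   `buffer_spec`), `volume` (fl), `edge_length` (um), `ca_eq` (uM),
#'   `D_Ca` (um^2/ms or `NULL`).
#' @examples
#' sys <- ca_system("CaM", volume = 0.125, ca_eq = 0.1)
#' equilibrium_state(sys)
#' @export
ca_system <- function(buffers = list(), volume = 1, ca_eq = 0.1,
                      D_Ca = NULL) {
  if (inherits(buffers, "buffer_spec") || is.character(buffers))
    buffers <- as.list(buffers)
  buffers <- lapply(buffers, as_buffer_spec)
  nms <- vapply(buffers, `[[`, "", "name")
  if (anyDuplicated(nms))
    stop("buffer names must be unique")
  if (!is.numeric(volume) || length(volume) != 1L || !is.finite(volume) ||
      volume <= 0)
    stop("'volume' must be a single positive number (fl)")
  if (!is.numeric(ca_eq) || length(ca_eq) != 1L || !is.finite(ca_eq) ||
      ca_eq <= 0)
    stop("'ca_eq' must be a single positive number (uM)")
  if (!is.null(D_Ca)) {
    if (!is.numeric(D_Ca) || length(D_Ca) != 1L || !is.finite(D_Ca) ||
        D_Ca <= 0)
      stop("'D_Ca' must be a single positive number (um^2/ms) or NULL")
  }
  structure(
    list(buffers = buffers, volume = volume,
         edge_length = volume^(1 / 3), ca_eq = ca_eq, D_Ca = D_Ca),
    class = "ca_system")
}

#' @export
print.ca_system <- function(x, ...) {
  cat(sprintf("<ca_system> V = %g fl (L = %g um), [Ca]_eq = %g uM\n",
              x$volume, x$edge_length, x$ca_eq))
  if (length(x$buffers) == 0L) {
    cat("  no buffers\n")
  } else {
    for (b in x$buffers)
      cat(sprintf("  %-8s B_T = %g uM, k+ = %g, k- = %g, K_D = %g uM\n",
                  b$name, b$B_T, b$k_plus, b$k_minus, b$K_D))
  }
  if (is.null(x$D_Ca)) cat("  diffusion: none\n")
  else cat(sprintf("  diffusion: D_Ca = %g um^2/ms (c_d = %g ms^-1)\n",
                   x$D_Ca, x$D_Ca / x$edge_length^2))
  invisible(x)
}

#' @export
summary.ca_system <- function(object, ...) {
  eq <- equilibrium_state(object)
  np <- noise_params(object)
  print(object)
  cat(sprintf("  equilibrium: X = %.4g counts (%.4g uM), total Ca = %.4g uM\n",
              eq$counts$x_eq, eq$x_eq, eq$x_T))
  print(np)
  invisible(list(equilibrium = eq, noise = np))
}

# number of buffers
n_buffers <- function(system) length(system$buffers)

buffer_field <- function(system, field)
  vapply(system$buffers, `[[`, numeric(1), field)

#' Read a microdomain definition from a config file
#'
#' Reads a flat YAML (or JSON) file with keys `volume_fl`, `ca_eq_uM`,
#' optional `D_Ca_um2_per_ms`, and `buffers`: a list whose entries are
#' either a table name (`name: CaM`) or explicit parameters
#' (`B_T`/`k_plus`/`k_minus`).
#'
#' @param path Path to the config file.
#' @return A [ca_system()].
#' @export
read_system_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  buffers <- lapply(cfg$buffers, function(b) {
    if (is.character(b)) return(b)
    if (!is.null(b$name) && is.null(b$B_T)) return(b$name)
    b
  })
  ca_system(buffers = if (is.null(buffers)) list() else buffers,
            volume = cfg$volume_fl,
            ca_eq = cfg$ca_eq_uM,
            D_Ca = cfg$D_Ca_um2_per_ms)
}
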