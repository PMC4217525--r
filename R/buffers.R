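#' Define a calcium buffer species
#'
#' A buffer is a molecule that reversibly binds a single calcium ion,
#' `Ca + B <-> CaB`, characterized by its total concentration and the
#' association/dissociation rate constants. The dissociation constant
#' `K_D = k_minus / k_plus` is always derived from the rates, never stored
#' independently, so the triplet can never become inconsistent.
#'
#' @param name Character label for the buffer (must be unique in a system).
#' @param B_T Total buffer concentration (uM), > 0.
#' @param k_plus Association rate constant (uM^-1 ms^-1), > 0.
#' @param k_minus Dissociation rate constant (ms^-1), >= 0.
#' @param CV Optional coefficient-of-variation metadata carried along from a
#'   reference table; not used in any computation.
#' @param reference Optional literature reference string (metadata).
#' @return An object of class `buffer_spec`: a list with fields `name`,
#'   `B_T`, `k_plus`, `k_minus`, the derived `K_D` (uM), and any metadata.
#' @seealso [buffer_from_table()], [dissociation_constant()]
#' @examples
#' cam <- buffer_spec("CaM", B_T = 24, k_plus = 0.1, k_minus = 0.038)
#' cam$K_D  # 0.38 uM
#' @export
buffer_spec <- function(name, B_T, k_plus, k_minus, CV = NA_real_,
                        reference = NA_character_) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.numeric(B_T) || length(B_T) != 1L || !is.finite(B_T) || B_T <= 0)
    stop("'B_T' must be a single positive number (uM)")
  if (!is.numeric(k_plus) || length(k_plus) != 1L || !is.finite(k_plus) ||
      k_plus <= 0)
    stop("'k_plus' must be a single positive number (uM^-1 ms^-1)")
  if (!is.numeric(k_minus) || length(k_minus) != 1L || !is.finite(k_minus) ||
      k_minus < 0)
    stop("'k_minus' must be a single non-negative number (ms^-1)")
  structure(
    list(name = name, B_T = B_T, k_plus = k_plus, k_minus = k_minus,
         K_D = dissociation_constant(k_plus, k_minus),
         CV = CV, reference = reference),
    class = "buffer_spec")
}

#' @export
print.buffer_spec <- function(x, ...) {
  cat(sprintf(
    "<buffer_spec> %s: B_T = %g uM, k+ = %g uM^-1 ms^-1, k- = %g ms^-1, K_D = %g uM\n",
    x$name, x$B_T, x$k_plus, x$k_minus, x$K_D))
  invisible(x)
}

#' Buffer dissociation constant
#'
#' @param k_plus Association rate constant (uM^-1 ms^-1), > 0.
#' @param k_minus Dissociation rate constant (ms^-1), >= 0.
#' @return `k_minus / k_plus` in uM.
#' @examples
#' dissociation_constant(0.1, 0.038)  # 0.38
#' @export
dissociation_constant <- function(k_plus, k_minus) {
  if (any(!is.finite(k_plus)) || any(k_plus <= 0))
    stop("'k_plus' must be positive")
  if (any(!is.finite(k_minus)) || any(k_minus < 0))
    stop("'k_minus' must be non-negative")
  k_minus / k_plus
}

#' Reference table of physiological and artificial calcium buffers
#'
#' Returns the built-in table of commonly used calcium buffers and indicator
#' dyes (calmodulin, troponin C, parvalbumin, EGTA, Fluo-4, OGB-5N) with
#' their total concentrations and kinetic rate constants as collected from
#' the modelling literature. The dissociation constant is recomputed from
#' the rates; the `CV` column is carried as metadata only.
#'
#' @return A data.frame with columns `name`, `B_T_uM`, `k_plus`, `k_minus`,
#'   `K_D_uM` (derived), `alpha` (`K_D / B_T`, derived), `CV`, `reference`.
#' @seealso [buffer_from_table()]
#' @export
buffer_table <- function() {
  path <- system.file("extdata", "buffer_table.tsv", package = "camnoise",
                      mustWork = TRUE)
  tab <- read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  tab$K_D_uM <- dissociation_constant(tab$k_plus, tab$k_minus)
  tab$alpha <- tab$K_D_uM / tab$B_T_uM
  tab[, c("name", "B_T_uM", "k_plus", "k_minus", "K_D_uM", "alpha",
          "CV", "reference")]
}

#' Look up a buffer from the built-in reference table
#'
#' @param name Buffer name; one of `"CaM"`, `"TnC"`, `"PV"`, `"EGTA"`,
#'   `"Fluo-4"`, `"OGB-5N"` (case-insensitive).
#' @return A [buffer_spec()] with the tabulated parameters and `K_D`
#'   recomputed from `k_minus / k_plus`.
#' @examples
#' buffer_from_table("CaM")
#' @export
buffer_from_table <- function(name) {
  stopifnot(is.character(name), length(name) == 1L)
  tab <- buffer_table()
  i <- match(tolower(name), tolower(tab$name))
  if (is.na(i))
    stop(sprintf("unknown buffer '%s'; available: %s",
                 name, paste(tab$name, collapse = ", ")))
  buffer_spec(tab$name[i], B_T = tab$B_T_uM[i], k_plus = tab$k_plus[i],
              k_minus = tab$k_minus[i], CV = tab$CV[i],
              reference = tab$reference[i])
}

# Coerce a buffer given as a name, buffer_spec, or parameter list.
as_buffer_spec <- function(b) {
  if (inherits(b, "buffer_spec")) return(b)
  if (is.character(b) && length(b) == 1L) return(buffer_from_table(b))
  if (is.list(b)) {
    nm <- if (is.null(b$name)) "buffer" else b$name
    return(buffer_spec(nm, B_T = b$B_T, k_plus = b$k_plus,
                       k_minus = b$k_minus))
  }
  stop("cannot interpret buffer specification; give a name, a buffer_spec, ",
       "or a list with B_T/k_plus/k_minus")
}
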