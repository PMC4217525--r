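# Internal constructor for uniformly sampled trajectories.
new_trajectory <- function(time, values, dt, engine, seed = NULL,
                           meta = list()) {
  if (is.null(dim(values))) values <- matrix(values, ncol = 1L,
                                             dimnames = list(NULL, "X"))
  stopifnot(nrow(values) == length(time))
  structure(
    list(time = time, values = values, dt = dt, t0 = time[1L],
         meta = c(list(engine = engine, seed = seed), meta)),
    class = "ca_trajectory")
}

#' @export
print.ca_trajectory <- function(x, ...) {
  cat(sprintf(
    "<ca_trajectory> engine = %s, %d samples, dt = %g ms, span [%g, %g] ms\n",
    x$meta$engine, length(x$time), x$dt, x$t0, x$time[length(x$time)]))
  cat(sprintf("  species: %s\n", paste(colnames(x$values), collapse = ", ")))
  if (!is.null(x$meta$seed)) cat(sprintf("  seed: %s\n", x$meta$seed))
  nc <- x$meta$n_clamp_species
  if (!is.null(nc) && nc > 0)
    cat(sprintf("  note: %g species clamps at 0 occurred\n", nc))
  invisible(x)
}

#' @export
as.data.frame.ca_trajectory <- function(x, ...) {
  data.frame(time_ms = x$time, x$values, check.names = FALSE)
}

#' @export
plot.ca_trajectory <- function(x, species = colnames(x$values)[1L], ...) {
  graphics::plot(x$time, x$values[, species], type = "l",
                 xlab = "time (ms)", ylab = paste(species, "(counts)"), ...)
  invisible(x)
}

# Free-calcium series of a trajectory (first column by convention).
traj_series <- function(traj, species = "X") {
  stopifnot(inherits(traj, "ca_trajectory"))
  if (!species %in% colnames(traj$values))
    stop(sprintf("species '%s' not present in trajectory", species))
  traj$values[, species]
}

#' Write a trajectory to a TSV file
#'
#' Writes a tab-separated table (`time_ms` plus one column per species)
#' with a commented header line recording the engine, seed and sampling
#' interval.
#'
#' @param traj A `ca_trajectory`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "ca_trajectory"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# engine=%s seed=%s dt=%g %s",
                     traj$meta$engine,
                     if (is.null(traj$meta$seed)) "NA" else traj$meta$seed,
                     traj$dt,
                     if (is.null(traj$meta$system)) "" else traj$meta$system),
             con)
  write.table(as.data.frame(traj), con, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Read a trajectory written by [write_trajectory()]
#'
#' @param path Path to a TSV trajectory file.
#' @return A `ca_trajectory`.
#' @export
read_trajectory <- function(path) {
  header <- readLines(path, n = 1L)
  tab <- read.delim(path, comment.char = "#", check.names = FALSE)
  time <- tab$time_ms
  vals <- as.matrix(tab[, setdiff(names(tab), "time_ms"), drop = FALSE])
  meta <- list()
  if (startsWith(header, "#")) {
    kv <- regmatches(header, gregexpr("[a-zA-Z_]+=[^ ]+", header))[[1L]]
    for (p in kv) {
      parts <- strsplit(p, "=", fixed = TRUE)[[1L]]
      meta[[parts[1L]]] <- parts[2L]
    }
  }
  engine <- if (is.null(meta$engine)) "unknown" else meta$engine
  dt <- if (length(time) > 1L) time[2L] - time[1L] else NA_real_
  new_trajectory(time, vals, dt, engine,
                 seed = meta$seed, meta = meta[setdiff(names(meta),
                                                       c("engine", "seed"))])
}

# short human-readable digest of a system, recorded in trajectory metadata
system_digest <- function(system) {
  bufs <- vapply(system$buffers, function(b)
    sprintf("%s:%g:%g:%g", b$name, b$B_T, b$k_plus, b$k_minus), "")
  sprintf("system=[%s]V%g.ca%g.D%s", paste(bufs, collapse = "+"),
          system$volume, system$ca_eq,
          if (is.null(system$D_Ca)) "0" else format(system$D_Ca))
}
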