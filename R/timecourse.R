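#' Construct a time course
#'
#' Container for dynamic concentration and flux data on a shared time grid,
#' optionally with replicate measurements (the third array dimension).
#'
#' @param times strictly increasing numeric vector of timepoints.
#' @param conc metabolite-by-timepoint matrix, or a 3-d array
#'   `metabolite x timepoint x replicate`.
#' @param flux reaction-by-timepoint matrix or 3-d array with the same
#'   replicate count as `conc`.
#' @param noise_applied,collapsed provenance flags: whether measurement
#'   noise has been added and whether replicates have been collapsed back
#'   to a single series.
#'
#' @return An object of class `scour_timecourse` with elements `times`,
#'   `conc`, `flux` (both stored as 3-d arrays), `replicates`, and the
#'   provenance flags.
#' @export
scour_timecourse <- function(times, conc, flux,
                             noise_applied = FALSE, collapsed = FALSE) {
  times <- as.numeric(times)
  if (is.unsorted(times, strictly = TRUE)) {
    stop("times must be strictly increasing", call. = FALSE)
  }
  as3d <- function(m) {
    if (length(dim(m)) == 2) m <- array(m, c(dim(m), 1L), dimnames = c(dimnames(m), list(NULL)))
    m
  }
  conc <- as3d(conc)
  flux <- as3d(flux)
  if (dim(conc)[2] != length(times) || dim(flux)[2] != length(times)) {
    stop("conc/flux timepoint dimension must match times", call. = FALSE)
  }
  if (dim(conc)[3] != dim(flux)[3]) {
    stop("conc and flux must have the same replicate count", call. = FALSE)
  }
  structure(
    list(times = times, conc = conc, flux = flux,
         replicates = dim(conc)[3],
         noise_applied = noise_applied, collapsed = collapsed),
    class = "scour_timecourse"
  )
}

#' @export
print.scour_timecourse <- function(x, ...) {
  cat(sprintf(
    "<scour_timecourse> %d metabolites, %d fluxes, %d timepoints [%g, %g], %d replicate(s)%s\n",
    dim(x$conc)[1], dim(x$flux)[1], length(x$times),
    min(x$times), max(x$times), x$replicates,
    if (x$noise_applied) ", noisy" else ""))
  invisible(x)
}

## extract a single species series (replicate r, default 1)
tc_series <- function(tc, type = c("metabolite", "flux"), id, rep = 1L) {
  type <- match.arg(type)
  arr <- if (type == "metabolite") tc$conc else tc$flux
  i <- match(id, rownames(arr))
  if (is.na(i)) stop(sprintf("unknown %s id '%s'", type, id), call. = FALSE)
  arr[i, , rep]
}

#' Read / write time courses as tidy CSV
#'
#' The tidy schema has columns `time`, `species_type`
#' (`metabolite`|`flux`), `species_id`, `replicate`, `value`; one row per
#' observation. `read_timecourse_wide` reads the alternative wide layout
#' (a `time` column plus one column per species); metabolite columns are
#' distinguished from flux columns by a name prefix (`v` marks fluxes by
#' default).
#'
#' @param tc a [scour_timecourse].
#' @param path CSV file path.
#' @param flux_prefix in the wide reader, column-name prefix identifying
#'   flux columns; all other non-time columns are metabolites.
#' @return `read_timecourse` and `read_timecourse_wide` return a
#'   [scour_timecourse]; `write_timecourse` returns `path` invisibly.
#' @export
write_timecourse <- function(tc, path) {
  rows <- list()
  for (type in c("metabolite", "flux")) {
    arr <- if (type == "metabolite") tc$conc else tc$flux
    for (r in seq_len(dim(arr)[3])) {
      m <- arr[, , r, drop = FALSE][, , 1]
      if (is.null(dim(m))) m <- matrix(m, nrow = 1, dimnames = list(rownames(arr), NULL))
      rows[[length(rows) + 1L]] <- data.frame(
        time = rep(tc$times, each = nrow(m)),
        species_type = type,
        species_id = rep(rownames(m), times = ncol(m)),
        replicate = r,
        value = as.vector(m)
      )
    }
  }
  df <- do.call(rbind, rows)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_timecourse
#' @export
read_timecourse <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("time", "species_type", "species_id", "replicate", "value")
  if (!all(need %in% names(df))) {
    stop("tidy time-course CSV must have columns: ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  times <- sort(unique(df$time))
  reps <- sort(unique(df$replicate))
  build <- function(type) {
    sub <- df[df$species_type == type, ]
    ids <- unique(sub$species_id)
    arr <- array(NA_real_, c(length(ids), length(times), length(reps)),
                 dimnames = list(ids, NULL, NULL))
    i <- cbind(match(sub$species_id, ids), match(sub$time, times),
               match(sub$replicate, reps))
    arr[i] <- sub$value
    arr
  }
  conc <- build("metabolite")
  flux <- build("flux")
  if (anyNA(conc) || anyNA(flux)) {
    stop("incomplete time-course table: missing species/time/replicate cells",
         call. = FALSE)
  }
  scour_timecourse(times, conc, flux,
                   noise_applied = length(reps) > 1, collapsed = FALSE)
}

#' @rdname write_timecourse
#' @export
read_timecourse_wide <- function(path, flux_prefix = "v") {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"time" %in% names(df)) {
    stop("wide time-course CSV must have a 'time' column", call. = FALSE)
  }
  species <- setdiff(names(df), c("time", "replicate"))
  is_flux <- startsWith(species, flux_prefix)
  reps <- if ("replicate" %in% names(df)) sort(unique(df$replicate)) else 1L
  times <- sort(unique(df$time))
  build <- function(ids) {
    arr <- array(NA_real_, c(length(ids), length(times), length(reps)),
                 dimnames = list(ids, NULL, NULL))
    for (r in seq_along(reps)) {
      sub <- if ("replicate" %in% names(df)) df[df$replicate == reps[r], ] else df
      sub <- sub[order(sub$time), ]
      for (id in ids) arr[id, , r] <- sub[[id]]
    }
    arr
  }
  scour_timecourse(times, build(species[!is_flux]), build(species[is_flux]),
                   noise_applied = length(reps) > 1, collapsed = FALSE)
}
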