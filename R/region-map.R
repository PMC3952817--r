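#' Spatial region map of the 1-D germarium geometry
#'
#' The model represents the anterior germarium as a line of cells: the somatic
#' cap cell (CC) compartment at the anterior end, followed by the germline
#' cells.  Germline cells are partitioned into four contiguous regions used
#' throughout for observations, objectives and experiment design.
#'
#' @param gsc,cb,cyst,posterior Integer vectors of 1-based germline cell
#'   indices for each region.  Defaults follow the standard geometry: one GSC,
#'   one cystoblast, seven cyst cells (cells 3--9) and eight posterior cells
#'   (cells 10--17), for 17 germline cells plus the CC (18 compartments).
#' @return An object of class `os_region_map`: a list with `regions` (named
#'   list of index vectors), `region_names`, `n_cells_germline` and
#'   `n_cells_total` (including the CC).
#' @examples
#' rm <- region_map()
#' rm$n_cells_total   # 18
#' rm$regions$Cyst    # 3:9
#' @export
region_map <- function(gsc = 1L, cb = 2L, cyst = 3:9, posterior = 10:17) {
  regions <- list(GSC = as.integer(gsc), CB = as.integer(cb),
                  Cyst = as.integer(cyst), Posterior = as.integer(posterior))
  all_idx <- sort(unlist(regions, use.names = FALSE))
  n <- length(all_idx)
  if (!identical(all_idx, seq_len(n))) {
    stop("region cell ranges must be contiguous, non-overlapping and cover 1..n",
         call. = FALSE)
  }
  for (r in regions) {
    if (!identical(as.integer(r), seq(min(r), max(r)))) {
      stop("each region must be a contiguous index range", call. = FALSE)
    }
  }
  structure(
    list(regions = regions,
         region_names = names(regions),
         n_cells_germline = n,
         n_cells_total = n + 1L),
    class = "os_region_map")
}

#' @export
print.os_region_map <- function(x, ...) {
  cat("<os_region_map> CC +", x$n_cells_germline, "germline cells\n")
  for (nm in x$region_names)
    cat(" ", nm, ": cells", min(x$regions[[nm]]), "-", max(x$regions[[nm]]), "\n")
  invisible(x)
}

#' Region label of each germline cell
#'
#' @param rm An `os_region_map`.
#' @return Character vector of length `rm$n_cells_germline`.
#' @keywords internal
region_of_cells <- function(rm) {
  out <- character(rm$n_cells_germline)
  for (nm in rm$region_names) out[rm$regions[[nm]]] <- nm
  out
}
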