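#' Ordinal observation tables
#'
#' Observations are qualitative measurements of one species under one genetic
#' condition: a small-integer rank (1 = lowest) per spatial region, with
#' unobserved regions masked (`NA`).  Each observation belongs to one of three
#' data categories — `WildType`, `Mutant` or `Behavioral` — and may be flagged
#' `dynamic` (scored on the post-division 12 h protocol rather than at steady
#' state).
#'
#' An observation set is a tibble of class `os_observations` with columns
#' `index`, `species`, `condition` (label string), `category`, `dynamic`,
#' `n_categories`, and one `rank_<Region>` column per region, plus a
#' `region_map` attribute.
#'
#' @name os_observations
NULL

OBS_SPECIES <- c("pMad", "Bam", "Nos", "Brat", "Phenotype", "dMyc", "Dpp")
OBS_CATEGORIES <- c("WildType", "Mutant", "Behavioral")

new_observations <- function(df, rm) {
  df <- tibble::as_tibble(df)
  structure(df, region_map = rm,
            class = c("os_observations", class(df)))
}

rank_cols <- function(rm) paste0("rank_", rm$region_names)

validate_observations <- function(df, rm, file = NULL) {
  where <- if (is.null(file)) "" else paste0(" in ", file)
  need <- c("index", "species", "condition", "category", "dynamic",
            "n_categories", rank_cols(rm))
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("missing column(s)", where, ": ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(df$index))
    stop("observation indices must be unique", where, call. = FALSE)
  bad_sp <- setdiff(unique(df$species), OBS_SPECIES)
  if (length(bad_sp))
    stop("unknown species", where, ": ", paste(bad_sp, collapse = ", "),
         call. = FALSE)
  bad_cat <- setdiff(unique(df$category), OBS_CATEGORIES)
  if (length(bad_cat))
    stop("unknown category", where, ": ", paste(bad_cat, collapse = ", "),
         call. = FALSE)
  rk <- as.matrix(df[rank_cols(rm)])
  for (i in seq_len(nrow(df))) {
    r <- rk[i, ]
    if (all(is.na(r)))
      stop("observation ", df$index[i], " has no observed region", call. = FALSE)
    nc <- df$n_categories[i]
    if (nc < 1)
      stop("observation ", df$index[i], ": n_categories must be >= 1",
           call. = FALSE)
    obs_r <- r[!is.na(r)]
    if (any(obs_r < 1 | obs_r > nc | obs_r != round(obs_r)))
      stop("observation ", df$index[i], ": ranks must be integers in 1..",
           nc, call. = FALSE)
  }
  # conditions must parse
  invisible(lapply(df$condition, parse_condition))
  invisible(df)
}

#' Read an ordinal observation table from CSV
#'
#' The CSV dialect has header
#' `index,species,condition,category,dynamic,n_categories,rank_GSC,rank_CB,rank_Cyst,rank_Posterior`;
#' masked (unobserved) regions are empty cells, conditions are canonical
#' labels as produced by [condition_label()].
#'
#' @param path Path to a CSV file.
#' @param rm Region map (default [region_map()]); its region names define the
#'   expected rank columns.
#' @return An `os_observations` tibble.
#' @seealso [write_observations()], [packaged_fixture()]
#' @export
read_observations <- function(path, rm = region_map()) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  need <- c("index", "species", "condition", "category", "dynamic",
            "n_categories", rank_cols(rm))
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("missing column(s) in ", path, ": ", paste(missing, collapse = ", "),
         call. = FALSE)
  df$index <- as.integer(df$index)
  df$dynamic <- as.logical(df$dynamic)
  df$n_categories <- as.integer(df$n_categories)
  for (cc in rank_cols(rm)) {
    v <- df[[cc]]
    v[v == ""] <- NA
    df[[cc]] <- as.integer(v)
  }
  validate_observations(df, rm, file = path)
  new_observations(df[need], rm)
}

#' Write an ordinal observation table to CSV
#'
#' Inverse of [read_observations()]; masked regions are written as empty
#' cells so that a read/write round trip reproduces the table field for
#' field.
#'
#' @param obs An `os_observations` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_observations <- function(obs, path) {
  df <- as.data.frame(obs)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Region map attached to an observation set
#' @param obs An `os_observations` tibble.
#' @return The `os_region_map`.
#' @export
obs_region_map <- function(obs) attr(obs, "region_map")

#' Per-cell ranks of one observation
#'
#' Expands the per-region ranks of observation row `i` to the germline cells,
#' `NA` for masked regions.
#'
#' @param obs An `os_observations` tibble.
#' @param i Row number.
#' @return Integer vector of length `n_cells_germline`.
#' @keywords internal
obs_cell_ranks <- function(obs, i) {
  rm <- obs_region_map(obs)
  out <- rep(NA_integer_, rm$n_cells_germline)
  for (nm in rm$region_names) {
    out[rm$regions[[nm]]] <- obs[[paste0("rank_", nm)]][i]
  }
  out
}

#' Build an observation set from per-row values
#'
#' Convenience constructor used by the fixture and the synthetic generator.
#'
#' @param rows A data frame with the dialect columns.
#' @param rm Region map.
#' @return An `os_observations` tibble.
#' @export
as_observations <- function(rows, rm = region_map()) {
  validate_observations(rows, rm)
  new_observations(rows, rm)
}
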