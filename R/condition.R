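#' Genetic conditions (perturbations)
#'
#' A genetic condition is a set of per-species perturbations drawn from the
#' kinds used in germline genetics: `null` (homozygous loss, production set to
#' zero), `heterozygous` (production halved), `doubled` (doubled genomic
#' content, production doubled, written `2x`), and `overexpress` (ectopic
#' uniform production on top of the endogenous gene).  An empty set is Wild
#' Type.  The single allowed combination on one species is `null` +
#' `overexpress` (a knockout rescued by ectopic expression).
#'
#' @param ... Perturbations given as `species = kind` pairs, e.g.
#'   `genetic_condition(Nos = "null", Dpp = "heterozygous")`.  No arguments
#'   gives Wild Type.
#' @return An object of class `os_condition`: a data frame with columns
#'   `species` and `kind`.
#' @examples
#' genetic_condition()                      # wild type
#' genetic_condition(Bam = "null")
#' genetic_condition(Brat = "doubled", Bam = "null")
#' @export
genetic_condition <- function(...) {
  kinds <- c(...)
  if (length(kinds) == 0L) {
    df <- data.frame(species = character(), kind = character(),
                     stringsAsFactors = FALSE)
    return(structure(df, class = c("os_condition", "data.frame")))
  }
  species <- names(kinds)
  if (is.null(species) || any(species == ""))
    stop("perturbations must be named by species", call. = FALSE)
  kind_levels <- c("null", "heterozygous", "doubled", "overexpress")
  bad <- setdiff(kinds, kind_levels)
  if (length(bad))
    stop("unknown perturbation kind(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  df <- data.frame(species = species, kind = unname(kinds),
                   stringsAsFactors = FALSE)
  # at most one perturbation per species, except the null+overexpress rescue
  for (sp in unique(df$species)) {
    k <- sort(df$kind[df$species == sp])
    if (length(k) > 1L && !identical(k, c("null", "overexpress")))
      stop("species ", sp, " carries conflicting perturbations", call. = FALSE)
  }
  df <- df[order(df$species, df$kind), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, class = c("os_condition", "data.frame"))
}

#' @export
print.os_condition <- function(x, ...) {
  cat("<os_condition>", condition_label(x), "\n")
  invisible(x)
}

is_wild_type <- function(cond) nrow(cond) == 0L

#' Canonical text label for a genetic condition
#'
#' Deterministic (species-alphabetical) labels using the field's shorthand:
#' `Nos-/-` for null, `Dpp+/-` for heterozygous, `2xBrat` for doubled genomic
#' content, `dMycOE` for overexpression, and `WT` for the empty set.
#'
#' @param cond An `os_condition`.
#' @return A single string.
#' @examples
#' condition_label(genetic_condition())                  # "WT"
#' condition_label(genetic_condition(Nos = "null"))      # "Nos-/-"
#' @export
condition_label <- function(cond) {
  if (is_wild_type(cond)) return("WT")
  suffix <- c(null = "-/-", heterozygous = "+/-", overexpress = "OE")
  parts <- vapply(seq_len(nrow(cond)), function(i) {
    sp <- cond$species[i]; k <- cond$kind[i]
    if (k == "doubled") paste0("2x", sp) else paste0(sp, suffix[[k]])
  }, character(1))
  paste(parts, collapse = " ")
}

#' Parse a condition label back into a genetic condition
#'
#' Inverse of [condition_label()]: accepts space-separated tokens of the form
#' `Species-/-`, `Species+/-`, `2xSpecies`, `SpeciesOE`, or the literal `WT`.
#'
#' @param label A single string.
#' @return An `os_condition`.
#' @export
parse_condition <- function(label) {
  label <- trimws(label)
  if (label == "" || toupper(label) == "WT") return(genetic_condition())
  toks <- strsplit(label, "[ ,]+")[[1]]
  kinds <- character(0)
  for (tk in toks) {
    if (grepl("-/-$", tk)) {
      sp <- sub("-/-$", "", tk); k <- "null"
    } else if (grepl("\\+/-$", tk)) {
      sp <- sub("\\+/-$", "", tk); k <- "heterozygous"
    } else if (grepl("^2x", tk)) {
      sp <- sub("^2x", "", tk); k <- "doubled"
    } else if (grepl("OE$", tk)) {
      sp <- sub("OE$", "", tk); k <- "overexpress"
    } else {
      stop("cannot parse condition token: ", tk, call. = FALSE)
    }
    kinds <- c(kinds, stats::setNames(k, sp))
  }
  do.call(genetic_condition, as.list(kinds))
}
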