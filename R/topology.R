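#' Regulatory network topologies
#'
#' A topology lists the intracellular species and the signed regulatory edges
#' among them.  Edges are repressive (`sign = "repress"`) or activating
#' (`sign = "activate"`); each contributes one Hill factor (coefficient 2) to
#' the target's production term.  Edges targeting `pMad` act on Mad
#' phosphorylation (multiplying the signaling-driven production).
#'
#' @param species Character vector of intracellular species names.
#' @param edges Data frame with columns `from`, `to`, `sign`.
#' @param name Topology name.
#' @return An object of class `os_topology`.
#' @export
network_topology <- function(species, edges, name = "custom") {
  if (is.null(edges) || nrow(edges) == 0L) {
    edges <- data.frame(from = character(), to = character(),
                        sign = character(), stringsAsFactors = FALSE)
  }
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  stopifnot(all(c("from", "to", "sign") %in% names(edges)))
  bad <- setdiff(c(edges$from, edges$to), species)
  if (length(bad))
    stop("edge species not in species list: ",
         paste(unique(bad), collapse = ", "), call. = FALSE)
  if (any(!edges$sign %in% c("repress", "activate")))
    stop("edge sign must be 'repress' or 'activate'", call. = FALSE)
  if (any(edges$from == edges$to))
    stop("self-edges are not allowed", call. = FALSE)
  if (anyDuplicated(edges[c("from", "to")]))
    stop("duplicate edges", call. = FALSE)
  rownames(edges) <- NULL
  structure(list(name = name, species = species, edges = edges),
            class = "os_topology")
}

#' @export
print.os_topology <- function(x, ...) {
  cat("<os_topology>", x$name, "-", length(x$species), "species,",
      nrow(x$edges), "edges\n")
  if (nrow(x$edges)) {
    sym <- ifelse(x$edges$sign == "repress", " -| ", " -> ")
    cat(paste0("  ", x$edges$from, sym, x$edges$to), sep = "\n")
  }
  invisible(x)
}

#' The consensus Core germarium network
#'
#' A chain of repressors pMad -| Bam -| Nos -| Brat, closed by feedback of
#' Brat on Mad (phosphorylation).  dMyc is carried as an unconnected species
#' so that perturbation/measurement conditions involving it are simulatable
#' in every network.
#'
#' @return An `os_topology`.
#' @export
core_topology <- function() {
  network_topology(
    species = c("pMad", "Bam", "Nos", "Brat", "dMyc"),
    edges = data.frame(
      from = c("pMad", "Bam", "Nos", "Brat"),
      to   = c("Bam",  "Nos", "Brat", "pMad"),
      sign = "repress", stringsAsFactors = FALSE),
    name = "Core")
}

#' The Alt1 network: Core without Brat feedback on Mad
#'
#' Identical to [core_topology()] except that the Brat -| pMad feedback edge
#' is absent; the two differ in no other way, so comparing them isolates the
#' support the data give to the feedback element.
#'
#' @return An `os_topology`.
#' @export
alt1_topology <- function() {
  topo <- core_topology()
  keep <- !(topo$edges$from == "Brat" & topo$edges$to == "pMad")
  network_topology(topo$species, topo$edges[keep, ], name = "Alt1")
}

#' Drop an edge from a topology
#' @param topo An `os_topology`.
#' @param from,to Edge to remove.
#' @param name Name for the reduced topology.
#' @return An `os_topology`.
#' @export
drop_edge <- function(topo, from, to, name = paste0(topo$name, "-")) {
  keep <- !(topo$edges$from == from & topo$edges$to == to)
  if (all(keep)) stop("edge not present", call. = FALSE)
  network_topology(topo$species, topo$edges[keep, ], name = name)
}

#' Read / write topology JSON
#'
#' Format: `{"name": ..., "species": [...], "edges": [{"from","to","sign"}]}`.
#'
#' @param path File path.
#' @return `read_topology()` returns an `os_topology`; `write_topology()`
#'   returns `path` invisibly.
#' @export
read_topology <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  edges <- if (is.null(x$edges) || length(x$edges) == 0L) NULL else
    as.data.frame(x$edges, stringsAsFactors = FALSE)
  network_topology(x$species, edges, name = x$name %||% "unnamed")
}

#' @rdname read_topology
#' @param topo An `os_topology`.
#' @export
write_topology <- function(topo, path) {
  jsonlite::write_json(list(name = topo$name, species = topo$species,
                            edges = topo$edges),
                       path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
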