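#' Region ontologies
#'
#' A `region_ontology` is the hierarchical tree of brain regions used to
#' aggregate cell counts: each node has a positive integer `id`, a short
#' `acronym`, a `name`, and a `parent_id` (`NA` for the single root). Both
#' dialects of the Allen structure graph are accepted: a nested tree where
#' each node carries a `children` list, and a flat record list where each
#' node carries `parent_structure_id` / `parent_id`.
#'
#' @name region_ontology
NULL

#' Build a region ontology from a node table
#'
#' @param nodes data.frame with columns `id`, `acronym`, `name`, `parent_id`
#'   (`NA` for the root).
#' @return A `region_ontology`: the validated node table plus index lookups.
#' @export
region_ontology <- function(nodes) {
  nodes <- as.data.frame(nodes, stringsAsFactors = FALSE)
  req <- c("id", "acronym", "name", "parent_id")
  if (!all(req %in% names(nodes)))
    stop("ontology nodes need columns: ", paste(req, collapse = ", "))
  nodes$id <- as.integer(nodes$id)
  nodes$parent_id <- as.integer(nodes$parent_id)
  if (any(is.na(nodes$id)) || any(nodes$id <= 0L))
    stop("region ids must be positive integers")
  if (anyDuplicated(nodes$id))
    stop("duplicate region id: ",
         paste(unique(nodes$id[duplicated(nodes$id)]), collapse = ", "))
  if (anyDuplicated(nodes$acronym))
    stop("duplicate region acronym: ",
         paste(unique(nodes$acronym[duplicated(nodes$acronym)]), collapse = ", "))
  roots <- nodes$id[is.na(nodes$parent_id)]
  if (length(roots) != 1L)
    stop("ontology must have exactly one root, found ", length(roots))
  known <- c(NA_integer_, nodes$id)
  if (!all(nodes$parent_id %in% known))
    stop("parent_id refers to unknown node: ",
         paste(setdiff(nodes$parent_id, known), collapse = ", "))
  # cycle check / topological depth by walking to the root
  depth <- rep(NA_integer_, nrow(nodes))
  idx_of <- stats::setNames(seq_len(nrow(nodes)), nodes$id)
  for (r in seq_len(nrow(nodes))) {
    seen <- integer(0)
    cur <- r
    hops <- 0L
    while (!is.na(nodes$parent_id[cur])) {
      if (nodes$id[cur] %in% seen) stop("ontology parent links contain a cycle")
      seen <- c(seen, nodes$id[cur])
      cur <- idx_of[[as.character(nodes$parent_id[cur])]]
      hops <- hops + 1L
      if (hops > nrow(nodes)) stop("ontology parent links contain a cycle")
    }
    depth[r] <- hops
  }
  nodes$depth <- depth
  structure(list(nodes = nodes, root_id = roots,
                 by_id = idx_of,
                 by_acronym = stats::setNames(nodes$id, nodes$acronym)),
            class = "region_ontology")
}

#' @export
print.region_ontology <- function(x, ...) {
  cat(sprintf("<region_ontology> %d regions, root id %d ('%s'), max depth %d\n",
              nrow(x$nodes), x$root_id,
              x$nodes$acronym[x$by_id[[as.character(x$root_id)]]],
              max(x$nodes$depth)))
  invisible(x)
}

#' Read a region ontology from JSON
#'
#' Accepts the nested Allen structure-graph form (possibly wrapped in a
#' `msg` envelope), where each node lists its `children`, and the flat form:
#' an array of records each carrying its parent id. The two forms of the same
#' tree parse to identical ontologies.
#'
#' @param path JSON file.
#' @return A [region_ontology()].
#' @export
read_ontology <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!is.null(doc$msg)) doc <- doc$msg
  # single nested root object may arrive bare or as a 1-element list
  recs <- list()
  grab <- function(node, inherited_parent = NULL) {
    pid <- node$parent_structure_id
    if (is.null(pid)) pid <- node$parent_id
    # nested dialect: parent comes from the enclosing node, not the record
    if (is.null(pid)) pid <- inherited_parent
    recs[[length(recs) + 1L]] <<- data.frame(
      id = as.integer(node$id),
      acronym = as.character(node$acronym),
      name = as.character(if (is.null(node$name)) node$acronym else node$name),
      parent_id = if (is.null(pid) || is.na(suppressWarnings(as.integer(pid))))
        NA_integer_ else as.integer(pid),
      stringsAsFactors = FALSE)
    for (ch in node$children) grab(ch, node$id)
  }
  if (!is.null(doc$id)) grab(doc) else for (node in doc) grab(node)
  nodes <- do.call(rbind, recs)
  region_ontology(nodes)
}

#' Write a region ontology to JSON (flat records)
#' @param ontology a [region_ontology()].
#' @param path output JSON file.
#' @return `path`, invisibly.
#' @export
write_ontology <- function(ontology, path) {
  nodes <- ontology$nodes[, c("id", "acronym", "name", "parent_id")]
  jsonlite::write_json(nodes, path, dataframe = "rows", na = "null",
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' All descendant ids of a region
#'
#' @param ontology a [region_ontology()].
#' @param id region id (or acronym).
#' @param include_self include `id` itself? Default `FALSE`.
#' @return Integer vector of descendant ids.
#' @export
descendants <- function(ontology, id, include_self = FALSE) {
  id <- resolve_region_id(ontology, id)
  kids_of <- split(ontology$nodes$id, factor(ontology$nodes$parent_id,
                                             levels = ontology$nodes$id))
  out <- integer(0)
  frontier <- id
  while (length(frontier) > 0L) {
    nxt <- unlist(kids_of[as.character(frontier)], use.names = FALSE)
    nxt <- nxt[!is.na(nxt)]
    out <- c(out, nxt)
    frontier <- nxt
  }
  if (include_self) out <- c(id, out)
  sort(unique(out))
}

#' Ancestor chain of a region (nearest first, root last)
#' @inheritParams descendants
#' @return Integer vector of ancestor ids.
#' @export
ancestors <- function(ontology, id) {
  id <- resolve_region_id(ontology, id)
  out <- integer(0)
  cur <- id
  repeat {
    p <- ontology$nodes$parent_id[ontology$by_id[[as.character(cur)]]]
    if (is.na(p)) break
    out <- c(out, p)
    cur <- p
  }
  out
}

resolve_region_id <- function(ontology, id) {
  if (is.character(id)) {
    if (!id %in% names(ontology$by_acronym)) stop("unknown region acronym: ", id)
    return(unname(ontology$by_acronym[[id]]))
  }
  id <- as.integer(id)
  if (!id %in% ontology$nodes$id) stop("unknown region id: ", id)
  id
}

#' Check that every label used in an annotation volume exists in the ontology
#'
#' @param annotation [voxel_grid()] of non-negative integer labels
#'   (0 = background).
#' @param ontology a [region_ontology()].
#' @return `TRUE` invisibly; errors listing unknown labels otherwise.
#' @export
validate_annotation <- function(annotation, ontology) {
  stopifnot(is_voxel_grid(annotation))
  labs <- sort(unique(as.vector(annotation$values)))
  labs <- labs[labs != 0]
  if (any(labs < 0)) stop("annotation labels must be non-negative")
  unknown <- setdiff(labs, ontology$nodes$id)
  if (length(unknown) > 0L)
    stop("annotation labels missing from ontology: ",
         paste(unknown, collapse = ", "))
  invisible(TRUE)
}
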