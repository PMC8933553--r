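#' Create an empty knowledge graph under a schema
#'
#' A `trial_kg` holds one attribute table per node type (first column
#' `node_id`, remaining columns free-form character attributes) and one edge
#' table per relation type (`head_id`, `tail_id`). All attribute values are
#' stored as text; empty strings are normalized to `NA`.
#'
#' @param schema A `trial_schema`; defaults to [trial_schema()].
#' @return An object of class `trial_kg`.
#' @export
kg_new <- function(schema = trial_schema()) {
  stopifnot(inherits(schema, "trial_schema"))
  nodes <- lapply(schema$node_types$node_type, function(t)
    data.table::data.table(node_id = character(0)))
  names(nodes) <- schema$node_types$node_type
  edges <- lapply(schema$relations$relation, function(r)
    data.table::data.table(head_id = character(0), tail_id = character(0)))
  names(edges) <- schema$relations$relation
  structure(list(schema = schema, nodes = nodes, edges = edges),
            class = "trial_kg")
}

#' Add nodes or edges to a knowledge graph
#'
#' `kg_add_nodes()` appends rows to the attribute table of one node type;
#' `kg_add_edges()` appends endpoint pairs to one relation. Both are cheap
#' plumbing: structural rules (referential integrity, cardinality) are checked
#' by [validate_graph()], not at insertion time, so a graph can be assembled
#' in any order.
#'
#' @param kg A `trial_kg`.
#' @param node_type,relation Schema type name.
#' @param nodes A data.frame with a `node_id` column plus attribute columns.
#' @param head_id,tail_id Character vectors of endpoint node ids (recycled to
#'   common length).
#' @param attrs Optional data.frame of edge attribute columns (e.g. per-group
#'   affected counts on event-group/adverse-event edges), stored as text.
#' @return The modified `trial_kg`.
#' @export
kg_add_nodes <- function(kg, node_type, nodes) {
  stopifnot(inherits(kg, "trial_kg"))
  if (!node_type %in% names(kg$nodes))
    stop("unknown node type: ", node_type, call. = FALSE)
  nodes <- as_chr_dt(nodes)
  if (!"node_id" %in% names(nodes))
    stop("nodes table must have a node_id column", call. = FALSE)
  data.table::setcolorder(nodes, "node_id")
  kg$nodes[[node_type]] <- data.table::rbindlist(
    list(kg$nodes[[node_type]], nodes), use.names = TRUE, fill = TRUE)
  kg
}

#' @rdname kg_add_nodes
#' @export
kg_add_edges <- function(kg, relation, head_id, tail_id, attrs = NULL) {
  stopifnot(inherits(kg, "trial_kg"))
  if (!relation %in% names(kg$edges))
    stop("unknown relation type: ", relation, call. = FALSE)
  if (length(head_id) == 0L && length(tail_id) == 0L) return(kg)
  add <- data.table::data.table(head_id = as.character(head_id),
                                tail_id = as.character(tail_id))
  if (!is.null(attrs) && ncol(attrs)) add <- cbind(add, as_chr_dt(attrs))
  kg$edges[[relation]] <- data.table::rbindlist(
    list(kg$edges[[relation]], add), use.names = TRUE, fill = TRUE)
  kg
}

# id -> type lookup over all node tables
kg_node_index <- function(kg) {
  data.table::rbindlist(lapply(names(kg$nodes), function(t)
    data.table::data.table(node_id = kg$nodes[[t]]$node_id, node_type = t)))
}

#' Validate a knowledge graph against its schema
#'
#' Checks every structural invariant and returns the violations as a table
#' (empty table = valid graph). Violations are reported, never raised. Rules:
#' \itemize{
#'   \item `duplicate_id`: a node id occurs more than once;
#'   \item `missing_owner`: a node of a study-specific type lacks a non-missing
#'     `nct_id` attribute;
#'   \item `dangling_endpoint`: an edge references a non-existent node id;
#'   \item `endpoint_type`: an edge endpoint exists but has the wrong type;
#'   \item `cardinality`: a node carries a number of edges incompatible with
#'     the relation's declared cardinality class (e.g. an event group with two
#'     study edges, an adverse event without an organ edge).
#' }
#'
#' @param kg A `trial_kg`.
#' @return A data.table with columns `rule`, `where` (relation or node type),
#'   `id` (offending node id, or `NA`), `message`.
#' @export
validate_graph <- function(kg) {
  stopifnot(inherits(kg, "trial_kg"))
  out <- list()
  emit <- function(rule, where, id, message)
    out[[length(out) + 1L]] <<- data.table::data.table(
      rule = rule, where = where, id = id, message = message)

  idx <- kg_node_index(kg)
  if (nrow(idx)) {
    dup <- idx$node_id[duplicated(idx$node_id)]
    for (d in unique(dup))
      emit("duplicate_id", "nodes", d, "node id occurs more than once")
  }

  specific <- kg$schema$node_types[kg$schema$node_types$study_specific == TRUE,
                                   ][["node_type"]]
  for (t in specific) {
    tab <- kg$nodes[[t]]
    if (!nrow(tab)) next
    if (!"nct_id" %in% names(tab)) {
      for (id in tab$node_id)
        emit("missing_owner", t, id, "study-specific node lacks nct_id attribute")
    } else {
      bad <- tab$node_id[is.na(tab$nct_id)]
      for (id in bad)
        emit("missing_owner", t, id, "study-specific node lacks nct_id attribute")
    }
  }

  type_of <- idx$node_type
  names(type_of) <- idx$node_id
  for (i in seq_len(nrow(kg$schema$relations))) {
    r <- kg$schema$relations[i, ]
    ed <- kg$edges[[r$relation]]
    if (nrow(ed)) {
      for (side in c("head", "tail")) {
        ids <- if (side == "head") ed$head_id else ed$tail_id
        want <- if (side == "head") r$head_type else r$tail_type
        have <- type_of[ids]
        dangle <- unique(ids[is.na(have)])
        for (id in dangle)
          emit("dangling_endpoint", r$relation, id,
               sprintf("%s endpoint does not exist", side))
        wrong <- unique(ids[!is.na(have) & have != want])
        for (id in wrong)
          emit("endpoint_type", r$relation, id,
               sprintf("%s endpoint has type %s, expected %s",
                       side, type_of[[id]], want))
      }
    }
    # cardinality over *all* nodes of the constrained type (zero edges counts)
    for (side in c("head", "tail")) {
      card <- if (side == "head") r$head_card else r$tail_card
      if (card == "many") next
      typ <- if (side == "head") r$head_type else r$tail_type
      all_ids <- kg$nodes[[typ]]$node_id
      if (!length(all_ids)) next
      ids <- if (side == "head") ed$head_id else ed$tail_id
      cnt <- table(factor(ids, levels = all_ids))
      if (card == "one") bad <- names(cnt)[cnt != 1L]
      else bad <- names(cnt)[cnt > 1L]  # at_most_one
      for (id in bad)
        emit("cardinality", r$relation, id,
             sprintf("%s node has %d %s edges, cardinality class '%s'",
                     typ, as.integer(cnt[[id]]), r$relation, card))
    }
  }

  if (!length(out))
    return(data.table::data.table(rule = character(0), where = character(0),
                                  id = character(0), message = character(0)))
  data.table::rbindlist(out)
}

#' Node and relation statistics of a knowledge graph
#'
#' Mirrors the published statistics layout: per node type the node count; per
#' relation type the number of unique head nodes participating, unique tail
#' nodes participating, and edges.
#'
#' @param kg A `trial_kg`.
#' @return A list of two data.tables: `nodes` (`node_type`, `n_nodes`) and
#'   `relations` (`relation`, `head_type`, `n_head`, `tail_type`, `n_tail`,
#'   `n_edges`).
#' @export
graph_statistics <- function(kg) {
  stopifnot(inherits(kg, "trial_kg"))
  nodes <- data.table::data.table(
    node_type = names(kg$nodes),
    n_nodes = vapply(kg$nodes, nrow, integer(1)))
  rel <- kg$schema$relations
  relations <- data.table::data.table(
    relation = rel$relation,
    head_type = rel$head_type,
    n_head = vapply(rel$relation, function(r)
      length(unique(kg$edges[[r]]$head_id)), integer(1)),
    tail_type = rel$tail_type,
    n_tail = vapply(rel$relation, function(r)
      length(unique(kg$edges[[r]]$tail_id)), integer(1)),
    n_edges = vapply(rel$relation, function(r)
      nrow(kg$edges[[r]]), integer(1)))
  list(nodes = nodes, relations = relations)
}

#' Export and import a knowledge graph as tab-separated tables
#'
#' Writes one UTF-8 TSV per node type (`nodes_<Type>.tsv`: `node_id` plus
#' attribute columns) and one per relation type (`edges_<Relation>.tsv`:
#' `head_id`, `relation`, `tail_id`), plus the schema as `schema.json`. Values
#' containing the delimiter are quoted. Missing attribute values are written
#' as empty fields and read back as `NA`, so `import_graph(export_graph(kg))`
#' is the identity on graphs whose attributes carry no empty-string values
#' (the container normalizes those to `NA` on insertion).
#'
#' @param kg A `trial_kg`.
#' @param out_dir Directory to write into (created if absent).
#' @return `export_graph()` returns `out_dir` invisibly; `import_graph()`
#'   returns a `trial_kg`.
#' @export
export_graph <- function(kg, out_dir) {
  stopifnot(inherits(kg, "trial_kg"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir))
    stop("cannot create output directory: ", out_dir, call. = FALSE)
  write_schema(kg$schema, file.path(out_dir, "schema.json"))
  # write.table with doubled quotes: the one TSV dialect that round-trips
  # embedded delimiters, quotes and newlines through read.delim
  put <- function(tab, file)
    utils::write.table(tab, file, sep = "\t", quote = TRUE,
                       qmethod = "double", row.names = FALSE, na = "",
                       fileEncoding = "UTF-8")
  for (t in names(kg$nodes))
    put(kg$nodes[[t]], file.path(out_dir, paste0("nodes_", t, ".tsv")))
  for (r in names(kg$edges)) {
    ed <- data.table::copy(kg$edges[[r]])
    ed[, relation := r]
    data.table::setcolorder(ed, c("head_id", "relation", "tail_id"))
    put(ed, file.path(out_dir, paste0("edges_", r, ".tsv")))
  }
  invisible(out_dir)
}

#' @rdname export_graph
#' @param dir Directory previously written by `export_graph()`.
#' @param schema Optional `trial_schema`; by default read from `schema.json`
#'   in `dir`.
#' @export
import_graph <- function(dir, schema = NULL) {
  if (is.null(schema)) schema <- read_schema(file.path(dir, "schema.json"))
  kg <- kg_new(schema)
  get <- function(f)
    data.table::as.data.table(utils::read.delim(
      f, sep = "\t", colClasses = "character", na.strings = "",
      check.names = FALSE, fileEncoding = "UTF-8"))
  for (t in names(kg$nodes)) {
    f <- file.path(dir, paste0("nodes_", t, ".tsv"))
    if (!file.exists(f)) next
    tab <- get(f)
    if (nrow(tab)) kg <- kg_add_nodes(kg, t, tab)
    else if (ncol(tab) > 1L)  # keep attribute headers of empty tables
      kg$nodes[[t]] <- tab
  }
  for (r in names(kg$edges)) {
    f <- file.path(dir, paste0("edges_", r, ".tsv"))
    if (!file.exists(f)) next
    ed <- get(f)
    if (nrow(ed)) {
      attrs <- ed[, setdiff(names(ed), c("head_id", "relation", "tail_id")),
                  with = FALSE]
      kg <- kg_add_edges(kg, r, ed$head_id, ed$tail_id,
                         attrs = if (ncol(attrs)) attrs)
    }
  }
  kg
}

#' @export
print.trial_kg <- function(x, ...) {
  st <- graph_statistics(x)
  cat(sprintf("<trial_kg> %d nodes (%d types), %d edges (%d relations)\n",
              sum(st$nodes$n_nodes), sum(st$nodes$n_nodes > 0),
              sum(st$relations$n_edges), sum(st$relations$n_edges > 0)))
  invisible(x)
}
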