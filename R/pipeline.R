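#' Run the full construction pipeline
#'
#' Chains the stages end to end: read the trial tables, filter studies,
#' normalize and assemble the knowledge graph, validate it against the
#' schema, export it as per-type tables, and (optionally) train TransE
#' embeddings. A run manifest (`run_manifest.json`: package version, seed,
#' per-stage filter counts, node and edge totals) is written alongside the
#' export for provenance. The run is deterministic given the seed.
#'
#' @param tables_dir Directory of input `.tsv` tables
#'   (see [read_trial_tables()]).
#' @param dict_file Adverse-event hierarchy file (see [term_hierarchy()]).
#' @param lexicon_file Drug lexicon file (see [drug_lexicon()]).
#' @param out_dir Output directory for the exported graph.
#' @param abbrev_file Optional drug abbreviation file.
#' @param clusters Outcome cluster count (`NULL` = min(200, outcomes)).
#' @param seed Integer seed for clustering and embedding.
#' @param embed Train embeddings after export? Default `FALSE`.
#' @param embed_config A [train_config()] used when `embed = TRUE` (its seed
#'   is overridden by `seed`).
#' @param config An [assemble_config()]; its `clusters`/`seed` are overridden
#'   by the arguments above.
#' @return Invisibly, a list: `kg`, `filter`, `violations` (always empty on
#'   success), and `embedding` (`NULL` unless `embed`).
#' @export
run_pipeline <- function(tables_dir, dict_file, lexicon_file, out_dir,
                         abbrev_file = NULL, clusters = NULL, seed = 1L,
                         embed = FALSE, embed_config = train_config(),
                         config = assemble_config()) {
  for (p in c(tables_dir, dict_file, lexicon_file, abbrev_file))
    if (!file.exists(p)) stop("input path not found: ", p, call. = FALSE)

  tables <- read_trial_tables(tables_dir)
  dict <- term_hierarchy(file = dict_file)
  lex <- drug_lexicon(file = lexicon_file, abbrev_file = abbrev_file)

  config$clusters <- clusters
  config$seed <- as.integer(seed)
  kg <- assemble(tables, dict, lex, config)

  viol <- validate_graph(kg)
  if (nrow(viol))
    stop("assembled graph violates its schema (", nrow(viol),
         " violation(s)); first: ", viol$message[1], call. = FALSE)

  export_graph(kg, out_dir)
  st <- graph_statistics(kg)
  manifest <- list(
    package = "trialgraph",
    version = as.character(utils::packageVersion("trialgraph")),
    seed = as.integer(seed),
    studies_in = kg$meta$filter$n_input,
    excluded = as.list(kg$meta$filter$excluded),
    studies_kept = length(kg$meta$filter$kept),
    nodes = sum(st$nodes$n_nodes),
    edges = sum(st$relations$n_edges))
  jsonlite::write_json(manifest, file.path(out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  emb <- NULL
  if (embed) {
    embed_config$seed <- as.integer(seed)
    emb <- train_transe(kg, embed_config)
    write_embeddings(emb, file.path(out_dir, "embeddings.tsv"))
  }
  invisible(list(kg = kg, filter = kg$meta$filter, violations = viol,
                 embedding = emb))
}

#' Write or read an embedding table as a delimited matrix
#'
#' One row per entity or relation: `id`, `kind` (entity/relation), then the
#' `dim` vector components.
#'
#' @param emb An `embedding_table`.
#' @param file Path of the TSV file.
#' @export
write_embeddings <- function(emb, file) {
  stopifnot(inherits(emb, "embedding_table"))
  mat <- rbind(emb$entities, emb$relations)
  out <- data.table::data.table(
    id = c(rownames(emb$entities), rownames(emb$relations)),
    kind = c(rep("entity", nrow(emb$entities)),
             rep("relation", nrow(emb$relations))))
  out <- cbind(out, data.table::as.data.table(mat))
  data.table::fwrite(out, file, sep = "\t", quote = "auto")
  invisible(file)
}
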