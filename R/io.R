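# Plain-text readers/writers for the pipeline's tabular interchange formats.

PROFILE_HIT_COLS <- c("protein_id", "profile_id", "e_value", "bit_score",
                      "q_start", "q_end", "profile_len", "coverage")

OUTFMT6_COLS <- c("qseqid", "sseqid", "pident", "length", "mismatch",
                  "gapopen", "qstart", "qend", "sstart", "send",
                  "evalue", "bitscore")

#' Write / read the domtblout-like profile-hit table
#'
#' Tab-separated with a header row; columns `protein_id`, `profile_id`,
#' `e_value`, `bit_score`, `q_start`, `q_end` (1-based inclusive protein
#' coordinates), `profile_len`, `coverage` (fraction of the profile matched).
#'
#' @param hits data.frame of profile hits.
#' @param path file path.
#' @return `write_profile_hits_tsv`: the path, invisibly;
#'   `read_profile_hits_tsv`: the data.frame.
#' @export
write_profile_hits_tsv <- function(hits, path) {
  stopifnot(all(PROFILE_HIT_COLS %in% names(hits)))
  write.table(hits[, PROFILE_HIT_COLS, drop = FALSE], path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_profile_hits_tsv
#' @export
read_profile_hits_tsv <- function(path) {
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  stopifnot(all(PROFILE_HIT_COLS %in% names(df)))
  df
}

#' Empty profile-hit table with the canonical columns
#' @return zero-row data.frame.
#' @export
empty_profile_hits <- function() {
  data.frame(protein_id = character(), profile_id = character(),
             e_value = numeric(), bit_score = numeric(),
             q_start = integer(), q_end = integer(),
             profile_len = integer(), coverage = numeric(),
             stringsAsFactors = FALSE)
}

#' An empty synthetic dataset (for degenerate-case plumbing)
#' @return `synth_dataset` with zero records.
#' @export
empty_synth_dataset <- function() {
  structure(list(
    proteins = data.frame(protein_id = character(), species_key = character(),
                          strain_key = character(), taxon_group = character(),
                          sequence = character(), length = integer(),
                          stringsAsFactors = FALSE),
    profile_hits = empty_profile_hits(),
    features = data.frame(genome_id = character(), contig_id = character(),
                          feature_id = character(), start = integer(),
                          end = integer(), strand = character(),
                          product_id = character(),
                          product_profile = character(),
                          stringsAsFactors = FALSE),
    truth_labels = setNames(character(0), character(0)),
    truth_clusters = setNames(integer(0), character(0)),
    params = NULL
  ), class = "synth_dataset")
}

#' Write / read gene features as GFF3
#'
#' CDS features, 1-based inclusive coordinates, with `ID=`, `genome=` and
#' `product_profile=` (comma-separated) attributes. Reading uses
#' `rtracklayer::readGFF`.
#'
#' @param features data.frame with columns `genome_id`, `contig_id`,
#'   `feature_id`, `start`, `end`, `strand`, `product_id`,
#'   `product_profile`.
#' @param path file path.
#' @return `write_gff3`: the path invisibly; `read_gff3`: the data.frame.
#' @export
write_gff3 <- function(features, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  if (nrow(features) > 0L) {
    attrs <- sprintf("ID=%s;genome=%s;product_id=%s;product_profile=%s",
                     features$feature_id, features$genome_id,
                     features$product_id, features$product_profile)
    lines <- paste(features$contig_id, "lhrfam", "CDS",
                   features$start, features$end, ".", features$strand, "0",
                   attrs, sep = "\t")
    writeLines(lines, con)
  }
  invisible(path)
}

#' @rdname write_gff3
#' @export
read_gff3 <- function(path) {
  g <- rtracklayer::readGFF(path)
  g <- as.data.frame(g, stringsAsFactors = FALSE)
  if (nrow(g) == 0L) return(empty_synth_dataset()$features)
  collapse <- function(x) {
    if (is.list(x)) vapply(x, paste, character(1), collapse = ",")
    else as.character(x)
  }
  out <- data.frame(
    genome_id = collapse(g$genome),
    contig_id = as.character(g$seqid),
    feature_id = collapse(g$ID),
    start = as.integer(g$start),
    end = as.integer(g$end),
    strand = as.character(g$strand),
    product_id = collapse(g$product_id),
    product_profile = collapse(g$product_profile),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Write / read pairwise hits in BLAST outfmt-6 layout
#'
#' The 12 standard columns (`qseqid sseqid pident length mismatch gapopen
#' qstart qend sstart send evalue bitscore`), tab-separated, no header —
#' the layout `blastp -outfmt 6` emits.
#'
#' @param hits data.frame of pairwise hits as returned by [all_vs_all()].
#' @param path file path.
#' @return `write_hits_tsv`: the path invisibly; `read_hits_tsv`: a
#'   data.frame with the internal column names used by the graph builder.
#' @export
write_hits_tsv <- function(hits, path) {
  out <- data.frame(
    qseqid = hits$query_id, sseqid = hits$subject_id,
    pident = sprintf("%.3f", hits$identity_pct), length = hits$aln_len,
    mismatch = hits$mismatch, gapopen = hits$gapopen,
    qstart = hits$q_start, qend = hits$q_end,
    sstart = hits$s_start, send = hits$s_end,
    evalue = format(hits$e_value, digits = 6, scientific = TRUE),
    bitscore = sprintf("%.1f", hits$bit_score),
    stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_hits_tsv
#' @export
read_hits_tsv <- function(path) {
  df <- read.delim(path, sep = "\t", header = FALSE,
                   stringsAsFactors = FALSE)
  names(df) <- OUTFMT6_COLS
  data.frame(
    query_id = df$qseqid, subject_id = df$sseqid,
    identity_pct = as.numeric(df$pident), aln_len = as.integer(df$length),
    mismatch = as.integer(df$mismatch), gapopen = as.integer(df$gapopen),
    q_start = as.integer(df$qstart), q_end = as.integer(df$qend),
    s_start = as.integer(df$sstart), s_end = as.integer(df$send),
    e_value = as.numeric(df$evalue), bit_score = as.numeric(df$bitscore),
    stringsAsFactors = FALSE)
}

#' Write a similarity graph as an edge-list TSV and in MCL ABC format
#'
#' The edge list carries `node_a`, `node_b`, `weight`, `identity_pct` with a
#' header; ABC format is the three-column headerless `node node weight`
#' dialect consumed by external MCL tooling.
#'
#' @param graph an igraph similarity graph (edge attributes `weight`,
#'   `identity_pct`).
#' @param path file path.
#' @return the path, invisibly.
#' @export
write_edgelist_tsv <- function(graph, path) {
  el <- igraph::as_edgelist(graph)
  df <- data.frame(node_a = el[, 1], node_b = el[, 2],
                   weight = igraph::E(graph)$weight,
                   identity_pct = igraph::E(graph)$identity_pct,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_edgelist_tsv
#' @export
write_abc <- function(graph, path) {
  el <- igraph::as_edgelist(graph)
  df <- data.frame(a = el[, 1], b = el[, 2],
                   w = igraph::E(graph)$weight, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read an edge-list TSV back into an igraph similarity graph
#' @param path edge-list TSV written by [write_edgelist_tsv()].
#' @param nodes optional character vector of node ids (to keep isolated
#'   nodes); defaults to the nodes present in the edge list.
#' @return igraph object with `weight` and `identity_pct` edge attributes.
#' @export
read_edgelist_tsv <- function(path, nodes = NULL) {
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  if (is.null(nodes)) nodes <- sort(unique(c(df$node_a, df$node_b)))
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, length(nodes), name = nodes)
  if (nrow(df) > 0L) {
    g <- igraph::add_edges(g, rbind(df$node_a, df$node_b),
                           weight = df$weight,
                           identity_pct = df$identity_pct)
  }
  g
}
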