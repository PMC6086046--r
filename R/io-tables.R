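#' Write and read the internal graph exchange format
#'
#' The class graph round-trips through two tab-separated files: an edge list
#' (`from`, `to`, `relation`) and a vertex table (`id`, `label`,
#' `definition`, `text`, `text_source`). Embedded tabs/newlines in text
#' fields are escaped as `\\t` / `\\n`.
#'
#' @param graph An `ontology_graph`.
#' @param edge_path,vertex_path Output/input file paths.
#' @return `write_ontology_graph()` returns the graph invisibly;
#'   `read_ontology_graph()` returns an `ontology_graph`.
#' @export
write_ontology_graph <- function(graph, edge_path, vertex_path) {
  stopifnot(inherits(graph, "ontology_graph"))
  esc <- function(x) {
    x[is.na(x)] <- ""
    gsub("\n", "\\\\n", gsub("\t", "\\\\t", gsub("\\\\", "\\\\\\\\", x)))
  }
  e <- graph$edges
  writeLines(c("from\tto\trelation",
               paste(esc(e$from), esc(e$to), esc(e$relation), sep = "\t")),
             edge_path)
  v <- graph$vertices
  writeLines(c("id\tlabel\tdefinition\ttext\ttext_source",
               paste(esc(v$id), esc(v$label), esc(v$definition),
                     esc(v$text), esc(v$text_source), sep = "\t")),
             vertex_path)
  invisible(graph)
}

#' @rdname write_ontology_graph
#' @export
read_ontology_graph <- function(edge_path, vertex_path) {
  unesc <- function(x) {
    x <- gsub("\\\\n", "\n", gsub("\\\\t", "\t", x))
    gsub("\\\\\\\\", "\\\\", x)
  }
  read_tsv0 <- function(path) {
    df <- utils::read.delim(path, sep = "\t", quote = "", colClasses = "character",
                            check.names = FALSE, na.strings = NULL)
    as_tibble(lapply(df, unesc))
  }
  v <- read_tsv0(vertex_path)
  e <- read_tsv0(edge_path)
  v$text[!nzchar(v$text)] <- NA_character_
  v$text_source[!nzchar(v$text_source)] <- NA_character_
  structure(list(vertices = v, edges = e), class = "ontology_graph")
}

#' Write a numeric matrix as dense tab-separated text
#'
#' First row is a header of vertex ids; each following row starts with the
#' row's vertex id. Infinite entries are written as `Inf`.
#'
#' @param m A numeric matrix with dimnames.
#' @param path Output path.
#' @export
write_matrix_tsv <- function(m, path) {
  ids <- rownames(m) %||% as.character(seq_len(nrow(m)))
  lines <- c(
    paste(c("id", colnames(m) %||% ids), collapse = "\t"),
    vapply(seq_len(nrow(m)), function(i) {
      paste(c(ids[i], format(m[i, ], digits = 12, trim = TRUE, scientific = FALSE)),
            collapse = "\t")
    }, character(1))
  )
  writeLines(lines, path)
  invisible(m)
}

#' Save or load embeddings in the word-vector text format
#'
#' The common text format for embedding tables: a first line `n dim`
#' followed by one `id v1 ... v_dim` line per vertex, whitespace-separated.
#'
#' @param emb A numeric matrix with one row per vertex; rownames are ids.
#' @param path File path.
#' @return `read_embeddings()` returns such a matrix.
#' @export
write_embeddings <- function(emb, path) {
  stopifnot(is.matrix(emb), !is.null(rownames(emb)))
  lines <- c(
    paste(nrow(emb), ncol(emb)),
    vapply(seq_len(nrow(emb)), function(i) {
      paste(c(rownames(emb)[i],
              format(emb[i, ], digits = 17, trim = TRUE, scientific = TRUE)),
            collapse = " ")
    }, character(1))
  )
  writeLines(lines, path)
  invisible(emb)
}

#' @rdname write_embeddings
#' @export
read_embeddings <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- as.integer(strsplit(trimws(lines[1]), "\\s+")[[1]])
  n <- hdr[1]; d <- hdr[2]
  out <- matrix(0, n, d)
  ids <- character(n)
  for (i in seq_len(n)) {
    parts <- strsplit(trimws(lines[i + 1L]), "\\s+")[[1]]
    ids[i] <- parts[1]
    out[i, ] <- as.numeric(parts[-1])
  }
  rownames(out) <- ids
  out
}

# flat key-value report file (key<TAB>value per line)
write_report_kv <- function(x, path) {
  vals <- vapply(x, function(v) paste(format(v, digits = 15, trim = TRUE),
                                      collapse = ","), character(1))
  writeLines(paste(names(x), vals, sep = "\t"), path)
  invisible(x)
}
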